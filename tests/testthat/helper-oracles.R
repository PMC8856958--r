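# Independent oracles used to validate the implementation paths.

# random DNA string, independent of the package's generator internals
rndDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# brute-force substring membership: does s occur in any transcript?
bruteHasSubstring <- function(s, transcripts) {
  any(vapply(transcripts, function(tx) grepl(s, tx, fixed = TRUE),
             logical(1)))
}

# naive longest-common-substring: enumerate every substring of the
# shorter string, longest first, and test membership in the other.
naiveLcs <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  for (len in seq(nchar(a), 1L)) {
    starts <- 1:(nchar(a) - len + 1L)
    subs <- unique(substring(a, starts, starts + len - 1L))
    if (any(vapply(subs, grepl, logical(1), x = b, fixed = TRUE)))
      return(len)
  }
  0L
}

# permutation oracle for the linear-by-linear trend test: two-sided
# mid-p from B random relabellings of the column scores. Margins are
# fixed under permutation, so comparing |S - n*mean(u)*mean(v)| is
# equivalent to comparing |r|. The statistic is integer-valued with
# substantial tie mass at small n, so ties count half (mid-p), which
# is what a continuous asymptotic approximation estimates.
permTrendP <- function(tab, u = seq_len(nrow(tab)),
                       v = seq_len(ncol(tab)), B = 1e4, seed = 1) {
  set.seed(seed)
  uv <- rep(u[as.vector(row(tab))], as.vector(tab))
  vv <- rep(v[as.vector(col(tab))], as.vector(tab))
  n <- length(uv)
  centre <- n * mean(uv) * mean(vv)
  obs <- abs(sum(uv * vv) - centre)
  above <- 0; ties <- 0
  for (b in seq_len(B)) {
    s <- abs(sum(uv * sample(vv)) - centre)
    if (s > obs + 1e-9) above <- above + 1
    else if (s > obs - 1e-9) ties <- ties + 1
  }
  (above + 0.5 * ties + 1) / (B + 1)
}

# small random null contingency table with non-degenerate margins
randomNullTable <- function(nr = 3L, nc = 4L, n = 60L) {
  repeat {
    pr <- as.vector(stats::rgamma(nr, 2)); pr <- pr / sum(pr)
    pc <- as.vector(stats::rgamma(nc, 2)); pc <- pc / sum(pc)
    tab <- matrix(stats::rmultinom(1, n, outer(pr, pc)), nr, nc)
    if (sum(rowSums(tab) > 0) >= 2 && sum(colSums(tab) > 0) >= 2)
      return(tab)
  }
}
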