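# Guide enumeration, ranking, filtering, and the 21 -> 22 nt mirE
# duplex transformation.

#' Design configuration for shRNAmir guide selection
#'
#' Holds the numeric rules of the design pipeline. The defaults encode
#' the published procedure: 21-nt siRNA candidates, 22-nt fully
#' overlapping mirE duplexes, rejection of any window with more than
#' 15 nt of contiguous complementarity to a non-target transcript
#' (screened with 16-mers: a shared 16-mer is exactly a >15 nt run),
#' three guides for the monocistronic mirE scaffold and four for the
#' polycistronic mir17-19b scaffold.
#'
#' @slot guideLength Length of the enumerated sense window (21).
#' @slot duplexLength Length of the mirE duplex (22 = guideLength + 1).
#' @slot maxOfftargetComplementarity Longest tolerated contiguous match
#'   to a non-target transcript, in nt (15).
#' @slot seedK K-mer length of the off-target screen; must equal
#'   `maxOfftargetComplementarity + 1`.
#' @slot nSelectMirE Guides taken for the mirE scaffold (3).
#' @slot nSelectPolycistron Guides taken for the mir17-19b scaffold (4).
#' @slot scorer Name of the ranking strategy (see [guideScorers]).
#' @export
setClass("DesignConfig",
  representation(guideLength = "integer", duplexLength = "integer",
                 maxOfftargetComplementarity = "integer",
                 seedK = "integer", nSelectMirE = "integer",
                 nSelectPolycistron = "integer", scorer = "character"),
  prototype(guideLength = 21L, duplexLength = 22L,
            maxOfftargetComplementarity = 15L, seedK = 16L,
            nSelectMirE = 3L, nSelectPolycistron = 4L,
            scorer = "default"),
  validity = function(object) {
    if (object@duplexLength != object@guideLength + 1L)
      return("duplexLength must equal guideLength + 1")
    if (object@seedK != object@maxOfftargetComplementarity + 1L)
      return("seedK must equal maxOfftargetComplementarity + 1")
    if (object@nSelectMirE < 1L || object@nSelectPolycistron < 1L)
      return("selection counts must be >= 1")
    TRUE
  })

#' Construct a DesignConfig
#'
#' @param maxOfftargetComplementarity,seedK Off-target rule; `seedK`
#'   defaults to the threshold plus one.
#' @param nSelectMirE,nSelectPolycistron Guides to select per scaffold.
#' @param scorer Ranking strategy name.
#' @return A [DesignConfig-class].
#' @export
designConfig <- function(maxOfftargetComplementarity = 15L,
                         seedK = maxOfftargetComplementarity + 1L,
                         nSelectMirE = 3L, nSelectPolycistron = 4L,
                         scorer = "default") {
  methods::new("DesignConfig",
               maxOfftargetComplementarity =
                 as.integer(maxOfftargetComplementarity),
               seedK = as.integer(seedK),
               nSelectMirE = as.integer(nSelectMirE),
               nSelectPolycistron = as.integer(nSelectPolycistron),
               scorer = scorer)
}

setMethod("show", "DesignConfig", function(object) {
  cat("DesignConfig: 21/22 nt, off-target >",
      object@maxOfftargetComplementarity, "nt (seed k =",
      object@seedK, "), select", object@nSelectMirE, "(mirE) /",
      object@nSelectPolycistron, "(polycistron), scorer:",
      object@scorer, "\n")
})

#' Enumerate 21-nt guide candidates on a target sequence
#'
#' One candidate per admissible window. Because the 22-nt duplex needs
#' two nucleotides of upstream target context, windows start at 0-based
#' position 2 at the earliest; the last window ends at the final base.
#' A target of length L therefore yields L - 22 candidates (starts
#' `2 .. L - 21`), in ascending start order.
#'
#' @param target A single named [Biostrings::DNAStringSet] element,
#'   [Biostrings::DNAString], or named character string (the reference
#'   isoform).
#' @param cfg A [DesignConfig-class].
#' @param maskAmbiguous If `TRUE`, windows whose 22-nt context contains
#'   N are silently skipped; if `FALSE` (default) ambiguity codes are an
#'   error.
#' @return A [S4Vectors::DataFrame] with columns `target_id`, `start`
#'   (0-based), `sense21`.
#' @export
enumerateCandidates <- function(target, cfg = designConfig(),
                                maskAmbiguous = FALSE) {
  if (methods::is(target, "DNAString"))
    target <- Biostrings::DNAStringSet(target)
  if (methods::is(target, "DNAStringSet")) {
    stopifnot(length(target) == 1L)
    target <- setNames(as.character(target), names(target))
  }
  id <- names(target)
  if (is.null(id) || !nzchar(id)) id <- "target"
  seq <- unname(target)
  .assertDna(seq, "target", allowAmbiguous = maskAmbiguous)
  L <- nchar(seq)
  gl <- cfg@guideLength
  empty <- S4Vectors::DataFrame(target_id = character(0),
                                start = integer(0),
                                sense21 = character(0))
  if (L < gl + 2L) {
    warning("target shorter than ", gl + 2L,
            " nt: no admissible windows")
    return(empty)
  }
  starts <- 2L:(L - gl)               # 0-based
  sense <- substring(seq, starts + 1L, starts + gl)
  if (maskAmbiguous) {
    ctx <- substring(seq, starts - 1L, starts + gl)  # 22-nt context
    ok <- !grepl("N", ctx, fixed = TRUE)
    starts <- starts[ok]; sense <- sense[ok]
  }
  S4Vectors::DataFrame(target_id = rep(id, length(starts)),
                       start = starts, sense21 = sense)
}

.gcFraction <- function(x) {
  (nchar(x) - nchar(gsub("[GC]", "", x))) / nchar(x)
}

#' Built-in guide scoring strategies
#'
#' Ranking of siRNA candidates is pluggable: the published designs were
#' ranked by the external DSIR webtool, whose regression model this
#' package does not reproduce. The `"default"` heuristic awards one
#' point for a GC fraction in \[0.30, 0.65\] plus a thermodynamic
#' asymmetry proxy: the AT fraction of the last four sense bases (the
#' guide's 5' end on the antisense strand) minus the AT fraction of the
#' first four, favouring duplexes whose guide 5' end is easier to
#' unwind. `"constant"` scores everything 0 (enumeration order wins).
#' External scores (e.g. pasted DSIR output) can be supplied directly to
#' [rankCandidates()] as a numeric vector.
#'
#' @format A named list of functions `character -> numeric`.
#' @export
guideScorers <- list(
  default = function(sense21) {
    gc <- .gcFraction(sense21)
    at <- function(s) 1 - .gcFraction(s)
    n <- nchar(sense21)
    asym <- at(substring(sense21, n - 3L, n)) -
      at(substring(sense21, 1L, 4L))
    as.numeric(gc >= 0.30 & gc <= 0.65) + asym
  },
  constant = function(sense21) rep(0, length(sense21))
)

#' Rank guide candidates
#'
#' Orders candidates by descending score; ties are broken by smaller
#' start, then lexicographic `sense21`, so the order is total and
#' deterministic.
#'
#' @param candidates Output of [enumerateCandidates()].
#' @param scorer A scorer name (see [guideScorers]), a function mapping
#'   a character vector of 21-mers to numeric scores, or a numeric
#'   vector of externally computed scores (one per candidate, e.g. DSIR
#'   output).
#' @return The candidates with a `score` column, ranked.
#' @export
rankCandidates <- function(candidates, scorer = "default") {
  score <- if (is.numeric(scorer)) {
    if (length(scorer) != nrow(candidates))
      stop("external score vector must have one score per candidate")
    as.numeric(scorer)
  } else {
    f <- if (is.function(scorer)) scorer else guideScorers[[scorer]]
    if (is.null(f)) stop("unknown scorer: ", scorer)
    f(candidates$sense21)
  }
  candidates$score <- score
  ord <- order(-score, candidates$start, candidates$sense21)
  candidates[ord, , drop = FALSE]
}

#' Does a candidate's target window occur in every isoform?
#'
#' The filter operates on the 22-nt pre-mismatch target window (the
#' sequence actually complementary to the guide), requiring an exact
#' occurrence in each isoform.
#'
#' @param window22 The 22-nt target window (character).
#' @param isoforms [Biostrings::DNAStringSet] (or character vector) of
#'   all known isoforms of the target gene.
#' @return `TRUE` iff the window is a substring of every isoform.
#' @export
checkIsoformCoverage <- function(window22, isoforms) {
  stopifnot(length(window22) == 1L)
  if (is.character(isoforms)) isoforms <- Biostrings::DNAStringSet(isoforms)
  if (length(isoforms) == 0L) stop("need at least one isoform")
  all(Biostrings::vcountPattern(window22, isoforms) > 0L)
}

#' Off-target screen of one target window
#'
#' A window fails iff any of its length-`k` substrings (k = 16 by
#' default) occurs in a non-target transcript -- equivalently, iff its
#' longest contiguous complementarity to such a transcript exceeds
#' k - 1 = 15 nt. The screen runs on the sense (mRNA) strand of the
#' transcriptome, which by reverse-complement symmetry is identical to
#' screening the antisense guide against the transcripts.
#'
#' @param window22 The 22-nt pre-mismatch target window.
#' @param index A [KmerIndex-class] built with `k = seedK`.
#' @return List with `pass` (logical) and `n_hit_kmers` (how many of
#'   the window's k-mers hit the index).
#' @seealso [maxComplementarityRun()] for the exact run length.
#' @export
offtargetScan <- function(window22, index) {
  stopifnot(length(window22) == 1L)
  k <- index@k
  if (nchar(window22) < k)
    return(list(pass = TRUE, n_hit_kmers = 0L))
  kmers <- substring(window22, 1:(nchar(window22) - k + 1L),
                     k:nchar(window22))
  hits <- hasKmer(index, kmers)
  list(pass = !any(hits), n_hit_kmers = sum(hits))
}

#' Exact longest off-target complementarity run of a window
#'
#' Brute-force maximum of [longestCommonSubstring()] between the window
#' and every non-target transcript. Slower than the k-mer screen but
#' exact; used for audits and as the reference the screen must agree
#' with (`pass == (maxComplementarityRun <= 15)`).
#'
#' @param window22 The target window (character).
#' @param transcripts Named [Biostrings::DNAStringSet] or character
#'   vector.
#' @param targetIds Transcript names to exclude (the target's isoforms).
#' @return Integer: the longest contiguous match to any non-target
#'   transcript (0 if the background is empty).
#' @export
maxComplementarityRun <- function(window22, transcripts,
                                  targetIds = character(0)) {
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  keep <- transcripts[!(names(transcripts) %in% targetIds)]
  if (!length(keep)) return(0L)
  max(vapply(keep, function(tx)
    longestCommonSubstring(window22, tx), integer(1)))
}

#' Apply the miR-30a first-position sense mismatch
#'
#' The first nucleotide of the 22-nt sense strand is edited to mimic
#' the mismatch of the endogenous miR-30a duplex: C or G becomes A, and
#' A or T becomes C. All other positions are untouched, so the output
#' differs from the input at exactly position one.
#'
#' @param sense22raw Character vector of 22-nt sense strands.
#' @return The edited sense strands.
#' @export
applySenseMismatch <- function(sense22raw) {
  if (any(nchar(sense22raw) != 22L))
    stop("sense strand must be exactly 22 nt")
  .assertDna(sense22raw, "sense strand")
  first <- substring(sense22raw, 1L, 1L)
  newFirst <- ifelse(first %in% c("C", "G"), "A", "C")
  paste0(newFirst, substring(sense22raw, 2L))
}

#' Build the fully overlapping 22-nt mirE duplex for a candidate
#'
#' The 21-nt DSIR-style candidate (a duplex with 2-nt 3' overhangs) is
#' converted to a blunt 22-mer by dropping one base from the sense 3'
#' end and extending two bases at the 5' end, taken from the upstream
#' target context (`start - 2`); the antisense strand is the exact
#' reverse complement of that pre-mismatch window, so the duplex is
#' fully overlapping with no overhangs. The sense strand then receives
#' the first-position mismatch via [applySenseMismatch()].
#'
#' @param start 0-based start of the 21-nt sense window on `target`
#'   (must be >= 2 to provide upstream context).
#' @param target The reference isoform (character string, DNAString, or
#'   single DNAStringSet element).
#' @return List with `sense22_raw`, `sense22` (mismatch applied),
#'   `antisense22`, and `start22` (0-based start of the 22-nt window).
#' @examples
#' d <- makeMirEDuplex(2, "AAACCCGGGTTTAAACCCGGGTTTAAA")
#' d$sense22_raw   # "AAACCCGGGTTTAAACCCGGGT"
#' d$antisense22   # "ACCCGGGTTTAAACCCGGGTTT"
#' @export
makeMirEDuplex <- function(start, target) {
  if (methods::is(target, "DNAString") ||
      methods::is(target, "DNAStringSet"))
    target <- as.character(target)[1L]
  start <- as.integer(start)
  if (start < 2L)
    stop("start must be >= 2: the 22-nt duplex needs two upstream ",
         "context bases")
  if (start + 20L > nchar(target))
    stop("window extends past the end of the target")
  sense22raw <- substring(target, start - 1L, start + 20L)  # [start-2, start+20)
  list(sense22_raw = sense22raw,
       sense22 = applySenseMismatch(sense22raw),
       antisense22 = revComp(sense22raw),
       start22 = start - 2L)
}

#' Run the full guide-design pipeline
#'
#' enumerate -> rank -> filter (isoform coverage) -> filter (off-target)
#' -> take the top `n` survivors and transform each into a mirE duplex.
#' Enumeration runs on the reference isoform (the longest, by default);
#' the coverage filter then enforces presence of the 22-nt target
#' window in every isoform. If fewer than `n` candidates survive, the
#' survivors are returned with a warning.
#'
#' @param targetIsoforms Named [Biostrings::DNAStringSet] of all
#'   isoforms of the target gene.
#' @param transcriptome Named [Biostrings::DNAStringSet] of background
#'   transcripts. Any entries named like a target isoform are excluded
#'   from off-target screening automatically.
#' @param cfg A [DesignConfig-class].
#' @param n Number of guides to select (default `cfg@nSelectMirE`; use
#'   `cfg@nSelectPolycistron` for the four-hairpin scaffold).
#' @param scorer Passed to [rankCandidates()].
#' @param referenceId Name of the isoform to enumerate on; default the
#'   longest.
#' @return A [S4Vectors::DataFrame] of selected guides with columns
#'   `rank`, `target_id`, `start`, `sense21`, `sense22_raw`, `sense22`,
#'   `antisense22`, `score`. The per-candidate audit log (every
#'   enumerated window with its score and filter outcomes) is attached
#'   as `metadata(x)$audit`.
#' @export
designGuides <- function(targetIsoforms, transcriptome,
                         cfg = designConfig(), n = cfg@nSelectMirE,
                         scorer = cfg@scorer, referenceId = NULL) {
  stopifnot(methods::is(targetIsoforms, "DNAStringSet"),
            length(targetIsoforms) >= 1L)
  if (is.null(names(targetIsoforms)))
    stop("target isoforms must be named")
  if (is.null(referenceId))
    referenceId <- names(targetIsoforms)[which.max(
      Biostrings::width(targetIsoforms))]
  ref <- targetIsoforms[referenceId]

  index <- buildKmerIndex(transcriptome,
                          targetIds = intersect(names(transcriptome),
                                                names(targetIsoforms)),
                          k = cfg@seedK)

  cand <- rankCandidates(enumerateCandidates(ref, cfg), scorer)
  refSeq <- as.character(ref)[[1L]]
  win22 <- substring(refSeq, cand$start - 1L, cand$start + 20L)
  cand$window22 <- win22
  cand$coverage_ok <- vapply(win22, checkIsoformCoverage,
                             logical(1), isoforms = targetIsoforms,
                             USE.NAMES = FALSE)
  scan <- lapply(win22, offtargetScan, index = index)
  cand$offtarget_ok <- vapply(scan, `[[`, logical(1), "pass")
  cand$n_hit_kmers <- vapply(scan, `[[`, integer(1), "n_hit_kmers")
  keep <- cand$coverage_ok & cand$offtarget_ok
  cand$selected <- FALSE
  surv <- which(keep)
  if (length(surv) < n)
    warning("only ", length(surv), " candidates survive filtering ",
            "(requested ", n, ")")
  sel <- surv[seq_len(min(n, length(surv)))]
  cand$selected[sel] <- TRUE

  dup <- lapply(cand$start[sel], makeMirEDuplex, target = refSeq)
  out <- S4Vectors::DataFrame(
    rank = seq_along(sel),
    target_id = cand$target_id[sel],
    start = cand$start[sel],
    sense21 = cand$sense21[sel],
    sense22_raw = vapply(dup, `[[`, character(1), "sense22_raw"),
    sense22 = vapply(dup, `[[`, character(1), "sense22"),
    antisense22 = vapply(dup, `[[`, character(1), "antisense22"),
    score = cand$score[sel])
  S4Vectors::metadata(out)$audit <- cand
  out
}

#' Write selected guides as TSV
#'
#' @param guides Output of [designGuides()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGuidesTsv <- function(guides, path) {
  df <- as.data.frame(guides)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read guides from TSV
#'
#' @param path A TSV written by [writeGuidesTsv()].
#' @return A [S4Vectors::DataFrame].
#' @export
readGuidesTsv <- function(path) {
  S4Vectors::DataFrame(utils::read.delim(path, stringsAsFactors = FALSE))
}
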