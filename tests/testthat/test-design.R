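test_that("candidate enumeration yields one window per admissible start", {
  cfg <- designConfig()
  tgt <- setNames(rndDna(100), "t")
  set.seed(21)
  cand <- enumerateCandidates(tgt, cfg)
  expect_identical(nrow(cand), 78L)                # starts 2..79
  expect_identical(cand$start, 2:79)
  # every sense21 equals the target substring at its (0-based) start
  expect_identical(cand$sense21,
                   substring(tgt, cand$start + 1L, cand$start + 21L))
  one <- enumerateCandidates(setNames(rndDna(23), "t"), cfg)
  expect_identical(one$start, 2L)
  expect_warning(short <- enumerateCandidates(setNames(rndDna(22), "t"), cfg),
                 "no admissible windows")
  expect_identical(nrow(short), 0L)
})

test_that("ambiguous bases are rejected by default and maskable", {
  tgt <- setNames(paste0(rndDna(30), "N", rndDna(30)), "t")
  expect_error(enumerateCandidates(tgt), "outside")
  masked <- enumerateCandidates(tgt, maskAmbiguous = TRUE)
  # no surviving window's 22-nt context may contain the N
  ctx <- substring(tgt, masked$start - 1L, masked$start + 21L)
  expect_false(any(grepl("N", ctx)))
  expect_true(nrow(masked) > 0L)
})

test_that("ranking is deterministic, stable, and honours injected scores", {
  set.seed(22)
  cand <- enumerateCandidates(setNames(rndDna(80), "t"))
  # constant scorer: enumeration (start) order is the tie-break
  expect_identical(rankCandidates(cand, "constant")$start, cand$start)
  # injected scores ascending with position exactly reverse the order
  revd <- rankCandidates(cand, as.numeric(seq_len(nrow(cand))))
  expect_identical(revd$start, rev(cand$start))
  # default scorer is deterministic across runs
  expect_identical(as.data.frame(rankCandidates(cand, "default")),
                   as.data.frame(rankCandidates(cand, "default")))
  expect_error(rankCandidates(cand, "nope"), "unknown scorer")
})

test_that("isoform coverage requires the window in every isoform", {
  tx <- makeTranscriptome(nDecoys = 0L, cdsLength = 120L,
                          nIsoforms = 4L, seed = 23)
  # a window inside the shared CDS occurs in all isoforms
  inCds <- substring(tx$cds, 10, 31)
  expect_true(checkIsoformCoverage(inCds, tx$isoforms))
  # a window spanning iso1's UTR/CDS junction is iso1-specific
  iso1 <- as.character(tx$isoforms[["iso1"]])
  junction <- substring(iso1, 50, 71)  # UTR is 60 nt: spans the boundary
  expect_true(grepl(junction, iso1, fixed = TRUE))
  expect_false(checkIsoformCoverage(junction, tx$isoforms))
  # single isoform: any of its windows passes
  expect_true(checkIsoformCoverage(junction, tx$isoforms["iso1"]))
})

test_that("off-target scan decision equals the LCS oracle decision", {
  tx <- makeTranscriptome(
    nDecoys = 6L, decoyLength = 300L, cdsLength = 150L, seed = 24,
    plantedRuns = data.frame(start = c(10L, 60L, 100L),
                             k = c(16L, 15L, 17L)))
  idx <- buildKmerIndex(tx$transcriptome,
                        targetIds = names(tx$isoforms), k = 16L)
  ref <- as.character(tx$isoforms[[1]])
  cand <- enumerateCandidates(tx$isoforms[1])
  win <- substring(ref, cand$start - 1L, cand$start + 20L)
  pass <- vapply(win, function(w) offtargetScan(w, idx)$pass, logical(1),
                 USE.NAMES = FALSE)
  runs <- vapply(win, maxComplementarityRun, integer(1),
                 transcripts = tx$transcriptome,
                 targetIds = names(tx$isoforms), USE.NAMES = FALSE)
  expect_identical(pass, runs <= 15L)
  expect_true(any(!pass))    # the 16/17-nt plants do knock windows out
  expect_true(any(runs == 15L))  # and the 15-nt plant is tolerated
  # transcriptome of only target isoforms: everything passes
  idxT <- buildKmerIndex(tx$isoforms, targetIds = names(tx$isoforms))
  expect_true(all(vapply(win[1:10], function(w)
    offtargetScan(w, idxT)$pass, logical(1))))
})

test_that("mirE duplex construction follows the 21->22 nt rules", {
  d <- makeMirEDuplex(2, "AAACCCGGGTTTAAACCCGGGTTTAAA")
  expect_identical(d$sense22_raw, "AAACCCGGGTTTAAACCCGGGT")
  expect_identical(d$antisense22, "ACCCGGGTTTAAACCCGGGTTT")
  set.seed(25)
  tgt <- rndDna(120)
  cand <- enumerateCandidates(setNames(tgt, "t"))
  for (s in sample(cand$start, 10)) {
    d <- makeMirEDuplex(s, tgt)
    expect_identical(nchar(d$sense22_raw), 22L)
    expect_identical(d$antisense22, revComp(d$sense22_raw))
    # 3'-trimmed candidate: sense22_raw positions 3..22 equal the
    # 21-mer's first 20 bases
    sense21 <- substring(tgt, s + 1L, s + 21L)
    expect_identical(substring(d$sense22_raw, 3L, 22L),
                     substring(sense21, 1L, 20L))
  }
  expect_error(makeMirEDuplex(1, tgt), "start must be >= 2")
})

test_that("the first-position sense mismatch map is exhaustive", {
  tail21 <- substring("GGGTTTAAACCCGGGTTTAAAC", 2)
  mapped <- applySenseMismatch(paste0(c("A", "C", "G", "T"), tail21))
  expect_identical(substring(mapped, 1, 1), c("C", "A", "A", "C"))
  expect_identical(substring(mapped, 2), rep(tail21, 4))
  # the output always differs from the input at exactly one position
  orig <- paste0(c("A", "C", "G", "T"), tail21)
  diffs <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), orig, mapped)
  expect_true(all(diffs == 1L))
  expect_error(applySenseMismatch("ACGT"), "22 nt")
})

test_that("the design pipeline filters, selects and is deterministic", {
  tx <- makeTranscriptome(
    nDecoys = 8L, decoyLength = 400L, cdsLength = 200L, seed = 26,
    plantedRuns = data.frame(start = 40L, k = 18L))
  g1 <- designGuides(tx$isoforms, tx$transcriptome)
  g2 <- designGuides(tx$isoforms, tx$transcriptome)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_identical(nrow(g1), 3L)
  audit <- S4Vectors::metadata(g1)$audit
  # every emitted guide passed both filters with exact lengths and the
  # mismatch applied at exactly position one
  expect_true(all(nchar(g1$sense21) == 21L))
  expect_true(all(nchar(g1$sense22) == 22L))
  expect_true(all(g1$antisense22 == revComp(g1$sense22_raw)))
  diffs <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    g1$sense22, g1$sense22_raw)
  expect_true(all(diffs == 1L))
  sel <- audit[audit$selected, ]
  expect_true(all(sel$coverage_ok & sel$offtarget_ok))
  # no selected window overlaps the planted 18-nt off-target run
  bad <- audit[!audit$offtarget_ok, ]
  expect_true(nrow(bad) > 0L)
  expect_false(any(g1$start %in% bad$start))
})

test_that("guides TSV round-trips", {
  tx <- makeTranscriptome(nDecoys = 3L, cdsLength = 120L, seed = 27)
  g <- designGuides(tx$isoforms, tx$transcriptome)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeGuidesTsv(g, tmp)
  back <- readGuidesTsv(tmp)
  expect_identical(back$sense22, g$sense22)
  expect_identical(back$start, g$start)
})
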