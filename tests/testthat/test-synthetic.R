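# Generators: determinism, planted structure, and parameter recovery.

test_that("transcriptome generation is seed-deterministic with intact CDS", {
  t1 <- makeTranscriptome(nDecoys = 5L, seed = 51)
  t2 <- makeTranscriptome(nDecoys = 5L, seed = 51)
  expect_identical(as.character(t1$transcriptome),
                   as.character(t2$transcriptome))
  t3 <- makeTranscriptome(nDecoys = 5L, seed = 52)
  expect_false(identical(as.character(t1$decoys),
                         as.character(t3$decoys)))
  # every isoform contains the shared CDS verbatim
  expect_true(all(vapply(as.character(t1$isoforms), grepl, logical(1),
                         pattern = t1$cds, fixed = TRUE)))
  # FASTA bytes are reproducible end to end
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeFastaDNA(t1$transcriptome, f1)
  writeFastaDNA(t2$transcriptome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted off-target runs steer the design pipeline", {
  # a 16-nt planted run excludes exactly the windows that contain it;
  # a 15-nt run is tolerated
  tx <- makeTranscriptome(nDecoys = 6L, cdsLength = 200L, seed = 53,
                          plantedRuns = data.frame(start = c(30L, 120L),
                                                   k = c(16L, 15L)))
  g <- designGuides(tx$isoforms, tx$transcriptome)
  audit <- S4Vectors::metadata(g)$audit
  failed <- audit$start[!audit$offtarget_ok]
  runs <- vapply(audit$window22, maxComplementarityRun, integer(1),
                 transcripts = tx$transcriptome,
                 targetIds = names(tx$isoforms), USE.NAMES = FALSE)
  expect_identical(sort(failed), sort(audit$start[runs > 15L]))
  expect_true(length(failed) > 0L)
  expect_true(any(runs == 15L & audit$offtarget_ok))
  expect_error(makeTranscriptome(
    plantedRuns = data.frame(start = 295L, k = 10L)), "past the CDS")
})

test_that("cell-table simulation is deterministic and respects its spec", {
  s1 <- simulateCellTable(coexprSpec(), seed = 54)
  s2 <- simulateCellTable(coexprSpec(), seed = 54)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$regions, s2$regions)
  # untreated cells are RU, treated never RU
  expect_true(all(s1$cells$reporter_level[!s1$cells$treated] == "RU"))
  expect_true(all(s1$cells$reporter_level[s1$cells$treated] != "RU"))
  # densities land in the configured 8-15 cells/mm^2 band (Poisson
  # scatter allowed)
  dens <- vapply(split(s1$cells, s1$cells$region_id), nrow,
                 integer(1))[s1$regions$region_id] / s1$regions$area_mm2
  expect_true(all(dens > 5 & dens < 19))
})

test_that("a null simulation leaves category ratios indistinguishable", {
  pvals <- vapply(1:200, function(i) {
    # a large untreated pool keeps the estimated reference ratios close
    # to fixed, as the asymptotic GOF assumes
    sim <- simulateCellTable(
      coexprSpec(beta = 0, lambda = 0, nTreated = 3L, nUntreated = 30L,
                 areaRange = c(2.5, 3)), seed = 5400 + i)
    ref <- table(factor(sim$cells$marker_level[!sim$cells$treated],
                        markerLevels))
    obs <- table(factor(sim$cells$marker_level[sim$cells$treated],
                        markerLevels))
    chisqGoodnessOfFit(as.integer(obs),
                       as.integer(ref) / sum(ref))$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("strong knockdown produces the expected ordinal signature", {
  sim <- simulateCellTable(coexprSpec(beta = 0.9, nTreated = 16L,
                                      nUntreated = 16L), seed = 55)
  tab <- buildCategoryTable(sim$cells)
  expect_gt(linearByLinearTest(tab)$Z, 5)
  rs <- tab[, "RS"]
  expect_lt(rs[["strong"]] / sum(rs), 0.05)
})

test_that("increasing knockdown strictly lowers strong cells at RS", {
  strongAtRS <- function(beta, seed) {
    sim <- simulateCellTable(coexprSpec(beta = beta), seed = seed)
    tab <- buildCategoryTable(sim$cells)
    tab["strong", "RS"] / max(1L, sum(tab[, "RS"]))
  }
  frac <- vapply(c(0, 0.3, 0.6, 0.9), function(b)
    mean(vapply(1:20, function(s) strongAtRS(b, 5600 + s),
                numeric(1))), numeric(1))
  # expected fraction is non-increasing in beta (large beta floors the
  # strong category at zero, so strictness holds only overall)
  expect_true(all(diff(frac) <= 0))
  expect_lt(frac[4], frac[1])
})

test_that("rendered images carry truth sufficient for the full pipeline", {
  sim <- simulateCellTable(coexprSpec(beta = 0.5), seed = 57)
  bright <- sim$cells[sim$cells$mean_intensity > 60, ][1:12, ]
  r <- renderImages(bright, dim = c(200L, 200L), spacing = 40L,
                    seed = 57)
  expect_identical(max(r$labels), 12L)
  # zero cells: background only, nothing segmentable
  r0 <- renderImages(bright[0, ], dim = c(64L, 64L), seed = 57)
  expect_identical(max(r0$labels), 0L)
  expect_identical(max(naiveSegment(r0$chat, threshold = 140)), 0L)
  # determinism
  rb <- renderImages(bright, dim = c(200L, 200L), spacing = 40L,
                     seed = 57)
  expect_identical(imagePixels(r$chat), imagePixels(rb$chat))
})

test_that("planted knockdown and leakage parameters are recoverable", {
  sim <- simulateCellTable(coexprSpec(beta = 0.5, lambda = 0.05,
                                      nTreated = 20L, nUntreated = 20L),
                           seed = 58)
  est <- recoverParameters(sim$cells)
  expect_lt(abs(est$beta_hat - 0.5), 0.1)
  expect_lt(abs(est$lambda_hat - 0.05), 0.02)
  # null recovery: confidence intervals cover zero most of the time
  cover <- vapply(1:20, function(i) {
    s <- simulateCellTable(coexprSpec(beta = 0, lambda = 0),
                           seed = 5800 + i)
    e <- recoverParameters(s$cells)
    c(beta = e$beta_ci[1] <= 0 && e$beta_ci[2] >= 0,
      lambda = e$lambda_ci[1] <= 0 && e$lambda_ci[2] >= 0)
  }, logical(2))
  expect_gte(mean(cover["beta", ]), 0.9)
  expect_gte(mean(cover["lambda", ]), 0.9)
})
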