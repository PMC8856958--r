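# Ordinal co-expression statistics: table building, GOF, trend tests,
# densities, penetrance.

smallCells <- function() {
  data.frame(
    cell_id = paste0("c", 1:6), section_id = "S1",
    region_id = c("T1", "T1", "T1", "U1", "U1", "U1"),
    compartment = "putamen",
    treated = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    marker = "ChAT",
    marker_level = c("strong", "weak", "medium", "strong", "medium",
                     "weak"),
    reporter_level = c("RN", "RS", "RM", "RU", "RU", "RU"))
}

test_that("category tables count cells exactly and conserve totals", {
  cells <- smallCells()
  tab <- buildCategoryTable(cells)
  expect_identical(sum(tab), 6L)
  expect_identical(dim(tab), c(3L, 5L))
  expect_identical(tab["strong", "RN"], 1L)
  expect_identical(tab["weak", "RS"], 1L)
  expect_identical(sum(tab[, "RU"]), 3L)
  noRu <- buildCategoryTable(cells, includeUntreated = FALSE)
  expect_identical(dim(noRu), c(3L, 4L))
  expect_identical(sum(noRu), 3L)
  expect_error(buildCategoryTable(cells, marker = "AChE"), "no cells")
  # planted counts from the generator match the table exactly
  sim <- simulateCellTable(coexprSpec(), seed = 31)
  tab2 <- buildCategoryTable(sim$cells)
  expect_identical(sum(tab2), nrow(sim$cells))
  hand <- table(factor(sim$cells$marker_level, markerLevels),
                factor(sim$cells$reporter_level, reporterLevels))
  expect_identical(as.integer(tab2), as.integer(hand))
})

test_that("merging disjoint collections adds tables elementwise", {
  sim <- simulateCellTable(coexprSpec(), seed = 32)
  half <- nrow(sim$cells) %/% 2L
  a <- sim$cells[1:half, ]; b <- sim$cells[(half + 1L):nrow(sim$cells), ]
  expect_identical(
    mergeCategoryTables(buildCategoryTable(a), buildCategoryTable(b)),
    buildCategoryTable(sim$cells))
})

test_that("chi-square goodness-of-fit matches hand computation", {
  expect_equal(chisqGoodnessOfFit(c(30, 60, 10), c(0.3, 0.6, 0.1))$X2, 0)
  g <- chisqGoodnessOfFit(c(10, 40, 50), c(0.3, 0.6, 0.1))
  expect_equal(g$X2, 180)          # 400/30 + 400/60 + 1600/10
  expect_identical(g$df, 2L)
  expect_warning(chisqGoodnessOfFit(c(10, 10), c(2, 2)), "renormalizing")
  expect_error(chisqGoodnessOfFit(c(10, 10), c(1, 0)), "undefined")
})

test_that("linear-by-linear test matches its closed form and conventions", {
  res <- linearByLinearTest(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$r, 1)
  expect_equal(res$Z, sqrt(19))
  # uniform table: no association
  expect_equal(linearByLinearTest(matrix(5, 3, 5))$Z, 0)
  # Z = r * sqrt(n - 1) identity to 1e-12 on random tables
  set.seed(33)
  for (i in 1:10) {
    tab <- randomNullTable()
    r <- linearByLinearTest(tab)
    expect_equal(r$Z, r$r * sqrt(r$n - 1), tolerance = 1e-12)
    expect_true(abs(r$r) <= 1)
    expect_true(r$p > 0 && r$p <= 1)
    # affine score rescaling leaves Z unchanged
    r2 <- linearByLinearTest(tab, u = 2 * seq_len(nrow(tab)) + 3)
    expect_equal(r2$Z, r$Z, tolerance = 1e-12)
    # reported metadata: equivalent 1-df chi-square and table df
    expect_equal(r$Z2, r$Z^2)
    expect_identical(r$df_table,
                     (nrow(tab) - 1L) * (ncol(tab) - 1L))
  }
  expect_error(linearByLinearTest(matrix(c(3, 0, 4, 0), 2)),
               "degenerate")
})

test_that("knockdown simulations give positive Z growing with sqrt(n)", {
  zAt <- function(mult, seed) {
    sim <- simulateCellTable(
      coexprSpec(beta = 0.6, nTreated = 2L * mult,
                 nUntreated = 2L * mult), seed = seed)
    linearByLinearTest(buildCategoryTable(sim$cells))$Z
  }
  z <- vapply(c(1, 4, 16), zAt, numeric(1), seed = 34)  # n ~ 200/800/3200
  expect_true(all(z > 0))
  expect_true(all(diff(z) > 0))
  expect_true(z[3] > 2 * z[1])
})

test_that("Pearson trend on ordered proportions matches the formula", {
  pt <- pearsonTrend(c(0.5, 0.4, 0.3, 0.2, 0.1))
  expect_equal(pt$r, -1)
  expect_error(pearsonTrend(rep(0.3, 5)), "zero variance")
  set.seed(35)
  for (i in 1:5) {
    p <- runif(5)
    k <- seq_along(p)
    # direct textbook formula
    rHand <- sum((p - mean(p)) * (k - mean(k))) /
      sqrt(sum((p - mean(p))^2) * sum((k - mean(k))^2))
    expect_equal(pearsonTrend(p)$r, rHand, tolerance = 1e-12)
  }
})

test_that("density comparison uses the exact rank-sum test at small n", {
  regions <- data.frame(
    region_id = paste0("R", 1:6), section_id = "S1",
    compartment = "putamen",
    treated = rep(c(TRUE, FALSE), each = 3),
    construct = rep(c("x", "none"), each = 3),
    area_mm2 = rep(1, 6))
  regions$area_mm2 <- 2
  counts <- c(10, 12, 11, 18, 20, 19)   # densities 5,6,5.5,9,10,9.5
  cells <- do.call(rbind, lapply(1:6, function(i)
    data.frame(cell_id = paste0("c", i, "_", seq_len(counts[i])),
               region_id = regions$region_id[i],
               treated = regions$treated[i], marker = "ChAT",
               marker_level = "medium",
               reporter_level = ifelse(regions$treated[i], "RW", "RU"))))
  res <- compareDensities(cells, regions)
  expect_equal(sort(res$densities$density),
               sort(c(5, 6, 5.5, 9, 10, 9.5)))
  expect_equal(res$p, 0.1)   # exact enumeration of all 20 assignments
  # identical groups: p = 1
  same <- data.frame(region_id = rep(paste0("R", 1:6), each = 4),
                     marker = "ChAT")
  expect_equal(compareDensities(same, regions)$p, 1)
  expect_error(compareDensities(cells, regions[regions$treated, ]),
               "at least one")
})

test_that("penetrance counts detectable reporter among marker cells", {
  cells <- data.frame(
    region_id = rep("T1", 100), treated = TRUE, marker = "ChAT",
    marker_level = "medium",
    reporter_level = c(rep("RN", 20), rep("RW", 30), rep("RM", 30),
                       rep("RS", 20)))
  p <- penetrance(cells)
  expect_equal(p$pooled, 0.80)
  allRn <- transform(cells, reporter_level = "RN")
  expect_equal(penetrance(allRn)$pooled, 0)
  expect_error(penetrance(cells[0, ]), "no treated")
})

test_that("cell and region CSVs round-trip with validation", {
  sim <- simulateCellTable(coexprSpec(), seed = 36)
  dir <- withr::local_tempdir()
  paths <- writeCellTables(sim, dir)
  cells <- readCellTable(paths[["cells"]])
  regions <- readRegionTable(paths[["regions"]])
  expect_identical(nrow(cells), nrow(sim$cells))
  expect_identical(regions$region_id, sim$regions$region_id)
  bad <- sim$cells
  bad$reporter_level[which(!bad$treated)[1]] <- "RS"
  badPath <- file.path(dir, "bad.csv")
  utils::write.csv(bad, badPath, row.names = FALSE)
  expect_error(readCellTable(badPath), "RU")
})
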