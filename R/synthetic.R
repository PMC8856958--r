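# Seed-deterministic generators: transcriptome fixtures with planted
# off-target runs, striatal co-expression cell tables with knockdown
# and channel leakage, rendered two-channel images with truth masks,
# and recovery of the planted parameters.

.randomDna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic transcriptome with a multi-isoform target
#'
#' Builds a target gene whose isoforms all contain a shared CDS
#' verbatim (flanked by isoform-specific UTRs) plus random decoy
#' transcripts. Off-target matches of controlled length are planted by
#' copying target windows into decoys, so the off-target screen has
#' known ground truth: a window with a planted run of length > 15
#' must be rejected, one with a run of exactly 15 must survive.
#'
#' @param nDecoys Number of background transcripts.
#' @param decoyLength Decoy length in nt.
#' @param cdsLength Length of the shared CDS (ignored when `targetCds`
#'   is given).
#' @param targetCds Optional explicit CDS sequence.
#' @param nIsoforms Number of target isoforms (default 4).
#' @param utrLength Length of each isoform-specific UTR block.
#' @param plantedRuns data.frame with columns `start` (0-based start of
#'   the run on the CDS) and `k` (run length, 1..22); run i is copied
#'   into decoy `1 + (i-1) %% nDecoys`.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return List with `isoforms` (DNAStringSet, names iso1..), `decoys`
#'   (DNAStringSet, names decoy1..), `transcriptome` (both combined),
#'   `cds`, and `truth` (the planted-run table with the receiving decoy
#'   and its insertion offset).
#' @export
makeTranscriptome <- function(nDecoys = 20L, decoyLength = 500L,
                              cdsLength = 300L, targetCds = NULL,
                              nIsoforms = 4L, utrLength = 60L,
                              plantedRuns = NULL, seed = 1L) {
  set.seed(seed)
  cds <- if (is.null(targetCds)) .randomDna(1L, cdsLength) else targetCds
  .assertDna(cds, "target CDS")
  cdsLength <- nchar(cds)
  isoforms <- vapply(seq_len(nIsoforms), function(i)
    paste0(.randomDna(1L, utrLength), cds, .randomDna(1L, utrLength)),
    character(1))
  names(isoforms) <- paste0("iso", seq_len(nIsoforms))
  decoys <- .randomDna(nDecoys, decoyLength)
  if (nDecoys > 0L) names(decoys) <- paste0("decoy", seq_len(nDecoys))

  truth <- NULL
  if (!is.null(plantedRuns) && nrow(plantedRuns) > 0L) {
    stopifnot(all(plantedRuns$k >= 1L), all(plantedRuns$k <= 22L))
    recv <- integer(nrow(plantedRuns)); offs <- integer(nrow(plantedRuns))
    for (i in seq_len(nrow(plantedRuns))) {
      s <- plantedRuns$start[i]; k <- plantedRuns$k[i]
      if (s + k > cdsLength)
        stop("planted run ", i, " extends past the CDS")
      frag <- substring(cds, s + 1L, s + k)
      d <- 1L + (i - 1L) %% nDecoys
      # place the fragment away from the decoy edges, deterministic
      pos <- 10L + ((i * 37L) %% max(1L, decoyLength - k - 20L))
      decoys[d] <- paste0(substring(decoys[d], 1L, pos),
                          frag,
                          substring(decoys[d], pos + k + 1L))
      recv[i] <- d; offs[i] <- pos
    }
    truth <- cbind(plantedRuns, decoy = recv, offset = offs)
  }
  iso <- Biostrings::DNAStringSet(isoforms)
  dec <- Biostrings::DNAStringSet(decoys)
  list(isoforms = iso, decoys = dec,
       transcriptome = c(iso, dec), cds = cds, truth = truth)
}

#' Specification of a synthetic striatal co-expression experiment
#'
#' Defaults encode the study conditions the analyses assume: untreated
#' strong/medium/weak marker-category proportions of 0.30/0.60/0.10,
#' region densities of 8-15 cells/mm^2, 0.80 penetrance, a knockdown
#' slope `beta` in \[0,1\] (fractional marker reduction per unit
#' normalized reporter dose), and a small linear channel leakage
#' `lambda` from the marker into the reporter channel.
#'
#' @param nTreated,nUntreated Number of regions per arm.
#' @param areaRange Region areas (mm^2), drawn uniformly.
#' @param densityRange Marker-positive cell density (cells/mm^2).
#' @param baselineProps Untreated strong/medium/weak proportions.
#' @param penetrance Probability that a treated cell receives a
#'   nonzero reporter dose.
#' @param beta Knockdown slope in \[0, 1\].
#' @param lambda Leakage gain (reporter channel per marker gray level).
#' @param sigma Intensity noise SD (gray levels).
#' @param markerBands Intensity band edges `c(lo, weak|medium,
#'   medium|strong, hi)` defining the latent mixture and the
#'   categorization thresholds.
#' @param reporterThresholds Cutoffs RN|RW, RW|RM, RM|RS on the
#'   reporter intensity.
#' @param doseShape Beta-distribution shape parameters of the
#'   normalized reporter dose.
#' @param reporterScale Reporter gray levels per unit dose.
#' @param construct Construct label written into the region table.
#' @return A list of class `coexprSpec`.
#' @export
coexprSpec <- function(nTreated = 8L, nUntreated = 8L,
                       areaRange = c(3, 8), densityRange = c(8, 15),
                       baselineProps = c(strong = 0.30, medium = 0.60,
                                         weak = 0.10),
                       penetrance = 0.80, beta = 0.5, lambda = 0.05,
                       sigma = 5,
                       markerBands = c(30, 80, 150, 220),
                       reporterThresholds = c(20, 80, 150),
                       doseShape = c(2, 2), reporterScale = 200,
                       construct = "hM4Di_CFP-mirE1") {
  stopifnot(abs(sum(baselineProps) - 1) < 1e-8,
            beta >= 0, beta <= 1, lambda >= 0,
            !is.unsorted(markerBands, strictly = TRUE),
            !is.unsorted(reporterThresholds, strictly = TRUE),
            penetrance >= 0, penetrance <= 1)
  structure(as.list(environment()), class = "coexprSpec")
}

.categorizeMarker <- function(intensity, bands) {
  # strong >= bands[3], weak < bands[2]
  ifelse(intensity >= bands[3L], "strong",
         ifelse(intensity >= bands[2L], "medium", "weak"))
}

.categorizeReporter <- function(intensity, thr) {
  ifelse(intensity >= thr[3L], "RS",
         ifelse(intensity >= thr[2L], "RM",
                ifelse(intensity >= thr[1L], "RW", "RN")))
}

#' Simulate a striatal co-expression cell table
#'
#' Per region, the marker-positive cell count is Poisson(density x
#' area). Every cell draws a latent marker intensity C from a
#' three-component mixture matching the baseline proportions after
#' thresholding (category drawn at the baseline proportions, intensity
#' uniform within the category's band). Treated cells receive, with
#' probability `penetrance`, a normalized reporter dose R ~
#' Beta(doseShape); their observed marker intensity is
#' C' = C (1 - beta R) + noise, and their reporter intensity is
#' `reporterScale` R + lambda C' + noise (untreated cells have dose 0
#' and leakage only). Ordinal categories come from thresholding the
#' observed intensities; untreated cells are categorized RU by
#' definition.
#'
#' @param spec A [coexprSpec()].
#' @param seed Integer seed.
#' @return List with `cells` (data.frame in cell-record layout plus
#'   truth columns `dose` and `latent_C`), `regions` (region-record
#'   layout), and `truth` (the spec parameters).
#' @export
simulateCellTable <- function(spec = coexprSpec(), seed = 1L) {
  set.seed(seed)
  s <- spec
  nReg <- s$nTreated + s$nUntreated
  regions <- data.frame(
    region_id = sprintf("R%02d", seq_len(nReg)),
    section_id = sprintf("S%02d", 1L + (seq_len(nReg) - 1L) %/% 2L),
    compartment = rep_len(c("caudate", "putamen"), nReg),
    treated = rep(c(TRUE, FALSE), c(s$nTreated, s$nUntreated)),
    construct = rep(c(s$construct, "none"),
                    c(s$nTreated, s$nUntreated)),
    area_mm2 = runif(nReg, s$areaRange[1L], s$areaRange[2L]))
  dens <- runif(nReg, s$densityRange[1L], s$densityRange[2L])
  counts <- rpois(nReg, dens * regions$area_mm2)

  cells <- lapply(seq_len(nReg), function(ri) {
    n <- counts[ri]
    if (n == 0L) return(NULL)
    treated <- regions$treated[ri]
    cat0 <- sample(markerLevels, n, replace = TRUE,
                   prob = s$baselineProps)
    lo <- s$markerBands[c(strong = 3L, medium = 2L, weak = 1L)[cat0]]
    hi <- s$markerBands[c(strong = 4L, medium = 3L, weak = 2L)[cat0]]
    C <- runif(n, lo, hi)
    dose <- if (treated)
      ifelse(runif(n) < s$penetrance,
             rbeta(n, s$doseShape[1L], s$doseShape[2L]), 0)
    else rep(0, n)
    Cobs <- pmin(pmax(C * (1 - s$beta * dose) + rnorm(n, 0, s$sigma),
                      0), 255)
    rep_int <- pmin(pmax(s$reporterScale * dose + s$lambda * Cobs +
                           rnorm(n, 0, s$sigma), 0), 255)
    data.frame(
      cell_id = NA_character_,
      section_id = regions$section_id[ri],
      region_id = regions$region_id[ri],
      compartment = regions$compartment[ri],
      treated = treated,
      marker = "ChAT",
      marker_level = .categorizeMarker(Cobs, s$markerBands),
      reporter_level = if (treated)
        .categorizeReporter(rep_int, s$reporterThresholds)
      else "RU",
      mean_intensity = Cobs,
      reporter_intensity = rep_int,
      area_px = as.integer(round(pi * runif(n, 4, 8) * runif(n, 4, 8))),
      dose = dose, latent_C = C)
  })
  cells <- do.call(rbind, cells)
  cells$cell_id <- sprintf("C%05d", seq_len(nrow(cells)))
  list(cells = cells, regions = regions,
       truth = list(beta = s$beta, lambda = s$lambda,
                    penetrance = s$penetrance,
                    baselineProps = s$baselineProps))
}

#' Render synthetic two-channel images with truth masks
#'
#' Draws a subset of cells as filled ellipses (axes 8-16 px) on
#' Poisson-noise backgrounds -- gray level about 100 for the marker
#' channel and about 10 for the reporter channel -- with each cell's
#' channel intensities added over the background. Cell centres are laid
#' out on a jittered grid, so cells are well separated by
#' construction; the drawn pixel sets are returned as the truth label
#' mask.
#'
#' @param cells Cell table rows to draw (uses `mean_intensity` and
#'   `reporter_intensity`).
#' @param dim Image size in pixels (rows, cols).
#' @param chatBackground,reporterBackground Poisson background means.
#' @param spacing Grid spacing between cell centres in px.
#' @param seed Integer seed.
#' @return List with `chat` and `reporter` ([ChannelImage-class]),
#'   `labels` (truth label matrix), and `placed` (the drawn cells with
#'   centre coordinates and label ids).
#' @export
renderImages <- function(cells, dim = c(256L, 256L),
                         chatBackground = 100, reporterBackground = 10,
                         spacing = 32L, seed = 1L) {
  set.seed(seed)
  nr <- dim[1L]; nc <- dim[2L]
  margin <- spacing %/% 2L
  gr <- seq(margin, nr - margin, by = spacing)
  gc <- seq(margin, nc - margin, by = spacing)
  sites <- expand.grid(r = gr, c = gc)
  nDraw <- min(nrow(cells), nrow(sites))
  if (nDraw < nrow(cells))
    warning("frame holds ", nDraw, " of ", nrow(cells), " cells")
  sites <- sites[sample.int(nrow(sites), nDraw), , drop = FALSE]
  drawn <- cells[seq_len(nDraw), , drop = FALSE]
  drawn$centre_row <- sites$r + sample(-3:3, nDraw, replace = TRUE)
  drawn$centre_col <- sites$c + sample(-3:3, nDraw, replace = TRUE)
  drawn$label <- seq_len(nDraw)

  chat <- matrix(rpois(nr * nc, chatBackground), nr, nc)
  rep_ <- matrix(rpois(nr * nc, reporterBackground), nr, nc)
  labels <- matrix(0L, nr, nc)
  rowIdx <- row(labels); colIdx <- col(labels)
  for (i in seq_len(nDraw)) {
    a <- runif(1, 4, 8); b <- runif(1, 4, 8)   # semi-axes: 8-16 px axes
    inside <- ((rowIdx - drawn$centre_row[i]) / a)^2 +
      ((colIdx - drawn$centre_col[i]) / b)^2 <= 1
    labels[inside] <- i
    chat[inside] <- rpois(sum(inside),
                          chatBackground + drawn$mean_intensity[i])
    rep_[inside] <- rpois(sum(inside),
                          reporterBackground +
                            drawn$reporter_intensity[i])
  }
  chat <- pmin(chat, 255); rep_ <- pmin(rep_, 255)
  list(chat = channelImage(chat, "ChAT"),
       reporter = channelImage(rep_, "reporter"),
       labels = labels, placed = drawn)
}

#' Recover the planted knockdown and leakage parameters
#'
#' The knockdown slope is estimated from treated cells by least
#' squares of observed marker intensity on the reporter dose: with
#' E\[C'|R\] = mu0 (1 - beta R), the fit C' = a + b R gives
#' beta_hat = -b / a, with a delta-method confidence interval. The
#' leakage gain is the slope of reporter intensity on marker intensity
#' over untreated cells, with its standard lm confidence interval.
#'
#' @param cells Output of [simulateCellTable()] (needs the `dose`
#'   truth column for the knockdown fit).
#' @param level Confidence level (default 0.95).
#' @return List with `beta_hat`, `beta_ci`, `lambda_hat`, `lambda_ci`.
#' @export
recoverParameters <- function(cells, level = 0.95) {
  tr <- cells[cells$treated, , drop = FALSE]
  un <- cells[!cells$treated, , drop = FALSE]
  if (nrow(tr) < 10L) stop("insufficient treated cells")
  fit <- stats::lm(mean_intensity ~ dose, data = tr)
  a <- coef(fit)[1L]; b <- coef(fit)[2L]
  V <- stats::vcov(fit)
  betaHat <- unname(-b / a)
  # delta method on g(a, b) = -b/a
  grad <- c(b / a^2, -1 / a)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  betaCi <- betaHat + c(-1, 1) * zq * se

  lambdaHat <- NA_real_; lambdaCi <- c(NA_real_, NA_real_)
  if (nrow(un) >= 10L) {
    lfit <- stats::lm(reporter_intensity ~ mean_intensity, data = un)
    lambdaHat <- unname(coef(lfit)[2L])
    lambdaCi <- unname(confint(lfit, level = level)[2L, ])
  }
  list(beta_hat = betaHat, beta_ci = betaCi,
       lambda_hat = lambdaHat, lambda_ci = lambdaCi)
}

#' Write simulated cells / regions as CSV
#'
#' @param sim Output of [simulateCellTable()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
writeCellTables <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cp <- file.path(dir, "cells.csv")
  rp <- file.path(dir, "regions.csv")
  utils::write.csv(sim$cells, cp, row.names = FALSE)
  utils::write.csv(sim$regions, rp, row.names = FALSE)
  invisible(c(cells = cp, regions = rp))
}
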