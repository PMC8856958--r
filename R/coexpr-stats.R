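# Ordinal co-expression statistics: category tables, goodness-of-fit
# against untreated ratios, the linear-by-linear trend test, ordered
# Pearson trends, density comparisons, penetrance.

#' Ordinal level codes
#'
#' Marker (ChAT / AChE staining) categories are ordered strong = 1,
#' medium = 2, weak = 3. Reporter categories are ordered RU = 1
#' (untreated), RN = 2 (reporter not detected), RW = 3 (weak), RM = 4
#' (medium), RS = 5 (strong). With these orientations an inverse
#' marker/reporter relation (more reporter, weaker marker) gives a
#' positive trend statistic.
#'
#' @name levelCodes
#' @aliases markerLevels reporterLevels
NULL

#' @rdname levelCodes
#' @export
markerLevels <- c("strong", "medium", "weak")

#' @rdname levelCodes
#' @export
reporterLevels <- c("RU", "RN", "RW", "RM", "RS")

.asMarkerFactor <- function(x) factor(x, levels = markerLevels)
.asReporterFactor <- function(x) factor(x, levels = reporterLevels)

#' Read cell / region observation tables
#'
#' CSV files with the exact column names of the cell and region
#' records: cells have `cell_id, section_id, region_id, compartment,
#' treated, marker, marker_level, reporter_level` (optionally
#' `mean_intensity`, `area_px`); regions have `region_id, section_id,
#' compartment, treated, construct, area_mm2`.
#'
#' @param path CSV path.
#' @return data.frame with `treated` as logical and levels validated.
#' @export
readCellTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "region_id", "treated", "marker",
            "marker_level", "reporter_level")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cell table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$treated <- as.logical(df$treated)
  bad <- !(df$marker_level %in% markerLevels)
  if (any(bad)) stop("unknown marker_level values: ",
                     paste(unique(df$marker_level[bad]), collapse = ", "))
  bad <- !(df$reporter_level %in% reporterLevels)
  if (any(bad)) stop("unknown reporter_level values: ",
                     paste(unique(df$reporter_level[bad]), collapse = ", "))
  if (any(df$reporter_level == "RU" & df$treated) ||
      any(df$reporter_level != "RU" & !df$treated))
    stop("reporter_level must be RU exactly for untreated cells")
  df
}

#' @rdname readCellTable
#' @export
readRegionTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "treated", "construct", "area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("region table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$treated <- as.logical(df$treated)
  if (any(df$area_mm2 <= 0)) stop("region areas must be positive")
  df
}

#' Build a marker-by-reporter contingency table
#'
#' Counts cells of one marker into the 3 x 5 (or 3 x 4 when the
#' untreated RU column is excluded) table of marker level by reporter
#' level. When `regions` and `construct` are given, treated cells are
#' restricted to regions of that construct; untreated (RU) cells are
#' included whenever `includeUntreated` is `TRUE`.
#'
#' @param cells Cell table (see [readCellTable()]).
#' @param regions Optional region table used to select a construct.
#' @param construct Optional construct label.
#' @param marker Marker to tabulate (default "ChAT").
#' @param includeUntreated Keep the RU column? (default `TRUE`).
#' @return An integer matrix with marker levels as rows and reporter
#'   levels as columns; empty levels are kept as zero columns only
#'   within the requested column set.
#' @export
buildCategoryTable <- function(cells, regions = NULL, construct = NULL,
                               marker = "ChAT",
                               includeUntreated = TRUE) {
  sel <- cells$marker == marker
  if (!is.null(construct)) {
    if (is.null(regions)) stop("construct filtering needs a region table")
    rid <- regions$region_id[regions$construct == construct &
                               regions$treated]
    sel <- sel & ((cells$treated & cells$region_id %in% rid) |
                    (!cells$treated & includeUntreated))
  } else if (!includeUntreated) {
    sel <- sel & cells$treated
  }
  if (!any(sel))
    stop("no cells match filter (marker=", marker,
         if (!is.null(construct)) paste0(", construct=", construct),
         ")")
  cols <- if (includeUntreated) reporterLevels else reporterLevels[-1L]
  tab <- table(marker_level = .asMarkerFactor(cells$marker_level[sel]),
               reporter_level = factor(cells$reporter_level[sel],
                                       levels = cols))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Chi-square goodness-of-fit against reference category ratios
#'
#' Tests whether observed marker-category counts (typically from
#' treated regions) are distributed according to reference ratios
#' (typically the untreated category ratio): X2 =
#' sum (O_c - n p_c)^2 / (n p_c), df = categories - 1, asymptotic
#' upper-tail p. No continuity correction.
#'
#' @param observed Integer counts over the ordered categories.
#' @param referenceRatios Reference proportions; renormalized with a
#'   warning if they do not sum to 1.
#' @return List (`gof` class) with `X2`, `df`, `p`,
#'   `reference_ratios`, `observed`, `expected`.
#' @examples
#' chisqGoodnessOfFit(c(10, 40, 50), c(0.3, 0.6, 0.1))$X2  # 180
#' @export
chisqGoodnessOfFit <- function(observed, referenceRatios) {
  stopifnot(length(observed) == length(referenceRatios),
            all(observed >= 0), sum(observed) > 0)
  if (any(referenceRatios < 0)) stop("reference ratios must be >= 0")
  if (any(referenceRatios == 0 & observed > 0))
    stop("reference ratio 0 with positive observed count: ",
         "X2 undefined")
  s <- sum(referenceRatios)
  if (abs(s - 1) > 1e-8) {
    warning("reference ratios sum to ", signif(s, 6),
            "; renormalizing")
    referenceRatios <- referenceRatios / s
  }
  ct <- suppressWarnings(stats::chisq.test(observed, p = referenceRatios))
  structure(list(X2 = unname(ct$statistic),
                 df = as.integer(ct$parameter),
                 p = ct$p.value, reference_ratios = referenceRatios,
                 observed = observed, expected = unname(ct$expected)),
            class = "gof")
}

#' @export
print.gof <- function(x, ...) {
  cat(sprintf("Chi-square goodness-of-fit: X2 = %.4g, df = %d, p = %.4g\n",
              x$X2, x$df, x$p))
  invisible(x)
}

#' Asymptotic linear-by-linear association trend test
#'
#' The 1-df trend test for an ordered r x c contingency table: with row
#' scores u and column scores v (equally spaced integers by default),
#' the score statistic is T = sum_ij u_i v_j n_ij; the standardized
#' statistic equals Z = r * sqrt(n - 1) where r is the sample
#' correlation of the (u, v) score pairs over the n cells. The
#' two-sided p comes from the standard normal. With the package's level
#' orientation (strong = 1 to weak = 3; RU = 1 to RS = 5) a positive Z
#' means higher reporter levels go with weaker marker staining.
#'
#' The table's conventional degrees of freedom (r-1)(c-1) are reported
#' as `df_table` metadata alongside `Z2 = Z^2`, the equivalent 1-df
#' chi-square; the test itself has one degree of freedom.
#'
#' @param tab Matrix of counts (rows = marker levels, columns =
#'   reporter levels).
#' @param u,v Row / column scores; default `1:nrow`, `1:ncol`.
#' @return List (`lbl` class) with `T`, `Z`, `p`, `r`, `n`, `u`, `v`,
#'   `Z2`, `df_table`.
#' @examples
#' linearByLinearTest(matrix(c(10, 0, 0, 10), 2))$Z  # sqrt(19)
#' @export
linearByLinearTest <- function(tab, u = seq_len(nrow(tab)),
                               v = seq_len(ncol(tab))) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2L, ncol(tab) >= 2L, all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty table")
  rowm <- rowSums(tab); colm <- colSums(tab)
  if (sum(rowm > 0) < 2L || sum(colm > 0) < 2L)
    stop("degenerate margins: correlation undefined with a single ",
         "nonzero row or column")
  Tstat <- sum(outer(u, v) * tab)
  Eu <- sum(u * rowm) / n; Ev <- sum(v * colm) / n
  Vu <- sum((u - Eu)^2 * rowm) / n
  Vv <- sum((v - Ev)^2 * colm) / n
  r <- (Tstat / n - Eu * Ev) / sqrt(Vu * Vv)
  Z <- r * sqrt(n - 1)
  p <- 2 * stats::pnorm(-abs(Z))
  structure(list(T = Tstat, Z = Z, p = p, r = r, n = n, u = u, v = v,
                 Z2 = Z^2,
                 df_table = (nrow(tab) - 1L) * (ncol(tab) - 1L)),
            class = "lbl")
}

#' @export
print.lbl <- function(x, ...) {
  cat(sprintf(paste0("Linear-by-linear association: Z = %.4g, ",
                     "p = %.4g (r = %.4g, n = %d)\n"),
              x$Z, x$p, x$r, x$n))
  invisible(x)
}

#' Pearson trend of ordered proportions
#'
#' Pearson correlation of a vector of proportions (e.g. the strong or
#' weak marker ratio per reporter level, ordered RU, RN, RW, RM, RS)
#' against their ranks 1..k, with the two-sided test on k points.
#'
#' @param proportions Numeric vector of at least 3 ordered proportions.
#' @return List with `r`, `p`, `slope`, `intercept` (least squares on
#'   rank).
#' @export
pearsonTrend <- function(proportions) {
  k <- length(proportions)
  if (k < 3L) stop("need at least 3 ordered points")
  if (stats::sd(proportions) == 0)
    stop("zero variance: correlation undefined")
  rank <- seq_len(k)
  ct <- stats::cor.test(proportions, rank)
  fit <- stats::lm(proportions ~ rank)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Compare marker-positive cell densities of treated vs untreated regions
#'
#' Density is the number of marker-positive cells per region divided by
#' the region area (cells/mm^2); regions with zero annotated cells
#' count as density 0. The treated and untreated densities are
#' compared with a two-sided Wilcoxon-Mann-Whitney rank-sum test:
#' exact enumeration when both groups have at most `exactMax` regions
#' and no ties, tie-corrected normal approximation otherwise.
#'
#' @param cells Cell table.
#' @param regions Region table.
#' @param construct Optional: restrict treated regions to one construct.
#' @param marker Marker to count (default "ChAT").
#' @param exactMax Largest group size for the exact test (default 8).
#' @return List with `densities` (data.frame region_id, treated,
#'   density), `W`, `p`, `medians`.
#' @export
compareDensities <- function(cells, regions, construct = NULL,
                             marker = "ChAT", exactMax = 8L) {
  reg <- regions
  if (!is.null(construct))
    reg <- reg[!reg$treated | reg$construct == construct, , drop = FALSE]
  if (!any(reg$treated) || !any(!reg$treated))
    stop("need at least one treated and one untreated region")
  counts <- vapply(reg$region_id, function(rid)
    sum(cells$region_id == rid & cells$marker == marker), integer(1))
  dens <- counts / reg$area_mm2
  treated <- dens[reg$treated]; untreated <- dens[!reg$treated]
  exact <- length(treated) <= exactMax && length(untreated) <= exactMax &&
    !anyDuplicated(c(treated, untreated))
  if (stats::sd(dens) == 0) {
    # completely tied data carry no evidence either way
    wt <- list(statistic = length(treated) * length(untreated) / 2,
               p.value = 1)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(treated, untreated, exact = exact,
                         correct = FALSE))
  }
  list(densities = data.frame(region_id = reg$region_id,
                              treated = reg$treated, density = dens),
       W = unname(wt$statistic), p = wt$p.value,
       medians = c(treated = stats::median(treated),
                   untreated = stats::median(untreated)))
}

#' Penetrance of reporter expression among marker-positive cells
#'
#' The fraction of marker-positive cells inside treated regions whose
#' reporter level is at least RW (weak but detectable); RN ("reporter
#' not detected") counts as negative. Reported per region and pooled.
#'
#' @param cells Cell table (treated cells only are used).
#' @param marker Marker defining positivity (default "ChAT").
#' @return List with `pooled` (fraction) and `per_region` (data.frame
#'   region_id, n_cells, penetrance). Regions without marker-positive
#'   cells are skipped with a warning.
#' @export
penetrance <- function(cells, marker = "ChAT") {
  tc <- cells[cells$treated & cells$marker == marker, , drop = FALSE]
  if (nrow(tc) == 0L) stop("no treated marker-positive cells")
  pos <- match(tc$reporter_level, reporterLevels) >=
    match("RW", reporterLevels)
  per <- do.call(rbind, lapply(split(pos, tc$region_id), function(x)
    data.frame(n_cells = length(x), penetrance = mean(x))))
  per <- data.frame(region_id = rownames(per), per, row.names = NULL)
  empt <- setdiff(unique(cells$region_id[cells$treated]), per$region_id)
  if (length(empt))
    warning("treated region(s) without ", marker,
            "-positive cells skipped: ", paste(empt, collapse = ", "))
  list(pooled = mean(pos), per_region = per)
}

#' Elementwise sum of contingency tables
#'
#' Merging two disjoint cell collections adds their tables; provided as
#' a checked convenience.
#'
#' @param ... Matrices with identical dimnames.
#' @return Their elementwise sum.
#' @export
mergeCategoryTables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  for (t in tabs[-1L])
    stopifnot(identical(dimnames(t), dimnames(tabs[[1L]])))
  Reduce(`+`, tabs)
}
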