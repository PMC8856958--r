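# Per-cell intensity quantification from label masks, background
# normalization, distribution-shift tests, correlation, IoU evaluation
# and a naive baseline segmenter. Images are plain numeric matrices on
# the 8-bit 0-255 scale; cell masks are integer label matrices
# (0 = background, k = cell k).

#' Single-channel 8-bit image with a compartment mask
#'
#' @slot pixels Numeric matrix of gray levels in \[0, 255\].
#' @slot channel Channel label ("ChAT" or "reporter").
#' @slot regionMask Logical matrix of the same shape marking the
#'   compartment (caudate / putamen) pixels used for background
#'   estimation.
#' @slot normScale Scale factor applied by the last
#'   [normalizeBackground()] call (NA if never normalized).
#' @slot clampedCount Number of pixels clamped to 255 at normalization.
#' @export
setClass("ChannelImage",
  representation(pixels = "matrix", channel = "character",
                 regionMask = "matrix", normScale = "numeric",
                 clampedCount = "integer"),
  prototype(normScale = NA_real_, clampedCount = 0L),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (min(object@pixels) < 0 || max(object@pixels) > 255)
      return("pixel intensities must lie in [0, 255]")
    if (!identical(dim(object@pixels), dim(object@regionMask)))
      return("regionMask must have the same shape as pixels")
    if (!is.logical(object@regionMask))
      return("regionMask must be logical")
    TRUE
  })

#' @rdname ChannelImage-class
#' @param pixels,channel,regionMask See slots; `regionMask` defaults to
#'   the whole frame.
#' @export
channelImage <- function(pixels, channel = "ChAT",
                         regionMask = NULL) {
  if (is.null(regionMask))
    regionMask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  methods::new("ChannelImage", pixels = pixels, channel = channel,
               regionMask = regionMask)
}

setMethod("show", "ChannelImage", function(object) {
  cat("ChannelImage [", object@channel, "] ",
      nrow(object@pixels), "x", ncol(object@pixels),
      " px, background region ", sum(object@regionMask), " px",
      if (!is.na(object@normScale))
        sprintf(", normalized (scale %.3f, %d px clamped)",
                object@normScale, object@clampedCount),
      "\n", sep = "")
})

#' Pixel matrix of a ChannelImage
#' @param img A [ChannelImage-class].
#' @return Numeric matrix.
#' @export
imagePixels <- function(img) img@pixels

#' Normalize the background intensity of a channel image
#'
#' Scales all pixels by `target / mean(background pixels)` so the
#' background mean equals the target gray level (about 100 for the
#' marker channel, about 10 for the reporter channel). For the marker
#' channel the background is the compartment mask itself; for the
#' reporter channel a separate mask of pixels away from the injection
#' site must be supplied. Values above 255 are clamped (the image stays
#' 8-bit); the clamped-pixel count is recorded on the object.
#' Renormalizing an already-normalized image is a no-op up to rounding.
#'
#' @param img A [ChannelImage-class].
#' @param target Target background gray level (> 0).
#' @param backgroundMask Logical matrix defining the background pixels;
#'   defaults to the image's compartment mask.
#' @return The normalized [ChannelImage-class].
#' @export
normalizeBackground <- function(img, target = 100,
                                backgroundMask = NULL) {
  stopifnot(methods::is(img, "ChannelImage"), target > 0)
  if (is.null(backgroundMask)) backgroundMask <- img@regionMask
  stopifnot(identical(dim(backgroundMask), dim(img@pixels)))
  bg <- mean(img@pixels[backgroundMask])
  if (!is.finite(bg) || bg <= 0)
    stop("background mean must be positive (got ", bg, ")")
  scaled <- img@pixels * (target / bg)
  clamped <- sum(scaled > 255)
  scaled[scaled > 255] <- 255
  methods::initialize(img, pixels = scaled,
                      normScale = target / bg,
                      clampedCount = as.integer(clamped))
}

#' Measure per-cell mean intensity and area from a label mask
#'
#' For each labelled cell, the mean gray level over its pixels minus
#' the background level, floored at 0 (negative brightness is not
#' physically meaningful), and the pixel count. Masks outlined on the
#' marker channel transfer unchanged to the reporter channel: pass the
#' same label matrix with the other image.
#'
#' @param img A [ChannelImage-class] (or plain matrix).
#' @param labels Integer label matrix, same shape (0 = background).
#' @param background Background gray level to subtract (e.g. the
#'   normalization target).
#' @param cellIds Optional label ids to measure; an id with no pixels
#'   is an error.
#' @return data.frame with `cell_id`, `mean_intensity`, `area_px`,
#'   ordered by `cell_id`.
#' @export
measureCells <- function(img, labels, background = 0,
                         cellIds = NULL) {
  px <- if (methods::is(img, "ChannelImage")) img@pixels else img
  stopifnot(identical(dim(px), dim(labels)))
  present <- sort(unique(labels[labels > 0L]))
  if (is.null(cellIds)) cellIds <- present
  missing <- setdiff(cellIds, present)
  if (length(missing))
    stop("empty cell mask for id(s): ", paste(missing, collapse = ", "))
  if (length(cellIds) == 0L)
    return(data.frame(cell_id = integer(0), mean_intensity = numeric(0),
                      area_px = integer(0)))
  sel <- labels %in% cellIds
  f <- factor(labels[sel], levels = cellIds)
  means <- tapply(px[sel], f, mean)
  areas <- tabulate(f, nbins = length(cellIds))
  data.frame(cell_id = cellIds,
             mean_intensity = pmax(as.numeric(means) - background, 0),
             area_px = areas, row.names = NULL)
}

#' Kolmogorov-Smirnov test for an intensity distribution shift
#'
#' Two-sample KS test of treated vs untreated per-cell intensities with
#' Bonferroni correction for `m` comparisons (the family size is an
#' explicit argument; there is no hidden default). Medians of both
#' samples are returned so the direction of the shift is visible.
#'
#' @param treated,untreated Numeric samples (each of size >= 2).
#' @param m Number of comparisons in the Bonferroni family (>= 1).
#' @return List with `D`, `p_raw`, `p_adj` (= min(1, m * p_raw)),
#'   `medians`.
#' @export
ksMedianShift <- function(treated, untreated, m) {
  stopifnot(length(treated) >= 2L, length(untreated) >= 2L)
  if (missing(m) || m < 1) stop("Bonferroni family size m must be >= 1")
  kt <- suppressWarnings(stats::ks.test(treated, untreated))
  list(D = unname(kt$statistic), p_raw = kt$p.value,
       p_adj = min(1, m * kt$p.value),
       medians = c(treated = stats::median(treated),
                   untreated = stats::median(untreated)))
}

#' Pearson correlation of per-cell marker vs reporter intensities
#'
#' @param markerMeans,reporterMeans Paired per-cell mean intensities
#'   (>= 3 pairs, both with positive variance).
#' @return List with `r`, `p`, `slope`, `intercept` (least-squares line
#'   for plotting).
#' @export
intensityCorrelation <- function(markerMeans, reporterMeans) {
  stopifnot(length(markerMeans) == length(reporterMeans),
            length(markerMeans) >= 3L)
  if (stats::sd(markerMeans) == 0 || stats::sd(reporterMeans) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(markerMeans, reporterMeans)
  fit <- stats::lm(reporterMeans ~ markerMeans)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]))
}

#' Label connected components (8-connectivity)
#'
#' Two-pass flood labelling of a logical matrix where diagonal
#' neighbours are connected.
#'
#' @param mask Logical matrix.
#' @return Integer label matrix (0 = background).
#' @export
labelComponents <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  # neighbour offsets in linear (column-major) indexing, with row
  # wrap-around guarded explicitly
  cur <- 0L
  todo <- which(mask)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      i <- ((frontier - 1L) %% nr) + 1L
      j <- ((frontier - 1L) %/% nr) + 1L
      nb <- integer(0)
      for (dj in -1L:1L) {
        jj <- j + dj
        ok <- jj >= 1L & jj <= nc
        for (di in -1L:1L) {
          if (di == 0L && dj == 0L) next
          ii <- i + di
          keep <- ok & ii >= 1L & ii <= nr
          if (any(keep))
            nb <- c(nb, (jj[keep] - 1L) * nr + ii[keep])
        }
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Naive threshold-and-label baseline segmenter
#'
#' Connected components (8-connectivity) of pixels above a gray-level
#' threshold, keeping components of at least `minArea` pixels. A
#' baseline stand-in for any external segmenter (e.g. a trained
#' network) whose label masks the measurement functions consume.
#'
#' @param img A [ChannelImage-class] or numeric matrix.
#' @param threshold Gray-level threshold in (0, 255).
#' @param minArea Minimum component area in pixels.
#' @return Integer label matrix with consecutive ids 1..n (0 if no
#'   component survives).
#' @export
naiveSegment <- function(img, threshold, minArea = 1L) {
  px <- if (methods::is(img, "ChannelImage")) img@pixels else img
  stopifnot(threshold > 0, threshold < 255)
  lab <- labelComponents(px > threshold)
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minArea)
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  lab
}

#' Evaluate a predicted segmentation against truth by IoU
#'
#' Predicted and ground-truth objects are matched greedily by
#' descending pixel overlap (each object used at most once); each
#' matched pair is scored intersection/union, unmatched truth objects
#' score 0, and the mean is taken over truth objects. IoU is 0 for
#' disjoint and 1 for identical objects.
#'
#' @param predicted,truth Integer label matrices on the same frame.
#' @return List (`iouReport` class) with `per_object` (data.frame
#'   truth_id, pred_id, iou), `mean_iou`, `matching`.
#' @export
iouEvaluate <- function(predicted, truth) {
  stopifnot(identical(dim(predicted), dim(truth)))
  truthIds <- sort(unique(truth[truth > 0L]))
  if (length(truthIds) == 0L) stop("empty truth set")
  predIds <- sort(unique(predicted[predicted > 0L]))
  areaT <- table(factor(truth[truth > 0L], levels = truthIds))
  areaP <- table(factor(predicted[predicted > 0L], levels = predIds))
  both <- truth > 0L & predicted > 0L
  ov <- as.data.frame(table(truth_id = factor(truth[both],
                                              levels = truthIds),
                            pred_id = factor(predicted[both],
                                             levels = predIds)),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0L, , drop = FALSE]
  ov <- ov[order(-ov$Freq), , drop = FALSE]
  usedT <- character(0); usedP <- character(0)
  match <- list()
  for (i in seq_len(nrow(ov))) {
    t <- ov$truth_id[i]; p <- ov$pred_id[i]
    if (t %in% usedT || p %in% usedP) next
    usedT <- c(usedT, t); usedP <- c(usedP, p)
    inter <- ov$Freq[i]
    uni <- as.numeric(areaT[[t]]) + as.numeric(areaP[[p]]) - inter
    match[[length(match) + 1L]] <-
      data.frame(truth_id = as.integer(t), pred_id = as.integer(p),
                 iou = inter / uni)
  }
  matched <- if (length(match)) do.call(rbind, match) else
    data.frame(truth_id = integer(0), pred_id = integer(0),
               iou = numeric(0))
  unmatched <- setdiff(as.integer(truthIds), matched$truth_id)
  per <- rbind(matched,
               data.frame(truth_id = unmatched,
                          pred_id = rep(NA_integer_, length(unmatched)),
                          iou = rep(0, length(unmatched))))
  per <- per[order(per$truth_id), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(per_object = per, mean_iou = mean(per$iou),
                 matching = matched[, c("truth_id", "pred_id")]),
            class = "iouReport")
}

#' @export
print.iouReport <- function(x, ...) {
  cat(sprintf("IoU report: %d truth objects, %d matched, mean IoU %.3f\n",
              nrow(x$per_object), nrow(x$matching), x$mean_iou))
  invisible(x)
}

#' Read / write a label mask as CSV
#'
#' Plain-text exchange format for label masks: one row per labelled
#' pixel (`row`, `col`, 1-based, and `cell_id`), plus the frame size in
#' the header comment.
#'
#' @param labels Integer label matrix.
#' @param path CSV path.
#' @return The writer returns `path` invisibly; the reader the label
#'   matrix.
#' @export
writeLabelCsv <- function(labels, path) {
  idx <- which(labels > 0L, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1L], col = idx[, 2L],
                   cell_id = labels[idx])
  con <- file(path, "w")
  writeLines(sprintf("# dim %d %d", nrow(labels), ncol(labels)), con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = ",",
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname writeLabelCsv
#' @export
readLabelCsv <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  d <- as.integer(hdr[3:4])
  df <- utils::read.csv(path, skip = 1L)
  lab <- matrix(0L, d[1L], d[2L])
  lab[cbind(df$row, df$col)] <- as.integer(df$cell_id)
  lab
}
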