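#' Default colorblind-safe palette for categorical values
#'
#' Okabe-Ito colors, avoiding red-green pairs; fixed and documented so maps
#' are bit-reproducible.
#'
#' @param values distinct values to map (character or numeric; ordered)
#' @return named character vector value -> hex color
#' @export
defaultPalette <- function(values) {
  base <- c("#0072B2", "#56B4E9", "#009E73", "#F0E442", "#E69F00",
            "#D55E00", "#CC79A7", "#999999", "#000000")
  values <- as.character(values)
  if (length(values) > length(base))
    base <- grDevices::hcl.colors(length(values), "Viridis")
  stats::setNames(base[seq_along(values)], values)
}

#' Render a pseudocolor cell map
#'
#' One filled circle per cell at its centroid, all sharing one radius (the
#' mean ROI radius, so every cell reads equally), colored by a per-cell
#' value through a categorical palette. Cells whose value is NA are drawn
#' in \code{naColor} when given, otherwise skipped. Rendering is
#' deterministic: same inputs, byte-identical raster.
#'
#' @param rois a [RoiSet]
#' @param values per-cell values (named by cell_id or in ROI order)
#' @param palette named vector value -> color; default [defaultPalette()]
#'   over the sorted distinct values
#' @param naColor color for NA-valued (e.g. unresponsive) cells, or NULL to
#'   skip them
#' @param background background color
#' @return a CellMap: list(raster = H x W x 3 array in \[0, 1\],
#'   key = data.frame(value, color), radius_px, value_semantics)
#' @export
renderMap <- function(rois, values, palette = NULL, naColor = "#DDDDDD",
                      background = "#FFFFFF") {
  stopifnot(is(rois, "RoiSet"))
  n <- length(rois@cellIds)
  if (!is.null(names(values))) values <- values[rois@cellIds]
  if (length(values) != n)
    stop("need one value per cell")
  vchar <- as.character(values)
  if (is.null(palette))
    palette <- defaultPalette(sort(unique(stats::na.omit(values))))
  missing <- setdiff(unique(stats::na.omit(vchar)), names(palette))
  if (length(missing))
    stop("palette error: no color for value(s) ", paste(missing, collapse = ", "))
  dimIm <- rois@imageDim
  raster <- array(0, c(dimIm[1], dimIm[2], 3))
  bg <- grDevices::col2rgb(background) / 255
  for (ch in 1:3) raster[, , ch] <- bg[ch]
  radius <- mean(vapply(rois@masks, function(m) sqrt(nrow(m) / pi),
                        numeric(1)))
  cen <- centroids(rois) / rois@pixelSizeUm    # pixel units
  for (i in seq_len(n)) {
    col <- if (is.na(vchar[i])) naColor else palette[[vchar[i]]]
    if (is.null(col) || is.na(col)) next
    disk <- ovalMaskFromBox(cen[i, 2] - radius, cen[i, 1] - radius,
                            cen[i, 2] + radius, cen[i, 1] + radius, dimIm)
    rgb <- grDevices::col2rgb(col) / 255
    for (ch in 1:3) raster[cbind(disk, ch)] <- rgb[ch]
  }
  list(raster = raster,
       key = data.frame(value = names(palette),
                        color = unname(palette),
                        stringsAsFactors = FALSE),
       radius_px = radius,
       value_semantics = attr(values, "semantics") %||% "value")
}

#' Write a CellMap as PNG with a JSON color-key sidecar
#'
#' @param map a CellMap from [renderMap()]
#' @param path output .png path; the key is written next to it as
#'   \code{<path>_key.json}
#' @return invisibly, \code{path}
#' @export
writeMapPng <- function(map, path) {
  png::writePNG(map$raster, path)
  jsonlite::write_json(
    list(value_semantics = map$value_semantics, radius_px = map$radius_px,
         key = map$key),
    sub("\\.png$", "_key.json", path), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}

#' Cumulative distribution of best frequencies
#'
#' Fraction of cells with BTF at or below each grid frequency; reaches 1 at
#' the maximum.
#'
#' @param btfs per-cell best frequencies (non-empty)
#' @param gridFreqsHz evaluation points (default the sorted distinct BTFs)
#' @return data.frame (freq_hz, cum_fraction)
#' @export
cumulativeDistribution <- function(btfs, gridFreqsHz = NULL) {
  btfs <- btfs[!is.na(btfs)]
  if (!length(btfs)) stop("invalid argument: no best frequencies")
  if (is.null(gridFreqsHz)) gridFreqsHz <- sort(unique(btfs))
  data.frame(freq_hz = gridFreqsHz,
             cum_fraction = vapply(gridFreqsHz,
                                   function(f) mean(btfs <= f), numeric(1)))
}

#' Class fractions per compartment
#'
#' Counts and fractions of each class within every non-empty compartment;
#' fractions within a compartment sum to 1.
#'
#' @param classes per-cell class labels (character/factor)
#' @param compartments per-cell compartment labels
#' @param dropNa drop NA-classed cells before computing fractions (default
#'   TRUE)
#' @return data.frame (compartment, class, n, fraction)
#' @export
populationSummary <- function(classes, compartments, dropNa = TRUE) {
  stopifnot(length(classes) == length(compartments))
  keep <- if (dropNa) !is.na(classes) else rep(TRUE, length(classes))
  classes <- as.character(classes)[keep]
  compartments <- as.character(compartments)[keep]
  res <- do.call(rbind, lapply(split(classes, compartments), function(cl) {
    tab <- table(cl)
    data.frame(class = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / length(cl),
               stringsAsFactors = FALSE)
  }))
  res$compartment <- sub("\\.[0-9]+$", "", rownames(res))
  rownames(res) <- NULL
  res[, c("compartment", "class", "n", "fraction")]
}

#' ROC validation of the correlation-based flagging method
#'
#' Exact empirical ROC over every distinct score used as a cut (predicting
#' positive when score > cut, matching the strict flagging rule), with AUC
#' by trapezoidal integration. At the stated threshold the confusion counts
#' and derived metrics are reported: sensitivity = TP/(TP+FN), specificity
#' = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN).
#'
#' @param scores per-cell mean correlation (or any ranking score)
#' @param labels logical ground-truth/human labels (both classes required)
#' @param threshold cutoff for the confusion metrics (default 0.4, the
#'   somatosensory flagging cutoff)
#' @return a ValidationReport: list(roc = data.frame(threshold, fpr, tpr),
#'   auc, threshold, counts, sensitivity, specificity, ppv, npv)
#' @export
rocValidation <- function(scores, labels, threshold = 0.4) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (all(labels) || !any(labels))
    stop("undefined AUC: both classes must be present in labels")
  nP <- sum(labels); nN <- sum(!labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(cuts, function(c) sum(scores >= c & labels) / nP, numeric(1))
  fpr <- vapply(cuts, function(c) sum(scores >= c & !labels) / nN, numeric(1))
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  tp <- sum(scores > threshold & labels)
  fp <- sum(scores > threshold & !labels)
  fn <- nP - tp
  tn <- nN - fp
  list(roc = data.frame(threshold = cuts, fpr = fpr, tpr = tpr),
       auc = auc, threshold = threshold,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}
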