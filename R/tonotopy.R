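#' Named anatomical axis presets
#'
#' The four lateral-cortex axes and the dorsal-cortex rostromedial to
#' caudolateral axis, all with origin (0, 0). Coordinates follow the
#' package convention x = rostral to caudal (+), y = dorsal to ventral (+).
#'
#' @param name one of "dorsal-ventral", "rostral-caudal",
#'   "dorsocaudal-ventrorostral", "dorsorostral-ventrocaudal",
#'   "rostromedial-caudolateral"
#' @param origin axis starting point (x, y) in microns
#' @return an [AxisSpec]
#' @export
axisPreset <- function(name = c("dorsal-ventral", "rostral-caudal",
                                "dorsocaudal-ventrorostral",
                                "dorsorostral-ventrocaudal",
                                "rostromedial-caudolateral"),
                       origin = c(0, 0)) {
  name <- match.arg(name)
  dirs <- list(
    "dorsal-ventral" = c(0, 1),
    "rostral-caudal" = c(1, 0),
    "dorsocaudal-ventrorostral" = c(-1, 1) / sqrt(2),
    "dorsorostral-ventrocaudal" = c(1, 1) / sqrt(2),
    "rostromedial-caudolateral" = c(1, 1) / sqrt(2)
  )
  new("AxisSpec", name = name, origin = as.numeric(origin),
      direction = dirs[[name]])
}

#' Axis from an angle
#'
#' @param angleDeg direction angle in degrees (0 = +x)
#' @param origin starting point (x, y) in microns
#' @param name optional label
#' @return an [AxisSpec]
#' @export
axisFromAngle <- function(angleDeg, origin = c(0, 0),
                          name = sprintf("axis_%gdeg", angleDeg)) {
  new("AxisSpec", name = name, origin = as.numeric(origin),
      direction = c(cos(angleDeg * pi / 180), sin(angleDeg * pi / 180)))
}

#' Distance of each cell along an anatomical axis
#'
#' Default ("projection"): the scalar projection of each cell onto the axis
#' direction from the starting point, which is what makes different axes
#' through the same field distinguishable; for a cell lying on the axis
#' line it coincides with the straight-line distance
#' \eqn{d = \sqrt{(x_2 - x_1)^2 + (y_2 - y_1)^2}} from the starting point,
#' available verbatim as \code{method = "euclidean"}. Cells lying behind
#' the origin along the axis direction (negative projection) are excluded
#' (NA) with a message.
#'
#' @param centroids cells x 2 matrix of (x_um, y_um) positions
#' @param axis an [AxisSpec]
#' @param method "projection" (default) or "euclidean"
#' @return numeric vector of distances in microns (NA for excluded cells)
#' @export
projectDistance <- function(centroids, axis,
                            method = c("projection", "euclidean")) {
  method <- match.arg(method)
  centroids <- as.matrix(centroids)
  stopifnot(ncol(centroids) == 2L, all(is.finite(centroids)))
  dx <- centroids[, 1] - axis@origin[1]
  dy <- centroids[, 2] - axis@origin[2]
  proj <- dx * axis@direction[1] + dy * axis@direction[2]
  d <- if (method == "euclidean") sqrt(dx^2 + dy^2) else proj
  behind <- proj < 0
  if (any(behind)) {
    message(sum(behind), " cell(s) behind the axis origin excluded")
    d[behind] <- NA_real_
  }
  d
}

#' Bin BTFs by distance and take geometric means
#'
#' Half-open 50 um bins \code{[k*bin, (k+1)*bin)}: per bin, the geometric
#' mean of member BTFs and of member distances. A zero distance would make
#' the geometric mean degenerate, so zero distances are substituted by the
#' bin's lower edge + 1 um (reported via a message). Empty bins are absent.
#'
#' @param distances per-cell distances (um); NA entries are dropped
#' @param btfs per-cell best tone frequencies (Hz, > 0)
#' @param binSizeUm bin size (default 50)
#' @return data.frame (bin, distance_um, btf_hz, n_cells)
#' @export
binGeometric <- function(distances, btfs, binSizeUm = 50) {
  stopifnot(length(distances) == length(btfs))
  keep <- !is.na(distances) & !is.na(btfs)
  distances <- distances[keep]; btfs <- btfs[keep]
  if (any(btfs <= 0)) stop("invalid input: BTFs must be positive")
  if (any(distances < 0)) stop("invalid input: distances must be >= 0")
  if (any(distances == 0)) {
    message(sum(distances == 0),
            " zero distance(s) substituted by bin lower edge + 1 um")
    distances[distances == 0] <- 1
  }
  bin <- floor(distances / binSizeUm)
  geo <- function(v) exp(mean(log(v)))
  res <- do.call(rbind, lapply(split(seq_along(bin), bin), function(ix) {
    data.frame(bin = bin[ix[1]],
               distance_um = geo(distances[ix]),
               btf_hz = geo(btfs[ix]),
               n_cells = length(ix))
  }))
  res <- res[order(res$bin), ]
  rownames(res) <- NULL
  res
}

#' Linear and quadratic regression of binned BTF on distance
#'
#' Ordinary least squares of the per-bin geometric-mean BTF on the per-bin
#' geometric-mean distance, degree 1 and degree 2, with R-squared for both.
#' Because the geometric mean implies multiplicative structure, the default
#' fits log2(BTF); \code{scale = "hz"} fits raw Hz. At least 3 bins are
#' required for the linear fit and 4 for the quadratic (otherwise the
#' quadratic is omitted, NA).
#'
#' @param bins data.frame from [binGeometric()]
#' @param axis the [AxisSpec] the distances came from
#' @param scale "log2" (default) or "hz"
#' @param binSizeUm bin size recorded in the fit
#' @return a [TonotopyFit]
#' @export
fitTonotopy <- function(bins, axis = axisPreset("rostral-caudal"),
                        scale = c("log2", "hz"), binSizeUm = 50) {
  scale <- match.arg(scale)
  if (nrow(bins) < 3L)
    stop("insufficient data: need >= 3 bins for the linear fit")
  y <- if (scale == "log2") log2(bins$btf_hz) else bins$btf_hz
  d <- bins$distance_um
  fitL <- stats::lm(y ~ d)
  r2L <- r2OfFit(fitL, y)
  if (nrow(bins) >= 4L) {
    fitQ <- stats::lm(y ~ d + I(d^2))
    r2Q <- r2OfFit(fitQ, y)
    coQ <- unname(stats::coef(fitQ))
  } else {
    r2Q <- NA_real_
    coQ <- numeric(0)
  }
  new("TonotopyFit", axis = axis, binSizeUm = binSizeUm, bins = bins,
      scale = scale, r2Linear = r2L, r2Quadratic = r2Q,
      coefLinear = unname(stats::coef(fitL)), coefQuadratic = coQ)
}

#' Tonotopy assessment from centroids and BTFs in one call
#'
#' [projectDistance()] then [binGeometric()] then [fitTonotopy()].
#'
#' @param centroids cells x 2 matrix of positions (um)
#' @param btfs per-cell best tone frequencies (Hz)
#' @param axis an [AxisSpec]
#' @param binSizeUm bin size (default 50)
#' @param scale "log2" or "hz"
#' @return a [TonotopyFit]
#' @export
assessTonotopy <- function(centroids, btfs, axis, binSizeUm = 50,
                           scale = "log2", method = "projection") {
  d <- projectDistance(centroids, axis, method)
  bins <- binGeometric(d, btfs, binSizeUm)
  fitTonotopy(bins, axis, scale, binSizeUm)
}

#' Serialize a TonotopyFit to JSON (plus an optional CSV of bins)
#'
#' @param fit a [TonotopyFit]
#' @param jsonPath output JSON path
#' @param csvPath optional CSV path for the binned values
#' @return invisibly, \code{jsonPath}
#' @export
writeTonotopyFit <- function(fit, jsonPath, csvPath = NULL) {
  obj <- list(axis = fit@axis@name, origin = fit@axis@origin,
              direction = fit@axis@direction, bin_size_um = fit@binSizeUm,
              scale = fit@scale, r2_linear = fit@r2Linear,
              r2_quadratic = fit@r2Quadratic,
              coef_linear = fit@coefLinear,
              coef_quadratic = fit@coefQuadratic,
              bins = fit@bins)
  jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(csvPath)) utils::write.csv(fit@bins, csvPath,
                                          row.names = FALSE)
  invisible(jsonPath)
}
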