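# ImageJ .roi binary records and .zip ROI archives.
#
# Only the subset of the format the pipeline needs is supported: rectangle
# (type 1), oval (type 2) and polygon/freehand/traced outlines (types 0, 7,
# 8). Coordinates follow ImageJ conventions: 0-based pixel units with the
# bounding box given as top/left/bottom/right and pixel (x, y) covering
# [x, x+1) x [y, y+1).

ROI_MAGIC <- charToRaw("Iout")

# Rasterize an ImageJ oval bounding box into 1-based (row, col) pixels.
# A pixel belongs to the oval if its center lies inside the inscribed
# ellipse. Shared by the ROI reader and the movie renderer so disk ROIs
# round-trip exactly.
ovalMaskFromBox <- function(top, left, bottom, right, imageDim) {
  w <- right - left; h <- bottom - top
  if (w <= 0 || h <= 0) return(matrix(integer(0), 0, 2))
  xc <- left + w / 2; yc <- top + h / 2
  cols <- seq.int(max(0L, floor(left)), min(imageDim[2] - 1L, ceiling(right) - 1L))
  rows <- seq.int(max(0L, floor(top)), min(imageDim[1] - 1L, ceiling(bottom) - 1L))
  if (!length(cols) || !length(rows)) return(matrix(integer(0), 0, 2))
  gx <- ((rep(cols, each = length(rows)) + 0.5 - xc) / (w / 2))^2
  gy <- ((rep(rows, times = length(cols)) + 0.5 - yc) / (h / 2))^2
  keep <- gx + gy <= 1
  cbind(row = rep(rows, times = length(cols))[keep] + 1L,
        col = rep(cols, each = length(rows))[keep] + 1L)
}

rectMaskFromBox <- function(top, left, bottom, right, imageDim) {
  rows <- seq.int(max(0L, top), min(imageDim[1] - 1L, bottom - 1L))
  cols <- seq.int(max(0L, left), min(imageDim[2] - 1L, right - 1L))
  as.matrix(expand.grid(row = rows + 1L, col = cols + 1L))
}

# Even-odd point-in-polygon test on pixel centers.
polygonMask <- function(xs, ys, imageDim) {
  cols <- seq.int(max(0L, floor(min(xs))), min(imageDim[2] - 1L, ceiling(max(xs))))
  rows <- seq.int(max(0L, floor(min(ys))), min(imageDim[1] - 1L, ceiling(max(ys))))
  px <- rep(cols, each = length(rows)) + 0.5
  py <- rep(rows, times = length(cols)) + 0.5
  n <- length(xs)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross)
    j <- i
  }
  cbind(row = rep(rows, times = length(cols))[inside] + 1L,
        col = rep(cols, each = length(rows))[inside] + 1L)
}

#' Read a single ImageJ .roi record
#'
#' Supports rectangle, oval and polygon/freehand outlines, rasterized to a
#' pixel mask.
#'
#' @param path path to a .roi file (or a raw vector)
#' @param imageDim image dimensions c(rows, cols) used to clip the mask
#' @return list(type, box = c(top, left, bottom, right), mask) where mask is
#'   a (row, col) matrix of 1-based pixel indices
#' @export
readImageJRoi <- function(path, imageDim) {
  bytes <- if (is.raw(path)) path else readBin(path, "raw", file.size(path))
  if (length(bytes) < 64L || !identical(bytes[1:4], ROI_MAGIC))
    stop("format error: not an ImageJ ROI record")
  u16 <- function(off) readBin(bytes[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = "big")
  s16 <- function(off) readBin(bytes[(off + 1):(off + 2)], "integer",
                               size = 2, signed = TRUE, endian = "big")
  type <- as.integer(bytes[7])
  top <- s16(8); left <- s16(10); bottom <- s16(12); right <- s16(14)
  nC <- u16(16)
  if (type == 1L) {
    mask <- rectMaskFromBox(top, left, bottom, right, imageDim)
    typeName <- "rect"
  } else if (type == 2L) {
    mask <- ovalMaskFromBox(top, left, bottom, right, imageDim)
    typeName <- "oval"
  } else if (type %in% c(0L, 7L, 8L)) {
    if (nC < 3L) stop("format error: polygon ROI with < 3 points")
    xs <- vapply(seq_len(nC), function(i) s16(64 + 2 * (i - 1)), numeric(1)) + left
    ys <- vapply(seq_len(nC), function(i) s16(64 + 2 * nC + 2 * (i - 1)),
                 numeric(1)) + top
    mask <- polygonMask(xs, ys, imageDim)
    typeName <- "polygon"
  } else {
    stop(sprintf("format error: unsupported ROI type %d", type))
  }
  list(type = typeName, box = c(top = top, left = left, bottom = bottom,
                                right = right), mask = mask)
}

#' Write a single ImageJ .roi record
#'
#' @param box bounding box c(top, left, bottom, right) in 0-based ImageJ
#'   pixel coordinates
#' @param type "oval", "rect" or "polygon"
#' @param coords for polygons, a two-column (x, y) matrix of absolute
#'   0-based vertex coordinates
#' @param path output file
#' @return invisibly, the raw record
#' @export
writeImageJRoi <- function(box, type = c("oval", "rect", "polygon"),
                           coords = NULL, path = NULL) {
  type <- match.arg(type)
  typeCode <- c(oval = 2L, rect = 1L, polygon = 0L)[[type]]
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(ROI_MAGIC, con)
  writeBin(228L, con, size = 2, endian = "big")          # version
  writeBin(as.raw(c(typeCode, 0L)), con)                 # type + pad
  writeBin(as.integer(box[c("top", "left", "bottom", "right")]), con,
           size = 2, endian = "big")
  nC <- if (is.null(coords)) 0L else nrow(coords)
  writeBin(nC, con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)                            # rest of header
  if (nC > 0L) {
    writeBin(as.integer(round(coords[, 1] - box[["left"]])), con, size = 2,
             endian = "big")
    writeBin(as.integer(round(coords[, 2] - box[["top"]])), con, size = 2,
             endian = "big")
  }
  rec <- rawConnectionValue(con)
  if (!is.null(path)) writeBin(rec, path)
  invisible(rec)
}

## ---- minimal ZIP (stored entries) ----

# R's bitwShiftR is a logical shift on the 32-bit pattern, which is exactly
# what the reflected CRC-32 (polynomial 0xEDB88320, here as signed
# -306674912L) requires.
crc32Table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(c, 1))
          else bitwShiftR(c, 1)
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32Table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8), tab[idx + 1])
  }
  bitwXor(crc, -1L)
}

u32raw <- function(x) {
  # little-endian raw4 from a (possibly negative) 32-bit integer
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}
u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

# Write a zip archive with stored (uncompressed) entries; fixed timestamps
# keep the output byte-deterministic.
writeStoredZip <- function(entries, path) {
  offs <- integer(0)
  body <- raw(0)
  central <- raw(0)
  for (nm in names(entries)) {
    data <- entries[[nm]]
    fname <- charToRaw(nm)
    crc <- crc32(data)
    offs <- c(offs, length(body))
    local <- c(u32raw(0x04034b50), u16raw(20), u16raw(0), u16raw(0),
               u16raw(0), u16raw(0x21), u32raw(crc), u32raw(length(data)),
               u32raw(length(data)), u16raw(length(fname)), u16raw(0),
               fname, data)
    body <- c(body, local)
    central <- c(central, u32raw(0x02014b50), u16raw(20), u16raw(20),
                 u16raw(0), u16raw(0), u16raw(0), u16raw(0x21), u32raw(crc),
                 u32raw(length(data)), u32raw(length(data)),
                 u16raw(length(fname)), u16raw(0), u16raw(0), u16raw(0),
                 u16raw(0), u32raw(0), u32raw(offs[length(offs)]), fname)
  }
  eocd <- c(u32raw(0x06054b50), u16raw(0), u16raw(0),
            u16raw(length(entries)), u16raw(length(entries)),
            u32raw(length(central)), u32raw(length(body)), u16raw(0))
  writeBin(c(body, central, eocd), path)
  invisible(path)
}

#' Write an RoiSet as an ImageJ ROI zip archive
#'
#' Disk-shaped masks are stored as oval records; anything else as a polygon
#' over the mask's convex outline is not attempted — non-oval sets must
#' provide a bounding box-faithful mask, and are stored as rectangles when
#' the mask fills its bounding box, polygons otherwise (traced outline of
#' the mask boundary).
#'
#' @param rois a [RoiSet] whose masks came from oval/rect rasterization
#' @param path output .zip path
#' @return invisibly, \code{path}
#' @export
writeRoiZip <- function(rois, path) {
  stopifnot(is(rois, "RoiSet"))
  entries <- list()
  for (i in seq_along(rois@cellIds)) {
    m <- rois@masks[[i]]
    top <- min(m[, 1]) - 1L; bottom <- max(m[, 1])
    left <- min(m[, 2]) - 1L; right <- max(m[, 2])
    box <- c(top = top, left = left, bottom = bottom, right = right)
    ov <- ovalMaskFromBox(top, left, bottom, right, rois@imageDim)
    type <- if (nrow(ov) == nrow(m) &&
                all(ov[order(ov[, 1], ov[, 2]), ] ==
                    m[order(m[, 1], m[, 2]), ])) "oval" else "rect"
    entries[[paste0(rois@cellIds[i], ".roi")]] <-
      writeImageJRoi(box, type = type)
  }
  writeStoredZip(entries, path)
  invisible(path)
}

#' Read an ImageJ ROI zip archive into an RoiSet
#'
#' @param path .zip archive of .roi records
#' @param imageDim image dimensions c(rows, cols); masks beyond the bounds
#'   are clipped with a warning
#' @param pixelSizeUm microns per pixel (default 1)
#' @param compartments optional per-cell labels ("module"/"matrix"),
#'   recycled "unknown" if absent
#' @return a [RoiSet]
#' @export
readRoiZip <- function(path, imageDim, pixelSizeUm = 1,
                       compartments = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- tryCatch(utils::unzip(path, exdir = exdir),
                    error = function(e) character(0),
                    warning = function(w) character(0))
  files <- sort(files[grepl("\\.roi$", files)])
  if (!length(files)) stop("format error: empty or unreadable ROI archive")
  ids <- sub("\\.roi$", "", basename(files))
  maskList <- vector("list", length(files))
  for (i in seq_along(files)) {
    roi <- readImageJRoi(files[i], imageDim)
    box <- roi$box
    if (box["top"] < 0 || box["left"] < 0 ||
        box["bottom"] > imageDim[1] || box["right"] > imageDim[2])
      warning(sprintf("ROI '%s' extends beyond image bounds; clipped", ids[i]))
    if (nrow(roi$mask) == 0L)
      stop(sprintf("format error: ROI '%s' is empty after clipping", ids[i]))
    maskList[[i]] <- roi$mask
  }
  if (is.null(compartments)) compartments <- rep("unknown", length(ids))
  new("RoiSet", cellIds = ids, masks = maskList,
      compartments = as.character(compartments),
      pixelSizeUm = pixelSizeUm, imageDim = as.integer(imageDim))
}

#' Load ROIs from an ImageJ zip archive or a labeled-mask TIFF
#'
#' For a labeled mask, each distinct non-zero pixel value is one cell.
#'
#' @param path .zip archive or labeled-mask .tif
#' @param imageDim image dimensions (required for .zip; inferred for TIFF)
#' @inheritParams readRoiZip
#' @return a [RoiSet]
#' @export
loadRois <- function(path, imageDim = NULL, pixelSizeUm = 1,
                     compartments = NULL) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    if (is.null(imageDim))
      stop("imageDim is required when reading an ROI zip archive")
    return(readRoiZip(path, imageDim, pixelSizeUm, compartments))
  }
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labels <- sort(setdiff(unique(as.vector(img)), 0))
  if (!length(labels)) stop("format error: labeled mask contains no cells")
  maskList <- lapply(labels, function(l) which(img == l, arr.ind = TRUE)[, 1:2,
                                                                          drop = FALSE])
  ids <- sprintf("cell_%03d", seq_along(labels))
  if (is.null(compartments)) compartments <- rep("unknown", length(ids))
  new("RoiSet", cellIds = ids, masks = maskList,
      compartments = as.character(compartments),
      pixelSizeUm = pixelSizeUm, imageDim = as.integer(dim(img)[1:2]))
}
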