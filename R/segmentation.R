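# thin wrappers around EBImage keep the rest of the package matrix-typed
as_img <- function(m) EBImage::Image(m)
img_data <- function(x) {
  d <- EBImage::imageData(x)
  dim(d) <- dim(d)[1:2]
  d
}
disc_brush <- function(r) EBImage::makeBrush(2 * as.integer(r) + 1, "disc")

dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  img_data(EBImage::dilate(as_img(mask * 1), disc_brush(r))) > 0.5
}
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  img_data(EBImage::erode(as_img(mask * 1), disc_brush(r))) > 0.5
}

#' Segment nuclei from the DNA channel
#'
#' Global Otsu threshold, hole filling, and a distance-transform watershed
#' to split touching nuclei; objects below the minimum area or touching
#' the image border (under the default `exclude` policy) are removed.
#'
#' @param dna 2-D numeric matrix (DNA / DAPI channel).
#' @param pixel_size micrometres per pixel (converts the area cutoff).
#' @param params a [quant_params()].
#' @return integer label matrix (0 = background, 1..K = nuclei); an
#'   all-zero input yields an all-zero matrix, not an error.
#' @export
segment_nuclei <- function(dna, pixel_size = 0.1, params = quant_params()) {
  stopifnot(is.matrix(dna), length(dna) > 0)
  out0 <- matrix(0L, nrow(dna), ncol(dna))
  if (max(dna) <= 0) return(out0)
  rng <- range(dna)
  if (diff(rng) < 1e-12) return(out0)
  thr <- EBImage::otsu(as_img(dna), range = rng)
  mask <- dna > thr
  if (!any(mask)) return(out0)
  mask <- img_data(EBImage::fillHull(as_img(mask * 1))) > 0.5
  dm <- EBImage::distmap(as_img(mask * 1))
  labels <- img_data(EBImage::watershed(dm,
                                        tolerance = params$watershed_tolerance_px,
                                        ext = 1))
  labels <- prune_labels(labels,
                         min_area = params$min_nucleus_area_um2 / pixel_size^2,
                         drop_border = params$border_policy == "exclude")
  labels
}

# drop small / border-touching objects, relabel 1..K preserving order
prune_labels <- function(labels, min_area = 0, drop_border = FALSE) {
  labs <- as.integer(labels)
  k <- max(labs)
  if (k == 0) return(matrix(0L, nrow(labels), ncol(labels)))
  areas <- tabulate(labs, nbins = k)
  keep <- areas >= min_area & areas > 0
  if (drop_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    keep[intersect(border[border > 0], seq_len(k))] <- FALSE
  }
  remap <- integer(k)
  remap[keep] <- seq_len(sum(keep))
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labs > 0
  out[nz] <- remap[labs[nz]]
  out
}

#' Centroids and areas of labeled objects
#'
#' @param labels integer label matrix.
#' @param pixel_size micrometres per pixel.
#' @return tibble with `label`, `row`, `col` (centroid, pixels),
#'   `area_px`, `area_um2`.
#' @export
mask_centroids <- function(labels, pixel_size = 0.1) {
  k <- max(labels)
  if (k == 0) {
    return(tibble(label = integer(0), row = numeric(0), col = numeric(0),
                  area_px = integer(0), area_um2 = numeric(0)))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  rows <- tapply(idx[, 1], lab, mean)
  cols <- tapply(idx[, 2], lab, mean)
  areas <- tabulate(lab, nbins = k)
  present <- sort(unique(lab))
  tibble(label = as.integer(present),
         row = as.numeric(rows[as.character(present)]),
         col = as.numeric(cols[as.character(present)]),
         area_px = areas[present],
         area_um2 = areas[present] * pixel_size^2)
}

#' Segment NPM1-positive nucleoli within one nucleus
#'
#' Otsu threshold computed on the in-nucleus NPM1 intensities only, then
#' connected components of at least the minimum size.  A nucleus with no
#' NPM1 contrast (near-uniform signal) yields zero nucleoli, which
#' downstream marks the cell as lacking an NPM1-positive nucleolus.
#'
#' @param npm1 2-D numeric matrix (NPM1 channel, may be a cropped window).
#' @param nucleus logical matrix of the same shape (the nucleus mask).
#' @param params a [quant_params()].
#' @return integer label matrix of nucleoli (possibly all zero).
#' @export
segment_nucleoli <- function(npm1, nucleus, params = quant_params()) {
  stopifnot(is.matrix(npm1), identical(dim(npm1), dim(nucleus)))
  if (!any(nucleus)) abort("segment_nucleoli: empty nucleus mask.")
  v <- npm1[nucleus]
  if (diff(range(v)) < 0.02) {
    return(matrix(0L, nrow(npm1), ncol(npm1)))
  }
  thr <- EBImage::otsu(as_img(matrix(v, nrow = 1)), range = range(v))
  mask <- npm1 > thr & nucleus
  labels <- img_data(EBImage::bwlabel(as_img(mask * 1)))
  prune_labels(labels, min_area = params$min_nucleolus_area_px)
}
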