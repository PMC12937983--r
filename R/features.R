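#' Detect nucleolar-cap segments on one nucleolus
#'
#' Within an annular band around the nucleolus boundary (boundary +/-
#' `rim_width_px`), fibrillarin-positive pixels (above `median + mad_k *
#' MAD` of the in-nucleus fibrillarin intensities) are grouped into
#' connected segments.  A segment qualifies as a cap when its mean
#' fibrillarin intensity is at least `enrichment_ratio` times the
#' nucleoplasmic mean — the operational form of "peripheral accumulation
#' of FBL at NPM1-positive nucleoli".
#'
#' @param fbl 2-D numeric matrix (fibrillarin channel, may be cropped).
#' @param nucleolus logical mask of the nucleolus under test.
#' @param nucleus logical mask of the parent nucleus (same shape).
#' @param nucleoli_all logical mask of all nucleoli of this nucleus (used
#'   to define the nucleoplasm); defaults to `nucleolus`.
#' @param pixel_size micrometres per pixel.
#' @param params a [quant_params()].
#' @return tibble of segments: `segment`, `area_px`, `area_um2`,
#'   `mean_fbl`, `is_cap`; attribute `rim_degenerate` is `TRUE` when the
#'   rim band is empty (nucleolus flush with the nucleus edge).
#' @export
detect_caps <- function(fbl, nucleolus, nucleus, nucleoli_all = nucleolus,
                        pixel_size = 0.1, params = quant_params()) {
  stopifnot(is.matrix(fbl), identical(dim(fbl), dim(nucleolus)),
            identical(dim(fbl), dim(nucleus)))
  if (!any(nucleolus)) abort("detect_caps: empty nucleolus mask.")
  band <- dilate_mask(nucleolus, params$rim_width_px) &
    !erode_mask(nucleolus, params$rim_width_px) & nucleus
  empty_band <- !any(band)
  if (empty_band) {
    warn("detect_caps: rim band is empty (nucleolus at the nucleus edge).")
  }
  v <- fbl[nucleus]
  thr <- median(v) + params$mad_k * mad(v)
  pos <- fbl > thr & band
  labels <- img_data(EBImage::bwlabel(as_img(pos * 1)))
  nucleoplasm <- nucleus & !dilate_mask(nucleoli_all, params$exclusion_dilation_px)
  np_mean <- if (any(nucleoplasm)) mean(fbl[nucleoplasm]) else 0
  # enrichment cutoff; an infinite ratio must suppress caps even on a
  # zero-background nucleoplasm (Inf * 0 is NaN)
  cap_cut <- params$enrichment_ratio * np_mean
  if (is.nan(cap_cut)) cap_cut <- Inf
  k <- max(labels)
  if (k == 0) {
    segs <- tibble(segment = integer(0), area_px = integer(0),
                   area_um2 = numeric(0), mean_fbl = numeric(0),
                   is_cap = logical(0))
  } else {
    areas <- tabulate(as.integer(labels), nbins = k)
    means <- vapply(seq_len(k), function(j) mean(fbl[labels == j]), numeric(1))
    segs <- tibble(segment = seq_len(k), area_px = areas,
                   area_um2 = areas * pixel_size^2, mean_fbl = means,
                   is_cap = areas >= params$min_cap_area_px &
                     means >= cap_cut)
  }
  attr(segs, "rim_degenerate") <- empty_band
  attr(segs, "nucleoplasmic_mean") <- np_mean
  segs
}

# scale-normalized Laplacian-of-Gaussian kernel (zero-sum); the negated
# response is maximal at the centre of a bright blob of matching sigma.
log_kernel <- function(sigma) {
  rad <- ceiling(3.5 * sigma)
  x <- -rad:rad
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  r2 <- outer(x^2, x^2, "+")
  k <- (r2 - 2 * sigma^2) / (2 * pi * sigma^4) * g
  k - mean(k)
}

shift_mat <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Detect nucleoplasmic fibrillarin foci
#'
#' Multi-scale Laplacian-of-Gaussian spot detection restricted to the
#' nucleoplasm (nucleus minus nucleoli dilated by
#' `exclusion_dilation_px`).  A focus is a strict local maximum of the
#' scale-maximal LoG response exceeding both the robust in-nucleus
#' response threshold (`median + mad_k * MAD`) and the absolute
#' `min_prominence` floor.
#'
#' @param fbl 2-D numeric matrix (fibrillarin channel, may be cropped).
#' @param nucleus logical nucleus mask (same shape).
#' @param nucleoli logical mask of all nucleoli (same shape).
#' @param params a [quant_params()].
#' @return tibble of foci: `row`, `col` (pixel coordinates in the input
#'   matrix), `response`, `intensity`.
#' @export
detect_nucleoplasmic_foci <- function(fbl, nucleus, nucleoli,
                                      params = quant_params()) {
  stopifnot(is.matrix(fbl), identical(dim(fbl), dim(nucleus)),
            identical(dim(fbl), dim(nucleoli)))
  if (!any(nucleus)) abort("detect_nucleoplasmic_foci: empty nucleus mask.")
  region <- nucleus & !dilate_mask(nucleoli, params$exclusion_dilation_px)
  if (!any(region)) {
    return(tibble(row = integer(0), col = integer(0),
                  response = numeric(0), intensity = numeric(0)))
  }
  sigmas <- seq(params$log_sigma_px[1], params$log_sigma_px[2],
                by = params$log_sigma_step_px)
  resp <- matrix(-Inf, nrow(fbl), ncol(fbl))
  for (s in sigmas) {
    r <- -img_data(EBImage::filter2(as_img(fbl), log_kernel(s),
                                    boundary = "replicate"))
    resp <- pmax(resp, r)
  }
  rn <- resp[nucleus]
  thr <- max(params$min_prominence, median(rn) + params$mad_k * mad(rn))
  is_max <- matrix(TRUE, nrow(resp), ncol(resp))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (resp > shift_mat(resp, dr, dc))
  }
  sel <- which(is_max & region & resp > thr, arr.ind = TRUE)
  tibble(row = as.integer(sel[, 1]), col = as.integer(sel[, 2]),
         response = resp[sel], intensity = fbl[sel])
}

#' Extract an intensity line profile
#'
#' Bilinear sampling along the segment from `p0` to `p1` at approximately
#' 1-pixel steps; each channel is additionally normalized to its maximum
#' along the line (an all-zero channel stays all zero).
#'
#' @param field a [fluor_field()].
#' @param p0,p1 numeric `c(row, col)` endpoints (pixels, inside the
#'   raster); a zero-length segment is an error.
#' @param channels channel names to sample (default: all).
#' @param step sampling step in pixels.
#' @return tibble of class `line_profile`: `channel`, `distance_px`,
#'   `distance_um`, `intensity`, `normalized`.
#' @export
extract_line_profile <- function(field, p0, p1, channels = NULL, step = 1) {
  stopifnot(inherits(field, "fluor_field"), length(p0) == 2, length(p1) == 2)
  d <- dim(field$channels[[1]])
  if (any(c(p0, p1) < 1) || p0[1] > d[1] || p1[1] > d[1] ||
      p0[2] > d[2] || p1[2] > d[2]) {
    abort("line profile endpoints must lie inside the raster.")
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) abort("zero-length profile segment.")
  channels <- channels %||% names(field$channels)
  missing_ch <- setdiff(channels, names(field$channels))
  if (length(missing_ch)) {
    abort(sprintf("unknown channel(s): %s", paste(missing_ch, collapse = ", ")))
  }
  n <- max(2L, floor(len / step) + 1L)
  t <- seq(0, 1, length.out = n)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  sample_one <- function(m) {
    r0 <- pmin(pmax(floor(rr), 1), nrow(m) - 1)
    c0 <- pmin(pmax(floor(cc), 1), ncol(m) - 1)
    fr <- rr - r0; fc <- cc - c0
    m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      m[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  out <- purrr::map_dfr(channels, function(ch) {
    v <- sample_one(field$channels[[ch]])
    mx <- max(v)
    tibble(channel = ch, distance_px = t * len,
           distance_um = t * len * field$pixel_size,
           intensity = v,
           normalized = if (mx > 0) v / mx else v * 0)
  })
  class(out) <- c("line_profile", class(out))
  out
}

#' Fraction of foci apposed to a second focus population
#'
#' Fraction of foci in `foci_a` whose nearest neighbour in `foci_b` lies
#' within `d_um` — a distance-threshold operationalization of the "closely
#' apposed / partial overlap" readout of two-channel focus imaging.
#'
#' @param foci_a,foci_b tibbles with pixel columns `row`, `col`.
#' @param d_um distance threshold in micrometres (> 0).
#' @param pixel_size micrometres per pixel.
#' @return fraction in [0, 1]; `0` with attribute `empty_a = TRUE` when
#'   `foci_a` is empty.
#' @export
proximity_fraction <- function(foci_a, foci_b, d_um, pixel_size = 0.1) {
  stopifnot(d_um > 0)
  a <- tibble::as_tibble(foci_a); b <- tibble::as_tibble(foci_b)
  if (nrow(a) == 0) {
    return(structure(0, empty_a = TRUE))
  }
  if (nrow(b) == 0) return(0)
  d2 <- outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2
  nearest <- sqrt(apply(d2, 1, min)) * pixel_size
  mean(nearest <= d_um)
}
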