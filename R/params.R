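#' Quantification parameters
#'
#' Bundle of the tunable thresholds used by the imaging pipeline.  All
#' length units are micrometres unless the name says pixels (`_px`).
#'
#' @param min_nucleus_area_um2 nuclei smaller than this are discarded
#'   during segmentation (debris, mitotic fragments).
#' @param min_nucleolus_area_px minimum connected-component size for an
#'   NPM1-positive nucleolus, in pixels.
#' @param rim_width_px half-width of the annular band around each
#'   nucleolus boundary inside which cap segments are sought.
#' @param exclusion_dilation_px nucleoli are dilated by this many pixels
#'   before being excluded from the nucleoplasmic focus-search region.
#' @param mad_k fibrillarin-positive pixels are those above
#'   `median + mad_k * MAD` of the in-nucleus fibrillarin intensities.
#' @param enrichment_ratio a rim segment counts as a nucleolar cap only if
#'   its mean fibrillarin intensity is at least this multiple of the
#'   nucleoplasmic mean.
#' @param min_cap_area_px minimum pixel area for a rim segment to qualify
#'   as a cap; rejects single-pixel noise speckle (real caps span
#'   hundreds of pixels at 0.1 um/px).
#' @param log_sigma_px range of Laplacian-of-Gaussian scales (pixels) used
#'   for nucleoplasmic focus detection; spans the expected focus radii.
#' @param log_sigma_step_px spacing of the LoG scale grid.
#' @param min_prominence absolute floor on the LoG response of a reported
#'   focus, on the [0, 1] working intensity scale; rejects shallow texture
#'   when the robust (MAD-based) threshold degenerates on clean images.
#' @param foci_threshold number of nucleoplasmic fibrillarin foci at and
#'   above which a cell is scored nucleoplasmic-FBL positive.
#' @param watershed_tolerance_px minimum distance-map depth separating two
#'   watershed seeds for touching nuclei to be split.
#' @param border_policy `"exclude"` drops nuclei touching the image
#'   border; `"keep"` retains them.
#'
#' @return a named list of class `quant_params`.
#' @export
quant_params <- function(min_nucleus_area_um2 = 20,
                         min_nucleolus_area_px = 20,
                         rim_width_px = 3,
                         exclusion_dilation_px = 2,
                         mad_k = 3,
                         enrichment_ratio = 1.5,
                         min_cap_area_px = 5,
                         log_sigma_px = c(1.5, 4),
                         log_sigma_step_px = 0.5,
                         min_prominence = 0.1,
                         foci_threshold = 5L,
                         watershed_tolerance_px = 3,
                         border_policy = c("exclude", "keep")) {
  border_policy <- match.arg(border_policy)
  stopifnot(min_nucleus_area_um2 > 0, rim_width_px >= 1,
            exclusion_dilation_px >= 0, mad_k > 0, enrichment_ratio > 0,
            length(log_sigma_px) == 2, all(log_sigma_px > 0),
            foci_threshold >= 1)
  structure(list(
    min_nucleus_area_um2 = min_nucleus_area_um2,
    min_nucleolus_area_px = min_nucleolus_area_px,
    rim_width_px = rim_width_px,
    exclusion_dilation_px = exclusion_dilation_px,
    mad_k = mad_k,
    enrichment_ratio = enrichment_ratio,
    min_cap_area_px = min_cap_area_px,
    log_sigma_px = log_sigma_px,
    log_sigma_step_px = log_sigma_step_px,
    min_prominence = min_prominence,
    foci_threshold = as.integer(foci_threshold),
    watershed_tolerance_px = watershed_tolerance_px,
    border_policy = border_policy
  ), class = "quant_params")
}

#' Noise model for synthetic fields
#'
#' @param gaussian_sd standard deviation of additive Gaussian read noise on
#'   the [0, 1] intensity scale.
#' @param poisson_scale photon-count scaling for shot noise: each pixel is
#'   replaced by `rpois(intensity * poisson_scale) / poisson_scale`.  `0`
#'   disables shot noise.
#' @param psf_sigma sigma (pixels) of the Gaussian blur emulating the
#'   microscope point-spread function.  `0` disables blurring.
#' @param background camera baseline added after shot noise, on the [0, 1]
#'   intensity scale; keeps the background off the zero clip so robust
#'   (median/MAD) statistics stay meaningful.
#'
#' @return named list of class `noise_params`.
#' @export
noise_params <- function(gaussian_sd = 0.01, poisson_scale = 500,
                         psf_sigma = 0.8, background = 0.05) {
  stopifnot(gaussian_sd >= 0, poisson_scale >= 0, psf_sigma >= 0,
            background >= 0)
  structure(list(gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 psf_sigma = psf_sigma, background = background),
            class = "noise_params")
}

as_noise_params <- function(noise) {
  if (inherits(noise, "noise_params")) return(noise)
  if (is.numeric(noise) && length(noise) == 1 && noise == 0) {
    return(noise_params(0, 0, 0, 0))
  }
  if (is.list(noise)) return(do.call(noise_params, noise))
  abort("`noise` must be noise_params(), a list of its fields, or 0.")
}
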