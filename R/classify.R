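#' Quantify every cell in a field
#'
#' Runs the full per-cell pipeline: nucleus segmentation on the DNA
#' channel, NPM1 nucleolus segmentation, cap detection on each nucleolus,
#' nucleoplasmic focus detection, intensity summaries, and rule-based
#' classification.  A cell is cap-positive when any nucleolus carries a
#' qualifying cap segment and the nucleolar fibrillarin mean is at least
#' the nucleoplasmic mean; nucleoplasmic-FBL positive when its focus
#' count reaches `params$foci_threshold` (>= 5 by default).
#'
#' @param field a [fluor_field()] with channels `dna`, `npm1`, `fbl`.
#' @param params a [quant_params()].
#' @return tibble, one row per cell: centroid and area, `n_nucleoli`,
#'   `has_npm1_nucleolus`, `n_cap_segments`, `cap_area_um2`, `n_foci`,
#'   `fbl_nucleolar_mean`, `fbl_nucleoplasmic_mean`, the two labels, and a
#'   `foci` list-column of per-cell focus coordinates (global pixels).
#'   Attributes: `nucleus_labels` (the label raster), `params`,
#'   `sample_id`.
#' @export
quantify_field <- function(field, params = quant_params()) {
  stopifnot(inherits(field, "fluor_field"))
  need <- c("dna", "npm1", "fbl")
  if (!all(need %in% names(field$channels))) {
    abort(sprintf("field must carry channels %s.", paste(need, collapse = ", ")))
  }
  px <- field$pixel_size
  labels <- segment_nuclei(field$channels$dna, px, params)
  cents <- mask_centroids(labels, px)
  margin <- params$rim_width_px + params$exclusion_dilation_px + 8L
  nr <- nrow(labels); nc <- ncol(labels)
  rows <- vector("list", nrow(cents))
  for (i in seq_len(nrow(cents))) {
    lab <- cents$label[i]
    idx <- which(labels == lab, arr.ind = TRUE)
    wr <- max(1, min(idx[, 1]) - margin):min(nr, max(idx[, 1]) + margin)
    wc <- max(1, min(idx[, 2]) - margin):min(nc, max(idx[, 2]) + margin)
    nucleus <- labels[wr, wc] == lab
    npm1 <- field$channels$npm1[wr, wc]
    fbl <- field$channels$fbl[wr, wc]
    ncl <- segment_nucleoli(npm1, nucleus, params)
    n_nucleoli <- max(ncl)
    nucleoli_mask <- ncl > 0
    n_cap_segments <- 0L
    cap_area_um2 <- 0
    if (n_nucleoli > 0) {
      for (j in seq_len(n_nucleoli)) {
        segs <- detect_caps(fbl, ncl == j, nucleus, nucleoli_mask,
                            pixel_size = px, params = params)
        n_cap_segments <- n_cap_segments + sum(segs$is_cap)
        cap_area_um2 <- cap_area_um2 + sum(segs$area_um2[segs$is_cap])
      }
    }
    foci <- detect_nucleoplasmic_foci(fbl, nucleus, nucleoli_mask, params)
    foci$row <- foci$row + wr[1] - 1L
    foci$col <- foci$col + wc[1] - 1L
    nucleolar_region <- dilate_mask(nucleoli_mask, params$rim_width_px) & nucleus
    nucleoplasm <- nucleus &
      !dilate_mask(nucleoli_mask, params$exclusion_dilation_px)
    rows[[i]] <- tibble(
      cell_id = i,
      row = cents$row[i], col = cents$col[i],
      area_um2 = cents$area_um2[i],
      n_nucleoli = n_nucleoli,
      has_npm1_nucleolus = n_nucleoli > 0,
      n_cap_segments = as.integer(n_cap_segments),
      cap_area_um2 = cap_area_um2,
      n_foci = nrow(foci),
      fbl_nucleolar_mean = if (any(nucleolar_region))
        mean(fbl[nucleolar_region]) else 0,
      fbl_nucleoplasmic_mean = if (any(nucleoplasm))
        mean(fbl[nucleoplasm]) else 0,
      foci = list(foci))
  }
  cells <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    cell_id = integer(0), row = numeric(0), col = numeric(0),
    area_um2 = numeric(0), n_nucleoli = integer(0),
    has_npm1_nucleolus = logical(0), n_cap_segments = integer(0),
    cap_area_um2 = numeric(0), n_foci = integer(0),
    fbl_nucleolar_mean = numeric(0), fbl_nucleoplasmic_mean = numeric(0),
    foci = list())
  cells <- classify_cells(cells, params$foci_threshold)
  attr(cells, "nucleus_labels") <- labels
  attr(cells, "params") <- params
  attr(cells, "sample_id") <- field$sample_id
  cells
}

#' Classify cells from their numeric metrics
#'
#' Pure function of the numeric columns (re-classification is
#' idempotent): `cap_positive` requires at least one qualifying cap
#' segment, nucleolar fibrillarin mean at least the nucleoplasmic mean,
#' and an NPM1-positive nucleolus; `nucleoplasmic_fbl_positive` requires
#' at least `foci_threshold` nucleoplasmic foci.  Cells without an
#' NPM1-positive nucleolus keep their labels for audit but are excluded
#' from proportions by [summarize_sample()].
#'
#' @param cells tibble from [quantify_field()] (or any table with columns
#'   `n_cap_segments`, `fbl_nucleolar_mean`, `fbl_nucleoplasmic_mean`,
#'   `has_npm1_nucleolus`, `n_foci`).
#' @param foci_threshold positivity cutoff on the focus count (default 5).
#' @return `cells` with logical columns `cap_positive` and
#'   `nucleoplasmic_fbl_positive` (re)computed.
#' @export
classify_cells <- function(cells, foci_threshold = 5L) {
  mutate(cells,
         cap_positive = .data$n_cap_segments >= 1L &
           .data$fbl_nucleolar_mean >= .data$fbl_nucleoplasmic_mean &
           .data$has_npm1_nucleolus,
         nucleoplasmic_fbl_positive = .data$n_foci >= foci_threshold)
}

#' Per-sample summary of classified cells
#'
#' Proportions are computed over cells with an NPM1-positive nucleolus
#' only, matching the scoring population used for cap / focus
#' quantification.
#'
#' @param cells classified cell table ([quantify_field()] output).
#' @param replicate_id label recorded in the summary row.
#' @param sample_id label used in error messages; defaults to the
#'   `sample_id` attribute of `cells` if present.
#' @return one-row tibble: `replicate_id`, `n_cells_scored`,
#'   `prop_cap_positive`, `prop_nucleoplasmic_fbl_positive`,
#'   `mean_cap_area_um2`.
#' @export
summarize_sample <- function(cells, replicate_id = "rep1", sample_id = NULL) {
  sample_id <- sample_id %||% attr(cells, "sample_id") %||% "sample"
  scored <- filter(cells, .data$has_npm1_nucleolus)
  if (nrow(scored) == 0) {
    abort(sprintf("sample '%s': no scorable cells (none with an NPM1-positive nucleolus).",
                  sample_id))
  }
  tibble(replicate_id = replicate_id,
         n_cells_scored = nrow(scored),
         prop_cap_positive = mean(scored$cap_positive),
         prop_nucleoplasmic_fbl_positive =
           mean(scored$nucleoplasmic_fbl_positive),
         mean_cap_area_um2 = mean(scored$cap_area_um2))
}

#' Mean and SD across replicate summaries
#'
#' @param summaries row-bound [summarize_sample()] outputs (>= 1 row).
#' @return tibble with one row per metric: `metric`, `mean`, `sd`
#'   (sample SD, n - 1 denominator; `NA` for a single replicate),
#'   `n_replicates`.
#' @export
summarize_replicates <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  metrics <- c("prop_cap_positive", "prop_nucleoplasmic_fbl_positive",
               "mean_cap_area_um2")
  purrr::map_dfr(metrics, function(mcol) {
    v <- summaries[[mcol]]
    tibble(metric = mcol, mean = mean(v),
           sd = if (length(v) > 1) sd(v) else NA_real_,
           n_replicates = length(v))
  })
}

#' Match quantified cells to a generator truth table
#'
#' Joins each segmented cell to the nearest truth centroid (within
#' `max_dist_px`), attaching the true phenotype and counts — the basis of
#' planted-truth recovery checks.
#'
#' @param cells [quantify_field()] output.
#' @param truth truth tibble from [generate_field()].
#' @param max_dist_px maximum centroid distance for a match.
#' @return `cells` with columns `true_phenotype`, `true_n_foci`,
#'   `true_cap_area_um2`, `true_n_caps` (NA where unmatched).
#' @export
match_truth <- function(cells, truth, max_dist_px = 15) {
  if (nrow(cells) == 0) {
    cells$true_phenotype <- character(0)
    cells$true_n_foci <- integer(0)
    cells$true_cap_area_um2 <- numeric(0)
    cells$true_n_caps <- integer(0)
    return(cells)
  }
  d2 <- outer(cells$row, truth$row, "-")^2 + outer(cells$col, truth$col, "-")^2
  nearest <- apply(d2, 1, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(cells)), nearest)])
  ok <- dist <= max_dist_px
  cells$true_phenotype <- ifelse(ok, truth$phenotype[nearest], NA_character_)
  cells$true_n_foci <- ifelse(ok, truth$n_foci[nearest], NA_integer_)
  cells$true_cap_area_um2 <- ifelse(ok, truth$cap_area_um2[nearest], NA_real_)
  cells$true_n_caps <- ifelse(ok, truth$n_caps[nearest], NA_integer_)
  cells
}

#' Expected labels implied by a truth table
#'
#' @param truth truth tibble from [generate_field()].
#' @param foci_threshold positivity cutoff (default 5).
#' @return `truth` with logical columns `cap_positive` (phenotype is
#'   cap_positive) and `nucleoplasmic_fbl_positive` (true focus count >=
#'   threshold).
#' @export
truth_labels <- function(truth, foci_threshold = 5L) {
  mutate(truth,
         cap_positive = .data$phenotype == "cap_positive",
         nucleoplasmic_fbl_positive = .data$n_foci >= foci_threshold)
}
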