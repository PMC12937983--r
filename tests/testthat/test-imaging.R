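test_that("nucleus segmentation handles blank input and recovers planted nuclei", {
  expect_equal(max(segment_nuclei(matrix(0, 50, 50))), 0)
  g <- small_field()
  labels <- segment_nuclei(g$field$channels$dna, g$field$pixel_size)
  cents <- mask_centroids(labels, g$field$pixel_size)
  expect_equal(nrow(cents), nrow(g$truth))
  # each truth centroid has a segmented centroid within 2 px
  d <- sqrt(outer(g$truth$row, cents$row, "-")^2 +
              outer(g$truth$col, cents$col, "-")^2)
  expect_true(all(apply(d, 1, min) <= 2))
})

test_that("distance-transform watershed splits two touching nuclei", {
  m <- matrix(0, 120, 200)
  for (ctr in list(c(60, 70), c(60, 130))) {
    idx <- which(((row(m) - ctr[1]) / 30)^2 + ((col(m) - ctr[2]) / 35)^2 <= 1)
    m[idx] <- 0.6
  }
  labels <- segment_nuclei(m, pixel_size = 0.1)
  expect_equal(max(labels), 2)
})

test_that("nucleolus segmentation matches truth on intact cells and rejects flat signal", {
  g <- small_field()
  cells <- quantify_field(g$field)
  m <- match_truth(cells, g$truth)
  intact <- m[m$true_phenotype == "intact", ]
  d <- sqrt(outer(intact$row, g$truth$row, "-")^2 +
              outer(intact$col, g$truth$col, "-")^2)
  truth_n <- g$truth$n_nucleoli[apply(d, 1, which.min)]
  expect_equal(intact$n_nucleoli, truth_n)
  # uniform NPM1 inside the nucleus -> no nucleoli
  nuc <- matrix(FALSE, 40, 40); nuc[10:30, 10:30] <- TRUE
  flat <- matrix(0.5, 40, 40)
  expect_equal(max(segment_nucleoli(flat, nuc)), 0)
})

test_that("cap detection recovers planted cap area and respects the enrichment limit", {
  g <- small_field()
  cells <- quantify_field(g$field)
  m <- match_truth(cells, g$truth)
  pos <- m[m$true_phenotype == "cap_positive", ]
  expect_true(nrow(pos) >= 1)
  expect_true(all(abs(pos$cap_area_um2 - pos$true_cap_area_um2) <=
                    0.1 * pos$true_cap_area_um2))
  intact <- m[m$true_phenotype == "intact", ]
  expect_true(all(intact$n_cap_segments == 0))
  # enrichment ratio -> infinity suppresses all caps
  params_inf <- quant_params(enrichment_ratio = Inf)
  cells_inf <- quantify_field(g$field, params_inf)
  expect_true(all(cells_inf$n_cap_segments == 0))
})

test_that("focus detection counts planted foci exactly and honors the exclusion zone", {
  g <- small_field()
  cells <- quantify_field(g$field)
  m <- match_truth(cells, g$truth)
  expect_equal(m$n_foci, m$true_n_foci)
  # constructed boundary case: a spot just inside the dilated nucleolus is excluded
  n <- 80
  nucleus <- matrix(TRUE, n, n)
  nucleoli <- matrix(FALSE, n, n)
  nucleoli[which((row(nucleoli) - 40)^2 + (col(nucleoli) - 40)^2 <= 10^2)] <- TRUE
  fbl <- matrix(0, n, n)
  # centroid at distance 11 from centre: inside the 2-px dilated nucleolus
  fbl <- nucleostress:::add_gaussian_spot(fbl, 40, 51, sigma = 2, amp = 0.9)
  inside <- detect_nucleoplasmic_foci(fbl, nucleus, nucleoli)
  expect_equal(nrow(inside), 0)
  fbl2 <- matrix(0, n, n)
  fbl2 <- nucleostress:::add_gaussian_spot(fbl2, 40, 60, sigma = 2, amp = 0.9)
  outside <- detect_nucleoplasmic_foci(fbl2, nucleus, nucleoli)
  expect_equal(nrow(outside), 1)
  expect_lte(abs(outside$col - 60), 1)
})

test_that("classification is a pure, idempotent function with the >=5 focus rule", {
  base <- tibble::tibble(n_cap_segments = 0L, fbl_nucleolar_mean = 1,
                         fbl_nucleoplasmic_mean = 0, has_npm1_nucleolus = TRUE,
                         n_foci = c(0L, 4L, 5L, 9L))
  out <- classify_cells(base)
  expect_equal(out$nucleoplasmic_fbl_positive, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(classify_cells(out), classify_cells(classify_cells(out)))
  # caps present but nucleoplasmic FBL exceeds nucleolar FBL -> cap-negative
  flipped <- tibble::tibble(n_cap_segments = 2L, fbl_nucleolar_mean = 0.2,
                            fbl_nucleoplasmic_mean = 0.5,
                            has_npm1_nucleolus = TRUE, n_foci = 0L)
  expect_false(classify_cells(flipped)$cap_positive)
  # no NPM1-positive nucleolus -> never cap-positive
  nonpm <- dplyr::mutate(flipped, fbl_nucleolar_mean = 1,
                         fbl_nucleoplasmic_mean = 0, has_npm1_nucleolus = FALSE)
  expect_false(classify_cells(nonpm)$cap_positive)
})

test_that("raising the focus threshold never increases the positive proportion", {
  g <- small_field()
  cells <- quantify_field(g$field)
  props <- vapply(1:12, function(thr) {
    mean(classify_cells(cells, thr)$nucleoplasmic_fbl_positive)
  }, numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("line profiles sample and normalize correctly", {
  f <- fluor_field(list(dna = matrix(0.3, 60, 60),
                        fbl = matrix(0, 60, 60),
                        npm1 = matrix(0, 60, 60)))
  # constant channel -> all ones; all-zero channel -> all zeros
  pr <- extract_line_profile(f, c(10, 10), c(50, 50))
  expect_true(all(abs(pr$normalized[pr$channel == "dna"] - 1) < 1e-12))
  expect_true(all(pr$normalized[pr$channel == "fbl"] == 0))
  expect_equal(max(pr$normalized[pr$channel == "dna"]), 1)
  # Gaussian spot on the line peaks within 1 px of the spot centre
  spot <- matrix(0, 60, 60)
  spot <- nucleostress:::add_gaussian_spot(spot, 30, 30, sigma = 2, amp = 1)
  f2 <- fluor_field(list(dna = spot, npm1 = spot, fbl = spot))
  pr2 <- extract_line_profile(f2, c(30, 5), c(30, 55), channels = "fbl")
  peak <- pr2$distance_px[which.max(pr2$intensity)]
  expect_lte(abs((5 + peak) - 30), 1)
  expect_error(extract_line_profile(f, c(10, 10), c(10, 10)), "zero-length")
  expect_error(extract_line_profile(f, c(0, 10), c(10, 10)), "inside")
})

test_that("proximity fraction covers trivial and planted cases", {
  a <- tibble::tibble(row = c(10, 20, 30, 40), col = c(10, 20, 30, 40))
  expect_equal(proximity_fraction(a, a, d_um = 0.5), 1.0)
  empty <- a[0, ]
  expect_equal(as.numeric(proximity_fraction(a, empty, d_um = 0.5)), 0)
  pa <- proximity_fraction(empty, a, d_um = 0.5)
  expect_equal(as.numeric(pa), 0)
  expect_true(attr(pa, "empty_a"))
  # planted: half of A has a B partner within 0.5 um (5 px at 0.1 um/px)
  b <- tibble::tibble(row = c(10, 20, 100, 100), col = c(13, 17, 100, 100))
  expect_equal(proximity_fraction(a, b, d_um = 0.5, pixel_size = 0.1), 0.5)
})

test_that("sample summaries respect the NPM1-positive restriction and SD rules", {
  cells <- tibble::tibble(
    has_npm1_nucleolus = c(TRUE, TRUE, TRUE, FALSE),
    cap_positive = c(TRUE, TRUE, TRUE, FALSE),
    nucleoplasmic_fbl_positive = c(FALSE, FALSE, FALSE, TRUE),
    cap_area_um2 = c(1, 2, 3, 0))
  s <- summarize_sample(cells, "rep1")
  expect_equal(s$n_cells_scored, 3)
  expect_equal(s$prop_cap_positive, 1.0)
  expect_equal(s$prop_nucleoplasmic_fbl_positive, 0)
  none <- dplyr::mutate(cells, has_npm1_nucleolus = FALSE)
  expect_error(summarize_sample(none, sample_id = "s1"), "s1")
  # single replicate -> SD absent
  r1 <- summarize_replicates(s)
  expect_true(all(is.na(r1$sd)))
  r3 <- summarize_replicates(dplyr::bind_rows(s, s, s))
  expect_equal(r3$sd, rep(0, 3))
  expect_equal(r3$n_replicates, rep(3, 3))
})

test_that("field TIFF round-trip preserves channels and pixel size", {
  g <- generate_field(2, mixture = c(1, 0, 0), noise = 0, seed = 9)
  dir <- withr::local_tempdir()
  write_field(g$field, dir, truth = g$truth)
  back <- read_field(dir)
  expect_equal(names(back$channels), names(g$field$channels))
  expect_equal(back$pixel_size, g$field$pixel_size)
  # 16-bit quantization error only
  expect_lt(max(abs(back$channels$fbl - pmin(g$field$channels$fbl, 1))),
            1 / 65535 + 1e-9)
  expect_true(file.exists(file.path(dir, "synthetic_truth.tsv")))
})
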