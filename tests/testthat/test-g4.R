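test_that("BED loading validates, reports line numbers, and sorts", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr2\t500\t900", "chr1\t10\t20",
               "chr1\t1\t5"), path)
  bed <- load_bed(path)
  expect_equal(nrow(bed), 3)
  expect_identical(bed$start, c(1L, 10L, 500L))  # sorted within chrom order
  writeLines(c("chr1\t10\t20", "chr1\t30\t30"), path)
  expect_error(load_bed(path), "line 2")
  writeLines(c("chr1\t10\t20", "chr1\tx\t30"), path)
  expect_error(load_bed(path), "line 2")
  writeLines(c("chr1\t10"), path)
  expect_error(load_bed(path), "line 1")
})

test_that("TSS derivation is strand-aware and the upstream policy picks the 5'-most", {
  spans <- tibble::tibble(chrom = "chr1", start = c(100L, 150L, 300L),
                          end = c(200L, 260L, 400L),
                          strand = c("+", "+", "-"),
                          gene = c("GA", "GA", "GB"))
  tss_all <- load_tss(spans, tss_policy = "all")
  expect_equal(tss_all$tss[tss_all$gene == "GB"], 399L)
  expect_setequal(tss_all$tss[tss_all$gene == "GA"], c(100L, 150L))
  tss_up <- load_tss(spans, tss_policy = "most_upstream")
  expect_equal(tss_up$tss[tss_up$gene == "GA"], 100L)
  # minus-strand multi-record gene: 5'-most is the maximum coordinate
  spans2 <- tibble::tibble(chrom = "chr1", start = c(100L, 500L),
                           end = c(200L, 700L), strand = "-", gene = "GC")
  expect_equal(load_tss(spans2)$tss, 699L)
  bad <- tibble::tibble(chrom = "chr1", tss = 10L, strand = ".", gene = "G")
  expect_error(load_tss(bad), "strand")
})

test_that("promoter windows are symmetric, clipped at zero, half-open", {
  t1 <- tibble::tibble(chrom = "chr1", tss = 1000L, strand = "+", gene = "A")
  w <- promoter_window(t1, 1000)
  expect_equal(c(w$start, w$end), c(0L, 2000L))
  t2 <- tibble::tibble(chrom = "chr1", tss = 300L, strand = "-", gene = "B")
  w2 <- promoter_window(t2, 1000)
  expect_equal(c(w2$start, w2$end), c(0L, 1300L))
  # width = min(tss, flank) + flank over random TSS positions
  withr::with_seed(3, {
    tss <- sample(0:5000, 200, replace = TRUE)
    tt <- tibble::tibble(chrom = "chr1", tss = tss, strand = "+",
                         gene = sprintf("g%d", seq_along(tss)))
    ww <- promoter_window(tt, 1000)
    expect_equal(ww$end - ww$start, pmin(tss, 1000L) + 1000L)
  })
})

test_that("an interval ending exactly at the window start does not overlap", {
  tssr <- tibble::tibble(chrom = "chr1", tss = 1000L, strand = "+", gene = "A")
  # window is [0, 2000); [2000, 2100) must not hit, [1999, 2100) must
  miss <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2100L)
  hit <- tibble::tibble(chrom = "chr1", start = 1999L, end = 2100L)
  a_miss <- annotate_g4("A", tssr, list(c1 = miss))
  a_hit <- annotate_g4("A", tssr, list(c1 = hit))
  expect_false(a_miss$any_positive)
  expect_true(a_hit$any_positive)
})

test_that("planted fixture reproduces the 92/135 annotation and its fraction", {
  genes <- sprintf("GENE%03d", 1:135)
  fx <- generate_g4_fixture(genes, fraction_positive = 92 / 135,
                            n_collections = 2, seed = 3)
  ann <- annotate_g4(genes, fx$tss, fx$collections)
  expect_equal(sum(ann$any_positive), 92)
  expect_equal(attr(ann, "fraction_positive"), 92 / 135, tolerance = 1e-12)
  expect_equal(ann$any_positive, fx$truth$positive[match(ann$gene, fx$truth$gene)])
  g <- glance(ann)
  expect_equal(g$n_positive, 92)
  expect_equal(g$n_missing_tss, 0)
})

test_that("indexed overlap equals the brute-force oracle on random intervals", {
  withr::with_seed(13, {
    n_iv <- 10000
    intervals <- tibble::tibble(
      chrom = sample(paste0("chr", 1:4), n_iv, replace = TRUE),
      start = sample.int(500000, n_iv, replace = TRUE))
    intervals$end <- intervals$start + sample.int(500, n_iv, replace = TRUE)
    windows <- tibble::tibble(
      chrom = sample(paste0("chr", 1:4), 300, replace = TRUE),
      start = sample.int(500000, 300, replace = TRUE))
    windows$end <- windows$start + 2000L
    expect_identical(nucleostress:::windows_with_overlap(windows, intervals),
                     brute_force_overlap(windows, intervals))
  })
})

test_that("flank enlargement and added collections are monotone", {
  genes <- sprintf("GENE%03d", 1:60)
  fx <- generate_g4_fixture(genes, fraction_positive = 0.5,
                            n_collections = 2, seed = 8)
  flanks <- c(200, 500, 1000, 2000, 4000)
  fracs <- vapply(flanks, function(fl) {
    glance(annotate_g4(genes, fx$tss, fx$collections, flank = fl))$fraction_positive
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  # adding a collection never decreases the positive count
  one <- annotate_g4(genes, fx$tss, fx$collections[1])
  both <- annotate_g4(genes, fx$tss, fx$collections)
  expect_gte(sum(both$any_positive), sum(one$any_positive))
  # empty collections give fraction 0
  none <- annotate_g4(genes, fx$tss,
                      list(c1 = tibble::tibble(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0))))
  expect_equal(sum(none$any_positive), 0)
})

test_that("genes without a TSS are reported and excluded from the denominator", {
  genes <- c("A", "B", "C")
  tssr <- tibble::tibble(chrom = "chr1", tss = c(5000L, 9000L), strand = "+",
                         gene = c("A", "B"))
  iv <- tibble::tibble(chrom = "chr1", start = 4500L, end = 4600L)
  expect_message(ann <- annotate_g4(genes, tssr, list(c1 = iv)), "without a TSS")
  expect_equal(nrow(ann), 2)
  expect_identical(attr(ann, "missing_genes"), "C")
  expect_equal(attr(ann, "fraction_positive"), 0.5)
  # chr-prefix normalization toggle
  iv2 <- tibble::tibble(chrom = "1", start = 4500L, end = 4600L)
  expect_warning(suppressMessages(ann2 <- annotate_g4(genes, tssr, list(c1 = iv2))),
                 "chromosome")
  suppressMessages({
    ann3 <- annotate_g4(genes, tssr, list(c1 = iv2), normalize_chr = TRUE)
  })
  expect_equal(sum(ann3$any_positive), 1)
})
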