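test_that("symbol harmonization trims, uppercases, aliases, and is idempotent", {
  expect_equal(harmonize_symbols("fbl "), "FBL")
  expect_equal(harmonize_symbols(' "Npm1" '), "NPM1")
  expect_equal(harmonize_symbols("hnRNP A1", default_alias_map()), "HNRNPA1")
  x <- c(" maz", "FUS ", "hnRNP A1")
  h1 <- harmonize_symbols(x, default_alias_map())
  expect_identical(harmonize_symbols(h1, default_alias_map()), h1)
  expect_message(out <- harmonize_symbols(c("A", "  ")), "dropped 1")
  expect_identical(out, "A")
})

test_that("DEG loader filters by direction and thresholds like a row scan", {
  tbl <- tibble::tibble(
    gene_symbol = sprintf("g%02d", 1:8),
    direction = c(rep("up", 5), rep("down", 3)),
    log_fold_change = c(2, 1.2, 0.6, 3, 0.9, -2, -0.7, -1.5),
    adj_p = c(0.001, 0.2, 0.01, 0.03, 0.04, 0.001, 0.04, 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  expect_length(load_deg_table(path, "down"), 3)
  got <- load_deg_table(path, "up", lfc_threshold = 1, padj_threshold = 0.05)
  oracle <- toupper(tbl$gene_symbol[tbl$direction == "up" &
                                      abs(tbl$log_fold_change) >= 1 &
                                      tbl$adj_p <= 0.05])
  expect_setequal(got$members, oracle)
  # duplicate symbols collapse
  dup <- deg_as_gene_set(tibble::tibble(gene_symbol = c("A", "a", "A "),
                                        direction = "up"), "up")
  expect_length(dup, 1)
  # direction/sign contradictions are dropped with a warning
  expect_warning(
    clean <- deg_as_gene_set(tibble::tibble(gene_symbol = c("A", "B"),
                                            direction = c("up", "up"),
                                            log_fold_change = c(2, -2)), "up"),
    "contradicts")
  expect_identical(clean$members, "A")
  # unknown layout names expected headers
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(x = 1), bad)
  expect_error(load_deg_table(bad, "up"), "gene_symbol")
})

test_that("responsive-set algebra matches planted truth and set identities", {
  spec <- planted_set_spec(universe_size = 20000, n_a = 2000, n_b = 1500,
                           n_c = 800, n_ab = 630, n_abc = 135)
  d <- generate_deg_tables(spec, seed = 11)
  A <- deg_as_gene_set(d$tables$up_p53ko_doxo, "up", name = "A")
  B <- deg_as_gene_set(d$tables$down_fbl_kd, "down", name = "B")
  C <- deg_as_gene_set(d$tables$down_ck2a_ko, "down", name = "C")
  fr <- fbl_responsive(A, B)
  expect_length(fr, 630)
  expect_false("FBL" %in% fr$members)
  ck <- ck2a_dependent(fr, C)
  expect_length(ck, 135)
  expect_lte(length(ck), length(fr))
  # commutativity and brute-force agreement
  expect_identical(ck$members,
                   ck2a_dependent(C, fr)$members)
  brute <- sort(d$truth$C[d$truth$C %in% intersect(d$truth$A, d$truth$B)])
  expect_identical(ck$members, setdiff(brute, "FBL"))
  # disjoint inputs and absent exclusions
  expect_length(fbl_responsive(c("X1"), c("X2")), 0)
  expect_length(fbl_responsive(c("X1", "X2"), c("X2"), exclude = "ZZZ"), 1)
})

test_that("over-representation matches the hypergeometric tail oracle", {
  withr::with_seed(21, {
    universe <- sprintf("U%04d", 1:1000)
    term <- sample(universe, 100)
    # a 2x-enriched query: 40 genes, 8 expected in term at random, plant 16
    query <- c(sample(term, 16), sample(setdiff(universe, term), 24))
    res <- over_representation(query, list(planted = term, empty = character(0)),
                               universe = universe)
    planted <- res[res$term == "planted", ]
    expect_equal(planted$k, 16)
    expect_equal(planted$p,
                 hyper_tail_oracle(16, 100, 1000, 40), tolerance = 1e-12)
    expect_equal(planted$rich_factor, 16 / 100)
    # degenerate: query == term == universe -> k=m=n=N, p = 1
    res1 <- over_representation(universe, list(all = universe),
                                universe = universe)
    expect_equal(res1$p, 1)
    # disjoint term -> k = 0, p = 1
    res0 <- over_representation(sample(setdiff(universe, term), 10),
                                list(t = term), universe = universe)
    expect_equal(res0$k, 0)
    expect_equal(res0$p, 1)
  })
  expect_error(over_representation("A", list(t = character(0)),
                                   universe = character(0)), "empty")
})

test_that("reported q-values are BH: monotone in p, >= p, equal to the oracle", {
  withr::with_seed(5, {
    for (rep in 1:3) {
      universe <- sprintf("U%04d", 1:500)
      coll <- lapply(1:40, function(i) sample(universe, sample(10:80, 1)))
      names(coll) <- paste0("t", 1:40)
      query <- sample(universe, 60)
      res <- over_representation(query, coll, universe = universe)
      expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
      expect_true(all(res$q >= res$p - 1e-12))
      o <- order(res$p)
      expect_true(all(diff(res$q[o]) >= -1e-12))
    }
  })
})

test_that("target annotation counts at-least-one-dataset genes once", {
  genes <- sprintf("T%03d", 1:135)
  tt <- generate_tf_targets(genes, 131, n_datasets = 3, seed = 4)
  res <- annotate_targets(genes, tt$table)
  expect_equal(sum(res$is_target), 131)
  expect_setequal(res$gene[res$is_target], tt$truth)
  # empty table -> zero positives
  empty <- tibble::tibble(gene = character(0), dataset = character(0))
  expect_equal(sum(annotate_targets(genes, empty)$is_target), 0)
  # duplicated gene-dataset rows count once
  dup <- tibble::tibble(gene = c("T001", "T001", "t001"),
                        dataset = c("d1", "d1", "d2"))
  res2 <- annotate_targets(genes, dup)
  expect_equal(res2$n_datasets[res2$gene == "T001"], 2L)
  expect_equal(sum(res2$is_target), 1)
})

test_that("GMT loading parses terms and rejects malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc\tA\tB\tC", "term2\tdesc\tb\tD"), path)
  coll <- load_gmt(path)
  expect_named(coll, c("term1", "term2"))
  expect_setequal(coll$term2, c("B", "D"))
  writeLines(c("term1\tdesc"), path)
  expect_error(load_gmt(path), "malformed")
})
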