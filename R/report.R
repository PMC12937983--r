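#' Assemble a deterministic analysis report bundle
#'
#' Collates the tabular outputs of the pipeline stages into one ordered
#' bundle and optionally writes it to disk as TSV files plus a JSON
#' summary and a plain-text digest.  Identical inputs regenerate
#' byte-identical files.
#'
#' @param sample_summaries row-bound [summarize_sample()] outputs.
#' @param tests named list of `welch_test` objects.
#' @param gene_counts named numeric vector of gene-set cardinalities.
#' @param g4 an [annotate_g4()] result.
#' @param convergence a [convergence_report()].
#' @param qpcr an [expression_summary()] table.
#' @param out_dir if non-`NULL`, the bundle is written there.
#' @return list of class `report_bundle` (tibbles in deterministic
#'   order); invisibly returns the same when writing.
#' @export
build_report <- function(sample_summaries = NULL, tests = NULL,
                         gene_counts = NULL, g4 = NULL, convergence = NULL,
                         qpcr = NULL, out_dir = NULL) {
  tests_tbl <- if (length(tests)) {
    purrr::map_dfr(sort(names(tests)), function(nm) {
      mutate(tidy(tests[[nm]]), comparison = nm, .before = 1)
    })
  } else tibble(comparison = character(0), estimate = numeric(0),
                statistic = numeric(0), df = numeric(0),
                p.value = numeric(0), stars = character(0))
  counts_tbl <- if (length(gene_counts)) {
    tibble(set = names(gene_counts), n = as.numeric(gene_counts)) %>%
      arrange(.data$set)
  } else tibble(set = character(0), n = numeric(0))
  g4_tbl <- if (!is.null(g4)) glance(g4) else NULL
  conv_tbl <- if (!is.null(convergence)) glance(convergence) else NULL
  bundle <- structure(list(
    sample_summaries = if (!is.null(sample_summaries)) {
      arrange(tibble::as_tibble(sample_summaries), .data$replicate_id)
    } else NULL,
    tests = tests_tbl,
    gene_counts = counts_tbl,
    g4 = g4_tbl,
    convergence = conv_tbl,
    convergence_members = if (!is.null(convergence)) tidy(convergence) else NULL,
    qpcr = if (!is.null(qpcr)) {
      arrange(tibble::as_tibble(qpcr), .data$target, .data$condition)
    } else NULL
  ), class = "report_bundle")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    tbl <- bundle[[nm]]
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_tsv(tbl, file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  summary <- list(
    n_samples = if (!is.null(bundle$sample_summaries))
      nrow(bundle$sample_summaries) else 0,
    tests = if (nrow(bundle$tests) > 0) {
      setNames(as.list(bundle$tests$stars), bundle$tests$comparison)
    } else NULL,
    gene_counts = if (nrow(bundle$gene_counts) > 0) {
      setNames(as.list(bundle$gene_counts$n), bundle$gene_counts$set)
    } else NULL,
    g4_fraction_positive = if (!is.null(bundle$g4))
      bundle$g4$fraction_positive else NULL,
    convergence_triple = if (!is.null(bundle$convergence_members))
      bundle$convergence_members$member else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  digest <- c("analysis report",
              sprintf("samples summarized: %d", summary$n_samples),
              if (!is.null(summary$gene_counts))
                sprintf("gene set %s: %g", names(summary$gene_counts),
                        unlist(summary$gene_counts)),
              if (!is.null(summary$g4_fraction_positive))
                sprintf("promoter G4 positive fraction: %.4f",
                        summary$g4_fraction_positive),
              if (!is.null(summary$convergence_triple))
                sprintf("convergence triple: %s",
                        paste(summary$convergence_triple, collapse = ", ")))
  writeLines(digest, file.path(out_dir, "summary.txt"))
  invisible(bundle)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: %d row(s)\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
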