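#' Gene set
#'
#' A named, deduplicated, case-normalized collection of gene symbols — the
#' substrate of the intersection-based gene-program definitions.
#'
#' @param name set name.
#' @param members character vector of symbols; harmonized and deduplicated.
#' @param alias_map optional alias map forwarded to [harmonize_symbols()].
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, members, alias_map = NULL) {
  members <- sort(unique(harmonize_symbols(members, alias_map)))
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'> %d members: %s%s\n", x$name,
              length(x$members),
              paste(utils::head(x$members, 6), collapse = ", "),
              if (length(x$members) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

# accept gene_set or plain character wherever members are needed
set_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else as.character(x)
}

#' Load a differential-expression table as a gene set
#'
#' Reads a TSV/CSV of per-gene differential-expression results, keeps rows
#' matching `direction_filter` (and optional effect-size / significance
#' thresholds), harmonizes symbols and collapses duplicates.  Rows whose
#' stated direction contradicts the sign of their log-fold-change are
#' dropped with a warning.
#'
#' @param path file path (TSV by default; `.csv` is auto-detected).
#' @param direction_filter `"up"` or `"down"`.
#' @param lfc_threshold optional: keep rows with `|log_fold_change| >=`
#'   this value.
#' @param padj_threshold optional: keep rows with `adj_p <=` this value.
#' @param columns named character vector remapping non-standard headers to
#'   the expected ones (`gene_symbol`, `direction`, `log_fold_change`,
#'   `adj_p`), e.g. `c(gene_symbol = "SYMBOL")`.
#' @param name set name; defaults to the file name.
#' @param alias_map optional alias map.
#' @return a [gene_set()]; empty result triggers a warning, not an error.
#' @export
load_deg_table <- function(path, direction_filter = c("up", "down"),
                           lfc_threshold = NULL, padj_threshold = NULL,
                           columns = NULL, name = NULL, alias_map = NULL) {
  direction_filter <- match.arg(direction_filter)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else readr::read_tsv
  tbl <- reader(path, show_col_types = FALSE)
  deg_as_gene_set(tbl, direction_filter, lfc_threshold, padj_threshold,
                  columns, name %||% basename(path), alias_map)
}

#' @rdname load_deg_table
#' @param tbl an in-memory DEG table (data frame) instead of a file.
#' @export
deg_as_gene_set <- function(tbl, direction_filter = c("up", "down"),
                            lfc_threshold = NULL, padj_threshold = NULL,
                            columns = NULL, name = "deg", alias_map = NULL) {
  direction_filter <- match.arg(direction_filter)
  tbl <- tibble::as_tibble(tbl)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (columns[[std]] %in% names(tbl)) {
        names(tbl)[names(tbl) == columns[[std]]] <- std
      }
    }
  }
  required <- c("gene_symbol", "direction")
  if (!all(required %in% names(tbl))) {
    abort(sprintf(
      paste0("unrecognized DEG table layout: need columns %s ",
             "(optionally log_fold_change, adj_p); found: %s. ",
             "Use `columns=` to remap headers."),
      paste(required, collapse = ", "), paste(names(tbl), collapse = ", ")))
  }
  if ("log_fold_change" %in% names(tbl)) {
    bad <- !is.na(tbl$log_fold_change) &
      ((tbl$direction == "up" & tbl$log_fold_change < 0) |
         (tbl$direction == "down" & tbl$log_fold_change > 0))
    if (any(bad)) {
      warn(sprintf("dropped %d row(s) whose direction contradicts the sign of log_fold_change.",
                   sum(bad)))
      tbl <- tbl[!bad, ]
    }
  }
  tbl <- dplyr::filter(tbl, .data$direction == direction_filter)
  if (!is.null(lfc_threshold) && "log_fold_change" %in% names(tbl)) {
    tbl <- dplyr::filter(tbl, abs(.data$log_fold_change) >= lfc_threshold)
  }
  if (!is.null(padj_threshold) && "adj_p" %in% names(tbl)) {
    tbl <- dplyr::filter(tbl, .data$adj_p <= padj_threshold)
  }
  if (nrow(tbl) == 0) warn(sprintf("gene set '%s' is empty after filtering.", name))
  gene_set(name, tbl$gene_symbol, alias_map)
}

#' Intersection-defined responsive gene set
#'
#' Intersects the genes upregulated in the p53-null stressed condition
#' with those downregulated on fibrillarin knockdown, then removes the
#' excluded symbols (by default the knocked-down gene itself, FBL) — the
#' definition of the "FBL-responsive" gene program.
#'
#' @param up_set,down_set [gene_set()]s (or character vectors).
#' @param exclude symbols removed from the intersection.
#' @return a [gene_set()] named `"FBL-responsive"`.
#' @export
fbl_responsive <- function(up_set, down_set, exclude = "FBL") {
  members <- setdiff(intersect(set_members(up_set), set_members(down_set)),
                     harmonize_symbols(exclude))
  gene_set("FBL-responsive", members)
}

#' CK2-alpha-dependent subset
#'
#' Plain intersection of the responsive gene set with the genes
#' downregulated on CK2-alpha knockout.
#'
#' @param responsive_set,down_ck2a [gene_set()]s (or character vectors).
#' @return a [gene_set()] named `"CK2a-dependent FBL-responsive"`.
#' @export
ck2a_dependent <- function(responsive_set, down_ck2a) {
  gene_set("CK2a-dependent FBL-responsive",
           intersect(set_members(responsive_set), set_members(down_ck2a)))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of a query gene set against each term of
#' a gene-set collection, with Benjamini-Hochberg adjustment across terms
#' and the rich factor (overlap / term size) used for ranking plots.
#'
#' @param query [gene_set()] or character vector.
#' @param collections named list of term gene sets (character vectors or
#'   [gene_set()]s), e.g. from [load_gmt()].
#' @param universe background set; defaults to the union of all collection
#'   members.  Query genes outside the universe are clipped with a message.
#' @return tibble with columns `term`, `k` (overlap), `m` (term size),
#'   `n` (query size in universe), `N` (universe size), `p`, `q`
#'   (BH-adjusted), `rich_factor`, sorted by `q` then descending rich
#'   factor.
#' @export
over_representation <- function(query, collections, universe = NULL) {
  if (length(collections) == 0 || is.null(names(collections))) {
    abort("`collections` must be a non-empty named list.")
  }
  coll <- lapply(collections, function(s) unique(set_members(s)))
  universe <- if (is.null(universe)) {
    sort(unique(unlist(coll)))
  } else sort(unique(set_members(universe)))
  if (length(universe) == 0) abort("enrichment universe is empty.")
  q_all <- unique(set_members(query))
  q_in <- intersect(q_all, universe)
  if (length(q_in) < length(q_all)) {
    inform(sprintf("clipped %d query gene(s) outside the universe.",
                   length(q_all) - length(q_in)))
  }
  N <- length(universe); n <- length(q_in)
  res <- purrr::map_dfr(names(coll), function(term) {
    members <- intersect(coll[[term]], universe)
    m <- length(members)
    k <- length(intersect(members, q_in))
    p <- if (m == 0) 1 else phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    tibble(term = term, k = k, m = m, n = n, N = N, p = p,
           rich_factor = if (m > 0) k / m else 0)
  })
  res$q <- p.adjust(res$p, method = "BH")
  res %>%
    select("term", "k", "m", "n", "N", "p", "q", "rich_factor") %>%
    arrange(.data$q, desc(.data$rich_factor), .data$term)
}

#' Annotate genes against a transcription-factor target table
#'
#' A gene is positive when it appears as a target in at least one dataset
#' of the annotation table (multiple appearances count once).
#'
#' @param genes [gene_set()] or character vector.
#' @param tf_target_table data frame with columns `gene` and `dataset`
#'   (one row per gene-dataset annotation), or a path to such a TSV.
#' @return tibble with columns `gene`, `is_target`, `n_datasets`; the
#'   number of positive genes is attached as attribute `n_annotated` and
#'   available via `sum(res$is_target)`.
#' @export
annotate_targets <- function(genes, tf_target_table) {
  genes <- set_members(genes)
  if (is.character(tf_target_table) && length(tf_target_table) == 1) {
    tf_target_table <- readr::read_tsv(tf_target_table, show_col_types = FALSE)
  }
  tbl <- tibble::as_tibble(tf_target_table)
  if (!all(c("gene", "dataset") %in% names(tbl))) {
    abort("target table needs columns `gene` and `dataset`.")
  }
  tbl$gene <- harmonize_symbols(tbl$gene)
  counts <- tbl %>%
    distinct(.data$gene, .data$dataset) %>%
    dplyr::count(.data$gene, name = "n_datasets")
  res <- tibble(gene = genes) %>%
    left_join(counts, by = "gene") %>%
    mutate(n_datasets = dplyr::coalesce(.data$n_datasets, 0L),
           is_target = .data$n_datasets >= 1L) %>%
    select("gene", "is_target", "n_datasets")
  attr(res, "n_annotated") <- sum(res$is_target)
  res
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, `term<TAB>description<TAB>gene...`.
#'
#' @param path GMT file.
#' @return named list of character vectors (harmonized symbols).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) {
    abort(sprintf("malformed GMT line(s): %s (need term, description, >=1 gene).",
                  paste(which(bad), collapse = ", ")))
  }
  out <- lapply(parts, function(p) unique(harmonize_symbols(p[-(1:2)])))
  names(out) <- vapply(parts, `[`, character(1), 1)
  out
}
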