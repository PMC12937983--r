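#' Load a BED3+ interval file
#'
#' Reads tab-separated BED (0-based half-open), skipping `track` /
#' `browser` / comment lines, validating every interval, and returning the
#' intervals sorted within each chromosome.
#'
#' @param path BED file.
#' @return tibble with columns `chrom`, `start`, `end` (integers, 0-based
#'   half-open), sorted by chromosome then start.
#' @export
load_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    line_no <- idx[i]
    if (length(p) < 3) {
      abort(sprintf("BED line %d: fewer than 3 tab-separated fields.", line_no))
    }
    s <- suppressWarnings(as.numeric(p[2]))
    e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e)) {
      abort(sprintf("BED line %d: non-numeric start/end.", line_no))
    }
    if (s < 0 || s >= e) {
      abort(sprintf("BED line %d: need 0 <= start < end (got %s, %s).",
                    line_no, p[2], p[3]))
    }
    rows[[i]] <- tibble(chrom = p[1], start = as.integer(s), end = as.integer(e))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(chrom = character(0), start = integer(0), end = integer(0))
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Load a TSS table
#'
#' Accepts either a direct TSS table (columns `chrom`, `tss`, `strand`,
#' `gene`) or a gene-span table (columns `chrom`, `start`, `end`,
#' `strand`, `gene`, 0-based half-open) from which the TSS is derived
#' strand-aware: `start` on the plus strand, `end - 1` on the minus
#' strand.  With multiple records per gene, `tss_policy` reduces them to
#' one TSS per gene.
#'
#' @param path TSV file, or a data frame.
#' @param tss_policy `"most_upstream"` keeps the 5'-most TSS per gene
#'   (minimum on `+`, maximum on `-`); `"all"` keeps every record.
#' @return tibble with columns `chrom`, `tss`, `strand`, `gene`.
#' @export
load_tss <- function(path, tss_policy = c("most_upstream", "all")) {
  tss_policy <- match.arg(tss_policy)
  tbl <- if (is.character(path) && length(path) == 1) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else tibble::as_tibble(path)
  if (all(c("chrom", "start", "end", "strand", "gene") %in% names(tbl)) &&
      !"tss" %in% names(tbl)) {
    tbl <- mutate(tbl, tss = ifelse(.data$strand == "+",
                                    .data$start, .data$end - 1L))
  }
  if (!all(c("chrom", "tss", "strand", "gene") %in% names(tbl))) {
    abort("TSS input needs columns chrom, tss, strand, gene (or chrom, start, end, strand, gene).")
  }
  if (!all(tbl$strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand symbol(s): %s",
                  paste(unique(setdiff(tbl$strand, c("+", "-"))), collapse = ", ")))
  }
  if (any(tbl$tss < 0)) abort("TSS positions must be >= 0.")
  tbl <- mutate(tbl, gene = harmonize_symbols(.data$gene),
                tss = as.integer(.data$tss))
  if (tss_policy == "most_upstream") {
    tbl <- tbl %>%
      group_by(.data$gene) %>%
      filter(if (.data$strand[1] == "+") .data$tss == min(.data$tss)
             else .data$tss == max(.data$tss)) %>%
      dplyr::slice(1) %>%
      ungroup()
  }
  select(tbl, "chrom", "tss", "strand", "gene")
}

#' Promoter-proximal window around a TSS
#'
#' Symmetric window `[max(0, tss - flank), tss + flank)` in 0-based
#' half-open coordinates; strand does not alter the window.
#'
#' @param tss TSS table as returned by [load_tss()] (columns `chrom`,
#'   `tss`, `gene`; `strand` ignored).
#' @param flank half-width in bp (> 0, default 1000).
#' @return tibble with columns `chrom`, `start`, `end`, `gene`.
#' @export
promoter_window <- function(tss, flank = 1000) {
  stopifnot(flank > 0)
  tss <- tibble::as_tibble(tss)
  tibble(chrom = tss$chrom,
         start = pmax(0L, as.integer(tss$tss - flank)),
         end = as.integer(tss$tss + flank),
         gene = tss$gene)
}

# indexed half-open overlap: which windows hit >=1 interval.
# 0-based half-open [s, e) maps to 1-based closed [s + 1, e]; closed-interval
# overlap then coincides with the half-open rule a.start < b.end & b.start < a.end.
windows_with_overlap <- function(windows, intervals) {
  hit <- logical(nrow(windows))
  if (nrow(intervals) == 0 || nrow(windows) == 0) return(hit)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    qr <- IRanges::IRanges(start = windows$start[wi] + 1L,
                           end = windows$end[wi])
    sr <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    hit[wi] <- IRanges::overlapsAny(qr, sr)
  }
  hit
}

#' Annotate genes for promoter-proximal G4 formation
#'
#' For each gene with a TSS record, tests whether any interval of each
#' collection overlaps the promoter window `[TSS - flank, TSS + flank)`
#' under the half-open rule, and scores the gene positive when at least
#' one collection has a hit.  Genes with no TSS record are reported and
#' excluded from the denominator.
#'
#' @param genes [gene_set()] or character vector.
#' @param tss TSS table ([load_tss()] layout).
#' @param collections named list of interval tables (`chrom`, `start`,
#'   `end`; e.g. from [load_bed()]).
#' @param flank promoter half-width in bp.
#' @param normalize_chr when `TRUE`, strips/ignores a leading `"chr"`
#'   prefix on both sides before matching chromosome names.
#' @return tibble of class `g4_annotation`: one row per gene with a TSS,
#'   one logical column per collection, plus `any_positive`.  Attributes:
#'   `missing_genes`, `fraction_positive`, `flank`.  See
#'   [glance.g4_annotation()].
#' @export
annotate_g4 <- function(genes, tss, collections, flank = 1000,
                        normalize_chr = FALSE) {
  genes <- unique(set_members(genes))
  if (length(collections) == 0 || is.null(names(collections))) {
    abort("`collections` must be a non-empty named list of interval tables.")
  }
  tss <- tibble::as_tibble(tss)
  tss_hit <- tss[match(genes, tss$gene), , drop = FALSE]
  missing <- genes[is.na(tss_hit$tss)]
  present <- genes[!is.na(tss_hit$tss)]
  tssp <- tss_hit[!is.na(tss_hit$tss), , drop = FALSE]
  windows <- promoter_window(tssp, flank)
  norm <- function(ch) if (normalize_chr) sub("^chr", "", ch) else ch
  windows$chrom <- norm(windows$chrom)
  res <- tibble(gene = present)
  for (nm in names(collections)) {
    iv <- tibble::as_tibble(collections[[nm]])
    iv$chrom <- norm(iv$chrom)
    shared <- intersect(unique(windows$chrom), unique(iv$chrom))
    if (nrow(iv) > 0 && length(shared) == 0 && nrow(windows) > 0) {
      warn(sprintf(
        "collection '%s': no chromosome names in common (%d window vs %d interval chroms); check chr-prefix conventions.",
        nm, length(unique(windows$chrom)), length(unique(iv$chrom))))
    }
    res[[nm]] <- windows_with_overlap(windows, iv)
  }
  res$any_positive <- if (length(collections) == 1) {
    res[[names(collections)]]
  } else {
    apply(as.matrix(res[names(collections)]), 1, any)
  }
  if (length(missing)) {
    inform(sprintf("%d gene(s) without a TSS record excluded from the denominator: %s%s",
                   length(missing), paste(utils::head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) ", ..." else ""))
  }
  structure(res,
            class = c("g4_annotation", class(res)),
            missing_genes = missing,
            fraction_positive = if (nrow(res)) mean(res$any_positive) else 0,
            flank = flank)
}

#' Summary of a G4 promoter annotation
#'
#' @param x result of [annotate_g4()].
#' @param ... unused.
#' @return one-row tibble: genes scored, positives, fraction, flank and
#'   number of genes missing a TSS record.
#' @export
glance.g4_annotation <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_positive = sum(x$any_positive),
         fraction_positive = attr(x, "fraction_positive"),
         flank = attr(x, "flank"),
         n_missing_tss = length(attr(x, "missing_genes")))
}
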