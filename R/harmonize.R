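#' Harmonize gene / protein symbols
#'
#' Trims whitespace, strips surrounding quotes, uppercases, and applies an
#' optional alias map (matched case-insensitively after trimming).  Empty
#' symbols are dropped with a message.  The operation is idempotent.
#'
#' @param symbols character vector.
#' @param alias_map optional two-column data frame (`alias`, `symbol`)
#'   mapping non-standard spellings (e.g. `"hnRNP A1"`) to official
#'   symbols; see [default_alias_map()].
#' @return harmonized character vector (possibly shorter if empties were
#'   dropped).
#' @export
harmonize_symbols <- function(symbols, alias_map = NULL) {
  x <- as.character(symbols)
  x <- stringr::str_trim(x)
  x <- stringr::str_remove_all(x, "^[\"']+|[\"']+$")
  x <- stringr::str_trim(x)
  x <- toupper(x)
  if (!is.null(alias_map)) {
    alias_map <- tibble::as_tibble(alias_map)
    if (!all(c("alias", "symbol") %in% names(alias_map))) {
      abort("`alias_map` needs columns `alias` and `symbol`.")
    }
    key <- toupper(stringr::str_trim(alias_map$alias))
    hit <- match(x, key)
    x[!is.na(hit)] <- toupper(alias_map$symbol[hit[!is.na(hit)]])
  }
  dropped <- !nzchar(x)
  if (any(dropped)) {
    inform(sprintf("dropped %d empty symbol(s) during harmonization.",
                   sum(dropped)))
    x <- x[!dropped]
  }
  x
}

#' Default alias map
#'
#' Covers common non-HGNC spellings of the proteins recurring in
#' nucleolar-stress interactome work.
#'
#' @return tibble with columns `alias`, `symbol`.
#' @export
default_alias_map <- function() {
  tibble(
    alias = c("hnRNP A1", "hnRNPA1", "B23", "nucleophosmin", "nucleolin",
              "fibrillarin", "CK2a", "CK2alpha"),
    symbol = c("HNRNPA1", "HNRNPA1", "NPM1", "NPM1", "NCL",
               "FBL", "CSNK2A1", "CSNK2A1"))
}

#' Read an alias map from a TSV file
#'
#' @param path two-column TSV with header `alias<TAB>symbol`.
#' @return tibble usable as `alias_map` in [harmonize_symbols()].
#' @export
read_alias_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("alias", "symbol") %in% names(tbl))) {
    abort("alias map file needs columns `alias` and `symbol`.")
  }
  tbl
}
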