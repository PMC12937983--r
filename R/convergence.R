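#' Load a protein set from a text file
#'
#' One symbol per line, or a TSV whose first column holds symbols (header
#' auto-detected by symbol reuse is not attempted: a first line that
#' repeats nowhere is kept — harmonization makes duplicates collapse
#' anyway).  Symbols are harmonized and deduplicated.
#'
#' @param path text/TSV file.
#' @param name set name; defaults to the file name.
#' @param alias_map optional alias map (see [default_alias_map()]).
#' @return object of class `protein_set` (same shape as [gene_set()], with
#'   a `provenance` field recording `path` verbatim).
#' @export
load_protein_set <- function(path, name = NULL, alias_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) abort(sprintf("protein list '%s' is empty.", path))
  symbols <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  protein_set(name %||% basename(path), symbols, alias_map, provenance = path)
}

#' @rdname load_protein_set
#' @param members symbol vector (constructor form).
#' @param provenance free-text origin, recorded verbatim.
#' @export
protein_set <- function(name, members, alias_map = NULL, provenance = "") {
  members <- sort(unique(harmonize_symbols(members, alias_map)))
  structure(list(name = as.character(name), members = members,
                 provenance = as.character(provenance)),
            class = c("protein_set", "gene_set"))
}

#' Asymmetric overlap fraction
#'
#' `|A intersect B| / |A|` — the fraction of the first set recovered in
#' the second (e.g. the share of fibrillarin-associated proteins also
#' found among nuclear CK2-alpha-associated proteins).
#'
#' @param a,b protein/gene sets or character vectors; `a` is the
#'   denominator and must be non-empty.
#' @return a number in [0, 1].
#' @export
overlap_fraction <- function(a, b) {
  am <- unique(set_members(a)); bm <- unique(set_members(b))
  if (length(am) == 0) abort("overlap_fraction: first set is empty.")
  length(intersect(am, bm)) / length(am)
}

#' Triple intersection
#'
#' @param a,b,c protein/gene sets or character vectors.
#' @return lexicographically sorted character vector of common members.
#' @export
triple_intersection <- function(a, b, c) {
  sort(intersect(intersect(set_members(a), set_members(b)), set_members(c)))
}

#' Interactome convergence report
#'
#' Sizes, the pairwise overlap fraction of the first set in the second,
#' and the triple-intersection membership across three protein sets.
#'
#' @param a,b,c protein sets (e.g. fibrillarin-associated, nuclear
#'   CK2-alpha-associated, and curated DNA-G4-binding proteins).
#' @return object of class `convergence_report`: list with `sizes`,
#'   `fraction_a_in_b`, `triple`; [tidy()] gives the triple as a tibble,
#'   [glance()] the scalar summary.
#' @export
convergence_report <- function(a, b, c) {
  triple <- triple_intersection(a, b, c)
  structure(list(
    sizes = c(a = length(unique(set_members(a))),
              b = length(unique(set_members(b))),
              c = length(unique(set_members(c)))),
    fraction_a_in_b = overlap_fraction(a, b),
    triple = triple), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> |A|=%d |B|=%d |C|=%d; %.1f%% of A in B; triple (n=%d): %s\n",
              x$sizes["a"], x$sizes["b"], x$sizes["c"],
              100 * x$fraction_a_in_b, length(x$triple),
              paste(x$triple, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.convergence_report <- function(x, ...) {
  tibble(member = x$triple)
}

#' @export
glance.convergence_report <- function(x, ...) {
  tibble(n_a = unname(x$sizes["a"]), n_b = unname(x$sizes["b"]),
         n_c = unname(x$sizes["c"]),
         fraction_a_in_b = x$fraction_a_in_b,
         n_triple = length(x$triple))
}
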