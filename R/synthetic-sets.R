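#' Specification of planted differential-expression set structure
#'
#' Describes three DEG tables whose pairwise / triple intersections are
#' planted exactly: set A (genes up in condition 1), B (down in condition
#' 2) and C (down in condition 3).  `n_ab` and `n_abc` count shared genes
#' *excluding* the seed gene: when `include_seed_gene` is `TRUE` the
#' literal symbol `"FBL"` is added to both A and B on top of `n_ab`, so the
#' raw A-and-B intersection has `n_ab + 1` members and exactly `n_ab`
#' survive the seed-gene exclusion applied by [fbl_responsive()].
#'
#' @param universe_size number of synthetic symbols (`G000001`, ...)
#'   available.
#' @param n_a,n_b,n_c set sizes (seed gene not counted).
#' @param n_ab planted size of the A-and-B intersection after seed-gene
#'   exclusion.
#' @param n_abc planted size of the triple intersection; C meets A and B
#'   only inside the triple intersection.
#' @param include_seed_gene place `"FBL"` in both A and B.
#' @param decoy_frac per-table fraction of extra opposite-direction rows,
#'   so that direction filtering is exercised downstream.
#' @return a validated list of class `planted_set_spec`.
#' @export
planted_set_spec <- function(universe_size = 20000, n_a, n_b, n_c,
                             n_ab, n_abc, include_seed_gene = TRUE,
                             decoy_frac = 0.1) {
  chk <- function(cond, msg) if (!cond) abort(paste0("infeasible spec: ", msg))
  chk(n_abc <= n_ab, "|A intersect B intersect C| <= |A intersect B| violated")
  chk(n_ab <= min(n_a, n_b), "|A intersect B| <= min(|A|, |B|) violated")
  chk(n_abc <= n_c, "|A intersect B intersect C| <= |C| violated")
  chk(max(n_a, n_b, n_c) <= universe_size, "set size exceeds universe_size")
  needed <- n_a + n_b - n_ab + (n_c - n_abc)
  chk(needed <= universe_size,
      sprintf("universe_size %d cannot host %d distinct members",
              universe_size, needed))
  structure(list(universe_size = universe_size, n_a = n_a, n_b = n_b,
                 n_c = n_c, n_ab = n_ab, n_abc = n_abc,
                 include_seed_gene = include_seed_gene,
                 decoy_frac = decoy_frac),
            class = "planted_set_spec")
}

#' Generate three DEG tables with planted intersections
#'
#' Emulates the upstream differential-expression inputs of the gene-set
#' integration stage: A = upregulated in p53-null cells under doxorubicin,
#' B = downregulated on FBL knockdown, C = downregulated on CK2-alpha
#' knockout.  Intersection cardinalities are realized exactly as planted.
#'
#' @param spec a [planted_set_spec()].
#' @param seed integer seed (private RNG stream).
#' @return list with `tables` (named list of tibbles with columns
#'   `gene_symbol`, `direction`, `log_fold_change`, `adj_p`) and `truth`
#'   (member vectors and planted cardinalities).
#' @export
generate_deg_tables <- function(spec, seed) {
  stopifnot(inherits(spec, "planted_set_spec"))
  withr::with_seed(as.integer(seed), {
    universe <- sprintf("G%06d", seq_len(spec$universe_size))
    n_core <- spec$n_a + spec$n_b - spec$n_ab + (spec$n_c - spec$n_abc)
    pool <- sample(universe, spec$universe_size)  # shuffled, draw in blocks
    take <- function(n) {
      if (n == 0) return(character(0))
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    abc <- take(spec$n_abc)
    ab_only <- take(spec$n_ab - spec$n_abc)
    a_only <- take(spec$n_a - spec$n_ab)
    b_only <- take(spec$n_b - spec$n_ab)
    c_only <- take(spec$n_c - spec$n_abc)
    seed_gene <- if (spec$include_seed_gene) "FBL" else character(0)
    A <- c(abc, ab_only, a_only, seed_gene)
    B <- c(abc, ab_only, b_only, seed_gene)
    C <- c(abc, c_only)

    mk_table <- function(members, direction) {
      n_decoy <- ceiling(spec$decoy_frac * length(members))
      decoys <- if (n_decoy > 0 && length(pool) >= n_decoy) {
        d <- pool[seq_len(n_decoy)]
        pool <<- pool[-seq_len(n_decoy)]
        d
      } else character(0)
      sgn <- if (direction == "up") 1 else -1
      tbl <- tibble(
        gene_symbol = c(members, decoys),
        direction = c(rep(direction, length(members)),
                      rep(if (direction == "up") "down" else "up",
                          length(decoys))),
        log_fold_change = c(sgn * runif(length(members), 0.5, 4),
                            -sgn * runif(length(decoys), 0.5, 4)),
        adj_p = 10^-runif(length(members) + length(decoys), 2, 10))
      tbl[sample(nrow(tbl)), ]
    }
    tables <- list(up_p53ko_doxo = mk_table(A, "up"),
                   down_fbl_kd = mk_table(B, "down"),
                   down_ck2a_ko = mk_table(C, "down"))
    truth <- list(A = sort(A), B = sort(B), C = sort(C),
                  n_ab = spec$n_ab, n_abc = spec$n_abc,
                  seed_gene = seed_gene)
    list(tables = tables, truth = truth)
  })
}

#' Generate a TSS table and BED collections with planted promoter overlap
#'
#' A planted fraction of `genes` receives at least one interval
#' intersecting its promoter window `[TSS - flank, TSS + flank)` in at
#' least one of `n_collections` interval collections; the remaining genes
#' receive only intervals wholly outside every promoter window (or none).
#' Genes are laid out on synthetic chromosomes with ample spacing so no
#' interval can stray into a neighbouring gene's window.
#'
#' @param genes character vector (or [gene_set()]) of gene symbols.
#' @param fraction_positive fraction in [0, 1]; the positive count is
#'   `round(fraction_positive * length(genes))`.
#' @param n_collections number of BED-style collections to emit.
#' @param flank promoter half-width in bp (> 0).
#' @param seed integer seed.
#' @return list with `tss` (tibble: chrom, tss, strand, gene),
#'   `collections` (named list of interval tibbles: chrom, start, end) and
#'   `truth` (tibble: gene, per-collection flags, positive).
#' @export
generate_g4_fixture <- function(genes, fraction_positive, n_collections = 2,
                                flank = 1000, seed) {
  genes <- set_members(genes)
  stopifnot(length(genes) >= 1, fraction_positive >= 0, fraction_positive <= 1,
            flank > 0, n_collections >= 1)
  n <- length(genes)
  n_pos <- round(fraction_positive * n)
  withr::with_seed(as.integer(seed), {
    n_chrom <- max(1L, ceiling(n / 50))
    spacing <- 2 * flank + 4000
    chrom <- paste0("chr", ((seq_len(n) - 1) %% n_chrom) + 1)
    slot <- (seq_len(n) - 1) %/% n_chrom
    tss <- flank + 1000 + slot * spacing + sample(0:500, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss_tbl <- tibble(chrom = chrom, tss = as.integer(tss),
                      strand = strand, gene = genes)

    positive <- rep(FALSE, n)
    positive[sample.int(n, n_pos)] <- TRUE
    coll_names <- paste0("collection", seq_len(n_collections))
    hits <- matrix(FALSE, n, n_collections, dimnames = list(genes, coll_names))
    ivs <- stats::setNames(
      replicate(n_collections, list(chrom = character(0), start = integer(0),
                                    end = integer(0)), simplify = FALSE),
      coll_names)
    push <- function(ci, ch, s, e) {
      ivs[[ci]]$chrom <<- c(ivs[[ci]]$chrom, ch)
      ivs[[ci]]$start <<- c(ivs[[ci]]$start, as.integer(s))
      ivs[[ci]]$end <<- c(ivs[[ci]]$end, as.integer(e))
    }
    for (i in seq_len(n)) {
      win_s <- max(0, tss[i] - flank); win_e <- tss[i] + flank
      if (positive[i]) {
        in_coll <- runif(n_collections) < 0.6
        if (!any(in_coll)) in_coll[sample.int(n_collections, 1)] <- TRUE
        for (ci in which(in_coll)) {
          len <- sample(80:300, 1)
          s <- sample(seq(max(0, win_s - len + 1), win_e - 1), 1)
          push(ci, chrom[i], s, s + len)
          hits[i, ci] <- TRUE
        }
      } else if (runif(1) < 0.5) {
        # decoy interval in the dead zone downstream of this gene's window
        len <- sample(80:300, 1)
        s <- tss[i] + flank + 200 + sample(0:1000, 1)
        push(sample.int(n_collections, 1), chrom[i], s, s + len)
      }
    }
    collections <- lapply(ivs, function(v) {
      tbl <- tibble(chrom = v$chrom, start = v$start, end = v$end)
      tbl[sample(nrow(tbl)), ]  # unsorted on purpose
    })
    truth <- tibble::as_tibble(hits, rownames = "gene")
    truth$positive <- positive
    list(tss = tss_tbl, collections = collections, truth = truth)
  })
}

#' Generate three protein lists with planted overlap structure
#'
#' Emulates association-proteomics inputs to the interactome-convergence
#' stage: the fraction of set A also present in B and the size of the
#' triple intersection are realized exactly; C meets A and B only in the
#' triple intersection.
#'
#' @param sizes length-3 integer vector `c(|A|, |B|, |C|)`.
#' @param fraction_ab planted `|A intersect B| / |A|`;
#'   `round(fraction_ab * sizes[1])` members of A are copied into B.
#' @param n_triple planted size of the triple intersection.
#' @param canonical_triple if `TRUE` (requires `n_triple == 5`) the triple
#'   intersection is forced to NPM1, HNRNPA1, NCL, FUS, MAZ.
#' @param seed integer seed.
#' @return list with `sets` (named list of symbol vectors) and `truth`.
#' @export
generate_protein_sets <- function(sizes, fraction_ab, n_triple,
                                  canonical_triple = FALSE, seed) {
  stopifnot(length(sizes) == 3, all(sizes >= 1),
            fraction_ab >= 0, fraction_ab <= 1)
  n_ab <- round(fraction_ab * sizes[1])
  if (n_triple > min(sizes) || n_triple > n_ab) {
    abort(sprintf(paste0("infeasible spec: planted triple %d exceeds a set ",
                         "size or the planted |A intersect B| = %d."),
                  n_triple, n_ab))
  }
  if (canonical_triple && n_triple != 5) {
    abort("canonical_triple requires n_triple == 5.")
  }
  withr::with_seed(as.integer(seed), {
    pool <- sprintf("P%05d", sample.int(99999, sum(sizes) + 10))
    take <- function(n) {
      if (n == 0) return(character(0))
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    triple <- if (canonical_triple) {
      c("NPM1", "HNRNPA1", "NCL", "FUS", "MAZ")
    } else take(n_triple)
    ab_only <- take(n_ab - n_triple)
    a_only <- take(sizes[1] - n_ab)
    b_only <- take(sizes[2] - n_ab)
    c_only <- take(sizes[3] - n_triple)
    sets <- list(
      fbl_ap = sample(c(triple, ab_only, a_only)),
      ck2a_ap = sample(c(triple, ab_only, b_only)),
      g4bp = sample(c(triple, c_only)))
    list(sets = sets,
         truth = list(fraction_ab = n_ab / sizes[1], n_ab = n_ab,
                      triple = sort(triple)))
  })
}

#' Generate a planted transcription-factor target annotation table
#'
#' Marks a chosen number of `genes` as targets in one or more synthetic
#' datasets, for validating [annotate_targets()].
#'
#' @param genes character vector (or [gene_set()]).
#' @param n_annotated number of genes annotated in at least one dataset.
#' @param n_datasets number of synthetic dataset identifiers.
#' @param seed integer seed.
#' @return list with `table` (tibble: gene, dataset) and `truth`
#'   (annotated gene vector).
#' @export
generate_tf_targets <- function(genes, n_annotated, n_datasets = 3, seed) {
  genes <- set_members(genes)
  stopifnot(n_annotated >= 0, n_annotated <= length(genes), n_datasets >= 1)
  withr::with_seed(as.integer(seed), {
    annotated <- sort(sample(genes, n_annotated))
    rows <- lapply(annotated, function(g) {
      ds <- sample(paste0("dataset_", seq_len(n_datasets)),
                   sample.int(n_datasets, 1))
      tibble(gene = g, dataset = ds)
    })
    tbl <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble(gene = character(0), dataset = character(0))
    list(table = tbl[sample(nrow(tbl)), ], truth = annotated)
  })
}
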