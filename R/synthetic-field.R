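#' Generate a ground-truthed synthetic fluorescence field
#'
#' Renders a three-channel (DNA / NPM1 / FBL) 2-D field containing a
#' mixture of cells with three nucleolar phenotypes, together with an
#' exact per-cell truth table.  The rendering makes the peripheral
#' (nucleolar-cap) versus nucleoplasmic (focus) distinction geometrically
#' unambiguous at zero noise:
#'
#' * `intact` — NPM1-bright nucleoli inside the nucleus; fibrillarin as
#'   small dots strictly interior to each nucleolus; no nucleoplasmic foci.
#' * `cap_positive` — fibrillarin crescents (40–90 degrees of arc) hugging
#'   the nucleolar rim, emulating stress-induced nucleolar caps; diffuse
#'   nucleoplasmic NPM1.
#' * `cap_disrupted` — a single rounded nucleolus with only a dim
#'   fibrillarin rim, plus `n_foci` Gaussian fibrillarin puncta scattered
#'   in the nucleoplasm well clear of the (dilated) nucleolus.
#'
#' Intensities live on a [0, 1] working scale (written as 16-bit by
#' [write_field()]).  All randomness is drawn from one stream seeded by
#' `seed`; the same seed reproduces the field and truth byte-for-byte.
#'
#' @param n_cells number of nuclei to place (>= 1).  Ignored when `cells`
#'   is supplied.
#' @param mixture length-3 proportions of (intact, cap_positive,
#'   cap_disrupted); must sum to 1 within 1e-9.
#' @param image_shape `c(rows, cols)` in pixels, or `NULL` to size the
#'   canvas automatically so nuclei occupy about 30% of it.
#' @param noise a [noise_params()] object, a list of its fields, or `0`
#'   for a noise- and blur-free field.
#' @param seed integer seed for the generator's private RNG stream.
#' @param pixel_size micrometres per pixel.
#' @param cells optional tibble of explicit per-cell specifications with
#'   column `phenotype` and optionally `n_nucleoli`, `n_caps_per_nucleolus`,
#'   `n_foci`, `cap_intensity_scale`, `foci_intensity_scale`; overrides the
#'   mixture draw (one row per cell).
#' @param sample_id carried into the returned field.
#'
#' @return list with elements `field` (a [fluor_field()]) and `truth`
#'   (tibble, one row per cell: centroid, phenotype, realized nucleolus /
#'   cap / focus counts and cap area).
#' @export
generate_field <- function(n_cells, mixture = c(1, 0, 0), image_shape = NULL,
                           noise = noise_params(), seed, pixel_size = 0.1,
                           cells = NULL, sample_id = "synthetic") {
  phenos <- c("intact", "cap_positive", "cap_disrupted")
  if (is.null(cells)) {
    if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1) {
      abort("`n_cells` must be a single integer >= 1.")
    }
    n_cells <- as.integer(n_cells)
    if (length(mixture) != 3 || any(mixture < 0)) {
      abort("`mixture` must be 3 non-negative proportions.")
    }
    if (abs(sum(mixture) - 1) > 1e-9) {
      abort(sprintf("`mixture` must sum to 1 (got %.12g).", sum(mixture)))
    }
  } else {
    cells <- tibble::as_tibble(cells)
    if (!"phenotype" %in% names(cells)) abort("`cells` needs a `phenotype` column.")
    if (!all(cells$phenotype %in% phenos)) {
      abort("`cells$phenotype` must be intact / cap_positive / cap_disrupted.")
    }
    n_cells <- nrow(cells)
    if (n_cells < 1) abort("`cells` must have at least one row.")
  }
  noise <- as_noise_params(noise)
  if (missing(seed)) abort("`seed` is required.")

  withr::with_seed(as.integer(seed), {
    spec <- build_cell_specs(n_cells, mixture, cells, phenos)
    geom <- place_nuclei(n_cells, image_shape)
    render_field(spec, geom, noise, pixel_size, sample_id)
  })
}

# draw per-cell phenotype specs (or validate user-supplied ones)
build_cell_specs <- function(n_cells, mixture, cells, phenos) {
  if (is.null(cells)) {
    phenotype <- sample(phenos, n_cells, replace = TRUE, prob = mixture)
    cells <- tibble(phenotype = phenotype)
  }
  defaults <- function(df) {
    fill <- function(col, val) if (col %in% names(df)) df[[col]] else val
    ph <- df$phenotype
    n_nucleoli <- fill("n_nucleoli",
                       ifelse(ph == "cap_disrupted", 1L,
                              sample(1:3, nrow(df), replace = TRUE)))
    n_caps <- fill("n_caps_per_nucleolus",
                   ifelse(ph == "cap_positive",
                          sample(1:3, nrow(df), replace = TRUE), 0L))
    n_foci <- fill("n_foci",
                   ifelse(ph == "cap_disrupted",
                          sample(5:10, nrow(df), replace = TRUE), 0L))
    df$n_nucleoli <- as.integer(n_nucleoli)
    df$n_caps_per_nucleolus <- as.integer(n_caps)
    df$n_foci <- as.integer(n_foci)
    df$cap_intensity_scale <- fill("cap_intensity_scale", 1)
    df$foci_intensity_scale <- fill("foci_intensity_scale", 1)
    df
  }
  spec <- defaults(cells)
  bad <- with(spec,
    (phenotype == "intact" & (n_caps_per_nucleolus != 0 | n_foci != 0)) |
    (phenotype == "cap_positive" & n_caps_per_nucleolus < 1) |
    (phenotype == "cap_disrupted" & n_foci < 1) |
    n_nucleoli < 1 | cap_intensity_scale <= 0 | foci_intensity_scale <= 0)
  if (any(bad)) {
    abort(sprintf("phenotype spec invariants violated in rows: %s",
                  paste(which(bad), collapse = ", ")))
  }
  spec
}

# rejection-sample non-overlapping nucleus ellipses
place_nuclei <- function(n_cells, image_shape,
                         ax_range = c(32, 40), max_retries = 2000) {
  a <- runif(n_cells, ax_range[1], ax_range[2])
  b <- runif(n_cells, ax_range[1], ax_range[2])
  theta <- runif(n_cells, 0, pi)
  rb <- pmax(a, b) + 3
  rmax <- ax_range[2] + 3
  if (is.null(image_shape)) {
    side <- ceiling(sqrt(n_cells * pi * rmax^2 / 0.30))
    image_shape <- c(max(side, 2 * ceiling(rmax) + 12),
                     max(side, 2 * ceiling(rmax) + 12))
  }
  stopifnot(length(image_shape) == 2, all(image_shape > 2 * rmax + 4))
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  r0 <- numeric(n_cells); c0 <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      rr <- runif(1, rb[i] + 2, nr - rb[i] - 1)
      cc <- runif(1, rb[i] + 2, nc - rb[i] - 1)
      if (i == 1 || all((rr - r0[seq_len(i - 1)])^2 +
                        (cc - c0[seq_len(i - 1)])^2 >
                        (rb[i] + rb[seq_len(i - 1)] + 2)^2)) {
        r0[i] <- rr; c0[i] <- cc; placed <- TRUE; break
      }
    }
    if (!placed) {
      abort(sprintf(
        paste0("could not place nucleus %d of %d in a %dx%d px field; ",
               "about %d non-overlapping nuclei fit at this density — ",
               "reduce n_cells or enlarge image_shape."),
        i, n_cells, nr, nc, floor(0.30 * nr * nc / (pi * rmax^2))))
    }
  }
  list(r0 = r0, c0 = c0, a = a, b = b, theta = theta,
       shape = c(nr, nc))
}

# add a truncated (3 sigma) 2-D Gaussian to `mat` in place-ish
add_gaussian_spot <- function(mat, r0, c0, sigma, amp) {
  rad <- ceiling(3 * sigma)
  nr <- nrow(mat); nc <- ncol(mat)
  wr <- max(1, floor(r0) - rad):min(nr, ceiling(r0) + rad)
  wc <- max(1, floor(c0) - rad):min(nc, ceiling(c0) + rad)
  d2 <- outer((wr - r0)^2, (wc - c0)^2, "+")
  g <- amp * exp(-d2 / (2 * sigma^2))
  g[d2 > (3 * sigma)^2] <- 0
  mat[wr, wc] <- mat[wr, wc] + g
  mat
}

circ_dist <- function(x, y) {
  d <- abs(x - y) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

render_field <- function(spec, geom, noise, pixel_size, sample_id) {
  nr <- geom$shape[1]; nc <- geom$shape[2]
  dna <- matrix(0, nr, nc); npm1 <- matrix(0, nr, nc); fbl <- matrix(0, nr, nc)
  n_cells <- nrow(spec)
  truth <- vector("list", n_cells)

  for (i in seq_len(n_cells)) {
    ph <- spec$phenotype[i]
    a <- geom$a[i]; b <- geom$b[i]; th <- geom$theta[i]
    r0 <- geom$r0[i]; c0 <- geom$c0[i]
    rad <- ceiling(max(a, b)) + 2
    wr <- max(1, floor(r0) - rad):min(nr, ceiling(r0) + rad)
    wc <- max(1, floor(c0) - rad):min(nc, ceiling(c0) + rad)
    dx <- outer(wr - r0, rep(1, length(wc)))
    dy <- outer(rep(1, length(wr)), wc - c0)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1

    dna_w <- dna[wr, wc]
    dna_w[inside] <- 0.55 * runif(1, 0.9, 1.1)
    dna[wr, wc] <- dna_w

    treated <- ph != "intact"
    npm1_w <- npm1[wr, wc]
    npm1_w[inside] <- if (treated) 0.12 else 0.02
    npm1[wr, wc] <- npm1_w

    # --- nucleoli -----------------------------------------------------
    k <- spec$n_nucleoli[i]
    r_range <- if (ph == "cap_disrupted") c(9, 11) else c(9, 13)
    ncl <- list()
    for (j in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(300)) {
        rj <- runif(1, r_range[1], r_range[2])
        # uniform point in ellipse shrunk so the nucleolus sits well inside
        ang <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
        uu <- rho * cos(ang) * (a - rj - 6)
        vv <- rho * sin(ang) * (b - rj - 6)
        cr <- r0 + uu * cos(th) - vv * sin(th)
        cc <- c0 + uu * sin(th) + vv * cos(th)
        if (length(ncl) == 0 ||
            all(vapply(ncl, function(p)
              (cr - p$r)^2 + (cc - p$c)^2 > (rj + p$rad + 9)^2, logical(1)))) {
          ncl[[length(ncl) + 1]] <- list(r = cr, c = cc, rad = rj)
          ok <- TRUE; break
        }
      }
      if (!ok) break  # keep what fits; truth records the realized count
    }
    for (p in ncl) {
      nwr <- max(1, floor(p$r - p$rad - 1)):min(nr, ceiling(p$r + p$rad + 1))
      nwc <- max(1, floor(p$c - p$rad - 1)):min(nc, ceiling(p$c + p$rad + 1))
      d2 <- outer((nwr - p$r)^2, (nwc - p$c)^2, "+")
      sel <- d2 <= p$rad^2
      npm1_w <- npm1[nwr, nwc]; npm1_w[sel] <- 0.8
      npm1[nwr, nwc] <- npm1_w
    }

    # --- fibrillarin --------------------------------------------------
    n_caps <- 0L; cap_px <- 0L
    if (ph == "intact") {
      for (p in ncl) {
        for (d in seq_len(sample(2:4, 1))) {
          rr <- sqrt(runif(1)) * max(p$rad - 7.5, 0)
          aa <- runif(1, 0, 2 * pi)
          fbl <- add_gaussian_spot(fbl, p$r + rr * cos(aa), p$c + rr * sin(aa),
                                   sigma = 1.5, amp = 0.7)
        }
      }
    } else if (ph == "cap_positive") {
      for (p in ncl) {
        arcs <- list()
        for (ci in seq_len(spec$n_caps_per_nucleolus[i])) {
          phi <- runif(1, 40, 90) * pi / 180
          for (try in seq_len(100)) {
            alpha <- runif(1, 0, 2 * pi)
            if (length(arcs) == 0 ||
                all(vapply(arcs, function(q)
                  circ_dist(alpha, q$alpha) > (phi + q$phi) / 2 + 10 * pi / 180,
                  logical(1)))) {
              arcs[[length(arcs) + 1]] <- list(alpha = alpha, phi = phi)
              break
            }
          }
        }
        nwr <- max(1, floor(p$r - p$rad - 3)):min(nr, ceiling(p$r + p$rad + 3))
        nwc <- max(1, floor(p$c - p$rad - 3)):min(nc, ceiling(p$c + p$rad + 3))
        ddx <- outer(nwr - p$r, rep(1, length(nwc)))
        ddy <- outer(rep(1, length(nwr)), nwc - p$c)
        rho <- sqrt(ddx^2 + ddy^2)
        angm <- atan2(ddy, ddx) %% (2 * pi)
        fbl_w <- fbl[nwr, nwc]
        for (q in arcs) {
          sel <- rho >= p$rad - 2 & rho <= p$rad + 2 &
            circ_dist(angm, q$alpha) <= q$phi / 2
          fbl_w[sel] <- 0.75 * spec$cap_intensity_scale[i]
          cap_px <- cap_px + sum(sel)
          n_caps <- n_caps + 1L
        }
        fbl[nwr, nwc] <- fbl_w
      }
    }

    n_foci <- 0L
    if (ph == "cap_disrupted") {
      for (p in ncl) {  # dim residual rim
        nwr <- max(1, floor(p$r - p$rad - 2)):min(nr, ceiling(p$r + p$rad + 2))
        nwc <- max(1, floor(p$c - p$rad - 2)):min(nc, ceiling(p$c + p$rad + 2))
        rho <- sqrt(outer((nwr - p$r)^2, (nwc - p$c)^2, "+"))
        sel <- rho >= p$rad - 2 & rho <= p$rad + 2
        fbl_w <- fbl[nwr, nwc]
        fbl_w[sel] <- pmax(fbl_w[sel], 0.02 * spec$cap_intensity_scale[i])
        fbl[nwr, nwc] <- fbl_w
      }
      foci <- list()
      for (f in seq_len(spec$n_foci[i])) {
        ok <- FALSE
        for (try in seq_len(500)) {
          sig <- if (try <= 400) runif(1, 2, 4) else 2
          ang <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
          uu <- rho * cos(ang) * (a - 6); vv <- rho * sin(ang) * (b - 6)
          fr <- r0 + uu * cos(th) - vv * sin(th)
          fc <- c0 + uu * sin(th) + vv * cos(th)
          clear_ncl <- all(vapply(ncl, function(p)
            (fr - p$r)^2 + (fc - p$c)^2 > (p$rad + 7)^2, logical(1)))
          sep <- if (try <= 400) 4 else 3
          clear_foci <- length(foci) == 0 ||
            all(vapply(foci, function(q)
              sqrt((fr - q$r)^2 + (fc - q$c)^2) >
                1.25 * (sig + q$sig) + sep, logical(1)))
          if (clear_ncl && clear_foci) {
            foci[[length(foci) + 1]] <- list(r = fr, c = fc, sig = sig)
            ok <- TRUE; break
          }
        }
        if (!ok) break
      }
      if (length(foci) < spec$n_foci[i]) {
        warn(sprintf("cell %d: placed %d of %d requested foci (crowded nucleus).",
                     i, length(foci), spec$n_foci[i]))
      }
      for (q in foci) {
        fbl <- add_gaussian_spot(fbl, q$r, q$c, sigma = q$sig,
                                 amp = 0.85 * spec$foci_intensity_scale[i])
      }
      n_foci <- length(foci)
    }

    truth[[i]] <- tibble(
      cell_id = i, row = r0, col = c0,
      phenotype = ph, n_nucleoli = length(ncl),
      n_caps = n_caps, n_foci = n_foci,
      cap_area_px = as.integer(cap_px),
      cap_area_um2 = cap_px * pixel_size^2)
  }

  channels <- list(dna = dna, npm1 = npm1, fbl = fbl)
  if (noise$psf_sigma > 0) {
    channels <- lapply(channels, function(m)
      as.matrix(EBImage::gblur(EBImage::Image(m), sigma = noise$psf_sigma)))
  }
  if (noise$poisson_scale > 0) {
    channels <- lapply(channels, function(m) {
      m2 <- matrix(rpois(length(m), pmax(m, 0) * noise$poisson_scale) /
                     noise$poisson_scale, nrow(m), ncol(m))
      m2
    })
  }
  if (noise$background > 0) {
    channels <- lapply(channels, function(m) m + noise$background)
  }
  if (noise$gaussian_sd > 0) {
    channels <- lapply(channels, function(m)
      m + matrix(rnorm(length(m), 0, noise$gaussian_sd), nrow(m), ncol(m)))
  }
  channels <- lapply(channels, function(m) pmax(m, 0))

  truth <- dplyr::bind_rows(truth)
  attr(truth, "pixel_size") <- pixel_size
  attr(truth, "mixture_realized") <-
    prop.table(table(factor(truth$phenotype,
                            c("intact", "cap_positive", "cap_disrupted"))))
  list(field = fluor_field(channels, pixel_size = pixel_size,
                           sample_id = sample_id),
       truth = truth)
}
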