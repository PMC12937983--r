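#' Welch's two-sample t-test
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom, plus the conventional significance stars (`*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, strict inequalities).
#'
#' Convention for degenerate input: if both samples have zero variance and
#' equal means, `t = 0`, `p = 1`, `df = NA`; zero variance in both samples
#' with unequal means is an error (the statistic is undefined).
#'
#' @param x,y numeric samples, each of length >= 2, all finite.
#' @return object of class `welch_test` with fields `t`, `df`,
#'   `p_two_sided`, `stars`, `estimate` (the two means), `n`; see
#'   [tidy.welch_test()].
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_t_test needs at least 2 observations per sample.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("welch_t_test requires finite values.")
  }
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mx == my) {
      t <- 0; df <- NA_real_; p <- 1
    } else {
      abort("welch_t_test: zero variance in both samples with unequal means.")
    }
  } else {
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p_two_sided = p,
                 stars = p_stars(p), estimate = c(mean_x = mx, mean_y = my),
                 n = c(nx = nx, ny = ny),
                 method = "Welch two-sided t-test"),
            class = "welch_test")
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `"ns"` (strict inequalities).
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4g, df = %.3g, p = %.4g %s (n = %d, %d)\n",
              x$t, x$df, x$p_two_sided, x$stars, x$n["nx"], x$n["ny"]))
  invisible(x)
}

#' Tidy a Welch test result
#'
#' @param x a `welch_test` object.
#' @param ... unused.
#' @return one-row tibble (broom layout): estimate (difference of means),
#'   the two group means, statistic, df, p.value, stars.
#' @export
tidy.welch_test <- function(x, ...) {
  tibble(estimate = unname(x$estimate["mean_x"] - x$estimate["mean_y"]),
         estimate1 = unname(x$estimate["mean_x"]),
         estimate2 = unname(x$estimate["mean_y"]),
         statistic = x$t, df = x$df, p.value = x$p_two_sided,
         stars = x$stars, method = x$method)
}

#' @rdname tidy.welch_test
#' @export
glance.welch_test <- function(x, ...) tidy(x)

#' Relative qPCR expression (delta-delta-Ct)
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean
#' dCt(control)` within each target; `fold = 2^-ddCt`, assuming 100%
#' amplification efficiency.  The condition-level fold reported by
#' [expression_summary()] is `2^-mean(ddCt)` (the geometric mean of the
#' replicate folds), which is exactly 1 for the control condition.
#'
#' @param measurements data frame with columns `condition`, `replicate`,
#'   `target_ct`, `reference_ct` and optionally `target` (gene name; a
#'   single implicit target otherwise).
#' @param control condition label used as the calibrator; must be present.
#' @return tibble per replicate: `target`, `condition`, `replicate`,
#'   `delta_ct`, `delta_delta_ct`, `fold`.
#' @export
relative_expression <- function(measurements, control) {
  m <- tibble::as_tibble(measurements)
  need <- c("condition", "replicate", "target_ct", "reference_ct")
  if (!all(need %in% names(m))) {
    abort(sprintf("qPCR input needs columns %s.", paste(need, collapse = ", ")))
  }
  if (!"target" %in% names(m)) m$target <- "target"
  bad_ref <- !is.finite(m$reference_ct)
  if (any(bad_ref)) {
    abort(sprintf("missing/non-finite reference Ct for replicate(s): %s",
                  paste(unique(m$replicate[bad_ref]), collapse = ", ")))
  }
  if (!all(is.finite(m$target_ct)) || any(m$target_ct <= 0) ||
      any(m$reference_ct <= 0)) {
    abort("Ct values must be finite and > 0.")
  }
  if (!control %in% m$condition) {
    abort(sprintf("control condition '%s' not present.", control))
  }
  m %>%
    mutate(delta_ct = .data$target_ct - .data$reference_ct) %>%
    group_by(.data$target) %>%
    mutate(delta_delta_ct = .data$delta_ct -
             mean(.data$delta_ct[.data$condition == control]),
           fold = 2^(-.data$delta_delta_ct)) %>%
    ungroup() %>%
    select("target", "condition", "replicate", "delta_ct",
           "delta_delta_ct", "fold")
}

#' @rdname relative_expression
#' @param folds output of [relative_expression()].
#' @return `expression_summary()`: one row per target x condition with the
#'   geometric-mean fold (`fold = 2^-mean(ddCt)`), the arithmetic mean and
#'   SD of replicate folds, and n.
#' @export
expression_summary <- function(folds) {
  folds %>%
    group_by(.data$target, .data$condition) %>%
    summarise(mean_fold = mean(.data$fold),
              sd_fold = if (n() > 1) sd(.data$fold) else NA_real_,
              fold = 2^(-mean(.data$delta_delta_ct)),
              n = n(), .groups = "drop") %>%
    select("target", "condition", "fold", "mean_fold", "sd_fold", "n") %>%
    arrange(.data$target, .data$condition)
}
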