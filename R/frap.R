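#' Normalize a FRAP recording (double normalization + full-scale anchoring)
#'
#' Applies the standard double-normalization chain: (1) subtract the
#' background trace framewise from the bleach ROI and the bleach control;
#' (2) divide the ROI by the bleach control framewise, undoing acquisition
#' photofading; (3) full-scale anchoring, setting the mean of the pre-bleach
#' frames to 100% and the bleach-frame value to 0%:
#' `y = 100 * (x - x_bleach) / (x_pre - x_bleach)`.
#'
#' @param rec a `frap_recording`.
#' @return a `normalized_curve`: list with `data` (tibble: `t_post`, seconds
#'   since the bleach frame, and `y`, percent recovery), `n_prebleach`,
#'   `y_pre` (always 100), and the pre-bleach/bleach raw anchors.
#' @export
normalize_frap <- function(rec) {
  if (!inherits(rec, "frap_recording")) abort("`rec` must be a frap_recording.")
  d <- rec$data
  bi <- rec$bleach_index
  if (bi < 3L) {
    if (bi < 2L) abort("need >= 1 pre-bleach frame.")
  }
  ctrl <- d$control - d$background
  if (any(ctrl <= 0)) abort("bleach-control trace must be positive after background subtraction.")
  x <- (d$roi - d$background) / ctrl
  pre <- seq_len(bi - 1L)
  x_pre <- mean(x[pre])
  x_bleach <- x[bi]
  if (x_pre == x_bleach) abort("no bleach depth: pre-bleach mean equals bleach-frame value.")
  y <- 100 * (x - x_bleach) / (x_pre - x_bleach)
  structure(
    list(
      data = tibble(t_post = d$time_s - d$time_s[bi], y = y),
      n_prebleach = bi - 1L,
      x_pre = x_pre, x_bleach = x_bleach
    ),
    class = "normalized_curve"
  )
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf(
    "<normalized_curve> %d frames (%d pre-bleach), plateau region ~%.1f%%\n",
    nrow(x$data), x$n_prebleach,
    mean(tail(x$data$y, max(3, ceiling(nrow(x$data) / 10))))
  ))
  invisible(x)
}

#' @method as_tibble normalized_curve
#' @export
as_tibble.normalized_curve <- function(x, ...) x$data

#' Fit a single-component exponential recovery model
#'
#' Least-squares fit of `y(t) = A * (1 - exp(-k t))` to the post-bleach
#' frames of a normalized FRAP curve (the bleach frame, anchored at
#' `y(0) = 0`, is included; the model passes through it exactly). On a
#' full-scale-normalized curve the plateau `A` is the mobile fraction in
#' percent; the recovery half-time is `t_half = ln(2)/k`.
#'
#' Initialization: `A0` is the mean of the final 10% of frames and `k0 =
#' ln(2) / t(A0/2)`, the time at which the curve first reaches half of
#' `A0`. The Levenberg-Marquardt fit bounds `k > 0`; non-convergence is
#' reported via the `converged` flag with parameters from the best iterate.
#'
#' @param curve a `normalized_curve` from [normalize_frap()].
#' @return a `frap_fit`: list with `plateau` (percent), `k` (per second),
#'   `t_half` (seconds, `ln(2)/k`), `r_squared`, `converged`, and the fitted
#'   data.
#' @export
fit_single_exponential <- function(curve) {
  if (!inherits(curve, "normalized_curve")) abort("`curve` must come from normalize_frap().")
  d <- curve$data
  post <- d[d$t_post >= 0, ]
  if (nrow(post) < 10) abort("need >= 10 post-bleach frames to fit.")
  tp <- post$t_post
  y <- post$y

  n_tail <- max(2L, ceiling(nrow(post) * 0.10))
  a0 <- mean(tail(y, n_tail))
  if (!is.finite(a0) || a0 <= 0) a0 <- max(y, 1)
  i_half <- which(y >= a0 / 2)[1]
  t_half0 <- if (!is.na(i_half) && tp[i_half] > 0) tp[i_half] else max(tp) / 4
  k0 <- log(2) / t_half0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-k * tp)),
      data = data.frame(tp = tp, y = y),
      start = list(A = a0, k = k0),
      lower = c(A = 0, k = 1e-9),
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8, maxiter = 1000)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # fall back to the initial guess so a degenerate curve still yields a row
    pars <- c(A = a0, k = k0)
    converged <- FALSE
    fitted_y <- pars[["A"]] * (1 - exp(-pars[["k"]] * tp))
  } else {
    pars <- stats::coef(fit)
    converged <- fit$convInfo$isConv %||% TRUE
    fitted_y <- stats::fitted(fit)
  }
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(
      plateau = unname(pars[["A"]]),
      k = unname(pars[["k"]]),
      t_half = log(2) / unname(pars[["k"]]),
      r_squared = r2,
      converged = isTRUE(converged),
      data = tibble(t_post = tp, y = y, fitted = fitted_y)
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> plateau = %.1f%%, k = %.4g /s, t_half = %.3g s, R^2 = %.4f%s\n",
    x$plateau, x$k, x$t_half, x$r_squared,
    if (!x$converged) " (NOT converged)" else ""
  ))
  invisible(x)
}

#' @rdname fit_single_exponential
#' @param x a `frap_fit`.
#' @param ... unused.
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("plateau", "k", "t_half"),
    estimate = c(x$plateau, x$k, x$t_half)
  )
}

#' @rdname fit_single_exponential
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    plateau = x$plateau, k = x$k, t_half = x$t_half,
    r_squared = x$r_squared, converged = x$converged
  )
}

#' Normalize and fit a batch of FRAP recordings
#'
#' @param recordings list of `frap_recording` objects.
#' @param group character vector of condition labels (one per recording, or
#'   one label recycled).
#' @return tibble with one row per recording: `group`, `recording`,
#'   `plateau`, `k`, `t_half`, `r_squared`, `converged`.
#' @export
frap_fit_batch <- function(recordings, group) {
  if (length(group) == 1L) group <- rep(group, length(recordings))
  if (length(group) != length(recordings)) abort("`group` must match `recordings`.")
  purrr::map2(recordings, seq_along(recordings), function(rec, i) {
    g <- tryCatch(glance(fit_single_exponential(normalize_frap(rec))),
      error = function(e) {
        warn(sprintf("recording %d failed: %s", i, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(g)) return(NULL)
    dplyr::bind_cols(tibble(group = group[[i]], recording = i), g)
  }) |> dplyr::bind_rows()
}

#' Compare FRAP half-times between variants and a reference
#'
#' Per-group summaries of the recovery half-time (median and boxplot
#' five-number statistics, as FRAP results are conventionally displayed)
#' plus Dunnett-adjusted comparisons of each group against the reference
#' (typically the wild-type protein), computed on the per-recording fitted
#' half-times. Groups with fewer than 2 fits are excluded with a warning.
#'
#' @param fits tibble from [frap_fit_batch()] (needs columns `group`,
#'   `t_half`).
#' @param reference reference group label.
#' @param ... passed to [dunnett_test()] (e.g. `n_draws`, `seed`).
#' @return list with `summary` (per-group tibble) and `dunnett` (a
#'   `dunnett_test` object).
#' @export
group_frap_compare <- function(fits, reference, ...) {
  if (!reference %in% fits$group) abort(sprintf("reference group '%s' not present.", reference))
  counts <- dplyr::count(fits, .data$group)
  small <- counts$group[counts$n < 2]
  if (length(small) > 0) {
    warn(paste0("excluding groups with < 2 fits: ", paste(small, collapse = ", ")))
    fits <- dplyr::filter(fits, !.data$group %in% small)
  }
  if (dplyr::n_distinct(fits$group) < 2) abort("need >= 2 groups after exclusions.")
  summ <- fits |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_t_half = median(.data$t_half),
      q1 = quantile(.data$t_half, 0.25)[[1]],
      q3 = quantile(.data$t_half, 0.75)[[1]],
      min = min(.data$t_half), max = max(.data$t_half),
      mean_t_half = mean(.data$t_half),
      sem = sd(.data$t_half) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  dt <- dunnett_test(fits, value = "t_half", group = "group", reference = reference, ...)
  list(summary = summ, dunnett = dt)
}
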