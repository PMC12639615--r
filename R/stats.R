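as_grouped <- function(data, value, group) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!value %in% names(data) || !group %in% names(data)) {
    abort("`value` and `group` must name columns of `data`.")
  }
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  if (any(!keep)) abort("missing values inside observation vectors are not allowed.")
  split(v, g)
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition (delegated to
#' [stats::oneway.test()] with `var.equal = TRUE`). All-constant data (zero
#' within-group variance everywhere) is flagged degenerate with an undefined
#' p-value rather than silently reported.
#'
#' @param data tidy data frame of observations.
#' @param value,group column names of the measurement and the group label.
#' @return one-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`, `degenerate`.
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  groups <- as_grouped(data, value, group)
  k <- length(groups)
  n <- sum(lengths(groups))
  if (k < 2) abort("need >= 2 groups.")
  if (n <= k) abort("total n must exceed the number of groups.")
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ss_within == 0) {
    return(tibble(
      f_statistic = NA_real_, p_value = NA_real_,
      df_between = k - 1L, df_within = n - k, degenerate = TRUE
    ))
  }
  ot <- stats::oneway.test(
    stats::reformulate(group, value),
    data = data, var.equal = TRUE
  )
  tibble(
    f_statistic = unname(ot$statistic),
    p_value = unname(ot$p.value),
    df_between = as.integer(unname(ot$parameter[1])),
    df_within = as.integer(unname(ot$parameter[2])),
    degenerate = FALSE
  )
}

# P(max_j |T_j| >= |t|) under the equicorrelated multivariate-t null of
# Dunnett's procedure, by seeded Monte-Carlo: T_j = (sqrt(l_j) Z0 +
# sqrt(1 - l_j) E_j) / S with shared S = sqrt(chi^2_df / df), which realizes
# the correlation rho_ij = sqrt(l_i l_j) (= 1/2 in balanced designs).
# Returns the empirical distribution of max_j |T_j| as a sorted vector.
dunnett_maxt_sample <- function(lambda, df, n_draws, seed) {
  k <- length(lambda)
  with_seed(seed, {
    z0 <- rnorm(n_draws)
    s <- sqrt(rchisq(n_draws, df) / df)
    mx <- rep(0, n_draws)
    for (j in seq_len(k)) {
      tj <- (sqrt(lambda[j]) * z0 + sqrt(1 - lambda[j]) * rnorm(n_draws)) / s
      mx <- pmax(mx, abs(tj))
    }
    sort(mx)
  })
}

#' Dunnett's many-to-one post hoc test
#'
#' Compares every group against a designated reference (the post hoc
#' procedure applied after one-way ANOVA throughout this package):
#' `t_i = (mean_i - mean_ref) / sqrt(MSE * (1/n_i + 1/n_ref))` with the
#' pooled within-group mean square error, and two-sided adjusted p-values
#' `p_i = P(max_j |T_j| >= |t_i|)` under the equicorrelated multivariate-t
#' null with `rho_ij = sqrt(lambda_i lambda_j)`, `lambda_i = n_i / (n_i +
#' n_ref)` (0.5 in balanced designs) and the pooled error degrees of
#' freedom. The probability is evaluated by seeded Monte-Carlo integration;
#' the draw count, seed, and the Monte-Carlo standard error of each p-value
#' are reported. Adjusted p-values are floored at the exact unadjusted
#' pooled-t p-value, so `p_adj >= p_unadjusted` holds even against
#' Monte-Carlo noise. With a single comparison group the procedure reduces
#' to the plain pooled two-sample t-test.
#'
#' @inheritParams one_way_anova
#' @param reference label of the reference/control group.
#' @param n_draws Monte-Carlo draws (>= 1e4; default 1e5).
#' @param seed integer seed for the Monte-Carlo integration.
#' @return a `dunnett_test` object; `tidy()` returns the per-comparison
#'   tibble (`group`, `estimate` = mean difference vs reference, `n`,
#'   `t_statistic`, `p_unadjusted`, `p_adjusted`, `p_mc_se`).
#' @export
dunnett_test <- function(data, value = "value", group = "group",
                         reference, n_draws = 1e5, seed = 1L) {
  groups <- as_grouped(data, value, group)
  if (missing(reference) || !reference %in% names(groups)) {
    abort("`reference` must name a group present in the data.")
  }
  if (any(lengths(groups) < 2)) abort("every group needs n >= 2.")
  if (n_draws < 1e4) abort("`n_draws` must be >= 1e4.")
  k_all <- length(groups)
  n_tot <- sum(lengths(groups))
  df <- n_tot - k_all
  mse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df
  others <- setdiff(names(groups), reference)
  n_ref <- length(groups[[reference]])
  m_ref <- mean(groups[[reference]])

  est <- vapply(others, function(g) mean(groups[[g]]) - m_ref, numeric(1))
  n_i <- vapply(others, function(g) length(groups[[g]]), numeric(1))
  degenerate <- mse == 0
  if (degenerate) {
    tstat <- rep(NA_real_, length(others))
    p_un <- p_adj <- p_se <- rep(NA_real_, length(others))
  } else {
    se <- sqrt(mse * (1 / n_i + 1 / n_ref))
    tstat <- est / se
    p_un <- 2 * pt(-abs(tstat), df)
    lambda <- n_i / (n_i + n_ref)
    mx <- dunnett_maxt_sample(lambda, df, n_draws, seed)
    # P(max >= |t|) via the sorted sample; findInterval counts draws < |t|
    exceed <- n_draws - findInterval(abs(tstat) - 1e-12, mx)
    p_mc <- exceed / n_draws
    p_se <- sqrt(p_mc * (1 - p_mc) / n_draws)
    p_adj <- pmin(1, pmax(p_mc, p_un))
  }
  structure(
    list(
      comparisons = tibble(
        group = others, estimate = unname(est), n = as.integer(n_i),
        t_statistic = unname(tstat),
        p_unadjusted = unname(p_un), p_adjusted = unname(p_adj),
        p_mc_se = unname(p_se)
      ),
      reference = reference, n_reference = n_ref,
      df = df, mse = mse, degenerate = degenerate,
      method = "dunnett-mc", n_draws = as.integer(n_draws), seed = as.integer(seed)
    ),
    class = "dunnett_test"
  )
}

#' @export
print.dunnett_test <- function(x, ...) {
  cat(sprintf(
    "Dunnett many-to-one test vs '%s' (df = %d, MSE = %.4g, %d MC draws, seed %d)%s\n",
    x$reference, x$df, x$mse, x$n_draws, x$seed,
    if (x$degenerate) " [degenerate: zero MSE]" else ""
  ))
  print(x$comparisons)
  invisible(x)
}

#' @rdname dunnett_test
#' @param x a `dunnett_test`.
#' @param ... unused.
#' @method tidy dunnett_test
#' @export
tidy.dunnett_test <- function(x, ...) x$comparisons

#' @rdname dunnett_test
#' @method glance dunnett_test
#' @export
glance.dunnett_test <- function(x, ...) {
  tibble(
    reference = x$reference, df = x$df, mse = x$mse,
    n_comparisons = nrow(x$comparisons),
    n_draws = x$n_draws, seed = x$seed, degenerate = x$degenerate
  )
}

#' Per-group summary statistics
#'
#' Mean, SEM, median and the boxplot five-number summary for each group of a
#' tidy measurement table.
#'
#' @inheritParams one_way_anova
#' @return tibble with one row per group.
#' @export
summarize_groups <- function(data, value = "value", group = "group") {
  groups <- as_grouped(data, value, group)
  purrr::map2(names(groups), groups, function(g, x) {
    fn <- stats::fivenum(x)
    tibble(
      group = g, n = length(x), mean = mean(x),
      sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
      median = fn[3], min = fn[1], q1 = fn[2], q3 = fn[4], max = fn[5]
    )
  }) |> dplyr::bind_rows()
}
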