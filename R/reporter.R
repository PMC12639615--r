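#' Simulation parameters for one dual-luciferase condition
#'
#' @param mean_repression expected fractional reduction in relative activity
#'   vs the empty-vector control, in `[0, 1)`; the wild-type protein
#'   represses its AT-rich MAR reporter targets by about 0.75.
#' @param n_replicates replicate wells (>= 2).
#' @param cv multiplicative coefficient of variation (>= 0), applied as an
#'   independent mean-1 log-normal factor to the firefly and the Renilla
#'   counts of each replicate.
#' @param renilla_mean expected Renilla counts (> 0).
#' @param firefly_control_mean expected firefly counts of the empty-vector
#'   control (> 0); a condition's expected firefly counts are
#'   `firefly_control_mean * (1 - mean_repression)`.
#' @param seed optional per-condition seed; when `NULL` the table-level seed
#'   of [generate_reporter_table()] governs all draws.
#' @return a `reporter_sim_params` list.
#' @export
reporter_sim_params <- function(mean_repression = 0,
                                n_replicates = 8L,
                                cv = 0.1,
                                renilla_mean = 1e5,
                                firefly_control_mean = 2e4,
                                seed = NULL) {
  if (mean_repression < 0 || mean_repression >= 1) abort("`mean_repression` must be in [0, 1).")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  if (cv < 0) abort("`cv` must be >= 0.")
  if (renilla_mean <= 0 || firefly_control_mean <= 0) abort("luminescence means must be > 0.")
  structure(
    list(
      mean_repression = mean_repression, n_replicates = as.integer(n_replicates),
      cv = cv, renilla_mean = renilla_mean,
      firefly_control_mean = firefly_control_mean, seed = seed
    ),
    class = "reporter_sim_params"
  )
}

# mean-1 log-normal multiplicative noise with coefficient of variation cv
lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sigma^2 / 2, sigma))
}

#' Simulate a dual-luciferase reporter plate
#'
#' Generates (condition, replicate, firefly, renilla) rows for a set of
#' transfection conditions, one of which must be the empty-vector control
#' with `mean_repression = 0`. The expected firefly/Renilla ratio of a
#' condition relative to the control equals `1 - mean_repression`.
#'
#' @param conditions named list of [reporter_sim_params()], one per
#'   condition label.
#' @param control label of the empty-vector control condition.
#' @param seed integer seed.
#' @return a tibble (`condition`, `replicate`, `firefly`, `renilla`) with
#'   attribute `control` carrying the control label.
#' @export
generate_reporter_table <- function(conditions, control = "control", seed = 1L) {
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    abort("`conditions` must be a named list.")
  }
  if (!control %in% names(conditions)) abort("missing empty-vector control condition.")
  if (conditions[[control]]$mean_repression != 0) {
    abort("the control condition must have mean_repression = 0.")
  }
  with_seed(seed, {
    rows <- purrr::imap(conditions, function(p, label) {
      if (!inherits(p, "reporter_sim_params")) abort("each condition needs reporter_sim_params().")
      draw <- function() {
        n <- p$n_replicates
        tibble(
          condition = label,
          replicate = seq_len(n),
          firefly = p$firefly_control_mean * (1 - p$mean_repression) * lnorm_factor(n, p$cv),
          renilla = p$renilla_mean * lnorm_factor(n, p$cv)
        )
      }
      if (is.null(p$seed)) draw() else with_seed(p$seed, draw())
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "control") <- control
    out
  })
}

#' Renilla-normalized relative luciferase activity
#'
#' Computes the per-replicate firefly/Renilla ratio and expresses it
#' relative to the mean ratio of the empty-vector control condition, so the
#' control's mean relative activity is 1 by construction. Per-condition
#' mean +/- SEM summaries are available via [reporter_summary()].
#'
#' @param table data frame with columns `condition`, `replicate`, `firefly`
#'   (>= 0), `renilla` (> 0).
#' @param control label of the empty-vector control condition (defaults to
#'   the table's `control` attribute).
#' @return the input tibble with added columns `ratio` and
#'   `relative_activity`; attribute `control` is preserved.
#' @export
relative_activity <- function(table, control = attr(table, "control") %||% "control") {
  needed <- c("condition", "firefly", "renilla")
  if (!all(needed %in% names(table))) {
    abort("`table` needs columns condition, firefly, renilla.")
  }
  if (!control %in% table$condition) abort(sprintf("control condition '%s' not present.", control))
  if (any(table$renilla <= 0)) abort("renilla counts must be strictly positive.")
  if (any(table$firefly < 0)) abort("firefly counts must be nonnegative.")
  if (sum(table$condition == control) < 2) abort("control condition needs >= 2 replicates.")
  out <- dplyr::mutate(table, ratio = .data$firefly / .data$renilla)
  ctrl_mean <- mean(out$ratio[out$condition == control])
  out <- dplyr::mutate(out, relative_activity = .data$ratio / ctrl_mean)
  attr(out, "control") <- control
  out
}

#' Per-condition summary of relative activities
#'
#' @param activities output of [relative_activity()].
#' @return tibble with `condition`, `n`, `mean_relative_activity`, `sem`.
#' @export
reporter_summary <- function(activities) {
  activities |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_relative_activity = mean(.data$relative_activity),
      sem = sd(.data$relative_activity) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Classify transcriptional-repression outcomes vs the wild type
#'
#' Dunnett-adjusted comparison of each condition's relative activity against
#' the wild-type protein: `reduced_repression` when activity is
#' significantly higher than WT (the variant fails to repress),
#' `increased_repression` when significantly lower, `retained` otherwise.
#' Conditions with degenerate variance are flagged uncallable (`NA`).
#'
#' @param activities output of [relative_activity()].
#' @param wt label of the wild-type condition (statistical reference).
#' @param alpha two-sided significance level.
#' @param exclude conditions to leave out of the comparison family (the
#'   empty-vector control by default).
#' @param ... passed to [dunnett_test()].
#' @return tibble: `condition`, `mean_relative_activity`, `estimate` (mean
#'   difference vs WT), `p_adjusted`, `call`.
#' @export
repression_call <- function(activities, wt = "WT", alpha = 0.05,
                            exclude = attr(activities, "control") %||% "control", ...) {
  if (!wt %in% activities$condition) abort(sprintf("WT condition '%s' not present.", wt))
  dat <- dplyr::filter(activities, !.data$condition %in% exclude)
  counts <- dplyr::count(dat, .data$condition)
  if (any(counts$n < 2)) abort("every condition needs >= 2 replicates.")
  dt <- dunnett_test(dat, value = "relative_activity", group = "condition",
                     reference = wt, ...)
  means <- dat |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_relative_activity = mean(.data$relative_activity), .groups = "drop")
  tidy(dt) |>
    dplyr::rename(condition = "group") |>
    dplyr::left_join(means, by = "condition") |>
    dplyr::mutate(
      call = dplyr::case_when(
        is.na(.data$p_adjusted) ~ NA_character_,
        .data$p_adjusted < alpha & .data$estimate > 0 ~ "reduced_repression",
        .data$p_adjusted < alpha & .data$estimate < 0 ~ "increased_repression",
        TRUE ~ "retained"
      )
    ) |>
    dplyr::select("condition", "mean_relative_activity", "estimate", "p_adjusted", "call")
}
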