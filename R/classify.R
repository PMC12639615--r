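call_levels <- c("increased", "normal", "decreased")
repr_levels <- c("reduced_repression", "retained", "increased_repression")

profile_call_cols <- c(
  "aggregation_call", "coloc_call", "nuclear_fraction_call",
  "repression_call_ctip2", "repression_call_nr4a2", "mobility_call"
)

#' Classification rule table
#'
#' Returns the versioned decision rule used by [assign_subgroup()]. Version
#' `"v1"` operationalizes the verbal criteria for the functional subgroups:
#' \itemize{
#'   \item `condensate_class`: the localization pattern is `condensate`, or
#'     the variant lies in the HOX domain and shows at least one abnormal
#'     call (healthy HOX-region variants with all-normal profiles are not
#'     swept into this class);
#'   \item `increased_function`: DNA colocalization is increased and neither
#'     reporter shows reduced repression (reduced nuclear mobility supports
#'     the call but is not required);
#'   \item `partial_LoF`: at least one reporter shows reduced repression and
#'     colocalization is not increased;
#'   \item `unclassified` otherwise.
#' }
#' Condensate-forming variants take precedence over `partial_LoF` because
#' their reduced repression accompanies a qualitatively different
#' (aggregating) localization mechanism.
#'
#' @param version rule-table version string.
#' @return a list describing the rules (for provenance logging).
#' @export
classification_rules <- function(version = "v1") {
  if (!identical(version, "v1")) abort(sprintf("unknown rule-table version '%s'.", version))
  list(
    version = "v1",
    order = c("condensate_class", "increased_function", "partial_LoF", "unclassified"),
    condensate_class = "pattern == 'condensate' OR (domain == 'HOX' AND any abnormal call)",
    increased_function = "coloc_call == 'increased' AND no repression call == 'reduced_repression'",
    partial_LoF = "any repression call == 'reduced_repression' AND coloc_call != 'increased'"
  )
}

#' Assign functional subgroups to variant profiles
#'
#' Applies the versioned rule table (see [classification_rules()]) to a
#' profile tibble, adding a `subgroup` column with values
#' `increased_function`, `partial_LoF`, `condensate_class`, or
#' `unclassified`. Assignment is a pure function of the call fields: the
#' same profile always receives the same label, and no profile can be both
#' `increased_function` and `partial_LoF`.
#'
#' @param profiles tibble with columns `variant`, `domain`, `pattern`, and
#'   the six call columns (`aggregation_call`, `coloc_call`,
#'   `nuclear_fraction_call`, `repression_call_ctip2`,
#'   `repression_call_nr4a2`, `mobility_call`). Rows with every call `NA`
#'   raise an error.
#' @param rules_version rule-table version.
#' @return the input tibble with a `subgroup` column appended.
#' @export
assign_subgroup <- function(profiles, rules_version = "v1") {
  rules <- classification_rules(rules_version)
  missing_cols <- setdiff(c("variant", "domain", profile_call_cols), names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("profiles are missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"pattern" %in% names(profiles)) profiles$pattern <- NA_character_
  calls <- profiles[profile_call_cols]
  all_na <- apply(is.na(calls), 1, all)
  if (any(all_na)) {
    abort(paste0("profiles with every call NA cannot be classified: ",
                 paste(profiles$variant[all_na], collapse = ", ")))
  }
  not_na_eq <- function(x, v) !is.na(x) & x == v
  abnormal <- not_na_eq(profiles$aggregation_call, "increased") |
    not_na_eq(profiles$aggregation_call, "decreased") |
    not_na_eq(profiles$coloc_call, "increased") |
    not_na_eq(profiles$coloc_call, "decreased") |
    not_na_eq(profiles$nuclear_fraction_call, "increased") |
    not_na_eq(profiles$nuclear_fraction_call, "decreased") |
    not_na_eq(profiles$repression_call_ctip2, "reduced_repression") |
    not_na_eq(profiles$repression_call_ctip2, "increased_repression") |
    not_na_eq(profiles$repression_call_nr4a2, "reduced_repression") |
    not_na_eq(profiles$repression_call_nr4a2, "increased_repression") |
    not_na_eq(profiles$mobility_call, "reduced_mobility")
  any_reduced <- not_na_eq(profiles$repression_call_ctip2, "reduced_repression") |
    not_na_eq(profiles$repression_call_nr4a2, "reduced_repression")
  coloc_up <- not_na_eq(profiles$coloc_call, "increased")
  condensate <- not_na_eq(profiles$pattern, "condensate") |
    (not_na_eq(profiles$domain, "HOX") & abnormal)
  profiles$subgroup <- dplyr::case_when(
    condensate ~ "condensate_class",
    coloc_up & !any_reduced ~ "increased_function",
    any_reduced & !coloc_up ~ "partial_LoF",
    TRUE ~ "unclassified"
  )
  attr(profiles, "rules_version") <- rules$version
  profiles
}

#' Subgroup counts and fractions for a variant cohort
#'
#' @param profiles tibble with a `subgroup` column (see [assign_subgroup()]).
#' @return tibble: `subgroup`, `n`, `fraction` of all profiles. Counts sum
#'   to the number of profiles.
#' @export
cohort_summary <- function(profiles) {
  if (nrow(profiles) < 1) abort("need at least one profile.")
  if (!"subgroup" %in% names(profiles)) abort("run assign_subgroup() first.")
  all_levels <- c("increased_function", "partial_LoF", "condensate_class", "unclassified")
  profiles |>
    dplyr::count(.data$subgroup, name = "n") |>
    dplyr::right_join(tibble(subgroup = all_levels), by = "subgroup") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      fraction = .data$n / nrow(profiles)
    ) |>
    dplyr::arrange(match(.data$subgroup, all_levels))
}

sign_call <- function(estimate, p_adjusted, alpha) {
  dplyr::case_when(
    is.na(p_adjusted) ~ NA_character_,
    p_adjusted < alpha & estimate > 0 ~ "increased",
    p_adjusted < alpha & estimate < 0 ~ "decreased",
    TRUE ~ "normal"
  )
}

metric_calls <- function(metrics, metric, wt, alpha, n_draws, seed) {
  dat <- metrics |>
    dplyr::filter(.data$ok, !is.na(.data[[metric]])) |>
    dplyr::select(group = "group", value = dplyr::all_of(metric))
  counts <- dplyr::count(dat, .data$group)
  dat <- dplyr::filter(dat, .data$group %in% counts$group[counts$n >= 2])
  if (!wt %in% dat$group || dplyr::n_distinct(dat$group) < 2) {
    return(tibble(variant = character(), call = character(),
                  estimate = numeric(), p_adjusted = numeric()))
  }
  dt <- dunnett_test(dat, reference = wt, n_draws = n_draws, seed = seed)
  tidy(dt) |>
    dplyr::transmute(
      variant = .data$group,
      call = sign_call(.data$estimate, .data$p_adjusted, alpha),
      estimate = .data$estimate, p_adjusted = .data$p_adjusted
    )
}

#' Build per-variant assay profiles from the three assay outputs
#'
#' Joins the imaging, FRAP, and reporter readouts keyed by variant, turns
#' each Dunnett-adjusted comparison against the wild type into a
#' standardized call, and returns one profile row per variant. Imaging
#' metrics give `increased`/`normal`/`decreased` calls; FRAP half-times give
#' `reduced_mobility` when significantly longer than WT; reporter assays
#' give the [repression_call()] labels per reporter construct. The wild type
#' itself receives all-`normal`/`retained` calls. Variants present in no
#' table are excluded with a warning. Every call is traceable through the
#' `provenance` attribute (readout, estimate, adjusted p).
#'
#' @param metrics [batch_quantify()] output with `group` = variant (may be
#'   `NULL`).
#' @param frap_fits [frap_fit_batch()] output (may be `NULL`).
#' @param activity_ctip2,activity_nr4a2 [relative_activity()] outputs for
#'   the two MAR reporter constructs (may be `NULL`).
#' @param metadata tibble with columns `variant`, `domain` (`CUT1`, `CUT2`,
#'   `HOX`, `none`) and optionally `pattern`.
#' @param wt wild-type variant label.
#' @param alpha significance level for all calls.
#' @param n_draws,seed Monte-Carlo settings for [dunnett_test()].
#' @return tibble of variant profiles (one row per variant) ready for
#'   [assign_subgroup()].
#' @export
build_profiles <- function(metrics = NULL, frap_fits = NULL,
                           activity_ctip2 = NULL, activity_nr4a2 = NULL,
                           metadata, wt = "WT", alpha = 0.05,
                           n_draws = 1e5, seed = 1L) {
  if (!all(c("variant", "domain") %in% names(metadata))) {
    abort("`metadata` needs columns variant and domain.")
  }
  if (!"pattern" %in% names(metadata)) metadata$pattern <- NA_character_
  prov <- list()
  empty <- tibble(variant = character(), call = character())

  img_calls <- list(aggregation_call = empty, coloc_call = empty, nuclear_fraction_call = empty)
  if (!is.null(metrics)) {
    if (!wt %in% metrics$group) abort("WT must be present in the imaging table.")
    for (m in c("aggregation_ratio", "coloc_ratio", "nuclear_fraction")) {
      cc <- metric_calls(metrics, m, wt, alpha, n_draws, seed)
      prov[[m]] <- dplyr::mutate(cc, readout = m)
      nm <- switch(m, aggregation_ratio = "aggregation_call",
                   coloc_ratio = "coloc_call", nuclear_fraction = "nuclear_fraction_call")
      img_calls[[nm]] <- dplyr::select(cc, "variant", "call")
    }
  }

  mob <- empty
  if (!is.null(frap_fits)) {
    if (!wt %in% frap_fits$group) abort("WT must be present in the FRAP table.")
    dat <- dplyr::select(frap_fits, group = "group", value = "t_half")
    dt <- dunnett_test(dat, reference = wt, n_draws = n_draws, seed = seed)
    mob <- tidy(dt) |>
      dplyr::transmute(
        variant = .data$group,
        call = dplyr::case_when(
          is.na(.data$p_adjusted) ~ NA_character_,
          .data$p_adjusted < alpha & .data$estimate > 0 ~ "reduced_mobility",
          TRUE ~ "normal"
        ),
        estimate = .data$estimate, p_adjusted = .data$p_adjusted
      )
    prov$t_half <- dplyr::mutate(mob, readout = "t_half")
    mob <- dplyr::select(mob, "variant", "call")
  }

  repr <- function(activities, label) {
    if (is.null(activities)) return(empty)
    cc <- repression_call(activities, wt = wt, alpha = alpha, n_draws = n_draws, seed = seed)
    prov[[label]] <<- dplyr::transmute(cc, variant = .data$condition, call = .data$call,
                                       estimate = .data$estimate,
                                       p_adjusted = .data$p_adjusted, readout = label)
    dplyr::transmute(cc, variant = .data$condition, call = .data$call)
  }
  rc <- repr(activity_ctip2, "repression_ctip2")
  rn <- repr(activity_nr4a2, "repression_nr4a2")

  assayed <- unique(c(
    img_calls$aggregation_call$variant, img_calls$coloc_call$variant,
    img_calls$nuclear_fraction_call$variant, mob$variant, rc$variant, rn$variant
  ))
  join_call <- function(base, calls, name) {
    calls <- setNames(calls, c("variant", name))
    dplyr::left_join(base, calls, by = "variant")
  }
  out <- dplyr::filter(metadata, .data$variant %in% c(assayed, wt))
  dropped <- setdiff(metadata$variant, out$variant)
  if (length(dropped) > 0) {
    warn(paste0("variants present in no assay table were excluded: ",
                paste(dropped, collapse = ", ")))
  }
  out <- out |>
    join_call(img_calls$aggregation_call, "aggregation_call") |>
    join_call(img_calls$coloc_call, "coloc_call") |>
    join_call(img_calls$nuclear_fraction_call, "nuclear_fraction_call") |>
    join_call(rc, "repression_call_ctip2") |>
    join_call(rn, "repression_call_nr4a2") |>
    join_call(mob, "mobility_call")
  # the reference is normal/retained by definition, for any assay it appears in
  is_wt <- out$variant == wt
  if (any(is_wt)) {
    if (!is.null(metrics)) {
      out$aggregation_call[is_wt] <- "normal"
      out$coloc_call[is_wt] <- "normal"
      out$nuclear_fraction_call[is_wt] <- "normal"
    }
    if (!is.null(frap_fits)) out$mobility_call[is_wt] <- "normal"
    if (!is.null(activity_ctip2)) out$repression_call_ctip2[is_wt] <- "retained"
    if (!is.null(activity_nr4a2)) out$repression_call_nr4a2[is_wt] <- "retained"
  }
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  attr(out, "alpha") <- alpha
  out
}

#' Curated functional-outcome calls for the SATB2 missense variant cohort
#'
#' Loads the bundled per-variant call table for 31 etiological SATB2
#' missense variants in the CUT1/CUT2/HOX DNA-binding domains plus 3 rare
#' population-control variants carried by healthy individuals. Calls for 22
#' etiological variants follow their individually published assay outcomes;
#' the remaining 9 rows (flagged `synthetic = TRUE`) are placeholder
#' encodings consistent with the published subgroup totals, since their
#' per-assay outcomes are only available in figure form. See the bundled CSV
#' `extdata/satb2_variant_calls_synthetic.csv`.
#'
#' @return tibble with one row per variant: `variant`, `domain`, `cohort`
#'   (`etiological` / `population_control`), `pattern`, the six call
#'   columns, and `synthetic`.
#' @export
satb2_variant_calls <- function() {
  path <- system.file("extdata", "satb2_variant_calls_synthetic.csv", package = "satb2quant")
  if (path == "") abort("bundled variant call table not found.")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
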