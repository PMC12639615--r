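profile_row <- function(variant = "v", domain = "CUT1", pattern = "diffuse",
                        aggregation = "normal", coloc = "normal",
                        nuclear = "normal", ctip2 = "retained",
                        nr4a2 = "retained", mobility = NA_character_) {
  tibble::tibble(
    variant = variant, domain = domain, pattern = pattern,
    aggregation_call = aggregation, coloc_call = coloc,
    nuclear_fraction_call = nuclear,
    repression_call_ctip2 = ctip2, repression_call_nr4a2 = nr4a2,
    mobility_call = mobility
  )
}

test_that("subgroup rules reproduce the documented decision table", {
  # stronger DNA colocalization with retained/increased repression and
  # reduced mobility -> increased function
  gof <- profile_row(coloc = "increased", aggregation = "decreased",
                     ctip2 = "increased_repression", mobility = "reduced_mobility")
  expect_equal(assign_subgroup(gof)$subgroup, "increased_function")
  # mobility is supportive, not required
  gof2 <- profile_row(coloc = "increased", ctip2 = "retained", mobility = NA)
  expect_equal(assign_subgroup(gof2)$subgroup, "increased_function")

  lof <- profile_row(coloc = "decreased", ctip2 = "reduced_repression",
                     nr4a2 = "reduced_repression")
  expect_equal(assign_subgroup(lof)$subgroup, "partial_LoF")
  # one reporter suffices for a partial-LoF call
  lof1 <- profile_row(ctip2 = "reduced_repression")
  expect_equal(assign_subgroup(lof1)$subgroup, "partial_LoF")

  cond <- profile_row(domain = "HOX", pattern = "condensate",
                      ctip2 = "reduced_repression", nr4a2 = "reduced_repression")
  expect_equal(assign_subgroup(cond)$subgroup, "condensate_class")

  # an all-normal profile in the HOX domain stays unclassified (benign-like)
  benign_hox <- profile_row(variant = "p.His646Tyr", domain = "HOX")
  expect_equal(assign_subgroup(benign_hox)$subgroup, "unclassified")
  benign <- profile_row(variant = "p.Arg431His")
  expect_equal(assign_subgroup(benign)$subgroup, "unclassified")
})

test_that("assignment is pure, exclusive, and rejects empty profiles", {
  p <- profile_row(coloc = "increased")
  expect_identical(assign_subgroup(p)$subgroup, assign_subgroup(p)$subgroup)
  # no profile can be both increased_function and partial_LoF: coloc increased
  # together with reduced repression satisfies neither rule
  both <- profile_row(coloc = "increased", ctip2 = "reduced_repression")
  expect_equal(assign_subgroup(both)$subgroup, "unclassified")
  allna <- profile_row(aggregation = NA, coloc = NA, nuclear = NA,
                       ctip2 = NA, nr4a2 = NA, mobility = NA)
  expect_error(assign_subgroup(allna), "every call NA")
  expect_error(assign_subgroup(p, rules_version = "v99"), "unknown rule-table")
})

test_that("the bundled cohort yields 8/31 increased-function etiological variants", {
  calls <- satb2_variant_calls()
  expect_equal(nrow(calls), 34)
  classified <- assign_subgroup(calls)
  etio <- classified[classified$cohort == "etiological", ]
  expect_equal(nrow(etio), 31)
  summ <- cohort_summary(etio)
  expect_equal(summ$n[summ$subgroup == "increased_function"], 8L)
  expect_equal(round(100 * summ$fraction[summ$subgroup == "increased_function"]), 26)
  expect_equal(sum(summ$n), 31L)
  # population controls stay unclassified
  ctrl <- classified[classified$cohort == "population_control", ]
  expect_true(all(ctrl$subgroup == "unclassified"))
})

test_that("cohort_summary conserves counts and reports empty subgroups as 0", {
  p <- assign_subgroup(profile_row(coloc = "increased"))
  s <- cohort_summary(p)
  expect_equal(sum(s$n), 1L)
  expect_equal(s$n[s$subgroup == "partial_LoF"], 0L)
  expect_equal(s$fraction[s$subgroup == "partial_LoF"], 0)
})

test_that("build_profiles joins assay outputs into traceable calls", {
  # imaging: WT vs a high-coloc variant vs an imaging-only variant
  pairs <- c(
    lapply(1:6, function(s) generate_nucleus_image(
      nucleus_phenotype("dna_cage", coloc_level = 0.45), seed = s)),
    lapply(7:12, function(s) generate_nucleus_image(
      nucleus_phenotype("dna_cage", coloc_level = 0.9), seed = s)),
    lapply(13:18, function(s) generate_nucleus_image(
      nucleus_phenotype("dna_cage", coloc_level = 0.45), seed = s))
  )
  metrics <- batch_quantify(pairs, rep(c("WT", "gof", "imaging_only"), each = 6))

  # FRAP: the candidate variant recovers at half the rate
  recs <- c(lapply(1:10, function(s) generate_frap_recording(
              frap_sim_params(k = 0.05, noise_sd = 15), seed = s)),
            lapply(11:20, function(s) generate_frap_recording(
              frap_sim_params(k = 0.025, noise_sd = 15), seed = s)))
  fits <- frap_fit_batch(recs, rep(c("WT", "gof"), each = 10))

  # reporters: variant represses at least as strongly as WT
  tab <- generate_reporter_table(list(
    control = reporter_sim_params(0, cv = 0.1),
    WT = reporter_sim_params(0.75, cv = 0.1),
    gof = reporter_sim_params(0.9, cv = 0.1)
  ), seed = 31)
  act <- relative_activity(tab)

  meta <- tibble::tibble(
    variant = c("WT", "gof", "imaging_only", "never_assayed"),
    domain = c("none", "CUT1", "CUT1", "CUT2"),
    pattern = c("diffuse", "dna_cage", "dna_cage", NA)
  )
  expect_warning(
    profiles <- build_profiles(
      metrics = metrics, frap_fits = fits,
      activity_ctip2 = act, activity_nr4a2 = act,
      metadata = meta, wt = "WT", n_draws = 1e4, seed = 2
    ),
    "never_assayed"
  )
  expect_equal(sort(profiles$variant), sort(c("WT", "gof", "imaging_only")))
  wt <- profiles[profiles$variant == "WT", ]
  expect_equal(wt$coloc_call, "normal")
  expect_equal(wt$repression_call_ctip2, "retained")
  gof <- profiles[profiles$variant == "gof", ]
  expect_equal(gof$coloc_call, "increased")
  expect_equal(gof$mobility_call, "reduced_mobility")
  expect_false(identical(gof$repression_call_ctip2, "reduced_repression"))
  im <- profiles[profiles$variant == "imaging_only", ]
  expect_true(is.na(im$repression_call_ctip2))
  expect_true(is.na(im$mobility_call))

  # every call traceable to an adjusted p and effect direction
  prov <- attr(profiles, "provenance")
  expect_true(all(c("variant", "readout", "estimate", "p_adjusted") %in% names(prov)))
  expect_gt(nrow(prov), 0)

  classified <- assign_subgroup(profiles)
  expect_equal(classified$subgroup[classified$variant == "gof"], "increased_function")
})
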