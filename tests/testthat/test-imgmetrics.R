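same_channel_pair <- function(img, pixel_size = NA_real_) {
  structure(list(protein = img, dna = img, pixel_size = pixel_size,
                 phenotype = NULL, style = "airyscan", seed = NA_integer_, truth = NULL),
            class = "image_pair")
}

test_that("identical channels give ratio 1 for aggregation and colocalization", {
  # noiseless, so Moments and Minimum both cut inside the same empty
  # intensity gap and the two masks coincide exactly
  p <- generate_nucleus_image(nucleus_phenotype("dna_cage"), seed = 3, noise_sd = 0)
  pair <- same_channel_pair(p$dna)
  expect_equal(as.numeric(aggregation_ratio(pair)), 1.0)
  expect_equal(as.numeric(coloc_ratio(pair)), 1.0)
})

test_that("empty masks yield missing ratios, never silent zeros", {
  flat <- same_channel_pair(matrix(0.4, 64, 64))
  expect_true(is.na(suppressWarnings(as.numeric(aggregation_ratio(flat)))))
  expect_true(is.na(as.numeric(coloc_ratio(flat))))
  expect_true(is.na(as.numeric(nuclear_fraction(flat))))
})

test_that("ratios recover generator truth on noiseless images (within 0.02)", {
  for (lab in c("diffuse", "dna_cage", "anti_dna_aggregate", "condensate")) {
    for (s in 1:3) {
      p <- generate_nucleus_image(nucleus_phenotype(lab), seed = s, noise_sd = 0)
      expect_lt(abs(as.numeric(coloc_ratio(p)) - p$truth$coloc_fraction), 0.02)
      expect_lt(abs(as.numeric(aggregation_ratio(p)) - p$truth$aggregation), 0.02)
    }
  }
  # the nuclear-fraction readout is defined on the field-of-view regime
  for (cf in c(0, 0.5)) {
    p <- generate_nucleus_image(nucleus_phenotype("diffuse", cytoplasm_fraction = cf),
                                seed = 2, noise_sd = 0, style = "field")
    expect_lt(abs(as.numeric(nuclear_fraction(p)) - p$truth$nuclear_fraction), 0.02)
  }
})

test_that("aggregated phenotypes give strictly smaller aggregation ratios than diffuse", {
  agg <- mean(sapply(1:8, function(s)
    as.numeric(aggregation_ratio(generate_nucleus_image(
      nucleus_phenotype("anti_dna_aggregate"), seed = s)))))
  dif <- mean(sapply(1:8, function(s)
    as.numeric(aggregation_ratio(generate_nucleus_image(
      nucleus_phenotype("diffuse"), seed = s)))))
  expect_lt(agg, dif)
})

test_that("channel-method pairing is asymmetric by design", {
  p <- generate_nucleus_image(nucleus_phenotype("dna_cage"), seed = 9)
  swapped <- structure(list(protein = p$dna, dna = p$protein,
                            pixel_size = p$pixel_size, phenotype = NULL,
                            style = p$style, seed = NA_integer_, truth = NULL),
                       class = "image_pair")
  # colocalization uses Moments on both channels, so swapping channels only
  # swaps numerator conventions: areas must swap accordingly
  a <- coloc_ratio(p); b <- coloc_ratio(swapped)
  expect_equal(attr(a, "areas")[["protein"]], attr(b, "areas")[["dna"]])
  expect_equal(attr(a, "areas")[["both"]], attr(b, "areas")[["both"]])
  # aggregation uses Moments/Minimum, so the swapped ratio is not the inverse
  expect_false(isTRUE(all.equal(
    as.numeric(aggregation_ratio(p)) * as.numeric(aggregation_ratio(swapped)), 1)))
})

test_that("intensity_profile matches closed forms on constructed images", {
  const <- same_channel_pair(matrix(0.5, 32, 32))
  prof <- intensity_profile(const, c(2, 10), c(28, 10))
  expect_true(all(abs(prof$protein - 0.5) < 1e-12))

  # axis-aligned line equals direct row extraction
  img <- matrix(runif(32 * 32), 32, 32)
  pair <- same_channel_pair(img)
  prof2 <- intensity_profile(pair, c(0, 7), c(31, 7))
  expect_equal(prof2$protein, img[8, 1:32])

  # diagonal on a linear ramp has the ramp's directional derivative as slope
  ramp <- outer(seq_len(64), seq_len(64), function(r, c) 0.3 * r + 0.7 * c) / 64
  rpair <- same_channel_pair(ramp, pixel_size = 0.1)
  prof3 <- intensity_profile(rpair, c(5, 5), c(45, 45))
  slopes <- diff(prof3$protein) / diff(prof3$distance)
  expect_equal(slopes, rep((0.3 + 0.7) / 64 / sqrt(2), length(slopes)), tolerance = 1e-8)
  expect_equal(prof3$distance_um, prof3$distance * 0.1)

  expect_error(intensity_profile(const, c(5, 5), c(5, 5)), "zero-length")
  expect_error(intensity_profile(const, c(-1, 5), c(10, 5)), "inside")
})

test_that("batch_quantify handles grouping, failures and summaries", {
  pairs <- c(
    lapply(1:3, function(s) generate_nucleus_image(nucleus_phenotype("dna_cage", coloc_level = 0.9), seed = s)),
    lapply(4:6, function(s) generate_nucleus_image(nucleus_phenotype("dna_cage", coloc_level = 0.3), seed = s))
  )
  groups <- rep(c("high", "low"), each = 3)
  tab <- batch_quantify(pairs, groups)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$ok))
  summ <- summarize_metrics(tab)
  hi <- summ$mean[summ$group == "high" & summ$metric == "coloc_ratio"]
  lo <- summ$mean[summ$group == "low" & summ$metric == "coloc_ratio"]
  expect_gt(hi, lo)

  # identical images give SEM 0
  same <- lapply(1:4, function(i) pairs[[1]])
  ssum <- summarize_metrics(batch_quantify(same, "g"))
  expect_true(all(ssum$sem == 0))

  # a corrupt entry is flagged and the batch continues
  bad <- pairs
  bad[[2]] <- structure(list(protein = matrix(1, 4, 4), dna = matrix(1, 5, 5)),
                        class = "image_pair")
  tab2 <- suppressWarnings(batch_quantify(bad, groups))
  expect_equal(sum(!tab2$ok), 1)
  expect_equal(nrow(tab2), 6)

  expect_error(batch_quantify(list(), "g"), "at least one")
  expect_error(batch_quantify(pairs, c("a", "")), "label")
})
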