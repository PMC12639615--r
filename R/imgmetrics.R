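check_pair <- function(pair) {
  if (!inherits(pair, "image_pair")) abort("`pair` must be an image_pair.")
  if (!identical(dim(pair$protein), dim(pair$dna))) {
    abort("protein and dna channels must have identical dimensions.")
  }
  invisible(pair)
}

ratio_or_na <- function(num, denom) {
  if (is.na(denom) || denom == 0) NA_real_ else num / denom
}

#' Aggregation ratio of a two-channel nucleus image
#'
#' Thresholded-area ratio quantifying how clustered the protein signal is:
#' area of the protein mask (Moments threshold) divided by the area of the
#' DNA-stain mask (Minimum threshold). Aggregated/clustered protein covers
#' fewer pixels, giving a smaller ratio than a diffuse signal. Returns `NA`
#' (with a warning naming the cause) when the DNA mask is empty or the
#' Minimum threshold fails on a non-bimodal histogram.
#'
#' @param pair an `image_pair` (see [generate_nucleus_image()],
#'   [read_image_pair()]).
#' @return a single numeric ratio (dimensionless, >= 0) with attributes
#'   `areas` (named numerator/denominator pixel counts) and `levels`.
#' @export
aggregation_ratio <- function(pair) {
  check_pair(pair)
  pm <- apply_threshold(pair$protein, "moments")
  dm <- tryCatch(apply_threshold(pair$dna, "minimum"), error = function(e) {
    warn(paste0("Minimum threshold failed on DNA channel: ", conditionMessage(e)))
    NULL
  })
  if (is.null(dm) || dm$area == 0) {
    return(structure(NA_real_,
      areas = c(protein = pm$area, dna = if (is.null(dm)) NA_integer_ else dm$area),
      levels = c(protein = pm$level, dna = if (is.null(dm)) NA_integer_ else dm$level)
    ))
  }
  structure(pm$area / dm$area,
    areas = c(protein = pm$area, dna = dm$area),
    levels = c(protein = pm$level, dna = dm$level)
  )
}

#' Colocalization ratio of protein with the DNA stain
#'
#' Fraction of protein-foreground pixels that are also DNA-stain foreground,
#' both masks from the Moments threshold: area(protein AND dna) /
#' area(protein). `NA` when the protein mask is empty.
#'
#' @inheritParams aggregation_ratio
#' @return numeric in `[0, 1]` or `NA`, with `areas` and `levels` attributes.
#' @export
coloc_ratio <- function(pair) {
  check_pair(pair)
  pm <- apply_threshold(pair$protein, "moments")
  dm <- apply_threshold(pair$dna, "moments")
  both <- sum(pm$mask & dm$mask)
  structure(ratio_or_na(both, pm$area),
    areas = c(both = both, protein = pm$area, dna = dm$area),
    levels = c(protein = pm$level, dna = dm$level)
  )
}

#' Nuclear fraction of the protein signal
#'
#' Fraction of protein-foreground pixels lying inside the DNA-stain
#' foreground, with the protein channel thresholded by the Li method and the
#' DNA channel by the Otsu method: area(protein AND dna) / area(protein).
#' Intended for the lower-magnification field-of-view regime in which the
#' DNA-stain foreground is the whole nucleus, so the ratio reads as the
#' nuclear (vs cytoplasmic) proportion of the protein. `NA` when the protein
#' mask is empty.
#'
#' @inheritParams aggregation_ratio
#' @return numeric in `[0, 1]` or `NA`, with `areas` and `levels` attributes.
#' @export
nuclear_fraction <- function(pair) {
  check_pair(pair)
  pm <- apply_threshold(pair$protein, "li")
  dm <- apply_threshold(pair$dna, "otsu")
  both <- sum(pm$mask & dm$mask)
  structure(ratio_or_na(both, pm$area),
    areas = c(both = both, protein = pm$area, dna = dm$area),
    levels = c(protein = pm$level, dna = dm$level)
  )
}

#' Intensity line profile across both channels
#'
#' Samples both channels along the segment from `p0` to `p1` at 1-pixel
#' steps using bilinear interpolation (the Plot Profile equivalent used to
#' display co-localization of the protein with the DNA stain along a line
#' crossing the nucleus). Coordinates are 0-based `(x, y)` with `x` the
#' column and `y` the row.
#'
#' @inheritParams aggregation_ratio
#' @param p0,p1 numeric length-2 vectors, 0-based `(x, y)` pixel coordinates
#'   inside the image.
#' @return a tibble with columns `distance` (pixels from `p0`),
#'   `distance_um` (if the pair carries a pixel size), `protein`, `dna`.
#' @export
intensity_profile <- function(pair, p0, p1) {
  check_pair(pair)
  if (length(p0) != 2 || length(p1) != 2) abort("`p0` and `p1` must be (x, y) pairs.")
  nr <- nrow(pair$protein); nc <- ncol(pair$protein)
  inside <- function(p) p[1] >= 0 && p[1] <= nc - 1 && p[2] >= 0 && p[2] <= nr - 1
  if (!inside(p0) || !inside(p1)) abort("profile endpoints must lie inside the image.")
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) abort("zero-length profile segment.")
  n <- floor(len) + 1L
  tt <- seq(0, len, length.out = n)
  xs <- p0[1] + (p1[1] - p0[1]) * tt / len
  ys <- p0[2] + (p1[2] - p0[2]) * tt / len
  bilinear <- function(img, x, y) {
    # 0-based (x=col, y=row) to 1-based matrix indices
    x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
    fx <- x - x0; fy <- y - y0
    i <- y0 + 1L; j <- x0 + 1L
    img[cbind(i, j)] * (1 - fx) * (1 - fy) +
      img[cbind(i, j + 1)] * fx * (1 - fy) +
      img[cbind(i + 1, j)] * (1 - fx) * fy +
      img[cbind(i + 1, j + 1)] * fx * fy
  }
  out <- tibble(
    distance = tt,
    protein = bilinear(pair$protein, xs, ys),
    dna = bilinear(pair$dna, xs, ys)
  )
  if (!is.null(pair$pixel_size) && is.finite(pair$pixel_size)) {
    out <- dplyr::mutate(out, distance_um = .data$distance * pair$pixel_size, .after = "distance")
  }
  out
}

#' Quantify one image pair with all three localization metrics
#'
#' @inheritParams aggregation_ratio
#' @return one-row tibble with the three ratios, mask areas, and threshold
#'   levels.
#' @export
quantify_pair <- function(pair) {
  agg <- aggregation_ratio(pair)
  col <- coloc_ratio(pair)
  nuc <- nuclear_fraction(pair)
  tibble(
    aggregation_ratio = as.numeric(agg),
    coloc_ratio = as.numeric(col),
    nuclear_fraction = as.numeric(nuc),
    area_protein_moments = attr(col, "areas")[["protein"]],
    area_dna_moments = attr(col, "areas")[["dna"]],
    area_dna_minimum = attr(agg, "areas")[["dna"]],
    area_protein_li = attr(nuc, "areas")[["protein"]],
    area_dna_otsu = attr(nuc, "areas")[["dna"]],
    level_protein_moments = attr(col, "levels")[["protein"]],
    level_dna_moments = attr(col, "levels")[["dna"]],
    level_dna_minimum = attr(agg, "levels")[["dna"]],
    level_protein_li = attr(nuc, "levels")[["protein"]],
    level_dna_otsu = attr(nuc, "levels")[["dna"]]
  )
}

#' Batch quantification of grouped image pairs
#'
#' Runs [quantify_pair()] over a collection of image pairs grouped by
#' variant/condition (mirroring the 20-single-nucleus-images-per-variant
#' design). Unreadable or failing images are flagged and skipped; the batch
#' continues. Group summaries (mean +/- SEM per metric) are available via
#' [summarize_metrics()].
#'
#' @param pairs list of `image_pair` objects.
#' @param group character vector of group labels, one per image (or a single
#'   label recycled).
#' @return tibble with one row per image: `group`, `image`, the metric
#'   columns of [quantify_pair()], and a logical `ok` flag.
#' @export
batch_quantify <- function(pairs, group) {
  if (length(pairs) == 0) abort("`pairs` must contain at least one image.")
  if (length(group) == 1L) group <- rep(group, length(pairs))
  if (length(group) != length(pairs)) abort("`group` must have one label per image.")
  if (any(is.na(group) | group == "")) abort("empty group label.")
  ids <- names(pairs) %||% as.character(seq_along(pairs))
  ids[ids == ""] <- as.character(seq_along(pairs))[ids == ""]
  rows <- purrr::map(seq_along(pairs), function(i) {
    res <- tryCatch(quantify_pair(pairs[[i]]), error = function(e) {
      warn(sprintf("image %s failed: %s", ids[[i]], conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      tibble(group = group[[i]], image = ids[[i]], ok = FALSE)
    } else {
      dplyr::bind_cols(tibble(group = group[[i]], image = ids[[i]], ok = TRUE), res)
    }
  })
  dplyr::bind_rows(rows)
}

#' Per-group mean and SEM of localization metrics
#'
#' @param metrics output of [batch_quantify()].
#' @return tibble with one row per group and metric: `group`, `metric`, `n`
#'   (non-missing), `n_excluded` (missing/failed, excluded from the mean),
#'   `mean`, `sem`.
#' @export
summarize_metrics <- function(metrics) {
  metrics |>
    dplyr::filter(.data$ok) |>
    tidyr::pivot_longer(
      cols = c("aggregation_ratio", "coloc_ratio", "nuclear_fraction"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      n_excluded = sum(is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sem = stats::sd(.data$value, na.rm = TRUE) / sqrt(pmax(sum(!is.na(.data$value)), 1)),
      .groups = "drop"
    )
}
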