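#' Write / read an image pair as a two-page TIFF with a JSON sidecar
#'
#' The protein and DNA channels are stored as two 32-bit float grayscale
#' TIFF pages (lossless for the generator's [0, 1] intensities); ground
#' truth, seed, phenotype, and pixel size travel in a `.json` sidecar next
#' to the TIFF. A missing sidecar loads the pair with empty truth.
#'
#' @param pair an `image_pair`.
#' @param path TIFF path (`.tif`); the sidecar is `<path>.json`.
#' @return `write_image_pair()` the path, invisibly; `read_image_pair()` an
#'   `image_pair`.
#' @export
write_image_pair <- function(pair, path) {
  check_pair(pair)
  tiff::writeTIFF(list(pair$protein, pair$dna), path,
                  bits.per.sample = 32L, compression = "none")
  side <- list(
    pixel_size = pair$pixel_size,
    seed = pair$seed,
    style = pair$style,
    phenotype = if (!is.null(pair$phenotype)) unclass(pair$phenotype) else NULL,
    truth = if (!is.null(pair$truth)) {
      list(
        coloc_fraction = pair$truth$coloc_fraction,
        nuclear_fraction = pair$truth$nuclear_fraction,
        aggregation = pair$truth$aggregation,
        protein_mask_idx = which(pair$truth$protein_mask),
        dna_mask_idx = which(pair$truth$dna_mask),
        nucleus_mask_idx = which(pair$truth$nucleus_mask),
        dim = dim(pair$protein)
      )
    } else {
      NULL
    }
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 2) abort(sprintf("expected a 2-page TIFF, found %d page(s).", length(pages)))
  grayscale <- function(p) {
    if (length(dim(p)) == 3) {
      if (dim(p)[3] != 1) abort("grayscale TIFF required (got a multi-sample/RGB image).")
      p <- p[, , 1]
    }
    p
  }
  protein <- grayscale(pages[[1]])
  dna <- grayscale(pages[[2]])
  if (!identical(dim(protein), dim(dna))) abort("page dimensions differ.")
  sidecar <- paste0(path, ".json")
  pixel_size <- NA_real_; seed <- NA_integer_; truth <- NULL; phen <- NULL; style <- NA_character_
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- side$pixel_size %||% NA_real_
    seed <- side$seed %||% NA_integer_
    style <- side$style %||% NA_character_
    if (!is.null(side$phenotype)) {
      phen <- nucleus_phenotype(
        side$phenotype$label,
        aggregation_level = side$phenotype$aggregation_level,
        coloc_level = side$phenotype$coloc_level,
        cytoplasm_fraction = side$phenotype$cytoplasm_fraction
      )
    }
    if (!is.null(side$truth)) {
      dims <- side$truth$dim
      from_idx <- function(idx) {
        m <- matrix(FALSE, dims[1], dims[2])
        m[idx] <- TRUE
        m
      }
      truth <- list(
        protein_mask = from_idx(side$truth$protein_mask_idx),
        dna_mask = from_idx(side$truth$dna_mask_idx),
        nucleus_mask = from_idx(side$truth$nucleus_mask_idx),
        coloc_fraction = side$truth$coloc_fraction,
        nuclear_fraction = side$truth$nuclear_fraction,
        aggregation = side$truth$aggregation
      )
    }
  }
  structure(
    list(protein = protein, dna = dna, pixel_size = pixel_size,
         phenotype = phen, style = style, seed = seed, truth = truth),
    class = "image_pair"
  )
}

#' Write / read a FRAP recording as CSV
#'
#' Columns `time_s`, `roi`, `background`, `control`, with the bleach frame
#' index carried in a `# bleach_index: <i>` header comment.
#'
#' @param rec a `frap_recording`.
#' @param path CSV path.
#' @export
write_frap_csv <- function(rec, path) {
  if (!inherits(rec, "frap_recording")) abort("`rec` must be a frap_recording.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bleach_index: %d", rec$bleach_index), con)
  utils::write.csv(rec$data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  first <- readLines(path, n = 1)
  bleach_index <- NULL
  if (grepl("^#\\s*bleach_index:", first)) {
    bleach_index <- as.integer(sub("^#\\s*bleach_index:\\s*", "", first))
  }
  d <- utils::read.csv(path, comment.char = "#")
  needed <- c("time_s", "roi", "background", "control")
  if (!all(needed %in% names(d))) {
    abort(paste0("FRAP CSV needs columns: ", paste(needed, collapse = ", ")))
  }
  frap_recording(d$time_s, d$roi, d$background, d$control, bleach_index = bleach_index)
}

#' Write / read a reporter table as CSV
#'
#' @param table reporter tibble (`condition`, `replicate`, `firefly`,
#'   `renilla`); the control label is stored in a header comment.
#' @param path CSV path.
#' @export
write_reporter_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ctrl <- attr(table, "control") %||% "control"
  writeLines(sprintf("# control: %s", ctrl), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reporter_csv
#' @export
read_reporter_csv <- function(path) {
  first <- readLines(path, n = 1)
  ctrl <- if (grepl("^#\\s*control:", first)) {
    trimws(sub("^#\\s*control:\\s*", "", first))
  } else {
    "control"
  }
  d <- as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(d, "control") <- ctrl
  d
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration holds paths, threshold-method overrides, the
#' significance level, Monte-Carlo settings, generator parameter blocks, and
#' the classification rule-table version. Unknown top-level keys are
#' rejected by name so typos fail loudly.
#'
#' @param path YAML file.
#' @return a named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("paths", "alpha", "mc_draws", "seed", "thresholds",
               "generator", "rules_version", "wt", "control")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$mc_draws <- cfg$mc_draws %||% 1e5
  cfg$seed <- cfg$seed %||% 1L
  cfg$rules_version <- cfg$rules_version %||% "v1"
  cfg$wt <- cfg$wt %||% "WT"
  cfg$control <- cfg$control %||% "control"
  cfg
}

#' @rdname read_config
#' @param config named configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
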