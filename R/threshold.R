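#' Quantize an intensity image to 8-bit gray levels
#'
#' Linearly rescales a finite intensity grid to the integer range 0..255
#' (min-max normalization followed by round-half-up). A constant image maps
#' to all zeros. All automatic threshold algorithms in this package operate
#' on the 256-bin histogram of this quantization, matching the ImageJ
#' convention in which the named methods are defined.
#'
#' @param image numeric matrix of finite intensities.
#' @return integer matrix with values in 0..255, same dimensions as `image`.
#' @export
quantize_to_8bit <- function(image) {
  if (!is.matrix(image) || length(image) == 0) {
    abort("`image` must be a non-empty numeric matrix.")
  }
  if (!all(is.finite(image))) abort("`image` must contain only finite values.")
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) {
    q <- matrix(0L, nrow(image), ncol(image))
    return(q)
  }
  # round half up, not banker's rounding, so the mapping is monotone and
  # matches integer ramp inputs exactly
  q <- floor((image - lo) / (hi - lo) * 255 + 0.5)
  storage.mode(q) <- "integer"
  q
}

#' 256-bin histogram of an 8-bit image
#'
#' @param image8 integer matrix with values in 0..255 (see [quantize_to_8bit()]).
#' @return integer vector of 256 counts; bin `i` holds the count of gray
#'   level `i - 1`.
#' @export
hist256 <- function(image8) {
  v <- as.integer(image8)
  if (length(v) == 0) abort("empty image")
  if (any(v < 0L | v > 255L)) abort("gray levels must lie in 0..255")
  tabulate(v + 1L, nbins = 256L)
}

check_hist <- function(counts) {
  if (length(counts) != 256L) abort("histogram must have exactly 256 bins")
  if (any(counts < 0) || sum(counts) <= 0) abort("histogram counts must be nonnegative with positive total")
  as.numeric(counts)
}

level_result <- function(level, degenerate = FALSE, converged = TRUE) {
  level <- as.integer(level)
  stopifnot(level >= 0L, level <= 255L)
  structure(level, degenerate = degenerate, converged = converged)
}

#' Otsu automatic threshold
#'
#' Returns the gray level `t` maximizing the between-class variance of the
#' two classes `{<= t}` and `{> t}` of a 256-bin histogram. Ties are broken
#' toward the lowest level. A single-occupied-bin histogram is degenerate:
#' that bin's index is returned with attribute `degenerate = TRUE`.
#'
#' @param counts 256-bin histogram (see [hist256()]).
#' @return integer threshold level in 0..255 with attributes `degenerate`
#'   and `converged`. Foreground convention everywhere in this package is
#'   strictly greater than the level.
#' @export
otsu_threshold <- function(counts) {
  p <- check_hist(counts)
  p <- p / sum(p)
  occupied <- which(p > 0)
  if (length(occupied) == 1L) {
    return(level_result(occupied - 1L, degenerate = TRUE))
  }
  g <- 0:255
  w <- cumsum(p)            # P(level <= t), index t + 1
  mu <- cumsum(p * g)       # partial mean mass
  mu_t <- mu[256]
  t_all <- 0:254
  w0 <- w[t_all + 1]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t_all + 1][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # lowest level attaining the maximum; tolerance keeps tie-breaking stable
  # against floating-point noise across empty-gap plateaus
  v_max <- max(sigma_b)
  level_result(t_all[which(sigma_b >= v_max - 1e-9 * max(1, abs(v_max)))[1]])
}

#' Li minimum cross-entropy threshold (iterative)
#'
#' Li & Tam's iterative scheme: starting from the image mean, alternately
#' compute foreground/background mean gray levels under the current
#' threshold and update `t <- (mu_b - mu_f) / (log(mu_b) - log(mu_f))`
#' until successive iterates differ by less than 0.5 gray level.
#'
#' @inheritParams otsu_threshold
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with attribute `converged = FALSE` and a warning.
#' @return integer threshold level (foreground strictly above it).
#' @export
li_threshold <- function(counts, max_iter = 100L) {
  cts <- check_hist(counts)
  if (sum(cts > 0) < 2L) {
    return(level_result(which(cts > 0)[1] - 1L, degenerate = TRUE))
  }
  g <- 0:255
  eps <- 1e-10
  li_update <- function(t_cur) {
    back <- g <= t_cur
    sb <- sum(cts[back]); sf <- sum(cts[!back])
    # guard empty classes by nudging the mean toward the mass
    mu_b <- if (sb > 0) sum(g[back] * cts[back]) / sb else eps
    mu_f <- if (sf > 0) sum(g[!back] * cts[!back]) / sf else 255
    mu_b <- max(mu_b, eps)
    mu_f <- max(mu_f, eps)
    if (abs(mu_b - mu_f) < eps) return(NA_real_)
    (mu_b - mu_f) / (log(mu_b) - log(mu_f))
  }
  t_cur <- sum(g * cts) / sum(cts)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    t_new <- li_update(t_cur)
    if (is.na(t_new)) return(level_result(round(t_cur), degenerate = TRUE))
    if (abs(t_new - t_cur) < 0.5) {
      converged <- TRUE
      # polish to the real-valued fixed point so the integer level below
      # inherits it cleanly
      for (j in 1:64) {
        t_next <- li_update(t_new)
        if (is.na(t_next) || abs(t_next - t_new) < 1e-6) break
        t_new <- t_next
      }
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  if (!converged) warn("Li threshold did not converge; returning last iterate.")
  # the integer level is the rounded fixed point; the converged real-valued
  # threshold travels along as an attribute (the Li update is a step function
  # of t, so only the real iterate is an exact fixed point)
  out <- level_result(max(0, min(255, round(t_cur))), converged = converged)
  attr(out, "t_star") <- t_cur
  out
}

# Tsai moment-preserving quantities shared by the implementation and exposed
# for inspection: gray-level moments m1..m3 of the normalized histogram, the
# two representative levels z0 < z1, and the background fraction p0 assigned
# to z0.
tsai_moments <- function(counts) {
  p <- check_hist(counts)
  p <- p / sum(p)
  g <- 0:255
  m1 <- sum(g * p)
  m2 <- sum(g^2 * p)
  m3 <- sum(g^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) return(NULL)
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(NULL)
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  if (z1 <= z0) return(NULL)
  p0 <- (z1 - m1) / (z1 - z0)
  list(m1 = m1, m2 = m2, m3 = m3, z0 = z0, z1 = z1, p0 = p0)
}

#' Tsai moment-preserving threshold ("Moments")
#'
#' Matches the first three gray-level moments of the image with a two-level
#' image, yielding a target background fraction `p0`; the threshold is the
#' smallest level whose cumulative histogram fraction reaches `p0`
#' (percentile selection). Zero-variance histograms are degenerate and
#' return the modal bin with `degenerate = TRUE`.
#'
#' @inheritParams otsu_threshold
#' @export
moments_threshold <- function(counts) {
  cts <- check_hist(counts)
  tm <- tsai_moments(cts)
  if (is.null(tm)) {
    return(level_result(which.max(cts) - 1L, degenerate = TRUE))
  }
  cum <- cumsum(cts) / sum(cts)
  lev <- which(cum >= tm$p0)[1] - 1L
  if (is.na(lev)) lev <- 255L
  level_result(lev)
}

#' Minimum-method threshold (iterative histogram smoothing)
#'
#' Repeatedly smooths the 256-bin histogram with a 3-point running mean
#' (edge bins replicated) until exactly two local maxima remain, then
#' returns the bin of the minimum between them. Histograms that never
#' become bimodal (e.g. monotone) raise an error.
#'
#' @inheritParams otsu_threshold
#' @param max_iter smoothing iteration cap.
#' @export
minimum_threshold <- function(counts, max_iter = 10000L) {
  y <- check_hist(counts)
  # edge bins can be genuine modes (e.g. clipped signal piling up at 0), so
  # pad with -Inf rather than replicating the edges
  local_maxima <- function(v) {
    left <- c(-Inf, v[-256])
    right <- c(v[-1], -Inf)
    which(v > left & v >= right)
  }
  iter <- 0L
  while (length(local_maxima(y)) > 2L && iter < max_iter) {
    y <- (c(y[1], y[-256]) + y + c(y[-1], y[256])) / 3
    iter <- iter + 1L
  }
  peaks <- local_maxima(y)
  if (length(peaks) != 2L) {
    abort("histogram is not bimodal: Minimum threshold undefined")
  }
  between <- (peaks[1] + 1):(peaks[2] - 1)
  if (length(between) == 0) abort("histogram is not bimodal: adjacent peaks")
  lev <- between[which.min(y[between])] - 1L
  level_result(lev)
}

#' Threshold an intensity image with a named automatic method
#'
#' Quantizes the image to 8 bits, computes the 256-bin histogram, derives the
#' threshold level with the requested algorithm, and returns the binary mask
#' with foreground defined as quantized intensity strictly greater than the
#' level (the ImageJ "above threshold is object" convention). On a degenerate
#' (constant) image the mask is empty and flagged.
#'
#' @param image numeric intensity matrix.
#' @param method one of `"otsu"`, `"li"`, `"moments"`, `"minimum"`.
#' @return an object of class `binary_mask`: a list with `mask` (logical
#'   matrix), `level` (integer), `method`, `degenerate`, `area`
#'   (foreground pixel count).
#' @export
apply_threshold <- function(image, method = c("otsu", "li", "moments", "minimum")) {
  method <- match.arg(method)
  q <- quantize_to_8bit(image)
  h <- hist256(q)
  lev <- switch(method,
    otsu = otsu_threshold(h),
    li = li_threshold(h),
    moments = moments_threshold(h),
    minimum = minimum_threshold(h)
  )
  mask <- q > as.integer(lev)
  structure(
    list(
      mask = mask,
      level = as.integer(lev),
      method = method,
      degenerate = isTRUE(attr(lev, "degenerate")),
      area = sum(mask)
    ),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %dx%d, method=%s, level=%d, area=%d px%s\n",
    nrow(x$mask), ncol(x$mask), x$method, x$level, x$area,
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask a `binary_mask` or logical matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  tiff::writeTIFF(m * 1.0, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
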