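# Signal-detection estimate of the number of distinguishable synaptic
# strength levels across the spine-size dynamic range, and the bits of
# information they represent.

#' Gaussian half-width for a discrimination threshold
#'
#' Converts a discrimination probability \eqn{c} (the fraction of correct
#' assignments an ideal observer achieves between two adjacent strength
#' levels) into the half-width \eqn{z = \sqrt{2}\,\mathrm{erf}^{-1}(c)} of a
#' standard Gaussian. Two unit-variance Gaussians whose means are \eqn{2z}
#' apart overlap by \eqn{1 - c}, so a sample is assigned to the correct one
#' with probability \eqn{c}.
#'
#' @param confidence Discrimination probability in `[0, 1)`. The value 0.69
#'   corresponds to the conventional SNR = 1 psychophysical threshold;
#'   0.76 to SNR = 2.
#' @return The Gaussian half-width \eqn{z} (dimensionless), monotone
#'   increasing in `confidence`; `z_from_confidence(0)` is 0.
#' @examples
#' z_from_confidence(0.69)   # ~1.015
#' z_from_confidence(0.9545) # ~2, the two-sigma two-sided coverage
#' @export
z_from_confidence <- function(confidence) {
  if (!is.numeric(confidence) || anyNA(confidence) ||
      any(confidence < 0) || any(confidence >= 1)) {
    stop("`confidence` must be a probability in [0, 1)", call. = FALSE)
  }
  # sqrt(2) * erfinv(c) == qnorm((1 + c) / 2)
  stats::qnorm((1 + confidence) / 2)
}

#' Spacing between adjacent strength-level means
#'
#' For strength levels with constant coefficient of variation `cv`, adjacent
#' level means separated by \eqn{s = \mu \cdot 2\,\mathrm{CV}\,z} are
#' discriminable at the confidence implied by `z`.
#'
#' @param mean Level mean (e.g. spine head volume, um^3); must be positive.
#' @param cv Per-level coefficient of variation (dimensionless).
#' @param z Gaussian half-width from [z_from_confidence()].
#' @return Spacing in the units of `mean`; linear in `mean`.
#' @export
level_spacing <- function(mean, cv, z) {
  if (!is.numeric(mean) || any(mean <= 0)) {
    stop("`mean` must be positive", call. = FALSE)
  }
  if (any(cv < 0) || any(z < 0)) {
    stop("`cv` and `z` must be non-negative", call. = FALSE)
  }
  mean * 2 * cv * z
}

#' Number of distinguishable strength levels across a dynamic range
#'
#' The number of Gaussian strength distributions of constant coefficient of
#' variation `cv`, spaced for a given discrimination threshold, that tile a
#' `range_factor`-fold dynamic range:
#' \deqn{N = \ln(\mathrm{range}) / \ln(1 + 2\,\mathrm{CV}\,z).}
#' The result is base-independent and real-valued; see
#' [discrimination_model()] for the integer conventions.
#'
#' @param range_factor Ratio of the largest to smallest distinguishable
#'   strength (dimensionless, > 1). The hippocampal spine-head population
#'   spans about a factor of 60.
#' @param cv Per-level coefficient of variation; the axon-coupled pair
#'   estimate is 0.083.
#' @param confidence Discrimination probability, see [z_from_confidence()].
#' @return Real-valued level count `N`.
#' @examples
#' n_distinguishable(60, 0.083, 0.69) # ~26.3
#' n_distinguishable(60, 0.083, 0.76) # ~23.0
#' @export
n_distinguishable <- function(range_factor, cv, confidence) {
  if (!is.numeric(range_factor) || any(range_factor <= 1)) {
    stop("`range_factor` must be > 1", call. = FALSE)
  }
  if (any(cv <= 0)) stop("`cv` must be positive", call. = FALSE)
  z <- z_from_confidence(confidence)
  log(range_factor) / log(1 + 2 * cv * z)
}

#' Bits of information implied by a number of distinguishable levels
#'
#' @param n Real-valued level count (> 0).
#' @return \eqn{\log_2(n)} bits.
#' @examples
#' bits_from_levels(26.3) # ~4.72
#' @export
bits_from_levels <- function(n) {
  if (!is.numeric(n) || any(n <= 0)) {
    stop("`n` must be positive", call. = FALSE)
  }
  log2(n)
}

#' Overlap between adjacent level distributions (equal-sigma convention)
#'
#' Under the equal-sigma convention two adjacent levels are unit-variance
#' Gaussians whose means differ by \eqn{2z}; their overlapping area is
#' \eqn{2\Phi(-z)}, which satisfies the identity
#' \eqn{2\Phi(-z) = 1 - c} exactly. A 69% discrimination threshold therefore
#' corresponds to a 31% overlap.
#'
#' @param confidence Discrimination probability in `(0, 1)`.
#' @return Overlapping probability mass (dimensionless, in `(0, 1)`).
#' @seealso [adjacent_overlap_exact()] for the unequal-sigma diagnostic.
#' @export
adjacent_overlap <- function(confidence) {
  if (!is.numeric(confidence) || anyNA(confidence) ||
      any(confidence <= 0) || any(confidence >= 1)) {
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  }
  2 * stats::pnorm(-z_from_confidence(confidence))
}

#' Exact overlap of two adjacent levels with size-proportional sigma
#'
#' Diagnostic companion to [adjacent_overlap()]: the standard deviation of a
#' strength level is proportional to its mean (sigma = cv * mu), so two
#' adjacent levels do not actually share a common sigma. This computes the
#' overlapping area \eqn{\int \min(f_1, f_2)} of the two unequal-sigma
#' Gaussians by numeric integration. At cv = 0.083 and a 69% threshold the
#' exact overlap is ~0.35 rather than the 0.31 of the equal-sigma
#' convention; the discrepancy quantifies the approximation, it does not
#' enter the headline level count.
#'
#' @inheritParams adjacent_overlap
#' @param cv Per-level coefficient of variation.
#' @return Overlapping probability mass of the two adjacent unequal-sigma
#'   Gaussians.
#' @export
adjacent_overlap_exact <- function(cv, confidence) {
  if (any(cv <= 0)) stop("`cv` must be positive", call. = FALSE)
  z <- z_from_confidence(confidence)
  mu1 <- 1
  mu2 <- 1 + 2 * cv * z
  f <- function(x) {
    pmin(stats::dnorm(x, mu1, cv * mu1), stats::dnorm(x, mu2, cv * mu2))
  }
  stats::integrate(f, mu1 - 8 * cv * mu1, mu2 + 8 * cv * mu2,
                   rel.tol = 1e-10)$value
}

#' Fit the discriminable-level model of synaptic strength
#'
#' Builds the full signal-detection description of how many distinguishable
#' synaptic strength levels, each a Gaussian of constant coefficient of
#' variation, tile the observed dynamic range of spine head volumes -- and
#' how many bits of information the level count represents.
#'
#' The real-valued level count is
#' \eqn{N = \ln(\mathrm{range}) / \ln(1 + 2\,\mathrm{CV}\,z)} with
#' \eqn{z = \sqrt{2}\,\mathrm{erf}^{-1}(c)}. Both rounding conventions for
#' the headline integer are exposed: `n_levels_round` (nearest integer, the
#' headline count: 26 at the 69% threshold, 23 at 76%) and `n_levels_floor`
#' (the number of whole levels that fit, used for the level ladder).
#'
#' @param cv Per-level coefficient of variation; default 0.083, the median
#'   per-pair CV of axon-coupled same-dendrite spine head volumes.
#' @param range_factor Dynamic range of the population (max/min), default 60.
#' @param confidence Discrimination probability, default 0.69 (SNR = 1).
#' @param min_volume Smallest observed head volume in um^3; anchors the level
#'   ladder. Only affects the ladder means, not N or bits.
#' @return An object of class `"discrimination_model"`: a list with elements
#'   `cv`, `range_factor`, `confidence`, `z`, `spacing_ratio`
#'   (\eqn{1 + 2\,\mathrm{CV}\,z}), `n_levels` (real-valued),
#'   `n_levels_round`, `n_levels_floor`, `bits` (\eqn{\log_2 N}), `overlap`
#'   (equal-sigma adjacent overlap) and `levels` (the ladder data frame from
#'   [build_level_ladder()]).
#' @examples
#' m <- discrimination_model()
#' m$n_levels       # 26.3
#' m$bits           # 4.72
#' summary(m)
#' @export
discrimination_model <- function(cv = 0.083, range_factor = 60,
                                 confidence = 0.69, min_volume = 0.01) {
  if (length(cv) != 1 || length(range_factor) != 1 || length(confidence) != 1) {
    stop("`cv`, `range_factor` and `confidence` must be scalars",
         call. = FALSE)
  }
  z <- z_from_confidence(confidence)
  n <- n_distinguishable(range_factor, cv, confidence)
  model <- structure(
    list(
      cv = cv,
      range_factor = range_factor,
      confidence = confidence,
      min_volume = min_volume,
      z = z,
      spacing_ratio = 1 + 2 * cv * z,
      n_levels = n,
      n_levels_round = round(n),
      n_levels_floor = floor(n),
      bits = bits_from_levels(n),
      overlap = adjacent_overlap(confidence),
      levels = NULL
    ),
    class = "discrimination_model"
  )
  model$levels <- build_level_ladder(min_volume, model)
  model
}

#' Geometric ladder of distinguishable strength levels
#'
#' Lays out the `floor(N)` level means as an exact geometric progression with
#' ratio \eqn{1 + 2\,\mathrm{CV}\,z}, so the levels are uniform in width and
#' spacing on a log scale (a non-uniform quantization of the linear range).
#' The first mean is placed at `min_volume * (1 + cv * z)`, i.e. one
#' half-spacing above the bottom of the range, so the floor(N) levels tile
#' the whole `[min, min * range_factor]` interval: all means lie inside it
#' and one more step of the ratio would overshoot the top.
#'
#' @param min_volume Smallest observed volume (um^3), > 0.
#' @param model A `"discrimination_model"` object.
#' @return A data frame with one row per level: `level`, `mean` (um^3) and
#'   `sd` (`cv * mean`, um^3).
#' @export
build_level_ladder <- function(min_volume, model) {
  stopifnot(inherits(model, "discrimination_model"))
  if (!is.numeric(min_volume) || length(min_volume) != 1 || min_volume <= 0) {
    stop("`min_volume` must be a positive scalar", call. = FALSE)
  }
  if (model$n_levels < 1) {
    stop("model admits fewer than one distinguishable level", call. = FALSE)
  }
  k <- model$n_levels_floor
  means <- min_volume * (1 + model$cv * model$z) *
    model$spacing_ratio^(seq_len(k) - 1)
  data.frame(level = seq_len(k), mean = means, sd = model$cv * means)
}

#' @export
print.discrimination_model <- function(x, ...) {
  cat("Discriminable synaptic strength levels (signal-detection model)\n")
  cat(sprintf("  per-level CV:            %.4g\n", x$cv))
  cat(sprintf("  dynamic range (max/min): %.4g-fold\n", x$range_factor))
  cat(sprintf("  discrimination:          %.0f%% (z = %.4f, overlap %.0f%%)\n",
              100 * x$confidence, x$z, 100 * x$overlap))
  cat(sprintf("  spacing ratio:           %.4f per level\n", x$spacing_ratio))
  cat(sprintf("  distinguishable levels:  N = %.1f (~%d)\n",
              x$n_levels, x$n_levels_round))
  cat(sprintf("  information:             %.2f bits per synapse\n", x$bits))
  invisible(x)
}

#' @export
summary.discrimination_model <- function(object, ...) {
  print(object)
  cat(sprintf("\nLevel ladder: %d levels from %.4g to %.4g um^3 ",
              nrow(object$levels), object$levels$mean[1],
              object$levels$mean[nrow(object$levels)]))
  cat(sprintf("(anchored at min volume %.4g um^3)\n", object$min_volume))
  cat(sprintf("Exact unequal-sigma adjacent overlap: %.3f (vs %.3f equal-sigma)\n",
              adjacent_overlap_exact(object$cv, object$confidence),
              object$overlap))
  invisible(object)
}

#' Plot the ladder of distinguishable strength levels
#'
#' Draws each level as a Gaussian density over volume on a log-scaled x axis,
#' illustrating how levels of constant CV tile the dynamic range with uniform
#' width and spacing on the log scale.
#'
#' @param x A `"discrimination_model"` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.discrimination_model <- function(x, ...) {
  lv <- x$levels
  xs <- exp(seq(log(lv$mean[1] / (1 + 4 * x$cv)),
                log(lv$mean[nrow(lv)] * (1 + 4 * x$cv)), length.out = 2000))
  dens <- vapply(seq_len(nrow(lv)),
                 function(i) stats::dnorm(xs, lv$mean[i], lv$sd[i]),
                 numeric(length(xs)))
  # normalize each level's peak to 1 for display
  dens <- sweep(dens, 2, apply(dens, 2, max), "/")
  graphics::plot(NA, xlim = range(xs), ylim = c(0, 1.05), log = "x",
                 xlab = expression("spine head volume (" * mu * m^3 * ")"),
                 ylab = "relative density",
                 main = sprintf("%d distinguishable levels, CV = %.3f, %d%% threshold",
                                nrow(lv), x$cv, round(100 * x$confidence)),
                 ...)
  cols <- grDevices::hcl.colors(nrow(lv), "Zissou 1")
  for (i in seq_len(nrow(lv))) {
    graphics::lines(xs, dens[, i], col = cols[i])
  }
  invisible(x)
}
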