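# Multiplicity adjustment for co-primary outcomes: the pragmatic "halfway"
# rule. The true family-wise-adjusted threshold lies between no adjustment
# (divide by 1) and Bonferroni (divide by m); the base threshold is divided by
# the value halfway between the two.

#' Multiplicity-adjusted significance threshold
#'
#' Divides the pre-specified P-value threshold by \eqn{(1 + m)/2}, the value
#' halfway between 1 (no adjustment) and the number of primary outcome
#' comparisons m (Bonferroni). The Bonferroni bound `alpha_base/m` is reported
#' alongside for reference. The adjusted value is kept at full precision.
#'
#' @param alpha_base unadjusted two-sided threshold, e.g. 0.05.
#' @param m number of primary outcomes (>= 1).
#' @return An `adjusted_threshold` object with `m`, `alpha_base`, `divisor`,
#'   `alpha_adjusted`, `bonferroni` and `ci_level`.
#' @export
adjusted_alpha <- function(alpha_base, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be a count >= 1")
  m <- as.integer(m)
  if (alpha_base <= 0 || alpha_base >= 1) stop("alpha_base must be in (0, 1)")
  divisor <- (1 + m) / 2
  structure(list(m = m, alpha_base = alpha_base, divisor = divisor,
                 alpha_adjusted = alpha_base / divisor,
                 bonferroni = alpha_base / m,
                 ci_level = 1 - alpha_base / divisor),
            class = "adjusted_threshold")
}

#' Confidence level matching an adjusted threshold
#'
#' Adjusted confidence intervals are obtained by feeding this level to the
#' pooling functions, so that the interval widens in step with the stricter
#' P-value threshold.
#'
#' @param threshold an `adjusted_threshold` from [adjusted_alpha()].
#' @return `1 - alpha_adjusted`.
#' @export
adjusted_ci_level <- function(threshold) {
  stopifnot(inherits(threshold, "adjusted_threshold"))
  1 - threshold$alpha_adjusted
}

#' @export
print.adjusted_threshold <- function(x, ...) {
  cat(sprintf("Multiplicity adjustment: m = %d primary outcomes\n", x$m))
  cat(sprintf("  alpha %.4g / %.3g -> %.4g (Bonferroni bound %.4g); CI level %.4g\n",
              x$alpha_base, x$divisor, x$alpha_adjusted, x$bonferroni, x$ci_level))
  invisible(x)
}
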