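# Bayes factor against the anticipated intervention effect. The pooled
# estimate theta_hat is treated as normal with standard deviation SE under
# both hypotheses; the Bayes factor is the ratio of its likelihood under the
# null (effect 0) to its likelihood under the point alternative mu_A:
#
#   BF = phi(theta_hat; 0, SE) / phi(theta_hat; mu_A, SE)
#      = exp[(mu_A^2 - 2 * mu_A * theta_hat) / (2 * SE^2)].
#
# BF = 1 exactly when theta_hat = mu_A / 2, and BF decreases strictly as the
# observed effect grows towards and beyond the anticipated effect (mu_A > 0).
# Values below the threshold (default 0.1, i.e. data ten times more compatible
# with the alternative) count as significant.

#' Bayes factor for a meta-analysis result
#'
#' Ratio of the probability of the pooled result under the null hypothesis to
#' its probability under the anticipated intervention effect `mu_A` (the same
#' effect used for the required information size), with normal likelihoods.
#'
#' @param theta_hat pooled effect on the analysis scale (log ratio or mean
#'   difference).
#' @param se_hat standard error of `theta_hat` (> 0).
#' @param mu_A anticipated intervention effect, non-zero, same scale.
#' @param threshold significance threshold (default 0.1).
#' @return A `bayes_factor` object with `bf`, `significant`, and the inputs.
#' @export
bayes_factor <- function(theta_hat, se_hat, mu_A, threshold = 0.1) {
  if (!is.numeric(se_hat) || se_hat <= 0) stop("se_hat must be > 0")
  if (!is.numeric(mu_A) || mu_A == 0) stop("mu_A must be non-zero (alternative equals null)")
  bf <- exp((mu_A^2 - 2 * mu_A * theta_hat) / (2 * se_hat^2))
  structure(list(mu_A = mu_A, theta_hat = theta_hat, se_hat = se_hat,
                 bf = bf, threshold = threshold,
                 significant = bf < threshold),
            class = "bayes_factor")
}

#' Sceptical anticipated effect
#'
#' A smaller ("sceptical") anticipated intervention effect for sensitivity
#' analysis: the relative risk halfway between the anticipated ratio and 1.0
#' (no effect), returned on the log scale for direct use in [bayes_factor()].
#' A log-scale halfway option is available since "halfway" is ambiguous
#' between the two scales; the natural-ratio scale is the default.
#'
#' @param mu_A_ratio anticipated effect on the ratio scale (> 0, not 1).
#' @param scale `"ratio"` (default) or `"log"`.
#' @return The sceptical effect on the log scale.
#' @export
sceptical_effect <- function(mu_A_ratio, scale = c("ratio", "log")) {
  scale <- match.arg(scale)
  if (mu_A_ratio <= 0) stop("ratio-scale effect must be > 0")
  if (mu_A_ratio == 1) stop("anticipated ratio of 1 has no sceptical midpoint")
  if (scale == "ratio") log((mu_A_ratio + 1) / 2) else log(mu_A_ratio) / 2
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("Bayes factor (H0 vs anticipated effect %.4g): %.4g\n", x$mu_A, x$bf))
  cat(sprintf("  theta_hat = %.4g (SE %.4g); threshold %.3g -> %s\n",
              x$theta_hat, x$se_hat, x$threshold,
              if (x$significant) "favours the alternative (significant)"
              else "not below threshold"))
  invisible(x)
}
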