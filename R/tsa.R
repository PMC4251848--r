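# Trial sequential analysis: diversity-adjusted required information size,
# Lan-DeMets alpha-spending monitoring boundaries of the O'Brien-Fleming type
# (computed by recursive numerical integration over the joint law of the
# sequential z-statistics, which have the independent-increments Brownian
# structure), beta-spending futility wedge, cumulative z-curve, crossing
# assessment, and the TSA-adjusted confidence interval.

#' Required information size
#'
#' The a-priori number of participants a meta-analysis needs to detect (or
#' reject) the anticipated intervention effect, analogous to a single trial's
#' sample size, inflated for between-trial diversity:
#' \deqn{n = 4 (z_{1-\alpha/2} + z_{1-\beta})^2 \bar p(1-\bar p)/(p_c-p_e)^2}
#' for dichotomous outcomes (with \eqn{\bar p = (p_c+p_e)/2} and the
#' experimental risk implied by the anticipated effect), or
#' \eqn{4 (z_{1-\alpha/2} + z_{1-\beta})^2 \sigma^2/\mathrm{MD}^2} for
#' continuous ones, and \eqn{DIS = \lceil n/(1-D^2)\rceil}. When the observed
#' diversity is zero in a random-effects analysis, the fallback heterogeneity
#' (default 25%) is substituted and recorded.
#'
#' @param spec an [outcome_spec()].
#' @param alpha two-sided type-I error (use the multiplicity-adjusted value
#'   for primary outcomes).
#' @param beta type-II error.
#' @param D2 diversity fraction in `[0, 1)`.
#' @param apply_fallback substitute `spec$heterogeneity_fallback` when
#'   `D2 == 0` (set `FALSE` for a fixed-effect information size, where the
#'   between-trial variance is zero by assumption).
#' @param mu_A optional override of the anticipated effect (used by the
#'   sensitivity reruns with the meta-analysis point estimate / CI limit).
#' @return An `information_size` object: `n_fixed` (rounded up), `n_fixed_raw`,
#'   `dis`, `D2_used`, `fallback_used`, `alpha_used`, `beta_used`, `mu_A`,
#'   `p_c`/`p_e` or `anticipated_sd`, and `drift` (implied mean of the
#'   z-statistic at full information).
#' @export
required_information_size <- function(spec, alpha, beta, D2 = 0,
                                      apply_fallback = TRUE, mu_A = NULL) {
  stopifnot(inherits(spec, "outcome_spec"))
  if (D2 < 0 || D2 >= 1) stop("D2 must be in [0, 1)")
  mu <- mu_A %||% spec$mu_A
  if (mu == 0) stop("anticipated effect must be non-zero")
  za <- stats::qnorm(1 - alpha / 2); zb <- stats::qnorm(1 - beta)
  p_c <- p_e <- NULL
  if (spec$data_type == "dichotomous") {
    p_c <- spec$p_c
    p_e <- switch(spec$measure,
                  logRR = p_c * exp(mu),
                  logOR = stats::plogis(stats::qlogis(p_c) + mu),
                  RD = p_c + mu)
    if (p_e <= 0 || p_e >= 1)
      stop("implied experimental risk outside (0, 1): ", format(p_e))
    pbar <- (p_c + p_e) / 2
    n_raw <- 4 * (za + zb)^2 * pbar * (1 - pbar) / (p_c - p_e)^2
  } else {
    n_raw <- 4 * (za + zb)^2 * spec$anticipated_sd^2 / mu^2
  }
  fallback_used <- FALSE
  D2_used <- D2
  if (D2 == 0 && apply_fallback && spec$heterogeneity_fallback > 0) {
    D2_used <- spec$heterogeneity_fallback / 100
    fallback_used <- TRUE
  }
  dis <- ceiling(n_raw / (1 - D2_used))
  structure(list(n_fixed = ceiling(n_raw), n_fixed_raw = n_raw,
                 D2_used = D2_used, fallback_used = fallback_used, dis = dis,
                 alpha_used = alpha, beta_used = beta, mu_A = mu,
                 p_c = p_c, p_e = p_e, anticipated_sd = spec$anticipated_sd,
                 drift = (za + zb) * sqrt(dis / n_raw)),
            class = "information_size")
}

#' @export
print.information_size <- function(x, ...) {
  cat(sprintf("Required information size: %d participants (unadjusted %d)\n",
              x$dis, x$n_fixed))
  cat(sprintf("  alpha = %.4g, beta = %.3g, anticipated effect = %.4g, D2 = %.3g%s\n",
              x$alpha_used, x$beta_used, x$mu_A, x$D2_used,
              if (x$fallback_used) " (fallback)" else ""))
  invisible(x)
}

#' O'Brien-Fleming alpha-spending function
#'
#' Cumulative two-sided type-I error spent by information fraction `t`:
#' \eqn{\alpha^*(t) = 2(1 - \Phi(z_{1-\alpha/2}/\sqrt t))}. Spends almost
#' nothing early and reaches `alpha` at `t = 1`; fractions above 1 are clamped
#' for spending purposes.
#'
#' @param t information fraction(s), each > 0.
#' @param alpha total two-sided type-I error.
#' @return Cumulative spent error, same length as `t`.
#' @export
alpha_spent <- function(t, alpha) {
  if (any(t <= 0)) stop("information fraction must be > 0")
  t <- pmin(t, 1)
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)))
}

# Recursive-integration engine. Maintains the sub-density of the sequential
# z-statistic over the continuation region on a trapezoid grid and returns,
# per look, the bound solving the incremental crossing-probability equation.
# type = "efficacy": symmetric two-sided bounds under the null.
# type = "futility": one-sided lower bounds under `drift`.
.gs_bounds <- function(frac, spend, type = c("efficacy", "futility"),
                       drift = 0, nodes = 512, zmax = 8, cap = 8) {
  type <- match.arg(type)
  K <- length(frac)
  stopifnot(length(spend) == K)
  if (K == 0L) return(numeric(0))
  if (any(diff(frac) <= 0) || any(frac <= 0) || any(frac > 1))
    stop("information fractions must be strictly increasing in (0, 1]")
  bound <- numeric(K)
  capped <- logical(K)
  x <- NULL; g <- NULL   # grid and sub-density over the continuation region
  trap <- function(n, a, b) {
    h <- (b - a) / (n - 1)
    list(x = seq(a, b, length.out = n), w = h * c(0.5, rep(1, n - 2), 0.5))
  }
  for (k in seq_len(K)) {
    t1 <- frac[k]
    mean_k <- drift * sqrt(t1)
    pik <- spend[k] - if (k == 1L) 0 else spend[k - 1L]
    if (k == 1L) {
      if (type == "efficacy") {
        if (pik < 1e-10) { bound[k] <- cap; capped[k] <- TRUE }
        else bound[k] <- stats::qnorm(1 - pik / 2)
      } else {
        if (pik < 1e-12) { bound[k] <- mean_k - zmax; capped[k] <- TRUE }
        else bound[k] <- mean_k + stats::qnorm(pik)
      }
      lim <- if (type == "efficacy") c(-bound[k], bound[k])
             else c(bound[k], mean_k + zmax)
      gr <- trap(nodes, lim[1], lim[2])
      x <- gr$x; g <- gr$w * stats::dnorm(x, mean_k, 1)
      next
    }
    t0 <- frac[k - 1L]
    rho <- sqrt(t0 / t1)
    s <- sqrt((t1 - t0) / t1)
    m <- x * rho + drift * (t1 - t0) / sqrt(t1)
    if (type == "efficacy") {
      crossp <- function(u)
        sum(g * (stats::pnorm((-u - m) / s) + stats::pnorm((u - m) / s, lower.tail = FALSE)))
      if (pik < 1e-10) { bound[k] <- cap; capped[k] <- TRUE }
      else bound[k] <- stats::uniroot(function(u) crossp(u) - pik,
                                      c(0, cap + 4), tol = 1e-10)$root
      lim <- c(-min(bound[k], cap), min(bound[k], cap))
    } else {
      crossp <- function(f) sum(g * stats::pnorm((f - m) / s))
      if (pik < 1e-12) { bound[k] <- mean_k - zmax; capped[k] <- TRUE }
      else bound[k] <- stats::uniroot(function(f) crossp(f) - pik,
                                      c(mean_k - 3 * zmax, mean_k + zmax),
                                      tol = 1e-10)$root
      lim <- c(bound[k], mean_k + zmax)
    }
    gr <- trap(nodes, lim[1], lim[2])
    dens <- outer(gr$x, m, function(z, mm) stats::dnorm((z - mm) / s) / s)
    g <- gr$w * as.numeric(dens %*% g)
    x <- gr$x
  }
  attr(bound, "capped") <- capped
  bound
}

#' Lan-DeMets monitoring boundaries for benefit and harm
#'
#' Symmetric two-sided boundary values \eqn{u_k} such that the cumulative
#' probability, under the null, of the sequential z-statistic ever exceeding
#' the boundary by look k equals the O'Brien-Fleming-type spent error
#' \eqn{\alpha^*(t_k)}, solved by recursive numerical integration. Looks with
#' information fraction above 1 use the fixed-sample critical value (full
#' information reached). Boundaries whose incremental spending underflows
#' (below 1e-10) are reported at the display cap 8 and flagged.
#'
#' @param fractions strictly increasing information fractions, each > 0.
#' @param alpha total two-sided type-I error.
#' @param nodes integration grid nodes per look (default 512).
#' @return data.frame with `t`, `alpha_spent`, `upper`, `lower`, `capped`,
#'   `fixed_sample`.
#' @export
monitoring_boundaries <- function(fractions, alpha, nodes = 512) {
  if (any(diff(fractions) <= 0)) stop("information fractions must be strictly increasing")
  if (any(fractions <= 0)) stop("information fractions must be > 0")
  over <- fractions > 1
  inner <- fractions[!over]
  # a look exactly at (or clamped near) full information stays in the recursion
  u <- if (length(inner))
    .gs_bounds(inner, alpha_spent(inner, alpha), "efficacy", nodes = nodes)
  else numeric(0)
  capped <- c(attr(u, "capped") %||% logical(0), rep(FALSE, sum(over)))
  zfix <- stats::qnorm(1 - alpha / 2)
  upper <- c(as.numeric(u), rep(zfix, sum(over)))
  data.frame(t = fractions, alpha_spent = alpha_spent(fractions, alpha),
             upper = upper, lower = -upper, capped = capped,
             fixed_sample = over)
}

#' Futility (inner-wedge) boundaries
#'
#' Non-binding futility bounds from a beta-spending function of the same
#' O'Brien-Fleming type, \eqn{\beta^*(t) = 2(1-\Phi(z_{1-\beta/2}/\sqrt t))},
#' computed by the same recursive integration under the drift implied by the
#' anticipated effect and the required information size. On the
#' benefit-oriented z scale the wedge at look k is \eqn{(-f_k, f_k)}; it is
#' reported only at looks where it is non-empty (\eqn{f_k > 0}). At full
#' information the wedge closes at the conventional critical value.
#'
#' @inheritParams monitoring_boundaries
#' @param beta total type-II error.
#' @param drift implied mean of the z-statistic at full information (see
#'   [required_information_size()]).
#' @return data.frame with `t`, `fut_upper`, `fut_lower`, `present`.
#' @export
futility_boundaries <- function(fractions, alpha, beta, drift, nodes = 512) {
  if (any(diff(fractions) <= 0)) stop("information fractions must be strictly increasing")
  if (any(fractions <= 0)) stop("information fractions must be > 0")
  if (drift <= 0) stop("drift must be > 0")
  over <- fractions > 1
  inner <- fractions[!over]
  spend <- 2 * (1 - stats::pnorm(stats::qnorm(1 - beta / 2) / sqrt(inner)))
  f <- if (length(inner)) as.numeric(.gs_bounds(inner, spend, "futility",
                                                drift = drift, nodes = nodes))
       else numeric(0)
  zfix <- stats::qnorm(1 - alpha / 2)
  f <- c(pmin(f, zfix), rep(zfix, sum(over)))
  present <- f > 0
  data.frame(t = fractions, fut_upper = ifelse(present, f, NA_real_),
             fut_lower = ifelse(present, -f, NA_real_), present = present)
}

#' Cumulative z-curve
#'
#' Pools the first k trials (ordered by publication year, ties by trial id)
#' for every k and records \eqn{z_k = \hat\theta_k / SE_k} together with the
#' information fraction \eqn{t_k} = cumulative randomised participants / DIS.
#' The random model uses DerSimonian-Laird z-statistics (asymptotically
#' normal, as the boundary construction assumes).
#'
#' @param effects data.frame from [trial_effects()] (needs `theta`, `se`,
#'   `n_total`; `year`/`trial_id` if not already ordered).
#' @param model `"fixed"` or `"random"`.
#' @param dis diversity-adjusted required information size (> 0).
#' @return data.frame with `look`, `trial_id`, `cum_n`, `t`, `theta`, `se`, `z`.
#' @export
cumulative_z_curve <- function(effects, model = c("fixed", "random"), dis) {
  model <- match.arg(model)
  stopifnot(dis > 0)
  e <- effects
  if (all(c("year", "trial_id") %in% names(e)))
    e <- e[order(e$year, e$trial_id), , drop = FALSE]
  k <- nrow(e)
  if (k < 1L) stop("need at least one trial")
  if (model == "fixed") {
    w <- 1 / e$se^2
    cw <- cumsum(w); cth <- cumsum(w * e$theta)
    theta <- cth / cw; se <- 1 / sqrt(cw)
  } else {
    theta <- se <- numeric(k)
    for (i in seq_len(k)) {
      fit <- dersimonian_laird_pool(e[seq_len(i), , drop = FALSE])
      theta[i] <- fit$theta; se[i] <- fit$se
    }
  }
  cum_n <- cumsum(e$n_total)
  data.frame(look = seq_len(k),
             trial_id = e$trial_id %||% as.character(seq_len(k)),
             cum_n = cum_n, t = cum_n / dis,
             theta = theta, se = se, z = theta / se,
             stringsAsFactors = FALSE)
}

#' Assess boundary crossing
#'
#' Finds the first look at which the benefit-oriented z-statistic crosses the
#' benefit boundary, the harm boundary, or enters the futility wedge. Once the
#' information fraction reaches 1, the conventional fixed-sample threshold
#' applies.
#'
#' @param zcurve data.frame from [cumulative_z_curve()].
#' @param bounds data.frame from [monitoring_boundaries()] on the same
#'   fractions.
#' @param futility optional data.frame from [futility_boundaries()].
#' @param benefit_sign +1 if benefit corresponds to positive z (i.e. to a
#'   positive pooled effect), -1 otherwise; typically `sign(mu_A)`.
#' @param alpha the spending alpha (for the fixed-sample threshold at t >= 1).
#' @return List with `crossing` (`"none"`, `"benefit"`, `"harm"` or
#'   `"futility"`) and `look` (index, or `NA`).
#' @export
assess_crossing <- function(zcurve, bounds, futility = NULL, benefit_sign = 1,
                            alpha = 0.05) {
  stopifnot(nrow(zcurve) == nrow(bounds))
  zfix <- stats::qnorm(1 - alpha / 2)
  for (k in seq_len(nrow(zcurve))) {
    zo <- benefit_sign * zcurve$z[k]
    full <- zcurve$t[k] >= 1
    u <- if (full) zfix else bounds$upper[k]
    if (zo >= u) return(list(crossing = "benefit", look = k))
    if (zo <= -u) return(list(crossing = "harm", look = k))
    if (!is.null(futility)) {
      f <- if (full) zfix else futility$fut_upper[k]
      if (!is.na(f) && (if (full) TRUE else futility$present[k]) && abs(zo) <= f)
        return(list(crossing = "futility", look = k))
    }
  }
  list(crossing = "none", look = NA_integer_)
}

#' TSA-adjusted confidence interval
#'
#' Widens the conventional interval to the current monitoring boundary:
#' \eqn{\hat\theta \pm u \cdot SE}. Equals the conventional interval exactly
#' once full information is reached (u = fixed-sample critical value).
#'
#' @param theta_hat,se_hat pooled estimate and its standard error.
#' @param boundary boundary value u at the current look.
#' @return Numeric interval `c(low, high)`.
#' @export
tsa_adjusted_ci <- function(theta_hat, se_hat, boundary) {
  c(theta_hat - boundary * se_hat, theta_hat + boundary * se_hat)
}

#' Trial sequential analysis
#'
#' Runs the full sequential assessment for one outcome: cumulative z-curve
#' against the required information size, alpha-spending boundaries for
#' benefit and harm, non-binding beta-spending futility wedge, crossing
#' verdict, and the TSA-adjusted confidence interval at the current look.
#'
#' @param effects data.frame from [trial_effects()].
#' @param ris an [required_information_size()] result.
#' @param model `"fixed"` or `"random"` z-curve.
#' @param futility compute the futility wedge (default `TRUE`).
#' @param nodes integration grid nodes per look.
#' @return A `tsa_result`: `looks` (per-look table joining z-curve, boundaries
#'   and wedge), `crossing`, `crossing_look`, `adjusted_ci`, `ris`, `model`,
#'   `benefit_sign`.
#' @export
tsa <- function(effects, ris, model = c("fixed", "random"), futility = TRUE,
                nodes = 512) {
  model <- match.arg(model)
  stopifnot(inherits(ris, "information_size"))
  zc <- cumulative_z_curve(effects, model, ris$dis)
  bounds <- monitoring_boundaries(zc$t, ris$alpha_used, nodes = nodes)
  fut <- if (futility)
    futility_boundaries(zc$t, ris$alpha_used, ris$beta_used, ris$drift,
                        nodes = nodes)
  else NULL
  bsign <- sign(ris$mu_A)
  cr <- assess_crossing(zc, bounds, fut, benefit_sign = bsign,
                        alpha = ris$alpha_used)
  K <- nrow(zc)
  u_now <- if (zc$t[K] >= 1) stats::qnorm(1 - ris$alpha_used / 2) else bounds$upper[K]
  looks <- cbind(zc, bounds[, c("alpha_spent", "upper", "lower", "capped",
                                "fixed_sample")])
  if (!is.null(fut)) looks <- cbind(looks, fut[, c("fut_upper", "fut_lower",
                                                   "present")])
  structure(list(looks = looks, crossing = cr$crossing,
                 crossing_look = cr$look,
                 adjusted_ci = tsa_adjusted_ci(zc$theta[K], zc$se[K], u_now),
                 boundary_now = u_now, ris = ris, model = model,
                 benefit_sign = bsign),
            class = "tsa_result")
}

#' @export
print.tsa_result <- function(x, ...) {
  K <- nrow(x$looks)
  cat(sprintf("Trial sequential analysis (%s model, %d looks)\n", x$model, K))
  cat(sprintf("  DIS = %d; information fraction reached = %.3f\n",
              x$ris$dis, x$looks$t[K]))
  cat(sprintf("  crossing: %s%s\n", x$crossing,
              if (!is.na(x$crossing_look)) sprintf(" at look %d", x$crossing_look) else ""))
  cat(sprintf("  TSA-adjusted CI at current look: [%.4f, %.4f] (boundary %.3f)\n",
              x$adjusted_ci[1], x$adjusted_ci[2], x$boundary_now))
  invisible(x)
}

#' Plot a trial sequential analysis
#'
#' Benefit-oriented cumulative z-curve with the monitoring boundaries and the
#' futility wedge, in base graphics.
#'
#' @param x a `tsa_result`.
#' @param ... passed to [plot()].
#' @export
plot.tsa_result <- function(x, ...) {
  lk <- x$looks
  zo <- x$benefit_sign * lk$z
  ylim <- range(c(zo, lk$upper, lk$lower, 2, -2), na.rm = TRUE)
  graphics::plot(lk$t, zo, type = "b", pch = 19, xlab = "Information fraction",
                 ylab = "Cumulative z (benefit upward)", ylim = ylim,
                 xlim = c(0, max(1, lk$t)), ...)
  graphics::lines(lk$t, lk$upper, lty = 2, col = "red3")
  graphics::lines(lk$t, lk$lower, lty = 2, col = "red3")
  if (!is.null(lk$fut_upper)) {
    graphics::lines(lk$t, lk$fut_upper, lty = 3, col = "blue3")
    graphics::lines(lk$t, lk$fut_lower, lty = 3, col = "blue3")
  }
  graphics::abline(h = c(-1, 1) * stats::qnorm(1 - x$ris$alpha_used / 2),
                   col = "grey70")
  graphics::abline(v = 1, col = "grey70")
  invisible(x)
}

#' TSA plot-data export
#'
#' Per-look table (information fraction, z, boundaries, wedge) suitable for
#' external plotting, written as TSV when `path` is given.
#'
#' @param x a `tsa_result`.
#' @param path optional output path.
#' @return The per-look data.frame, invisibly if written.
#' @export
tsa_data <- function(x, path = NULL) {
  stopifnot(inherits(x, "tsa_result"))
  out <- x$looks
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
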