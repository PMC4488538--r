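## Score-type confidence intervals for the Youden Index.
##
## Once the optimal cut c* is fixed, J = p1 - p2 with p1 = P(X <= c*) and
## p2 = P(Y < c*) two independent binomial proportions.  Each proportion gets
## a Wilson score interval; the two are combined by the square-and-add
## (MOVER) construction into an interval for the difference.

#' Wilson score limits for a binomial proportion
#'
#' The lower and upper limits are the two roots of
#' `(p - p_hat)^2 = z^2 p (1 - p) / n`, i.e. the score interval that treats
#' the proportion inside the variance as unknown.  Computed in the closed
#' form: shrunken centre `(p_hat + z^2/2n) / (1 + z^2/n)` plus/minus the
#' scaled half-width.  `n` need not be an integer (the adjusted-estimate
#' pipeline uses an effective size `n + z^2`).
#'
#' @param p_hat Proportion estimate in `[0, 1]`.
#' @param n Effective number of trials (positive).
#' @param conf.level Confidence level in (0, 1).
#' @return An object of class `"wilson_ci"`: list with `lower`, `upper`,
#'   `p_hat`, `n`, `conf.level`.  Always `0 <= lower <= p_hat <= upper <= 1`.
#' @examples
#' wilson_ci(24 / 33, 33)
#' @export
wilson_ci <- function(p_hat, n, conf.level = 0.95) {
  if (!is.numeric(p_hat) || length(p_hat) != 1L || is.na(p_hat) ||
      p_hat < 0 || p_hat > 1)
    stop("'p_hat' must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("'n' must be a single positive number", call. = FALSE)
  check_conf_level(conf.level)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  lims <- wilson_limits(p_hat, n, z)
  structure(list(lower = lims[[1L]], upper = lims[[2L]], p_hat = p_hat,
                 n = n, conf.level = conf.level),
            class = "wilson_ci")
}

#' @export
print.wilson_ci <- function(x, digits = 3, ...) {
  cat(sprintf("%g%% Wilson score interval for a proportion (p_hat = %.*f, n = %g):\n",
              100 * x$conf.level, digits, x$p_hat, x$n))
  cat(sprintf("  (%.*f, %.*f)\n", digits, x$lower, digits, x$upper))
  invisible(x)
}

## Closed-form Wilson roots; bare numeric version used in hot loops.
wilson_limits <- function(p_hat, n, z) {
  z2 <- z * z
  denom <- 1 + z2 / n
  centre <- (p_hat + z2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z2 / (4 * n * n)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Square-and-add combination of two Wilson limits
#'
#' Combines single-proportion Wilson limits `(l1, u1)` for `p1` (denominator
#' `m`) and `(l2, u2)` for `p2` (denominator `n`) into an interval for the
#' difference `J = p1 - p2`, centred at `j_hat`:
#' `lower = j_hat - z * sqrt(l1(1-l1)/m + u2(1-u2)/n)` and
#' `upper = j_hat + z * sqrt(u1(1-u1)/m + l2(1-l2)/n)`, clipped to
#' `[-1, 1]` (the theoretical range of the index).
#'
#' @param j_hat Point estimate used as the centre.
#' @param w1,w2 `"wilson_ci"` objects for the two component proportions, built
#'   at the same confidence level.
#' @param m,n Group sizes used inside the square-and-add variance terms.
#' @param conf.level Confidence level; must match `w1` and `w2`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
square_add_interval <- function(j_hat, w1, w2, m, n, conf.level = 0.95) {
  stopifnot(inherits(w1, "wilson_ci"), inherits(w2, "wilson_ci"))
  check_conf_level(conf.level)
  if (abs(w1$conf.level - conf.level) > 1e-12 ||
      abs(w2$conf.level - conf.level) > 1e-12)
    stop("'w1' and 'w2' must be built at the same 'conf.level' as the combination",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  square_add_limits(j_hat, w1$lower, w1$upper, w2$lower, w2$upper, m, n, z)
}

square_add_limits <- function(j_hat, l1, u1, l2, u2, m, n, z) {
  a <- z * sqrt(l1 * (1 - l1) / m + u2 * (1 - u2) / n)
  b <- z * sqrt(u1 * (1 - u1) / m + l2 * (1 - l2) / n)
  clip_unit_interval(c(j_hat - a, j_hat + b))
}

clip_unit_interval <- function(bounds) {
  pmin(1, pmax(-1, bounds))
}

new_youden_ci <- function(lower, upper, conf.level, method, estimate, ...) {
  structure(c(list(lower = lower, upper = upper, conf.level = conf.level,
                   method = method, estimate = estimate), list(...)),
            class = "youden_ci")
}

#' @export
print.youden_ci <- function(x, digits = 3, ...) {
  cat(sprintf("%g%% %s confidence interval for the Youden Index:\n",
              100 * x$conf.level, x$method))
  cat(sprintf("  (%.*f, %.*f)\n", digits, x$lower, digits, x$upper))
  centre <- if (x$method == "BAC") x$boot_mean else x$estimate$j_hat
  cat(sprintf("  point estimate J = %.*f (cut point c* = %g)\n",
              digits, x$estimate$j_hat, x$estimate$cut))
  if (x$method == "BAC")
    cat(sprintf("  bootstrap: B = %d, mean = %.*f, sd = %.*f, seed = %d\n",
                x$B, digits, x$boot_mean, digits, x$boot_sd, x$seed))
  invisible(x)
}

## Bare-numeric NP bounds used both by ci_np() and the simulation engine.
np_bounds <- function(x, y, z) {
  ct <- youden_counts(x, y)
  k <- which.max(ct$cx * ct$n - ct$cy * ct$m)   # integer-exact tie-break
  p1 <- ct$cx[k] / ct$m
  p2 <- ct$cy[k] / ct$n
  w1 <- wilson_limits(p1, ct$m, z)
  w2 <- wilson_limits(p2, ct$n, z)
  square_add_limits(p1 - p2, w1[1L], w1[2L], w2[1L], w2[2L], ct$m, ct$n, z)
}

## NPAC bounds: the Wilson roots for the adjusted fractions use the adjusted
## effective sizes m + z^2 and n + z^2 (the adjusted estimate behaves as a
## proportion out of size + z^2 trials), while the square-and-add variance
## terms keep the raw group sizes, exactly as the combination formula is
## written.  This pairing reproduces the published worked example.
npac_bounds <- function(x, y, z) {
  z2 <- z * z
  ct <- youden_counts(x, y)
  k <- which.max((ct$cx + z2 / 2) / (ct$m + z2) - (ct$cy + z2 / 2) / (ct$n + z2))
  p1 <- (ct$cx[k] + z2 / 2) / (ct$m + z2)
  p2 <- (ct$cy[k] + z2 / 2) / (ct$n + z2)
  w1 <- wilson_limits(p1, ct$m + z2, z)
  w2 <- wilson_limits(p2, ct$n + z2, z)
  square_add_limits(p1 - p2, w1[1L], w1[2L], w2[1L], w2[2L], ct$m, ct$n, z)
}

#' NP interval: Wilson square-and-add around the empirical estimate
#'
#' Computes the empirical Youden estimate, Wilson score limits for each
#' component proportion (denominators `m` and `n`), and combines them with
#' the square-and-add construction centred at the empirical estimate.
#'
#' @inheritParams candidate_cutpoints
#' @param conf.level Confidence level (default 0.95).
#' @return A `"youden_ci"` object (`method = "NP"`).
#' @examples
#' ci_np(prostate_nodal())   # (0.253, 0.698) at the 95% level
#' @export
ci_np <- function(sample, y = NULL, conf.level = 0.95) {
  s <- as_two_group(sample, y)
  check_conf_level(conf.level)
  est <- youden_empirical(s)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  w1 <- wilson_limits(est$p1_hat, est$m, z)
  w2 <- wilson_limits(est$p2_hat, est$n, z)
  b <- square_add_limits(est$j_hat, w1[1L], w1[2L], w2[1L], w2[2L],
                         est$m, est$n, z)
  new_youden_ci(b[1L], b[2L], conf.level, "NP", est)
}

#' NPAC interval: Wilson square-and-add around the adjusted estimate
#'
#' Same construction as [ci_np()] but centred at the Agresti-Coull-adjusted
#' estimate, with the adjusted component fractions as the proportion inputs.
#' The Wilson roots for an adjusted fraction use the adjusted effective size
#' (`m + z^2`, `n + z^2`), while the square-and-add variance terms keep the
#' raw `m` and `n`.
#'
#' @inheritParams ci_np
#' @return A `"youden_ci"` object (`method = "NPAC"`).
#' @examples
#' ci_npac(prostate_nodal())  # (0.179, 0.647) at the 95% level
#' @export
ci_npac <- function(sample, y = NULL, conf.level = 0.95) {
  s <- as_two_group(sample, y)
  check_conf_level(conf.level)
  est <- youden_ac(s, conf.level = conf.level)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  z2 <- z * z
  w1 <- wilson_limits(est$p1_hat, est$m + z2, z)
  w2 <- wilson_limits(est$p2_hat, est$n + z2, z)
  b <- square_add_limits(est$j_hat, w1[1L], w1[2L], w2[1L], w2[2L],
                         est$m, est$n, z)
  new_youden_ci(b[1L], b[2L], conf.level, "NPAC", est)
}

#' Confidence intervals for the Youden Index
#'
#' Front door computing any subset of the three intervals: `"np"` (Wilson
#' square-and-add around the empirical estimate), `"npac"` (around the
#' Agresti-Coull-adjusted estimate), and `"bac"` (bootstrap mean-and-variance
#' interval for the adjusted estimate).
#'
#' @inheritParams ci_np
#' @param methods Character vector, subset of `c("np", "npac", "bac")`.
#' @param B Number of bootstrap resamples for the BAC interval.
#' @param seed RNG seed for the BAC interval.
#' @return A named list of `"youden_ci"` objects (class `"youden_ci_list"`).
#' @examples
#' youden_ci(prostate_nodal(), methods = c("np", "npac"))
#' @export
youden_ci <- function(sample, y = NULL, methods = c("np", "npac", "bac"),
                      conf.level = 0.95, B = 500L, seed = 1234L) {
  s <- as_two_group(sample, y)
  methods <- match.arg(tolower(methods), c("np", "npac", "bac"),
                       several.ok = TRUE)
  out <- lapply(methods, function(mth)
    switch(mth,
           np   = ci_np(s, conf.level = conf.level),
           npac = ci_npac(s, conf.level = conf.level),
           bac  = ci_bac(s, conf.level = conf.level, B = B, seed = seed)))
  names(out) <- toupper(methods)
  structure(out, class = "youden_ci_list")
}

#' @export
print.youden_ci_list <- function(x, digits = 3, ...) {
  for (ci in x) print(ci, digits = digits)
  invisible(x)
}
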