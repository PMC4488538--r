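## Core point estimation of the Youden Index.
##
## The empirical objective D(c) = #{x_i <= c}/m - #{y_j < c}/n is a step
## function that only changes value at observed data points, so maximizing
## over all real c reduces to maximizing over the pooled unique values plus
## one sentinel below the pooled minimum (where D = 0, guaranteeing a
## non-negative estimate).

#' Candidate cut points for the empirical Youden objective
#'
#' Returns the sorted unique pooled values of the two groups, prepended with
#' a sentinel value strictly below the pooled minimum.  Every value attained
#' by the objective `c -> #\{x <= c\}/m - #\{y < c\}/n` over the whole real
#' line is attained on this finite set; the sentinel attains 0.
#'
#' @param sample A [two_group_sample()], or the `x` vector when `y` is given.
#' @param y Optional diseased-group vector (when `sample` is a raw vector).
#' @return Numeric vector of candidate cut points (sentinel first).
#' @examples
#' candidate_cutpoints(two_group_sample(c(1, 2), c(2, 3)))
#' @export
candidate_cutpoints <- function(sample, y = NULL) {
  s <- as_two_group(sample, y)
  pooled <- sort(unique(c(s$x, s$y)))
  c(pooled[1L] - 1, pooled)
}

## Counts of x <= c and y < c at each candidate cut.  Sorting once and using
## findInterval keeps this O((m+n) log(m+n)); used by every estimator and by
## the bootstrap.
youden_counts <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  cand <- c(pooled[1L] - 1, pooled)
  ## counts as doubles: the integer-scaled objective n*cx - m*cy would
  ## overflow 32-bit integers for large groups (doubles are exact here)
  list(cand = cand,
       cx = as.numeric(findInterval(cand, sort(x))),                    # #{x_i <= c}
       cy = as.numeric(findInterval(cand, sort(y), left.open = TRUE)),  # #{y_j <  c}
       m = length(x), n = length(y))
}

new_youden_estimate <- function(j_hat, cut, p1_hat, p2_hat, count_x, count_y,
                                m, n, estimator, conf.level = NA_real_) {
  structure(list(j_hat = j_hat, cut = cut, p1_hat = p1_hat, p2_hat = p2_hat,
                 count_x = count_x, count_y = count_y, m = m, n = n,
                 estimator = estimator, conf.level = conf.level),
            class = "youden_estimate")
}

#' @export
print.youden_estimate <- function(x, digits = 3, ...) {
  lab <- switch(x$estimator, empirical = "empirical",
                ac_adjusted = "Agresti-Coull adjusted")
  cat(sprintf("Youden Index estimate (%s): J = %.*f at cut point c* = %g\n",
              lab, digits, x$j_hat, x$cut))
  cat(sprintf("  specificity-type proportion  P(X <= c*): %.*f  (m = %d)\n",
              digits, x$p1_hat, x$m))
  cat(sprintf("  1 - sensitivity              P(Y <  c*): %.*f  (n = %d)\n",
              digits, x$p2_hat, x$n))
  invisible(x)
}

orientation_check <- function(j_hat) {
  if (j_hat < 0.05)
    warning("estimated Youden Index is near 0; check the group orientation ",
            "(the diseased group is assumed stochastically larger)",
            call. = FALSE)
}

#' Empirical Youden Index estimate
#'
#' Maximizes `D(c) = #\{x <= c\}/m - #\{y < c\}/n` over the candidate cut
#' points (ties at the cut count towards specificity, not against
#' sensitivity).  Among tied maximizers the smallest cut is returned.  The
#' estimate always lies in `[0, 1]`; a warning is issued when it is below
#' 0.05, which usually indicates that the groups are swapped.
#'
#' @inheritParams candidate_cutpoints
#' @return A `"youden_estimate"` object with components `j_hat`, `cut`,
#'   `p1_hat` (`P(X <= c*)` estimate), `p2_hat` (`P(Y < c*)` estimate), the
#'   underlying counts, group sizes, and `estimator = "empirical"`.
#' @examples
#' youden_empirical(prostate_nodal())
#' @export
youden_empirical <- function(sample, y = NULL) {
  s <- as_two_group(sample, y)
  ct <- youden_counts(s$x, s$y)
  ## maximize the integer-scaled objective n*#{x<=c} - m*#{y<c}: exact
  ## arithmetic, so exact ties break deterministically to the smallest cut
  ## (which.max returns the first maximizer)
  k <- which.max(ct$cx * ct$n - ct$cy * ct$m)
  j <- ct$cx[k] / ct$m - ct$cy[k] / ct$n
  orientation_check(j)
  new_youden_estimate(j, ct$cand[k], ct$cx[k] / ct$m, ct$cy[k] / ct$n,
                      ct$cx[k], ct$cy[k], ct$m, ct$n, "empirical")
}

#' Agresti-Coull-adjusted Youden Index estimate
#'
#' Replaces each empirical proportion in the Youden objective with its
#' adjusted version `(count + z^2/2) / (size + z^2)`, where
#' `z = qnorm(1 - alpha/2)` and `alpha = 1 - conf.level` (at the 95% level
#' this is approximately "add two successes and two failures"), and
#' re-maximizes over the candidate cut points.  The maximizer may differ from
#' the empirical one.
#'
#' @inheritParams candidate_cutpoints
#' @param conf.level Confidence level supplying `z` (default 0.95).
#' @return A `"youden_estimate"` with `estimator = "ac_adjusted"`; `p1_hat`
#'   and `p2_hat` are the adjusted fractions at the selected cut.
#' @examples
#' youden_ac(prostate_nodal())
#' @export
youden_ac <- function(sample, y = NULL, conf.level = 0.95) {
  s <- as_two_group(sample, y)
  check_conf_level(conf.level)
  z2 <- stats::qnorm(1 - (1 - conf.level) / 2)^2
  ct <- youden_counts(s$x, s$y)
  k <- which.max((ct$cx + z2 / 2) / (ct$m + z2) - (ct$cy + z2 / 2) / (ct$n + z2))
  p1 <- (ct$cx[k] + z2 / 2) / (ct$m + z2)
  p2 <- (ct$cy[k] + z2 / 2) / (ct$n + z2)
  new_youden_estimate(p1 - p2, ct$cand[k], p1, p2,
                      ct$cx[k], ct$cy[k], ct$m, ct$n, "ac_adjusted",
                      conf.level = conf.level)
}

check_conf_level <- function(conf.level) {
  if (!is.numeric(conf.level) || length(conf.level) != 1L ||
      !is.finite(conf.level) || conf.level <= 0 || conf.level >= 1)
    stop("'conf.level' must be a single number in (0, 1)", call. = FALSE)
  invisible(conf.level)
}
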