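## Bootstrap mean-and-variance (BAC) interval for the Youden Index.
##
## Resampling is within-group: each bootstrap replicate draws m values with
## replacement from x and n from y, and the Agresti-Coull-adjusted estimate
## is re-maximized on the resample.  A resample is represented by the
## multinomial vector of how many times each original observation was drawn;
## since a resample's objective only jumps at resampled values -- a subset of
## the original pooled values -- the original candidate grid is exact for
## every resample.  Cumulative counts over the grid are then two triangular
## matrix products, which keeps B = 500 resamples per call cheap enough for
## coverage studies.

## B adjusted-estimate replicates; consumes the current RNG stream.
boot_jac_replicates <- function(x, y, z, B) {
  z2 <- z * z
  ct <- youden_counts(x, y)
  ncand <- length(ct$cand)
  px <- match(x, ct$cand)
  py <- match(y, ct$cand)
  wx <- stats::rmultinom(B, ct$m, rep.int(1, ct$m))   # m x B resample weights
  wy <- stats::rmultinom(B, ct$n, rep.int(1, ct$n))
  mx <- matrix(0, ncand, B)
  rx <- rowsum(wx, group = px)
  mx[as.integer(rownames(rx)), ] <- rx
  my <- matrix(0, ncand, B)
  ry <- rowsum(wy, group = py)
  my[as.integer(rownames(ry)), ] <- ry
  lower_tri <- matrix(0, ncand, ncand)
  lower_tri[row(lower_tri) >= col(lower_tri)] <- 1
  cum_x <- lower_tri %*% mx                            # #{x* <= c}
  strict_tri <- lower_tri
  diag(strict_tri) <- 0
  cum_y <- strict_tri %*% my                           # #{y* <  c}
  d <- (cum_x + z2 / 2) / (ct$m + z2) - (cum_y + z2 / 2) / (ct$n + z2)
  d[cbind(max.col(t(d), ties.method = "first"), seq_len(B))]
}

bac_bounds <- function(x, y, z, B) {
  jacs <- boot_jac_replicates(x, y, z, B)
  mu <- mean(jacs)
  sdv <- stats::sd(jacs)
  list(bounds = clip_unit_interval(c(mu - z * sdv, mu + z * sdv)),
       boot_mean = mu, boot_sd = sdv)
}

#' BAC interval: bootstrap mean-and-variance interval for the Youden Index
#'
#' Draws `B` within-group bootstrap resamples, recomputes the
#' Agresti-Coull-adjusted Youden estimate on each (with full re-maximization
#' of the cut point), and returns the Wald-type interval
#' `bootstrap mean +/- z * bootstrap sd` (sample standard deviation with
#' `B - 1` denominator), clipped to `[-1, 1]`.  The interval is centred at
#' the bootstrap mean, not at the original-sample estimate; the returned
#' object carries the original-sample adjusted estimate for reference.
#'
#' Degenerate resamples (a group collapsing to a single repeated value) are
#' kept: the adjusted estimate is well defined on them, and redrawing would
#' bias the bootstrap distribution.
#'
#' @inheritParams ci_np
#' @param B Number of bootstrap resamples (default 500; at least 2).
#' @param seed Integer RNG seed; required so published intervals are
#'   reproducible.  The default is a fixed documented constant.
#' @return A `"youden_ci"` object (`method = "BAC"`) with additional
#'   components `B`, `seed`, `boot_mean`, `boot_sd`.
#' @examples
#' ci_bac(prostate_nodal(), B = 500, seed = 1)  # approximately (0.263, 0.653)
#' @export
ci_bac <- function(sample, y = NULL, conf.level = 0.95, B = 500L,
                   seed = 1234L) {
  s <- as_two_group(sample, y)
  check_conf_level(conf.level)
  B <- as.integer(B)
  if (is.na(B) || B < 2L)
    stop("'B' must be an integer >= 2 (the bootstrap variance needs at least two replicates)",
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  est <- youden_ac(s, conf.level = conf.level)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  res <- bac_bounds(s$x, s$y, z, B)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  new_youden_ci(res$bounds[1L], res$bounds[2L], conf.level, "BAC", est,
                B = B, seed = as.integer(seed),
                boot_mean = res$boot_mean, boot_sd = res$boot_sd)
}
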