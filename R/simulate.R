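## Monte-Carlo engine for coverage probability and average interval width.

#' Coverage and width of the interval methods under one scenario
#'
#' Simulates `n_sims` independent two-group samples from the scenario, computes
#' the requested confidence intervals on each, and summarizes per method the
#' coverage probability (fraction of intervals containing the scenario's true
#' index, closed-interval containment) and the average width.
#'
#' Per-replicate seeds are derived deterministically from the master `seed`,
#' and every method sees the identical sample within a replicate (paired
#' design), so results for one method do not change when another method is
#' toggled on or off.  A numerical failure in one method on one replicate is
#' counted in `n_failures` rather than aborting the cell; the failed
#' replicate is excluded from that method's coverage and width averages.
#'
#' @param spec A [scenario_spec()].
#' @param n_sims Number of simulated samples (default 5000).
#' @param methods Subset of `c("np", "npac", "bac")`.
#' @param conf.level Nominal level (default 0.95).
#' @param B Bootstrap resamples per replicate for the BAC method (default 500).
#' @param seed Master RNG seed.
#' @return A `data.frame` (class `"coverage_summary"`) with one row per
#'   method: `method`, `coverage`, `avg_width`, `n_failures`, plus the
#'   scenario descriptors `true_j`, `m`, `n`, `n_sims`, `B`, `seed`.
#' @examples
#' sc <- scenario_spec(dist_spec("normal", 0, 1),
#'                     dist_spec("normal", 1.0489, 1), m = 20, n = 20)
#' simulate_coverage(sc, n_sims = 50, methods = "np", seed = 1)
#' @export
simulate_coverage <- function(spec, n_sims = 5000L,
                              methods = c("np", "npac", "bac"),
                              conf.level = 0.95, B = 500L, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_sims <- as.integer(n_sims)
  stopifnot(n_sims >= 1L)
  methods <- match.arg(tolower(methods), c("np", "npac", "bac"),
                       several.ok = TRUE)
  check_conf_level(conf.level)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_sims)
  hit <- width <- fail <- stats::setNames(numeric(length(methods)), methods)
  bounds_fun <- list(
    np   = function(x, y) np_bounds(x, y, z),
    npac = function(x, y) npac_bounds(x, y, z),
    bac  = function(x, y) bac_bounds(x, y, z, B)$bounds)
  for (k in seq_len(n_sims)) {
    set.seed(rep_seeds[k])
    x <- dist_rand(spec$non_diseased, spec$m)
    y <- dist_rand(spec$diseased, spec$n)
    for (mth in methods) {
      b <- tryCatch(bounds_fun[[mth]](x, y), error = function(e) NULL)
      if (is.null(b)) {
        fail[mth] <- fail[mth] + 1
      } else {
        hit[mth] <- hit[mth] + (b[1L] <= spec$true_j && spec$true_j <= b[2L])
        width[mth] <- width[mth] + (b[2L] - b[1L])
      }
    }
  }
  ok <- n_sims - fail
  out <- data.frame(method = toupper(methods),
                    coverage = as.numeric(hit / ok),
                    avg_width = as.numeric(width / ok),
                    n_failures = as.integer(fail),
                    true_j = spec$true_j, m = spec$m, n = spec$n,
                    n_sims = n_sims,
                    B = ifelse(methods == "bac", as.integer(B), NA_integer_),
                    seed = as.integer(seed),
                    row.names = NULL)
  class(out) <- c("coverage_summary", "data.frame")
  attr(out, "scenario") <- spec
  out
}

#' Run a batch of coverage cells
#'
#' Applies [simulate_coverage()] to each scenario in `cells` and binds the
#' per-method rows into one long-format table with scenario-identifying
#' columns.  A cell whose scenario errors is recorded as a row with `NA`
#' results; the batch always completes.
#'
#' @param cells A list of [scenario_spec()] objects (or a single one).
#' @param ... Passed to [simulate_coverage()] (`n_sims`, `methods`,
#'   `conf.level`, `B`).
#' @param seed Master seed; cell `i` uses `seed + i - 1`.
#' @return A long-format `data.frame` with columns `scenario_id`, `family_x`,
#'   `family_y`, `params_x`, `params_y`, `true_j`, `m`, `n`, `method`,
#'   `coverage`, `avg_width`, `n_failures`, `n_sims`, `B`, `seed`.
#' @seealso [format_coverage_table()] for the wide "coverage (width)" layout.
#' @export
simulate_coverage_table <- function(cells, ..., seed = 1L) {
  if (inherits(cells, "scenario_spec")) cells <- list(cells)
  if (length(cells) == 0L) return(data.frame())
  rows <- lapply(seq_along(cells), function(i) {
    sc <- cells[[i]]
    res <- tryCatch(simulate_coverage(sc, ..., seed = as.integer(seed) + i - 1L),
                    error = function(e) {
                      data.frame(method = NA_character_, coverage = NA_real_,
                                 avg_width = NA_real_, n_failures = NA_integer_,
                                 true_j = sc$true_j, m = sc$m, n = sc$n,
                                 n_sims = NA_integer_, B = NA_integer_,
                                 seed = as.integer(seed) + i - 1L)
                    })
    cbind(data.frame(scenario_id = i,
                     family_x = sc$non_diseased$family,
                     family_y = sc$diseased$family,
                     params_x = dist_label(sc$non_diseased),
                     params_y = dist_label(sc$diseased)),
          as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wide "coverage (width)" layout for a coverage table
#'
#' Reformats the long table from [simulate_coverage_table()] into one row per
#' scenario/sample-size cell with one `"coverage (width)"` column per method,
#' mirroring the conventional presentation of coverage studies.
#'
#' @param long A `data.frame` from [simulate_coverage_table()].
#' @param digits Decimals for coverage and width (default 3).
#' @return A `data.frame` with columns `scenario`, `true_j`, `m`, `n`, and one
#'   character column per method.
#' @export
format_coverage_table <- function(long, digits = 3) {
  key <- interaction(long$scenario_id, long$m, long$n, drop = TRUE)
  rows <- lapply(split(long, key), function(d) {
    cell <- data.frame(scenario = sprintf("%s vs %s", d$params_x[1L], d$params_y[1L]),
                       true_j = round(d$true_j[1L], 4), m = d$m[1L], n = d$n[1L])
    for (i in seq_len(nrow(d)))
      cell[[d$method[i]]] <- sprintf("%.*f (%.*f)", digits, d$coverage[i],
                                     digits, d$avg_width[i])
    cell
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$scenario, out$m, out$n), , drop = FALSE]
}
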