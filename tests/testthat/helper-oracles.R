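## Independent brute-force oracles, deliberately coded without reusing the
## package's candidate-cut machinery.

## Exhaustive maximization of D(c) (or its adjusted version) over a dense
## grid spanning beyond the data range.  The objective is a step function,
## so a grid much finer than the smallest gap between distinct values is
## exact.
grid_youden_oracle <- function(x, y, z2 = 0, n_grid = 1e4) {
  m <- length(x); n <- length(y)
  grid <- seq(min(x, y) - 1, max(x, y) + 1, length.out = n_grid)
  grid <- sort(c(grid, x, y))   # make sure every jump location is included
  d <- vapply(grid, function(c) {
    (sum(x <= c) + z2 / 2) / (m + z2) - (sum(y < c) + z2 / 2) / (n + z2)
  }, numeric(1))
  k <- which.max(d)
  list(j = d[k], cut = grid[k])
}

## Random small sample with ties: values drawn from a small integer support.
random_tied_sample <- function(max_size = 12, support = 1:8) {
  m <- sample(1:max_size, 1)
  n <- sample(1:max_size, 1)
  two_group_sample(sample(support, m, replace = TRUE),
                   sample(support, n, replace = TRUE) + sample(0:2, 1))
}

z975 <- qnorm(0.975)
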