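# shared internal helpers

# index of the sample in `grid` nearest to each value of `x`;
# grid must be sorted increasing
nearest_index <- function(x, grid) {
  i <- findInterval(x, grid, all.inside = TRUE)
  lo <- abs(x - grid[i]) <= abs(grid[pmin(i + 1L, length(grid))] - x)
  ifelse(lo, i, pmin(i + 1L, length(grid)))
}

# causal FFT convolution, zero-padded to a 2-3-5-smooth length (plain
# stats::convolve can hit near-prime lengths where R's mixed-radix FFT
# degenerates to quadratic time)
causal_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  N <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, N - length(x))))
  H <- stats::fft(c(h, rep(0, N - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_along(x)] / N
}

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# format numeric columns at 6 significant digits so that repeated writes of
# the same data are byte-identical
format_num_df <- function(d, digits = 6) {
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]]))
      d[[j]] <- formatC(signif(d[[j]], digits), format = "g", digits = digits)
  }
  d
}

# round all numeric leaves of a nested list to `digits` significant digits
signif_list <- function(x, digits = 6) {
  if (is.list(x)) return(lapply(x, signif_list, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}

# draw k reproducible sub-seeds (< 2^31) from a master seed, one stream per
# sub-generator so adding a generator does not perturb the others
derive_seeds <- function(seed, labels) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(labels))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  stats::setNames(s, labels)
}
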