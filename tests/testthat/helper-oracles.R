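# independent oracles used across the suite; none of these call the
# implementation paths they check

# exhaustive search over contiguous partitions of the sorted values:
# the Fisher-Jenks objective oracle for small n
brute_jenks_objective <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  compositions <- function(n, k) {
    if (k == 1) return(list(n))
    out <- list()
    for (f in 1:(n - k + 1)) {
      for (p in compositions(n - f, k - 1)) out[[length(out) + 1]] <- c(f, p)
    }
    out
  }
  best <- Inf
  for (p in compositions(n, k)) {
    idx <- cumsum(p)
    start <- c(1, head(idx, -1) + 1)
    obj <- sum(mapply(function(a, b) {
      v <- x[a:b]
      sum((v - mean(v))^2)
    }, start, idx))
    best <- min(best, obj)
  }
  best
}

# one-line detrended-CV oracle (population SD of OLS-detrended values / mean)
oracle_cv <- function(x, t = seq_along(x)) {
  fit <- lm(x ~ t)
  det <- x - fitted(fit) + mean(x)
  sqrt(mean((det - mean(x))^2)) / mean(x)
}

# a palindromic series whose OLS slope is exactly zero and whose values are
# 8 and 12 in equal number: its detrended values are the series itself
palindrome_8_12 <- function() rep(c(8, 12, 12, 8), 10)

# random driver tibble with n rows
random_driver_tbl <- function(n, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * 10), n))
  names(d) <- driver_names()
  tibble::as_tibble(d)
}

reconstruction <- function(d) rowSums(cbind(d$imfs, 0)) + d$residual
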