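# Small simulation configs and brute-force oracles shared across tests.

tiny_grid <- c(12L, 14L, 12L)

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_dims = tiny_grid, n_timepoints = 60L,
                   n_per_group = c(control = 6L, patient = 6L),
                   n_dti = c(control = 8L, patient = 8L), rng_seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  do.call(sim_config, args)
}

symmetric_couplings <- function(w = 0.5) {
  list(
    list(target = "putamen_left", seed = "left",
         weights = c(control = w, patient = w)),
    list(target = "putamen_right", seed = "right",
         weights = c(control = w, patient = w))
  )
}

# Textbook sum-formula Pearson correlation (independent of stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Elementwise one-sample t over a list of arrays, plain loops
oracle_one_sample_t <- function(vals) {
  n <- length(vals)
  out <- array(0, dim(vals[[1]]))
  for (v in seq_along(out)) {
    x <- vapply(vals, function(a) a[v], 0)
    s <- sd(x)
    out[v] <- if (s == 0) 0 else mean(x) / (s / sqrt(n))
  }
  out
}

oracle_two_sample_t <- function(g1, g2) {
  out <- array(0, dim(g1[[1]]))
  n1 <- length(g1); n2 <- length(g2)
  for (v in seq_along(out)) {
    x <- vapply(g1, function(a) a[v], 0)
    y <- vapply(g2, function(a) a[v], 0)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    out[v] <- if (se == 0) 0 else (mean(x) - mean(y)) / se
  }
  out
}

oracle_fa <- function(l1, l2, l3) {
  lb <- (l1 + l2 + l3) / 3
  sqrt(3 / 2) * sqrt((l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2) /
    sqrt(l1^2 + l2^2 + l3^2)
}

random_zmaps <- function(n, dims = c(5, 6, 5), sd = 1, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(dims), sd = sd), dims))
}
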