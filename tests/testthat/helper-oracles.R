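# Independent brute-force oracles used to validate the vectorized engine.

# exhaustive O(n^2) pair-counting Mann-Kendall oracle with table()-based ties
oracle_mk <- function(y) {
  n <- length(y)
  S <- 0
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      S <- S + sign(y[j] - y[i])
  tie_sizes <- as.numeric(table(y))
  tie_term <- sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))
  varS <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  list(S = S, var_S = varS)
}

# median of all pairwise slopes, by explicit enumeration
oracle_sen <- function(y, t = seq_along(y)) {
  sl <- c()
  n <- length(y)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      sl <- c(sl, (y[j] - y[i]) / (t[j] - t[i]))
  median(sl)
}

# stationary AR(1) series matrix: n rows (time), m columns (replicates)
ar1_matrix <- function(n, m, phi, sd = 1) {
  E <- matrix(rnorm(n * m, sd = sd), n)
  E[1, ] <- E[1, ] / sqrt(1 - phi^2)
  if (phi != 0) for (t in 2:n) E[t, ] <- phi * E[t - 1, ] + E[t, ]
  E
}

# small cube with given per-month values recycled over cells
constant_cube <- function(value, n_lat = 2, n_lon = 2, n_years = 3) {
  g <- make_grid(n_lat, n_lon)
  data_cube(array(value, c(12 * n_years, n_lat, n_lon)), g, variable = "sm")
}

# cube whose monthly values at every cell are 1..12 repeated each year
month_ramp_cube <- function(n_years = 3, n_lat = 2, n_lon = 2) {
  g <- make_grid(n_lat, n_lon)
  v <- rep(1:12, n_years)
  data_cube(array(rep(v, n_lat * n_lon), c(12 * n_years, n_lat, n_lon)),
            g, variable = "sm")
}

# hand-built change_map for merge/cluster tests
fake_change_map <- function(grid, significant, sign, slope, ref_mean = NULL,
                            variable = "sm") {
  if (is.null(ref_mean)) ref_mean <- matrix(1, grid$n_lat, grid$n_lon)
  slope_all <- slope
  slope_all[is.na(slope_all)] <- 0
  structure(list(variable = variable, grid = grid,
                 significant = significant, sign = sign, slope = slope,
                 rel_slope = 100 * slope / ref_mean,
                 slope_all = slope_all,
                 rel_slope_all = 100 * slope_all / ref_mean,
                 ref_mean = ref_mean, quantiles = c(0.1, 0.25, 0.5, 0.75, 0.9)),
            class = "change_map")
}

# best-Jaccard match of a truth mask among a cluster set's labels
best_jaccard <- function(truth_mask, cluster_set) {
  best <- 0; best_label <- NA_integer_
  for (k in cluster_set$table$label) {
    m <- cluster_set$labels == k
    j <- sum(m & truth_mask) / sum(m | truth_mask)
    if (j > best) { best <- j; best_label <- k }
  }
  list(jaccard = best, label = best_label)
}
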