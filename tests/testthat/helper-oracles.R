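# Independent oracles used across the suite.

# OLS by explicit normal equations (X includes the intercept column).
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Exhaustive two-sided permutation p-value for a Pearson correlation
# (all n! orderings of y; feasible for n <= 8).
all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

exhaustive_perm_p <- function(x, y) {
  r_obs <- abs(cor(x, y))
  rs <- vapply(all_permutations(y), function(p) abs(cor(x, p)), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Small random site table with the canonical schema, for plumbing tests.
random_study_df <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    site_id = sprintf("X%02d", seq_len(n)),
    island = rep(c("Moorea", "VancouverEast"), length.out = n),
    status_local = sample(c(1, 2, 3, 5), n, replace = TRUE),
    status_10km = runif(n, 0, 5),
    status_60km = runif(n, 0, 5),
    dist_port_km = rexp(n, 1 / 3),
    dist_freshwater = runif(n),
    dist_pollution = runif(n),
    algae_cover = runif(n),
    wave_exposure = sample(1:5, n, replace = TRUE),
    traffic = sample(1:5, n, replace = TRUE),
    substrate = sample(1:5, n, replace = TRUE),
    aquaculture = runif(n, 0, 5),
    nis_prop = runif(n, 0, 0.6),
    n_native = sample(1:10, n, replace = TRUE),
    richness = runif(n, 0, 2.5),
    simpson = runif(n, 0, 0.9),
    stringsAsFactors = FALSE
  )
}
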