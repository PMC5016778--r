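#' Correlation-matrix principal component analysis with bootstrap
#'
#' Eigen-decomposition of the correlation matrix of the selected variables
#' (so each variable enters standardized, regardless of units), with
#' bootstrap confidence limits on the eigenvalues obtained by resampling
#' sites with replacement. Component sign is fixed so that the
#' largest-magnitude loading of each component is positive.
#'
#' @param data a [study_dataset()] or data frame.
#' @param variables column names to include (>= 2, none constant).
#' @param n_boot bootstrap replicates for the eigenvalue limits (default
#'   1000; 0 skips the bootstrap).
#' @param seed integer seed for the bootstrap resampling.
#' @return object of class `nis_pca`: list with `eigenvalues`,
#'   `boot_ci` (2 x p matrix of 2.5% and 97.5% limits, or `NULL`),
#'   `percent_var`, `loadings` (variables x components, unit-norm columns),
#'   `scores` (sites x components), `n_boot`, `seed`.
#' @examples
#' d <- packaged_table1()
#' p <- pca_correlation(d, c("nis_prop", "status_local", "aquaculture"),
#'                      n_boot = 0)
#' p$percent_var
#' @export
pca_correlation <- function(data, variables, n_boot = 1000, seed = 1L) {
  stopifnot(length(variables) >= 2L, all(variables %in% names(data)))
  X <- as.matrix(as.data.frame(data)[, variables])
  if (nrow(X) < 3L) stop("need at least 3 sites", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  }
  dec <- eigen(stats::cor(X), symmetric = TRUE)
  ev <- pmax(dec$values, 0)
  load <- dec$vectors
  # sign convention: dominant loading of each component is positive
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(variables, paste0("PC", seq_along(ev)))
  scores <- scale(X) %*% load
  boot_ci <- NULL
  if (n_boot > 0) {
    boot <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          idx <- sample(nrow(X), replace = TRUE)
          Xb <- X[idx, , drop = FALSE]
          if (all(apply(Xb, 2, stats::sd) > 0)) break
        }
        sort(pmax(eigen(stats::cor(Xb), symmetric = TRUE,
                        only.values = TRUE)$values, 0),
             decreasing = TRUE)
      }, numeric(length(ev)))
    })
    boot_ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975))
    colnames(boot_ci) <- colnames(load)
  }
  structure(list(
    eigenvalues = ev,
    boot_ci = boot_ci,
    percent_var = 100 * ev / sum(ev),
    loadings = load,
    scores = scores,
    n_boot = n_boot, seed = seed
  ), class = "nis_pca")
}

#' @export
print.nis_pca <- function(x, digits = 3, ...) {
  k <- min(4L, length(x$eigenvalues))
  cat(sprintf("Correlation PCA: %d variables, %d sites\n",
              nrow(x$loadings), nrow(x$scores)))
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `% variance` = x$percent_var[1:k])
  if (!is.null(x$boot_ci)) {
    tab <- rbind(tab, `2.5%` = x$boot_ci[1, 1:k], `97.5%` = x$boot_ci[2, 1:k])
  }
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, digits))
  invisible(x)
}

#' Gap-rule outlier screening on a single variable
#'
#' Flags sites whose value on one variable is separated from the rest of
#' the distribution by a large gap, the situation where a covariate becomes
#' discontinuous and distorts downstream regression. The rule peels extreme
#' values one at a time: the most extreme value is flagged while its gap to
#' the nearest remaining value exceeds `gap_factor` times the interquartile
#' range of the remaining values, on either tail.
#'
#' @param data a [study_dataset()] or data frame.
#' @param variable numeric column to screen.
#' @param gap_factor gap threshold in IQR units (default 1.5).
#' @param max_frac flag at most this fraction of sites (default 0.25).
#' @return character vector of flagged `site_id`s (possibly empty), with
#'   the screened values attached as attribute `"values"`.
#' @examples
#' d <- packaged_table1()
#' flag_outliers(d, "dist_port_km")   # the two far-from-port sites
#' @export
flag_outliers <- function(data, variable, gap_factor = 1.5, max_frac = 0.25) {
  stopifnot(variable %in% names(data), gap_factor > 0)
  x <- as.data.frame(data)[[variable]]
  if (!is.numeric(x)) stop("variable must be numeric", call. = FALSE)
  n <- length(x)
  if (n < 5L) stop("refusing to flag outliers with fewer than 5 sites",
                   call. = FALSE)
  ids <- if ("site_id" %in% names(data)) data[["site_id"]] else as.character(seq_len(n))
  active <- seq_len(n)
  flagged <- integer(0)
  while (length(flagged) < max_frac * n && length(active) >= 5L) {
    v <- x[active]
    i_hi <- which.max(v); i_lo <- which.min(v)
    gap_hi <- v[i_hi] - max(v[-i_hi])
    gap_lo <- min(v[-i_lo]) - v[i_lo]
    iqr_hi <- stats::IQR(v[-i_hi])
    iqr_lo <- stats::IQR(v[-i_lo])
    hit_hi <- gap_hi > gap_factor * iqr_hi
    hit_lo <- gap_lo > gap_factor * iqr_lo
    if (!hit_hi && !hit_lo) break
    drop <- if (hit_hi && (!hit_lo || gap_hi >= gap_lo)) i_hi else i_lo
    flagged <- c(flagged, active[drop])
    active <- active[-drop]
  }
  out <- ids[sort(flagged)]
  attr(out, "values") <- x[sort(flagged)]
  out
}
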