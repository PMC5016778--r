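# The 13-variable family screened against each other in the initial
# correlation pass, and the 12-predictor set used for modelling (diversity
# indices are excluded from the model stage: they show strong residual
# autocorrelation with the response and would double-count community
# structure).
.SCREEN_VARIABLES <- c(
  "status_local", "status_10km", "status_60km", "dist_port_km",
  "wave_exposure", "dist_freshwater", "algae_cover", "dist_pollution",
  "traffic", "substrate", "aquaculture", "n_native"
)
.DIVERSITY_VARIABLES <- c("richness", "simpson")

#' Full protection-vs-invasion analysis of a site table
#'
#' Runs the complete analysis on a scored site table, in order: (1) Pearson
#' screen of the response against the 12 covariates with Bonferroni
#' correction, on all sites; (2) autocorrelation check of the diversity
#' indices against the response (Durbin-Watson on the OLS residuals in row
#' order), which is the basis for keeping them out of the model stage;
#' (3) correlation-matrix PCA of the 13-variable block with bootstrap
#' eigenvalue limits; (4) gap-rule outlier screening on the distance-to-port
#' column; (5) on the outlier-free data, the multiple linear regression of
#' the response on the 12 covariates with the overall ANOVA F, and one
#' bivariate normal-family GLM per covariate (identity link; log link
#' optional); (6) residual diagnostics (Shapiro-Wilk normality,
#' Breusch-Pagan homoskedasticity, Durbin-Watson for the significant
#' bivariate fits). Outliers are removed for the model stages only; the
#' initial screen uses every site.
#'
#' @param data a [study_dataset()].
#' @param response response column (default `"nis_prop"`).
#' @param predictors model covariates (default: the 12-variable set).
#' @param outlier_variable column screened for discontinuity (default
#'   `"dist_port_km"`); `NULL` disables outlier removal.
#' @param gap_factor passed to [flag_outliers()].
#' @param glm_links links fitted per covariate (default identity only; add
#'   `"log"` for the logarithmic mean curve).
#' @param n_perm permutation count for correlation and Durbin-Watson
#'   p-values (0 skips them).
#' @param n_boot bootstrap replicates for the PCA eigenvalue limits.
#' @param seed integer seed governing every randomized step.
#' @return object of class `nis_analysis`; see [print.nis_analysis()].
#'   Components: `screen`, `diversity_check`, `pca`, `outliers`, `mlr`,
#'   `glm_table`, `diagnostics`, `data_used`, `provenance`.
#' @examples
#' fit <- nis_analysis(packaged_table1(), n_perm = 0, n_boot = 0)
#' fit
#' @export
nis_analysis <- function(data,
                         response = "nis_prop",
                         predictors = .SCREEN_VARIABLES,
                         outlier_variable = "dist_port_km",
                         gap_factor = 1.5,
                         glm_links = "identity",
                         n_perm = 999,
                         n_boot = 1000,
                         seed = 1L) {
  validate_study_dataset(data)
  stopifnot(response %in% names(data), all(predictors %in% names(data)))

  # 1. correlation screen on the full data
  screen <- correlation_screen(data, response, predictors,
                               n_perm = n_perm, seed = seed)

  # 2. diversity autocorrelation check (row order matters)
  div_vars <- intersect(.DIVERSITY_VARIABLES, names(data))
  diversity_check <- lapply(div_vars, function(v) {
    ols <- stats::lm(stats::reformulate(v, response), data = as.data.frame(data))
    c(list(variable = v, r = stats::cor(data[[v]], data[[response]])),
      durbin_watson(stats::resid(ols), n_perm = n_perm, seed = seed))
  })
  names(diversity_check) <- div_vars

  # 3. PCA of the variable block (response + covariates), full data
  pca_vars <- c(response, predictors)
  pca <- pca_correlation(data, pca_vars, n_boot = n_boot, seed = seed)

  # 4. outlier screening, then removal for the model stages only
  outliers <- character(0)
  if (!is.null(outlier_variable)) {
    outliers <- as.character(flag_outliers(data, outlier_variable,
                                           gap_factor = gap_factor))
  }
  data_used <- if (length(outliers)) {
    sub <- as.data.frame(data)[!data$site_id %in% outliers, , drop = FALSE]
    rownames(sub) <- NULL
    study_dataset(sub, scales = attr(data, "scales"))
  } else data

  # 5. models on outlier-free data
  mlr <- fit_mlr(data_used, response, predictors)
  glm_table <- do.call(rbind, lapply(predictors, function(v) {
    do.call(rbind, lapply(glm_links, function(lk) {
      g <- fit_glm_normal(data_used[[v]], data_used[[response]], link = lk)
      data.frame(variable = v, link = lk, slope = g$slope,
                 intercept = g$intercept, phi = g$phi, G = g$G,
                 p_slope = g$p_slope, r2 = g$r2, stringsAsFactors = FALSE)
    }))
  }))
  rownames(glm_table) <- NULL

  # 6. diagnostics on the outlier-free fits
  mlr_resid <- stats::resid(mlr$fit)
  X <- as.matrix(as.data.frame(data_used)[, predictors])
  diagnostics <- list(
    shapiro_p = stats::shapiro.test(mlr_resid)$p.value,
    breusch_pagan = breusch_pagan(X, mlr_resid),
    durbin_watson = durbin_watson(mlr_resid, n_perm = n_perm, seed = seed),
    bivariate_dw = lapply(stats::setNames(predictors, predictors), function(v) {
      ols <- stats::lm(stats::reformulate(v, response),
                       data = as.data.frame(data_used))
      durbin_watson(stats::resid(ols), n_perm = n_perm, seed = seed)
    })
  )

  structure(list(
    screen = screen,
    diversity_check = diversity_check,
    pca = pca,
    outliers = outliers,
    mlr = mlr,
    glm_table = glm_table,
    diagnostics = diagnostics,
    data_used = data_used,
    provenance = list(
      response = response, predictors = predictors,
      outlier_variable = outlier_variable, gap_factor = gap_factor,
      glm_links = glm_links, n_perm = n_perm, n_boot = n_boot, seed = seed,
      n_sites_screen = nrow(data), n_sites_model = nrow(data_used),
      package_version = as.character(utils::packageVersion("mpanis"))
    )
  ), class = "nis_analysis")
}

#' @export
print.nis_analysis <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("NIS ~ protection analysis: %d sites screened, %d modelled\n",
              pv$n_sites_screen, pv$n_sites_model))
  if (length(x$outliers)) {
    cat("  outliers removed (", pv$outlier_variable, "): ",
        paste(x$outliers, collapse = ", "), "\n", sep = "")
  }
  sig <- x$screen$variable[x$screen$significant]
  cat("  screen significant after Bonferroni: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  cat(sprintf("  PCA: first four components carry %.1f%% of the variance\n",
              sum(x$pca$percent_var[1:min(4, length(x$pca$percent_var))])))
  m <- x$mlr
  cat(sprintf("  MLR: R = %.3f, F(%d, %d) = %.3f, p = %s\n",
              m$R, m$df1, m$df2, m$F, fmt_p(m$p_overall)))
  gt <- x$glm_table[x$glm_table$link == x$glm_table$link[1], ]
  sig_glm <- gt$variable[gt$p_slope < 0.05]
  cat("  GLM slopes significant at 0.05: ",
      if (length(sig_glm)) paste(sig_glm, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.nis_analysis <- function(object, ...) {
  print(object)
  cat("\nCorrelation screen:\n"); print(object$screen)
  cat("\nMLR coefficients:\n")
  stats::printCoefmat(object$mlr$coefficients, signif.stars = FALSE)
  cat("\nBivariate GLM table:\n")
  gt <- object$glm_table
  gt$p_slope <- fmt_p(gt$p_slope)
  for (cn in c("slope", "intercept", "phi", "G", "r2")) gt[[cn]] <- round(gt[[cn]], 4)
  print(gt, row.names = FALSE)
  invisible(object)
}

#' Re-run the models on regional subsets
#'
#' Repeats the MLR and bivariate GLM stage on regional sample subsets, the
#' robustness check against artifacts of pooling very different regions.
#' Covariates that are constant within a subset are dropped (and recorded)
#' rather than failing the fit; outlier removal uses the same gap rule per
#' subset.
#'
#' @param data a [study_dataset()].
#' @param subsets named list of island-label vectors; the default is the
#'   four regional combinations: west-coast Vancouver + Moorea, east-coast
#'   Vancouver + Moorea, Vancouver alone, Moorea alone.
#' @param response,predictors,outlier_variable,gap_factor,glm_links as in
#'   [nis_analysis()]; by default no per-subset outlier removal is applied,
#'   so the subset sample sizes are the full regional counts.
#' @return named list, one entry per subset, each with `n`, `mlr`,
#'   `glm_table`, `dropped` (constant covariates removed), `outliers`.
#' @export
run_subsets <- function(data,
                        subsets = list(
                          "VancouverW+Moorea" = c("VancouverWest", "Moorea"),
                          "VancouverE+Moorea" = c("VancouverEast", "Moorea"),
                          "Vancouver"         = c("VancouverWest", "VancouverEast"),
                          "Moorea"            = "Moorea"
                        ),
                        response = "nis_prop",
                        predictors = .SCREEN_VARIABLES,
                        outlier_variable = NULL,
                        gap_factor = 1.5,
                        glm_links = "identity") {
  validate_study_dataset(data)
  lapply(subsets, function(islands) {
    d <- subset(data, islands = islands)
    outliers <- character(0)
    if (!is.null(outlier_variable) && nrow(d) >= 5L) {
      outliers <- as.character(flag_outliers(d, outlier_variable,
                                             gap_factor = gap_factor))
      if (length(outliers)) {
        keep <- !d$site_id %in% outliers
        d <- study_dataset(as.data.frame(d)[keep, , drop = FALSE],
                           scales = attr(d, "scales"))
      }
    }
    sds <- vapply(predictors, function(v) stats::sd(d[[v]]), numeric(1))
    dropped <- predictors[sds == 0]
    keep_preds <- predictors[sds > 0]
    # with small subsets the full covariate list can exceed the sample;
    # drop from the tail of the declared list until the fit is defined
    while (nrow(d) <= length(keep_preds) + 1L && length(keep_preds) > 1L) {
      dropped <- c(dropped, keep_preds[length(keep_preds)])
      keep_preds <- keep_preds[-length(keep_preds)]
    }
    mlr <- fit_mlr(d, response, keep_preds)
    glm_table <- do.call(rbind, lapply(keep_preds, function(v) {
      do.call(rbind, lapply(glm_links, function(lk) {
        g <- fit_glm_normal(d[[v]], d[[response]], link = lk)
        data.frame(variable = v, link = lk, slope = g$slope,
                   intercept = g$intercept, phi = g$phi, G = g$G,
                   p_slope = g$p_slope, stringsAsFactors = FALSE)
      }))
    }))
    rownames(glm_table) <- NULL
    list(n = nrow(d), islands = islands, mlr = mlr, glm_table = glm_table,
         dropped = dropped, outliers = outliers)
  })
}
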