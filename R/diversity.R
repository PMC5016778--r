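#' Simpson's diversity index
#'
#' Evenness-sensitive diversity of a vector of species abundances. Two
#' variants: the bias-corrected form `1 - sum n_i (n_i - 1) / (N (N - 1))`
#' (the default, matching common ecological software) and the plug-in form
#' `1 - sum (n_i / N)^2`. Both are 0 for a single-species sample and
#' approach 1 for many equally abundant species.
#'
#' @param counts positive integer abundances, one per species (zeros are
#'   dropped).
#' @param variant `"unbiased"` (default) or `"plugin"`.
#' @return index value in `[0, 1)` (unbiased variant can reach 1 for all
#'   singletons).
#' @examples
#' simpson_index(c(50, 50))              # 0.50505...
#' simpson_index(c(50, 50), "plugin")    # 0.5
#' @export
simpson_index <- function(counts, variant = c("unbiased", "plugin")) {
  variant <- match.arg(variant)
  counts <- counts[counts != 0]
  if (length(counts) == 0L) stop("no nonzero counts", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  N <- sum(counts)
  if (variant == "unbiased") {
    if (N < 2) stop("unbiased Simpson needs at least 2 individuals",
                    call. = FALSE)
    return(1 - sum(counts * (counts - 1)) / (N * (N - 1)))
  }
  1 - sum((counts / N)^2)
}

#' Margalef's species richness index
#'
#' Sample-size-adjusted species richness `d = (S - 1) / ln(N)`: 0 for a
#' single-species sample regardless of how many individuals were collected.
#'
#' @param S species count (>= 1).
#' @param N total number of individuals (>= 2).
#' @return nonnegative richness index.
#' @examples
#' margalef_richness(5, 97)   # 4 / log(97)
#' @export
margalef_richness <- function(S, N) {
  stopifnot(S >= 1, S == round(S))
  if (any(N < 2)) stop("richness index needs N >= 2", call. = FALSE)
  (S - 1) / log(N)
}

#' Per-site diversity and invasion summary from an abundance table
#'
#' Collapses a long-format abundance table into one summary row per site:
#' species counts, NIS species and NIS individual proportions, Margalef
#' richness and Simpson's index.
#'
#' @param abund data frame with columns `site_id`, `species`, `count`
#'   (nonnegative integer) and `is_nis` (logical).
#' @param simpson_variant passed to [simpson_index()].
#' @return data frame with one row per site and columns `site_id`,
#'   `n_species`, `n_nis_species`, `n_individuals`, `n_nis_individuals`,
#'   `nis_species_prop`, `nis_individual_prop`, `richness`, `simpson`.
#' @export
diversity_summary <- function(abund, simpson_variant = "unbiased") {
  req <- c("site_id", "species", "count", "is_nis")
  miss <- setdiff(req, names(abund))
  if (length(miss)) stop("abundance table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(abund$count < 0)) stop("counts must be nonnegative", call. = FALSE)
  dup <- duplicated(abund[c("site_id", "species")])
  if (any(dup)) {
    stop("duplicated species within site: ",
         paste(unique(abund$species[dup]), collapse = ", "), call. = FALSE)
  }
  sites <- unique(abund$site_id)
  rows <- lapply(sites, function(s) {
    a <- abund[abund$site_id == s & abund$count > 0, , drop = FALSE]
    if (nrow(a) == 0L) stop("site ", s, " has no individuals", call. = FALSE)
    N <- sum(a$count)
    S <- nrow(a)
    nis <- a$is_nis
    data.frame(
      site_id = s,
      n_species = S,
      n_nis_species = sum(nis),
      n_individuals = N,
      n_nis_individuals = sum(a$count[nis]),
      nis_species_prop = sum(nis) / S,
      nis_individual_prop = sum(a$count[nis]) / N,
      richness = if (N >= 2) margalef_richness(S, N) else 0,
      simpson = if (N >= 2) simpson_index(a$count, simpson_variant) else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
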