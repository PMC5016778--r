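#' Configuration for the synthetic site generator
#'
#' Assembles the generative parameters for [simulate_sites()]. The defaults
#' emulate the two-island survey design the package reproduces: a tropical
#' island with a dense mosaic of young protected areas and almost no
#' aquaculture (16 sites), and a temperate island with older, sparser
#' protection and heavy east-coast shellfish farming (8 east + 6 west
#' sites). The response model is linear-with-clipping on the proportion
#' scale: `nis = clip(b0 + b_ps * status_local + b_aq * aquaculture +
#' b_sub * substrate + e)`, `e ~ N(0, sigma^2)`; a logit variant is
#' available for robustness studies. The default effect sizes give a
#' baseline NIS proportion around 0.3 at minimal protection, a strong
#' negative protection effect and a positive aquaculture effect, with noise
#' small enough that clipping at the [0,1] bounds is rare.
#'
#' @param n_moorea,n_vancouver_east,n_vancouver_west sites per region.
#' @param level_probs named list of probability vectors over the protection
#'   tiers (1, 2, 3, 5), one per region.
#' @param duration_decades named vector: mean protection age per region, in
#'   decades.
#' @param window_km length of the coastal window behind the 10-km
#'   protection score.
#' @param farm_rate named vector: mean number of farms near an unprotected
#'   site, per region.
#' @param farm_protection_decay exponential decay of the farm rate per
#'   protection level above 1 (protection excludes aquaculture).
#' @param status_mix probabilities that a farm cultivates a native, exotic
#'   or invader species (weights 1, 2, 3).
#' @param beta0,beta_ps,beta_aq,beta_sub,sigma response-model parameters.
#' @param response `"linear"` (clipped linear, default) or `"logit"`.
#' @param sample_size individuals sampled per site for the community block
#'   (default 100).
#' @param n_species_pool species pool size per site community.
#' @param dirichlet_conc Dirichlet concentration of community relative
#'   abundances (1 = uniform simplex).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_moorea = 16,
                             n_vancouver_east = 8,
                             n_vancouver_west = 6,
                             level_probs = list(
                               Moorea        = c(0.40, 0.12, 0.24, 0.24),
                               VancouverEast = c(0.62, 0.13, 0.19, 0.06),
                               VancouverWest = c(0.50, 0.10, 0.25, 0.15)
                             ),
                             duration_decades = c(Moorea = 1,
                                                  VancouverEast = 3,
                                                  VancouverWest = 3),
                             window_km = 10,
                             farm_rate = c(Moorea = 0.3,
                                           VancouverEast = 2.5,
                                           VancouverWest = 0.6),
                             farm_protection_decay = 0.5,
                             status_mix = c(native = 0.4, exotic = 0.4,
                                            invader = 0.2),
                             beta0 = 0.35, beta_ps = -0.05, beta_aq = 0.04,
                             beta_sub = 0.01, sigma = 0.05,
                             response = c("linear", "logit"),
                             sample_size = 100,
                             n_species_pool = 12,
                             dirichlet_conc = 1) {
  response <- match.arg(response)
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (any(farm_rate < 0)) stop("farm rates must be nonnegative", call. = FALSE)
  if (sample_size < 1) stop("sample_size must be >= 1", call. = FALSE)
  ok <- vapply(level_probs,
               function(p) length(p) == 4L && all(p >= 0) && sum(p) > 0,
               logical(1))
  if (!all(ok)) {
    stop("level_probs entries must be 4 nonnegative weights", call. = FALSE)
  }
  structure(mget(names(formals())), class = "synthetic_config")
}

# one random protection mosaic over a window, as a segment table
.random_mosaic <- function(window_km, level_probs, mean_duration) {
  n_seg <- 1L + stats::rpois(1, 2)
  len <- stats::rgamma(n_seg, shape = 1)
  len <- len / sum(len) * window_km
  data.frame(
    level = sample(c(1, 2, 3, 5), n_seg, replace = TRUE, prob = level_probs),
    duration = stats::rgamma(n_seg, shape = 2, scale = mean_duration / 2),
    length_km = len
  )
}

#' Generate a synthetic two-region study dataset
#'
#' Draws a full scored site table with the statistical structure the
#' analysis assumes, together with the generative truth, so that parameter
#' recovery and error rates of the whole pipeline can be verified. Per
#' site: a local protection tier is drawn from the regional tier mix;
#' 10-km and 60-km protection scores come from random coastline mosaics
#' evaluated with [weighted_protection()] (duration-weighted, in decades);
#' farms are drawn with a Poisson intensity that decays with protection
#' and scored with [aquaculture_vector()], then rescaled to the 0-5 band
#' with [likert_rescale()]; habitat covariates are drawn from simple
#' bounded distributions; the NIS proportion follows the configured
#' response model; and a community abundance table (via
#' [simulate_abundances()]) supplies the native species count and
#' diversity indices.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the same seed yields an identical dataset.
#' @return list with `dataset` (a [study_dataset()]) and `truth` (the
#'   generative coefficients, sigma, response type and the fraction of
#'   sites whose response was clipped at the [0,1] bounds).
#' @examples
#' sim <- simulate_sites(synthetic_config(), seed = 42)
#' nrow(sim$dataset)   # 30
#' sim$truth$beta_ps
#' @export
simulate_sites <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  regions <- rep(c("Moorea", "VancouverEast", "VancouverWest"),
                 c(cfg$n_moorea, cfg$n_vancouver_east, cfg$n_vancouver_west))
  n <- length(regions)
  with_local_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      reg <- regions[i]
      lp <- cfg$level_probs[[reg]]
      status_local <- sample(c(1, 2, 3, 5), 1, prob = lp)
      mos10 <- .random_mosaic(cfg$window_km, lp, cfg$duration_decades[[reg]])
      mos60 <- .random_mosaic(60, lp, cfg$duration_decades[[reg]])
      lambda <- cfg$farm_rate[[reg]] *
        exp(-cfg$farm_protection_decay * (status_local - 1))
      n_farms <- stats::rpois(1, lambda)
      farms <- if (n_farms > 0) {
        data.frame(
          species = paste0("sp", seq_len(n_farms)),
          status_weight = sample(c(1, 2, 3), n_farms, replace = TRUE,
                                 prob = cfg$status_mix),
          n_farms = 1L,
          distance_km = stats::runif(n_farms, 0, 12)
        )
      } else NULL
      data.frame(
        site_id = sprintf("S%02d", i),
        island = reg,
        status_local = status_local,
        status_10km = weighted_protection(mos10, cfg$window_km,
                                          include_duration = TRUE),
        status_60km = weighted_protection(mos60, 60, include_duration = TRUE),
        dist_port_km = stats::rexp(1, 1 / 3),
        dist_freshwater = round(stats::runif(1), 2),
        dist_pollution = round(stats::runif(1), 2),
        algae_cover = round(stats::runif(1), 2),
        wave_exposure = sample(1:5, 1),
        traffic = sample(1:5, 1),
        substrate = sample(1:5, 1),
        aq_raw = aquaculture_vector(farms, radius_km = 10),
        stringsAsFactors = FALSE
      )
    })
    d <- do.call(rbind, rows)
    d$aquaculture <- likert_rescale(d$aq_raw, 0, 5, anchor_zero = TRUE)
    d$aq_raw <- NULL

    mu <- cfg$beta0 + cfg$beta_ps * d$status_local +
      cfg$beta_aq * d$aquaculture + cfg$beta_sub * d$substrate
    eps <- if (cfg$sigma > 0) stats::rnorm(n, 0, cfg$sigma) else numeric(n)
    if (cfg$response == "linear") {
      raw <- mu + eps
      d$nis_prop <- pmin(pmax(raw, 0), 1)
      clipped <- mean(raw < 0 | raw > 1)
    } else {
      d$nis_prop <- stats::plogis(stats::qlogis(pmin(pmax(mu, 1e-6), 1 - 1e-6)) +
                                    eps)
      clipped <- 0
    }

    comm <- lapply(seq_len(n), function(i) {
      ab <- simulate_abundances(cfg$n_species_pool, cfg$sample_size,
                                nis_pressure = pmin(pmax(mu[i], 0), 1),
                                concentration = cfg$dirichlet_conc)
      ab$site_id <- d$site_id[i]
      ab
    })
    div <- diversity_summary(do.call(rbind, comm))
    d$n_native <- div$n_species[match(d$site_id, div$site_id)] -
      div$n_nis_species[match(d$site_id, div$site_id)]
    d$richness <- div$richness[match(d$site_id, div$site_id)]
    d$simpson <- div$simpson[match(d$site_id, div$site_id)]

    list(
      dataset = study_dataset(d),
      truth = list(beta0 = cfg$beta0, beta_ps = cfg$beta_ps,
                   beta_aq = cfg$beta_aq, beta_sub = cfg$beta_sub,
                   sigma = cfg$sigma, response = cfg$response,
                   clipped_fraction = clipped, seed = seed)
    )
  })
}

#' Simulate a site community abundance table
#'
#' Draws one site's community: relative abundances from a symmetric
#' Dirichlet (or supplied exactly), individual counts from a multinomial of
#' fixed sample size (default 100, mirroring a fixed-effort field sample),
#' and NIS flags assigned independently per species with probability equal
#' to the site's invasion pressure.
#'
#' @param n_species number of species in the community (>= 1).
#' @param n_individuals individuals sampled (default 100).
#' @param nis_pressure probability in [0,1] that a species is
#'   non-indigenous; 0 yields an all-native community.
#' @param concentration symmetric Dirichlet concentration for relative
#'   abundances (ignored when `probs` is given).
#' @param probs optional exact relative-abundance vector of length
#'   `n_species`.
#' @param seed optional integer seed (the caller may also manage the RNG).
#' @return data frame with columns `site_id` (`NA`, filled by the caller),
#'   `species`, `count`, `is_nis`; species with zero sampled individuals
#'   are dropped.
#' @examples
#' simulate_abundances(4, 100, probs = rep(0.25, 4), seed = 1)
#' @export
simulate_abundances <- function(n_species, n_individuals = 100,
                                nis_pressure = 0, concentration = 1,
                                probs = NULL, seed = NULL) {
  stopifnot(n_species >= 1, n_individuals >= 1,
            nis_pressure >= 0, nis_pressure <= 1)
  draw <- function() {
    p <- if (!is.null(probs)) {
      stopifnot(length(probs) == n_species, all(probs >= 0), sum(probs) > 0)
      probs / sum(probs)
    } else {
      g <- stats::rgamma(n_species, shape = concentration)
      if (sum(g) == 0) g <- rep(1, n_species)
      g / sum(g)
    }
    counts <- as.integer(stats::rmultinom(1, n_individuals, p))
    is_nis <- if (nis_pressure == 0) rep(FALSE, n_species)
              else stats::runif(n_species) < nis_pressure
    out <- data.frame(
      site_id = NA_character_,
      species = paste0("sp", seq_len(n_species)),
      count = counts,
      is_nis = is_nis,
      stringsAsFactors = FALSE
    )
    out[out$count > 0, , drop = FALSE]
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
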