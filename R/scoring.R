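#' Aquaculture invasion-vector value
#'
#' Scores the aquaculture pressure at a site as the sum, over cultivated
#' species with farms inside a radius, of a species status weight times the
#' number of farms: `AqV = sum_i X_i * Farm_i`. The weight `X` is 1 for a
#' native species, 2 for an exotic one and 3 for a recognized global invader
#' (IUCN/ISSG list); assigning it is the caller's responsibility.
#'
#' @param farms data frame with columns `species` (character),
#'   `status_weight` (1, 2 or 3), `n_farms` (positive integer) and
#'   `distance_km` (distance from the site, km). Zero rows mean no
#'   aquaculture.
#' @param radius_km farms farther than this are ignored (default 10 km).
#' @return nonnegative numeric score.
#' @examples
#' farms <- data.frame(species = c("oyster", "mussel"),
#'                     status_weight = c(1, 3), n_farms = c(2, 1),
#'                     distance_km = c(4, 8))
#' aquaculture_vector(farms)          # 1*2 + 3*1 = 5
#' @export
aquaculture_vector <- function(farms, radius_km = 10) {
  stopifnot(is.numeric(radius_km), length(radius_km) == 1L, radius_km > 0)
  if (is.null(farms) || nrow(farms) == 0L) return(0)
  req <- c("status_weight", "n_farms", "distance_km")
  miss <- setdiff(req, names(farms))
  if (length(miss)) stop("farm table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(farms$status_weight %in% c(1, 2, 3))) {
    stop("status_weight must be 1 (native), 2 (exotic) or 3 (invader)",
         call. = FALSE)
  }
  if (any(farms$n_farms < 1)) stop("n_farms must be >= 1", call. = FALSE)
  keep <- farms$distance_km <= radius_km
  sum(farms$status_weight[keep] * farms$n_farms[keep])
}

#' Rescale raw vector measurements onto a bounded Likert-style scale
#'
#' Maps raw measurements linearly onto `[lo, hi]` across the dataset.
#' Vectors with a natural zero (farm scores, traffic counts) should use the
#' max-anchored map `hi * x / max(x)` so that zero stays zero; general site
#' characteristics use the min-max map
#' `lo + (hi - lo) * (x - min) / (max - min)`.
#'
#' @param raw numeric vector of raw values.
#' @param lo,hi target range (defaults 0 and 5).
#' @param anchor_zero if `TRUE` (default), use the max-anchored map.
#' @return numeric vector on the target scale; rank order is preserved.
#' @examples
#' likert_rescale(c(0, 31.5, 63))       # 0.0 2.5 5.0
#' likert_rescale(1:4, lo = 1, hi = 5, anchor_zero = FALSE)
#' @export
likert_rescale <- function(raw, lo = 0, hi = 5, anchor_zero = TRUE) {
  stopifnot(is.numeric(raw), hi > lo)
  if (anyNA(raw)) stop("raw values contain NA", call. = FALSE)
  if (anchor_zero) {
    if (any(raw < 0)) stop("anchor_zero rescaling needs nonnegative values",
                           call. = FALSE)
    m <- max(raw)
    if (m == 0) return(rep(0, length(raw)))
    return(hi * raw / m)
  }
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    stop("constant vector: min-max rescaling is undefined", call. = FALSE)
  }
  lo + (hi - lo) * (raw - rng[1]) / (rng[2] - rng[1])
}

# Qualitative protection tiers, strongest first. Marine protected areas and
# national parks share the top tier; the jump from 3 to 5 reflects how many
# more uses are allowed outside the strictest tier.
.PROTECTION_TIERS <- c(
  "mpa"                = 5, "national_park"       = 5,
  "ecological_reserve" = 3, "fisheries_regulated" = 3,
  "regulated_fisheries" = 2, "regional_park"      = 2,
  "none"               = 1
)

#' Numeric protection level of a qualitative tier
#'
#' Maps the qualitative protection regime of a stretch of coast to the
#' four-level numeric score used throughout the analysis: 5 for marine
#' protected areas and national parks, 3 for ecological reserves and
#' strictly regulated fisheries, 2 for lightly regulated fisheries and
#' regional parks, 1 for unprotected coast.
#'
#' @param tier character; one of `"mpa"`, `"national_park"`,
#'   `"ecological_reserve"`, `"fisheries_regulated"`,
#'   `"regulated_fisheries"`, `"regional_park"`, `"none"`
#'   (case-insensitive, spaces/hyphens tolerated).
#' @return integer protection level in {1, 2, 3, 5}.
#' @export
protection_level <- function(tier) {
  key <- gsub("[ -]+", "_", tolower(trimws(tier)))
  out <- .PROTECTION_TIERS[key]
  if (anyNA(out)) {
    stop("unknown protection tier: ",
         paste(unique(tier[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Length-weighted coastal protection score
#'
#' Scores the protection of a coastal window as the length-weighted average
#' of segment protection levels, optionally weighted by protection age:
#' without duration `PS = sum_i PL_i * km_i / window`, with duration
#' `PS = sum_i PL_i * t_i * km_i / window` (units then standardized
#' protection-years per km, with `t` in the declared unit — decades by
#' convention here). Segments must tile the window exactly; pad unprotected
#' coast with level-1, duration-0 segments.
#'
#' @param segments data frame with columns `level` (in {1,2,3,5}),
#'   `duration` (protection age, same unit for all segments) and `length_km`
#'   (positive).
#' @param window_km total window length; segment lengths must sum to it.
#' @param include_duration multiply each level by its duration (default
#'   `FALSE`).
#' @return nonnegative protection score; in `[1, 5]` when duration is off.
#' @examples
#' seg <- data.frame(level = c(5, 3, 2, 1), duration = 0,
#'                   length_km = c(1, 3, 2, 4))
#' weighted_protection(seg, window_km = 10)   # 2.2
#' @export
weighted_protection <- function(segments, window_km, include_duration = FALSE) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            is.numeric(window_km), window_km > 0)
  req <- c("level", "length_km")
  if (include_duration) req <- c(req, "duration")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(segments$level %in% c(1, 2, 3, 5))) {
    stop("segment level must be one of 1, 2, 3, 5", call. = FALSE)
  }
  if (any(segments$length_km <= 0)) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  total <- sum(segments$length_km)
  if (abs(total - window_km) > 1e-8 * max(1, window_km)) {
    stop(sprintf("segments cover %.6g km but the window is %.6g km; %s",
                 total, window_km,
                 "pad unprotected coast with level-1 segments"),
         call. = FALSE)
  }
  w <- segments$level * segments$length_km
  if (include_duration) {
    if (any(segments$duration < 0)) {
      stop("durations must be nonnegative", call. = FALSE)
    }
    w <- w * segments$duration
  }
  sum(w) / window_km
}
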