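default_trait_frequencies <- function() {
  # relative commonness of growth forms in an Indo-Pacific reef-flat pool:
  # branching forms frequent, massive most common single form, free-living rare
  c(arborescent = 0.14, bushy = 0.18, table = 0.10, foliose = 0.10,
    column = 0.08, massive = 0.22, encrusting = 0.12, unattached = 0.06)
}

#' Simulate a species-by-trait table
#'
#' Draws a species pool in which each species carries one growth-form trait
#' (probability `1 - multi_trait_prob`) or two distinct traits (capturing
#' growth-form plasticity such as free-living corals that are both massive
#' and unattached). Trait identities are sampled from a configurable
#' frequency profile, so common forms recur across species and the pool
#' realizes far fewer entities than the 256 theoretical combinations.
#'
#' @param n_species Number of species (default 75, a reef-flat-scale pool).
#' @param multi_trait_prob Probability a species carries a second trait
#'   (default 0.15).
#' @param trait_freq Named sampling weights over [coral_traits()]; default
#'   [default_trait_frequencies()].
#' @param seed Optional integer seed (sets the RNG).
#' @return A validated trait tibble with species `sp001`, `sp002`, ...
#' @export
simulate_traits <- function(n_species = 75, multi_trait_prob = 0.15,
                            trait_freq = default_trait_frequencies(),
                            seed = NULL) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (multi_trait_prob < 0 || multi_trait_prob > 1) {
    stop("multi_trait_prob must lie in [0, 1]", call. = FALSE)
  }
  canon <- coral_traits()
  freq <- trait_freq[canon]
  if (any(is.na(freq)) || any(freq < 0) || sum(freq) <= 0) {
    stop("trait_freq must be nonnegative weights named by coral_traits()",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(0L, n_species, length(canon), dimnames = list(NULL, canon))
  for (i in seq_len(n_species)) {
    first <- sample(canon, 1, prob = freq)
    mat[i, first] <- 1L
    if (stats::runif(1) < multi_trait_prob) {
      rest <- setdiff(canon, first)
      second <- sample(rest, 1, prob = freq[rest])
      mat[i, second] <- 1L
    }
  }
  validate_trait_table(dplyr::bind_cols(
    tibble::tibble(species = sprintf("sp%03d", seq_len(n_species))),
    tibble::as_tibble(as.data.frame(mat))
  ))
}

trait_group <- function(traits) {
  # disturbance-response groups: branching forms are bleaching-sensitive,
  # massive/encrusting/columnar/unattached forms stress-tolerant,
  # foliose-only species neutral
  mat <- as.matrix(traits[coral_traits()])
  branching <- rowSums(mat[, c("arborescent", "bushy", "table"),
                           drop = FALSE]) > 0
  stress <- rowSums(mat[, c("massive", "encrusting", "column", "unattached"),
                        drop = FALSE]) > 0
  dplyr::case_when(branching ~ "branching",
                   stress ~ "stress_tolerant",
                   TRUE ~ "foliose")
}

#' Simulate a multi-year, multi-transect percent-cover series
#'
#' Generates cover data with the structure of a permanent-transect reef-flat
#' monitoring series hit by a bleaching-style disturbance. Each species gets
#' a log-normal baseline cover; per transect it occurs with a fixed
#' occupancy probability and, when present, its cover is gamma-distributed
#' around the year's expected value. From the disturbance year on, expected
#' covers are multiplied by a trait-group-specific survival factor
#' (branching groups crash, stress-tolerant groups may transiently gain) and
#' then relax geometrically back toward baseline at `recovery` per year:
#' `m(t) = b + (survival_g - 1) * b * (1 - recovery)^(t - t_dist)`.
#'
#' @param traits A trait table (e.g. from [simulate_traits()]).
#' @param years Integer survey years, strictly increasing; default the
#'   six-survey 1981-1988 design.
#' @param transects Number of transects per year (default 10).
#' @param disturbance_year Year the disturbance strikes (default 1983).
#' @param survival Named multipliers on expected cover in the disturbance
#'   year for the three response groups; default
#'   `c(branching = 0.02, stress_tolerant = 1.3, foliose = 1)`.
#' @param recovery Geometric recovery rate per year toward baseline, in
#'   [0, 1] (default 0.5; 1 restores baseline the following year).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline cover
#'   parameters (percent scale; defaults 0 and 1).
#' @param occupancy Per-transect presence probability (default 0.4).
#' @param shape Gamma shape of transect-level cover noise (default 2).
#' @param detection_limit Covers below this percent record as 0 (default
#'   0.05, roughly the 1-2 cm resolution of a 30 m line-intercept transect),
#'   so species whose cover collapses also drop out of the recorded
#'   assemblage.
#' @param seed Optional integer seed.
#' @return A wide cover tibble (`year`, `transect`, one column per species)
#'   with the configuration attached as attribute `"config"`.
#' @export
simulate_cover <- function(traits,
                           years = c(1981, 1983, 1984, 1985, 1987, 1988),
                           transects = 10,
                           disturbance_year = 1983,
                           survival = c(branching = 0.02,
                                        stress_tolerant = 1.3,
                                        foliose = 1),
                           recovery = 0.5,
                           baseline_meanlog = 0, baseline_sdlog = 1,
                           occupancy = 0.4, shape = 2,
                           detection_limit = 0.05, seed = NULL) {
  traits <- validate_trait_table(traits)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing",
                                  call. = FALSE)
  if (occupancy < 0 || occupancy > 1) stop("occupancy must lie in [0, 1]",
                                           call. = FALSE)
  if (recovery < 0 || recovery > 1) stop("recovery must lie in [0, 1]",
                                         call. = FALSE)
  if (any(survival < 0)) stop("survival multipliers must be >= 0",
                              call. = FALSE)
  groups <- trait_group(traits)
  if (!all(unique(groups) %in% names(survival))) {
    stop("survival needs entries for: ",
         paste(unique(groups), collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_sp <- nrow(traits)
  baseline <- stats::rlnorm(n_sp, baseline_meanlog, baseline_sdlog)
  mult <- unname(survival[groups])
  rows <- list()
  for (yr in years) {
    m <- if (yr < disturbance_year) baseline else
      baseline + (mult - 1) * baseline * (1 - recovery)^(yr - disturbance_year)
    for (tr in seq_len(transects)) {
      present <- stats::rbinom(n_sp, 1, occupancy) == 1
      cov <- numeric(n_sp)
      live <- present & m > 0
      cov[live] <- stats::rgamma(sum(live), shape = shape,
                                 rate = shape / m[live])
      cov[cov < detection_limit] <- 0
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(year = yr, transect = sprintf("t%02d", tr)),
        tibble::as_tibble(as.list(stats::setNames(cov, traits$species)))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- list(
    years = years, transects = transects,
    disturbance_year = disturbance_year, survival = survival,
    recovery = recovery, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, occupancy = occupancy, shape = shape,
    detection_limit = detection_limit, seed = seed
  )
  out
}
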