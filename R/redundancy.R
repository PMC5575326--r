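check_counts <- function(n) {
  if (inherits(n, "data.frame")) n <- n$n
  n <- as.numeric(n)
  if (length(n) == 0) return(numeric(0))
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n))) {
    stop("entity counts must be positive integers", call. = FALSE)
  }
  n
}

#' Functional redundancy
#'
#' Mean number of species per functional entity, `FR = N / FE`: how many
#' species, on average, back up each morphological function. `FR = 1` means
#' every entity rests on a single species.
#'
#' @param n Species-per-entity counts: a positive integer vector, or the
#'   tibble returned by [entity_counts()].
#' @return `sum(n) / length(n)`; `NA` for an empty assemblage.
#' @export
#' @examples
#' functional_redundancy(c(3, 1, 1))
functional_redundancy <- function(n) {
  n <- check_counts(n)
  if (length(n) == 0) return(NA_real_)
  sum(n) / length(n)
}

#' Functional vulnerability
#'
#' Percentage of functional entities supported by exactly one species —
#' entities whose function disappears with a single extinction:
#' `FV = 100 * (FE - sum(min(n_i - 1, 1))) / FE`.
#'
#' @inheritParams functional_redundancy
#' @return Percent in [0, 100]; `NA` for an empty assemblage.
#' @export
functional_vulnerability <- function(n) {
  n <- check_counts(n)
  if (length(n) == 0) return(NA_real_)
  100 * sum(n == 1) / length(n)
}

#' Functional over-redundancy
#'
#' Percentage of species packed into entities beyond the average level:
#' with `FR = N / FE`, `FOR = 100 * sum(max(n_i - FR, 0)) / N`. High values
#' mean species are concentrated in a few species-rich entities while other
#' entities stay thin.
#'
#' @inheritParams functional_redundancy
#' @return Percent in [0, 100); `NA` for an empty assemblage.
#' @export
functional_over_redundancy <- function(n) {
  n <- check_counts(n)
  if (length(n) == 0) return(NA_real_)
  fr <- sum(n) / length(n)
  100 * sum(pmax(n - fr, 0)) / sum(n)
}

#' All three redundancy indices at once
#'
#' @inheritParams functional_redundancy
#' @return A one-row tibble: `n_species`, `n_fe`, `redundancy`,
#'   `vulnerability`, `over_redundancy`.
#' @export
redundancy_indices <- function(n) {
  n <- check_counts(n)
  tibble::tibble(
    n_species = sum(n), n_fe = length(n),
    redundancy = functional_redundancy(n),
    vulnerability = functional_vulnerability(n),
    over_redundancy = functional_over_redundancy(n)
  )
}

#' Constrained null model for vulnerability and over-redundancy
#'
#' Simulates assemblages in which `n_species` species are assigned at random
#' to `n_entities` functional entities while `N` and `FE` are held at their
#' observed values: each entity is first guaranteed one species, then the
#' remaining `N - FE` species are distributed uniformly at random
#' (equal-probability multinomial). Vulnerability and over-redundancy are
#' computed for every replicate, giving the null distributions against which
#' observed values are standardized.
#'
#' The closed-form mean vulnerability under this scheme,
#' `100 * (1 - 1/FE)^(N - FE)`, is a useful analytic cross-check.
#'
#' @param n_species Observed species richness `N`.
#' @param n_entities Observed entity count `FE` (`<= n_species`).
#' @param reps Number of simulated assemblages (default 9999).
#' @param seed Optional integer seed, recorded in the result for audit.
#' @return An object of class `fe_null` holding the per-replicate
#'   `vulnerability` and `over_redundancy` draws plus the configuration.
#' @seealso [ses_p()], [tidy.fe_null()], [glance.fe_null()]
#' @export
fe_null_model <- function(n_species, n_entities, reps = 9999, seed = NULL) {
  if (n_entities < 1) stop("n_entities must be >= 1", call. = FALSE)
  if (n_species < n_entities) {
    stop("n_species must be >= n_entities", call. = FALSE)
  }
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  extra <- stats::rmultinom(reps, size = n_species - n_entities,
                            prob = rep(1 / n_entities, n_entities))
  counts <- extra + 1
  fr <- n_species / n_entities
  structure(
    list(
      vulnerability = 100 * colMeans(counts == 1),
      over_redundancy = 100 * colSums(pmax(counts - fr, 0)) / n_species,
      n_species = n_species, n_entities = n_entities,
      reps = reps, seed = seed
    ),
    class = "fe_null"
  )
}

#' @export
print.fe_null <- function(x, ...) {
  cat(sprintf("Null model: N = %d species over FE = %d entities, %d reps\n",
              x$n_species, x$n_entities, x$reps))
  cat(sprintf("  vulnerability   %5.1f +/- %.1f %%\n",
              mean(x$vulnerability), stats::sd(x$vulnerability)))
  cat(sprintf("  over-redundancy %5.1f +/- %.1f %%\n",
              mean(x$over_redundancy), stats::sd(x$over_redundancy)))
  invisible(x)
}

#' Tidy the null distributions
#'
#' @param x An [fe_null_model()] object.
#' @param ... Unused.
#' @return A tibble with one row per metric: `metric`, `null_mean`,
#'   `null_sd`.
#' @export
tidy.fe_null <- function(x, ...) {
  tibble::tibble(
    metric = c("vulnerability", "over_redundancy"),
    null_mean = c(mean(x$vulnerability), mean(x$over_redundancy)),
    null_sd = c(stats::sd(x$vulnerability), stats::sd(x$over_redundancy))
  )
}

#' One-row null-model summary
#'
#' @param x An [fe_null_model()] object.
#' @param ... Unused.
#' @return A one-row tibble with the configuration and both null moments.
#' @export
glance.fe_null <- function(x, ...) {
  tibble::tibble(
    n_species = x$n_species, n_entities = x$n_entities, reps = x$reps,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    vulnerability_mean = mean(x$vulnerability),
    vulnerability_sd = stats::sd(x$vulnerability),
    over_redundancy_mean = mean(x$over_redundancy),
    over_redundancy_sd = stats::sd(x$over_redundancy)
  )
}

#' Standardized effect size and quantile p-value
#'
#' Compares an observed percentage with its null distribution:
#' `SES = (observed - null mean) / null sd` on unrounded moments, and an
#' empirical quantile p-value with the `(r + 1) / (reps + 1)` correction
#' (two-tailed by default, doubling the smaller tail and capping at 1). When
#' the null distribution is degenerate (`sd = 0`) the SES is undefined and
#' the p-value falls back to exact equality counting.
#'
#' @param observed Observed value (percent).
#' @param null An [fe_null_model()] object, or a numeric vector of null
#'   draws.
#' @param metric Which null metric to use when `null` is an `fe_null`
#'   object.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return A one-row tibble: `observed`, `null_mean`, `null_sd`, `ses`,
#'   `p_value`, `signif` (stars at 0.05 / 0.01 / 0.001), `reps`.
#' @export
ses_p <- function(observed, null,
                  metric = c("vulnerability", "over_redundancy"),
                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (inherits(null, "fe_null")) {
    metric <- match.arg(metric)
    draws <- null[[metric]]
  } else {
    draws <- as.numeric(null)
  }
  reps <- length(draws)
  mu <- mean(draws)
  sdv <- stats::sd(draws)
  ses <- if (isTRUE(sdv > 0)) (observed - mu) / sdv else NA_real_
  p_hi <- (sum(draws >= observed) + 1) / (reps + 1)
  p_lo <- (sum(draws <= observed) + 1) / (reps + 1)
  p <- switch(alternative,
    two.sided = min(1, 2 * min(p_hi, p_lo)),
    greater = p_hi,
    less = p_lo
  )
  tibble::tibble(observed = observed, null_mean = mu, null_sd = sdv,
                 ses = ses, p_value = p, signif = p_stars(p), reps = reps)
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Year-level redundancy summary with null models
#'
#' Builds the assemblage-level summary table: for every year, the pooled
#' species richness and entity count, the mean per-transect entity count
#' with its standard error, the regularity ratio (mean per-transect FE over
#' pooled FE), the three redundancy indices, and null-model results (mean,
#' sd, SES, quantile p) for vulnerability and over-redundancy.
#'
#' @inheritParams relative_abundances
#' @param reps Null-model replicates per year (default 9999).
#' @param seed Optional integer seed; year-specific streams are derived from
#'   it so the table is reproducible.
#' @param alternative Tail for the null-model p-value (see [ses_p()]).
#' @return A tibble with one row per year.
#' @export
redundancy_summary <- function(cover, traits, reps = 9999, seed = NULL,
                               alternative = "two.sided") {
  ent <- yearly_entities(cover, traits)
  memb <- fe_membership(traits)
  cover <- check_cover(cover, traits)
  sp_cols <- cover_species_cols(cover)
  years <- sort(unique(cover$year))
  purrr::map_dfr(seq_along(years), function(i) {
    yr <- years[i]
    sub <- cover[cover$year == yr, , drop = FALSE]
    tot <- colSums(as.matrix(sub[sp_cols]))
    present <- normalize_species(sp_cols[tot > 0])
    cnt <- entity_counts(traits, present)
    base <- dplyr::bind_cols(
      ent[ent$year == yr, ],
      dplyr::select(redundancy_indices(cnt$n), -"n_species", -"n_fe")
    )
    nm <- fe_null_model(sum(cnt$n), nrow(cnt),
                        reps = reps,
                        seed = if (is.null(seed)) NULL else seed + i)
    fv <- ses_p(base$vulnerability, nm, "vulnerability", alternative)
    fo <- ses_p(base$over_redundancy, nm, "over_redundancy", alternative)
    dplyr::bind_cols(
      base,
      fv |> dplyr::select(-"observed", -"reps") |>
        dplyr::rename_with(~ paste0("vulnerability_", .x)),
      fo |> dplyr::select(-"observed", -"reps") |>
        dplyr::rename_with(~ paste0("over_redundancy_", .x))
    )
  })
}
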