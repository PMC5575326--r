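#' Pooled and per-transect entity richness by year
#'
#' For each year: species richness and entity count of the pooled
#' assemblage (all transects combined; a species is present when its summed
#' cover exceeds zero), the mean per-transect entity count with its standard
#' error, and the regularity ratio mean-FE-per-transect / pooled-FE — an
#' indicator of how homogeneously the entities are spread across transects
#' (1 when every transect carries every entity).
#'
#' @inheritParams relative_abundances
#' @return A tibble with one row per year: `year`, `n_species`, `n_fe`,
#'   `fe_bar`, `fe_bar_se`, `n_transects`, `ratio`.
#' @export
yearly_entities <- function(cover, traits) {
  cover <- check_cover(cover, traits)
  sp_cols <- cover_species_cols(cover)
  has_tr <- "transect" %in% names(cover)
  purrr::map_dfr(sort(unique(cover$year)), function(yr) {
    sub <- cover[cover$year == yr, , drop = FALSE]
    tot <- colSums(as.matrix(sub[sp_cols]))
    pooled <- entity_counts(traits, sp_cols[tot > 0])
    if (has_tr) {
      per_tr <- vapply(split(sub, sub$transect), function(tr) {
        v <- colSums(as.matrix(tr[sp_cols]))
        nrow(entity_counts(traits, sp_cols[v > 0]))
      }, numeric(1))
    } else {
      per_tr <- nrow(pooled)
    }
    n_tr <- length(per_tr)
    tibble::tibble(
      year = yr,
      n_species = sum(pooled$n),
      n_fe = nrow(pooled),
      fe_bar = mean(per_tr),
      fe_bar_se = if (n_tr > 1) stats::sd(per_tr) / sqrt(n_tr) else 0,
      n_transects = n_tr,
      ratio = mean(per_tr) / nrow(pooled)
    )
  })
}

#' Year-level means and standard errors of the indices
#'
#' Summarizes a per-sample index table (e.g. from [fd_indices()]) by year:
#' mean, standard error and the number of transects with a defined value,
#' for every numeric index column.
#'
#' @param indices Per-sample tibble with a `year` column and numeric index
#'   columns.
#' @param cols Tidy-selection of the columns to summarize; defaults to all
#'   numeric columns except the sample keys.
#' @return A long tibble: `year`, `index`, `mean`, `se`, `n`.
#' @export
yearly_summary <- function(indices, cols = NULL) {
  indices <- tibble::as_tibble(indices)
  cols <- rlang::enquo(cols)
  if (rlang::quo_is_null(cols)) {
    keep <- setdiff(names(indices)[vapply(indices, is.numeric, logical(1))],
                    c("year"))
  } else {
    keep <- names(dplyr::select(indices, !!cols))
  }
  indices |>
    tidyr::pivot_longer(dplyr::all_of(keep),
                        names_to = "index", values_to = "value") |>
    dplyr::group_by(.data$year, .data$index) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      se = ifelse(.data$n > 1,
                  stats::sd(.data$value, na.rm = TRUE) / sqrt(.data$n), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean = ifelse(is.nan(.data$mean), NA_real_, .data$mean)) |>
    dplyr::select("year", "index", "mean", "se", "n")
}

#' Welch two-sample t-test
#'
#' Two-tailed t-test with the Welch correction for unequal variances
#' (Welch-Satterthwaite degrees of freedom). Returns a missing row with the
#' reason instead of erroring when a sample has fewer than two defined
#' values or both samples are constant.
#'
#' @param a,b Numeric vectors (NAs dropped).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n_a`, `n_b`,
#'   `missing_reason`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  out <- tibble::tibble(statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, n_a = length(a), n_b = length(b),
                        missing_reason = NA_character_)
  if (length(a) < 2 || length(b) < 2) {
    out$missing_reason <- "fewer than 2 values in a group"
    return(out)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      out$statistic <- 0; out$p_value <- 1
      out$df <- length(a) + length(b) - 2
      return(out)
    }
    out$missing_reason <- "zero variance in both groups"
    return(out)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  out$statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out
}

#' Paired t-test over matched transects
#'
#' Two-tailed paired t-test on per-transect differences; pairs where either
#' member is undefined are excluded and the surviving pair count reported.
#'
#' @param a,b Numeric vectors of equal length, matched by position
#'   (transect).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n_pairs`,
#'   `missing_reason`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  out <- tibble::tibble(statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, n_pairs = length(d),
                        missing_reason = NA_character_)
  if (length(d) < 2) {
    out$missing_reason <- "fewer than 2 complete pairs"
    return(out)
  }
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      out$statistic <- 0; out$p_value <- 1; out$df <- length(d) - 1
      return(out)
    }
    out$missing_reason <- "zero variance of differences"
    return(out)
  }
  tt <- stats::t.test(d)
  out$statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out
}

#' Adjust p-values for multiple comparisons
#'
#' Thin validated wrapper around [stats::p.adjust()]: Benjamini-Hochberg
#' step-up by default, Holm step-down as the conservative option. Adjusted
#' values are order-preserving and never smaller than the raw ones.
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs passed through).
#' @param method `"BH"` (default) or `"holm"` (any [stats::p.adjust.methods]
#'   name is accepted).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  pp <- p[!is.na(p)]
  if (any(pp < 0 | pp > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length (pairs with NA dropped).
#' @return A one-row tibble: `r`, `r_squared`, `p_value`, `n`,
#'   `missing_reason` (set when n < 3 or a variable has zero variance).
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  out <- tibble::tibble(r = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, n = length(x),
                        missing_reason = NA_character_)
  if (length(x) < 3) {
    out$missing_reason <- "fewer than 3 paired values"
    return(out)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out$missing_reason <- "zero variance"
    return(out)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  out$r <- unname(ct$estimate)
  out$r_squared <- out$r^2
  out$p_value <- ct$p.value
  out
}

year_pairs <- function(years, baseline, family) {
  years <- sort(unique(years))
  pairs <- list()
  if (family %in% c("baseline", "both")) {
    for (y in setdiff(years, baseline)) {
      pairs[[length(pairs) + 1]] <- c(baseline, y)
    }
  }
  if (family %in% c("consecutive", "both")) {
    for (i in seq_len(length(years) - 1)) {
      pairs[[length(pairs) + 1]] <- c(years[i], years[i + 1])
    }
  }
  unique(pairs)
}

#' Between-year tests of the functional indices
#'
#' Runs, for each index and each year pair of the comparison family, a
#' two-tailed Welch t-test over transect values (transects treated as
#' independent replicates) and a paired t-test over transects defined in
#' both years. p-values are adjusted per index and test type across all
#' comparisons in the family.
#'
#' @param indices Per-sample tibble with `year`, `transect` and numeric
#'   index columns (e.g. from [fd_indices()]).
#' @param cols Tidy-selection of index columns; default all numeric except
#'   keys.
#' @param baseline Baseline year for the `"baseline"` family; defaults to
#'   the earliest year.
#' @param family `"baseline"` (each year vs. the baseline), `"consecutive"`
#'   (successive pairs), or `"both"` (default).
#' @param adjust Adjustment method passed to [adjust_pvalues()].
#' @return A tibble: `index`, `year_a`, `year_b`, `test`, `statistic`,
#'   `df`, `p_raw`, `p_adj`, `n`, `signif`, `missing_reason`.
#' @export
compare_years <- function(indices, cols = NULL, baseline = NULL,
                          family = c("both", "baseline", "consecutive"),
                          adjust = "BH") {
  family <- match.arg(family)
  indices <- tibble::as_tibble(indices)
  if (!all(c("year", "transect") %in% names(indices))) {
    stop("indices need 'year' and 'transect' columns", call. = FALSE)
  }
  cols <- rlang::enquo(cols)
  if (rlang::quo_is_null(cols)) {
    keep <- setdiff(names(indices)[vapply(indices, is.numeric, logical(1))],
                    "year")
  } else {
    keep <- names(dplyr::select(indices, !!cols))
  }
  if (is.null(baseline)) baseline <- min(indices$year)
  pairs <- year_pairs(indices$year, baseline, family)
  res <- purrr::map_dfr(keep, function(idx) {
    purrr::map_dfr(pairs, function(pr) {
      a <- indices[indices$year == pr[1], c("transect", idx)]
      b <- indices[indices$year == pr[2], c("transect", idx)]
      m <- dplyr::full_join(a, b, by = "transect", suffix = c("_a", "_b"))
      va <- m[[paste0(idx, "_a")]]; vb <- m[[paste0(idx, "_b")]]
      w <- welch_t_test(va, vb)
      p <- paired_t_test(va, vb)
      tibble::tibble(
        index = idx, year_a = pr[1], year_b = pr[2],
        test = c("welch", "paired"),
        statistic = c(w$statistic, p$statistic),
        df = c(w$df, p$df),
        p_raw = c(w$p_value, p$p_value),
        n = c(min(w$n_a, w$n_b), p$n_pairs),
        missing_reason = c(w$missing_reason, p$missing_reason)
      )
    })
  })
  res |>
    dplyr::group_by(.data$index, .data$test) |>
    dplyr::mutate(p_adj = adjust_pvalues(.data$p_raw, method = adjust)) |>
    dplyr::ungroup() |>
    dplyr::mutate(signif = p_stars(.data$p_adj)) |>
    dplyr::select("index", "year_a", "year_b", "test", "statistic", "df",
                  "p_raw", "p_adj", "n", "signif", "missing_reason")
}

#' Correlations of yearly assemblage metrics with species richness
#'
#' Pearson correlation (with r-squared and two-tailed p) of each yearly
#' metric against yearly species richness, asking which facets of the
#' functional structure simply track richness and which move independently.
#'
#' @param yearly A tibble with one row per year, a richness column and
#'   numeric metric columns (e.g. from [yearly_entities()] joined with index
#'   summaries).
#' @param richness Name of the richness column (default `"n_species"`).
#' @return A tibble: `metric`, `r`, `r_squared`, `p_value`, `n`,
#'   `missing_reason`.
#' @export
richness_correlations <- function(yearly, richness = "n_species") {
  yearly <- tibble::as_tibble(yearly)
  if (!richness %in% names(yearly)) {
    stop("no column '", richness, "' in yearly table", call. = FALSE)
  }
  metrics <- setdiff(names(yearly)[vapply(yearly, is.numeric, logical(1))],
                     c("year", richness))
  purrr::map_dfr(metrics, function(m) {
    dplyr::bind_cols(tibble::tibble(metric = m),
                     pearson_correlation(yearly[[m]], yearly[[richness]]))
  })
}
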