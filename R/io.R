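#' Read a species-by-trait CSV
#'
#' Expects the header `species,arborescent,bushy,table,foliose,column,
#' massive,encrusting,unattached` (trait columns in any order) and 0/1
#' values; the table is validated with [validate_trait_table()].
#'
#' @param path File path.
#' @return A validated trait tibble.
#' @export
read_trait_csv <- function(path) {
  validate_trait_table(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a wide percent-cover CSV
#'
#' Expects columns `year,transect,<species...>` (transect optional). Empty
#' cells become 0; negative covers or non-numeric years are rejected with
#' the offending row.
#'
#' @param path File path.
#' @return A cover tibble with numeric `year` and species columns.
#' @export
read_cover_csv <- function(path) {
  cover <- readr::read_csv(path, show_col_types = FALSE)
  if (!"year" %in% names(cover)) {
    stop("cover CSV needs a 'year' column", call. = FALSE)
  }
  yr <- suppressWarnings(as.numeric(cover$year))
  if (any(is.na(yr))) {
    stop("malformed year in row(s): ",
         paste(which(is.na(yr)), collapse = ", "), call. = FALSE)
  }
  cover$year <- yr
  check_cover(cover)
}

#' Write a trait or cover tibble to CSV
#'
#' @param x Tibble to write.
#' @param path Destination path.
#' @return `x`, invisibly.
#' @export
write_fd_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Run the full trait-based analysis pipeline
#'
#' One call from raw tables to the complete output bundle: builds the
#' functional space from the full species pool, computes per-sample indices
#' and community-weighted trait means, the year-level entity/redundancy
#' summary with null models, between-year tests and richness correlations,
#' and (optionally) writes everything to CSV/JSON in an output directory.
#'
#' @param traits Trait table or path to a trait CSV.
#' @param cover Cover table or path to a cover CSV.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param axes Retained functional axes (default 2).
#' @param null_reps Null-model replicates per year (default 9999).
#' @param seed Integer seed for the null models (default 1).
#' @param baseline_year Baseline for between-year comparisons; default the
#'   earliest year.
#' @param family Comparison family passed to [compare_years()].
#' @param adjust p-value adjustment method (default `"BH"`).
#' @param level Level for the hull/MST indices (`"fe"` or `"species"`).
#' @param fric_normalize Report FRic relative to the full-pool hull.
#' @return Invisibly, a list with `space`, `indices`, `cwm`, `summary`
#'   (year-level table), `index_summary`, `stats`, `correlations`, and
#'   `metadata`.
#' @export
run_analysis <- function(traits, cover, out_dir = NULL, axes = 2,
                         null_reps = 9999, seed = 1, baseline_year = NULL,
                         family = "both", adjust = "BH", level = "fe",
                         fric_normalize = FALSE) {
  if (is.character(traits)) traits <- read_trait_csv(traits)
  if (is.character(cover)) cover <- read_cover_csv(cover)
  traits <- validate_trait_table(traits)
  cover <- check_cover(cover, traits)

  space <- functional_space(traits, axes = axes)
  indices <- fd_indices(cover, traits, space = space, level = level,
                        fric_normalize = fric_normalize)
  cwm_tbl <- cwm(cover, traits)
  summary_tbl <- redundancy_summary(cover, traits, reps = null_reps,
                                    seed = seed)
  index_summary <- yearly_summary(
    indices, cols = c("n_species", "n_fe", "fric", "feve", "fdiv",
                      "fdis", "rao_q"))
  stats_tbl <- if ("transect" %in% names(cover) &&
                   length(unique(cover$year)) > 1) {
    compare_years(indices,
                  cols = c("n_species", "fric", "feve", "fdiv", "fdis",
                           "rao_q"),
                  baseline = baseline_year, family = family,
                  adjust = adjust)
  } else {
    NULL
  }
  cors <- richness_correlations(
    dplyr::select(summary_tbl, -dplyr::ends_with("_p_value"),
                  -dplyr::ends_with("_signif")))
  metadata <- list(
    seed = seed, null_reps = null_reps, axes = axes, level = level,
    adjust = adjust, family = family, fric_normalize = fric_normalize,
    baseline_year = if (is.null(baseline_year)) min(cover$year)
                    else baseline_year,
    n_species_pool = nrow(traits),
    n_entities_pool = nrow(derive_entities(traits)),
    cailliez = space$cailliez,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("coralfd"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(space$coordinates, file.path(out_dir, "coordinates.csv"))
    readr::write_csv(
      tibble::tibble(axis = seq_along(space$eigenvalues),
                     eigenvalue = space$eigenvalues),
      file.path(out_dir, "eigenvalues.csv"))
    readr::write_csv(space$trait_vectors,
                     file.path(out_dir, "trait_vectors.csv"))
    readr::write_csv(indices, file.path(out_dir, "indices.csv"))
    readr::write_csv(cwm_tbl, file.path(out_dir, "cwm.csv"))
    readr::write_csv(summary_tbl, file.path(out_dir, "yearly_summary.csv"))
    readr::write_csv(index_summary, file.path(out_dir, "index_summary.csv"))
    if (!is.null(stats_tbl)) {
      readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
    }
    readr::write_csv(cors, file.path(out_dir, "correlations.csv"))
    jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(space = space, indices = indices, cwm = cwm_tbl,
                 summary = summary_tbl, index_summary = index_summary,
                 stats = stats_tbl, correlations = cors,
                 metadata = metadata))
}
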