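#' Canonical coral growth-form traits
#'
#' The eight binary colony-morphology traits used throughout the package, in
#' canonical order. Every trait table must contain exactly these columns
#' (in any order); all outputs use this order.
#'
#' @return A character vector of length 8.
#' @export
#' @examples
#' coral_traits()
coral_traits <- function() {
  c("arborescent", "bushy", "table", "foliose", "column",
    "massive", "encrusting", "unattached")
}

normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x
}

#' Validate a species-by-trait table
#'
#' Checks and normalizes a binary species x morphology table: species labels
#' are whitespace-trimmed (internal runs collapsed) and must be unique after
#' case-insensitive comparison; trait columns must be exactly the eight
#' canonical growth forms (any input order) with values 0 or 1; every species
#' must carry at least one trait. Free-living growth forms such as fungiids
#' are expressed as multi-trait rows (e.g. massive and unattached both 1).
#'
#' @param traits A data frame with a `species` column (or species labels in
#'   the first column) and the eight trait columns of [coral_traits()].
#' @return A tibble with columns `species` followed by the eight traits in
#'   canonical order; values are integer 0/1.
#' @export
#' @examples
#' validate_trait_table(data.frame(
#'   species = c("Fungia fungites", "Acropora formosa"),
#'   arborescent = c(0, 1), bushy = 0, table = 0, foliose = 0,
#'   column = 0, massive = c(1, 0), encrusting = 0, unattached = c(1, 0)
#' ))
validate_trait_table <- function(traits) {
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  canon <- coral_traits()
  nm <- names(traits)
  sp_col <- if ("species" %in% nm) "species" else setdiff(nm, canon)[1]
  if (is.na(sp_col) || !sp_col %in% nm) {
    stop("trait table needs a species label column", call. = FALSE)
  }
  missing_tr <- setdiff(canon, nm)
  extra <- setdiff(nm, c(sp_col, canon))
  if (length(missing_tr) > 0) {
    stop("missing trait column(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra) > 0) {
    stop("unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  species <- normalize_species(traits[[sp_col]])
  if (anyDuplicated(tolower(species))) {
    dups <- unique(species[duplicated(tolower(species))])
    stop("duplicate species after normalization: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(traits[canon])
  mode(mat) <- "numeric"
  bad <- !is.finite(mat) | !(mat == 0 | mat == 1)
  if (any(bad)) {
    offenders <- species[apply(bad, 1, any)]
    stop("non-binary trait value(s) for: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    stop("species with no trait membership: ",
         paste(species[zero], collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(mat))
  out[] <- lapply(out, as.integer)
  dplyr::bind_cols(tibble::tibble(species = species), out)
}

fe_id_from_combo <- function(combo) {
  canon <- coral_traits()
  paste(canon[combo == 1], collapse = "-")
}

#' Derive functional entities from a trait table
#'
#' A functional entity (FE) is a unique combination of the eight binary
#' morphological traits; species sharing a combination belong to the same FE
#' and occupy the same point in the functional space. Entity ids are the
#' hyphen-joined member trait names in canonical order (e.g.
#' `"massive-unattached"`), which is stable and human-readable.
#'
#' @param traits A trait table; validated with [validate_trait_table()].
#' @return A tibble with one row per FE: `fe_id`, the eight trait columns,
#'   `n_species`, and a `members` list-column of sorted species names. Rows
#'   are ordered by `fe_id`.
#' @export
derive_entities <- function(traits) {
  traits <- validate_trait_table(traits)
  canon <- coral_traits()
  fe_id <- apply(as.matrix(traits[canon]), 1, fe_id_from_combo)
  traits |>
    dplyr::mutate(fe_id = fe_id) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("fe_id", canon)))) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      members = list(sort(.data$species)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$fe_id)
}

#' Species membership of functional entities
#'
#' Long companion to [derive_entities()]: one row per species with the id of
#' the FE it belongs to.
#'
#' @inheritParams derive_entities
#' @return A tibble with columns `species` and `fe_id`.
#' @export
fe_membership <- function(traits) {
  traits <- validate_trait_table(traits)
  canon <- coral_traits()
  tibble::tibble(
    species = traits$species,
    fe_id = apply(as.matrix(traits[canon]), 1, fe_id_from_combo)
  )
}

#' Species-per-entity counts for an assemblage
#'
#' Restricts the FE map to the species present in an assemblage and counts
#' species per FE (the n_i feeding the redundancy indices). Only FEs with at
#' least one present species are retained, so `sum(n) == length(present)`.
#'
#' @param traits A trait table covering (at least) the present species.
#' @param present Character vector of present species names (normalized as in
#'   [validate_trait_table()]); duplicates are collapsed.
#' @return A tibble with columns `fe_id` and `n`, ordered by `fe_id`; zero
#'   rows for an empty assemblage.
#' @export
entity_counts <- function(traits, present) {
  memb <- fe_membership(traits)
  present <- unique(normalize_species(present))
  present <- present[present != ""]
  unknown <- setdiff(tolower(present), tolower(memb$species))
  if (length(unknown) > 0) {
    stop("species absent from trait table: ",
         paste(present[tolower(present) %in% unknown], collapse = ", "),
         call. = FALSE)
  }
  memb |>
    dplyr::filter(tolower(.data$species) %in% tolower(present)) |>
    dplyr::count(.data$fe_id, name = "n") |>
    dplyr::arrange(.data$fe_id)
}

#' Theoretical number of trait combinations
#'
#' Number of conceivable binary combinations of `n_traits` traits, the
#' denominator used when reporting how much of the possible morphological
#' repertoire a species pool realizes (for eight traits: 256; realized
#' combinations additionally exclude the all-zero row).
#'
#' @param n_traits Positive integer count of binary traits.
#' @return `2^n_traits` as a double.
#' @export
#' @examples
#' theoretical_combination_count(8)
theoretical_combination_count <- function(n_traits) {
  if (length(n_traits) != 1 || !is.finite(n_traits) || n_traits < 1 ||
      n_traits != as.integer(n_traits)) {
    stop("n_traits must be a positive integer", call. = FALSE)
  }
  2^n_traits
}
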