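cover_species_cols <- function(cover) {
  setdiff(names(cover), c("year", "transect"))
}

check_cover <- function(cover, traits = NULL) {
  cover <- tibble::as_tibble(cover)
  if (!"year" %in% names(cover)) {
    stop("cover table needs a 'year' column", call. = FALSE)
  }
  sp <- cover_species_cols(cover)
  if (length(sp) == 0) stop("cover table has no species columns", call. = FALSE)
  vals <- as.matrix(cover[sp])
  vals[is.na(vals)] <- 0
  if (any(vals < 0)) {
    bad <- which(rowSums(vals < 0) > 0)
    stop("negative cover in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cover[sp] <- as.data.frame(vals)
  if (!is.null(traits)) {
    traits <- validate_trait_table(traits)
    unknown <- setdiff(tolower(normalize_species(sp)),
                       tolower(traits$species))
    if (length(unknown) > 0) {
      stop("cover species absent from trait table: ",
           paste(sp[tolower(normalize_species(sp)) %in% unknown],
                 collapse = ", "), call. = FALSE)
    }
  }
  cover
}

#' Relative abundance weights per sample
#'
#' Converts percent cover to relative-abundance weights, either per species
#' or aggregated to functional entities (summed member-species cover divided
#' by total cover). Weights sum to 1 within each sample; samples with zero
#' total cover yield no rows.
#'
#' @param cover Wide cover tibble: `year`, `transect` (optional), then one
#'   percent-cover column per species.
#' @param traits Trait table covering the cover species.
#' @param level `"fe"` (default) or `"species"`.
#' @return A long tibble: sample keys, `fe_id` or `species`, `weight`.
#' @export
relative_abundances <- function(cover, traits, level = c("fe", "species")) {
  level <- match.arg(level)
  cover <- check_cover(cover, traits)
  keys <- intersect(c("year", "transect"), names(cover))
  long <- cover |>
    tidyr::pivot_longer(-dplyr::all_of(keys),
                        names_to = "species", values_to = "cover") |>
    dplyr::filter(.data$cover > 0) |>
    dplyr::mutate(species = normalize_species(.data$species))
  if (level == "fe") {
    memb <- fe_membership(traits)
    long <- long |>
      dplyr::left_join(memb, by = "species") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "fe_id")))) |>
      dplyr::summarise(cover = sum(.data$cover), .groups = "drop")
    unit <- "fe_id"
  } else {
    unit <- "species"
  }
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(weight = .data$cover / sum(.data$cover)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c(keys, unit, "weight"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, unit))))
}

#' Community-level weighted means of traits
#'
#' Cover-weighted percent contribution of each morphological trait to the
#' assemblage: `CWM_t = 100 * sum(cover_i * x_it) / sum(cover_i)`. Species
#' with several traits contribute their full cover to each (full-membership
#' convention), so trait percentages can sum above 100; `normalize = TRUE`
#' rescales each sample's profile to sum to 100 instead.
#'
#' @inheritParams relative_abundances
#' @param by `"sample"` (default; one value per year x transect) or
#'   `"year"` (covers pooled over transects first).
#' @param normalize Rescale each sample's trait profile to sum to 100.
#' @return A long tibble: sample keys, `trait`, `cwm` (percent). Samples
#'   with zero total cover yield no rows.
#' @export
cwm <- function(cover, traits, by = c("sample", "year"), normalize = FALSE) {
  by <- match.arg(by)
  cover <- check_cover(cover, traits)
  traits <- validate_trait_table(traits)
  keys <- intersect(c("year", "transect"), names(cover))
  if (by == "year") keys <- "year"
  canon <- coral_traits()
  long <- cover |>
    tidyr::pivot_longer(-dplyr::any_of(c("year", "transect")),
                        names_to = "species", values_to = "cover") |>
    dplyr::mutate(species = normalize_species(.data$species)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "species")))) |>
    dplyr::summarise(cover = sum(.data$cover), .groups = "drop") |>
    dplyr::left_join(traits, by = "species") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::filter(sum(.data$cover) > 0) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(canon),
                    ~ 100 * sum(cover * .x) / sum(cover)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(canon),
                        names_to = "trait", values_to = "cwm") |>
    dplyr::mutate(trait = factor(.data$trait, levels = canon))
  if (normalize) {
    long <- long |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::mutate(cwm = 100 * .data$cwm / sum(.data$cwm)) |>
      dplyr::ungroup()
  }
  long
}

distinct_points <- function(coords, tol = 1e-9) {
  key <- apply(round(coords / tol) * tol, 1, paste, collapse = "|")
  coords[!duplicated(key), , drop = FALSE]
}

#' Convex-hull area (functional richness kernel)
#'
#' Area of the 2-D convex hull of a point set (monotone hull via
#' [grDevices::chull()] plus the shoelace formula). Functional richness of a
#' sample is this area over its present-FE coordinates.
#'
#' @param coords Numeric matrix (points x 2).
#' @return Hull area; `NA` when fewer than 3 distinct points remain or the
#'   points are collinear (degenerate hull).
#' @export
fd_fric <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("fd_fric expects 2-D coordinates", call. = FALSE)
  pts <- distinct_points(coords)
  if (nrow(pts) < 3) return(NA_real_)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  x <- pts[h, 1]; y <- pts[h, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area < 1e-12) return(NA_real_)
  area
}

prim_mst <- function(dmat) {
  # Prim's algorithm; rows assumed pre-sorted by label so that distance ties
  # resolve to the lexicographically first candidate (deterministic output)
  n <- nrow(dmat)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    best <- c(Inf, 0L, 0L)
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        if (dmat[i, j] < best[1]) best <- c(dmat[i, j], i, j)
      }
    }
    edges[k, ] <- best[2:3]
    in_tree[best[3]] <- TRUE
  }
  edges
}

#' Functional evenness kernel
#'
#' Regularity of the abundance distribution along the minimum spanning tree
#' of the community in functional space. Each MST branch `l` joining points
#' `a`, `b` gets `EW_l = d_ab / (w_a + w_b)`; with `PEW_l = EW_l / sum(EW)`
#' and `S` points, `FEve = (sum(min(PEW_l, 1/(S-1))) - 1/(S-1)) /
#' (1 - 1/(S-1))`, ranging over [0, 1] with 1 for perfectly even spacing and
#' abundance.
#'
#' @param coords Numeric matrix (points x axes), rows ordered by a stable
#'   label (ties in the MST resolve to the first row).
#' @param w Abundance weights summing to 1.
#' @return FEve in [0, 1]; `NA` with fewer than 3 points.
#' @export
fd_feve <- function(coords, w) {
  coords <- as.matrix(coords)
  s <- nrow(coords)
  if (s < 3) return(NA_real_)
  stopifnot(length(w) == s)
  dmat <- as.matrix(stats::dist(coords))
  edges <- prim_mst(dmat)
  ew <- dmat[edges] / (w[edges[, 1]] + w[edges[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional divergence kernel
#'
#' Degree to which abundance is carried by points far from the gravity
#' center `G` of the convex-hull vertices. With `dG_i` the distance of each
#' point to `G`, `dbar` their unweighted mean, `Dd = sum(w_i (dG_i - dbar))`
#' and `D|d| = sum(w_i |dG_i - dbar|)`:
#' `FDiv = (Dd + dbar) / (D|d| + dbar)`.
#'
#' @inheritParams fd_feve
#' @return FDiv in (0, 1]; `NA` for a degenerate (collinear or < 3 distinct
#'   points) hull.
#' @export
fd_fdiv <- function(coords, w) {
  coords <- as.matrix(coords)
  stopifnot(length(w) == nrow(coords))
  if (ncol(coords) != 2) stop("fd_fdiv expects 2-D coordinates", call. = FALSE)
  pts <- distinct_points(coords)
  if (nrow(pts) < 3 || is.na(fd_fric(coords))) return(NA_real_)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  g <- colMeans(pts[h, , drop = FALSE])
  dg <- sqrt(rowSums(sweep(coords, 2, g)^2))
  dbar <- mean(dg)
  dd <- sum(w * (dg - dbar))
  dad <- sum(w * abs(dg - dbar))
  (dd + dbar) / (dad + dbar)
}

#' Functional dispersion kernel
#'
#' Abundance-weighted mean distance of community points to their
#' abundance-weighted centroid.
#'
#' @inheritParams fd_feve
#' @return FDis >= 0 (0 for a single point).
#' @export
fd_fdis <- function(coords, w) {
  coords <- as.matrix(coords)
  stopifnot(length(w) == nrow(coords))
  centroid <- colSums(coords * w)
  sum(w * sqrt(rowSums(sweep(coords, 2, centroid)^2)))
}

#' Rao quadratic entropy
#'
#' Abundance-weighted sum of pairwise functional dissimilarities:
#' `Q = sum_ij w_i w_j d_ij`. Zero for a monoculture.
#'
#' @param w Named weights summing to 1 (names matched against the labels of
#'   `d`; unnamed weights are taken in order).
#' @param d A [stats::dist] object or symmetric dissimilarity matrix.
#' @return Q >= 0.
#' @export
rao_q <- function(w, d) {
  m <- as_dist_matrix(d)
  if (!is.null(names(w))) {
    miss <- setdiff(names(w), rownames(m))
    if (length(miss) > 0) {
      stop("weights name species absent from d: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    m <- m[names(w), names(w), drop = FALSE]
  } else if (length(w) != nrow(m)) {
    stop("length(w) must match the dissimilarity matrix", call. = FALSE)
  }
  drop(t(w) %*% m %*% w)
}

#' Per-sample functional-diversity indices
#'
#' Computes, for every year x transect sample of a cover table, species and
#' entity richness and the abundance-weighted indices in the functional
#' space: FRic (convex-hull area over present-FE coordinates, optionally
#' normalized by the full-pool hull), FEve, FDiv, FDis, and Rao's Q
#' (species-level weights on raw Gower dissimilarities). Hull- and MST-based
#' indices need at least 3 functionally singular (distinct-coordinate) FEs
#' and a non-degenerate hull; samples failing the support rule get `NA` with
#' the reason recorded.
#'
#' @inheritParams relative_abundances
#' @param space A [functional_space()] built from `traits`; built on the fly
#'   when `NULL`.
#' @param level Level for the hull/MST indices: `"fe"` (default) or
#'   `"species"` (coincident members then contribute separately).
#' @param fric_normalize Report FRic as a proportion of the full-pool hull
#'   area.
#' @return A tibble with one row per sample: keys, `total_cover`,
#'   `n_species`, `n_fe`, `fric`, `feve`, `fdiv`, `fdis`, `rao_q`,
#'   `missing_reason`.
#' @export
fd_indices <- function(cover, traits, space = NULL,
                       level = c("fe", "species"), fric_normalize = FALSE) {
  level <- match.arg(level)
  cover <- check_cover(cover, traits)
  traits <- validate_trait_table(traits)
  if (is.null(space)) space <- functional_space(traits)
  stopifnot(inherits(space, "functional_space"))
  keys <- intersect(c("year", "transect"), names(cover))
  ax <- axis_cols(space)
  unit_col <- if (level == "fe") "fe_id" else "species"
  unit_coords <- if (level == "fe") fe_coordinates(space) else
    dplyr::select(space$coordinates, -"fe_id")
  memb <- fe_membership(traits)
  dmat <- as.matrix(space$distance)

  pool_hull <- fd_fric(as.matrix(fe_coordinates(space)[ax[1:2]]))

  samples <- cover |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split()

  purrr::map_dfr(samples, function(smp) {
    key <- smp[1, keys]
    covs <- colSums(as.matrix(smp[cover_species_cols(smp)]))
    names(covs) <- normalize_species(names(covs))
    covs <- covs[covs > 0]
    total <- sum(covs)
    out <- dplyr::bind_cols(key, tibble::tibble(
      total_cover = total, n_species = length(covs),
      n_fe = NA_integer_, fric = NA_real_, feve = NA_real_,
      fdiv = NA_real_, fdis = NA_real_, rao_q = NA_real_,
      missing_reason = NA_character_
    ))
    if (total == 0) {
      out$n_fe <- 0L
      out$missing_reason <- "zero total cover"
      return(out)
    }
    fe_w <- tibble::tibble(species = names(covs), cover = unname(covs)) |>
      dplyr::left_join(memb, by = "species") |>
      dplyr::group_by(.data$fe_id) |>
      dplyr::summarise(cover = sum(.data$cover), .groups = "drop") |>
      dplyr::mutate(weight = .data$cover / sum(.data$cover))
    out$n_fe <- nrow(fe_w)

    if (level == "fe") {
      w_tbl <- fe_w |> dplyr::arrange(.data$fe_id)
    } else {
      w_tbl <- tibble::tibble(species = names(covs),
                              weight = unname(covs) / total) |>
        dplyr::arrange(.data$species)
    }
    pts_tbl <- dplyr::left_join(w_tbl, unit_coords, by = unit_col)
    pts <- as.matrix(pts_tbl[ax])
    w <- pts_tbl$weight

    sw <- covs / total
    out$rao_q <- rao_q(sw, dmat)
    out$fdis <- fd_fdis(pts, w)

    n_singular <- nrow(distinct_points(pts))
    if (n_singular < 3) {
      out$missing_reason <- "insufficient functional singularity"
      return(out)
    }
    p2 <- pts[, 1:2, drop = FALSE]
    area <- fd_fric(p2)
    out$fric <- if (fric_normalize && !is.na(area)) area / pool_hull else area
    out$feve <- fd_feve(pts, w)
    out$fdiv <- fd_fdiv(p2, w)
    if (is.na(area)) out$missing_reason <- "insufficient functional singularity"
    out
  })
}
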