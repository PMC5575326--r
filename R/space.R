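#' Gower dissimilarity among species from binary traits
#'
#' Computes pairwise Gower dissimilarity on the binary trait table: the mean
#' over usable traits of `|x_it - x_jt|`, i.e. the proportion of mismatching
#' traits. Traits with zero range across the pool (possessed by all species
#' or by none) carry no information and are dropped from the average with a
#' warning. Values lie in [0, 1]; functionally identical species are at
#' distance 0.
#'
#' @param traits A trait table (validated with [validate_trait_table()]).
#' @return A [stats::dist] object labelled by species.
#' @export
gower_distance <- function(traits) {
  traits <- validate_trait_table(traits)
  if (nrow(traits) < 2) stop("need at least 2 species", call. = FALSE)
  mat <- as.matrix(traits[coral_traits()])
  rownames(mat) <- traits$species
  rng <- apply(mat, 2, function(x) diff(range(x)))
  if (any(rng == 0)) {
    warning("trait(s) with zero range dropped from Gower average: ",
            paste(colnames(mat)[rng == 0], collapse = ", "), call. = FALSE)
    mat <- mat[, rng > 0, drop = FALSE]
    if (ncol(mat) == 0) stop("no trait varies across the pool", call. = FALSE)
  }
  stats::dist(mat, method = "manhattan") / ncol(mat)
}

as_dist_matrix <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-10)) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  diag(m) <- 0
  m
}

double_center <- function(m2) {
  # Gower double-centering of -1/2 * m2 (m2 = squared distances or distances)
  n <- nrow(m2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% m2 %*% J
}

#' Cailliez additive constant
#'
#' Smallest constant `c` such that adding it to every off-diagonal
#' dissimilarity makes the matrix Euclidean (no negative principal-coordinate
#' eigenvalues). Computed as the largest real eigenvalue of the 2n x 2n block
#' matrix `[[0, 2*D1], [-I, -4*D2]]` with `D1 = -J (D o D) J / 2` and
#' `D2 = -J D J / 2`. Returns 0 when the matrix is already Euclidean.
#'
#' @param d A symmetric dissimilarity matrix or [stats::dist] object.
#' @param tol Relative tolerance on the smallest double-centered eigenvalue
#'   below which the matrix counts as Euclidean.
#' @return A nonnegative scalar.
#' @export
cailliez_constant <- function(d, tol = 1e-8) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  b <- double_center(m^2)
  ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol * max(abs(ev), 1)) return(0)
  d1 <- double_center(m^2)
  d2 <- double_center(m)
  block <- rbind(
    cbind(matrix(0, n, n), 2 * d1),
    cbind(-diag(n), -4 * d2)
  )
  lambda <- eigen(block, only.values = TRUE)$values
  max(Re(lambda[abs(Im(lambda)) < 1e-8]))
}

fix_signs <- function(vectors, labels) {
  # deterministic orientation: the largest-|loading| entry of each axis is
  # positive; |loading| ties resolve to the smallest label so the result is
  # invariant to row order
  for (k in seq_len(ncol(vectors))) {
    v <- vectors[, k]
    cand <- which(abs(v) >= max(abs(v)) - 1e-10)
    i <- cand[order(labels[cand])][1]
    if (v[i] < 0) vectors[, k] <- -v
  }
  vectors
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Metric embedding of a dissimilarity matrix: optionally Cailliez-corrects
#' the off-diagonal entries, double-centers the squared distances,
#' eigendecomposes, and returns coordinates `eigvec_k * sqrt(lambda_k)` for
#' every axis with eigenvalue above `tol * lambda_max`. Axes are sorted by
#' decreasing eigenvalue and given a deterministic orientation (the
#' largest-magnitude loading on each axis is positive), so results are
#' reproducible across platforms.
#'
#' @inheritParams cailliez_constant
#' @param correction Apply the Cailliez correction before embedding
#'   (default `TRUE`).
#' @param tol Relative eigenvalue tolerance for axis retention.
#' @return A list with `coordinates` (n x k matrix, labelled axes
#'   `PCoA1..PCoAk`), `eigenvalues` (all n, descending), `cailliez` (the
#'   constant applied, 0 if `correction = FALSE` or already Euclidean), and
#'   `corrected` (the dissimilarity matrix actually embedded).
#' @export
pcoa_embed <- function(d, correction = TRUE, tol = 1e-8) {
  m <- as_dist_matrix(d)
  cc <- 0
  if (correction) {
    cc <- cailliez_constant(m, tol = tol)
    if (cc > 0) {
      m <- m + cc
      diag(m) <- 0
    }
  }
  b <- double_center(m^2)
  e <- eigen(b, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  coords <- if (any(keep)) {
    fix_signs(e$vectors[, keep, drop = FALSE], labels) %*%
      diag(sqrt(e$values[keep]), sum(keep))
  } else {
    matrix(0, nrow(m), 0)
  }
  rownames(coords) <- rownames(m)
  if (ncol(coords) > 0) colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values, cailliez = cc,
       corrected = m)
}

#' Build the morpho-functional space of a species pool
#'
#' End-to-end construction of the functional space used by all downstream
#' indices: Gower dissimilarities among species, Cailliez correction, PCoA,
#' and trait vectors (per-trait Pearson correlations with the retained axes).
#' The space is built once from the full species pool and reused for every
#' year/transect, so assemblages through time are compared on fixed axes.
#' Species with identical trait combinations (one FE) occupy identical
#' coordinates.
#'
#' @param traits A trait table (validated).
#' @param axes Number of axes retained for index computation (default 2, the
#'   dimension on which hulls and trait-vector plots are drawn).
#' @param correction Apply the Cailliez correction (default `TRUE`).
#' @param tol Relative eigenvalue tolerance.
#' @return An object of class `functional_space`: a list with `coordinates`
#'   (tibble: species, fe_id, retained axes), `all_coordinates` (matrix over
#'   every positive axis, used for exact distance reconstruction),
#'   `eigenvalues`, `cailliez`, `axes`, `trait_vectors` (tibble), `distance`
#'   (uncorrected Gower [stats::dist]), and `traits`.
#' @seealso [tidy.functional_space()], [glance.functional_space()],
#'   [autoplot.functional_space()]
#' @export
functional_space <- function(traits, axes = 2, correction = TRUE, tol = 1e-8) {
  traits <- validate_trait_table(traits)
  if (axes < 1) stop("axes must be >= 1", call. = FALSE)
  d <- gower_distance(traits)
  emb <- pcoa_embed(d, correction = correction, tol = tol)
  k <- min(axes, ncol(emb$coordinates))
  coords <- emb$coordinates[, seq_len(k), drop = FALSE]
  memb <- fe_membership(traits)
  space <- structure(
    list(
      coordinates = dplyr::bind_cols(
        memb,
        tibble::as_tibble(coords)
      ),
      all_coordinates = emb$coordinates,
      eigenvalues = emb$eigenvalues,
      cailliez = emb$cailliez,
      axes = k,
      distance = d,
      corrected_distance = stats::as.dist(emb$corrected),
      traits = traits
    ),
    class = "functional_space"
  )
  space$trait_vectors <- trait_vectors(traits, space)
  space
}

#' Trait vectors on the functional axes
#'
#' Loading of each binary trait on each retained axis, computed as the
#' Pearson correlation between the trait column and the axis coordinates
#' across species. Traits with zero variance across the pool get a zero
#' vector with a warning.
#'
#' @param traits The trait table the space was built from.
#' @param space A [functional_space()] object.
#' @return A tibble with columns `trait` and one column per retained axis.
#' @export
trait_vectors <- function(traits, space) {
  traits <- validate_trait_table(traits)
  stopifnot(inherits(space, "functional_space"))
  ax <- axis_cols(space)
  coords <- as.matrix(space$coordinates[ax])
  canon <- coral_traits()
  tmat <- as.matrix(traits[canon])
  load <- matrix(0, length(canon), length(ax),
                 dimnames = list(canon, ax))
  zerovar <- apply(tmat, 2, stats::sd) == 0
  if (any(zerovar)) {
    warning("zero-variance trait(s), zero vector returned: ",
            paste(canon[zerovar], collapse = ", "), call. = FALSE)
  }
  for (t in canon[!zerovar]) {
    for (a in ax) {
      v <- stats::sd(coords[, a])
      load[t, a] <- if (v > 0) stats::cor(tmat[, t], coords[, a]) else 0
    }
  }
  dplyr::bind_cols(tibble::tibble(trait = canon),
                   tibble::as_tibble(load))
}

axis_cols <- function(space) {
  setdiff(names(space$coordinates), c("species", "fe_id"))
}

#' FE-level coordinates of a functional space
#'
#' One coordinate row per functional entity (members of an FE are coincident
#' by construction).
#'
#' @param space A [functional_space()] object.
#' @return A tibble with `fe_id` and the retained axis columns.
#' @export
fe_coordinates <- function(space) {
  stopifnot(inherits(space, "functional_space"))
  space$coordinates |>
    dplyr::group_by(.data$fe_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"species") |>
    dplyr::arrange(.data$fe_id)
}

#' @export
print.functional_space <- function(x, ...) {
  ev <- x$eigenvalues
  pos <- ev[ev > 0]
  cat("Morpho-functional space\n")
  cat("  species:", nrow(x$coordinates),
      " entities:", dplyr::n_distinct(x$coordinates$fe_id), "\n")
  cat("  retained axes:", x$axes,
      sprintf(" (%.1f%% of positive inertia)",
              100 * sum(ev[seq_len(x$axes)]) / sum(pos)), "\n")
  cat("  Cailliez constant:", format(x$cailliez, digits = 4), "\n")
  invisible(x)
}

#' Tidy a functional space into species coordinates
#'
#' @param x A [functional_space()] object.
#' @param ... Unused.
#' @return The coordinates tibble (species, fe_id, retained axes).
#' @export
tidy.functional_space <- function(x, ...) x$coordinates

#' One-row summary of a functional space
#'
#' @param x A [functional_space()] object.
#' @param ... Unused.
#' @return A tibble with species/entity counts, retained axes, the Cailliez
#'   constant and the proportion of positive inertia carried by the retained
#'   axes.
#' @export
glance.functional_space <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(
    n_species = nrow(x$coordinates),
    n_entities = dplyr::n_distinct(x$coordinates$fe_id),
    axes = x$axes,
    cailliez = x$cailliez,
    inertia_retained = sum(ev[seq_len(x$axes)]) / sum(ev[ev > 0])
  )
}
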