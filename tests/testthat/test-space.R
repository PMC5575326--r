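test_that("Gower distance is the trait mismatch proportion", {
  # extend the tiny pool so every trait has range (none dropped): the
  # denominator is then the full 8 traits
  tt <- dplyr::bind_rows(
    tiny_traits(),
    tibble::tibble(species = c("Acropora tbl", "Psammocora h"),
                   arborescent = 0, bushy = 0, table = c(1, 0),
                   foliose = 0, column = c(0, 1), massive = 0,
                   encrusting = 0, unattached = 0))
  d <- as.matrix(gower_distance(tt))
  # identical combos -> 0
  expect_equal(d["Porites d", "Favites e"], 0)
  # massive vs massive+unattached: 1 of 8 traits differs
  expect_equal(d["Porites d", "Fungia c"], 1 / 8)
  # arborescent-only vs massive+unattached: 3 of 8 differ
  expect_equal(d["Acropora a", "Fungia c"], 3 / 8)
  # complementary combos differ everywhere
  comp <- tibble::tibble(species = c("a", "b"),
                         arborescent = c(1, 0), bushy = c(1, 0),
                         table = c(1, 0), foliose = c(1, 0),
                         column = c(0, 1), massive = c(0, 1),
                         encrusting = c(0, 1), unattached = c(0, 1))
  expect_equal(max(as.matrix(gower_distance(comp))), 1)
  expect_error(gower_distance(tt[1, ]), "at least 2")
})

test_that("Gower matches vegan and satisfies metric properties", {
  skip_if_not_installed("vegan")
  for (seed in c(21, 22, 23)) {
    tt <- random_trait_table(25, seed)
    mat <- as.matrix(tt[coral_traits()])
    keep <- apply(mat, 2, function(x) diff(range(x)) > 0)
    d <- suppressWarnings(as.matrix(gower_distance(tt)))
    ref <- as.matrix(vegan::vegdist(mat[, keep, drop = FALSE],
                                    method = "gower"))
    expect_equal(unname(d), unname(ref), tolerance = 1e-12)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    # triangle inequality on a sample of triples
    idx <- utils::combn(8, 3)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]; l <- idx[3, k]
      expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-12)
    }
  }
})

test_that("zero-range traits are dropped with a warning", {
  tt <- tiny_traits()[3:5, ]  # nobody arborescent etc.
  expect_warning(gower_distance(tt), "zero range")
})

test_that("Cailliez constant is zero for Euclidean input and fixes the rest", {
  # collinear points are Euclidean already
  d_lin <- as.matrix(dist(c(0, 1, 3)))
  expect_equal(cailliez_constant(d_lin), 0)

  # classic non-Euclidean 4-point configuration
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 2] <- m[2, 1] <- 2  # violates the Euclidean embedding
  cc <- cailliez_constant(m)
  expect_gt(cc, 0)
  corrected <- m + cc
  diag(corrected) <- 0
  ev <- eigen(-0.5 * (diag(4) - 1 / 4) %*% corrected^2 %*% (diag(4) - 1 / 4),
              symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  # agrees with the base-R additive-constant routine
  ac <- stats::cmdscale(m, k = 2, add = TRUE)$ac
  expect_equal(cc, ac, tolerance = 1e-6)

  # adding the constant to a Euclidean matrix keeps it Euclidean
  d_eu <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  shifted <- d_eu + 0.5
  diag(shifted) <- 0
  expect_gt(cailliez_constant(shifted), -1e-12)
  expect_error(cailliez_constant(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA embeds a 3-4-5 triangle exactly", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 3
  m[1, 3] <- m[3, 1] <- 4
  m[2, 3] <- m[3, 2] <- 5
  emb <- pcoa_embed(m, correction = TRUE)
  expect_equal(emb$cailliez, 0)
  expect_equal(ncol(emb$coordinates), 2)
  rec <- as.matrix(dist(emb$coordinates))
  expect_equal(unname(rec), unname(m), tolerance = 1e-9)
})

test_that("PCoA axes and signs are deterministic and match ape", {
  skip_if_not_installed("ape")
  tt <- random_trait_table(20, seed = 31)
  d <- gower_distance(tt)
  emb <- pcoa_embed(d, correction = TRUE)
  ref <- ape::pcoa(d, correction = "cailliez")
  k <- min(4, ncol(emb$coordinates))
  refc <- ref$vectors.cor[, seq_len(k)]
  for (j in seq_len(k)) {
    expect_equal(abs(unname(emb$coordinates[, j])), abs(unname(refc[, j])),
                 tolerance = 1e-6)
  }
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(emb$coordinates))) {
    v <- emb$coordinates[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # rerun is bit-identical
  expect_identical(emb$coordinates, pcoa_embed(d, correction = TRUE)$coordinates)
})

test_that("full-rank round trip reconstructs corrected distances", {
  for (seed in c(41, 42)) {
    tt <- random_trait_table(30, seed)
    sp <- functional_space(tt)
    rec <- as.matrix(dist(sp$all_coordinates))
    target <- as.matrix(sp$corrected_distance)
    expect_lt(max(abs(rec - target)), 1e-8)
    ev <- sp$eigenvalues
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("functionally identical species are coincident in the space", {
  sp <- suppressWarnings(functional_space(tiny_traits()))
  co <- sp$coordinates
  axc <- setdiff(names(co), c("species", "fe_id"))
  a <- co[co$species == "Porites d", axc]
  b <- co[co$species == "Favites e", axc]
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
  expect_equal(nrow(fe_coordinates(sp)), 6)
})

test_that("trait vectors pick up the separating trait and ignore constants", {
  # two clusters separated purely by the massive trait
  tt <- tibble::tibble(
    species = sprintf("sp%02d", 1:10),
    arborescent = c(rep(1, 5), rep(0, 5)),
    bushy = 0, table = 0, foliose = 0, column = 0,
    massive = c(rep(0, 5), rep(1, 5)),
    encrusting = rep(c(0, 1), 5), unattached = 0
  )
  sp <- suppressWarnings(functional_space(tt))
  tv <- sp$trait_vectors
  expect_gt(abs(tv$PCoA1[tv$trait == "massive"]), 0.9)
  expect_lt(abs(tv$PCoA2[tv$trait == "massive"]), 0.3)
  # constant traits get zero vectors (and warned during construction)
  expect_equal(tv$PCoA1[tv$trait == "bushy"], 0)
  w <- capture_warnings(functional_space(tt))
  expect_true(any(grepl("zero", w)))
  # invariant to row order
  sp2 <- suppressWarnings(functional_space(tt[sample(10), ]))
  tv2 <- sp2$trait_vectors
  expect_equal(tv$PCoA1, tv2$PCoA1, tolerance = 1e-9)
})

test_that("tidy and glance expose coordinates and inertia", {
  sp <- suppressWarnings(functional_space(tiny_traits()))
  td <- tidy(sp)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("species", "fe_id", "PCoA1", "PCoA2") %in% names(td)))
  gl <- glance(sp)
  expect_equal(gl$n_species, 7)
  expect_equal(gl$n_entities, 6)
  expect_true(gl$inertia_retained > 0 && gl$inertia_retained <= 1)
})
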