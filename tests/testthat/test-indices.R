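test_that("relative abundances aggregate member cover and sum to one", {
  tt <- tiny_traits()
  cov <- tibble::tibble(year = 1981, transect = "t01",
                        `Acropora a` = 30, `Pocillopora b` = 10)
  w <- relative_abundances(cov, tt)
  expect_equal(sort(w$weight, decreasing = TRUE), c(0.75, 0.25))

  # two species of one FE (10, 10) plus one other (20) -> 0.5 / 0.5
  cov2 <- tibble::tibble(year = 1981, transect = "t01",
                         `Porites d` = 10, `Favites e` = 10,
                         `Acropora a` = 20)
  w2 <- relative_abundances(cov2, tt)
  expect_equal(nrow(w2), 2)
  expect_equal(unname(sort(w2$weight)), c(0.5, 0.5))

  # single species
  cov3 <- tibble::tibble(year = 1981, transect = "t01", `Porites d` = 7)
  expect_equal(relative_abundances(cov3, tt)$weight, 1)
  # zero-cover sample yields no rows
  cov4 <- tibble::tibble(year = 1981, transect = "t01", `Porites d` = 0)
  expect_equal(nrow(relative_abundances(cov4, tt)), 0)
})

test_that("CWM follows the full-membership convention", {
  tt <- tiny_traits()
  one <- tibble::tibble(year = 1, transect = "t1", `Porites d` = 40)
  cw <- cwm(one, tt)
  expect_equal(cw$cwm[cw$trait == "massive"], 100)
  expect_equal(sum(cw$cwm), 100)

  # equal covers of bushy-only and massive-only -> 50 / 50
  two <- tibble::tibble(year = 1, transect = "t1",
                        `Pocillopora b` = 10, `Porites d` = 10)
  cw2 <- cwm(two, tt)
  expect_equal(cw2$cwm[cw2$trait == "bushy"], 50)
  expect_equal(cw2$cwm[cw2$trait == "massive"], 50)

  # a dual-trait species contributes fully to both traits (sum > 100)
  fungiid <- tibble::tibble(year = 1, transect = "t1", `Fungia c` = 25)
  cw3 <- cwm(fungiid, tt)
  expect_equal(cw3$cwm[cw3$trait == "massive"], 100)
  expect_equal(cw3$cwm[cw3$trait == "unattached"], 100)
  expect_equal(sum(cw3$cwm), 200)
  cw3n <- cwm(fungiid, tt, normalize = TRUE)
  expect_equal(sum(cw3n$cwm), 100)
})

test_that("hull area matches the unit square and a fan-triangulation oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fd_fric(sq), 1)
  expect_true(is.na(fd_fric(rbind(c(0, 0), c(1, 1), c(2, 2)))))
  expect_true(is.na(fd_fric(rbind(c(0, 0), c(1, 1)))))

  for (seed in c(51, 52, 53, 54)) {
    set.seed(seed)
    pts <- matrix(rnorm(24), ncol = 2)  # 12 random points
    expect_equal(fd_fric(pts), fan_triangle_area(pts), tolerance = 1e-10)
  }
})

test_that("hull area is monotone under adding a point", {
  set.seed(61)
  for (rep in 1:10) {
    pts <- matrix(rnorm(16), ncol = 2)
    extra <- rbind(pts, rnorm(2))
    expect_gte(fd_fric(extra), fd_fric(pts) - 1e-12)
  }
})

test_that("FEve matches hand-computed MST examples", {
  # 3 equidistant points, equal weights -> perfect evenness
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(fd_feve(tri, rep(1 / 3, 3)), 1)

  # points at 0, 1, 3 on one axis, equal weights: PEW = (1/3, 2/3) -> 2/3
  line <- cbind(c(0, 1, 3), 0)
  expect_equal(fd_feve(line, rep(1 / 3, 3)), 2 / 3)

  expect_true(is.na(fd_feve(line[1:2, ], c(0.5, 0.5))))
})

test_that("the internal MST agrees with vegan on random point sets", {
  skip_if_not_installed("vegan")
  for (seed in c(71, 72, 73)) {
    set.seed(seed)
    pts <- matrix(rnorm(20), ncol = 2)
    dmat <- as.matrix(dist(pts))
    edges <- coralfd:::prim_mst(dmat)
    tot <- sum(dmat[edges])
    sp <- vegan::spantree(dist(pts))
    expect_equal(tot, sum(sp$dist), tolerance = 1e-10)
  }
})

test_that("FDiv is 1 on regular polygons and small for center-loaded mass", {
  # regular pentagon: all points equidistant from hull centroid
  ang <- 2 * pi * (0:4) / 5
  pent <- cbind(cos(ang), sin(ang))
  w <- c(0.4, 0.1, 0.2, 0.2, 0.1)
  expect_equal(fd_fdiv(pent, w), 1)

  # square corners plus a center point carrying all the weight
  sqc <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  w2 <- c(0, 0, 0, 0, 1)
  expect_lt(fd_fdiv(sqc, w2), 0.5)

  # concentrating weight on hull vertices raises divergence
  set.seed(81)
  pts <- matrix(runif(14), ncol = 2)
  h <- unique(grDevices::chull(pts))
  w_even <- rep(1 / nrow(pts), nrow(pts))
  w_vert <- rep(0.001, nrow(pts))
  w_vert[h] <- (1 - 0.001 * (nrow(pts) - length(h))) / length(h)
  expect_gt(fd_fdiv(pts, w_vert), fd_fdiv(pts, w_even))

  expect_true(is.na(fd_fdiv(cbind(c(0, 1, 2), 0), rep(1 / 3, 3))))
})

test_that("FDis matches closed forms and is translation invariant", {
  expect_equal(fd_fdis(matrix(c(2, 5), 1, 2), 1), 0)
  two <- rbind(c(0, 0), c(2, 0))
  expect_equal(fd_fdis(two, c(0.5, 0.5)), 1)
  set.seed(91)
  pts <- matrix(rnorm(12), ncol = 2)
  w <- runif(6); w <- w / sum(w)
  shifted <- sweep(pts, 2, c(3.2, -1.7), "+")
  expect_equal(fd_fdis(pts, w), fd_fdis(shifted, w), tolerance = 1e-12)
})

test_that("Rao Q matches arithmetic and a brute-force double loop", {
  d <- matrix(c(0, 0.375, 0.375, 0), 2, 2)
  expect_equal(rao_q(c(0.5, 0.5), d), 0.1875)
  expect_equal(rao_q(1, matrix(0, 1, 1)), 0)

  set.seed(101)
  tt <- random_trait_table(12, 101)
  dmat <- suppressWarnings(as.matrix(gower_distance(tt)))
  w <- runif(12); w <- w / sum(w)
  expect_equal(rao_q(w, dmat), rao_loop(w, dmat), tolerance = 1e-12)
  # equal weights = grand mean of the distance matrix
  we <- rep(1 / 12, 12)
  expect_equal(rao_q(we, dmat), mean(dmat))
})

test_that("per-sample indices respect support rules and invariances", {
  tt <- tiny_traits()
  cov <- tiny_cover()
  idx <- suppressWarnings(fd_indices(cov, tt))
  expect_equal(nrow(idx), 4)
  expect_true(all(idx$feve >= 0 & idx$feve <= 1, na.rm = TRUE))
  expect_true(all(idx$fdiv >= 0 & idx$fdiv <= 1, na.rm = TRUE))
  expect_true(all(idx$fric >= 0, na.rm = TRUE))
  expect_true(all(idx$rao_q >= 0))

  # uniform cover rescaling changes nothing
  cov10 <- cov
  spc <- setdiff(names(cov), c("year", "transect"))
  cov10[spc] <- cov[spc] * 10
  idx10 <- suppressWarnings(fd_indices(cov10, tt))
  expect_equal(idx$fric, idx10$fric)
  expect_equal(idx$rao_q, idx10$rao_q, tolerance = 1e-12)
  expect_equal(idx$fdis, idx10$fdis, tolerance = 1e-12)

  # splitting one species' cover across two functionally identical species
  # leaves every FE-level index and Q unchanged
  merged <- cov
  merged$`Porites d` <- cov$`Porites d` + cov$`Favites e`
  merged$`Favites e` <- 0
  idx_m <- suppressWarnings(fd_indices(merged, tt))
  expect_equal(idx$fric, idx_m$fric)
  expect_equal(idx$feve, idx_m$feve, tolerance = 1e-12)
  expect_equal(idx$fdiv, idx_m$fdiv, tolerance = 1e-12)
  expect_equal(idx$fdis, idx_m$fdis, tolerance = 1e-12)
  expect_equal(idx$rao_q, idx_m$rao_q, tolerance = 1e-12)

  # fewer than 3 singular FEs -> hull indices missing with reason
  low <- tibble::tibble(year = 1, transect = "t1",
                        `Porites d` = 5, `Fungia c` = 5)
  idx_low <- suppressWarnings(fd_indices(low, tt))
  expect_true(is.na(idx_low$fric))
  expect_identical(idx_low$missing_reason,
                   "insufficient functional singularity")
  expect_false(is.na(idx_low$rao_q))
})

test_that("monoculture gives Q = 0 and Q > 0 needs > 1 species", {
  tt <- tiny_traits()
  mono <- tibble::tibble(year = 1, transect = "t1", `Porites d` = 30)
  expect_equal(suppressWarnings(fd_indices(mono, tt))$rao_q, 0)
  duo <- tibble::tibble(year = 1, transect = "t1",
                        `Porites d` = 30, `Acropora a` = 1)
  expect_gt(suppressWarnings(fd_indices(duo, tt))$rao_q, 0)
})
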