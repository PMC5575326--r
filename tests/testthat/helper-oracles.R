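# independent geometry/statistics oracles used to cross-check the package

# gift-wrapping (Jarvis march) hull + fan-triangle areas; independent of the
# chull + shoelace route used in the package
jarvis_hull <- function(pts) {
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
  }
  hull
}

fan_triangle_area <- function(pts) {
  h <- jarvis_hull(pts)
  if (length(h) < 3) return(NA_real_)
  v <- pts[h, , drop = FALSE]
  a <- 0
  for (i in 2:(nrow(v) - 1)) {
    a <- a + abs(
      (v[i, 1] - v[1, 1]) * (v[i + 1, 2] - v[1, 2]) -
      (v[i, 2] - v[1, 2]) * (v[i + 1, 1] - v[1, 1])
    ) / 2
  }
  a
}

# brute-force Rao quadratic entropy: explicit double loop
rao_loop <- function(w, dmat) {
  q <- 0
  for (i in seq_along(w)) {
    for (j in seq_along(w)) {
      q <- q + w[i] * w[j] * dmat[i, j]
    }
  }
  q
}

# exact expectation of the over-redundancy index under the
# guarantee-one-then-uniform null, by enumerating multinomial outcomes
exact_null_for <- function(n_species, n_entities) {
  extra <- n_species - n_entities
  fr <- n_species / n_entities
  combos <- as.matrix(expand.grid(rep(list(0:extra), n_entities)))
  combos <- combos[rowSums(combos) == extra, , drop = FALSE]
  probs <- apply(combos, 1, function(k) {
    exp(lfactorial(extra) - sum(lfactorial(k)) -
        extra * log(n_entities))
  })
  fors <- apply(combos, 1, function(k) {
    n <- k + 1
    100 * sum(pmax(n - fr, 0)) / n_species
  })
  sum(probs * fors)
}
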