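# small hand-built trait table: 7 species, 6 entities (porites/favites share
# the massive combo; the fungiid is dual massive+unattached)
tiny_traits <- function() {
  tibble::tribble(
    ~species,       ~arborescent, ~bushy, ~table, ~foliose, ~column, ~massive, ~encrusting, ~unattached,
    "Acropora a",   1, 0, 0, 0, 0, 0, 0, 0,
    "Pocillopora b", 0, 1, 0, 0, 0, 0, 0, 0,
    "Fungia c",     0, 0, 0, 0, 0, 1, 0, 1,
    "Porites d",    0, 0, 0, 0, 0, 1, 0, 0,
    "Favites e",    0, 0, 0, 0, 0, 1, 0, 0,
    "Montipora f",  0, 0, 0, 0, 0, 0, 1, 0,
    "Turbinaria g", 0, 0, 0, 1, 0, 0, 0, 0
  )
}

tiny_cover <- function() {
  tibble::tibble(
    year = c(1981, 1981, 1983, 1983),
    transect = c("t01", "t02", "t01", "t02"),
    `Acropora a` = c(30, 25, 0, 0),
    `Pocillopora b` = c(10, 12, 0, 0.5),
    `Fungia c` = c(5, 0, 8, 6),
    `Porites d` = c(10, 10, 20, 22),
    `Favites e` = c(2, 3, 4, 5),
    `Montipora f` = c(1, 2, 3, 2),
    `Turbinaria g` = c(4, 4, 4, 4)
  )
}

# random binary trait table with every row nonempty
random_trait_table <- function(n_species, seed) {
  set.seed(seed)
  canon <- coral_traits()
  mat <- matrix(rbinom(n_species * 8, 1, 0.3), n_species, 8,
                dimnames = list(NULL, canon))
  empty <- rowSums(mat) == 0
  mat[cbind(which(empty), sample(8, sum(empty), replace = TRUE))] <- 1L
  dplyr::bind_cols(
    tibble::tibble(species = sprintf("sp%03d", seq_len(n_species))),
    tibble::as_tibble(as.data.frame(mat))
  )
}
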