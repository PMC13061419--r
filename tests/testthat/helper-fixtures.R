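# In-code fixtures shared across test files.

# tiny dense-count dataset with explicit metadata
toy_dataset <- function(counts = NULL, cell_type = NULL, species = "toy",
                        clone = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(5L, 0L, 2L,
                       1L, 3L, 0L), nrow = 3,
                     dimnames = list(c("MT-g1", "g2", "g3"), c("c1", "c2")))
  }
  ann <- tibble::tibble(cell_id = colnames(counts))
  if (!is.null(cell_type)) ann$cell_type <- cell_type
  if (!is.null(clone)) ann$clone <- clone
  species_dataset(Matrix::Matrix(counts, sparse = TRUE), ann, species = species)
}

# dataset of two well-separated expression groups for classifier tests
two_group_dataset <- function(n_per = 30, n_genes = 60, shift = 3,
                              species = "toy", seed = 1) {
  set.seed(seed)
  mu <- matrix(exp(rnorm(n_genes)), n_genes, 2)
  mu[1:10, 1] <- mu[1:10, 1] * exp(shift)
  mu[11:20, 2] <- mu[11:20, 2] * exp(shift)
  grp <- rep(c("A", "B"), each = n_per)
  counts <- sapply(seq_along(grp), function(i) {
    rnbinom(n_genes, size = 2, mu = mu[, match(grp[i], c("A", "B"))] * 5)
  })
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("c%03d", seq_along(grp)))
  ds <- toy_dataset(counts, cell_type = grp, species = species)
  lognormalize(ds)
}

# small multi-species simulation used by several integration tests
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_genes = 300, n_cells_per_species = 280, seed = seed, ...)
  simulate_experiment(cfg)
}

# adjusted Rand index (independent implementation for recovery checks)
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# deterministic two-species fixture with known reciprocal fractions:
# HRC A (species R) = 8 "u" cells + 2 "y" cells; HRC B (species T) =
# 6 "u" cells + 4 "z" cells. Training on R sends 6/10 of B to A; training
# on T sends 8/10 of A to B; averaged similarity(A, B) = 0.7.
recip_fixture <- function() {
  u <- 1:20; z <- 20:1
  y <- as.vector(rbind(20:11, 1:10))  # far from both u and z in rank space
  mk <- function(cols, ids, species, hrc) {
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(sprintf("g%02d", 1:20), ids)
    ds <- toy_dataset(counts, species = species)
    ds$annotation$hrc <- hrc
    lognormalize(ds)
  }
  R <- mk(c(replicate(8, u, simplify = FALSE), replicate(2, y, simplify = FALSE),
            replicate(10, z, simplify = FALSE)),
          sprintf("r%02d", 1:20), "R", rep(c("R_A", "R_Z"), each = 10))
  T_ <- mk(c(replicate(6, u, simplify = FALSE), replicate(4, z, simplify = FALSE),
             replicate(10, y, simplify = FALSE)),
           sprintf("t%02d", 1:20), "T", rep(c("T_B", "T_Y"), each = 10))
  list(R = R, T = T_)
}

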