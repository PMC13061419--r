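test_that("reciprocal similarity averages directional fractions (0.7 toy)", {
  fx <- recip_fixture()
  sm <- reciprocal_similarity(fx, seed = 1)
  expect_equal(sm$values["R_A", "T_B"], 0.7)
  expect_equal(sm$values["T_B", "R_A"], 0.7)
})

test_that("matched and unmatched HRC pairs score 1 and 0", {
  u <- 1:20; z <- 20:1
  mk <- function(species, ids) {
    counts <- cbind(matrix(rep(u, 10), 20), matrix(rep(z, 10), 20))
    dimnames(counts) <- list(sprintf("g%02d", 1:20), ids)
    ds <- toy_dataset(counts, species = species)
    ds$annotation$hrc <- rep(paste0(species, c("_U", "_Z")), each = 10)
    lognormalize(ds)
  }
  fx <- list(mk("R", sprintf("r%02d", 1:20)), mk("T", sprintf("t%02d", 1:20)))
  sm <- reciprocal_similarity(fx, seed = 1)
  expect_equal(sm$values["R_U", "T_U"], 1)
  expect_equal(sm$values["R_Z", "T_Z"], 1)
  expect_equal(sm$values["R_U", "T_Z"], 0)
  expect_equal(sm$values["R_Z", "T_U"], 0)
})

test_that("similarity matrix is symmetric, bounded, with rows of directional fractions summing to 1", {
  sim <- small_sim(seed = 11, cell_types = paste0("ct", 1:3))
  ds <- lapply(sim$datasets, function(d) {
    d <- lognormalize(d)
    d$annotation$hrc <- paste(d$species, d$annotation$cell_type, sep = "_")
    d
  })
  sm <- reciprocal_similarity(ds, seed = 2)
  expect_equal(sm$values, t(sm$values))
  expect_true(all(sm$values >= 0 & sm$values <= 1))
  sums <- sm$directional |>
    dplyr::group_by(target, direction) |>
    dplyr::summarise(s = sum(fraction), n = dplyr::first(n_target),
                     .groups = "drop")
  expect_true(all(abs(sums$s[sums$n > 0] - 1) < 1e-9))
})

test_that("perfect reciprocal best-hits score exactly 1", {
  sim <- small_sim(seed = 12, divergence_sigma = 0, switch_rate = 0,
                   cell_types = paste0("ct", 1:3))
  ds <- lapply(sim$datasets[1:2], function(d) {
    d <- lognormalize(d)
    d$annotation$hrc <- paste(d$species, d$annotation$cell_type, sep = "_")
    d
  })
  sm <- reciprocal_similarity(ds, seed = 3)
  for (ct in paste0("ct", 1:3)) {
    expect_equal(sm$values[paste0("human_", ct), paste0("orangutan_", ct)], 1)
  }
})

test_that("hierarchical OCC assignment matches a brute-force average-linkage oracle", {
  set.seed(20)
  n <- 5
  v <- matrix(runif(n * n), n)
  v <- (v + t(v)) / 2; diag(v) <- 1
  ids <- paste0("h", 1:n)
  dimnames(v) <- list(ids, ids)
  sm <- structure(list(values = v,
                       hrc_info = tibble::tibble(
                         species = "s", hrc = ids, n_cells = 10),
                       directional = NULL), class = "similarity_matrix")
  occ <- assign_occ(sm, n_occ = 2)
  # brute-force average linkage on 1 - v
  d <- 1 - v
  clusters <- as.list(ids)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    if (length(clusters) == 2) brute_2groups <- clusters
  }
  expect_equal(occ$hclust$height, heights, tolerance = 1e-12)
  grp <- split(occ$mapping$hrc, occ$mapping$occ)
  expect_true(setequal(lapply(grp, sort), lapply(brute_2groups, sort)))
})

test_that("block-diagonal similarity recovers planted groups exactly", {
  ids <- c("s1_a", "s2_a", "s3_a", "s1_b", "s2_b", "s1_c")
  groups <- c(1, 1, 1, 2, 2, 3)
  v <- outer(groups, groups, "==") * 1
  dimnames(v) <- list(ids, ids)
  sm <- structure(list(values = v,
                       hrc_info = tibble::tibble(
                         species = sub("_.*", "", ids), hrc = ids,
                         n_cells = c(5, 6, 7, 8, 9, 10))),
                  class = "similarity_matrix")
  occ <- assign_occ(sm, n_occ = 3)
  expect_equal(length(unique(occ$mapping$occ)), 3)
  expect_equal(ari(occ$mapping$occ, groups), 1)
  expect_equal(sum(occ$occ_info$n_cells), 45)
})

test_that("pseudobulk merging follows the cross-species mean rho decision", {
  # two species, three OCCs; occ1/occ2 identical profiles -> distance 0,
  # occ3 anti-correlated -> distance 2
  mkds <- function(sp, seed) {
    set.seed(seed)
    base <- matrix(rpois(30 * 30, 10), 30, 30,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("%s%02d", sp, 1:30)))
    base[, 21:30] <- matrix(rep(sort(rpois(30, 10), decreasing = TRUE), 10), 30)
    ds <- toy_dataset(base, species = sp)
    ds$annotation$hrc <- rep(c("h1", "h2", "h3"), each = 10)
    ds$annotation$hrc <- paste(sp, ds$annotation$hrc, sep = "_")
    lognormalize(ds)
  }
  d1 <- mkds("sp1", 1); d2 <- mkds("sp2", 2)
  # force occ1 == occ2 profiles: cells 1:10 and 11:20 drawn from same Poisson
  mapping <- tibble::tibble(
    species = rep(c("sp1", "sp2"), each = 3),
    hrc = c("sp1_h1", "sp1_h2", "sp1_h3", "sp2_h1", "sp2_h2", "sp2_h3"),
    n_cells = 10,
    occ = rep(c("OCC01", "OCC02", "OCC03"), 2))
  occ <- structure(list(mapping = mapping,
                        occ_info = orthocell:::occ_summary(mapping),
                        provenance = list()), class = "occ_assignment")
  merged <- merge_occ_pseudobulk(list(d1, d2), occ, n_hvg = 30,
                                 cut_height = 0.1)
  # expected rho-bar from first principles
  pb <- function(d, idx) Matrix::rowMeans(d$lognorm[, idx])
  rb12 <- mean(c(cor(pb(d1, 1:10), pb(d1, 11:20), method = "spearman"),
                 cor(pb(d2, 1:10), pb(d2, 11:20), method = "spearman")))
  if (1 - rb12 < 0.1) {
    expect_equal(merged$mapping$occ[merged$mapping$hrc == "sp1_h1"],
                 merged$mapping$occ[merged$mapping$hrc == "sp1_h2"])
  }
  # the reversed-profile OCC03 never merges into OCC01
  expect_false(merged$mapping$occ[merged$mapping$hrc == "sp1_h3"] ==
                 merged$mapping$occ[merged$mapping$hrc == "sp1_h1"])
})

test_that("OCC filtering needs both small size and species restriction", {
  mapping <- tibble::tibble(
    species = c("s1", "s2", "s1", "s2", "s3", "s1"),
    hrc = paste0("h", 1:6),
    n_cells = c(400, 399, 400, 200, 199, 800),
    occ = c("OCC01", "OCC01", "OCC02", "OCC02", "OCC02", "OCC03"))
  occ <- structure(list(mapping = mapping,
                        occ_info = orthocell:::occ_summary(mapping),
                        provenance = list()), class = "occ_assignment")
  out <- filter_occ(occ)  # defaults 800 / 3
  st <- setNames(out$occ_info$status, out$occ_info$occ)
  expect_equal(st[["OCC01"]], "excluded")   # 799 cells, 2 species
  expect_equal(st[["OCC02"]], "retained")   # 799 cells but 3 species
  expect_equal(st[["OCC03"]], "retained")   # 800 cells exactly (not < 800)
})

test_that("splitting an OCC conserves cells and can be undone", {
  mapping <- tibble::tibble(
    species = c("s1", "s1", "s2"),
    hrc = c("h1", "h2", "h3"),
    n_cells = c(10, 20, 30),
    occ = "OCC01")
  occ <- structure(list(mapping = mapping,
                        occ_info = orthocell:::occ_summary(mapping),
                        provenance = list()), class = "occ_assignment")
  sp <- split_occ(occ, "OCC01", c(h1 = "ipsc", h2 = "cardiac", h3 = "ipsc"))
  expect_equal(sum(sp$occ_info$n_cells), 60)
  expect_equal(nrow(sp$occ_info), 2)
  expect_error(split_occ(occ, "OCC01", c(h1 = "x")), "does not cover")
  # re-merging via a trivial split restores membership
  back <- split_occ(sp, "OCC01:ipsc", c(h1 = "u", h3 = "u"))
  expect_equal(sum(back$occ_info$n_cells), 60)
  expect_equal(length(sp$provenance$splits), 1)
})

test_that("HRC clustering is seeded, deterministic and over-splits cell types", {
  sim <- small_sim(seed = 13)
  d <- lognormalize(sim$datasets$human)
  c1 <- cluster_hrc(d, seed = 42)
  c2 <- cluster_hrc(d, seed = 42)
  expect_identical(c1$annotation$hrc, c2$annotation$hrc)
  # two separated types -> near-pure clusters
  tab <- table(c1$annotation$hrc, c1$annotation$cell_type)
  purity <- apply(tab, 1, max) / rowSums(tab)
  expect_gte(median(purity), 0.99)
  expect_error(cluster_hrc(subset_cells(d, d$annotation$cell_id[1:10]),
                           k = 20), "fewer cells than k")
})
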