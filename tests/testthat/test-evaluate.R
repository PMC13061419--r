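# direct term-by-term RBO summation used as the oracle
rbo_brute <- function(a, b, p = 0.9, depth = 100, extrapolate = TRUE) {
  depth <- min(depth, max(length(a), length(b)))
  s <- 0
  ad <- 0
  for (d in seq_len(depth)) {
    ad <- length(intersect(head(a, d), head(b, d))) / d
    s <- s + (1 - p) * p^(d - 1) * ad
  }
  if (extrapolate) s <- s + ad * p^depth
  s
}

test_that("rbo equals brute-force summation and honors its bounds", {
  set.seed(51)
  pool <- sprintf("g%03d", 1:200)
  for (r in 1:20) {
    la <- sample(pool, sample(5:100, 1))
    lb <- sample(pool, sample(5:100, 1))
    expect_equal(rbo(la, lb), rbo_brute(la, lb), tolerance = 1e-12)
  }
  x <- sample(pool, 50)
  expect_equal(rbo(x, x), 1, tolerance = 1e-12)
  expect_equal(rbo(pool[1:40], pool[51:90]), 0)
  expect_equal(rbo(x, x, extrapolate = FALSE),
               rbo_brute(x, x, extrapolate = FALSE), tolerance = 1e-12)
  expect_error(rbo(x, x, p = 1.2), "in \\(0, 1\\)")
  expect_error(rbo(c("a", "a"), c("a", "b")), "duplicates")
})

test_that("rbo is symmetric and decreases along a scramble ladder", {
  set.seed(52)
  x <- sprintf("g%03d", 1:60)
  y <- sample(x)
  expect_equal(rbo(x, y), rbo(y, x), tolerance = 1e-12)
  # progressively scramble a longer suffix; the common prefix shrinks
  scores <- sapply(c(0, 15, 30, 45, 60), function(k) {
    z <- x
    if (k > 0) z[(60 - k + 1):60] <- sample(x[(60 - k + 1):60])
    rbo(x, z)
  })
  expect_false(is.unsorted(rev(scores)))
})

test_that("top-k intersection patterns match exhaustive enumeration", {
  lists <- list(a = c("g1", "g2", "g3", "g4", "g5", "g6"),
                b = c("g1", "g2", "g7", "g8", "g9", "g10"),
                c = c("g1", "g11", "g12", "g2", "g13", "g14"),
                d = c("g15", "g16", "g17", "g18", "g19", "g20"))
  out <- topk_intersections(lists, k = 6)
  got <- setNames(out$count, out$pattern)
  expect_equal(got[["a&b&c"]], 2)   # g1, g2
  expect_equal(got[["a"]], 4)       # g3..g6
  expect_equal(got[["d"]], 6)
  expect_equal(sum(out$count), length(unique(unlist(lists))))
  # identical lists: only the all-species pattern
  same <- topk_intersections(list(x = lists$a, y = lists$a, z = lists$a), k = 6)
  expect_identical(same$pattern, "x&y&z")
  expect_equal(same$count, 6)
  # pairwise-disjoint lists: only singleton patterns
  dis <- topk_intersections(list(u = c("g1", "g2"), v = c("g3", "g4")), k = 2)
  expect_true(all(dis$n_lists == 1))
})

test_that("biotype subsetting preserves order and handles gaps", {
  ranked <- c("g3", "g1", "g5", "g2", "g4")
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    biotype = c("protein_coding", "lncRNA",
                                "protein_coding", "protein_coding"))
  expect_identical(subset_by_biotype(ranked, tab, subset = "all"), ranked)
  expect_message(
    pc <- subset_by_biotype(ranked, tab, subset = "protein_coding"),
    "1 genes absent")
  expect_identical(pc, c("g3", "g1", "g4"))
  expect_identical(subset_by_biotype(ranked, tab, subset = "lncRNA"), "g2")
  expect_identical(subset_by_biotype(ranked, tf_set = character(0),
                                     subset = "TF"), character(0))
  expect_identical(subset_by_biotype(ranked, tf_set = c("g5", "g2"),
                                     subset = "TF"), c("g5", "g2"))
})

test_that("F1 scores match closed forms and counting", {
  perfect <- f1_scores(c("a", "b", "a"), c("a", "b", "a"))
  expect_true(all(perfect$per_class == 1) && perfect$macro == 1)
  # constant prediction in a balanced 2-class problem: 2/3 and 0
  const <- f1_scores(rep(c("a", "b"), 10), rep("a", 20))
  expect_equal(unname(const$per_class["a"]), 2 / 3)
  expect_equal(unname(const$per_class["b"]), 0)
  expect_equal(const$macro, 1 / 3)
  # random confusion vs brute-force counting
  set.seed(53)
  tr <- sample(letters[1:3], 60, replace = TRUE)
  pr <- sample(letters[1:3], 60, replace = TRUE)
  out <- f1_scores(tr, pr)
  for (cl in letters[1:3]) {
    tp <- sum(tr == cl & pr == cl)
    fp <- sum(tr != cl & pr == cl); fn <- sum(tr == cl & pr != cl)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(unname(out$per_class[cl]), f1)
  }
  # relabeling invariance of the macro average
  map <- c(a = "z", b = "y", c = "x")
  out2 <- f1_scores(map[tr], map[pr])
  expect_equal(out2$macro, out$macro)
  expect_error(f1_scores(tr, rep("q", 60)), "vocabulary")
})

test_that("kNN prediction agrees with class::knn away from ties", {
  skip_if_not_installed("class")
  set.seed(54)
  train_x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
  train_y <- rep(c("a", "b"), each = 30)
  test_x <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 4), 15))
  mine <- orthocell:::knn_predict(train_x, train_y, test_x, k = 3)
  ref <- as.character(class::knn(train_x, test_x, train_y, k = 3))
  expect_identical(unname(mine), ref)
})

test_that("kNN marker evaluation is exact on separable data and bounds its CIs", {
  sim <- small_sim(seed = 55, divergence_sigma = 0, switch_rate = 0,
                   cell_types = paste0("ct", 1:4))
  ds <- lapply(sim$datasets[1:2], lognormalize)
  marker_lists <- lapply(setNames(paste0("ct", 1:4), paste0("ct", 1:4)),
                         function(ct) planted_marker_panel(
                           sim$truth, ct, "human")$gene)
  f1c <- knn_marker_eval(ds$human, list(self = ds$human,
                                        other = ds$orangutan),
                         marker_lists, m_range = c(1, 5), n_boot = 30,
                         seed = 1)
  mac <- dplyr::filter(f1c, cell_type == "macro")
  expect_true(all(mac$f1[mac$test == "self"] == 1))
  expect_true(all(f1c$ci_lo <= f1c$f1 + 1e-12 & f1c$f1 <= f1c$ci_hi + 1e-12))
})

test_that("bootstrap intervals tighten with more test cells", {
  width_at <- function(n_per) {
    cfg <- sim_config(n_genes = 200, cell_types = c("a", "b"),
                      cells_per_type = c(a = n_per, b = n_per),
                      divergence_sigma = 0.6, switch_rate = 0, seed = 56)
    sim <- simulate_experiment(cfg)
    ds <- lapply(sim$datasets[1:2], lognormalize)
    ml <- lapply(setNames(c("a", "b"), c("a", "b")), function(ct)
      planted_marker_panel(sim$truth, ct, "human")$gene)
    f1c <- knn_marker_eval(ds$human, list(t = ds$orangutan), ml,
                           m_range = 3, n_boot = 100, seed = 2)
    mac <- dplyr::filter(f1c, cell_type == "macro")
    mac$ci_hi - mac$ci_lo
  }
  expect_lte(width_at(150), width_at(25) + 1e-9)
})
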