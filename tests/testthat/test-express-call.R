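test_that("gene filter applies the per-clone 1% nonzero rule", {
  set.seed(1)
  n <- 300
  counts <- matrix(0L, 3, n, dimnames = list(c("g1", "g2", "g3"),
                                             sprintf("c%03d", 1:n)))
  counts[1, 1:2] <- 1L            # 2/300 = 0.67% in the single clone
  counts[2, 1:3] <- 1L            # 3/300 = 1%
  counts[3, ] <- 5L
  ds <- toy_dataset(counts, cell_type = rep("t1", n))
  out <- filter_for_calling(ds)
  expect_setequal(rownames(out$counts), c("g2", "g3"))
})

test_that("MAD cell filter drops exactly the planted outlier and tolerates MAD = 0", {
  n <- 30
  counts <- matrix(5L, 50, n, dimnames = list(sprintf("g%02d", 1:50),
                                              sprintf("c%02d", 1:n)))
  counts[, 30] <- 500L  # one extreme-depth cell
  ds <- toy_dataset(counts, cell_type = rep("t1", n))
  # hand check: all others share median depth, MAD = 0 band keeps them
  out <- filter_for_calling(ds, min_nonzero_frac = 0)
  expect_setequal(out$annotation$cell_id, sprintf("c%02d", 1:29))
  # small stratum: filter skipped with a warning
  ds2 <- toy_dataset(counts[, 1:4], cell_type = rep("t2", 4))
  expect_warning(out2 <- filter_for_calling(ds2, min_nonzero_frac = 0),
                 "MAD filter skipped")
  expect_equal(ncol(out2$counts), 4)
})

test_that("downsampling preserves proportions by largest remainder", {
  # proportions 50/30/20 at n = 10 -> 5/3/2
  n <- 100
  ct <- rep(c("a", "b", "c"), times = c(50, 30, 20))
  counts <- matrix(1L, 5, n, dimnames = list(paste0("g", 1:5),
                                             sprintf("c%03d", 1:n)))
  ds <- toy_dataset(counts, cell_type = ct)
  out <- downsample_equal(list(x = ds), n_per_species = 10, seed = 1)
  tab <- table(out$x$annotation$cell_type)
  expect_equal(as.numeric(tab[c("a", "b", "c")]), c(5, 3, 2))
  # determinism
  out2 <- downsample_equal(list(x = ds), n_per_species = 10, seed = 1)
  expect_identical(out$x$annotation$cell_id, out2$x$annotation$cell_id)
})

test_that("NB statistics recover simulated parameters and match glm.nb", {
  set.seed(2)
  ncell <- 2000
  counts <- matrix(rnbinom(2 * ncell, size = 1, mu = 2), 2, ncell,
                   dimnames = list(c("g1", "g2"), sprintf("c%04d", 1:ncell)))
  ct <- rep(c("A", "B"), each = ncell / 2)
  ds <- toy_dataset(counts, cell_type = ct)
  st <- fit_gene_stats(ds, offset = "none")
  g1 <- st[st$gene == "g1", ]
  expect_true(all(abs(g1$mu - 2) <= 3 * g1$se_mu))
  expect_true(g1$theta[1] > 0.7 && g1$theta[1] < 1.4)
  # independent route: MASS::glm.nb on the same gene
  m <- MASS::glm.nb(counts[1, ] ~ 0 + factor(ct))
  expect_equal(sort(g1$mu), sort(unname(exp(coef(m)))), tolerance = 1e-4)
  expect_equal(g1$theta[1], m$theta, tolerance = 1e-4)
  # detection fraction is simple counting
  expect_equal(g1$f[g1$cell_type == "A"], mean(counts[1, ct == "A"] > 0))
})

test_that("all-zero genes get mu 0, infinite s.e. and status 0", {
  counts <- matrix(c(0L, 3L), 2, 10, byrow = FALSE,
                   dimnames = list(c("gz", "g2"), sprintf("c%02d", 1:10)))
  counts["gz", ] <- 0L
  ds <- toy_dataset(counts, cell_type = rep(c("A", "B"), 5))
  st <- putative_status(fit_gene_stats(ds, offset = "none"))
  gz <- st[st$gene == "gz", ]
  expect_equal(gz$mu, c(0, 0))
  expect_true(all(!is.finite(gz$se_mu)))
  expect_equal(gz$status, c(0L, 0L))
})

test_that("hand-built count vector gives the counted detection fraction", {
  y <- c(0L, 0L, 0L, 0L, 1L, 2L, 3L, 4L, 5L, 6L)
  counts <- rbind(gx = y, filler = 1L)
  colnames(counts) <- sprintf("c%02d", 1:10)
  ds <- toy_dataset(counts, cell_type = rep("t", 10))
  st <- fit_gene_stats(ds, offset = "none")
  expect_equal(st$f[st$gene == "gx"], 0.6)
})

test_that("putative status matches a brute-force quantile computation", {
  set.seed(3)
  n <- 100
  st <- tibble::tibble(
    gene = sprintf("g%03d", 1:n), cell_type = "t1", species = "s",
    f = runif(n), mu = exp(rnorm(n)), se_mu = exp(rnorm(n, -1)), theta = 1)
  out <- putative_status(st, detect_q = 0.05, reliable_q = 0.90)
  q_lo <- quantile(log(st$mu), 0.05, type = 7)
  q_hi <- quantile(log(st$se_mu / st$mu), 0.90, type = 7)
  brute <- as.integer(log(st$mu) > q_lo & log(st$se_mu / st$mu) < q_hi)
  expect_identical(out$status, brute)
  # extremes behave as stated
  top <- which.max(st$mu / st$se_mu * st$mu)
  expect_equal(out$status[which(log(st$mu) < q_lo)[1]], 0L)
})

test_that("Firth fit matches a generic-optimizer maximization and stays finite", {
  set.seed(4)
  pen_nll <- function(b, x, y) {
    X <- cbind(1, x); eta <- drop(X %*% b); p <- plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    -(sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))) +
        0.5 * determinant(crossprod(X, X * W))$modulus)
  }
  for (r in 1:5) {
    x <- rnorm(50)
    y <- rbinom(50, 1, plogis(-0.5 + 2 * x))
    fit <- firth_logistic(y, x)
    o <- optim(c(0, 0), pen_nll, x = x, y = y, method = "BFGS",
               control = list(reltol = 1e-14))
    expect_lt(max(abs(c(fit$a, fit$b) - o$par)), 1e-4)
  }
  # complete separation still yields finite estimates
  xs <- c(-2, -1, -0.5, 0.5, 1, 2); ys <- c(0, 0, 0, 1, 1, 1)
  fs <- firth_logistic(ys, xs)
  expect_true(is.finite(fs$a) && is.finite(fs$b))
  # (y, x) -> (1 - y, -x) flips the intercept sign, keeps the slope
  f2 <- firth_logistic(1 - ys, -xs)
  expect_equal(fs$a, -f2$a, tolerance = 1e-8)
  expect_equal(fs$b, f2$b, tolerance = 1e-8)
  expect_error(firth_logistic(c(0, 1), c(1, 1)), "constant")
})

test_that("tidy and glance summarize Firth fits", {
  fit <- firth_logistic(c(0, 1, 0, 1), c(-1, 2, 0.5, 1))
  td <- generics::tidy(fit)
  expect_equal(td$estimate, c(fit$a, fit$b))
  expect_true(generics::glance(fit)$converged)
})

test_that("detection thresholds solve the fitted curve and harmonize by max", {
  # closed forms: a = 0 -> f* = 0 (clipped into (0,1)); a = -3, b = 10 -> 0.3
  set.seed(5)
  n <- 500
  f <- runif(n)
  status <- rbinom(n, 1, plogis(-4 + 16 * f))
  st <- tibble::tibble(gene = sprintf("g%03d", 1:n), cell_type = "t1",
                       species = "s1", f = f, mu = 1, se_mu = 0.1,
                       theta = 1, status = status)
  st2 <- st; st2$species <- "s2"
  set.seed(6)
  st2$status <- rbinom(n, 1, plogis(-6 + 16 * st2$f))  # higher threshold
  thr <- fit_detection_threshold(dplyr::bind_rows(st, st2))
  t1 <- thr$per_species$threshold[thr$per_species$species == "s1"]
  t2 <- thr$per_species$threshold[thr$per_species$species == "s2"]
  # generating curve s1 crosses 0.5 at 4/16 = 0.25
  expect_lt(abs(t1 - 0.25), 0.03)
  expect_equal(thr$harmonized$threshold, max(t1, t2))
  expect_true(all(thr$harmonized$threshold >= thr$per_species$threshold))
})

test_that("thresholds reject detection decreasing in f", {
  st <- tibble::tibble(gene = paste0("g", 1:50), cell_type = "t1",
                       species = "s1", f = seq(0, 1, length.out = 50),
                       mu = 1, se_mu = 0.1, theta = 1,
                       status = rep(c(1L, 0L), each = 25))
  expect_error(fit_detection_threshold(st), "not increasing")
})

test_that("expression calls use the inclusive boundary", {
  thr <- structure(list(
    per_species = tibble::tibble(species = "s", cell_type = c("t1", "t2"),
                                 a = -3, b = 10, converged = TRUE,
                                 threshold = c(0.3, 0.5)),
    harmonized = tibble::tibble(cell_type = c("t1", "t2"),
                                threshold = c(0.3, 0.5))),
    class = "threshold_table")
  st <- tidyr::expand_grid(gene = c("g1", "g2", "g3"),
                           cell_type = c("t1", "t2"), species = "s") |>
    dplyr::mutate(f = c(0.3, 0.5, 0, 0, 0.31, 0.49))
  calls <- call_expressed(st, thr)
  got <- setNames(calls$call, paste(calls$gene, calls$cell_type))
  expect_equal(got[["g1 t1"]], 1L)  # exactly at threshold -> expressed
  expect_equal(got[["g1 t2"]], 1L)
  expect_equal(got[["g2 t1"]], 0L)  # f = 0 under positive threshold
  expect_equal(got[["g3 t1"]], 1L)
  expect_equal(got[["g3 t2"]], 0L)  # 0.49 < 0.5
  # monotonicity: raising f never drops a call
  raised <- st |> dplyr::mutate(f = pmin(f + 0.2, 1))
  calls2 <- call_expressed(raised, thr)
  expect_true(all(calls2$call >= calls$call))
})

test_that("calls on simulated data agree with planted truth", {
  sim <- small_sim(seed = 21)
  ds <- lapply(sim$datasets, lognormalize)
  called <- lapply(ds, filter_for_calling)
  suppressMessages(called <- downsample_equal(called, 18800, seed = 21))
  st <- putative_status(dplyr::bind_rows(lapply(called, fit_gene_stats)))
  thr <- fit_detection_threshold(st)
  calls <- call_expressed(st, thr)
  tr <- sim$truth$status
  agree <- mapply(function(g, ct, sp, cl) tr[g, ct, sp] == cl,
                  calls$gene, calls$cell_type, calls$species, calls$call)
  expect_gte(mean(agree), 0.9)
})
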