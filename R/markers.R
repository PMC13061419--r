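#' Restrict datasets for marker testing
#'
#' Keeps only cells of the shared cell types, drops genes with zero counts
#' everywhere within them, and downsamples every species to the minimum
#' remaining cell number (preserving cell type proportions by largest
#' remainder). A shared type absent from a species is reported and simply
#' excluded from that species' tests.
#'
#' @param datasets named list of [species_dataset()] with `cell_type` labels
#' @param shared_types character vector of shared cell type labels
#' @param seed sampling seed
#' @return the restricted datasets
#' @export
prepare_marker_input <- function(datasets, shared_types, seed = 1L) {
  check_shared_genes(datasets)
  datasets <- lapply(datasets, function(d) {
    absent <- setdiff(shared_types, unique(d$annotation$cell_type))
    if (length(absent)) {
      message(d$species, ": shared types absent, excluded from tests: ",
              paste(absent, collapse = ", "))
    }
    keep <- d$annotation$cell_type %in% shared_types
    subset_cells(d, d$annotation$cell_id[keep])
  })
  nonzero <- Reduce(`+`, lapply(datasets, function(d) Matrix::rowSums(d$counts)))
  keep_gene <- nonzero > 0
  datasets <- lapply(datasets, function(d) {
    d$counts <- d$counts[keep_gene, , drop = FALSE]
    if (!is.null(d$lognorm)) d$lognorm <- d$lognorm[keep_gene, , drop = FALSE]
    d
  })
  n_min <- min(vapply(datasets, function(d) ncol(d$counts), numeric(1)))
  downsample_equal(datasets, n_per_species = n_min, seed = seed)
}

#' Self/other cell sampling for one pairwise comparison
#'
#' Skips cell types with fewer than `min_cells` cells; subsamples the self
#' group to at most `max_cells`; builds the other group as the union of all
#' remaining types, each capped at `max_cells` so the composition of
#' "other" stays comparable across species.
#'
#' @param ds a [species_dataset()] with `cell_type` labels
#' @param cell_type the self cell type
#' @param min_cells minimum self size (default 10)
#' @param max_cells cap per type (default 250)
#' @param seed sampling seed
#' @param group_col annotation column defining the groups (default
#'   `"cell_type"`; use `"clone"` for within-species clone analyses)
#' @return list(self, other) of cell IDs, or NULL when skipped
#' @export
sample_self_other <- function(ds, cell_type, min_cells = 10, max_cells = 250,
                              seed = 1L, group_col = "cell_type") {
  ann <- ds$annotation
  groups <- ann[[group_col]]
  self_pool <- ann$cell_id[groups == cell_type]
  if (length(self_pool) < min_cells) return(NULL)
  set.seed(seed)
  self <- if (length(self_pool) > max_cells) sample(self_pool, max_cells) else self_pool
  other <- unlist(lapply(setdiff(unique(groups), cell_type), function(g) {
    pool <- ann$cell_id[groups == g]
    if (length(pool) > max_cells) sample(pool, max_cells) else pool
  }), use.names = FALSE)
  list(self = self, other = other)
}

# Cauchy combination of p-values (valid under arbitrary dependence)
cauchy_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stat <- mean(tan((0.5 - p) * pi))
  stats::pcauchy(stat, lower.tail = FALSE)
}

#' Zero-inflated quantile rank-score test
#'
#' Two-part differential-distribution test for sparse counts: (i) a score
#' test for a difference in the zero proportion between the groups; (ii) on
#' the positive values only, quantile rank-score statistics at each tau of
#' `tau_grid` (rank scores `a_tau(r) = tau - 1{r <= tau-quantile rank}`,
#' standardized under the permutation variance). The zero-part p-value and
#' the per-tau p-values are combined by the Cauchy combination rule.
#'
#' @param self_expr non-negative vector (self group)
#' @param other_expr non-negative vector (other group)
#' @param tau_grid quantile grid (default c(0.25, 0.5, 0.75))
#' @return combined p-value in [0, 1]
#' @export
ziq_rank_test <- function(self_expr, other_expr,
                          tau_grid = c(0.25, 0.5, 0.75)) {
  n1 <- length(self_expr); n2 <- length(other_expr)
  if (!n1 || !n2) stop("both groups must be non-empty")
  # zero part: two-sample score (proportion) test
  z1 <- mean(self_expr == 0); z2 <- mean(other_expr == 0)
  pbar <- (sum(self_expr == 0) + sum(other_expr == 0)) / (n1 + n2)
  p_zero <- if (pbar %in% c(0, 1)) NA_real_ else {
    zstat <- (z1 - z2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    2 * stats::pnorm(-abs(zstat))
  }
  # positive part: quantile rank scores on pooled positive values
  pos1 <- self_expr[self_expr > 0]; pos2 <- other_expr[other_expr > 0]
  p_tau <- rep(NA_real_, length(tau_grid))
  m1 <- length(pos1); m2 <- length(pos2); m <- m1 + m2
  if (m1 > 0 && m2 > 0 && m > 2) {
    r <- rank(c(pos1, pos2), ties.method = "average")
    grp1 <- seq_len(m1)
    for (k in seq_along(tau_grid)) {
      tau <- tau_grid[k]
      cut_rank <- tau * m
      a <- tau - as.numeric(r <= cut_rank)
      abar <- mean(a)
      v <- m1 * m2 / (m * (m - 1)) * sum((a - abar)^2)
      if (v <= 0) next
      S <- sum(a[grp1]) - m1 * abar
      p_tau[k] <- 2 * stats::pnorm(-abs(S / sqrt(v)))
    }
  }
  ps <- c(p_zero, p_tau)
  if (all(is.na(ps))) return(1)
  cauchy_combine(ps)
}

#' Logistic-regression membership test
#'
#' Likelihood-ratio test of `membership ~ expression` against the
#' intercept-only logistic model; p-value from chi-squared with 1 df. Under
#' complete separation the LR statistic is computed from the (finite,
#' capped-iteration) deviance and flagged.
#'
#' @param expr expression vector (self then other, or any order matching
#'   `is_self`)
#' @param is_self logical/0-1 membership vector
#' @return list(p, statistic, separated)
#' @export
lr_membership_test <- function(expr, is_self) {
  y <- as.numeric(is_self)
  if (length(unique(y)) < 2) stop("both groups must be non-empty")
  sep <- FALSE
  fit1 <- withCallingHandlers(
    stats::glm.fit(cbind(1, expr), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(fit1$fitted.values < 1e-8 | fit1$fitted.values > 1 - 1e-8)) {
    sep <- TRUE
  }
  d1 <- fit1$deviance
  d0 <- stats::glm.fit(matrix(1, length(y)), y,
                       family = stats::binomial())$deviance
  stat <- max(d0 - d1, 0)
  list(p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = stat, separated = sep)
}

# per-gene statistics for one self/other comparison in one dataset
marker_stats_one <- function(ds, sel, unit_value) {
  ln <- ds$lognorm
  cm <- ds$counts
  self_c <- cm[, sel$self, drop = FALSE]
  other_c <- cm[, sel$other, drop = FALSE]
  self_l <- as.matrix(ln[, sel$self, drop = FALSE])
  other_l <- as.matrix(ln[, sel$other, drop = FALSE])
  f_self <- unname(Matrix::rowSums(self_c > 0) / ncol(self_c))
  f_other <- unname(Matrix::rowSums(other_c > 0) / ncol(other_c))
  logfc <- unname(rowMeans(self_l) - rowMeans(other_l))
  genes <- rownames(cm)
  is_self <- c(rep(1, ncol(self_l)), rep(0, ncol(other_l)))
  p_rank <- numeric(length(genes)); p_lr <- numeric(length(genes))
  for (g in seq_along(genes)) {
    es <- self_l[g, ]; eo <- other_l[g, ]
    p_rank[g] <- ziq_rank_test(es, eo)
    p_lr[g] <- lr_membership_test(c(es, eo), is_self)$p
  }
  tibble::tibble(gene = genes, unit = unit_value,
                 f_self = f_self, f_other = f_other,
                 delta = f_self - f_other, logfc = logfc,
                 p_rank = p_rank, p_lr = p_lr)
}

#' Marker tests for all cell types of one or more datasets
#'
#' Runs the zero-inflated quantile rank-score test and the
#' logistic-regression membership test for every gene x cell type of every
#' dataset, on self/other groups drawn by [sample_self_other()]. The unit of
#' analysis is the species (default) or the clone (`by = "clone"`, the
#' within-species variability analysis).
#'
#' @param datasets named list of log-normalized datasets with `cell_type`
#' @param by `"species"` or `"clone"`
#' @param min_cells,max_cells see [sample_self_other()]
#' @param seed sampling seed
#' @return tibble of per-gene statistics: gene, unit, cell_type, f_self,
#'   f_other, delta, logfc, p_rank, p_lr
#' @export
marker_tests <- function(datasets, by = c("species", "clone"),
                         min_cells = 10, max_cells = 250, seed = 1L) {
  by <- match.arg(by)
  rows <- list()
  for (d in datasets) {
    if (is.null(d$lognorm)) stop("run lognormalize() first")
    units <- if (by == "species") d$species else unique(d$annotation$clone)
    for (u in units) {
      dd <- if (by == "species") d else {
        subset_cells(d, d$annotation$cell_id[d$annotation$clone == u])
      }
      for (ct in sort(unique(dd$annotation$cell_type))) {
        sel <- sample_self_other(dd, ct, min_cells, max_cells,
                                 seed = seed + sum(utf8ToInt(paste(u, ct))) %% 1000L)
        if (is.null(sel)) {
          message(u, "/", ct, ": fewer than ", min_cells, " cells, skipped")
          next
        }
        st <- marker_stats_one(dd, sel, u)
        st$cell_type <- ct
        rows[[paste(u, ct)]] <- st
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Filter and rank marker genes
#'
#' Within each cell type x unit stratum, BH-adjusts the rank-score p-values
#' and keeps genes satisfying all five marker rules: `p_adj < alpha_adj`,
#' LR membership p below the same alpha, detection fraction at or above the
#' cell type's harmonized detection threshold, `logfc > min_logfc`, and
#' `delta > min_delta`. Survivors are ranked by decreasing delta (ties:
#' smaller p_adj, then gene ID).
#'
#' @param records a [marker_tests()] tibble
#' @param thresholds a [fit_detection_threshold()] result, or NULL to skip
#'   the detection-threshold rule
#' @param alpha_adj BH-adjusted significance level (default 0.1)
#' @param min_logfc log fold-change bound, exclusive (default 0.01)
#' @param min_delta detection-difference bound, exclusive (default 0.01)
#' @return a `marker_table` tibble with `p_adj` and `rank`, one row per
#'   surviving gene x cell type x unit
#' @export
call_and_rank_markers <- function(records, thresholds = NULL,
                                  alpha_adj = 0.1, min_logfc = 0.01,
                                  min_delta = 0.01) {
  out <- records |>
    dplyr::group_by(.data$unit, .data$cell_type) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_rank, "BH")) |>
    dplyr::ungroup()
  if (!is.null(thresholds)) {
    stopifnot(inherits(thresholds, "threshold_table"))
    out <- dplyr::left_join(out, thresholds$harmonized, by = "cell_type")
  } else {
    out$threshold <- 0
  }
  out <- out |>
    dplyr::filter(.data$p_adj < alpha_adj,
                  .data$p_lr < alpha_adj,
                  .data$f_self >= .data$threshold,
                  .data$logfc > min_logfc,
                  .data$delta > min_delta) |>
    dplyr::arrange(.data$unit, .data$cell_type, dplyr::desc(.data$delta),
                   .data$p_adj, .data$gene) |>
    dplyr::group_by(.data$unit, .data$cell_type) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  class(out) <- c("marker_table", class(out))
  out
}

#' Per-clone marker analysis
#'
#' The marker pipeline with the clone as the unit instead of the species,
#' used to gauge within-species variability of marker lists.
#'
#' @inheritParams marker_tests
#' @inheritParams call_and_rank_markers
#' @return a `marker_table`
#' @export
per_clone_markers <- function(datasets, thresholds = NULL, alpha_adj = 0.1,
                              min_logfc = 0.01, min_delta = 0.01,
                              min_cells = 10, max_cells = 250, seed = 1L) {
  marker_tests(datasets, by = "clone", min_cells = min_cells,
               max_cells = max_cells, seed = seed) |>
    call_and_rank_markers(thresholds, alpha_adj, min_logfc, min_delta)
}
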