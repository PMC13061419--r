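#' Rank-biased overlap of two ranked lists
#'
#' Top-weighted concordance: with prefix agreement
#' `A_d = |top-d(a) intersect top-d(b)| / d`, the score is
#' `(1-p) * sum_{d=1}^{depth} p^(d-1) A_d`, plus the standard extrapolation
#' term `A_depth * p^depth` when `extrapolate` is on. Identical lists score
#' 1, fully disjoint lists 0.
#'
#' @param list_a,list_b character vectors, no duplicates within a list
#' @param p persistence parameter in (0, 1) (default 0.9)
#' @param depth evaluation depth (default 100)
#' @param extrapolate add the `A_depth * p^depth` tail term (default TRUE)
#' @return RBO score in [0, 1]
#' @export
rbo <- function(list_a, list_b, p = 0.9, depth = 100, extrapolate = TRUE) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (!length(list_a) || !length(list_b)) stop("lists must be non-empty")
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    stop("ranked lists must not contain duplicates")
  }
  depth <- min(depth, max(length(list_a), length(list_b)))
  a_d <- numeric(depth)
  for (d in seq_len(depth)) {
    ta <- list_a[seq_len(min(d, length(list_a)))]
    tb <- list_b[seq_len(min(d, length(list_b)))]
    a_d[d] <- length(intersect(ta, tb)) / d
  }
  score <- (1 - p) * sum(p^(seq_len(depth) - 1) * a_d)
  if (extrapolate) score <- score + a_d[depth] * p^depth
  score
}

#' Top-k intersection patterns across ranked lists
#'
#' Counts, for the top-k genes of each list, how many genes fall in each
#' exclusive species-subset intersection pattern (as in an intersection
#' matrix / upset plot).
#'
#' @param lists named list of ranked gene vectors (one per species)
#' @param k top depth (default 100)
#' @return tibble: pattern (e.g. `"human&rhesus"`), n_lists, count
#' @export
topk_intersections <- function(lists, k = 100) {
  if (length(lists) < 2) stop("need at least 2 lists")
  if (is.null(names(lists))) names(lists) <- paste0("list", seq_along(lists))
  tops <- lapply(lists, function(l) utils::head(l, k))
  univ <- sort(unique(unlist(tops)))
  memb <- vapply(tops, function(tl) univ %in% tl, logical(length(univ)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(r) paste(names(lists)[r], collapse = "&"))
  tibble::tibble(pattern = pattern) |>
    dplyr::count(.data$pattern, name = "count") |>
    dplyr::mutate(n_lists = lengths(strsplit(.data$pattern, "&", fixed = TRUE))) |>
    dplyr::arrange(dplyr::desc(.data$n_lists), .data$pattern) |>
    dplyr::select("pattern", "n_lists", "count")
}

#' Filter a ranked list by gene biotype
#'
#' Subsets a ranked marker list to protein-coding genes, lncRNAs, or an
#' explicit transcription-factor set, preserving the ranking order. Genes
#' absent from the biotype table stay in the `"all"` subset but are excluded
#' from biotype subsets; their number is reported.
#'
#' @param ranked_list character vector of gene IDs in rank order
#' @param biotype_table data frame with columns `gene`, `biotype`
#'   (`"protein_coding"` or `"lncRNA"`). A small synthetic example ships as
#'   `system.file("extdata", "biotype_toy_synthetic.tsv", package =
#'   "orthocell")`; real runs supply their own annotation.
#' @param tf_set character vector of transcription-factor gene IDs (for
#'   `subset = "TF"`)
#' @param subset one of `"all"`, `"protein_coding"`, `"lncRNA"`, `"TF"`
#' @return the filtered ranked list
#' @export
subset_by_biotype <- function(ranked_list, biotype_table = NULL,
                              tf_set = NULL,
                              subset = c("all", "protein_coding", "lncRNA",
                                         "TF")) {
  subset <- match.arg(subset)
  if (subset == "all") return(ranked_list)
  if (subset == "TF") {
    if (is.null(tf_set)) tf_set <- character(0)
    return(ranked_list[ranked_list %in% tf_set])
  }
  if (is.null(biotype_table)) stop("biotype_table required for ", subset)
  uncovered <- sum(!ranked_list %in% biotype_table$gene)
  if (uncovered) {
    message(uncovered, " genes absent from biotype table (excluded from '",
            subset, "')")
  }
  keep <- biotype_table$gene[biotype_table$biotype == subset]
  ranked_list[ranked_list %in% keep]
}

#' Per-class and macro F1 scores
#'
#' Standard harmonic mean of precision and recall per class; the macro
#' score is the unweighted mean over the classes present in `truth`.
#' Classes never predicted get F1 = 0.
#'
#' @param truth true labels
#' @param predicted predicted labels (same length)
#' @return list(per_class = named numeric, macro = numeric)
#' @export
f1_scores <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  classes <- sort(unique(truth))
  if (!any(predicted %in% classes)) {
    stop("predicted labels share no vocabulary with the truth")
  }
  per <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(per_class = per, macro = mean(per))
}

# kNN prediction: Euclidean distance, majority vote, ties broken by the
# class with the smallest mean distance among its voting neighbors
knn_predict <- function(train_x, train_y, test_x, k = 3) {
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    means <- vapply(top, function(cl) mean(row[nn][train_y[nn] == cl]),
                    numeric(1))
    top[which.min(means)]
  })
}

#' kNN marker-panel transferability evaluation
#'
#' Trains a k-nearest-neighbor classifier (default k = 3, Euclidean on the
#' log-normalized expression of the union of the top-m markers per cell
#' type) on the training dataset, predicts cell types in each test dataset,
#' and reports the per-cell-type and macro F1 per panel size m, with 95%
#' bootstrap confidence intervals from resampling test cells (stratified by
#' true class).
#'
#' @param train a log-normalized [species_dataset()] with `cell_type` labels
#' @param tests named list of log-normalized datasets with `cell_type`
#' @param marker_lists named list (per cell type) of ranked marker gene IDs
#' @param m_range marker panel sizes (default 1:30)
#' @param k neighbors (default 3)
#' @param n_boot bootstrap resamples (default 200)
#' @param seed bootstrap seed
#' @return an `f1_curve` tibble: test, m, cell_type (`"macro"` row per m),
#'   f1, ci_lo, ci_hi
#' @export
knn_marker_eval <- function(train, tests, marker_lists, m_range = 1:30,
                            k = 3, n_boot = 200, seed = 1L) {
  stopifnot(inherits(train, "species_dataset"))
  if (is.null(train$lognorm)) stop("run lognormalize() first")
  train_y <- train$annotation$cell_type
  out <- list()
  for (m in m_range) {
    feats <- sort(unique(unlist(lapply(marker_lists, utils::head, m))))
    feats_tr <- intersect(feats, rownames(train$lognorm))
    if (!length(feats_tr)) next
    train_x <- t(as.matrix(train$lognorm[feats_tr, , drop = FALSE]))
    for (tn in names(tests)) {
      te <- tests[[tn]]
      feats_te <- intersect(feats_tr, rownames(te$lognorm))
      if (length(feats_te) < length(feats_tr)) {
        warning("markers absent from test '", tn, "' dropped: ",
                length(feats_tr) - length(feats_te))
      }
      tx <- t(as.matrix(te$lognorm[feats_te, , drop = FALSE]))
      pred <- knn_predict(train_x[, feats_te, drop = FALSE], train_y, tx, k)
      truth <- te$annotation$cell_type
      f1 <- f1_scores(truth, pred)
      # stratified bootstrap of test cells over the fixed predictions
      set.seed(seed + m)
      idx_by_class <- split(seq_along(truth), truth)
      boot_macro <- numeric(n_boot)
      boot_per <- matrix(0, n_boot, length(f1$per_class),
                         dimnames = list(NULL, names(f1$per_class)))
      for (b in seq_len(n_boot)) {
        idx <- unlist(lapply(idx_by_class, function(ix)
          sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
        fb <- f1_scores(truth[idx], pred[idx])
        boot_macro[b] <- fb$macro
        boot_per[b, names(fb$per_class)] <- fb$per_class
      }
      point_per <- unname(f1$per_class)
      lo_per <- pmin(apply(boot_per, 2, stats::quantile, 0.025), point_per)
      hi_per <- pmax(apply(boot_per, 2, stats::quantile, 0.975), point_per)
      per_rows <- tibble::tibble(
        test = tn, m = m, cell_type = names(f1$per_class),
        f1 = point_per, ci_lo = unname(lo_per), ci_hi = unname(hi_per))
      point_mac <- f1$macro
      macro_row <- tibble::tibble(
        test = tn, m = m, cell_type = "macro", f1 = point_mac,
        ci_lo = min(stats::quantile(boot_macro, 0.025), point_mac),
        ci_hi = max(stats::quantile(boot_macro, 0.975), point_mac))
      out[[paste(tn, m)]] <- dplyr::bind_rows(per_rows, macro_row)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("f1_curve", class(res))
  res
}
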