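#' Build a pseudobulk rank-correlation reference
#'
#' Aggregates log-normalized expression per cluster label into pseudobulk
#' mean profiles and, for every ordered label pair (A, B), records the top
#' `n_markers_per_pair` genes by the profile difference A - B. The union of
#' all pairwise marker sets is the evaluation gene set of the classifier.
#' Ties in the marker ranking are broken lexicographically by gene ID, so
#' the reference is deterministic.
#'
#' @param ds a log-normalized [species_dataset()]
#' @param labels character/factor vector of cluster labels, one per cell (in
#'   the dataset's cell order), or the name of an annotation column
#' @param n_markers_per_pair genes kept per ordered label pair (default 50)
#' @return a `reference_profiles`: `labels`, `profiles` (gene x label
#'   matrix), `pairwise_markers` (named list "A|B"), `eval_genes`
#' @export
build_reference <- function(ds, labels, n_markers_per_pair = 50) {
  stopifnot(inherits(ds, "species_dataset"))
  if (is.null(ds$lognorm)) stop("run lognormalize() first")
  if (length(labels) == 1 && is.character(labels)) {
    labels <- ds$annotation[[labels]]
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(ds$counts)) stop("labels must cover all cells")
  if (anyNA(labels)) stop("labels must not contain NA")
  ulab <- sort(unique(labels))
  if (!length(ulab)) stop("empty label set")
  small <- names(which(table(labels) < 2))
  if (length(small)) {
    warning("labels with < 2 cells included in reference: ",
            paste(small, collapse = ", "))
  }
  ln <- ds$lognorm
  profiles <- vapply(ulab, function(l) {
    Matrix::rowMeans(ln[, labels == l, drop = FALSE])
  }, numeric(nrow(ln)))
  rownames(profiles) <- rownames(ln)

  genes <- rownames(profiles)
  ord_lex <- order(genes)
  pairwise <- list()
  for (a in ulab) for (b in ulab) {
    if (a == b) next
    d <- profiles[, a] - profiles[, b]
    # decreasing by difference, ties lexicographic by gene ID
    o <- ord_lex[order(-d[ord_lex])]
    pairwise[[paste(a, b, sep = "|")]] <-
      genes[o][seq_len(min(n_markers_per_pair, length(genes)))]
  }
  structure(list(labels = ulab, profiles = profiles,
                 pairwise_markers = pairwise,
                 eval_genes = sort(unique(unlist(pairwise)))),
            class = "reference_profiles")
}

# column-wise average ranks of a dense matrix (ties = average)
col_ranks <- function(m) {
  apply(m, 2, rank, ties.method = "average")
}

# Spearman correlations between columns of cell matrix and profile matrix,
# restricted to `genes`; returns cells x labels matrix. Zero-variance cell
# columns give NA.
spearman_scores <- function(cell_mat, profiles, genes) {
  cm <- as.matrix(cell_mat[genes, , drop = FALSE])
  pm <- profiles[genes, , drop = FALSE]
  rc <- col_ranks(cm)
  rp <- col_ranks(pm)
  rc <- scale(rc)
  rp <- scale(rp)
  n <- length(genes)
  suppressWarnings(crossprod(rc, rp) / (n - 1))
}

#' Classify cells against a reference by Spearman correlation
#'
#' Scores every cell against every reference label by Spearman rank
#' correlation over the union of pairwise marker genes; optional fine-tuning
#' iteratively restricts to the labels scoring within `tune_margin` of the
#' best and re-correlates on the union of markers among the surviving
#' labels, until one label remains or the label set stabilizes. Cells with
#' zero variance over the evaluation genes get label `"unassigned"`.
#'
#' @param target a log-normalized [species_dataset()] sharing the reference's
#'   gene namespace
#' @param ref a [build_reference()] object
#' @param fine_tune enable iterative fine-tuning (default TRUE)
#' @param tune_margin score margin for keeping labels during fine-tuning
#' @return a `classification_result`: tibble `assignment` (cell_id, label,
#'   score) and matrix `scores` (cells x labels, initial full scores)
#' @export
classify_cells <- function(target, ref, fine_tune = TRUE, tune_margin = 0.05) {
  stopifnot(inherits(target, "species_dataset"),
            inherits(ref, "reference_profiles"))
  if (is.null(target$lognorm)) stop("run lognormalize() first")
  classify_matrix(target$lognorm, ref, fine_tune = fine_tune,
                  tune_margin = tune_margin)
}

#' Classify an expression matrix against a reference
#'
#' Matrix-level work-horse behind [classify_cells()]; accepts any
#' gene x cell (or gene x profile) matrix of log-normalized values.
#'
#' @param mat gene x cell matrix with dimnames
#' @inheritParams classify_cells
#' @return a `classification_result`
#' @export
classify_matrix <- function(mat, ref, fine_tune = TRUE, tune_margin = 0.05) {
  stopifnot(inherits(ref, "reference_profiles"))
  genes <- intersect(ref$eval_genes, rownames(mat))
  if (length(genes) < 2) stop("evaluation gene set not present in target")
  scores <- spearman_scores(mat, ref$profiles, genes)
  rownames(scores) <- colnames(mat)

  pick <- function(v) ref$labels[which.max(v)]  # which.max: first (lex) on ties
  assigned <- character(nrow(scores))
  final_score <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    v <- scores[i, ]
    if (anyNA(v)) { assigned[i] <- "unassigned"; final_score[i] <- NA_real_; next }
    if (!fine_tune) {
      assigned[i] <- pick(v); final_score[i] <- max(v); next
    }
    keep <- ref$labels
    repeat {
      cand <- keep[v[keep] >= max(v[keep]) - tune_margin]
      if (length(cand) == 1 || setequal(cand, keep)) { keep <- cand; break }
      keep <- cand
      sub_genes <- sort(unique(unlist(
        ref$pairwise_markers[outer(keep, keep, paste, sep = "|")[
          upper.tri(diag(length(keep))) | lower.tri(diag(length(keep)))]])))
      sub_genes <- intersect(sub_genes, rownames(mat))
      if (length(sub_genes) < 2) break
      v2 <- spearman_scores(mat[, i, drop = FALSE],
                            ref$profiles[, keep, drop = FALSE], sub_genes)[1, ]
      if (anyNA(v2)) break
      v <- stats::setNames(rep(-Inf, length(ref$labels)), ref$labels)
      v[keep] <- v2
    }
    best <- keep[which.max(v[keep])]
    assigned[i] <- best
    final_score[i] <- v[best]
  }
  structure(list(
    assignment = tibble::tibble(cell_id = rownames(scores),
                                label = assigned, score = final_score),
    scores = scores),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %d cells, %d labels\n",
              nrow(x$assignment), ncol(x$scores)))
  print(utils::head(sort(table(x$assignment$label), decreasing = TRUE)))
  invisible(x)
}
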