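#' High-resolution clustering of one species
#'
#' Community detection (Leiden, modularity objective) on a k-nearest-neighbor
#' graph of a PCA embedding of the log-normalized expression. The resolution
#' is deliberately high so that each expected cell type is split into at
#' least two high-resolution clusters (HRCs), protecting rare types before
#' cross-species matching. Precomputed labels may be supplied instead via
#' the `hrc` annotation column.
#'
#' @param ds a log-normalized [species_dataset()]
#' @param resolution Leiden resolution (default 2)
#' @param n_pcs number of principal components (default 30)
#' @param k neighbors for the kNN graph (default 20)
#' @param n_hvg number of most-variable genes used for the embedding
#' @param seed RNG seed (community detection is stochastic)
#' @return the dataset with an `hrc` annotation column of labels
#'   `"<species>_h<k>"`
#' @export
cluster_hrc <- function(ds, resolution = 2, n_pcs = 30, k = 20,
                        n_hvg = 2000, seed = 1L) {
  stopifnot(inherits(ds, "species_dataset"))
  if (is.null(ds$lognorm)) stop("run lognormalize() first")
  ncell <- ncol(ds$lognorm)
  if (ncell <= k) {
    stop("fewer cells than k neighbors; supply precomputed labels in the ",
         "'hrc' annotation column instead")
  }
  gv <- rowVars_sparse(ds$lognorm)
  hvg <- order(gv, decreasing = TRUE)[seq_len(min(n_hvg, nrow(ds$lognorm)))]
  x <- t(as.matrix(ds$lognorm[hvg, , drop = FALSE]))
  x <- scale(x)
  x[, !is.finite(colSums(x))] <- 0
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  n_pcs <- min(n_pcs, ncol(x) - 1, nrow(x) - 1)
  set.seed(seed)
  pcs <- stats::prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)$x

  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(ncell), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    cbind(i, nn)
  }))
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, ncell - igraph::vcount(g)))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  labs <- igraph::membership(comm)
  ds$annotation$hrc <- sprintf("%s_h%02d", ds$species, as.integer(labs))
  ds
}

rowVars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2
}

#' Reciprocal classification similarity between all HRCs
#'
#' For each ordered species pair, a rank-correlation reference is trained on
#' the reference species' HRCs and the target species' cells are classified;
#' the directional similarity of target HRC t to reference HRC r is the
#' fraction of t's classified cells assigned to r. Within-species entries
#' use a stratified 80/20 split: train on 80% of cells, classify the held-out
#' 20%. The final similarity of an HRC pair is the mean of its two
#' directional fractions, giving a symmetric matrix in [0, 1].
#'
#' @param datasets named list of log-normalized [species_dataset()] with
#'   `hrc` labels, sharing one gene namespace
#' @param split_frac within-species reference fraction (default 0.8)
#' @param n_markers_per_pair passed to [build_reference()]
#' @param fine_tune,tune_margin passed to [classify_cells()]
#' @param seed seed for the within-species splits
#' @return a `similarity_matrix`: `values` (HRC x HRC symmetric matrix),
#'   `directional` (long tibble of the raw directional fractions),
#'   `hrc_info` (tibble: hrc, species, n_cells)
#' @export
reciprocal_similarity <- function(datasets, split_frac = 0.8,
                                  n_markers_per_pair = 50,
                                  fine_tune = TRUE, tune_margin = 0.05,
                                  seed = 1L) {
  check_shared_genes(datasets)
  for (d in datasets) {
    if (is.null(d$annotation$hrc)) stop("all datasets need 'hrc' labels")
    if (is.null(d$lognorm)) stop("run lognormalize() first")
  }
  species <- vapply(datasets, function(d) d$species, character(1))
  names(datasets) <- species
  hrc_info <- purrr::map_dfr(datasets, function(d) {
    dplyr::count(d$annotation, .data$species, hrc = .data$hrc, name = "n_cells")
  })
  all_hrc <- sort(hrc_info$hrc)

  # directional fraction table: target hrc x reference hrc
  frac_rows <- list()
  tally <- function(target_hrc, assigned, ref_labels, direction) {
    keep <- assigned != "unassigned"
    tab <- table(factor(target_hrc[keep], levels = sort(unique(target_hrc))),
                 factor(assigned[keep], levels = ref_labels))
    n <- rowSums(tab)
    frac <- sweep(tab, 1, pmax(n, 1), "/")
    as.data.frame(frac, stringsAsFactors = FALSE) |>
      stats::setNames(c("target", "reference", "fraction")) |>
      dplyr::mutate(n_target = as.numeric(n[.data$target]),
                    direction = direction)
  }

  for (r in species) {
    ref <- build_reference(datasets[[r]], datasets[[r]]$annotation$hrc,
                           n_markers_per_pair = n_markers_per_pair)
    for (t in species) {
      if (t == r) next
      res <- classify_cells(datasets[[t]], ref, fine_tune, tune_margin)
      frac_rows[[paste(t, r)]] <- tally(datasets[[t]]$annotation$hrc,
                                        res$assignment$label, ref$labels,
                                        paste(t, "->", r))
    }
  }
  # within-species: stratified split by HRC
  set.seed(seed)
  for (s in species) {
    ann <- datasets[[s]]$annotation
    ref_cells <- unlist(lapply(split(ann$cell_id, ann$hrc), function(ids) {
      n_ref <- max(1, round(length(ids) * split_frac))
      if (n_ref >= length(ids)) n_ref <- length(ids) - 1L
      if (n_ref < 1) return(ids[0])  # 1-cell HRC: no split possible
      sample(ids, n_ref)
    }), use.names = FALSE)
    test_cells <- setdiff(ann$cell_id, ref_cells)
    empty_test <- setdiff(unique(ann$hrc),
                          unique(ann$hrc[ann$cell_id %in% test_cells]))
    if (length(empty_test)) {
      warning("HRCs with no test cells in within-species split (row imputed 0): ",
              paste(empty_test, collapse = ", "))
    }
    ref_ds <- subset_cells(datasets[[s]], ref_cells)
    ref <- build_reference(ref_ds, ref_ds$annotation$hrc,
                           n_markers_per_pair = n_markers_per_pair)
    test_ds <- subset_cells(datasets[[s]], test_cells)
    res <- classify_cells(test_ds, ref, fine_tune, tune_margin)
    fr <- tally(test_ds$annotation$hrc, res$assignment$label, ref$labels,
                paste(s, "->", s))
    if (length(empty_test)) {
      fr <- dplyr::bind_rows(fr, tidyr::expand_grid(
        target = empty_test, reference = ref$labels) |>
          dplyr::mutate(fraction = 0, n_target = 0,
                        direction = paste(s, "->", s)))
    }
    frac_rows[[paste(s, s)]] <- fr
  }

  directional <- dplyr::bind_rows(frac_rows) |>
    tibble::as_tibble() |>
    dplyr::mutate(target = as.character(.data$target),
                  reference = as.character(.data$reference))

  m <- matrix(0, length(all_hrc), length(all_hrc),
              dimnames = list(all_hrc, all_hrc))
  cnt <- m
  for (i in seq_len(nrow(directional))) {
    a <- directional$target[i]; b <- directional$reference[i]
    m[a, b] <- m[a, b] + directional$fraction[i]
    cnt[a, b] <- cnt[a, b] + 1
  }
  sym <- (m + t(m)) / pmax(cnt + t(cnt), 1)
  diag(sym) <- diag(m) / pmax(diag(cnt), 1)
  structure(list(values = sym, directional = directional,
                 hrc_info = hrc_info),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d HRCs across %d species\n",
              nrow(x$values), length(unique(x$hrc_info$species))))
  invisible(x)
}

#' Assign HRCs to orthologous cell type clusters
#'
#' Converts the averaged reciprocal similarity to a distance (1 - similarity),
#' clusters HRCs by average-linkage hierarchical clustering, and cuts the
#' tree into `n_occ` groups. HRCs of the same species falling into one group
#' are thereby merged; groups spanning species are the orthologous cell type
#' clusters (OCCs). `n_occ` is a user choice informed by inspection of the
#' dendrogram ([occ_dendrogram()]).
#'
#' @param sim a [reciprocal_similarity()] result
#' @param n_occ number of groups to cut the tree into
#' @return an `occ_assignment`: `mapping` tibble (hrc, species, n_cells,
#'   occ), `occ_info` tibble (occ, n_cells, n_species, status), `hclust`
#'   (the tree), `provenance` (list)
#' @export
assign_occ <- function(sim, n_occ) {
  stopifnot(inherits(sim, "similarity_matrix"))
  n_hrc <- nrow(sim$values)
  if (n_occ < 1 || n_occ > n_hrc) stop("n_occ must be in 1..", n_hrc)
  d <- stats::as.dist(1 - sim$values)
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, k = n_occ)
  mapping <- sim$hrc_info |>
    dplyr::mutate(occ = sprintf("OCC%02d", grp[.data$hrc]))
  occ <- occ_summary(mapping)
  structure(list(mapping = mapping, occ_info = occ, hclust = hc,
                 provenance = list(n_occ = n_occ, method = "average",
                                   distance = "1 - similarity")),
            class = "occ_assignment")
}

occ_summary <- function(mapping, status = NULL) {
  info <- mapping |>
    dplyr::group_by(.data$occ) |>
    dplyr::summarise(n_cells = sum(.data$n_cells),
                     n_species = dplyr::n_distinct(.data$species),
                     .groups = "drop")
  info$status <- if (is.null(status)) "retained" else status[info$occ]
  info
}

#' @export
print.occ_assignment <- function(x, ...) {
  cat(sprintf("<occ_assignment> %d HRCs -> %d OCCs (%d retained)\n",
              nrow(x$mapping), nrow(x$occ_info),
              sum(x$occ_info$status == "retained")))
  invisible(x)
}

#' Merge OCCs with near-identical pseudobulk profiles
#'
#' Per species, pseudobulk profiles (mean log-normalized expression) are
#' computed per OCC and Spearman's rho between all OCC pairs on the `n_hvg`
#' most variable genes (variance of the log pseudobulk across that species'
#' OCCs). The cross-species mean rho-bar feeds average-linkage clustering on
#' 1 - rho-bar; OCC pairs merging below `cut_height` are unioned. Pairs never
#' co-present in a species get the maximal distance and are never merged.
#'
#' @param datasets named list of log-normalized datasets with `hrc` labels
#' @param occ an [assign_occ()] result
#' @param n_hvg most-variable genes per species (default 2000)
#' @param cut_height merge cut height on 1 - rho-bar (default 0.1)
#' @return the updated `occ_assignment` (merged OCC ids `"<a>+<b>"`),
#'   with `merge_rho` (the rho-bar distance matrix) attached
#' @export
merge_occ_pseudobulk <- function(datasets, occ, n_hvg = 2000,
                                 cut_height = 0.1) {
  stopifnot(inherits(occ, "occ_assignment"))
  check_shared_genes(datasets)
  map <- stats::setNames(occ$mapping$occ, occ$mapping$hrc)
  occ_ids <- sort(unique(occ$mapping$occ))
  if (!length(occ_ids)) stop("no OCCs to merge")
  n_occ <- length(occ_ids)
  dsum <- matrix(0, n_occ, n_occ, dimnames = list(occ_ids, occ_ids))
  dcnt <- dsum
  seen <- stats::setNames(rep(FALSE, n_occ), occ_ids)
  for (d in datasets) {
    cells_occ <- map[d$annotation$hrc]
    present <- sort(unique(cells_occ))
    seen[present] <- TRUE
    if (length(present) < 2) next
    pb <- vapply(present, function(o) {
      Matrix::rowMeans(d$lognorm[, cells_occ == o, drop = FALSE])
    }, numeric(nrow(d$lognorm)))
    v <- apply(pb, 1, stats::var)
    hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(pb)))]
    rho <- stats::cor(pb[hvg, , drop = FALSE], method = "spearman")
    dsum[present, present] <- dsum[present, present] + (1 - rho)
    dcnt[present, present] <- dcnt[present, present] + 1
  }
  if (!all(seen)) {
    stop("OCC absent from all species: ",
         paste(occ_ids[!seen], collapse = ", "))
  }
  dd <- ifelse(dcnt > 0, dsum / pmax(dcnt, 1), 2)
  diag(dd) <- 0
  if (n_occ > 1) {
    hc <- stats::hclust(stats::as.dist(dd), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
  } else grp <- stats::setNames(1L, occ_ids)
  new_id <- vapply(split(occ_ids, grp), paste, character(1), collapse = "+")
  relabel <- stats::setNames(new_id[as.character(grp)], occ_ids)
  occ$mapping$occ <- unname(relabel[occ$mapping$occ])
  occ$occ_info <- occ_summary(occ$mapping)
  occ$merge_rho <- dd
  occ$provenance$merge <- list(n_hvg = n_hvg, cut_height = cut_height)
  occ
}

#' Filter out small, species-restricted OCCs
#'
#' An OCC is excluded iff it has fewer than `min_cells` cells AND is present
#' in fewer than `min_species` species; all other OCCs are retained.
#'
#' @param occ an `occ_assignment`
#' @param min_cells cell count bound, exclusive (default 800)
#' @param min_species species count bound, exclusive upper (default 3: OCCs
#'   in only 1 or 2 species fail)
#' @return the `occ_assignment` with `occ_info$status` set to `"excluded"`
#'   for filtered OCCs
#' @export
filter_occ <- function(occ, min_cells = 800, min_species = 3) {
  stopifnot(inherits(occ, "occ_assignment"))
  excl <- occ$occ_info$n_cells < min_cells &
    occ$occ_info$n_species < min_species
  occ$occ_info$status <- ifelse(excl, "excluded", "retained")
  occ$provenance$filter <- list(min_cells = min_cells,
                                min_species = min_species)
  occ
}

#' Split an over-merged OCC into named sub-OCCs
#'
#' Explicit, reproducible replacement for the interactive split: a mapping
#' from every member HRC of `occ_id` to a sub-label replaces the OCC by the
#' named sub-OCCs. Provenance (parent, timestamp, mapping hash) is recorded.
#'
#' @param occ an `occ_assignment`
#' @param occ_id OCC to split
#' @param new_mapping named character: HRC id -> sub-label, covering all
#'   member HRCs of `occ_id`
#' @return the updated `occ_assignment`
#' @export
split_occ <- function(occ, occ_id, new_mapping) {
  stopifnot(inherits(occ, "occ_assignment"))
  members <- occ$mapping$hrc[occ$mapping$occ == occ_id]
  if (!length(members)) stop("unknown OCC: ", occ_id)
  missing <- setdiff(members, names(new_mapping))
  if (length(missing)) {
    stop("new_mapping does not cover member HRCs: ",
         paste(missing, collapse = ", "))
  }
  idx <- occ$mapping$occ == occ_id
  occ$mapping$occ[idx] <- paste0(occ_id, ":",
                                 new_mapping[occ$mapping$hrc[idx]])
  occ$occ_info <- occ_summary(occ$mapping)
  occ$provenance$splits <- c(occ$provenance$splits, list(list(
    parent = occ_id, time = format(Sys.time(), tz = "UTC"),
    mapping_hash = sum(utf8ToInt(paste(names(new_mapping), new_mapping,
                                       collapse = ";"))))))
  occ
}

#' Cell-level OCC labels
#'
#' Applies an OCC assignment back to the datasets: each cell gets the OCC of
#' its HRC in a `cell_type` annotation column (excluded OCCs get NA).
#'
#' @param datasets named list of datasets with `hrc` labels
#' @param occ an `occ_assignment`
#' @return the datasets with `cell_type` set
#' @export
apply_occ_labels <- function(datasets, occ) {
  map <- stats::setNames(occ$mapping$occ, occ$mapping$hrc)
  keep <- occ$occ_info$occ[occ$occ_info$status == "retained"]
  lapply(datasets, function(d) {
    lab <- unname(map[d$annotation$hrc])
    lab[!lab %in% keep] <- NA_character_
    d$annotation$cell_type <- lab
    d
  })
}
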