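#' Simulation configuration for multi-species single-cell data
#'
#' Defines the generative model used to emulate a cross-species embryoid-body
#' style experiment: a quartet phylogeny, a set of shared cell types with
#' uneven compositions, negative-binomial counts with per-gene dispersion,
#' Brownian drift of cell type log-mean profiles along the tree (so
#' divergence scales with branch length), per-branch gain/loss switching of
#' cell type-specific expression, clone-level batch effects, and log-normal
#' library depths.
#'
#' @param phylogeny a [scaled_phylogeny()]; default [default_phylogeny()]
#' @param n_genes total number of genes
#' @param cell_types character vector of shared cell type labels
#' @param cells_per_type named numeric: cells per type per species (recycled
#'   across species); defaults to an uneven composition totalling
#'   `n_cells_per_species`
#' @param n_cells_per_species total cells per species when `cells_per_type`
#'   is not given
#' @param n_markers_per_type planted exclusive marker genes per cell type
#' @param marker_lfc natural-log expression elevation of planted markers in
#'   their own type
#' @param base_logmu optional gene x cell type matrix of baseline log-means
#'   (relative scale); generated when NULL
#' @param dispersion optional per-gene NB size parameter theta; drawn
#'   log-normal(log 2, 0.4) when NULL
#' @param divergence_sigma Brownian-motion standard deviation of log-mean
#'   drift per unit (scaled) branch length
#' @param switch_rate per-branch probability, per unit branch length, that a
#'   gene's expression status in a cell type is flipped (gain or loss)
#' @param n_clones clones per species
#' @param clone_sigma standard deviation of the per-clone, per-gene log-mean
#'   batch effect
#' @param depth_mean expected UMIs per cell
#' @param depth_sigma log-scale standard deviation of per-cell depth
#'   (0 = constant depth)
#' @param off_logmu log-mean offset applied to genes that are OFF in a cell
#'   type (natural-log units below baseline)
#' @param seed master seed; each species derives its own RNG stream by a
#'   fixed offset so adding a species does not perturb the others
#' @return a `sim_config` list, validated
#' @export
sim_config <- function(phylogeny = default_phylogeny(),
                       n_genes = 800,
                       cell_types = paste0("ct", 1:7),
                       cells_per_type = NULL,
                       n_cells_per_species = 700,
                       n_markers_per_type = 10,
                       marker_lfc = 2.5,
                       base_logmu = NULL,
                       dispersion = NULL,
                       divergence_sigma = 0.3,
                       switch_rate = 0.2,
                       n_clones = 2,
                       clone_sigma = 0.5,
                       depth_mean = 5000,
                       depth_sigma = 0.3,
                       off_logmu = -8,
                       seed = 1L) {
  stopifnot(inherits(phylogeny, "scaled_phylogeny"))
  if (is.null(cells_per_type)) {
    props <- c(0.22, 0.18, 0.16, 0.14, 0.12, 0.10, 0.08)
    props <- rep_len(props, length(cell_types))
    props <- props / sum(props)
    cells_per_type <- stats::setNames(
      largest_remainder(props, n_cells_per_species), cell_types)
  }
  if (is.null(names(cells_per_type)) ||
      !setequal(names(cells_per_type), cell_types)) {
    stop("cells_per_type must be named by cell_types")
  }
  cells_per_type <- cells_per_type[cell_types]
  bad <- c(
    if (divergence_sigma < 0) "divergence_sigma must be >= 0",
    if (switch_rate < 0) "switch_rate must be >= 0",
    if (clone_sigma < 0) "clone_sigma must be >= 0",
    if (depth_sigma < 0) "depth_sigma must be >= 0",
    if (any(cells_per_type < 0)) "cell counts must be >= 0",
    if (!is.null(dispersion) && any(dispersion <= 0)) "dispersion must be > 0",
    if (depth_mean <= 0) "depth_mean must be > 0",
    if (n_genes < length(cell_types) * n_markers_per_type)
      "n_genes too small for the requested marker panels"
  )
  if (length(bad)) stop(paste(bad, collapse = "; "))
  structure(list(
    phylogeny = phylogeny, n_genes = as.integer(n_genes),
    cell_types = cell_types, cells_per_type = cells_per_type,
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_lfc = marker_lfc, base_logmu = base_logmu,
    dispersion = dispersion, divergence_sigma = divergence_sigma,
    switch_rate = switch_rate, n_clones = as.integer(n_clones),
    clone_sigma = clone_sigma, depth_mean = depth_mean,
    depth_sigma = depth_sigma, off_logmu = off_logmu,
    seed = as.integer(seed)), class = "sim_config")
}

# largest-remainder apportionment of n into round(p*n) keeping sum exact
largest_remainder <- function(props, n) {
  raw <- props / sum(props) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# baseline log-mean matrix (gene x cell type, relative natural-log scale)
# and the root ON/OFF status. Gene blocks: per-type exclusive markers,
# broadly expressed housekeeping genes, genes ON in a random subset of
# types (graded specificity), and silent genes.
build_base_profiles <- function(cfg) {
  ng <- cfg$n_genes
  nt <- length(cfg$cell_types)
  genes <- sprintf("gene%04d", seq_len(ng))
  base <- stats::rnorm(ng, mean = 0, sd = 1)
  logmu <- matrix(rep(base, nt), ng, nt,
                  dimnames = list(genes, cfg$cell_types))
  status <- matrix(TRUE, ng, nt, dimnames = dimnames(logmu))
  n_mark <- cfg$n_markers_per_type * nt
  marker_idx <- matrix(seq_len(n_mark), ncol = nt)
  for (j in seq_len(nt)) {
    idx <- marker_idx[, j]
    status[idx, ] <- FALSE
    status[idx, j] <- TRUE
    logmu[idx, j] <- base[idx] + cfg$marker_lfc
  }
  rest <- setdiff(seq_len(ng), seq_len(n_mark))
  # 15% silent, 25% graded specificity (ON in 1..6 random types), rest broad
  n_rest <- length(rest)
  n_silent <- floor(0.15 * n_rest)
  n_graded <- floor(0.25 * n_rest)
  silent <- rest[seq_len(n_silent)]
  graded <- rest[n_silent + seq_len(n_graded)]
  status[silent, ] <- FALSE
  for (i in graded) {
    k <- sample(1:(nt - 1), 1)
    off <- sample(nt, nt - k)
    status[i, off] <- FALSE
  }
  list(genes = genes, logmu = logmu, status = status)
}

#' Simulate a multi-species single-cell experiment with known truth
#'
#' Counts for each species are drawn NB(mean = depth-scaled
#' exp(base log-mean + Brownian branch drift + clone effect), size = theta).
#' Drift accumulates along the path from the tree's midpoint root, with
#' variance `divergence_sigma^2 x path length`; species in the same clade
#' share the drift of (their half of) the internal branch. Gain/loss events
#' flip a cell type's expression status of a gene on a branch with
#' probability `switch_rate x branch length`; OFF genes sit `off_logmu`
#' natural-log units below baseline so NB sampling still applies.
#'
#' @param cfg a [sim_config()]
#' @return list with `datasets` (named list of [species_dataset()], one per
#'   leaf of the phylogeny) and `truth` (a `sim_truth`: `cell_type` per cell,
#'   binary `status` tensor gene x cell type x species, realized `logmu`
#'   per species, `markers` per type per species via
#'   [planted_marker_panel()], and the config)
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  species <- cfg$phylogeny$leaves
  nt <- length(cfg$cell_types)

  set.seed(cfg$seed)
  base <- build_base_profiles(cfg)
  ng <- cfg$n_genes
  theta <- cfg$dispersion
  if (is.null(theta)) theta <- stats::rlnorm(ng, log(2), 0.4)
  theta <- stats::setNames(rep_len(theta, ng), base$genes)

  # tree walk: root at the midpoint of the internal branch; each clade
  # shares drift/switches over its half of the internal branch, then each
  # leaf adds its terminal branch.
  half <- cfg$phylogeny$internal_bl / 2
  clade_of <- stats::setNames(
    rep(1:2, times = lengths(cfg$phylogeny$clades)),
    unlist(cfg$phylogeny$clades))[species]

  branch_effects <- function(bl) {
    drift <- matrix(stats::rnorm(ng * nt, 0, cfg$divergence_sigma * sqrt(bl)),
                    ng, nt)
    flips <- matrix(stats::runif(ng * nt) < cfg$switch_rate * bl, ng, nt)
    list(drift = drift, flips = flips)
  }
  # clade-shared internal-branch halves (drawn from the master stream)
  clade_fx <- lapply(1:2, function(i) branch_effects(half))

  datasets <- list(); status_arr <- array(
    FALSE, dim = c(ng, nt, length(species)),
    dimnames = list(base$genes, cfg$cell_types, species))
  logmu_sp <- list()

  for (si in seq_along(species)) {
    sp <- species[si]
    set.seed(cfg$seed + 1000L * si)
    fx_c <- clade_fx[[clade_of[sp]]]
    fx_t <- branch_effects(cfg$phylogeny$terminal_bl[[sp]])
    status <- xor(base$status, xor(fx_c$flips, fx_t$flips))
    drift <- fx_c$drift + fx_t$drift
    logmu <- base$logmu + drift + ifelse(status, 0, cfg$off_logmu)

    n_per <- cfg$cells_per_type
    ct <- rep(cfg$cell_types, times = n_per)
    ncell <- length(ct)
    clone <- paste0(sp, "_cl", rep_len(seq_len(cfg$n_clones), ncell))
    # shuffle clone assignment within type so clones mix across types
    clone <- unlist(lapply(split(clone, ct), sample), use.names = FALSE)[
      order(order(ct))]
    clone_fx <- matrix(stats::rnorm(ng * cfg$n_clones, 0, cfg$clone_sigma),
                       ng, cfg$n_clones,
                       dimnames = list(base$genes,
                                       paste0(sp, "_cl", seq_len(cfg$n_clones))))
    depth <- if (cfg$depth_sigma > 0) {
      stats::rlnorm(ncell, log(cfg$depth_mean) - cfg$depth_sigma^2 / 2,
                    cfg$depth_sigma)
    } else rep(cfg$depth_mean, ncell)

    counts <- matrix(0L, ng, ncell)
    for (j in seq_len(nt)) {
      for (cl in colnames(clone_fx)) {
        cells <- which(ct == cfg$cell_types[j] & clone == cl)
        if (!length(cells)) next
        lm <- logmu[, j] + clone_fx[, cl]
        p <- exp(lm); p <- p / sum(p)
        mu <- outer(p, depth[cells])
        counts[, cells] <- stats::rnbinom(ng * length(cells),
                                          size = theta, mu = mu)
      }
    }
    cell_ids <- sprintf("%s_c%05d", sp, seq_len(ncell))
    dimnames(counts) <- list(base$genes, cell_ids)
    ann <- tibble::tibble(cell_id = cell_ids, clone = clone,
                          timepoint = "d16", cell_type = ct)
    datasets[[sp]] <- species_dataset(methods::as(counts, "CsparseMatrix"),
                                      ann, species = sp)
    status_arr[, , sp] <- status
    logmu_sp[[sp]] <- logmu
  }

  truth <- structure(list(
    status = status_arr, logmu = logmu_sp, theta = theta,
    cell_types = cfg$cell_types, species = species, config = cfg),
    class = "sim_truth")
  list(datasets = datasets, truth = truth)
}

#' Planted marker panel from simulation truth
#'
#' Genes whose true expression status is ON in the given cell type and OFF
#' in every other cell type of that species, ranked by the true detection
#' fraction gap (expected detection in the type minus the mean expected
#' detection in other types, under the NB zero model
#' `P(detect) = 1 - (1 + mu/theta)^(-theta)` at the configured mean depth).
#'
#' @param truth a `sim_truth` from [simulate_experiment()]
#' @param cell_type cell type label
#' @param species species name
#' @return tibble with `gene` and `detection_gap`, sorted decreasing
#' @export
planted_marker_panel <- function(truth, cell_type, species) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!cell_type %in% truth$cell_types) stop("unknown cell type: ", cell_type)
  if (!species %in% truth$species) stop("unknown species: ", species)
  st <- truth$status[, , species]
  j <- match(cell_type, truth$cell_types)
  excl <- which(st[, j] & rowSums(st[, -j, drop = FALSE]) == 0)
  if (!length(excl)) {
    return(tibble::tibble(gene = character(0), detection_gap = numeric(0)))
  }
  cfg <- truth$config
  lm <- truth$logmu[[species]]
  p_rel <- exp(lm)
  p_rel <- sweep(p_rel, 2, colSums(p_rel), "/")
  mu <- p_rel * cfg$depth_mean
  pdet <- 1 - (1 + mu / truth$theta)^(-truth$theta)
  gap <- pdet[excl, j] - rowMeans(pdet[excl, -j, drop = FALSE])
  tibble::tibble(gene = rownames(st)[excl], detection_gap = as.numeric(gap)) |>
    dplyr::arrange(dplyr::desc(.data$detection_gap), .data$gene)
}
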