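#' Default run configuration
#'
#' All stage parameters with their standard defaults (high-resolution
#' clustering at resolution 2, 80/20 within-species split, OCC merge cut
#' height 0.1, OCC filter at 800 cells / 3 species, expression-calling
#' downsampling to 18,800 cells, status quantiles 0.05/0.90, marker rules
#' alpha 0.1 / logFC 0.01 / delta 0.01 with 10-250 cells per comparison,
#' RBO on the top 100, kNN k = 3 over panel sizes 1..30). Interactive
#' choices of the original workflow (the number of OCCs, merges, splits)
#' are explicit configuration here.
#'
#' @param ... named overrides of nested fields, e.g. `match = list(n_occ=7)`
#' @return nested configuration list of class `run_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_genes = 800, n_cells_per_species = 700,
                    divergence_sigma = 0.3, switch_rate = 0.2,
                    n_markers_per_type = 10, n_clones = 2),
    input = list(paths = NULL, tree = NULL),
    qc = list(min_genes = 1000, max_mito = 0.08),
    normalize = list(scale = 1e4),
    hrc = list(resolution = 2, n_pcs = 30, k = 20, n_hvg = 2000),
    match = list(split_frac = 0.8, n_markers_per_pair = 50, n_occ = NULL,
                 cut_height = 0.1, min_cells = 800, min_species = 3),
    call = list(n_downsample = 18800, min_nonzero_frac = 0.01, mad_k = 3,
                detect_q = 0.05, reliable_q = 0.90, prob_cut = 0.5),
    markers = list(alpha_adj = 0.1, min_logfc = 0.01, min_delta = 0.01,
                   min_cells = 10, max_cells = 250),
    evaluate = list(rbo_p = 0.9, rbo_depth = 100, top_k = 100,
                    m_max = 30, k = 3, n_boot = 200)
  )
  over <- list(...)
  validate_overrides <- function(base, upd, path = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base)) {
        stop("unknown configuration key: ", paste0(path, nm))
      }
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- validate_overrides(base[[nm]], upd[[nm]],
                                         paste0(path, nm, "$"))
      } else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- validate_overrides(cfg, over)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected by name; missing keys take their defaults.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

provenance_header <- function(stage, cfg) {
  hash <- sum(utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))) %% 1e9
  sprintf("# stage=%s seed=%d config_hash=%d package=orthocell", stage,
          as.integer(cfg$seed), as.integer(hash))
}

write_stage_tsv <- function(df, path, stage, cfg) {
  con <- file(path, "w")
  writeLines(provenance_header(stage, cfg), con)
  close(con)
  suppressWarnings(utils::write.table(
    format_num_df(df), path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  invisible(path)
}

format_num_df <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !all(df[[j]] == round(df[[j]]), na.rm = TRUE)) {
      df[[j]] <- sprintf("%.6g", df[[j]])
    }
  }
  df
}

#' Run the full cross-species pipeline
#'
#' Executes the stages in dependency order on simulated or supplied data:
#' QC and normalization, high-resolution clustering, reciprocal
#' classification similarity, OCC assignment/merging/filtering, expression
#' presence-absence calling, conservation scoring, marker detection, and
#' marker evaluation. Every output TSV carries a provenance header (stage,
#' seed, config hash); re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param cfg a `run_config` (or YAML path)
#' @param out_dir output directory
#' @return (invisibly) a list with the in-memory stage results
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = tempfile("run")) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  phylo <- if (!is.null(cfg$input$tree)) read_phylogeny(cfg$input$tree)
           else default_phylogeny()

  truth <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sc <- sim_config(phylogeny = phylo, n_genes = cfg$simulate$n_genes,
                     n_cells_per_species = cfg$simulate$n_cells_per_species,
                     divergence_sigma = cfg$simulate$divergence_sigma,
                     switch_rate = cfg$simulate$switch_rate,
                     n_markers_per_type = cfg$simulate$n_markers_per_type,
                     n_clones = cfg$simulate$n_clones, seed = cfg$seed)
    sim <- simulate_experiment(sc)
    datasets <- sim$datasets
    truth <- sim$truth
  } else {
    if (is.null(cfg$input$paths)) stop("input$paths required when not simulating")
    datasets <- purrr::imap(cfg$input$paths, function(p, sp) read_dataset(p, sp))
  }

  datasets <- lapply(datasets, qc_filter, min_genes = cfg$qc$min_genes,
                     max_mito = cfg$qc$max_mito)
  datasets <- lapply(datasets, lognormalize, scale = cfg$normalize$scale)

  datasets <- purrr::imap(datasets, function(d, sp) {
    cluster_hrc(d, resolution = cfg$hrc$resolution, n_pcs = cfg$hrc$n_pcs,
                k = cfg$hrc$k, n_hvg = cfg$hrc$n_hvg, seed = cfg$seed)
  })
  sim_mat <- reciprocal_similarity(
    datasets, split_frac = cfg$match$split_frac,
    n_markers_per_pair = cfg$match$n_markers_per_pair, seed = cfg$seed)
  write_stage_tsv(as.data.frame(sim_mat$values) |>
                    tibble::rownames_to_column("hrc"),
                  file.path(out_dir, "similarity.tsv"), "match", cfg)

  n_occ <- cfg$match$n_occ
  if (is.null(n_occ)) stop("match$n_occ is a required user choice; inspect ",
                           "the dendrogram (occ_dendrogram) to pick it")
  occ <- assign_occ(sim_mat, n_occ)
  ape::write.tree(ape::as.phylo(occ$hclust),
                  file.path(out_dir, "dendrogram.nwk"))
  occ <- merge_occ_pseudobulk(datasets, occ, cut_height = cfg$match$cut_height)
  occ <- filter_occ(occ, cfg$match$min_cells, cfg$match$min_species)
  write_stage_tsv(occ$mapping, file.path(out_dir, "occ_assignment.tsv"),
                  "match", cfg)
  datasets <- apply_occ_labels(datasets, occ)
  datasets_lab <- lapply(datasets, function(d) {
    subset_cells(d, d$annotation$cell_id[!is.na(d$annotation$cell_type)])
  })

  called <- lapply(datasets_lab, filter_for_calling,
                   min_nonzero_frac = cfg$call$min_nonzero_frac,
                   mad_k = cfg$call$mad_k)
  called <- downsample_equal(called, cfg$call$n_downsample, seed = cfg$seed)
  stats <- dplyr::bind_rows(lapply(called, fit_gene_stats)) |>
    putative_status(cfg$call$detect_q, cfg$call$reliable_q)
  shared_ct <- Reduce(intersect, lapply(called, function(d)
    unique(d$annotation$cell_type)))
  thr <- fit_detection_threshold(
    dplyr::filter(stats, .data$cell_type %in% shared_ct), cfg$call$prob_cut)
  calls <- call_expressed(dplyr::filter(stats, .data$cell_type %in% shared_ct),
                          thr)
  write_stage_tsv(stats, file.path(out_dir, "detection_stats.tsv"), "call", cfg)
  write_stage_tsv(thr$per_species, file.path(out_dir, "thresholds.tsv"),
                  "call", cfg)
  write_stage_tsv(calls, file.path(out_dir, "calls.tsv"), "call", cfg)

  cons <- conservation_score(calls, phylo)
  write_stage_tsv(cons, file.path(out_dir, "conservation.tsv"), "conserve", cfg)

  minput <- prepare_marker_input(datasets_lab, shared_ct, seed = cfg$seed)
  mtab <- marker_tests(minput, min_cells = cfg$markers$min_cells,
                       max_cells = cfg$markers$max_cells, seed = cfg$seed) |>
    call_and_rank_markers(thr, cfg$markers$alpha_adj, cfg$markers$min_logfc,
                          cfg$markers$min_delta)
  write_stage_tsv(mtab, file.path(out_dir, "markers.tsv"), "markers", cfg)

  ranked <- split(mtab$gene, list(mtab$unit, mtab$cell_type), drop = TRUE)
  units <- unique(mtab$unit)
  rbo_rows <- list()
  for (ct in unique(mtab$cell_type)) {
    for (i in seq_along(units)) for (j in seq_along(units)) {
      if (i >= j) next
      la <- ranked[[paste(units[i], ct, sep = ".")]]
      lb <- ranked[[paste(units[j], ct, sep = ".")]]
      if (is.null(la) || is.null(lb) || !length(la) || !length(lb)) next
      rbo_rows[[paste(ct, i, j)]] <- tibble::tibble(
        cell_type = ct, unit_a = units[i], unit_b = units[j],
        rbo = rbo(utils::head(la, cfg$evaluate$top_k),
                  utils::head(lb, cfg$evaluate$top_k),
                  p = cfg$evaluate$rbo_p, depth = cfg$evaluate$rbo_depth))
    }
  }
  rbo_tab <- dplyr::bind_rows(rbo_rows)
  if (nrow(rbo_tab)) {
    write_stage_tsv(rbo_tab, file.path(out_dir, "rbo.tsv"), "evaluate", cfg)
  }

  train_sp <- names(minput)[1]
  marker_lists <- split(mtab$gene[mtab$unit == train_sp],
                        mtab$cell_type[mtab$unit == train_sp])
  f1c <- NULL
  if (length(marker_lists)) {
    f1c <- knn_marker_eval(minput[[train_sp]], minput[-1], marker_lists,
                           m_range = seq_len(cfg$evaluate$m_max),
                           k = cfg$evaluate$k, n_boot = cfg$evaluate$n_boot,
                           seed = cfg$seed)
    write_stage_tsv(f1c, file.path(out_dir, "f1_curve.tsv"), "evaluate", cfg)
  }

  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_echo.yaml"))
  invisible(list(datasets = datasets_lab, truth = truth, similarity = sim_mat,
                 occ = occ, stats = stats, thresholds = thr, calls = calls,
                 conservation = cons, markers = mtab, rbo = rbo_tab,
                 f1 = f1c, out_dir = out_dir))
}

#' Dendrogram and silhouette diagnostics for choosing the OCC count
#'
#' Advisory outputs replacing the interactive inspection: the average-
#' linkage tree over HRCs and, for each candidate number of groups, the
#' mean silhouette width of the cut.
#'
#' @param sim a [reciprocal_similarity()] result
#' @param k_range candidate group counts
#' @return list(hclust, silhouette = tibble(k, mean_sil))
#' @export
occ_dendrogram <- function(sim, k_range = 2:15) {
  d <- 1 - sim$values
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  k_range <- k_range[k_range < nrow(d)]
  sil <- vapply(k_range, function(k) {
    grp <- stats::cutree(hc, k = k)
    mean(silhouette_widths(d, grp))
  }, numeric(1))
  list(hclust = hc, silhouette = tibble::tibble(k = k_range, mean_sil = sil))
}

silhouette_widths <- function(d, grp) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- grp == grp[i]; own[i] <- FALSE
    if (!any(own)) return(0)  # singleton clusters score 0 by convention
    a <- mean(d[i, own])
    bs <- vapply(setdiff(unique(grp), grp[i]), function(g)
      mean(d[i, grp == g]), numeric(1))
    if (!length(bs)) return(0)
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}
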