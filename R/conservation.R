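#' Cell type specificity of expression
#'
#' Number of (shared) cell types in which a gene is called expressed in the
#' given species; with 7 shared cell types the score is maximally 7.
#'
#' @param calls an [expression_calls()] tibble
#' @param species species name
#' @return tibble: gene, specificity
#' @export
specificity <- function(calls, species) {
  if (!species %in% calls$species) stop("unknown species: ", species)
  calls |>
    dplyr::filter(.data$species == !!species) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(specificity = sum(.data$call), .groups = "drop")
}

#' Branches on which expression is inferred
#'
#' For one gene in one cell type, a terminal branch is included iff that
#' species' call is 1; the single internal branch of the quartet is
#' included iff at least one species of each clade calls the gene expressed.
#'
#' @param calls_vec named binary vector of calls, one per species (names =
#'   phylogeny leaves)
#' @param phylo a [scaled_phylogeny()]
#' @return character vector of branch names (leaf names and/or "internal")
#' @export
infer_branch_expression <- function(calls_vec, phylo) {
  stopifnot(inherits(phylo, "scaled_phylogeny"))
  if (!setequal(names(calls_vec), phylo$leaves)) {
    stop("calls must be named by the phylogeny's leaves")
  }
  on <- names(calls_vec)[calls_vec == 1]
  br <- on
  if (any(phylo$clades[[1]] %in% on) && any(phylo$clades[[2]] %in% on)) {
    br <- c(br, "internal")
  }
  br
}

# sum of scaled branch lengths for a set of branch names
branch_length_sum <- function(branches, phylo) {
  sum(phylo$terminal_bl[setdiff(branches, "internal")]) +
    if ("internal" %in% branches) phylo$internal_bl else 0
}

#' Phylogenetically weighted expression conservation score
#'
#' For each gene, averages over the cell types in which the gene is detected
#' (in at least one species) the summed scaled branch lengths on which
#' expression is inferred ([infer_branch_expression()]):
#' `score = (1/N_ct) * sum_ct sum_{b in detected} bl`. Because branch
#' lengths total 1, the score lies in (0, 1]; it attains 1 iff every
#' detected cell type is detected in all four species, and its minimum is
#' the smallest terminal branch length (a gene seen only in one cell type
#' of one shortest-branch species). Genes detected nowhere (N_ct = 0) get
#' an undefined (NA) score.
#'
#' @param calls an [expression_calls()] tibble covering all 4 species
#' @param phylo a [scaled_phylogeny()]
#' @return a `conservation_record` tibble: gene, n_ct, score, and one
#'   `specificity_<species>` column per species
#' @export
conservation_score <- function(calls, phylo) {
  stopifnot(inherits(phylo, "scaled_phylogeny"))
  sp <- sort(unique(calls$species))
  missing_sp <- setdiff(sp, phylo$leaves)
  if (length(missing_sp)) {
    stop("species not in phylogeny: ", paste(missing_sp, collapse = ", "))
  }
  wide <- calls |>
    dplyr::select("gene", "cell_type", "species", "call") |>
    tidyr::pivot_wider(names_from = "species", values_from = "call",
                       values_fill = 0L)
  present <- intersect(phylo$leaves, names(wide))
  cl1 <- intersect(phylo$clades[[1]], present)
  cl2 <- intersect(phylo$clades[[2]], present)
  m <- as.matrix(wide[, present, drop = FALSE])
  term_bl <- phylo$terminal_bl[present]
  bl_sum <- drop(m %*% term_bl) +
    phylo$internal_bl *
    (rowSums(m[, cl1, drop = FALSE]) > 0 & rowSums(m[, cl2, drop = FALSE]) > 0)
  detected <- rowSums(m) > 0

  per_ct <- tibble::tibble(gene = wide$gene, detected = detected,
                           bl = bl_sum)
  rec <- per_ct |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_ct = sum(.data$detected),
                     score = ifelse(sum(.data$detected) > 0,
                                    sum(.data$bl[.data$detected]) /
                                      sum(.data$detected), NA_real_),
                     .groups = "drop")
  for (s in present) {
    spec <- specificity(calls, s)
    rec[[paste0("specificity_", s)]] <-
      spec$specificity[match(rec$gene, spec$gene)]
  }
  class(rec) <- c("conservation_record", class(rec))
  rec
}

#' Join a per-gene sequence-constraint table
#'
#' Left-joins an external per-gene annotation (e.g. the fraction of CDS
#' bases under strong sequence constraint) onto conservation records.
#' Unmatched genes get missing values; the match rate is reported.
#'
#' @param records a [conservation_score()] tibble (or any tibble with `gene`)
#' @param table data frame (or TSV path) with a `gene` column plus numeric
#'   columns
#' @return the joined tibble
#' @export
join_constraint_table <- function(records, table) {
  if (is.character(table) && length(table) == 1) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  if (!"gene" %in% names(table)) stop("constraint table needs a 'gene' column")
  table <- tibble::as_tibble(table)
  out <- dplyr::left_join(records, table, by = "gene")
  rate <- mean(records$gene %in% table$gene)
  message(sprintf("constraint table match rate: %.1f%% (%d/%d genes)",
                  100 * rate, sum(records$gene %in% table$gene),
                  nrow(records)))
  out
}

#' Expression-matched gene sampling across specificity bins
#'
#' Control analysis utility: matches genes across specificity bins by mean
#' expression (stratified nearest-mean matching without replacement on the
#' log scale, restricted to common support by a caliper), so that
#' conservation comparisons between bins are not confounded by expression
#' level. Reference genes come from the smallest bin; a reference gene is
#' kept only if every other bin offers a match within `caliper` log units,
#' so all retained bins have equal size and closely matched means.
#'
#' @param records tibble with `gene` and a specificity column
#' @param mean_expr named numeric: mean expression per gene (positive)
#' @param bin_col name of the specificity column (default the first
#'   `specificity_*` column)
#' @param caliper maximal log-expression distance for an acceptable match
#'   (default 0.2)
#' @param seed sampling seed (order of ties)
#' @return tibble of matched genes: gene, bin, mean_expr
#' @export
match_expression_bins <- function(records, mean_expr, bin_col = NULL,
                                  caliper = 0.2, seed = 1L) {
  if (is.null(bin_col)) {
    bin_col <- grep("^specificity_", names(records), value = TRUE)[1]
  }
  if (is.na(bin_col) || !bin_col %in% names(records)) {
    stop("no specificity column found")
  }
  df <- tibble::tibble(gene = records$gene, bin = records[[bin_col]],
                       mean_expr = unname(mean_expr[records$gene])) |>
    dplyr::filter(!is.na(.data$bin), .data$bin > 0,
                  !is.na(.data$mean_expr), .data$mean_expr > 0)
  df$log_expr <- log(df$mean_expr)
  bins <- split(df, df$bin)
  ref_name <- names(bins)[which.min(vapply(bins, nrow, numeric(1)))]
  ref_bin <- bins[[ref_name]]
  set.seed(seed)
  ref_bin <- ref_bin[order(-ref_bin$log_expr), ]  # extremes matched first
  avail <- lapply(bins, identity)
  kept_ref <- list(); matches <- list()
  for (r in seq_len(nrow(ref_bin))) {
    target <- ref_bin$log_expr[r]
    cand <- lapply(names(bins), function(bn) {
      if (bn == ref_name) return(NULL)
      a <- avail[[bn]]
      i <- which.min(abs(a$log_expr - target))
      if (!length(i) || abs(a$log_expr[i] - target) > caliper) return(NA)
      i
    })
    names(cand) <- names(bins)
    if (any(vapply(cand, function(z) length(z) == 1 && is.na(z), logical(1)))) {
      next  # no common support for this reference gene
    }
    kept_ref[[length(kept_ref) + 1]] <- ref_bin[r, ]
    for (bn in names(bins)) {
      if (bn == ref_name) next
      matches[[length(matches) + 1]] <- avail[[bn]][cand[[bn]], ]
      avail[[bn]] <- avail[[bn]][-cand[[bn]], , drop = FALSE]
    }
  }
  out <- dplyr::bind_rows(c(kept_ref, matches))
  out$log_expr <- NULL
  dplyr::arrange(out, .data$bin, .data$gene)
}
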