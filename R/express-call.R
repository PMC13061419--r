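#' Gene and cell filtering ahead of expression calling
#'
#' Drops genes whose nonzero fraction is below `min_nonzero_frac` in every
#' clone of the dataset (per-clone evaluation, union of survivors), and
#' drops cells whose total UMIs or detected-gene count fall outside
#' median +/- `mad_k` x MAD (MAD scaled by 1.4826) computed within their
#' cell type stratum. A degenerate MAD of 0 keeps the cells equal to the
#' median. Strata with fewer than 5 cells skip the MAD filter.
#'
#' @param ds a [species_dataset()] with `cell_type` annotation
#' @param min_nonzero_frac minimum per-clone nonzero fraction (default 0.01)
#' @param mad_k MAD multiplier (default 3)
#' @return the filtered dataset
#' @export
filter_for_calling <- function(ds, min_nonzero_frac = 0.01, mad_k = 3) {
  stopifnot(inherits(ds, "species_dataset"))
  ann <- ds$annotation
  if (is.null(ann$cell_type)) stop("cell_type annotation required")

  keep_gene <- rep(FALSE, nrow(ds$counts))
  for (cl in unique(ann$clone)) {
    sub <- ds$counts[, ann$clone == cl, drop = FALSE]
    keep_gene <- keep_gene |
      (Matrix::rowSums(sub > 0) / ncol(sub) >= min_nonzero_frac)
  }

  keep_cell <- rep(TRUE, ncol(ds$counts))
  for (ct in unique(ann$cell_type)) {
    idx <- which(ann$cell_type == ct)
    if (length(idx) < 5) {
      warning("stratum '", ct, "' has < 5 cells; MAD filter skipped")
      next
    }
    for (v in c("n_umi", "n_genes")) {
      x <- ann[[v]][idx]
      med <- stats::median(x)
      madv <- stats::mad(x)  # 1.4826 scaling
      keep_cell[idx] <- keep_cell[idx] &
        (if (madv == 0) x == med else abs(x - med) <= mad_k * madv)
    }
  }
  ds <- subset_cells(ds, ann$cell_id[keep_cell])
  ds$counts <- ds$counts[keep_gene, , drop = FALSE]
  if (!is.null(ds$lognorm)) ds$lognorm <- ds$lognorm[keep_gene, , drop = FALSE]
  ds
}

#' Downsample species to equal cell numbers
#'
#' Samples `n_per_species` cells from each dataset while preserving the
#' original cell type proportions via largest-remainder apportionment. If a
#' species has fewer cells, `n` is lowered to the minimum across species.
#'
#' @param datasets named list of [species_dataset()] with `cell_type` labels
#' @param n_per_species target cells per species (default 18800)
#' @param seed sampling seed
#' @return the downsampled datasets
#' @export
downsample_equal <- function(datasets, n_per_species = 18800, seed = 1L) {
  sizes <- vapply(datasets, function(d) ncol(d$counts), numeric(1))
  n <- min(n_per_species, sizes)
  if (n < n_per_species) {
    message("n_per_species lowered to ", n, " (smallest species)")
  }
  set.seed(seed)
  lapply(datasets, function(d) {
    ann <- d$annotation
    tab <- table(ann$cell_type)
    take <- largest_remainder(as.numeric(tab) / sum(tab), n)
    names(take) <- names(tab)
    ids <- unlist(lapply(names(tab), function(ct) {
      pool <- ann$cell_id[ann$cell_type == ct]
      sample(pool, min(take[[ct]], length(pool)))
    }), use.names = FALSE)
    subset_cells(d, ann$cell_id[ann$cell_id %in% ids])
  })
}

# Fisher-scoring fit of a per-cell-type NB log-mean with library-size
# offset and fixed dispersion theta. Returns list(beta, se_beta).
nb_group_mean <- function(y, off, theta, tol = 1e-8, max_iter = 50) {
  if (sum(y) == 0) return(list(beta = -Inf, se = Inf))
  beta <- log(sum(y) / sum(exp(off)))  # Poisson MLE init
  for (it in seq_len(max_iter)) {
    mu <- exp(beta + off)
    w <- 1 + mu / theta
    U <- sum((y - mu) / w)
    I <- sum(mu / w)
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  mu <- exp(beta + off)
  I <- sum(mu / (1 + mu / theta))
  list(beta = beta, se = 1 / sqrt(I))
}

#' Per-gene negative-binomial detection statistics
#'
#' For every gene, fits an NB regression with cell type as the only
#' covariate and a log library-size offset (scaled to the mean depth, so
#' fitted means are on the average-cell scale): one dispersion `theta` per
#' gene (maximum likelihood given the fitted means), a mean `mu` and its
#' standard error per cell type from the GLM information, plus the raw
#' detection fraction `f` (share of cells with a nonzero count).
#'
#' @param ds a [species_dataset()] with `cell_type` annotation; every cell
#'   type needs at least 2 cells
#' @param offset `"depth"` (log library size relative to the mean depth,
#'   the default) or `"none"` (constant offset; appropriate when library
#'   sizes are uninformative, e.g. few-gene fixtures)
#' @return a `detection_stats` tibble: gene, cell_type, species, f, mu,
#'   se_mu, theta
#' @export
fit_gene_stats <- function(ds, offset = c("depth", "none")) {
  stopifnot(inherits(ds, "species_dataset"))
  offset <- match.arg(offset)
  ann <- ds$annotation
  if (is.null(ann$cell_type)) stop("cell_type annotation required")
  cts <- sort(unique(ann$cell_type))
  small <- cts[vapply(cts, function(ct) sum(ann$cell_type == ct), numeric(1)) < 2]
  if (length(small)) stop("cell types with < 2 cells: ",
                          paste(small, collapse = ", "))
  off <- if (offset == "depth") log(ann$n_umi / mean(ann$n_umi))
         else rep(0, nrow(ann))
  if (any(!is.finite(off))) stop("cells with zero UMIs: use offset='none' or filter")
  idx_ct <- lapply(cts, function(ct) which(ann$cell_type == ct))
  counts <- ds$counts
  ng <- nrow(counts)
  genes <- rownames(counts)

  res <- vector("list", ng)
  for (g in seq_len(ng)) {
    y <- counts[g, ]
    if (sum(y) == 0) {
      res[[g]] <- tibble::tibble(gene = genes[g], cell_type = cts,
                                 f = 0, mu = 0, se_mu = Inf, theta = NA_real_)
      next
    }
    theta <- 1
    fit <- NULL
    for (round in 1:2) {
      fit <- lapply(idx_ct, function(ix) nb_group_mean(y[ix], off[ix], theta))
      mu_cell <- numeric(length(y))
      for (j in seq_along(cts)) {
        mu_cell[idx_ct[[j]]] <- exp(fit[[j]]$beta + off[idx_ct[[j]]])
      }
      th <- tryCatch(
        suppressWarnings(as.numeric(MASS::theta.ml(y, pmax(mu_cell, 1e-10),
                                                   limit = 25))),
        error = function(e) NA_real_)
      if (!is.na(th) && th > 0) theta <- min(th, 1e6) else break
    }
    mu <- vapply(fit, function(f) exp(f$beta), numeric(1))
    se_b <- vapply(fit, function(f) f$se, numeric(1))
    res[[g]] <- tibble::tibble(
      gene = genes[g], cell_type = cts,
      f = vapply(idx_ct, function(ix) mean(y[ix] > 0), numeric(1)),
      mu = mu, se_mu = mu * se_b, theta = theta)
  }
  out <- dplyr::bind_rows(res)
  out$species <- ds$species
  out <- out[, c("gene", "cell_type", "species", "f", "mu", "se_mu", "theta")]
  class(out) <- c("detection_stats", class(out))
  out
}

#' Putative expression status from quantile rules
#'
#' Per cell type (within each species), a gene is *detectable* if its
#' log mean exceeds the `detect_q` quantile of the log-mean distribution
#' over all genes of that cell type, and *reliably estimable* if
#' `log(se_mu/mu)` is below the `reliable_q` quantile of that distribution.
#' `status = 1` only when both hold, else 0 (including genes with zero or
#' inestimable means). Quantiles are linear-interpolation type 7.
#'
#' @param stats a [fit_gene_stats()] tibble (one or several species)
#' @param detect_q lower quantile on log(mu) (default 0.05)
#' @param reliable_q upper quantile on log(se_mu/mu) (default 0.90)
#' @return the tibble with a binary `status` column
#' @export
putative_status <- function(stats, detect_q = 0.05, reliable_q = 0.90) {
  stats |>
    dplyr::group_by(.data$species, .data$cell_type) |>
    dplyr::mutate(status = {
      lmu <- ifelse(.data$mu > 0, log(.data$mu), NA_real_)
      lrel <- ifelse(.data$mu > 0 & is.finite(.data$se_mu),
                     log(.data$se_mu / .data$mu), NA_real_)
      q_lo <- stats::quantile(lmu, detect_q, na.rm = TRUE, type = 7)
      q_hi <- stats::quantile(lrel, reliable_q, na.rm = TRUE, type = 7)
      as.integer(!is.na(lmu) & !is.na(lrel) & lmu > q_lo & lrel < q_hi)
    }) |>
    dplyr::ungroup()
}

#' Firth-penalized logistic regression (intercept + one covariate)
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l(beta) + 0.5 log det I(beta)` by Newton iteration with the
#' hat-value-adjusted score, guaranteeing finite estimates even under
#' complete separation.
#'
#' @param y binary response vector
#' @param x covariate vector (not constant)
#' @param max_iter Newton iteration cap (default 100)
#' @param tol convergence tolerance on the adjusted score (default 1e-10)
#' @return object of class `firth_fit`: list(a = intercept, b = slope,
#'   converged, iterations, loglik = penalized log-likelihood at optimum)
#' @export
firth_logistic <- function(y, x, max_iter = 100, tol = 1e-10) {
  y <- as.numeric(y)
  if (length(y) != length(x) || length(y) < 2) stop("need >= 2 paired observations")
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (stats::sd(x) == 0) stop("x is constant")
  X <- cbind(1, x)
  beta <- c(0, 0)
  penll <- function(b) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    info <- crossprod(X, X * W)
    lse <- ifelse(eta > 30, eta, log1p(exp(eta)))  # stable log(1 + e^eta)
    sum(y * eta - lse) + 0.5 * determinant(info)$modulus
  }
  ll_old <- penll(beta)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    info <- crossprod(X, X * W)
    XW <- X * sqrt(W)
    h <- rowSums((XW %*% solve(info)) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    step <- solve(info, U)
    # step-halving on the penalized likelihood
    for (s in 0:10) {
      cand <- beta + step / 2^s
      ll_new <- penll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    if (max(abs(cand - beta)) < tol) {
      beta <- cand; ll_old <- penll(beta); converged <- TRUE; break
    }
    beta <- cand
    ll_old <- ll_new
  }
  structure(list(a = beta[1], b = beta[2], converged = converged,
                 iterations = it, loglik = as.numeric(ll_old)),
            class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("<firth_fit> a = %.6g, b = %.6g (%s, %d iter)\n", x$a, x$b,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy firth_fit
#' @export
tidy.firth_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$a, x$b))
}

#' @method glance firth_fit
#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations)
}

#' Fit per-cell-type detection thresholds
#'
#' Per cell type and species, regresses the putative status on the
#' detection fraction with [firth_logistic()] and solves the fitted curve at
#' `prob_cut` for the detection fraction: `f* = (logit(prob_cut) - a)/b`,
#' the minimal detection needed to call a gene expressed. Thresholds are
#' harmonized per cell type as the maximum across species.
#'
#' @param stats a [putative_status()] tibble with `status`
#' @param prob_cut probability at which the threshold is solved (default 0.5)
#' @return a `threshold_table`: list with `per_species` tibble (species,
#'   cell_type, a, b, converged, threshold) and `harmonized` tibble
#'   (cell_type, threshold)
#' @export
fit_detection_threshold <- function(stats, prob_cut = 0.5) {
  if (is.null(stats$status)) stop("run putative_status() first")
  per <- stats |>
    dplyr::group_by(.data$species, .data$cell_type) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) {
      fit <- firth_logistic(g$status, g$f)
      if (fit$b <= 0) {
        stop("detection not increasing in f for ", g$species[1], "/",
             g$cell_type[1], ": degenerate input")
      }
      fstar <- (stats::qlogis(prob_cut) - fit$a) / fit$b
      if (fstar <= 0 || fstar >= 1) {
        warning("threshold outside (0,1) clipped for ", g$species[1],
                "/", g$cell_type[1])
        fstar <- min(max(fstar, 1e-6), 1 - 1e-6)
      }
      tibble::tibble(species = g$species[1], cell_type = g$cell_type[1],
                     a = fit$a, b = fit$b, converged = fit$converged,
                     threshold = fstar)
    })
  harm <- per |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(threshold = max(.data$threshold), .groups = "drop")
  structure(list(per_species = per, harmonized = harm),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("<threshold_table> harmonized thresholds (max over species):\n")
  print(as.data.frame(x$harmonized), row.names = FALSE)
  invisible(x)
}

#' Binary expression calls
#'
#' A gene is called expressed in a cell type and species iff its detection
#' fraction is at or above the cell type's harmonized threshold
#' (inclusive boundary).
#'
#' @param stats a detection-stats tibble with `f`
#' @param thresholds a [fit_detection_threshold()] result
#' @return an `expression_calls` tibble: gene, cell_type, species, f,
#'   threshold, call
#' @export
call_expressed <- function(stats, thresholds) {
  stopifnot(inherits(thresholds, "threshold_table"))
  out <- stats |>
    dplyr::select("gene", "cell_type", "species", "f") |>
    dplyr::left_join(thresholds$harmonized, by = "cell_type") |>
    dplyr::mutate(call = as.integer(.data$f >= .data$threshold))
  class(out) <- c("expression_calls", class(out))
  out
}

#' Assemble expression calls from a binary tensor
#'
#' Convenience constructor when the binary gene x cell type x species
#' detection pattern is already known (e.g. worked examples or external
#' calls).
#'
#' @param calls a data frame with columns gene, cell_type, species, call
#'   (0/1)
#' @return an `expression_calls` tibble
#' @export
expression_calls <- function(calls) {
  need <- c("gene", "cell_type", "species", "call")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(calls$call %in% c(0, 1))) stop("call must be binary")
  out <- tibble::as_tibble(calls)
  class(out) <- c("expression_calls", class(out))
  out
}
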