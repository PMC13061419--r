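#' Scaled quartet phylogeny
#'
#' A four-species unrooted tree with four terminal branches and one internal
#' branch, rescaled so that the five branch lengths sum to 1. The internal
#' branch splits the leaves into two clades of two; for the packaged default
#' these are the great apes (human, orangutan) and the macaques (cynomolgus,
#' rhesus). The scaled branch lengths drive both the expression conservation
#' score and the divergence model of the simulator.
#'
#' @param terminal_bl named numeric of length 4: branch length per leaf
#' @param internal_bl positive internal branch length
#' @param clades list of two character vectors of two leaf names each,
#'   giving the bipartition induced by the internal branch
#' @return a `scaled_phylogeny`: list with `leaves`, `terminal_bl` (rescaled),
#'   `internal_bl` (rescaled), `clades`, and `input_total` (the pre-scaling
#'   total length)
#' @export
scaled_phylogeny <- function(terminal_bl, internal_bl, clades) {
  if (length(terminal_bl) != 4 || is.null(names(terminal_bl))) {
    stop("terminal_bl must be a named numeric of length 4")
  }
  if (length(clades) != 2 || !setequal(unlist(clades), names(terminal_bl)) ||
      any(lengths(clades) != 2)) {
    stop("clades must bipartition the 4 leaves into two pairs")
  }
  bl <- c(terminal_bl, internal_bl)
  if (any(!is.finite(bl)) || any(bl <= 0)) {
    stop("all five branch lengths must be finite and > 0")
  }
  total <- sum(bl)
  structure(
    list(leaves = names(terminal_bl),
         terminal_bl = terminal_bl / total,
         internal_bl = internal_bl / total,
         clades = lapply(clades, as.character),
         input_total = total),
    class = "scaled_phylogeny"
  )
}

#' @export
print.scaled_phylogeny <- function(x, ...) {
  cat("<scaled_phylogeny> quartet, total branch length 1\n")
  cat("  clades: (", paste(x$clades[[1]], collapse = ", "), ") | (",
      paste(x$clades[[2]], collapse = ", "), ")\n", sep = "")
  cat("  terminal:", paste(sprintf("%s=%.4g", names(x$terminal_bl),
                                   x$terminal_bl), collapse = ", "),
      sprintf("; internal=%.4g\n", x$internal_bl))
  invisible(x)
}

#' Read and scale a quartet phylogeny from Newick
#'
#' The tree must have exactly 4 leaves, branch lengths on every edge, and one
#' internal branch (i.e. it is a resolved quartet, not a star). Branch
#' lengths are rescaled to sum to 1; the clade bipartition is inferred from
#' the topology.
#'
#' @param path Newick file
#' @return a [scaled_phylogeny()]
#' @export
read_phylogeny <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (length(tr$tip.label) != 4) {
    stop("phylogeny must have exactly 4 leaves, found ", length(tr$tip.label))
  }
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge)) {
    stop("all branches must carry lengths")
  }
  tr <- ape::unroot(tr)
  ntip <- 4L
  is_terminal <- tr$edge[, 2] <= ntip
  if (any(tr$edge.length[is_terminal] <= 0)) stop("zero-length terminal branch")
  internal_edges <- which(!is_terminal)
  # a star quartet has a single internal node and no internal edge
  if (length(internal_edges) != 1) {
    stop("phylogeny must be a resolved quartet with exactly one internal branch")
  }
  internal_bl <- tr$edge.length[internal_edges]
  if (internal_bl <= 0) stop("zero-length internal branch")
  terminal_bl <- stats::setNames(tr$edge.length[is_terminal][
    order(tr$edge[is_terminal, 2])], tr$tip.label)
  # clade = tips descending from the child node of the internal edge
  child <- tr$edge[internal_edges, 2]
  side1 <- tr$tip.label[phangorn_free_descendants(tr, child)]
  clades <- list(side1, setdiff(tr$tip.label, side1))
  scaled_phylogeny(terminal_bl, internal_bl, clades)
}

# tips below `node` in an (unrooted) ape tree, following edges away from
# the internal edge's parent
phangorn_free_descendants <- function(tr, node) {
  ntip <- length(tr$tip.label)
  out <- integer(0)
  stack <- tr$edge[tr$edge[, 1] == node, 2]
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, tr$edge[tr$edge[, 1] == v, 2])
  }
  sort(out)
}

#' The packaged default quartet phylogeny
#'
#' Scaled quartet with macaque terminal branches of 0.075 each (cynomolgus,
#' rhesus), human 0.20, orangutan 0.25 and internal branch 0.40; total 1.
#' Fully configurable by supplying any resolved quartet via
#' [read_phylogeny()].
#'
#' @return a [scaled_phylogeny()]
#' @export
default_phylogeny <- function() {
  scaled_phylogeny(
    terminal_bl = c(human = 0.20, orangutan = 0.25,
                    cynomolgus = 0.075, rhesus = 0.075),
    internal_bl = 0.40,
    clades = list(c("human", "orangutan"), c("cynomolgus", "rhesus"))
  )
}

#' Write a scaled phylogeny as Newick
#'
#' @param phylo a [scaled_phylogeny()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_phylogeny <- function(phylo, path) {
  c1 <- phylo$clades[[1]]; c2 <- phylo$clades[[2]]
  bl <- phylo$terminal_bl
  nwk <- sprintf("((%s:%.10g,%s:%.10g):%.10g,%s:%.10g,%s:%.10g);",
                 c1[1], bl[[c1[1]]], c1[2], bl[[c1[2]]], phylo$internal_bl,
                 c2[1], bl[[c2[1]]], c2[2], bl[[c2[2]]])
  writeLines(nwk, path)
  invisible(path)
}
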