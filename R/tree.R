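#' Simulate an ultrametric birth-death phylogeny
#'
#' Constant-rate birth-death simulation conditioned on the number of extant
#' tips, producing a rooted ultrametric tree in time-like units (My-like).
#' Trees are consumed by every downstream stage; they stand in for the
#' time-calibrated consensus trees a real study would supply.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0).
#' @param seed integer seed; the call is a pure function of its arguments.
#' @return an [ape::phylo] rooted ultrametric tree with `n_tips` tips.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  if (length(n_tips) != 1L || n_tips < 2L || n_tips != round(n_tips)) {
    stop("n_tips must be a single integer >= 2")
  }
  if (death < 0) stop("death rate must be >= 0")
  if (birth <= death) stop("birth rate must exceed death rate")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n = n_tips, birth = birth, death = death)
  tr$tip.label <- sprintf("t%d", seq_len(n_tips))
  tr
}

#' Read a rooted tree from a Newick file
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("malformed Newick in '", path, "': ", conditionMessage(e))
  })
  if (is.null(tr)) stop("malformed Newick in '", path, "'")
  if (is.null(tr$edge.length)) {
    stop("tree in '", path, "' has no branch lengths")
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Terminal branch length of every tip (species age)
#'
#' Species age is operationalised as the length of the branch leading to
#' each tip of the (consensus) tree.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return named numeric vector, one age per tip label.
#' @export
species_ages <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tip_edges <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
  ages <- tree$edge.length[tip_edges]
  names(ages) <- tree$tip.label
  if (any(ages <= 0)) {
    warning("zero-length terminal branch(es): ",
            paste(names(ages)[ages <= 0], collapse = ", "))
  }
  ages
}

# Edge indices of the subtree rooted at the child of `edge_idx`
# (the edge itself included: "a target branch plus its descendants").
descendant_edges <- function(tree, edge_idx, include_self = TRUE) {
  child <- tree$edge[edge_idx, 2]
  out <- integer(0)
  if (child > ape::Ntip(tree)) {
    todo <- child
    while (length(todo)) {
      rows <- which(tree$edge[, 1] %in% todo)
      out <- c(out, rows)
      todo <- tree$edge[rows, 2]
      todo <- todo[todo > ape::Ntip(tree)]
    }
  }
  if (include_self) out <- c(edge_idx, out)
  sort(unique(out))
}

# List of covered-edge sets for all edges (used by clade-scope scalars).
all_descendant_edge_sets <- function(tree, include_self = TRUE) {
  lapply(seq_len(nrow(tree$edge)), function(e) {
    descendant_edges(tree, e, include_self = include_self)
  })
}

# Node height above the tips on an ultrametric tree (clade age of the
# node's crown group).
node_height <- function(tree, node) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths[node]
}
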