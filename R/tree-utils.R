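# Dated-tree utilities. Trees are ape "phylo" objects, ultrametric, branch
# lengths in Ma. "Depth" = Ma since the root; "time" = Ma before present.

tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Node times in Ma before present
#'
#' @param tree an ultrametric `phylo` object with branch lengths in Ma.
#' @return numeric vector over all nodes (tips first, then internal nodes,
#'   in `ape` node order): time before present of each node.
#' @export
node_times <- function(tree) {
  tree_height(tree) - ape::node.depth.edgelength(tree)
}

# Parent node id for every node (0 for the root).
parent_vec <- function(tree) {
  np <- ape::Ntip(tree) + tree$Nnode
  p <- integer(np)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

assert_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  if (h <= 0) stop("tree has zero height")
  if (max(abs(d - h)) / h > tol) {
    stop("tree is not ultrametric within relative tolerance ", tol)
  }
  invisible(tree)
}

#' Stem age of a tip
#'
#' The stem age of a genus is the time of the branching event separating it
#' from its sister lineage, i.e. the node time of the tip's parent.
#'
#' @param tree ultrametric `phylo`, branch lengths in Ma.
#' @param tip character vector of tip labels.
#' @return numeric vector of stem ages in Ma before present.
#' @export
stem_age <- function(tree, tip) {
  if (ape::Ntip(tree) < 2) stop("tree has a single tip: no stem age defined")
  idx <- match(tip, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip(s): ", paste(tip[is.na(idx)], collapse = ", "))
  }
  nt <- node_times(tree)
  p <- parent_vec(tree)
  nt[p[idx]]
}

#' Attach unsampled genera at family or order crown nodes
#'
#' Genera absent from the molecular dataset are added as new children of the
#' crown node of their family, or of their order when the family has fewer
#' than two sampled members, with pendant branch length equal to the crown
#' age. This creates polytomies; see [resolve_polytomies()].
#'
#' @param tree ultrametric `phylo` over sampled genera.
#' @param additions data.frame with columns `genus`, `family`, `order`.
#' @param taxonomy data.frame with columns `genus`, `family`, `order`
#'   covering the tips of `tree`.
#' @return an ultrametric `phylo` containing the added tips; all
#'   pre-existing branch lengths are unchanged.
#' @export
attach_unsampled <- function(tree, additions, taxonomy) {
  if (nrow(additions) == 0) return(tree)
  stopifnot(all(c("genus", "family", "order") %in% names(additions)),
            all(c("genus", "family", "order") %in% names(taxonomy)))
  for (i in seq_len(nrow(additions))) {
    g <- additions$genus[i]
    node <- crown_node(tree, taxonomy, additions$family[i])
    if (is.na(node)) node <- crown_node(tree, taxonomy, additions$order[i],
                                        rank = "order")
    if (is.na(node)) {
      stop("no crown node for genus ", g, ": family '", additions$family[i],
           "' and order '", additions$order[i],
           "' each have fewer than two sampled members")
    }
    crown_age <- node_times(tree)[node]
    tree <- phytools::bind.tip(tree, g, edge.length = crown_age,
                               where = node, position = 0)
  }
  tree
}

# Crown node (MRCA) of the sampled members of a family or order; NA when the
# clade has fewer than two sampled tips.
crown_node <- function(tree, taxonomy, clade, rank = "family") {
  if (is.na(clade) || !nzchar(clade)) return(NA_integer_)
  members <- taxonomy$genus[taxonomy[[rank]] == clade]
  tips <- intersect(members, tree$tip.label)
  if (length(tips) < 2) return(NA_integer_)
  ape::getMRCA(tree, tips)
}

#' Stochastically resolve polytomies in a dated tree
#'
#' Each polytomy of k children is replaced by a random binary subtree built
#' by sequential random joins (coalescent-style): two child lineages are
#' picked uniformly at random and joined at a node whose time is drawn
#' uniformly between the time of the older of the two and the polytomy
#' node's time. The result is strictly binary and ultrametric; tip set, tip
#' ages, and all pre-existing node times are preserved. The same seed yields
#' an identical tree.
#'
#' @param tree ultrametric `phylo`, possibly with polytomies.
#' @param seed integer seed controlling both topology and node-time draws.
#' @return a binary ultrametric `phylo`.
#' @export
resolve_polytomies <- function(tree, seed) {
  if (ape::is.binary(tree)) return(tree)
  with_seed(seed, {
    nt <- node_times(tree)
    children <- split(tree$edge[, 2], tree$edge[, 1])
    ntip <- ape::Ntip(tree)
    root <- ntip + 1L

    # Build a newick string, resolving polytomies on the fly. Each lineage is
    # a (string, time) pair; joining two lineages at time u gives branch
    # lengths u - time.
    build <- function(node) {
      if (node <= ntip) return(list(s = tree$tip.label[node], t = nt[node]))
      kids <- lapply(children[[as.character(node)]], build)
      while (length(kids) > 2L) {
        pick <- sample.int(length(kids), 2L)
        a <- kids[[pick[1]]]; b <- kids[[pick[2]]]
        lo <- max(a$t, b$t)
        u <- runif(1, lo, nt[node])
        joined <- list(
          s = sprintf("(%s:%.15g,%s:%.15g)", a$s, u - a$t, b$s, u - b$t),
          t = u)
        kids <- c(kids[-pick], list(joined))
      }
      a <- kids[[1]]; b <- kids[[2]]
      list(s = sprintf("(%s:%.15g,%s:%.15g)", a$s, nt[node] - a$t,
                       b$s, nt[node] - b$t),
           t = nt[node])
    }
    ape::read.tree(text = paste0(build(root)$s, ";"))
  })
}

# Evaluate an expression under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
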