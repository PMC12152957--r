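# The five connectivity-only structural descriptors of a (BN)1-substituted
# cata-condensed polybenzenoid: ring count, longest linear stretch,
# inner/outer placement of each heteroatom, shortest-path carbon count
# between B and N, and the number of disrupted rings.  All are defined on the
# molecular graph and the dualist tree alone; no geometry or quantum
# chemistry is involved.

#' Longest linear stretch of a scaffold
#'
#' Number of linearly annulated tricyclic (anthracene-like) units in the
#' longest straight run of the dualist tree.  A middle ring is linearly
#' annulated when its two fusion bonds occupy opposite (para) hexagon edges,
#' i.e. consecutive dualist edges keep the same lattice direction.  A straight
#' run of \eqn{k} rings contains \eqn{k - 2} such units, hence
#' `n_LL = max(0, k_max - 2)`; `n_LL = n_rings - 2` only for a fully linear
#' scaffold, and any scaffold with fewer than three rings has `n_LL = 0`.
#'
#' @param tree a [dualist_tree()].
#' @return A non-negative integer.
#' @export
compute_n_LL <- function(tree) {
  stopifnot(inherits(tree, "dualist_tree"))
  n <- tree$n_rings
  if (n < 3) return(0L)
  longest <- 1L
  for (v in seq_len(n)) {
    for (d in 0:5) {
      # walk from v in constant direction d as far as edges allow
      len <- 1L
      cur <- v
      repeat {
        nb <- tree$adj[[cur]]
        nxt <- nb[!is.na(tree$dirmat[cur, nb]) & tree$dirmat[cur, nb] == d]
        if (!length(nxt)) break
        cur <- nxt[1]
        len <- len + 1L
      }
      longest <- max(longest, len)
    }
  }
  max(0L, longest - 2L)
}

#' Inner/outer classification of the substituted positions
#'
#' A heteroatom is *inner* when it sits on a ring-fusion bond (it belongs to
#' two rings and carries no hydrogen; inner boron makes three B--C bonds) and
#' *outer* otherwise.
#'
#' @param graph the parent `mol_graph`.
#' @param b_index,n_index atom indices of the boron and nitrogen positions.
#' @return A named integer vector `c(b_inner = 0/1, n_inner = 0/1)`.
#' @export
classify_inner_outer <- function(graph, b_index, n_index) {
  stopifnot(inherits(graph, "mol_graph"))
  memb <- lengths(graph$ring_membership)
  c(b_inner = as.integer(memb[b_index] == 2L),
    n_inner = as.integer(memb[n_index] == 2L))
}

#' Carbons between B and N along their shortest path
#'
#' The number of atoms strictly between the boron and nitrogen positions on a
#' shortest simple path in the molecular graph (all of which are carbons),
#' i.e. the graph distance minus one.  `n_SP = 0` exactly when B and N share
#' a bond.
#'
#' @inheritParams classify_inner_outer
#' @return A non-negative integer.
#' @export
compute_n_SP <- function(graph, b_index, n_index) {
  stopifnot(inherits(graph, "mol_graph"), b_index != n_index)
  d <- .atom_distances(graph)[b_index, n_index]
  if (!is.finite(d))
    stop("molecular graph is disconnected", call. = FALSE)
  as.integer(d) - 1L
}

# BFS distance matrix between all atoms (cached on the graph's environment
# would be nicer; callers that need many pairs use .atom_distances directly)
.atom_distances <- function(graph) {
  g <- .as_igraph(graph)
  igraph::distances(g)
}

#' Number of disrupted rings
#'
#' Incorporating B or N into a ring disrupts its cyclic (Clar-sextet)
#' delocalization, and every ring on the dualist path between the B-hosting
#' and N-hosting rings is forced into a quinoidal structure as well.  The
#' count is the size of the union of all rings containing B, all rings
#' containing N, and the rings on the shortest dualist-tree path between a
#' B-ring and an N-ring; when a heteroatom is inner (two host rings) the path
#' is minimized over the choice of host ring.  Always between 1 and `n_rings`.
#'
#' @inheritParams classify_inner_outer
#' @return An integer in `[1, n_rings]`.
#' @export
compute_n_DR <- function(graph, b_index, n_index) {
  stopifnot(inherits(graph, "mol_graph"))
  paths <- .ring_paths(graph$tree)
  rb <- graph$ring_membership[[b_index]]
  rn <- graph$ring_membership[[n_index]]
  best <- Inf
  for (i in rb) for (j in rn) {
    u <- base::union(base::union(rb, rn), paths[[i]][[j]])
    best <- min(best, length(u))
  }
  as.integer(best)
}

# vertex sets of the unique tree path between every ring pair
.ring_paths <- function(tree) {
  n <- tree$n_rings
  lapply(seq_len(n), function(src) {
    parent <- rep(NA_integer_, n)
    parent[src] <- 0L
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in tree$adj[[v]]) if (is.na(parent[w])) {
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
    lapply(seq_len(n), function(dst) {
      path <- dst
      while (path[1] != src) path <- c(parent[path[1]], path)
      path
    })
  })
}

#' Feature vector of a single (BN)1 isomer
#'
#' Assembles the five descriptors (six numeric components, since the
#' inner/outer classification is one flag per heteroatom):
#' `(n_rings, n_LL, b_inner, n_inner, n_SP, n_DR)`.
#'
#' @inheritParams classify_inner_outer
#' @return A named integer vector of length 6.
#' @export
featurize <- function(graph, b_index, n_index) {
  io <- classify_inner_outer(graph, b_index, n_index)
  c(n_rings = graph$tree$n_rings,
    n_LL = compute_n_LL(graph$tree),
    io,
    n_SP = compute_n_SP(graph, b_index, n_index),
    n_DR = compute_n_DR(graph, b_index, n_index))
}

#' Feature table for the full isomer space
#'
#' Vectorized featurization of every isomer in an [enumerate_bn_space()]
#' result: per scaffold the atom-distance matrix, ring paths and scaffold
#' descriptors are computed once and reused across all of its isomers.
#'
#' @param space result of [enumerate_bn_space()].
#' @return The `isomers` data frame with feature columns `n_rings`, `n_LL`,
#'   `b_inner`, `n_inner`, `n_SP`, `n_DR` appended.
#' @export
featurize_space <- function(space) {
  stopifnot(is.list(space), !is.null(space$isomers), !is.null(space$graphs))
  iso <- space$isomers
  iso$n_LL <- NA_integer_
  iso$b_inner <- NA_integer_
  iso$n_inner <- NA_integer_
  iso$n_SP <- NA_integer_
  iso$n_DR <- NA_integer_
  for (si in unique(iso$scaffold_index)) {
    rows <- which(iso$scaffold_index == si)
    graph <- space$graphs[[si]]
    tree <- graph$tree
    D <- .atom_distances(graph)
    memb <- lengths(graph$ring_membership)
    paths <- .ring_paths(tree)
    nll <- compute_n_LL(tree)
    b <- iso$b_index[rows]
    nn <- iso$n_index[rows]
    iso$n_LL[rows] <- nll
    iso$b_inner[rows] <- as.integer(memb[b] == 2L)
    iso$n_inner[rows] <- as.integer(memb[nn] == 2L)
    iso$n_SP[rows] <- as.integer(D[cbind(b, nn)]) - 1L
    # disrupted rings: union of host rings plus minimal connecting path
    rm_ <- graph$ring_membership
    iso$n_DR[rows] <- vapply(seq_along(rows), function(k) {
      rb <- rm_[[b[k]]]; rn <- rm_[[nn[k]]]
      best <- Inf
      for (i in rb) for (j in rn)
        best <- min(best, length(base::union(base::union(rb, rn),
                                             paths[[i]][[j]])))
      as.integer(best)
    }, integer(1))
  }
  iso
}

#' Write a feature table as CSV
#'
#' @param features data frame from [featurize_space()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
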