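#' Enumerate unique (BN)1 substitution isomers of a parent scaffold
#'
#' Every ordered pair of distinct carbon positions (boron site, nitrogen site)
#' is a candidate isomer; two placements describe the same molecule exactly
#' when a parent-graph automorphism maps one ordered pair onto the other.
#' Since boron and nitrogen substitution is isoelectronic, hydrogen counts are
#' inherited unchanged from the parent carbons, so the parent automorphism
#' group (which respects hydrogen counts) is the correct symmetry group.  One
#' representative per orbit is returned: the lexicographically smallest
#' (b_index, n_index) image under the group.
#'
#' @param graph an all-carbon `mol_graph` from [build_molecular_graph()].
#' @param group optional precomputed [automorphism_group()] of `graph`.
#' @return A data frame with one row per unique isomer: `b_index`, `n_index`,
#'   `canonical_key`, sorted by (`b_index`, `n_index`).
#' @export
enumerate_bn_isomers <- function(graph, group = NULL) {
  stopifnot(inherits(graph, "mol_graph"))
  if (any(graph$element != "C"))
    stop("parent graph must be all-carbon", call. = FALSE)
  if (is.null(group)) group <- automorphism_group(graph)
  n <- graph$n_atoms

  pairs <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), times = n))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  # canonical image of each ordered pair: lexicographic minimum over the group
  best_b <- rep(n + 1L, nrow(pairs))
  best_n <- rep(n + 1L, nrow(pairs))
  for (p in group) {
    gb <- p[pairs[, 1]]
    gn <- p[pairs[, 2]]
    better <- gb < best_b | (gb == best_b & gn < best_n)
    best_b[better] <- gb[better]
    best_n[better] <- gn[better]
  }
  keep <- pairs[, 1] == best_b & pairs[, 2] == best_n
  out <- data.frame(b_index = pairs[keep, 1],
                    n_index = pairs[keep, 2],
                    canonical_key = paste0(best_b[keep], "_", best_n[keep]))
  out[order(out$b_index, out$n_index), , drop = FALSE]
}

#' Burnside (Cauchy-Frobenius) count of (BN)1 isomer orbits
#'
#' Independent oracle for [enumerate_bn_isomers()]: the number of orbits of
#' ordered pairs of distinct atoms under the automorphism group equals
#' \deqn{\frac{1}{|G|}\sum_{g \in G} f(g)\,(f(g) - 1)}
#' where \eqn{f(g)} is the number of atoms fixed by \eqn{g}.  For naphthalene
#' the order-4 group gives (90 + 0 + 2 + 0) / 4 = 23.
#'
#' @inheritParams enumerate_bn_isomers
#' @return An integer orbit count.
#' @export
orbit_count_burnside <- function(graph, group = NULL) {
  stopifnot(inherits(graph, "mol_graph"))
  if (any(graph$element != "C"))
    stop("parent graph must be all-carbon", call. = FALSE)
  if (is.null(group)) group <- automorphism_group(graph)
  fixed <- vapply(group, function(p) sum(p == seq_along(p)), numeric(1))
  total <- sum(fixed * (fixed - 1))
  stopifnot(total %% length(group) == 0)
  as.integer(total / length(group))
}

#' Enumerate the full (BN)1 isomer space over a set of scaffolds
#'
#' Convenience driver joining [enumerate_scaffolds()],
#' [build_molecular_graph()] and [enumerate_bn_isomers()].  With
#' `max_rings = 6` this generates the complete 23,894-molecule space (57
#' scaffolds).
#'
#' @param scaffolds a list of [dualist_tree()] objects, or a single integer
#'   `max_rings` which is passed to [enumerate_scaffolds()].
#' @return A list with `scaffolds` (the input trees), `graphs` (their
#'   `mol_graph`s), and `isomers`, a data frame with columns `molecule_id`,
#'   `scaffold_code`, `n_rings`, `b_index`, `n_index`, `canonical_key`.
#' @export
enumerate_bn_space <- function(scaffolds) {
  if (is.numeric(scaffolds) && length(scaffolds) == 1)
    scaffolds <- enumerate_scaffolds(scaffolds)
  stopifnot(all(vapply(scaffolds, inherits, logical(1), "dualist_tree")))
  graphs <- lapply(scaffolds, build_molecular_graph)
  tabs <- lapply(seq_along(scaffolds), function(i) {
    iso <- enumerate_bn_isomers(graphs[[i]])
    if (!nrow(iso)) return(NULL)
    data.frame(scaffold_index = i,
               scaffold_code = scaffolds[[i]]$canonical_code,
               n_rings = scaffolds[[i]]$n_rings,
               iso)
  })
  isomers <- do.call(rbind, tabs)
  isomers$molecule_id <- sprintf("bn_%03d_%02d_%02d", isomers$scaffold_index,
                                 isomers$b_index, isomers$n_index)
  rownames(isomers) <- NULL
  list(scaffolds = scaffolds, graphs = graphs,
       isomers = isomers[, c("molecule_id", "scaffold_index", "scaffold_code",
                             "n_rings", "b_index", "n_index",
                             "canonical_key")])
}

#' Write an isomer table to a tab-separated file
#'
#' @param isomers the `isomers` data frame from [enumerate_bn_space()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isomers <- function(isomers, path) {
  utils::write.table(isomers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
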