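#' Dualist-tree representation of a cata-condensed benzenoid scaffold
#'
#' A cata-condensed polybenzenoid hydrocarbon (cc-PBH) is fully described by
#' its dualist graph: one vertex per hexagonal ring, one edge per ring-fusion
#' bond.  For cata-condensed systems the dualist is a tree embedded in the
#' hexagonal lattice.  The embedding is stored as parent pointers plus the
#' lattice direction (0..5, counter-clockwise) of each parent-to-child fusion;
#' cell coordinates are derived from these.  Fusion is defined *only* by tree
#' edges, so helicenes -- scaffolds whose planar embedding forces two
#' non-fused rings to clash or coincide -- are representable and are flagged
#' via [is_helicenic()].
#'
#' @param parent integer vector; `parent[i]` is the index of ring `i`'s parent
#'   in the tree (0 for the root, which must be ring 1).
#' @param dir integer vector of the same length; `dir[i]` is the lattice
#'   direction (0..5) from `parent[i]` to ring `i` (`NA` for the root).
#' @return An object of class `dualist_tree` with elements `n_rings`, `cells`
#'   (axial coordinate matrix), `edges` (two-column matrix, parent then
#'   child), `dirs` (direction per edge), `adj` (adjacency list) and `dirmat`
#'   (direction of every oriented edge).
#' @examples
#' anthracene  <- dualist_tree(c(0, 1, 2), c(NA, 0, 0))
#' phenanthrene <- dualist_tree(c(0, 1, 2), c(NA, 0, 1))
#' canonical_code(anthracene) == canonical_code(phenanthrene)
#' @export
dualist_tree <- function(parent, dir) {
  n <- length(parent)
  stopifnot(n >= 1, length(dir) == n, parent[1] == 0)
  if (n > 1 && any(parent[-1] >= seq_len(n)[-1] | parent[-1] < 1))
    stop("parent pointers must reference earlier rings", call. = FALSE)
  if (n > 1 && any(is.na(dir[-1]) | dir[-1] < 0 | dir[-1] > 5))
    stop("edge directions must be integers in 0..5", call. = FALSE)

  cells <- matrix(0L, n, 2)
  dirmat <- matrix(NA_integer_, n, n)
  adj <- rep(list(integer()), n)
  if (n > 1) {
    for (i in 2:n) {
      p <- parent[i]
      d <- as.integer(dir[i])
      cells[i, ] <- cells[p, ] + .hex_axial[d + 1L, ]
      dirmat[p, i] <- d
      dirmat[i, p] <- (d + 3L) %% 6L
      adj[[p]] <- c(adj[[p]], i)
      adj[[i]] <- c(adj[[i]], p)
    }
  }
  # two fusion bonds on one hexagon may not share an atom: incident
  # directions at any ring must be at least 120 degrees (2 steps) apart
  for (v in seq_len(n)) {
    dd <- dirmat[v, adj[[v]]]
    if (length(dd) > 1) {
      cmb <- utils::combn(dd, 2)
      gap <- pmin((cmb[1, ] - cmb[2, ]) %% 6L, (cmb[2, ] - cmb[1, ]) %% 6L)
      if (any(gap < 2))
        stop("fusion directions at a ring must differ by at least 120 degrees",
             call. = FALSE)
    }
  }
  edges <- if (n > 1) cbind(as.integer(parent[-1]), 2:n) else
    matrix(integer(), 0, 2)
  tree <- structure(
    list(n_rings = n, cells = cells, edges = edges,
         dirs = as.integer(dir[-1]), adj = adj, dirmat = dirmat),
    class = "dualist_tree"
  )
  tree$helicenic <- is_helicenic(tree)
  tree$canonical_code <- canonical_code(tree)
  tree
}

#' @export
print.dualist_tree <- function(x, ...) {
  cat(sprintf("<dualist_tree> %d ring(s)%s\n  code: %s\n",
              x$n_rings, if (x$helicenic) ", helicenic" else "",
              x$canonical_code))
  invisible(x)
}

# rooted AHU-style encoding of the direction-labelled tree under symmetry s
.encode_rooted <- function(adj, dirmat, v, parent, s) {
  kids <- setdiff(adj[[v]], parent)
  if (!length(kids)) return("")
  subs <- vapply(kids, function(k) {
    paste0(.sym_direction(dirmat[v, k], s), "(",
           .encode_rooted(adj, dirmat, k, v, s), ")")
  }, character(1))
  paste0(sort(subs), collapse = "")
}

#' Canonical code of a scaffold
#'
#' Minimum, over all 12 lattice symmetries (6 rotations and 6 reflections;
#' in-plane reflection is the mirror image, so enantiomeric helicenes share a
#' code) and all root choices, of a rooted tree encoding whose edge labels are
#' the symmetry-transformed fusion directions.  Two scaffolds receive equal
#' codes if and only if they are the same constitutional isomer.
#'
#' @param tree a [dualist_tree()].
#' @return A character scalar, stable across runs.
#' @export
canonical_code <- function(tree) {
  stopifnot(inherits(tree, "dualist_tree"))
  n <- tree$n_rings
  best <- NULL
  for (v in seq_len(n)) {
    for (s in 0:11) {
      code <- .encode_rooted(tree$adj, tree$dirmat, v, 0L, s)
      if (is.null(best) || code < best) best <- code
    }
  }
  paste0("h", n, ":", best)
}

#' Is a scaffold helicenic?
#'
#' A scaffold is helicenic when it cannot be drawn flat on the hexagonal
#' lattice without ring overlap: either two rings occupy the same lattice cell
#' (e.g. the seventh ring of a heptahelicene), or two rings sit on adjacent
#' cells without being fused, so their drawn perimeters would coincide along
#' the shared lattice edge (e.g. the terminal rings of hexahelicene).  Such
#' molecules escape the clash by winding out of plane.
#'
#' @param tree a [dualist_tree()].
#' @return `TRUE` or `FALSE`.
#' @export
is_helicenic <- function(tree) {
  stopifnot(inherits(tree, "dualist_tree"))
  n <- tree$n_rings
  if (n < 2) return(FALSE)
  fused <- matrix(FALSE, n, n)
  if (nrow(tree$edges)) fused[tree$edges] <- TRUE
  fused <- fused | t(fused)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- .hex_distance(tree$cells[i, ], tree$cells[j, ])
      if (d == 0) return(TRUE)
      if (d == 1 && !fused[i, j]) return(TRUE)
    }
  }
  FALSE
}

#' Enumerate all cata-condensed benzenoid scaffolds
#'
#' Breadth-first growth over dualist trees: every scaffold with `k` rings is
#' extended by fusing one new hexagon at every lattice direction of every ring
#' that keeps fusion bonds disjoint (at least 120 degrees apart on the host
#' hexagon), candidates are canonicalized and deduplicated.  Helicenic
#' embeddings (cell collision, or adjacent unfused cells) are retained and
#' flagged, so free constitutional isomers are counted: per size the counts
#' for 2..6 rings are 1, 2, 5, 12, 37.
#'
#' @param max_rings largest ring count to enumerate (2..8; the combinatorics
#'   beyond 8 rings are untested).
#' @return A list of [dualist_tree()] objects covering all scaffolds with
#'   2..`max_rings` rings, ordered by ring count then canonical code.
#' @export
enumerate_scaffolds <- function(max_rings) {
  if (!is.numeric(max_rings) || length(max_rings) != 1 || max_rings < 2)
    stop("max_rings must be a single integer >= 2", call. = FALSE)
  max_rings <- as.integer(max_rings)
  if (max_rings > 8)
    warning("enumeration beyond 8 rings is untested")

  naphthalene <- dualist_tree(c(0L, 1L), c(NA, 0L))
  by_size <- list(list(naphthalene))
  current <- list(naphthalene)
  size <- 2L
  while (size < max_rings) {
    seen <- new.env(parent = emptyenv())
    nxt <- list()
    for (sc in current) {
      for (cand in .grow_scaffold(sc)) {
        code <- cand$canonical_code
        if (!exists(code, envir = seen)) {
          assign(code, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    nxt <- nxt[order(vapply(nxt, `[[`, character(1), "canonical_code"))]
    by_size[[length(by_size) + 1L]] <- nxt
    current <- nxt
    size <- size + 1L
  }
  out <- do.call(c, by_size)
  out[order(vapply(out, `[[`, integer(1), "n_rings"),
            vapply(out, `[[`, character(1), "canonical_code"))]
}

# all single-ring extensions of a scaffold (as dualist_tree objects)
.grow_scaffold <- function(tree) {
  n <- tree$n_rings
  parent <- c(0L, tree$edges[, 1])
  dir <- c(NA_integer_, tree$dirs)
  out <- list()
  for (v in seq_len(n)) {
    used <- tree$dirmat[v, tree$adj[[v]]]
    for (d in 0:5) {
      gap <- pmin((d - used) %% 6L, (used - d) %% 6L)
      if (length(gap) && min(gap) < 2) next
      out[[length(out) + 1L]] <- dualist_tree(c(parent, v), c(dir, d))
    }
  }
  out
}

#' Tabulate scaffold counts by ring count
#'
#' @param scaffolds list of [dualist_tree()] objects, e.g. from
#'   [enumerate_scaffolds()].
#' @return A data frame with columns `n_rings` and `n_scaffolds`.
#' @export
scaffold_census <- function(scaffolds) {
  nr <- vapply(scaffolds, `[[`, integer(1), "n_rings")
  tab <- table(nr)
  data.frame(n_rings = as.integer(names(tab)),
             n_scaffolds = as.integer(tab))
}

#' Write scaffolds to a tab-separated file
#'
#' One scaffold per line: canonical code, ring count, helicenic flag and the
#' axial cell coordinates as a `q1,r1;q2,r2;...` string.
#'
#' @param scaffolds list of [dualist_tree()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scaffolds <- function(scaffolds, path) {
  rows <- vapply(scaffolds, function(sc) {
    cells <- apply(sc$cells, 1, paste, collapse = ",")
    dirs <- paste(c(0L, sc$edges[, 1]), c("", sc$dirs), sep = ":",
                  collapse = ";")
    paste(sc$canonical_code, sc$n_rings, as.integer(sc$helicenic),
          paste(cells, collapse = ";"), dirs, sep = "\t")
  }, character(1))
  writeLines(c("canonical_code\tn_rings\thelicenic\tcells\tparent_dirs", rows),
             path)
  invisible(path)
}

#' Read scaffolds written by [write_scaffolds()]
#'
#' @param path file written by [write_scaffolds()].
#' @return A list of [dualist_tree()] objects.
#' @export
read_scaffolds <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    pd <- strsplit(strsplit(tab$parent_dirs[i], ";", fixed = TRUE)[[1]],
                   ":", fixed = TRUE)
    parent <- vapply(pd, function(x) as.integer(x[1]), integer(1))
    dir <- vapply(pd, function(x)
      if (length(x) < 2 || x[2] == "") NA_integer_ else as.integer(x[2]),
      integer(1))
    dualist_tree(parent, dir)
  })
}
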