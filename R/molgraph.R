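#' Build the atom-level molecular graph of a scaffold
#'
#' Expands a dualist tree into its carbon framework: each ring contributes six
#' corner slots, and slots are identified across two rings exactly when a tree
#' edge fuses them (never by coordinate coincidence, so helicenes yield correct
#' graphs despite their two-dimensional overlap).  For a cata-condensed
#' scaffold with \eqn{n} rings the result has \eqn{4n + 2} atoms and
#' \eqn{5n + 1} bonds, with \eqn{n - 1} fused bonds.  Perimeter atoms that are
#' members of a single ring carry one implicit hydrogen; atoms on fused bonds
#' carry none.
#'
#' @param tree a [dualist_tree()] (a single-ring tree gives benzene, useful as
#'   a test input even though it is outside the enumerated space).
#' @return An object of class `mol_graph`: `element` (all "C"), `h_count`,
#'   `ring_membership` (list of ring indices per atom), `bonds` (two-column
#'   matrix), `rings` (atom indices of each ring in corner order),
#'   `fused_bonds`, `degree`, and the originating `tree`.
#' @export
build_molecular_graph <- function(tree) {
  stopifnot(inherits(tree, "dualist_tree"))
  n <- tree$n_rings
  # corner slot (ring i, corner c in 0..5) -> id; union-find over slots
  slot <- function(i, c) as.integer((i - 1L) * 6L + (c %% 6L) + 1L)
  uf <- seq_len(6L * n)
  find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
  merge_slots <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) uf[max(ra, rb)] <<- min(ra, rb)
  }

  if (nrow(tree$edges)) {
    for (e in seq_len(nrow(tree$edges))) {
      i <- tree$edges[e, 1]; j <- tree$edges[e, 2]; d <- tree$dirs[e]
      # hexagon i's edge facing direction d joins corners d and d+1;
      # seen from j the same edge faces d+3 and joins corners d+3, d+4,
      # with corner d of i coinciding with corner d+4 of j
      merge_slots(slot(i, d), slot(j, d + 4L))
      merge_slots(slot(i, d + 1L), slot(j, d + 3L))
    }
  }
  roots <- vapply(seq_len(6L * n), find, integer(1))
  atom_id <- match(roots, sort(unique(roots)))
  n_atoms <- max(atom_id)

  rings <- lapply(seq_len(n), function(i)
    atom_id[slot(i, 0:5)])
  ring_membership <- rep(list(integer()), n_atoms)
  for (i in seq_len(n))
    for (a in rings[[i]])
      ring_membership[[a]] <- base::union(ring_membership[[a]], i)

  bonds <- do.call(rbind, lapply(rings, function(r)
    cbind(r, r[c(2:6, 1)])))
  bonds <- unique(cbind(pmin(bonds[, 1], bonds[, 2]),
                        pmax(bonds[, 1], bonds[, 2])))
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]

  nmemb <- lengths(ring_membership)
  shared2 <- vapply(seq_len(nrow(bonds)), function(e)
    length(intersect(ring_membership[[bonds[e, 1]]],
                     ring_membership[[bonds[e, 2]]])) == 2L, logical(1))
  fused <- bonds[shared2, , drop = FALSE]
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n_atoms)

  structure(
    list(n_atoms = n_atoms,
         element = rep("C", n_atoms),
         h_count = as.integer(nmemb == 1L),
         ring_membership = ring_membership,
         bonds = bonds,
         rings = rings,
         fused_bonds = fused,
         degree = deg,
         tree = tree),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- table(x$element)
  cat(sprintf("<mol_graph> %s | %d atoms, %d bonds, %d rings, %d fused bond(s)\n",
              paste(names(comp), comp, sep = "", collapse = " "),
              x$n_atoms, nrow(x$bonds), length(x$rings), nrow(x$fused_bonds)))
  invisible(x)
}

# igraph view of a mol_graph (hydrogen-suppressed, element/h_count as colour)
.as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$bonds, directed = FALSE)
}

.atom_colors <- function(element, h_count) {
  as.integer(factor(paste(element, h_count)))
}

#' Automorphism group of a molecular graph
#'
#' The complete group of atom permutations preserving bonds, elements and
#' hydrogen counts, computed on the hydrogen-suppressed graph with the
#' hydrogen count as a vertex colour.  Generators come from BLISS (via
#' igraph); the full group is obtained by closure under composition, which is
#' cheap because these groups are tiny (order 12 for benzene, at most 4 for
#' the enumerated scaffolds).
#'
#' @param graph a [build_molecular_graph()] result, or any `mol_graph`.
#' @return A list of integer permutation vectors, the identity first; closed
#'   under composition.
#' @export
automorphism_group <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  g <- .as_igraph(graph)
  colors <- .atom_colors(graph$element, graph$h_count)
  gens <- igraph::automorphism_group(g, colors = colors)
  gens <- lapply(gens, as.integer)
  identity <- seq_len(graph$n_atoms)
  group <- list(identity)
  seen <- new.env(parent = emptyenv())
  assign(paste(identity, collapse = ","), TRUE, envir = seen)
  frontier <- list(identity)
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (gen in gens) {
        q <- gen[p]
        key <- paste(q, collapse = ",")
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          group[[length(group) + 1L]] <- q
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
  }
  group
}

#' Idealized Cartesian coordinates for a scaffold's carbon framework
#'
#' Places every ring as a regular hexagon (bond length `side` angstrom) at its
#' lattice cell, hydrogens 1.09 angstrom outward in plane.  Scaffolds whose
#' flat embedding brings non-bonded atoms into covalent range -- helicenes,
#' but also cove and fjord motifs whose bay hydrogens collide when drawn flat
#' -- additionally receive a vertical lift proportional to each ring's depth
#' in the dualist tree, an idealized stand-in for the out-of-plane distortion
#' of the optimized structure.  The lift keeps bonded atoms within covalent
#' range while separating clashing ones, so connectivity perception recovers
#' the intended bond set; it is applied only when the flat embedding clashes
#' (`lift = "auto"`, the default).
#'
#' @param graph a `mol_graph`.
#' @param side ring bond length in angstrom.
#' @param helix_step vertical rise per tree depth unit (angstrom).
#' @param hydrogens include explicit hydrogens?
#' @param lift `"auto"` (lift only when the flat embedding clashes),
#'   `"never"`, or `"always"`.
#' @return A data frame with columns `element`, `x`, `y`, `z`.
#' @export
atom_coordinates <- function(graph, side = 1.4, helix_step = 0.6,
                             hydrogens = TRUE,
                             lift = c("auto", "never", "always")) {
  stopifnot(inherits(graph, "mol_graph"))
  lift <- match.arg(lift)
  flat <- .place_atoms(graph, side, rep(0, graph$tree$n_rings), hydrogens)
  if (lift == "never") return(flat)
  if (lift == "auto" && !.has_close_contact(graph, flat)) return(flat)
  # search signed level assignments along the dualist tree: each ring one
  # step above or below its parent, like the rise of a helicene; take the
  # first assignment whose perceived connectivity matches the reference
  tree <- graph$tree
  n <- tree$n_rings
  depth <- .tree_depth(tree)
  ord <- order(depth)                     # parents before children
  parent <- rep(0L, n)
  if (nrow(tree$edges)) parent[tree$edges[, 2]] <- tree$edges[, 1]
  n_signed <- n - 1L
  for (mask in 0:(2^n_signed - 1L)) {
    signs <- ifelse(bitwAnd(mask, 2^(seq_len(n_signed) - 1L)) > 0, -1L, 1L)
    level <- numeric(n)
    k <- 0L
    for (v in ord[-1]) {
      k <- k + 1L
      level[v] <- level[parent[v]] + signs[k]
    }
    cand <- .place_atoms(graph, side, helix_step * level, hydrogens)
    if (!.has_close_contact(graph, cand)) return(cand)
  }
  stop("no clash-free helical embedding found; supply coordinates manually",
       call. = FALSE)
}

.place_atoms <- function(graph, side, ring_z, hydrogens) {
  tree <- graph$tree
  n <- tree$n_rings
  centers <- .hex_center(tree$cells[, 1], tree$cells[, 2], side)

  xy <- matrix(NA_real_, graph$n_atoms, 2)
  z <- numeric(graph$n_atoms)
  for (i in seq_len(n)) {
    corners <- .hex_corner(centers[rep(i, 6), , drop = FALSE], 0:5, side)
    xy[graph$rings[[i]], ] <- corners
  }
  for (a in seq_len(graph$n_atoms))
    z[a] <- mean(ring_z[graph$ring_membership[[a]]])

  out <- data.frame(element = graph$element,
                    x = xy[, 1], y = xy[, 2], z = z,
                    stringsAsFactors = FALSE)
  if (hydrogens) {
    idx <- which(graph$h_count == 1L)
    hx <- lapply(idx, function(a) {
      r <- graph$ring_membership[[a]][1]
      v <- xy[a, ] - centers[r, ]
      v <- v / sqrt(sum(v^2))
      data.frame(element = "H",
                 x = xy[a, 1] + 1.09 * v[1],
                 y = xy[a, 2] + 1.09 * v[2],
                 z = z[a], stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, hx))
  }
  rownames(out) <- NULL
  out
}

# would connectivity perception of these coordinates differ from the
# reference bond set (including host-hydrogen bonds)?
.has_close_contact <- function(graph, coords) {
  d <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  diag(d) <- Inf
  if (any(d < 0.4)) return(TRUE)
  r <- .covalent_radii[coords$element]
  within <- d <= 1.2 * outer(r, r, `+`)
  ref <- graph$bonds
  if (nrow(coords) > graph$n_atoms) {
    hosts <- which(graph$h_count == 1L)
    ref <- rbind(ref, cbind(hosts, graph$n_atoms + seq_along(hosts)))
  }
  expected <- matrix(FALSE, nrow(coords), nrow(coords))
  expected[ref] <- TRUE
  expected <- expected | t(expected)
  up <- upper.tri(within)
  any((within & up) != (expected & up))
}

# BFS depth of each ring from ring 1
.tree_depth <- function(tree) {
  n <- tree$n_rings
  depth <- rep(NA_integer_, n)
  depth[1] <- 0L
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in tree$adj[[v]]) {
      if (is.na(depth[w])) {
        depth[w] <- depth[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  depth
}

#' Line-notation (SMILES-style) export of a molecular graph
#'
#' Depth-first traversal with numbered ring-closure bonds; atoms are emitted
#' as bare element symbols (connectivity only, no bond orders -- all analyses
#' here are at the connectivity level).  [parse_linear_notation()] inverts it.
#'
#' @param graph a `mol_graph`.
#' @param elements optional element vector overriding `graph$element` (used to
#'   export substitution isomers without rebuilding the graph).
#' @return A character scalar.
#' @export
write_linear_notation <- function(graph, elements = graph$element) {
  stopifnot(inherits(graph, "mol_graph"), length(elements) == graph$n_atoms)
  n <- graph$n_atoms
  adj <- rep(list(integer()), n)
  for (e in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds[e, 1]; j <- graph$bonds[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  closure_of <- rep(list(character()), n)
  in_tree <- matrix(FALSE, n, n)
  next_digit <- 0L
  # spanning tree by depth-first traversal; remaining bonds become closures
  visited <- rep(FALSE, n)
  parent <- rep(0L, n)
  stack <- 1L
  visited[1] <- TRUE
  ordv <- integer()
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ordv <- c(ordv, v)
    for (w in rev(sort(adj[[v]]))) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        in_tree[v, w] <- TRUE; in_tree[w, v] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  # assign closure labels to back edges
  done <- matrix(FALSE, n, n)
  for (v in ordv) {
    for (w in sort(adj[[v]])) {
      if (!in_tree[v, w] && !done[v, w]) {
        next_digit <- next_digit + 1L
        lab <- if (next_digit < 10) as.character(next_digit) else
          paste0("%", next_digit)
        closure_of[[v]] <- c(closure_of[[v]], lab)
        closure_of[[w]] <- c(closure_of[[w]], lab)
        done[v, w] <- TRUE; done[w, v] <- TRUE
      }
    }
  }
  emit <- function(v, par) {
    kids <- setdiff(sort(adj[[v]])[in_tree[v, sort(adj[[v]])]], par)
    kids <- kids[parent[kids] == v]
    s <- paste0(elements[v], paste0(closure_of[[v]], collapse = ""))
    if (length(kids)) {
      inner <- vapply(kids, emit, character(1), par = v)
      branches <- if (length(inner) > 1)
        paste0("(", inner[-length(inner)], ")", collapse = "") else ""
      s <- paste0(s, branches, inner[length(inner)])
    }
    s
  }
  emit(1L, 0L)
}

#' Parse a line-notation string written by [write_linear_notation()]
#'
#' @param s a character scalar.
#' @return A list with `element` (character vector) and `bonds` (two-column
#'   matrix).
#' @export
parse_linear_notation <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  chars <- strsplit(s, "")[[1]]
  element <- character()
  bonds <- matrix(integer(), 0, 2)
  open <- list()     # closure label -> atom
  stack <- integer() # branch stack
  prev <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("B", "C", "N")) {
      element <- c(element, ch)
      at <- length(element)
      if (prev > 0L) bonds <- rbind(bonds, c(prev, at))
      prev <- at
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "%") {
      lab <- paste0("%", chars[i + 1L], chars[i + 2L])
      i <- i + 3L
      if (is.null(open[[lab]])) open[[lab]] <- prev else {
        bonds <- rbind(bonds, c(open[[lab]], prev)); open[[lab]] <- NULL
      }
    } else if (grepl("[0-9]", ch)) {
      lab <- ch
      i <- i + 1L
      if (is.null(open[[lab]])) open[[lab]] <- prev else {
        bonds <- rbind(bonds, c(open[[lab]], prev)); open[[lab]] <- NULL
      }
    } else {
      stop("unexpected character in line notation: ", ch, call. = FALSE)
    }
  }
  bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  list(element = element,
       bonds = bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE])
}
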