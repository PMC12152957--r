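# Shared fixtures and independent oracles.

benzene_tree <- function() dualist_tree(0, NA)
naphthalene_tree <- function() dualist_tree(c(0, 1), c(NA, 0))
anthracene_tree <- function() dualist_tree(c(0, 1, 2), c(NA, 0, 0))
phenanthrene_tree <- function() dualist_tree(c(0, 1, 2), c(NA, 0, 1))
linear_tree <- function(n) dualist_tree(c(0, seq_len(n - 1)),
                                        c(NA, rep(0, n - 1)))
# all-cis fibonacene path: consecutive fusion directions advance by 60 degrees
helicene_tree <- function(n) dualist_tree(c(0, seq_len(n - 1)),
                                          c(NA, (seq_len(n - 1) - 1) %% 6))

# brute-force automorphism oracle: all vertex permutations preserving bonds
# and hydrogen counts, found by backtracking on the adjacency matrix.
# Feasible only for small graphs (benzene..phenanthrene).
brute_force_automorphisms <- function(graph) {
  n <- graph$n_atoms
  A <- matrix(FALSE, n, n)
  A[graph$bonds] <- TRUE
  A <- A | t(A)
  h <- graph$h_count
  el <- graph$element
  perms <- list()
  assign_next <- function(perm, used) {
    v <- length(perm) + 1L
    if (v > n) {
      perms[[length(perms) + 1L]] <<- perm
      return(invisible())
    }
    for (img in seq_len(n)[!used]) {
      if (h[img] != h[v] || el[img] != el[v]) next
      ok <- TRUE
      for (w in seq_len(v - 1L)) {
        if (A[v, w] != A[img, perm[w]]) { ok <- FALSE; break }
      }
      if (ok) {
        used[img] <- TRUE
        assign_next(c(perm, img), used)
        used[img] <- FALSE
      }
    }
  }
  assign_next(integer(), rep(FALSE, n))
  perms
}

# breadth-first-search distance oracle on the bond list
bfs_distance <- function(graph, from, to) {
  n <- graph$n_atoms
  adj <- rep(list(integer()), n)
  for (e in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds[e, 1]; j <- graph$bonds[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  dist[to]
}

# naive scaffold-generation oracle: grow every placement sequence without
# intermediate deduplication, then take the distinct canonical codes
naive_scaffold_codes <- function(max_rings) {
  grow_all <- function(parent, dir) {
    n <- length(parent)
    out <- list()
    tree <- dualist_tree(parent, dir)
    for (v in seq_len(n)) {
      used <- tree$dirmat[v, tree$adj[[v]]]
      for (d in 0:5) {
        gap <- pmin((d - used) %% 6, (used - d) %% 6)
        if (length(gap) && min(gap) < 2) next
        out[[length(out) + 1L]] <- list(parent = c(parent, v),
                                        dir = c(dir, d))
      }
    }
    out
  }
  level <- list(list(parent = c(0, 1), dir = c(NA, 0)))
  codes <- list(`2` = canonical_code(naphthalene_tree()))
  for (k in 3:max_rings) {
    level <- do.call(c, lapply(level, function(t) grow_all(t$parent, t$dir)))
    codes[[as.character(k)]] <-
      unique(vapply(level, function(t)
        canonical_code(dualist_tree(t$parent, t$dir)), character(1)))
  }
  codes
}

# pull two non-bonded perimeter atoms (with their hydrogens) symmetrically
# along their connecting chord until they sit 1.5 angstrom apart: an extra
# ring-closing bond appears while everything else stays in place
cyclize_coords <- function(graph, co) {
  peri <- which(graph$h_count == 1L)
  xyz <- c("x", "y", "z")
  n_expected <- nrow(graph$bonds) + sum(graph$h_count)
  for (a in peri) for (b in peri) {
    if (a >= b) next
    pa <- unlist(co[a, xyz]); pb <- unlist(co[b, xyz])
    d <- sqrt(sum((pa - pb)^2))
    if (d < 2.0 || d > 3.5) next
    shift <- (pb - pa) / d * (d - 1.5) / 2
    cc <- co
    ha <- graph$n_atoms + match(a, peri)
    hb <- graph$n_atoms + match(b, peri)
    cc[c(a, ha), xyz] <- sweep(co[c(a, ha), xyz], 2, shift, `+`)
    cc[c(b, hb), xyz] <- sweep(co[c(b, hb), xyz], 2, shift, `-`)
    bonds <- tryCatch(perceive_bonds(cc), error = function(e) NULL)
    if (!is.null(bonds) && nrow(bonds) == n_expected + 1L) return(cc)
  }
  stop("no cyclizable perimeter pair found for this fixture")
}

# complete six-record optimization set for one molecule, optionally with one
# cyclized geometry ("method charge") or one imaginary-frequency record
make_records <- function(id, graph, cyclized = NULL, imag = NULL) {
  co <- atom_coordinates(graph)
  combos <- expand.grid(method = c("dft", "xtb"),
                        charge = c("neutral", "cation", "anion"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(k) {
    key <- paste(combos$method[k], combos$charge[k])
    cc <- if (!is.null(cyclized) && key == cyclized)
      cyclize_coords(graph, co) else co
    geometry_record(id, cc, combos$charge[k], combos$method[k],
                    imaginary_freq = !is.null(imag) && key == imag)
  })
}

# the full enumerated space with features is expensive enough to share
# across test files (computed once per session)
.space_cache <- new.env(parent = emptyenv())
full_space <- function() {
  if (is.null(.space_cache$space))
    .space_cache$space <- enumerate_bn_space(6)
  .space_cache$space
}
full_features <- function() {
  if (is.null(.space_cache$features))
    .space_cache$features <- featurize_space(full_space())
  .space_cache$features
}
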