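test_that("molecular graphs satisfy the cata-condensed counting identities", {
  for (tree in list(naphthalene_tree(), anthracene_tree(),
                    phenanthrene_tree(), linear_tree(6), helicene_tree(6))) {
    g <- build_molecular_graph(tree)
    n <- tree$n_rings
    expect_identical(g$n_atoms, 4L * n + 2L)
    expect_identical(nrow(g$bonds), 5L * n + 1L)
    expect_identical(length(g$rings), n)
    expect_identical(nrow(g$fused_bonds), n - 1L)
    expect_true(all(lengths(g$ring_membership) %in% 1:2))
    # each fused bond contributes two shared atoms, disjoint across bonds
    expect_identical(sum(lengths(g$ring_membership) == 2L), 2L * (n - 1L))
    # hydrogens sit exactly on single-ring perimeter atoms
    expect_identical(g$h_count, as.integer(lengths(g$ring_membership) == 1L))
    expect_true(all(vapply(g$rings, length, integer(1)) == 6L))
  }
})

test_that("helicene graphs are built topologically despite 2-D overlap", {
  g7 <- build_molecular_graph(helicene_tree(7))
  expect_identical(g7$n_atoms, 30L)       # 4*7 + 2, no coordinate merging
  expect_identical(nrow(g7$bonds), 36L)
})

test_that("automorphism group matches the brute-force oracle on small PBHs", {
  cases <- list(benzene = list(benzene_tree(), 12L),
                naphthalene = list(naphthalene_tree(), 4L),
                anthracene = list(anthracene_tree(), 4L),
                phenanthrene = list(phenanthrene_tree(), 2L))
  for (nm in names(cases)) {
    g <- build_molecular_graph(cases[[nm]][[1]])
    group <- automorphism_group(g)
    oracle <- brute_force_automorphisms(g)
    expect_identical(length(group), cases[[nm]][[2]])
    expect_setequal(vapply(group, paste, character(1), collapse = ","),
                    vapply(oracle, paste, character(1), collapse = ","))
  }
})

test_that("automorphism groups are closed and satisfy orbit-stabilizer", {
  for (tree in list(phenanthrene_tree(), linear_tree(4), helicene_tree(6))) {
    g <- build_molecular_graph(tree)
    group <- automorphism_group(g)
    keys <- vapply(group, paste, character(1), collapse = ",")
    # closure under composition
    for (p in group) for (q in group)
      expect_true(paste(p[q], collapse = ",") %in% keys)
    # |orbit(a)| * |stabilizer(a)| = |G| for every atom
    for (a in seq_len(g$n_atoms)) {
      images <- vapply(group, `[`, integer(1), a)
      orbit <- length(unique(images))
      stab <- sum(images == a)
      expect_identical(orbit * stab, length(group))
    }
  }
})

test_that("line notation round-trips to an isomorphic graph", {
  for (tree in list(naphthalene_tree(), phenanthrene_tree(),
                    helicene_tree(6))) {
    g <- build_molecular_graph(tree)
    # mark one B/N pair so element labels are exercised too
    el <- g$element
    el[c(1, 4)] <- c("B", "N")
    s <- write_linear_notation(g, elements = el)
    parsed <- parse_linear_notation(s)
    expect_identical(sort(parsed$element), sort(el))
    expect_identical(nrow(parsed$bonds), nrow(g$bonds))
    g1 <- igraph::graph_from_edgelist(g$bonds, directed = FALSE)
    g2 <- igraph::graph_from_edgelist(parsed$bonds, directed = FALSE)
    lv <- sort(unique(el))
    expect_true(igraph::is_isomorphic_to(
      g1, g2, method = "vf2",
      vertex.color1 = match(el, lv),
      vertex.color2 = match(parsed$element, lv)))
  }
})

test_that("idealized coordinates place fused corners exactly once", {
  g <- build_molecular_graph(phenanthrene_tree())
  co <- atom_coordinates(g, hydrogens = FALSE)
  d <- as.matrix(dist(co[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_gt(min(d), 1.39)  # nothing closer than a bond length
  # bonded atoms at the ring bond length
  for (e in seq_len(nrow(g$bonds)))
    expect_equal(d[g$bonds[e, 1], g$bonds[e, 2]], 1.4, tolerance = 1e-8)
})
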