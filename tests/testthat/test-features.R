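test_that("longest linear stretch counts anthracene-like units", {
  expect_identical(compute_n_LL(linear_tree(6)), 4L)   # fully linear: n-2
  expect_identical(compute_n_LL(anthracene_tree()), 1L)
  expect_identical(compute_n_LL(phenanthrene_tree()), 0L)
  expect_identical(compute_n_LL(naphthalene_tree()), 0L)
  expect_identical(compute_n_LL(helicene_tree(6)), 0L) # all-cis, no straight run
  # a kinked 5-ring with an embedded 3-ring straight run
  kinked <- dualist_tree(c(0, 1, 2, 3, 4), c(NA, 0, 0, 1, 1))
  expect_identical(compute_n_LL(kinked), 1L)
})

test_that("inner/outer classification follows fused-bond membership", {
  g <- build_molecular_graph(naphthalene_tree())
  bridge <- g$fused_bonds[1, ]
  io <- classify_inner_outer(g, bridge[1], bridge[2])
  expect_identical(unname(io), c(1L, 1L))
  # inner boron participates in three C-B bonds
  expect_identical(g$degree[bridge[1]], 3L)
  alpha <- which(g$h_count == 1L)[1]
  expect_identical(unname(classify_inner_outer(g, alpha, bridge[1])),
                   c(0L, 1L))
  outer2 <- which(g$h_count == 1L)[1:2]
  expect_identical(unname(classify_inner_outer(g, outer2[1], outer2[2])),
                   c(0L, 0L))
})

test_that("shortest-path carbon count matches the BFS oracle", {
  g <- build_molecular_graph(benzene_tree())
  # ortho / meta / para inside one ring
  expect_identical(compute_n_SP(g, 1, 2), 0L)
  ring <- g$rings[[1]]
  para <- c(ring[1], ring[4])
  expect_identical(compute_n_SP(g, para[1], para[2]), 2L)

  g3 <- build_molecular_graph(anthracene_tree())
  set.seed(42)
  for (k in 1:25) {
    pair <- sample(g3$n_atoms, 2)
    expect_identical(compute_n_SP(g3, pair[1], pair[2]),
                     bfs_distance(g3, pair[1], pair[2]) - 1L)
  }
})

test_that("disrupted-ring count unions host rings with the dualist path", {
  g <- build_molecular_graph(naphthalene_tree())
  outer_ring1 <- setdiff(g$rings[[1]], g$rings[[2]])
  # both heteroatoms outer in the same ring
  expect_identical(compute_n_DR(g, outer_ring1[1], outer_ring1[2]), 1L)
  # both on the fused bond: each atom belongs to both rings
  fb <- g$fused_bonds[1, ]
  expect_identical(compute_n_DR(g, fb[1], fb[2]), 2L)

  g3 <- build_molecular_graph(anthracene_tree())
  tip1 <- setdiff(g3$rings[[1]], g3$rings[[2]])
  tip3 <- setdiff(g3$rings[[3]], g3$rings[[2]])
  # opposite terminal rings: the middle ring is dragged in by the path
  expect_identical(compute_n_DR(g3, tip1[1], tip3[1]), 3L)
  # inner heteroatom: the path is minimized over its two host rings
  fused12 <- intersect(g3$rings[[1]], g3$rings[[2]])
  expect_identical(compute_n_DR(g3, fused12[1], tip1[1]), 2L)
})

test_that("featurize assembles the documented example vectors", {
  g <- build_molecular_graph(naphthalene_tree())
  fb <- g$fused_bonds[1, ]
  expect_identical(unname(featurize(g, fb[1], fb[2])),
                   c(2L, 0L, 1L, 1L, 0L, 2L))

  g6 <- build_molecular_graph(linear_tree(6))
  term <- setdiff(g6$rings[[1]], g6$rings[[2]])
  outer <- term[g6$h_count[term] == 1L]
  adjacent <- NULL
  for (i in outer) for (j in outer)
    if (i < j && any(g6$bonds[, 1] == i & g6$bonds[, 2] == j))
      adjacent <- c(i, j)
  expect_identical(unname(featurize(g6, adjacent[1], adjacent[2])),
                   c(6L, 4L, 0L, 0L, 0L, 1L))
  # purity
  expect_identical(featurize(g6, adjacent[1], adjacent[2]),
                   featurize(g6, adjacent[1], adjacent[2]))
})

test_that("vectorized featurization agrees with the scalar operations", {
  space <- enumerate_bn_space(3)
  ft <- featurize_space(space)
  set.seed(7)
  for (r in sample(nrow(ft), 20)) {
    g <- space$graphs[[ft$scaffold_index[r]]]
    expect_identical(
      unname(featurize(g, ft$b_index[r], ft$n_index[r])),
      unname(unlist(ft[r, c("n_rings", "n_LL", "b_inner", "n_inner",
                            "n_SP", "n_DR")])))
  }
})

test_that("features are invariant under automorphic relabeling", {
  for (tree in list(naphthalene_tree(), linear_tree(4), helicene_tree(6))) {
    g <- build_molecular_graph(tree)
    group <- automorphism_group(g)
    iso <- enumerate_bn_isomers(g, group)
    set.seed(11)
    rows <- sample(nrow(iso), min(10, nrow(iso)))
    for (r in rows) {
      base <- featurize(g, iso$b_index[r], iso$n_index[r])
      for (p in group)
        expect_identical(featurize(g, p[iso$b_index[r]], p[iso$n_index[r]]),
                         base)
    }
  }
})
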