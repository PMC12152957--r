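test_that("bond perception recovers the naphthalene framework exactly", {
  g <- build_molecular_graph(naphthalene_tree())
  co <- atom_coordinates(g)
  bonds <- perceive_bonds(co)
  heavy <- which(co$element != "H")
  cc <- bonds[bonds[, 1] %in% heavy & bonds[, 2] %in% heavy, , drop = FALSE]
  expect_identical(nrow(cc), 11L)
  expect_identical(unname(cc), unname(g$bonds))
  # every hydrogen bonded exactly once, to its host carbon
  hrows <- bonds[bonds[, 2] > g$n_atoms, , drop = FALSE]
  expect_identical(nrow(hrows), sum(g$h_count))
})

test_that("distance cutoffs behave at the boundaries", {
  two <- data.frame(element = c("C", "C"), x = c(0, 3), y = 0, z = 0)
  expect_identical(nrow(perceive_bonds(two)), 0L)
  near <- data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0)
  expect_identical(nrow(perceive_bonds(near)), 1L)
  clash <- data.frame(element = c("C", "C"), x = c(0, 0.2), y = 0, z = 0)
  expect_error(perceive_bonds(clash), "0.4")
  expect_error(perceive_bonds(data.frame(element = c("C", "Xx"),
                                         x = c(0, 2), y = 0, z = 0)),
               "covalent radius")
})

test_that("rearrangement detection is an isomorphism test, not identity", {
  g <- build_molecular_graph(naphthalene_tree())
  co <- atom_coordinates(g)
  expect_false(detect_rearrangement(g, co))
  # relabeled (reversed atom order) but isomorphic
  co_rev <- co[rev(seq_len(nrow(co))), ]
  expect_false(detect_rearrangement(g, co_rev))
  # cyclization: pull two non-bonded perimeter atoms into covalent range
  co2 <- cyclize_coords(g, co)
  bonds2 <- perceive_bonds(co2)
  expect_gt(nrow(bonds2), nrow(perceive_bonds(co)))
  expect_true(detect_rearrangement(g, co2, bonds2))
  # different atom multiset is an error, not a rearrangement verdict
  co_wrong <- co
  co_wrong$element[1] <- "N"
  expect_error(detect_rearrangement(g, co_wrong), "multiset")
})

test_that("filtration discards on any rearrangement and flags imaginary ionics", {
  g <- build_molecular_graph(naphthalene_tree())
  refs <- list(clean = g, cyc = g, imag = g)
  records <- c(make_records("clean", g),
               make_records("cyc", g, cyclized = "dft cation"),
               make_records("imag", g, imag = "xtb anion"))
  res <- apply_filtration(records, refs)
  expect_setequal(res$kept, c("clean", "imag"))
  expect_identical(res$discarded, "cyc")
  expect_identical(res$flagged, "imag")
  expect_identical(nrow(res$log), 18L)
  # neutral imaginary frequency does not flag
  res2 <- apply_filtration(make_records("m", g, imag = "dft neutral"),
                           list(m = g))
  expect_identical(res2$flagged, character(0))
  expect_identical(res2$kept, "m")
})

test_that("filtration is monotone and tolerates missing records", {
  g <- build_molecular_graph(naphthalene_tree())
  full <- make_records("m", g, cyclized = "xtb anion")
  clean_subset <- full[1:5]   # drop the corrupted sixth record
  expect_warning(res_partial <- apply_filtration(clean_subset, list(m = g)),
                 "5 of 6")
  expect_identical(res_partial$kept, "m")
  # adding the rearranged record can only move kept -> discarded
  res_full <- apply_filtration(full, list(m = g))
  expect_identical(res_full$discarded, "m")
})

test_that("multi-structure XYZ files round-trip with metadata", {
  g <- build_molecular_graph(phenanthrene_tree())
  recs <- make_records("phen", g, imag = "dft anion")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(recs, path)
  back <- read_xyz(path)
  expect_length(back, 6)
  expect_identical(vapply(back, `[[`, character(1), "charge_state"),
                   vapply(recs, `[[`, character(1), "charge_state"))
  expect_identical(vapply(back, `[[`, logical(1), "imaginary_freq"),
                   vapply(recs, `[[`, logical(1), "imaginary_freq"))
  expect_equal(back[[1]]$coords$x, recs[[1]]$coords$x, tolerance = 1e-7)
})
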