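test_that("constructed geometries yield exactly the planted bonds", {
  s <- synth_complex(complex_spec(
    contacts = data.frame(residue_key = "Trp74", distance = 2.5)), seed = 1)
  b <- detect_direct_hbonds(s)
  expect_equal(nrow(b), 1)
  expect_identical(b$residue_key, "Trp74")
  expect_false(b$bridged)
  expect_equal(b$length, 2.5, tolerance = 1e-9)

  # same pair beyond the cutoff: nothing
  far <- synth_complex(complex_spec(
    contacts = data.frame(residue_key = "Trp74", distance = 3.5)), seed = 1)
  expect_equal(nrow(detect_direct_hbonds(far)), 0)

  br <- synth_complex(complex_spec(
    bridges = data.frame(residue_key = "Ser73", d_ligand_water = 2.8,
                         d_water_protein = 2.9)), seed = 2)
  bb <- detect_water_bridges(br)
  expect_equal(nrow(bb), 1)
  expect_identical(bb$residue_key, "Ser73")
  expect_true(bb$bridged)
  expect_equal(bb$length, 2.8, tolerance = 1e-9)  # ligand-water leg
  expect_false(is.na(bb$water_serial))
  # sum-of-legs convention
  expect_equal(detect_water_bridges(br, length_mode = "sum")$length,
               2.8 + 2.9, tolerance = 1e-9)

  # second leg beyond the cutoff: no bridge
  nob <- synth_complex(complex_spec(
    bridges = data.frame(residue_key = "Ser73", d_ligand_water = 2.8,
                         d_water_protein = 3.2)), seed = 2)
  expect_equal(nrow(detect_water_bridges(nob)), 0)

  expect_error(detect_direct_hbonds(s, cutoff = 0), "positive")
  expect_error(detect_water_bridges(s, cutoff = -1), "positive")
})

test_that("detectors agree with brute-force enumeration on random complexes", {
  for (seed in 1:10) {
    s <- synth_random_complex(n_protein = 60, n_ligand = 6, n_water = 20,
                              seed = seed)
    expect_same_bonds(detect_direct_hbonds(s), oracle_direct_hbonds(s))
    expect_same_bonds(detect_water_bridges(s), oracle_water_bridges(s))
  }
})

test_that("bond lengths are rigid-motion covariant and order invariant", {
  s <- synth_random_complex(n_protein = 50, n_ligand = 6, n_water = 15,
                            seed = 5)
  b0d <- detect_direct_hbonds(s); b0w <- detect_water_bridges(s)
  expect_gt(nrow(b0d), 0)

  s_rt <- transform_structure(s, random_rotation(3), c(11.3, -4.2, 100))
  expect_same_bonds(detect_direct_hbonds(s_rt), b0d, tol = 1e-9)
  expect_same_bonds(detect_water_bridges(s_rt), b0w, tol = 1e-9)

  perm <- withr::with_seed(2, sample(nrow(s$atoms)))
  s_p <- s; s_p$atoms <- s$atoms[perm, ]
  expect_same_bonds(detect_direct_hbonds(s_p), b0d)
  expect_same_bonds(detect_water_bridges(s_p), b0w)
})

test_that("shrinking the cutoff never adds bonds", {
  s <- synth_random_complex(n_protein = 60, n_ligand = 8, n_water = 20,
                            seed = 7)
  wide <- detect_direct_hbonds(s, cutoff = 3.0)
  narrow <- detect_direct_hbonds(s, cutoff = 2.6)
  expect_true(all(narrow$length <= 2.6))
  key <- function(b) paste(b$ligand_atom_serial, b$protein_atom_serial)
  expect_true(all(key(narrow) %in% key(wide)))
  expect_identical(normalize_bonds(wide[wide$length <= 2.6, ]),
                   normalize_bonds(narrow))
})

test_that("feature matrix applies the minimum and fill rules", {
  # two contacts with the same residue key at 2.9 and 2.6 collapse to 2.6
  s1 <- synth_complex(complex_spec(
    contacts = data.frame(residue_key = c("Trp74", "Trp74", "Cys434"),
                          distance = c(2.9, 2.6, 2.4))), seed = 3,
    ligand_id = "12f")
  # no Cys434 contact in the second conformation -> fill 3.0
  s2 <- synth_complex(complex_spec(
    contacts = data.frame(residue_key = "Trp74", distance = 2.8)), seed = 4,
    ligand_id = "12e_2")
  fm <- build_feature_matrix(list(s1, s2), c(`12f` = 100, `12e_2` = 84.8))
  expect_s3_class(fm, "FeatureMatrix")
  expect_identical(dim(fm), c(2L, 2L))
  expect_identical(fm$catalog$label, c("Trp74", "Cys434"))  # first appearance
  expect_equal(fm$values["12f", "V1"], 2.6, tolerance = 1e-9)
  expect_equal(fm$values["12f", "V2"], 2.4, tolerance = 1e-9)
  expect_equal(fm$values["12e_2", "V2"], 3.0)               # fill
  expect_equal(fm$response, c(100, 84.8))
  expect_true(all(fm$values > 0 & fm$values <= 3.0))
})

test_that("bridged variables get the W prefix and their own column", {
  s <- synth_complex(complex_spec(
    contacts = data.frame(residue_key = "Ser73", distance = 2.5),
    bridges = data.frame(residue_key = "Ser73", d_ligand_water = 2.7,
                         d_water_protein = 2.8)), seed = 6)
  fm <- build_feature_matrix(list(s), 50)
  expect_setequal(fm$catalog$label, c("Ser73", "WSer73"))
  expect_equal(unname(fm$values[1, fm$catalog$label == "WSer73"]), 2.7,
               tolerance = 1e-9)
})

test_that("relabeling the seven protomer chains leaves the matrix identical", {
  sp <- complex_spec(
    contacts = data.frame(residue_key = c("Trp74", "Phe72"),
                          distance = c(2.5, 2.9)),
    bridges = data.frame(residue_key = "Arg75", d_ligand_water = 2.6,
                         d_water_protein = 2.7),
    chains = LETTERS[1:7])
  s <- synth_complex(sp, seed = 8)
  fm1 <- build_feature_matrix(list(s), 73.2)
  s_relab <- s
  map <- stats::setNames(LETTERS[c(3, 1, 7, 2, 6, 4, 5)], LETTERS[1:7])
  prot <- s_relab$atoms$role == "protein"
  s_relab$atoms$chain_id[prot] <- map[s_relab$atoms$chain_id[prot]]
  fm2 <- build_feature_matrix(list(s_relab), 73.2)
  expect_identical(fm1$values, fm2$values)
  expect_identical(fm1$catalog, fm2$catalog)
})

test_that("matrix construction rejects bad inputs", {
  s <- synth_complex(complex_spec(
    contacts = data.frame(residue_key = "Trp74", distance = 2.5)), seed = 1)
  expect_error(build_feature_matrix(list(), numeric(0)), "empty")
  expect_error(build_feature_matrix(list(s, s), c(50, 60)), "duplicate")
  expect_error(build_feature_matrix(list(s), 120), "\\[0, 100\\]")
})
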