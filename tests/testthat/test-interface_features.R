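test_that("quadrature SASA matches closed forms for isolated spheres", {
  a <- atom_sasa(matrix(0, 1, 3), radii = 1.7, probe = 1.4, n_points = 960)
  expect_lt(abs(a - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)

  # two atoms beyond occlusion range: sum of isolated areas
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  a2 <- atom_sasa(xyz, radii = c(1.7, 1.52), probe = 1.4, n_points = 960)
  expect_equal(a2, c(4 * pi * 3.1^2, 4 * pi * 2.92^2), tolerance = 0.01)

  expect_error(atom_sasa(rbind(c(0, 0, 0), c(0, 0, 0)), c(1.7, 1.7)),
               "coincident")
  expect_error(atom_sasa(matrix(0, 1, 3), 1.7, probe = -1), "probe")
  expect_error(atom_sasa(matrix(0, 1, 3), 1.7, n_points = 50), "n_points")
})

test_that("quadrature SASA agrees with the Monte-Carlo occlusion oracle", {
  worst <- 0
  for (s in 1:20) {
    cl <- random_cluster(n_atoms = sample(5:15, 1), seed = s)
    q <- atom_sasa(cl$xyz, cl$radii, n_points = 960)
    mc <- mc_sasa(cl$xyz, cl$radii, n_samples = 2e4, seed = s)
    rel <- abs(sum(q) - sum(mc)) / sum(mc)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.02)
})

test_that("per-residue ASA/BSA behave additively and vanish off-interface", {
  toy <- toy_fixture()
  m <- toy$model
  # residue far from any partner chain: identical occluders either way
  ab_pad <- residue_asa_bsa(m, "FC", 8)     # padding alanine
  expect_equal(unname(ab_pad["bsa"]), 0, tolerance = 1e-9)
  # planted interface residue buries area
  ab_int <- residue_asa_bsa(m, "FC", 1)
  expect_gt(ab_int["bsa"], 0)

  # additivity: sum of residue BSA = total isolated - total complex
  tabs <- fcaffinity:::.sasa_tables(m)
  total_gap <- sum(tabs$isolated) - sum(tabs$complex)
  sites <- complex_sites(m)
  bsa_sum <- sum(vapply(seq_len(nrow(sites)), function(i)
    unname(residue_asa_bsa(m, sites$role[i], sites$eu[i])["bsa"]),
    numeric(1)))
  expect_equal(bsa_sum, total_gap, tolerance = 1e-6 * max(1, total_gap))
})

test_that("solvation energy is linear in the parameter table", {
  toy <- toy_fixture()
  e1 <- solvation_energy(toy$model, "FC", 1)
  e2 <- solvation_energy(toy$model, "FC", 1,
                         asp = 2 * fcaffinity:::.ASP_TABLE)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  bad <- toy$model
  bad$atoms$element[1] <- "ZZ"
  expect_error(solvation_energy(bad, "FC", 1), "unknown element")
})

test_that("solvation energy equals the hand-computed sum over MC areas", {
  cl <- random_cluster(n_atoms = 8, seed = 11)
  m <- tiny_complex(do.call(rbind, lapply(1:8, function(i)
    tiny_atom("FC", "A", 1, "A", c("N", "CA", "C", "O", "CB", "CA", "C",
                                   "O")[i],
              cl$xyz[i, 1], cl$xyz[i, 2], cl$xyz[i, 3]))))
  m$atoms$radius <- cl$radii
  areas <- atom_sasa(cl$xyz, cl$radii, n_points = 960)
  byhand <- sum(fcaffinity:::.ASP_TABLE[m$atoms$element] * areas)
  expect_equal(fcaffinity:::.solv_from_area(m$atoms$element, areas),
               byhand, tolerance = 1e-12)
})

test_that("hydrogen bonds are counted at the 3.5 A donor-acceptor cutoff", {
  one <- make_toy_complex(hbonds = 2.9, n_fc = 2, n_fcrn = 2)
  hb <- count_hbonds(one$model)
  expect_equal(hb$count, 1)
  expect_equal(hb$mean_distance, 2.9, tolerance = 1e-9)

  # same geometry pushed to 3.6 A: outside the cutoff
  moved <- one$model
  sel <- moved$atoms$role == "FCRN_ALPHA"
  moved$atoms$y[sel] <- moved$atoms$y[sel] + 0.7
  expect_equal(count_hbonds(moved)$count, 0)
  expect_equal(count_hbonds(moved)$mean_distance, 0)

  three <- make_toy_complex(hbonds = c(2.8, 3.0, 3.2), n_fc = 4, n_fcrn = 4)
  hb3 <- count_hbonds(three$model)
  expect_equal(hb3$count, 3)
  expect_equal(hb3$mean_distance, 3.0, tolerance = 1e-9)
})

test_that("salt bridges count once per residue pair", {
  sb <- make_toy_complex(salt_bridges = 3.5, n_fc = 2, n_fcrn = 2)
  expect_equal(count_salt_bridges(sb$model), 1)

  # both carboxylate oxygens within 4 A of NZ: still one bridge
  both <- tiny_complex(rbind(
    tiny_atom("FC", "A", 1, "K", "N", -10, 0, 0),
    tiny_atom("FC", "A", 1, "K", "CA", -9, 0, 0),
    tiny_atom("FC", "A", 1, "K", "C", -8, 0, 0),
    tiny_atom("FC", "A", 1, "K", "O", -8, 1.2, 0),
    tiny_atom("FC", "A", 1, "K", "NZ", 0, 0, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "D", "N", 12, 0, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "D", "CA", 11, 0, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "D", "C", 10.5, 1, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "D", "O", 10.5, 2.2, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "D", "OD1", 3.5, 0, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "D", "OD2", 3.6, 1, 0)))
  expect_equal(count_salt_bridges(both), 1)

  far <- make_toy_complex(n_fc = 2, n_fcrn = 2)   # nothing planted
  expect_equal(count_salt_bridges(far$model), 0)
})

test_that("CA contacts, hydrophilic pairs and B2M contact atoms match the plant", {
  toy <- toy_fixture()
  m <- toy$model
  expect_equal(count_ca_contacts(m), toy$manifest$ca_contacts)
  expect_equal(count_paired_hydrophilic(m), toy$manifest$paired_hydrophilic)
  expect_equal(count_b2m_fc_atom_contacts(m),
               toy$manifest$b2m_fc_atom_contacts)

  none <- make_toy_complex(n_fc = 3, n_fcrn = 3, n_b2m = 2)
  expect_equal(count_ca_contacts(none$model), 0)
  expect_equal(count_paired_hydrophilic(none$model), 0)
  expect_equal(count_b2m_fc_atom_contacts(none$model), 0)
  expect_equal(interface_residue_count(none$model), 0)
})

test_that("geometric features are invariant under rigid motion", {
  toy <- toy_fixture()
  m <- toy$model
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  rot <- m
  rot$atoms$x <- xyz[, 1] + 5
  rot$atoms$y <- xyz[, 2] - 3
  rot$atoms$z <- xyz[, 3] + 1

  expect_identical(count_hbonds(rot)$count, count_hbonds(m)$count)
  expect_equal(count_hbonds(rot)$mean_distance,
               count_hbonds(m)$mean_distance, tolerance = 1e-9)
  expect_identical(count_salt_bridges(rot), count_salt_bridges(m))
  expect_identical(count_ca_contacts(rot), count_ca_contacts(m))
  expect_identical(count_paired_hydrophilic(rot),
                   count_paired_hydrophilic(m))
  expect_identical(interface_residue_count(rot),
                   interface_residue_count(m))
  # surface areas only to quadrature-orientation tolerance
  t1 <- fcaffinity:::.sasa_tables(m)
  t2 <- fcaffinity:::.sasa_tables(rot)
  expect_equal(sum(t2$complex), sum(t1$complex),
               tolerance = 0.01 * sum(t1$complex))
})

test_that("the default catalog has 147 aligned, deterministic features", {
  ref <- ref_fixture()
  catg <- catalog_fixture()
  expect_s3_class(catg, "feature_catalog")
  expect_equal(nrow(catg), 147)
  expect_true("asa_FCRN_ALPHA_129" %in% catg$feature_id)

  fv1 <- extract_features(ref, catg)
  fv2 <- extract_features(ref, catg)
  expect_identical(fv1, fv2)
  expect_equal(length(fv1), 147)
  expect_true(all(is.finite(fv1)))
  counts <- fv1[c("cx_hbonds", "cx_salt_bridges", "cx_ca_contacts",
                  "cx_paired_hydrophilic", "cx_b2m_fc_atom_contacts",
                  "cx_n_interface_residues")]
  expect_true(all(counts >= 0 & counts == round(counts)))

  perm <- sample(nrow(catg))
  catg_p <- catg[perm, ]
  class(catg_p) <- class(catg)
  expect_identical(unname(extract_features(ref, catg_p)),
                   unname(fv1[perm]))

  bad <- catg
  bad$eu[1] <- 9999
  expect_error(extract_features(ref, bad), "9999")
})
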