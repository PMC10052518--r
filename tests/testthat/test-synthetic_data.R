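test_that("every planted manifest count is recovered by the featurizer", {
  toy <- toy_fixture()
  m <- toy$model
  mf <- toy$manifest
  hb <- count_hbonds(m)
  expect_equal(hb$count, mf$hbonds)
  expect_equal(hb$mean_distance, mf$mean_hbond_distance, tolerance = 1e-9)
  expect_equal(count_salt_bridges(m), mf$salt_bridges)
  expect_equal(count_ca_contacts(m), mf$ca_contacts)
  expect_equal(count_paired_hydrophilic(m), mf$paired_hydrophilic)
  expect_equal(count_b2m_fc_atom_contacts(m), mf$b2m_fc_atom_contacts)
  expect_equal(interface_residue_count(m), mf$interface_residues)
})

test_that("cross-feature implications of planted geometry are bookkept", {
  # a salt bridge inside 3.5 A is also a donor-acceptor hydrogen bond
  tight <- make_toy_complex(salt_bridges = 3.4, n_fc = 2, n_fcrn = 2)
  expect_equal(tight$manifest$hbonds, 1)
  expect_equal(count_hbonds(tight$model)$count, 1)
  expect_equal(count_salt_bridges(tight$model), 1)
  # and always pairs two hydrophilic residues
  expect_equal(tight$manifest$paired_hydrophilic, 1)
  expect_equal(count_paired_hydrophilic(tight$model), 1)
})

test_that("an all-zero plant leaves the chains out of contact", {
  z <- make_toy_complex(n_fc = 4, n_fcrn = 3, n_b2m = 2)
  at <- z$model$atoms
  a <- at[at$role == "FC", c("x", "y", "z")]
  b <- at[at$role != "FC", c("x", "y", "z")]
  dmin <- min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
                     2 * as.matrix(a) %*% t(as.matrix(b))))
  expect_gte(dmin, 10)
  expect_equal(count_hbonds(z$model)$count, 0)
  expect_equal(interface_residue_count(z$model), 0)
})

test_that("infeasible plants and emitted PDBs are handled", {
  expect_error(make_toy_complex(hbonds = 3.8), "infeasible")
  expect_error(make_toy_complex(hbonds = c(2.9, 2.9, 2.9), n_fc = 2),
               "infeasible")
  expect_error(make_toy_complex(b2m_contacts = 3.8, n_b2m = 0),
               "infeasible")
  toy <- toy_fixture()
  expect_no_error(read_complex(toy$pdb, toy$chain_map, quiet = TRUE))
})

test_that("a noiseless synthetic table is perfectly linear in its features", {
  gen <- fixture("gen_zero", function()
    make_variant_table(synthetic_truth(n = 60, sigma = 0, seed = 3),
                       reference = ref_fixture(),
                       catalog = catalog_fixture()))
  wn <- names(gen$truth$weights)
  cv <- cross_validate(gen$truth$features[, wn], gen$truth$y_true, "MLR",
                       k = 10, seed = 1)
  expect_gte(cv$mean_r2, 0.999)
})

test_that("planted duplicates, pH 6 encoding and non-binders curate away", {
  gen <- gen_fixture()
  tab <- gen$table
  truth <- gen$truth
  sets <- build_learning_sets(tab, quiet = TRUE)
  expect_equal(sets$SLS$removed_duplicates, truth$dup_pairs)
  expect_equal(sets$SLS$removed_nonbinders, truth$nonbinders)
  expect_equal(nrow(sets$SLS$records), truth$n)

  # harmonization inverts the stored pH 6 encoding exactly
  h <- harmonize_ph(tab, quiet = TRUE)
  base <- h[seq_len(truth$n), ]
  is6 <- base$ph == 6
  expect_gt(sum(is6), 0)
  expect_equal(base$log10_kd[is6], truth$y_true[is6], tolerance = 1e-9)
  expect_equal(base$log10_kd[!is6], truth$y_true[!is6], tolerance = 1e-12)
})

test_that("single-effect estimates follow the planted weights exactly", {
  gen <- gen_fixture()
  # the truth has a positive weight on the ASA of position 252: mutating
  # M252 to a larger residue raises its surface area, hence the response
  singles <- make_singles_table(gen, positions = c(252, 434),
                                mutations = c("M252W", "M252G", "N434W"))
  eff <- stats::setNames(singles$effect, singles$mutation)
  expect_gt(eff[["M252W"]], 0)
  expect_lt(eff[["M252G"]], eff[["M252W"]])

  # recomputing from the truth function matches to numerical identity
  tr <- gen$truth
  wn <- names(tr$weights)
  x <- variant_features("M252W", gen$reference, gen$catalog)
  xs <- scale(x[, wn, drop = FALSE], center = tr$scaler_center[wn],
              scale = tr$scaler_scale[wn])
  xw <- variant_features("WT", gen$reference, gen$catalog)
  xws <- scale(xw[, wn, drop = FALSE], center = tr$scaler_center[wn],
               scale = tr$scaler_scale[wn])
  expect_equal(eff[["M252W"]],
               as.numeric(xs %*% tr$weights) - as.numeric(xws %*% tr$weights),
               tolerance = 1e-12)

  # a wild-type signature has zero effect by construction
  wt0 <- make_singles_table(gen, mutations = "WT")
  expect_equal(wt0$effect, 0, tolerance = 1e-12)
})

test_that("generation is reproducible from the seed", {
  g1 <- fixture("gen_zero", function()
    make_variant_table(synthetic_truth(n = 60, sigma = 0, seed = 3),
                       reference = ref_fixture(),
                       catalog = catalog_fixture()))
  g2 <- make_variant_table(synthetic_truth(n = 60, sigma = 0, seed = 3),
                           reference = ref_fixture(),
                           catalog = catalog_fixture())
  expect_identical(g1$table, g2$table)
  expect_identical(g1$truth$y_true, g2$truth$y_true)
})
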