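test_that("mutation strings parse to canonical, order-free variant specs", {
  a3 <- parse_mutations("M252W/M428K/N434W")
  expect_equal(nrow(a3$mutations), 3)
  expect_equal(a3$mutations$pos, c(252, 428, 434))
  expect_equal(mutation_string(a3), "M252W/M428K/N434W")

  expect_true(variant_equal(parse_mutations("N434Y/M252Y"),
                            parse_mutations("M252Y/N434Y")))
  expect_equal(mutation_string(parse_mutations("WT")), "WT")
})

test_that("malformed mutation strings are rejected with the bad token", {
  expect_error(parse_mutations("M252M"), "M252M")
  expect_error(parse_mutations("M252"), "M252")
  expect_error(parse_mutations("M252Y/S252T"), "duplicate")
  expect_error(parse_mutations("X252Y"), "X252Y")
  expect_error(parse_mutations(""), "empty")
  expect_error(parse_mutations(paste(
    paste0(c("L", "M", "I", "S", "R", "T", "P", "H", "N", "K", "T", "V", "L"),
           c(251:257, 285, 286, 288, 307:309), "A"), collapse = "/")),
    "limit")
})

test_that("side-chain replacement leaves everything else bitwise intact", {
  ref <- ref_fixture()
  mut <- apply_mutations(ref, "N434G")
  res <- mut$atoms[mut$atoms$role == "FC" & mut$atoms$eu == 434, ]
  expect_setequal(res$elety, c("N", "CA", "C", "O"))     # glycine
  expect_true(all(res$aa == "G"))

  mut_a <- apply_mutations(ref, "N434A")
  res_a <- mut_a$atoms[mut_a$atoms$role == "FC" & mut_a$atoms$eu == 434, ]
  expect_setequal(res_a$elety, c("N", "CA", "C", "O", "CB"))

  other <- mut$atoms$role != "FC" | mut$atoms$eu != 434
  other_ref <- ref$atoms$role != "FC" | ref$atoms$eu != 434
  expect_identical(unname(as.matrix(mut$atoms[other, c("x", "y", "z")])),
                   unname(as.matrix(ref$atoms[other_ref,
                                              c("x", "y", "z")])))
})

test_that("wild-type mismatches stop with expected vs found", {
  ref <- ref_fixture()
  expect_error(apply_mutations(ref, "S434A"), "expected S, found N")
  expect_error(apply_mutations(ref, "A999G"), "999")
  # applying a variant twice violates the wild-type precondition
  m1 <- apply_mutations(ref, "M252Y")
  expect_error(apply_mutations(m1, "M252Y"), "expected M, found Y")
})

test_that("mutation is deterministic and the chosen rotamer is clash-optimal", {
  ref <- ref_fixture()
  m1 <- apply_mutations(ref, "T256R")
  m2 <- apply_mutations(ref, "T256R")
  expect_identical(m1$atoms, m2$atoms)

  # recompute every scanned rotamer's clash score; chosen must be minimal
  res <- m1$atoms[m1$atoms$role == "FC" & m1$atoms$eu == 256, ]
  bbv <- function(nm) unlist(res[res$elety == nm, c("x", "y", "z")],
                             use.names = FALSE)
  env <- m1$atoms[!(m1$atoms$role == "FC" & m1$atoms$eu == 256), ]
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  chosen_sc <- res[!res$elety %in% c("N", "CA", "C", "O"), ]
  chosen_score <- fcaffinity:::.clash_score_cpp(
    as.matrix(chosen_sc[, c("x", "y", "z")]), chosen_sc$radius,
    env_xyz, env$radius)
  grid <- seq(-180, 150, by = 30)
  scores <- c()
  for (c1 in grid) for (c2 in grid) {
    sc <- fcaffinity:::.build_side_chain_mat("R", bbv("N"), bbv("CA"),
                                             bbv("C"), c1, c2)
    scores <- c(scores, fcaffinity:::.clash_score_cpp(
      sc$xyz, vdw_radius(sc$elements), env_xyz, env$radius))
  }
  expect_lte(chosen_score, min(scores) + 1e-9)
})

test_that("with no neighbors the first scanned rotamer wins", {
  iso <- tiny_complex(rbind(
    tiny_atom("FC", "A", 1, "A", "N", -1.2, -0.8, 0),
    tiny_atom("FC", "A", 1, "A", "CA", 0, 0, 0),
    tiny_atom("FC", "A", 1, "A", "C", 1.25, -0.45, 0),
    tiny_atom("FC", "A", 1, "A", "O", 1.5, -1.65, 0),
    tiny_atom("FC", "A", 1, "A", "CB", 0.2, 1.45, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "G", "N", 98.8, -0.8, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "G", "CA", 100, 0, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "G", "C", 101.25, -0.45, 0),
    tiny_atom("FCRN_ALPHA", "B", 1, "G", "O", 101.5, -1.65, 0)))
  mut <- apply_mutations(iso, "A1S")
  got <- mut$atoms[mut$atoms$elety %in% c("CB", "OG"), c("x", "y", "z")]
  first <- fcaffinity:::.build_side_chain("S",
    c(-1.2, -0.8, 0), c(0, 0, 0), c(1.25, -0.45, 0), chi1 = -180, chi2 = -180)
  expect_equal(unname(as.matrix(got)),
               unname(as.matrix(first[, c("x", "y", "z")])),
               tolerance = 1e-12)
})
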