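# Synthetic fixtures with known ground truth: toy complexes with planted,
# exactly countable interface geometry; a synthetic reference Fc/FcRn/B2M
# complex for the featurization and learning path; variant/affinity tables
# generated from a known linear function of the extracted features.

# ---------------------------------------------------------------------------
# toy complexes with planted geometry

.toy_bb <- function(x0, ybase, dir) {
  # backbone N/CA/C/O with the carbonyl O pointing away from the interface
  rbind(N = c(x0 - 1.20, ybase - dir * 0.80, 0),
        CA = c(x0, ybase, 0),
        C = c(x0 + 1.25, ybase - dir * 0.45, 0),
        O = c(x0 + 1.50, ybase - dir * 1.65, 0))
}

.toy_res <- function(aa, atoms) {
  data.frame(aa = aa, elety = rownames(atoms),
             element = substr(rownames(atoms), 1, 1),
             x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
             stringsAsFactors = FALSE)
}

#' Build a toy two- or three-chain complex with planted interface geometry
#'
#' Constructs short peptide chains (Fc-role chain A, FcRn-role chain B and,
#' when `b2m_contacts` are requested or `n_b2m > 0`, a B2M-role chain C)
#' in which every requested interaction is planted at an exact stated
#' distance inside its detection cutoff while every other cross-chain atom
#' pair stays outside cutoff + 0.5 Angstrom. Each planted interaction
#' occupies its own 14-Angstrom slot along x, so interactions cannot
#' interfere. The accompanying manifest records exactly the counts the
#' interface featurizer must return, including cross-feature implications
#' (a salt bridge within 3.5 A is also a hydrogen bond; every salt bridge
#' pairs two hydrophilic residues).
#'
#' @param hbonds numeric vector of donor-acceptor distances (<= 3.5) to
#'   plant as Ser OG to backbone O hydrogen bonds.
#' @param salt_bridges distances (<= 4.0) for Lys NZ to Asp OD1 bridges.
#' @param ca_contacts distances (<= 4.0) for Gly CA-CA contacts.
#' @param hydrophilic distances (<= 4.0) for Ser OG to Asn ND2 contacts.
#' @param b2m_contacts distances (<= 4.0) for Fc Ala CB to B2M Ala CB
#'   contacts.
#' @param n_fc,n_fcrn,n_b2m residue counts per chain (padding with
#'   non-interacting alanines).
#' @return list with `pdb` (PDB text), `model` (the `fc_complex`),
#'   `chain_map`, and `manifest`.
#' @export
make_toy_complex <- function(hbonds = numeric(0), salt_bridges = numeric(0),
                             ca_contacts = numeric(0),
                             hydrophilic = numeric(0),
                             b2m_contacts = numeric(0),
                             n_fc = 8L, n_fcrn = 6L, n_b2m = 0L) {
  chk <- function(v, lim, what) {
    if (any(v <= 0 | v > lim))
      stop("infeasible ", what, ": distances must be in (0, ", lim, "]")
  }
  chk(hbonds, 3.5, "hydrogen bonds")
  chk(salt_bridges, 4.0, "salt bridges")
  chk(ca_contacts, 4.0, "CA contacts")
  chk(hydrophilic, 4.0, "hydrophilic pairs")
  chk(b2m_contacts, 4.0, "B2M contacts")
  n_ab <- length(hbonds) + length(salt_bridges) + length(ca_contacts) +
    length(hydrophilic)
  n_ac <- length(b2m_contacts)
  if (n_ab + n_ac > n_fc)
    stop("infeasible packing: ", n_ab + n_ac, " planted Fc residues but ",
         "n_fc = ", n_fc)
  if (n_ab > n_fcrn)
    stop("infeasible packing: ", n_ab, " planted FcRn residues but ",
         "n_fcrn = ", n_fcrn)
  if (n_ac > 0 && n_ac > n_b2m)
    stop("infeasible packing: ", n_ac, " planted B2M residues but ",
         "n_b2m = ", n_b2m)

  slot_w <- 14
  slot <- 0L
  resA <- list(); resB <- list(); resC <- list()

  add_pair <- function(kind, d) {
    slot <<- slot + 1L
    x0 <- slot * slot_w
    if (kind == "hb") {
      a <- .toy_bb(x0, 0, +1)
      a <- rbind(a, CB = c(x0 + 0.2, 1.45, 0), OG = c(x0 + 0.2, 2.87, 0))
      resA[[length(resA) + 1L]] <<- .toy_res("S", a)
      yo <- 2.87 + d
      b <- rbind(O = c(x0 + 0.2, yo, 0),
                 C = c(x0 + 0.5, yo + 1.19, 0),
                 CA = c(x0 - 0.95, yo + 1.64, 0),
                 N = c(x0 - 2.15, yo + 2.44, 0))
      resB[[length(resB) + 1L]] <<- .toy_res("G", b[c("N", "CA", "C", "O"), ])
    } else if (kind == "sb") {
      a <- .toy_bb(x0, 0, +1)
      a <- rbind(a, CB = c(x0 + 0.2, 1.45, 0), CG = c(x0 - 0.1, 2.90, 0),
                 CD = c(x0 + 0.2, 4.35, 0), CE = c(x0 - 0.1, 5.80, 0),
                 NZ = c(x0 + 0.2, 7.20, 0))
      resA[[length(resA) + 1L]] <<- .toy_res("K", a)
      yo <- 7.20 + d
      b <- rbind(OD1 = c(x0 + 0.2, yo, 0),
                 CG = c(x0 + 0.7, yo + 1.15, 0),
                 OD2 = c(x0 + 1.8, yo + 1.75, 0),
                 CB = c(x0 - 0.1, yo + 2.45, 0),
                 CA = c(x0 + 0.2, yo + 3.95, 0),
                 N = c(x0 - 1.0, yo + 4.75, 0),
                 C = c(x0 + 1.45, yo + 4.40, 0),
                 O = c(x0 + 1.7, yo + 5.60, 0))
      resB[[length(resB) + 1L]] <<-
        .toy_res("D", b[c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"), ])
    } else if (kind == "ca") {
      resA[[length(resA) + 1L]] <<- .toy_res("G", .toy_bb(x0, 0, +1))
      resB[[length(resB) + 1L]] <<- .toy_res("G", .toy_bb(x0, d, -1))
    } else if (kind == "phil") {
      a <- .toy_bb(x0, 0, +1)
      a <- rbind(a, CB = c(x0 + 0.2, 1.45, 0), OG = c(x0 + 0.2, 2.87, 0))
      resA[[length(resA) + 1L]] <<- .toy_res("S", a)
      yo <- 2.87 + d
      b <- rbind(ND2 = c(x0 + 0.2, yo, 0),
                 CG = c(x0 + 0.7, yo + 1.23, 0),
                 OD1 = c(x0 + 1.8, yo + 1.78, 0),
                 CB = c(x0 - 0.1, yo + 2.53, 0),
                 CA = c(x0 + 0.2, yo + 4.03, 0),
                 N = c(x0 - 1.0, yo + 4.83, 0),
                 C = c(x0 + 1.45, yo + 4.48, 0),
                 O = c(x0 + 1.7, yo + 5.68, 0))
      resB[[length(resB) + 1L]] <<-
        .toy_res("N", b[c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"), ])
    } else if (kind == "b2m") {
      a <- .toy_bb(x0, 0, +1)
      a <- rbind(a, CB = c(x0 + 0.2, 1.45, 0))
      resA[[length(resA) + 1L]] <<- .toy_res("A", a)
      yb <- 1.45 + d
      c_ <- rbind(CB = c(x0 + 0.2, yb, 0),
                  CA = c(x0, yb + 1.45, 0),
                  N = c(x0 - 1.2, yb + 2.25, 0),
                  C = c(x0 + 1.25, yb + 1.90, 0),
                  O = c(x0 + 1.5, yb + 3.10, 0))
      resC[[length(resC) + 1L]] <<-
        .toy_res("A", c_[c("N", "CA", "C", "O", "CB"), ])
    }
  }
  for (d in hbonds) add_pair("hb", d)
  for (d in salt_bridges) add_pair("sb", d)
  for (d in ca_contacts) add_pair("ca", d)
  for (d in hydrophilic) add_pair("phil", d)
  for (d in b2m_contacts) add_pair("b2m", d)

  pad <- function(lst, n_total, ybase, dir) {
    while (length(lst) < n_total) {
      slot <<- slot + 1L
      x0 <- slot * slot_w
      a <- .toy_bb(x0, ybase, dir)
      a <- rbind(a, CB = c(x0 + 0.2, ybase + dir * 1.45, 0))
      lst[[length(lst) + 1L]] <- .toy_res("A", a)
    }
    lst
  }
  resA <- pad(resA, n_fc, 0, +1)
  resB <- pad(resB, n_fcrn, 12, -1)
  if (n_b2m > 0) resC <- pad(resC, n_b2m, 12, -1)

  assemble <- function(res_list, role, chain) {
    out <- list()
    for (i in seq_along(res_list)) {
      r <- res_list[[i]]
      out[[i]] <- data.frame(role = role, chain = chain, resno = i, eu = i,
                             aa = r$aa, elety = r$elety,
                             element = r$element, x = r$x, y = r$y,
                             z = r$z, radius = vdw_radius(r$element),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  atoms <- rbind(assemble(resA, "FC", "A"),
                 assemble(resB, "FCRN_ALPHA", "B"),
                 if (n_b2m > 0) assemble(resC, "B2M", "C"))
  rownames(atoms) <- NULL
  chain_map <- c(FC = "A", FCRN_ALPHA = "B",
                 if (n_b2m > 0) c(B2M = "C"))
  model <- structure(list(atoms = atoms, chain_map = chain_map,
                          source_id = "toy_complex"),
                     class = "fc_complex")

  hb_all <- c(hbonds, salt_bridges[salt_bridges <= 3.5],
              hydrophilic[hydrophilic <= 3.5])
  manifest <- list(
    hbonds = length(hb_all),
    mean_hbond_distance = if (length(hb_all)) mean(hb_all) else 0,
    salt_bridges = length(salt_bridges),
    ca_contacts = length(ca_contacts),
    paired_hydrophilic = length(hydrophilic) + length(salt_bridges),
    b2m_fc_atom_contacts = 2L * length(b2m_contacts),
    interface_residues = 2L * (n_ab + n_ac),
    residues_per_chain = c(FC = n_fc, FCRN_ALPHA = n_fcrn,
                           if (n_b2m > 0) c(B2M = n_b2m)))
  list(pdb = write_complex(model), model = model, chain_map = chain_map,
       manifest = manifest)
}

# ---------------------------------------------------------------------------
# synthetic reference complex for the featurization / learning path

.FCRN_SEQ <- c("E", "S", "K", "E", "Y", "L", "Q", "D", "N", "E",
               "T", "K", "S", "H", "R", "Q")          # author 120..135
.B2M_SEQ <- c("K", "T", "P", "Q", "D", "N", "S", "E") # author 1..8

#' Build the synthetic reference Fc/FcRn/B2M complex
#'
#' A deterministic stand-in for a crystallographic Fc/FcRn co-complex: the
#' Fc chain carries the 21 catalog interface positions (EU numbering, with
#' wild-type IgG1 identities), facing a 16-residue FcRn alpha-chain
#' segment (author numbering 120-135, including position 129) and an
#' 8-residue B2M segment across a parallel interface. Side chains are
#' built from the ideal template geometry. The complex is synthetic: its
#' absolute feature values mean nothing, but mutations change them in a
#' structured, reproducible way, which is what the learning pipeline
#' needs.
#'
#' @param y_sep distance between the facing backbone lines, Angstrom.
#' @return an `fc_complex` with 21 + 16 + 8 residues.
#' @export
make_reference_complex <- function(y_sep = 7.5) {
  mk_res <- function(aa, x0, ybase, dir) {
    bb <- .toy_bb(x0, ybase, dir)
    sc <- .build_side_chain(aa, bb["N", ], bb["CA", ], bb["C", ],
                            chi1 = -60, chi2 = 180)
    df <- .toy_res(aa, bb)
    if (nrow(sc))
      df <- rbind(df, data.frame(aa = aa, elety = sc$name,
                                 element = sc$element, x = sc$x, y = sc$y,
                                 z = sc$z, stringsAsFactors = FALSE))
    df
  }
  rows <- list()
  add <- function(aa, role, chain, resno, x0, ybase, dir) {
    r <- mk_res(aa, x0, ybase, dir)
    rows[[length(rows) + 1L]] <<- data.frame(
      role = role, chain = chain, resno = resno, eu = resno, aa = r$aa,
      elety = r$elety, element = r$element, x = r$x, y = r$y, z = r$z,
      radius = vdw_radius(r$element), stringsAsFactors = FALSE)
  }
  for (i in seq_along(.FC_CATALOG_POSITIONS)) {
    eu <- .FC_CATALOG_POSITIONS[i]
    add(.FC_WILDTYPE[[as.character(eu)]], "FC", "A", eu,
        6 * (i - 1), 0, +1)
  }
  for (i in seq_along(.FCRN_SEQ)) {
    add(.FCRN_SEQ[i], "FCRN_ALPHA", "B", 119 + i, 3 + 6 * (i - 1),
        y_sep, -1)
  }
  for (i in seq_along(.B2M_SEQ)) {
    add(.B2M_SEQ[i], "B2M", "C", i, 99 + 6 * (i - 1), y_sep, -1)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 chain_map = c(FC = "A", FCRN_ALPHA = "B", B2M = "C"),
                 source_id = "synthetic_reference"),
            class = "fc_complex")
}

# ---------------------------------------------------------------------------
# synthetic variant / affinity tables

#' Default generative truth for synthetic variant tables
#'
#' Linear weights on scaled features (surface areas of frequently mutated
#' Fc positions plus the hydrogen-bond count), noise on the log10 KD
#' scale, the sample size and nuisance-record structure emulating a
#' curated patent-derived dataset: a pH 6.0 minority measured by a less
#' accurate method, planted effective-signature duplicates, and a few
#' non-binders.
#'
#' @param n number of base variants.
#' @param sigma log10 KD noise standard deviation.
#' @param seed RNG seed.
#' @return list of generative parameters for [make_variant_table()].
#' @export
synthetic_truth <- function(n = 500L, sigma = 0.15, seed = 1L) {
  list(weights = c(asa_FC_252 = 0.8, bsa_FC_434 = -0.6, solv_FC_256 = 0.5,
                   asa_FC_308 = -0.4, asa_FC_286 = 0.4,
                   cx_paired_hydrophilic = -0.3),
       intercept = -7,
       sigma = sigma, n = as.integer(n),
       mutation_range = 1:5,
       dup_pairs = 5L, ph6_fraction = 0.17, nonbinders = 3L,
       seed = as.integer(seed))
}

#' Generate a synthetic variant/affinity table with known truth
#'
#' Samples unique variant specifications over the 21 catalog positions,
#' models each on the reference complex, extracts catalog features, and
#' draws `log10 KD = intercept + w . scaled(features) + Normal(0, sigma)`.
#' A fraction of records is stored at pH 6.0 with `KD / factor` (so the
#' curation step must invert the transformation), duplicate pairs are
#' planted by appending an off-catalog decoy mutation (L235R) to copies of
#' existing records, and a few non-binder rows are added.
#'
#' @param truth generative parameters, see [synthetic_truth()].
#' @param reference reference `fc_complex`
#'   (default [make_reference_complex()]).
#' @param catalog feature catalog (default [default_catalog()] on the
#'   reference).
#' @param factor pH harmonization factor used to *encode* pH 6 records.
#' @param n_points SASA quadrature points for featurization.
#' @return list with `table` (raw variant table data.frame), `truth`
#'   (augmented with the scaler, specs, true responses and feature
#'   matrix), `reference`, `catalog`.
#' @export
make_variant_table <- function(truth = synthetic_truth(),
                               reference = make_reference_complex(),
                               catalog = default_catalog(reference),
                               factor = harmonization_factor(),
                               n_points = 960L) {
  set.seed(truth$seed)
  wt <- .wildtype_at(reference, .FC_CATALOG_POSITIONS)
  aa20 <- names(.AA3)
  specs <- list(); seen <- character(0)
  while (length(specs) < truth$n) {
    k <- sample(truth$mutation_range, 1L)
    pos <- sort(sample(.FC_CATALOG_POSITIONS, k))
    mut <- vapply(as.character(pos), function(p)
      sample(setdiff(aa20, wt[[p]]), 1L), "")
    sp <- variant_spec(data.frame(wt = unname(wt[as.character(pos)]),
                                  pos = pos, mut = unname(mut),
                                  stringsAsFactors = FALSE))
    sig <- mutation_string(sp)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    specs[[length(specs) + 1L]] <- sp
  }

  x <- variant_features(specs, reference, catalog, n_points = n_points)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  wn <- names(truth$weights)
  missing <- setdiff(wn, colnames(x))
  if (length(missing))
    stop("truth weights name unknown features: ",
         paste(missing, collapse = ", "))
  degenerate <- wn[scl[wn] < 1e-9]
  if (length(degenerate))
    stop("truth weight features are constant in this design: ",
         paste(degenerate, collapse = ", "))
  xs <- scale(x[, wn, drop = FALSE], center = ctr[wn], scale = scl[wn])
  y_clean <- unname(truth$intercept + drop(xs %*% truth$weights))
  y <- y_clean + stats::rnorm(truth$n, 0, truth$sigma)

  muts <- vapply(specs, mutation_string, "")
  n <- truth$n
  ph <- rep(7, n)
  method <- rep("SPR", n)
  n6 <- round(truth$ph6_fraction * n)
  if (n6 > 0) {
    idx6 <- sample(n, n6)
    ph[idx6] <- 6
    method[idx6] <- "ELISA"
  }
  kd_true <- 10^y
  kd_stored <- ifelse(ph == 6, kd_true / factor, kd_true)
  tab <- data.frame(mutations = muts, kd_molar = kd_stored, ph = ph,
                    method = method, binder_flag = "measured",
                    stringsAsFactors = FALSE)

  # planted duplicates: copies with an off-catalog decoy; donor rows get
  # the partner decoy so the pair matches the classic S239K/L235R motif
  dup_src <- integer(0)
  if (truth$dup_pairs > 0) {
    dup_src <- sample(which(ph == 7), truth$dup_pairs)
    dups <- tab[dup_src, , drop = FALSE]
    tab$mutations[dup_src] <- paste0("S239K/", tab$mutations[dup_src])
    dups$mutations <- paste0("L235R/", dups$mutations)
    tab <- rbind(tab, dups)
  }
  if (truth$nonbinders > 0) {
    nb <- data.frame(mutations = rep("I253A", truth$nonbinders),
                     kd_molar = NA_real_, ph = 7, method = "SPR",
                     binder_flag = "non_binder", stringsAsFactors = FALSE)
    tab <- rbind(tab, nb)
  }
  rownames(tab) <- NULL

  truth$scaler_center <- ctr
  truth$scaler_scale <- scl
  truth$specs <- muts
  truth$y_true <- y
  truth$y_clean <- y_clean
  truth$features <- x
  truth$dup_rows <- dup_src
  list(table = tab, truth = truth, reference = reference,
       catalog = catalog)
}

#' Exact single-mutation effects under a synthetic truth
#'
#' For each candidate single mutation, the noiseless change in log10 KD
#' relative to wild type implied by the generative truth function
#' (weights on scaled features). Used to feed [constrained_library()].
#'
#' @param generated output of [make_variant_table()].
#' @param positions EU positions to scan (default the 21 catalog
#'   positions).
#' @param mutations optional character vector restricting the scan (e.g.
#'   `c("M252Y", "N434W")`).
#' @param n_points SASA quadrature points.
#' @return data.frame with columns `mutation` and `effect`.
#' @export
make_singles_table <- function(generated,
                               positions = .FC_CATALOG_POSITIONS,
                               mutations = NULL, n_points = 960L) {
  truth <- generated$truth
  reference <- generated$reference
  catalog <- generated$catalog
  wt <- .wildtype_at(reference, positions)
  if (is.null(mutations)) {
    mutations <- unlist(lapply(as.character(positions), function(p)
      paste0(wt[[p]], p, setdiff(names(.AA3), wt[[p]]))))
  }
  wn <- names(truth$weights)
  truth_value <- function(spec_str) {
    x <- variant_features(spec_str, reference, catalog,
                          n_points = n_points)
    xs <- scale(x[, wn, drop = FALSE],
                center = truth$scaler_center[wn],
                scale = truth$scaler_scale[wn])
    truth$intercept + drop(xs %*% truth$weights)
  }
  base <- truth_value("WT")
  eff <- vapply(mutations, function(m)
    unname(truth_value(m) - base), numeric(1))
  data.frame(mutation = mutations, effect = unname(eff),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# plain regression tables for the learning-module tests

#' Generate a plain synthetic regression table
#'
#' Independent standard-normal features, a linear response on the first
#' `length(weights)` of them plus Gaussian noise. Used to exercise the
#' selection and cross-validation machinery without the structural path.
#'
#' @param n sample size.
#' @param weights numeric weights of the informative features.
#' @param n_noise number of pure-noise features appended.
#' @param sigma noise standard deviation.
#' @param seed RNG seed.
#' @return list with `x` (matrix, named columns), `y`, `informative`
#'   (column names carrying signal), `weights`, `sigma`.
#' @export
make_regression_table <- function(n = 500L, weights = c(3, 2, 1),
                                  n_noise = 7L, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  p <- length(weights) + n_noise
  x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  y <- drop(x[, seq_along(weights), drop = FALSE] %*% weights) +
    stats::rnorm(n, 0, sigma)
  list(x = x, y = y, informative = colnames(x)[seq_along(weights)],
       weights = weights, sigma = sigma)
}
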