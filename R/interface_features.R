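# Structure-derived interface features: solvent accessibility, solvation
# energies, and inter-chain contact counts.

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by sphere-point quadrature: each atom's sphere of radius
#' `r_i + probe` is sampled on a deterministic quasi-uniform point set and
#' points falling inside any other expanded sphere are occluded.
#'
#' @param xyz numeric matrix (n x 3) of heavy-atom coordinates (Angstrom).
#' @param radii numeric vector of van der Waals radii.
#' @param probe solvent probe radius, Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 960; minimum 100).
#' @return numeric vector of per-atom areas (Angstrom^2).
#' @export
atom_sasa <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, length(radii) == nrow(xyz),
            all(is.finite(xyz)), all(radii > 0))
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 100) stop("n_points must be at least 100")
  .sasa_cpp(xyz, as.numeric(radii), probe, as.integer(n_points))
}

# Per-atom SASA of the model in complex and in isolated chains.
.sasa_tables <- function(model, probe = 1.4, n_points = 960L) {
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  complex_area <- atom_sasa(xyz, at$radius, probe, n_points)
  iso <- numeric(nrow(at))
  for (role in unique(at$role)) {
    sel <- at$role == role
    iso[sel] <- atom_sasa(xyz[sel, , drop = FALSE], at$radius[sel],
                          probe, n_points)
  }
  list(complex = complex_area, isolated = iso)
}

#' Accessible and buried surface area of one residue
#'
#' `ASA` is the residue's SASA summed over its atoms in the whole complex;
#' `BSA` is its SASA in the isolated chain minus `ASA` (area buried upon
#' complex formation). BSA can be a small negative number of quadrature
#' magnitude; it is not clipped.
#'
#' @param model an `fc_complex`.
#' @param role,eu residue site selector.
#' @param probe,n_points quadrature settings (see [atom_sasa()]).
#' @return named numeric vector `c(asa = ..., bsa = ...)`.
#' @export
residue_asa_bsa <- function(model, role, eu, probe = 1.4, n_points = 960L) {
  tabs <- .sasa_tables(model, probe, n_points)
  sel <- model$atoms$role == role & model$atoms$eu == eu
  if (!any(sel)) stop("no residue at ", role, " ", eu)
  asa <- sum(tabs$complex[sel])
  c(asa = asa, bsa = sum(tabs$isolated[sel]) - asa)
}

#' Atomic solvation energy of a residue
#'
#' Sum over the residue's atoms of `ASP(element) * SASA(atom)` with a fixed
#' atomic-solvation-parameter table (kcal/mol/A^2: C +0.016, S +0.021,
#' N/O -0.006). SASA is taken in the complex context.
#'
#' @inheritParams residue_asa_bsa
#' @param asp named replacement for the solvation parameter table.
#' @return energy in kcal/mol.
#' @export
solvation_energy <- function(model, role, eu, probe = 1.4, n_points = 960L,
                             asp = .ASP_TABLE) {
  tabs <- .sasa_tables(model, probe, n_points)
  sel <- model$atoms$role == role & model$atoms$eu == eu
  if (!any(sel)) stop("no residue at ", role, " ", eu)
  .solv_from_area(model$atoms$element[sel], tabs$complex[sel], asp)
}

.solv_from_area <- function(elements, areas, asp = .ASP_TABLE) {
  w <- asp[toupper(elements)]
  if (anyNA(w)) stop("unknown element for solvation parameters: ",
                     paste(unique(elements[is.na(w)]), collapse = ", "))
  sum(w * areas)
}

#' Solvation energy gain of complex formation
#'
#' `E(complex) - sum of E(isolated chains)`, both computed as
#' `sum(ASP * SASA)` over all atoms; negative values mean burial of apolar
#' area is favorable.
#'
#' @inheritParams residue_asa_bsa
#' @param asp solvation parameter table.
#' @return energy in kcal/mol.
#' @export
solvation_gain <- function(model, probe = 1.4, n_points = 960L,
                           asp = .ASP_TABLE) {
  tabs <- .sasa_tables(model, probe, n_points)
  el <- model$atoms$element
  .solv_from_area(el, tabs$complex, asp) - .solv_from_area(el, tabs$isolated,
                                                           asp)
}

# All inter-chain atom pairs within cutoff between two atom subsets.
# Returns data.frame i, j (row indices into model$atoms), d.
.cross_pairs <- function(model, sel_a, sel_b, cutoff) {
  a <- which(sel_a); b <- which(sel_b)
  if (!length(a) || !length(b))
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  at <- model$atoms
  ax <- as.matrix(at[a, c("x", "y", "z")])
  bx <- as.matrix(at[b, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  # tiny slack so pairs planted exactly at the cutoff are not lost to
  # floating-point roundoff in the cross-product distance formula
  hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  data.frame(i = a[hit[, 1]], j = b[hit[, 2]],
             d = sqrt(d2[hit]))
}

# Donor/acceptor atom masks for hydrogen bonding.
.hb_mask <- function(at, table) {
  mask <- at$elety %in% table$backbone
  for (aa in setdiff(names(table), "backbone")) {
    mask <- mask | (at$aa == aa & at$elety %in% table[[aa]])
  }
  mask
}

#' Count inter-chain hydrogen bonds
#'
#' Heavy-atom donor-acceptor pairs (N/O chemistry from a fixed per-residue
#' atom table) across different chain roles within `cutoff` (default 3.5
#' Angstrom). Both donor->acceptor directions are examined; an atom pair is
#' counted once.
#'
#' @param model an `fc_complex`.
#' @param cutoff donor-acceptor distance cutoff, Angstrom.
#' @return list with `count` and `mean_distance` (0 when count is 0).
#' @export
count_hbonds <- function(model, cutoff = 3.5) {
  at <- model$atoms
  don <- .hb_mask(at, .HB_DONORS)
  acc <- .hb_mask(at, .HB_ACCEPTORS)
  p1 <- .cross_pairs_roles(model, don, acc, cutoff)
  p2 <- .cross_pairs_roles(model, acc, don, cutoff)
  key <- unique(c(paste(pmin(p1$i, p1$j), pmax(p1$i, p1$j)),
                  paste(pmin(p2$i, p2$j), pmax(p2$i, p2$j))))
  all_p <- rbind(p1, p2)
  all_key <- paste(pmin(all_p$i, all_p$j), pmax(all_p$i, all_p$j))
  d <- all_p$d[match(key, all_key)]
  list(count = length(key),
       mean_distance = if (length(key)) mean(d) else 0)
}

# cross-pairs restricted to atoms on different chain roles
.cross_pairs_roles <- function(model, mask_a, mask_b, cutoff) {
  roles <- unique(model$atoms$role)
  out <- list()
  for (ra in roles) for (rb in roles) {
    if (ra >= rb) next
    p <- rbind(
      .cross_pairs(model, mask_a & model$atoms$role == ra,
                   mask_b & model$atoms$role == rb, cutoff),
      .cross_pairs(model, mask_a & model$atoms$role == rb,
                   mask_b & model$atoms$role == ra, cutoff))
    out[[paste(ra, rb)]] <- p
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count inter-chain salt bridges
#'
#' Pairs of oppositely charged side-chain group atoms (Asp/Glu carboxylate
#' oxygens vs Lys NZ, Arg NE/NH1/NH2, His ND1/NE2) on different chain roles
#' within `cutoff` (default 4.0 Angstrom), counted once per residue pair
#' regardless of how many atom pairs qualify.
#'
#' @inheritParams count_hbonds
#' @return integer count.
#' @export
count_salt_bridges <- function(model, cutoff = 4.0) {
  nrow(.salt_bridge_pairs(model, cutoff, per = "residue"))
}

.salt_bridge_pairs <- function(model, cutoff, per = c("residue", "atom")) {
  per <- match.arg(per)
  at <- model$atoms
  neg <- .hb_mask(at, c(list(backbone = character(0)), .SB_NEG))
  pos <- .hb_mask(at, c(list(backbone = character(0)), .SB_POS))
  p <- .cross_pairs_roles(model, neg, pos, cutoff)
  if (!nrow(p)) return(p)
  if (per == "atom") return(p)
  rk <- paste(at$role[p$i], at$eu[p$i], at$role[p$j], at$eu[p$j])
  p[!duplicated(rk), , drop = FALSE]
}

#' Count inter-chain C-alpha contacts
#'
#' C-alpha pairs on different chain roles within `cutoff` (default 4.0
#' Angstrom), counted per pair.
#'
#' @inheritParams count_hbonds
#' @return integer count.
#' @export
count_ca_contacts <- function(model, cutoff = 4.0) {
  ca <- model$atoms$elety == "CA"
  p <- .cross_pairs_roles(model, ca, ca, cutoff)
  if (!nrow(p)) return(0L)
  length(unique(paste(pmin(p$i, p$j), pmax(p$i, p$j))))
}

#' Count paired hydrophilic residues across the interface
#'
#' Residue pairs on different chain roles, both members of the hydrophilic
#' set (S, T, N, Q, Y, H, K, R, D, E), with any heavy-atom pair within
#' `cutoff` (default 4.0 Angstrom); counted per residue pair.
#'
#' @inheritParams count_hbonds
#' @return integer count.
#' @export
count_paired_hydrophilic <- function(model, cutoff = 4.0) {
  at <- model$atoms
  phil <- at$aa %in% .HYDROPHILIC
  p <- .cross_pairs_roles(model, phil, phil, cutoff)
  if (!nrow(p)) return(0L)
  ka <- paste(at$role[p$i], at$eu[p$i])
  kb <- paste(at$role[p$j], at$eu[p$j])
  length(unique(paste(pmin(ka, kb), pmax(ka, kb))))
}

#' Count atoms in contact between beta-2-microglobulin and the Fc
#'
#' Number of distinct heavy atoms (on either side) participating in at
#' least one Fc/B2M cross-chain pair within `cutoff` (default 4.0
#' Angstrom). Returns 0 when the model carries no B2M chain.
#'
#' @inheritParams count_hbonds
#' @return integer count of contact atoms.
#' @export
count_b2m_fc_atom_contacts <- function(model, cutoff = 4.0) {
  at <- model$atoms
  if (!any(at$role == "B2M")) return(0L)
  p <- .cross_pairs(model, at$role == "FC", at$role == "B2M", cutoff)
  length(unique(c(p$i, p$j)))
}

#' Count interface residues
#'
#' Residues with buried surface area above `bsa_min` (default 0.1
#' Angstrom^2).
#'
#' @inheritParams residue_asa_bsa
#' @param bsa_min BSA threshold in Angstrom^2.
#' @return integer count.
#' @export
interface_residue_count <- function(model, bsa_min = 0.1, probe = 1.4,
                                    n_points = 960L) {
  tabs <- .sasa_tables(model, probe, n_points)
  bsa_at <- tabs$isolated - tabs$complex
  key <- paste(model$atoms$role, model$atoms$eu)
  bsa_res <- tapply(bsa_at, key, sum)
  sum(bsa_res > bsa_min)
}

# Fraction of interface BSA contributed by apolar (C, S) atoms; a surrogate
# for an interface hydrophobicity score.
.hydrophobic_fraction <- function(model, tabs) {
  bsa_at <- pmax(tabs$isolated - tabs$complex, 0)
  tot <- sum(bsa_at)
  if (tot <= 0) return(0)
  apolar <- model$atoms$element %in% c("C", "S")
  sum(bsa_at[apolar]) / tot
}

#' Build the default feature catalog
#'
#' The default catalog has 147 entries: the 21 Fc interface positions
#' (EU 251-257, 285, 286, 288, 307-311, 314, 428, 433-436) x \{ASA, BSA,
#' solvation\} = 63; 24 receptor-side positions (FcRn alpha-chain and B2M
#' interface residues of the reference complex ranked by BSA, always
#' including FcRn position 129 when present) x 3 = 72; and 12 complex-level
#' features (interface residue count, solvation gain, hydrophobic-score
#' surrogate, binding-energy surrogate, wide-cutoff hydrogen-bond and
#' atom-pair salt-bridge counts, hydrogen bonds at 3.5 A, salt bridges at
#' 4.0 A, C-alpha contacts at 4.0 A, mean hydrogen-bond distance, paired
#' hydrophilic residues, B2M-Fc contact atoms).
#'
#' @param reference an `fc_complex` used to rank receptor-side residues.
#' @param fc_positions integer vector of Fc EU positions (default the 21).
#' @param n_receptor number of receptor-side positions (default 24).
#' @param probe,n_points quadrature settings for the BSA ranking.
#' @return a `feature_catalog` data.frame with columns `feature_id`, `kind`,
#'   `role`, `eu`, `metric`.
#' @export
default_catalog <- function(reference, fc_positions = .FC_CATALOG_POSITIONS,
                            n_receptor = 24L, probe = 1.4,
                            n_points = 960L) {
  stopifnot(inherits(reference, "fc_complex"))
  sites <- complex_sites(reference)
  missing_fc <- setdiff(fc_positions, sites$eu[sites$role == "FC"])
  if (length(missing_fc))
    stop("reference lacks Fc catalog positions: ",
         paste(missing_fc, collapse = ", "))

  tabs <- .sasa_tables(reference, probe, n_points)
  bsa_at <- tabs$isolated - tabs$complex
  at <- reference$atoms
  key <- paste(at$role, at$eu, sep = "|")
  bsa_res <- tapply(bsa_at, key, sum)

  rec <- sites[sites$role != "FC", , drop = FALSE]
  if (nrow(rec) < n_receptor)
    stop("reference has only ", nrow(rec), " receptor-side residues; ",
         n_receptor, " required")
  rec$bsa <- as.numeric(bsa_res[paste(rec$role, rec$eu, sep = "|")])
  rec <- rec[order(-rec$bsa, rec$role, rec$eu), , drop = FALSE]
  pick <- rec[seq_len(n_receptor), , drop = FALSE]
  has129 <- any(sites$role == "FCRN_ALPHA" & sites$eu == 129)
  if (has129 && !any(pick$role == "FCRN_ALPHA" & pick$eu == 129)) {
    p129 <- rec[rec$role == "FCRN_ALPHA" & rec$eu == 129, , drop = FALSE]
    pick <- rbind(pick[seq_len(n_receptor - 1L), , drop = FALSE], p129)
  }
  pick <- pick[order(pick$role, pick$eu), , drop = FALSE]

  per_res <- function(role, eu) {
    data.frame(
      feature_id = paste0(c("asa", "bsa", "solv"), "_", role, "_", eu),
      kind = c("PER_RESIDUE_ASA", "PER_RESIDUE_BSA", "PER_RESIDUE_SOLV"),
      role = role, eu = eu, metric = NA_character_,
      stringsAsFactors = FALSE)
  }
  fc_rows <- do.call(rbind, lapply(fc_positions, per_res, role = "FC"))
  rec_rows <- do.call(rbind, Map(per_res, pick$role, eu = pick$eu))

  metrics <- c("n_interface_residues", "solvation_gain",
               "hydrophobic_score", "binding_energy",
               "wide_hbonds", "atom_salt_bridges",
               "hbonds", "salt_bridges", "ca_contacts",
               "mean_hbond_distance", "paired_hydrophilic",
               "b2m_fc_atom_contacts")
  cx_rows <- data.frame(feature_id = paste0("cx_", metrics),
                        kind = "COMPLEX_LEVEL", role = NA_character_,
                        eu = NA_integer_, metric = metrics,
                        stringsAsFactors = FALSE)
  cat_df <- rbind(fc_rows, rec_rows, cx_rows)
  rownames(cat_df) <- NULL
  if (anyDuplicated(cat_df$feature_id)) stop("duplicate feature ids")
  class(cat_df) <- c("feature_catalog", "data.frame")
  cat_df
}

#' Extract the feature vector of a modeled complex
#'
#' Computes every catalog entry on `model`: per-residue ASA/BSA/solvation
#' (Shrake-Rupley quadrature) and the complex-level interface metrics.
#'
#' @param model an `fc_complex`.
#' @param catalog a `feature_catalog` (see [default_catalog()]).
#' @param probe,n_points quadrature settings.
#' @param hbond_cutoff,contact_cutoff,wide_hbond_cutoff distance cutoffs in
#'   Angstrom for hydrogen bonds (3.5), contact-type counts (4.0) and the
#'   wide-cutoff hydrogen-bond surrogate (3.9).
#' @return named numeric vector aligned to `catalog$feature_id`.
#' @export
extract_features <- function(model, catalog, probe = 1.4, n_points = 960L,
                             hbond_cutoff = 3.5, contact_cutoff = 4.0,
                             wide_hbond_cutoff = 3.9) {
  stopifnot(inherits(model, "fc_complex"),
            inherits(catalog, "feature_catalog"))
  at <- model$atoms
  tabs <- .sasa_tables(model, probe, n_points)
  key <- paste(at$role, at$eu, sep = "|")
  asa_res <- tapply(tabs$complex, key, sum)
  iso_res <- tapply(tabs$isolated, key, sum)
  solv_res <- tapply(.ASP_TABLE[at$element] * tabs$complex, key, sum)

  hb <- count_hbonds(model, hbond_cutoff)
  sgain <- .solv_from_area(at$element, tabs$complex) -
    .solv_from_area(at$element, tabs$isolated)
  bsa_at <- tabs$isolated - tabs$complex
  bsa_res_tab <- tapply(bsa_at, key, sum)

  cx <- c(
    n_interface_residues = sum(bsa_res_tab > 0.1),
    solvation_gain = sgain,
    hydrophobic_score = .hydrophobic_fraction(model, tabs),
    binding_energy = -sgain + 0.5 * hb$count,
    wide_hbonds = count_hbonds(model, wide_hbond_cutoff)$count,
    atom_salt_bridges = nrow(.salt_bridge_pairs(model, contact_cutoff,
                                                per = "atom")),
    hbonds = hb$count,
    salt_bridges = count_salt_bridges(model, contact_cutoff),
    ca_contacts = count_ca_contacts(model, contact_cutoff),
    mean_hbond_distance = hb$mean_distance,
    paired_hydrophilic = count_paired_hydrophilic(model, contact_cutoff),
    b2m_fc_atom_contacts = count_b2m_fc_atom_contacts(model, contact_cutoff))

  vals <- numeric(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    row <- catalog[i, ]
    if (row$kind == "COMPLEX_LEVEL") {
      vals[i] <- cx[[row$metric]]
      next
    }
    k <- paste(row$role, row$eu, sep = "|")
    if (is.na(asa_res[k]))
      stop("catalog site not resolvable in model: ", row$role, " ", row$eu)
    vals[i] <- switch(row$kind,
      PER_RESIDUE_ASA = asa_res[[k]],
      PER_RESIDUE_BSA = iso_res[[k]] - asa_res[[k]],
      PER_RESIDUE_SOLV = solv_res[[k]],
      stop("unknown catalog kind: ", row$kind))
  }
  stats::setNames(vals, catalog$feature_id)
}
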