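# Chemical tables shared across modules.

# van der Waals radii (Angstrom), Bondi-like heavy-atom values.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.VDW_DEFAULT <- 1.70

#' Van der Waals radius lookup
#'
#' Returns the heavy-atom van der Waals radius used throughout the package
#' (C 1.70, N 1.55, O 1.52, S 1.80, anything else 1.70 Angstrom). The table
#' can be overridden per call for sensitivity analyses.
#'
#' @param element character vector of element symbols.
#' @param table named numeric vector overriding the built-in radii.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, table = .VDW_RADII) {
  r <- unname(table[toupper(element)])
  r[is.na(r)] <- .VDW_DEFAULT
  r
}

# Atomic solvation parameters, kcal/mol/A^2 (Eisenberg-McLachlan style:
# carbon and sulfur favorable to bury, polar N/O unfavorable).
.ASP_TABLE <- c(C = 0.016, N = -0.006, O = -0.006, S = 0.021)

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.AA1 <- stats::setNames(names(.AA3), .AA3)

.CHAIN_ROLES <- c("FC", "FCRN_ALPHA", "B2M")

# Hydrogen-bond chemistry on heavy atoms: per-residue donor and acceptor
# atom names (N/O only; the reference crystal has no hydrogens, so a
# donor-acceptor distance cutoff stands in for explicit H geometry).
.HB_DONORS <- list(
  backbone = "N",
  S = "OG", T = "OG1", Y = "OH", N = "ND2", Q = "NE2",
  K = "NZ", R = c("NE", "NH1", "NH2"), H = c("ND1", "NE2"), W = "NE1"
)
.HB_ACCEPTORS <- list(
  backbone = "O",
  D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1", Q = "OE1",
  S = "OG", T = "OG1", Y = "OH", H = c("ND1", "NE2")
)

# Charged side-chain group atoms for salt bridges.
.SB_NEG <- list(D = c("OD1", "OD2"), E = c("OE1", "OE2"))
.SB_POS <- list(K = "NZ", R = c("NH1", "NH2", "NE"), H = c("ND1", "NE2"))

# Hydrophilic residue set (Cys and Trp deliberately excluded as borderline).
.HYDROPHILIC <- c("S", "T", "N", "Q", "Y", "H", "K", "R", "D", "E")

# Fc interface positions (EU numbering) carried by the default feature
# catalog; in silico libraries mutate these same 21 positions.
.FC_CATALOG_POSITIONS <- c(251, 252, 253, 254, 255, 256, 257,
                           285, 286, 288,
                           307, 308, 309, 310, 311, 314,
                           428, 433, 434, 435, 436)

# Wild-type human IgG1 heavy-chain identities at those positions.
.FC_WILDTYPE <- c(`251` = "L", `252` = "M", `253` = "I", `254` = "S",
                  `255` = "R", `256` = "T", `257` = "P", `285` = "H",
                  `286` = "N", `288` = "K", `307` = "T", `308` = "V",
                  `309` = "L", `310` = "H", `311` = "Q", `314` = "L",
                  `428` = "M", `433` = "H", `434` = "N", `435` = "H",
                  `436` = "Y")
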