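# Ideal side-chain geometry templates.
#
# Each side-chain heavy atom is placed by internal coordinates (bond length,
# bond angle, dihedral) relative to three previously placed atoms, in the
# order listed (NeRF construction). Dihedral entries are either numeric
# degrees (fixed) or strings "x1"/"x2" with an optional "+/-" offset,
# substituted by the scanned chi angles. Rings are built atom-by-atom along
# one path with ideal values; the closing bond is therefore approximate,
# which is irrelevant at the 3.5-4.0 Angstrom cutoff scale of the features.

.tpl <- function(name, refs, d, ang, dih) {
  list(name = name, refs = refs, d = d, ang = ang, dih = dih)
}

# CB is shared by all non-Gly residues: dihedral C-N-CA-CB fixes chirality.
.TPL_CB <- .tpl("CB", c("C", "N", "CA"), 1.53, 110.5, 122.5)

.SIDECHAIN_TEMPLATES <- list(
  G = list(),
  A = list(),
  S = list(.tpl("OG",  c("N", "CA", "CB"), 1.42, 110.5, "x1")),
  C = list(.tpl("SG",  c("N", "CA", "CB"), 1.81, 114.0, "x1")),
  T = list(.tpl("OG1", c("N", "CA", "CB"), 1.43, 109.5, "x1"),
           .tpl("CG2", c("N", "CA", "CB"), 1.52, 109.5, "x1-120")),
  V = list(.tpl("CG1", c("N", "CA", "CB"), 1.52, 110.5, "x1"),
           .tpl("CG2", c("N", "CA", "CB"), 1.52, 110.5, "x1+120")),
  L = list(.tpl("CG",  c("N", "CA", "CB"), 1.53, 116.0, "x1"),
           .tpl("CD1", c("CA", "CB", "CG"), 1.52, 110.5, "x2"),
           .tpl("CD2", c("CA", "CB", "CG"), 1.52, 110.5, "x2+120")),
  I = list(.tpl("CG1", c("N", "CA", "CB"), 1.53, 110.5, "x1"),
           .tpl("CG2", c("N", "CA", "CB"), 1.52, 110.5, "x1-120"),
           .tpl("CD1", c("CA", "CB", "CG1"), 1.52, 113.0, "x2")),
  M = list(.tpl("CG",  c("N", "CA", "CB"), 1.52, 114.0, "x1"),
           .tpl("SD",  c("CA", "CB", "CG"), 1.80, 112.7, "x2"),
           .tpl("CE",  c("CB", "CG", "SD"), 1.79, 100.9, 180)),
  P = list(.tpl("CG",  c("N", "CA", "CB"), 1.49, 104.0, -25),
           .tpl("CD",  c("CA", "CB", "CG"), 1.50, 105.0, 37)),
  F = list(.tpl("CG",  c("N", "CA", "CB"), 1.50, 113.8, "x1"),
           .tpl("CD1", c("CA", "CB", "CG"), 1.39, 120.8, "x2"),
           .tpl("CD2", c("CA", "CB", "CG"), 1.39, 120.8, "x2+180"),
           .tpl("CE1", c("CB", "CG", "CD1"), 1.39, 121.0, 180),
           .tpl("CE2", c("CB", "CG", "CD2"), 1.39, 121.0, 180),
           .tpl("CZ",  c("CG", "CD1", "CE1"), 1.39, 120.0, 0)),
  Y = list(.tpl("CG",  c("N", "CA", "CB"), 1.50, 113.8, "x1"),
           .tpl("CD1", c("CA", "CB", "CG"), 1.39, 120.8, "x2"),
           .tpl("CD2", c("CA", "CB", "CG"), 1.39, 120.8, "x2+180"),
           .tpl("CE1", c("CB", "CG", "CD1"), 1.39, 121.0, 180),
           .tpl("CE2", c("CB", "CG", "CD2"), 1.39, 121.0, 180),
           .tpl("CZ",  c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
           .tpl("OH",  c("CD1", "CE1", "CZ"), 1.38, 120.0, 180)),
  W = list(.tpl("CG",  c("N", "CA", "CB"), 1.50, 113.8, "x1"),
           .tpl("CD1", c("CA", "CB", "CG"), 1.37, 126.9, "x2"),
           .tpl("CD2", c("CA", "CB", "CG"), 1.43, 126.7, "x2+180"),
           .tpl("NE1", c("CB", "CG", "CD1"), 1.38, 110.0, 180),
           .tpl("CE2", c("CB", "CG", "CD2"), 1.41, 107.0, 180),
           .tpl("CE3", c("CB", "CG", "CD2"), 1.40, 133.9, 0),
           .tpl("CZ2", c("CG", "CD2", "CE2"), 1.40, 122.0, 180),
           .tpl("CZ3", c("CG", "CD2", "CE3"), 1.39, 118.0, 180),
           .tpl("CH2", c("CD2", "CE2", "CZ2"), 1.37, 117.0, 0)),
  D = list(.tpl("CG",  c("N", "CA", "CB"), 1.52, 113.0, "x1"),
           .tpl("OD1", c("CA", "CB", "CG"), 1.25, 119.0, "x2"),
           .tpl("OD2", c("CA", "CB", "CG"), 1.25, 119.0, "x2+180")),
  N = list(.tpl("CG",  c("N", "CA", "CB"), 1.52, 113.0, "x1"),
           .tpl("OD1", c("CA", "CB", "CG"), 1.23, 121.0, "x2"),
           .tpl("ND2", c("CA", "CB", "CG"), 1.33, 116.0, "x2+180")),
  E = list(.tpl("CG",  c("N", "CA", "CB"), 1.52, 114.0, "x1"),
           .tpl("CD",  c("CA", "CB", "CG"), 1.52, 113.0, "x2"),
           .tpl("OE1", c("CB", "CG", "CD"), 1.25, 119.0, 0),
           .tpl("OE2", c("CB", "CG", "CD"), 1.25, 119.0, 180)),
  Q = list(.tpl("CG",  c("N", "CA", "CB"), 1.52, 114.0, "x1"),
           .tpl("CD",  c("CA", "CB", "CG"), 1.52, 113.0, "x2"),
           .tpl("OE1", c("CB", "CG", "CD"), 1.23, 121.0, 0),
           .tpl("NE2", c("CB", "CG", "CD"), 1.33, 116.0, 180)),
  K = list(.tpl("CG",  c("N", "CA", "CB"), 1.52, 114.0, "x1"),
           .tpl("CD",  c("CA", "CB", "CG"), 1.52, 111.0, "x2"),
           .tpl("CE",  c("CB", "CG", "CD"), 1.52, 111.0, 180),
           .tpl("NZ",  c("CG", "CD", "CE"), 1.49, 112.0, 180)),
  R = list(.tpl("CG",  c("N", "CA", "CB"), 1.52, 114.0, "x1"),
           .tpl("CD",  c("CA", "CB", "CG"), 1.52, 111.0, "x2"),
           .tpl("NE",  c("CB", "CG", "CD"), 1.46, 112.0, 180),
           .tpl("CZ",  c("CG", "CD", "NE"), 1.33, 124.0, 180),
           .tpl("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
           .tpl("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, 180)),
  H = list(.tpl("CG",  c("N", "CA", "CB"), 1.49, 113.8, "x1"),
           .tpl("ND1", c("CA", "CB", "CG"), 1.38, 122.7, "x2"),
           .tpl("CD2", c("CA", "CB", "CG"), 1.36, 131.0, "x2+180"),
           .tpl("CE1", c("CB", "CG", "ND1"), 1.32, 109.0, 180),
           .tpl("NE2", c("CB", "CG", "CD2"), 1.37, 107.0, 180))
)

# Amino acids with a scannable chi2 (a gamma heavy atom continued beyond).
.HAS_CHI2 <- c("L", "I", "M", "F", "Y", "W", "D", "N", "E", "Q", "K", "R", "H")

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Place atom D bonded to c with |D-c| = d, angle(D,c,b) = ang and dihedral
# (D,c,b,a) = dih (degrees).
.place_atom <- function(a, b, c, d, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) { # colinear reference: pick any perpendicular
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- .cross3(ref, bc)
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- .cross3(n, bc)
  v <- c(-d * cos(ang), d * sin(ang) * cos(dih), d * sin(ang) * sin(dih))
  c + v[1] * bc + v[2] * m + v[3] * n
}

.resolve_dihedral <- function(spec, chi1, chi2) {
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^x([12])([+-][0-9.]+)?$", spec))[[1]]
  if (!length(m)) stop("bad dihedral spec: ", spec)
  base <- if (m[2] == "1") chi1 else chi2
  off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
  base + off
}

# Build side-chain heavy atoms (CB onward) for amino acid `aa` on the
# backbone frame N/CA/C (3-vectors). Returns a list with `names`,
# `elements` and the coordinate matrix `xyz` (possibly 0-row for Gly).
.build_side_chain_mat <- function(aa, N, CA, C, chi1 = -60, chi2 = 180) {
  if (aa == "G")
    return(list(names = character(0), elements = character(0),
                xyz = matrix(numeric(0), 0, 3)))
  pos <- list(N = N, CA = CA, C = C)
  tpls <- c(list(.TPL_CB), .SIDECHAIN_TEMPLATES[[aa]])
  nm <- character(length(tpls))
  xyz <- matrix(0, length(tpls), 3)
  for (i in seq_along(tpls)) {
    t <- tpls[[i]]
    dih <- .resolve_dihedral(t$dih, chi1, chi2)
    p <- .place_atom(pos[[t$refs[1]]], pos[[t$refs[2]]], pos[[t$refs[3]]],
                     t$d, t$ang, dih)
    pos[[t$name]] <- p
    nm[i] <- t$name
    xyz[i, ] <- p
  }
  list(names = nm, elements = substr(nm, 1, 1), xyz = xyz)
}

.build_side_chain <- function(aa, N, CA, C, chi1 = -60, chi2 = 180) {
  m <- .build_side_chain_mat(aa, N, CA, C, chi1, chi2)
  data.frame(name = m$names, element = m$elements,
             x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3],
             stringsAsFactors = FALSE)
}
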