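# Reading, writing and numbering of Fc/FcRn complex structures.
#
# The in-memory representation (`fc_complex`) is a flat atom table: one row
# per heavy atom with its chain role, author residue number, EU number,
# amino acid, atom name, element, coordinates and van der Waals radius.
# A flat table keeps every geometric operation vectorizable.

#' Read a PDB structure into a complex model
#'
#' Parses fixed-column PDB text (via \pkg{bio3d}), keeps heavy protein atoms
#' of the chains named in `chain_map`, resolves alternate locations to the
#' highest-occupancy conformer (ties broken alphabetically by altloc), and
#' drops waters, heteroatoms, hydrogens and non-canonical residues.
#'
#' Chain roles are declared, never inferred: `chain_map` maps the roles
#' `FC` (antibody Fc), `FCRN_ALPHA` (FcRn alpha chain) and optionally `B2M`
#' (beta-2-microglobulin) to PDB chain identifiers. EU numbers are
#' initialized to author numbering; apply [eu_renumber()] for offsets.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB text, or a
#'   path to a PDB file.
#' @param chain_map named character vector, names in
#'   `c("FC","FCRN_ALPHA","B2M")`, values PDB chain IDs. `B2M` is optional.
#' @param source_id provenance string stored on the model.
#' @param quiet suppress the per-chain residue count message.
#' @return an object of class `fc_complex`.
#' @export
read_complex <- function(pdb_text, chain_map, source_id = "unknown",
                         quiet = FALSE) {
  stopifnot(is.character(chain_map), !is.null(names(chain_map)))
  bad_roles <- setdiff(names(chain_map), .CHAIN_ROLES)
  if (length(bad_roles))
    stop("unknown chain roles: ", paste(bad_roles, collapse = ", "))
  if (!all(c("FC", "FCRN_ALPHA") %in% names(chain_map)))
    stop("chain_map must map at least FC and FCRN_ALPHA")

  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    lines <- readLines(pdb_text)
  } else {
    lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n",
                             fixed = TRUE))
  }
  .check_atom_lines(lines)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]

  # heavy atoms only
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  # canonical residues only
  canon <- at$resid %in% .AA3
  if (any(!canon)) {
    dropped <- unique(at$resid[!canon])
    if (!quiet)
      message("dropping non-canonical residues: ",
              paste(dropped, collapse = ", "))
    at <- at[canon, , drop = FALSE]
    elem <- elem[canon]
  }

  # altloc resolution: highest occupancy, ties by altloc letter; file
  # order restored afterwards so round trips preserve atom order
  alt <- ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  orig <- seq_len(nrow(at))
  ord <- order(key, -occ, alt)
  keep_idx <- sort(orig[ord][!duplicated(key[ord])])
  at <- at[keep_idx, , drop = FALSE]
  elem <- elem[keep_idx]

  rows <- list()
  for (role in names(chain_map)) {
    cid <- chain_map[[role]]
    sel <- at$chain == cid
    if (!any(sel))
      stop("no chain found for role ", role, " (chain id '", cid, "')")
    a <- at[sel, , drop = FALSE]
    o <- order(a$resno, a$insert, method = "radix")
    a <- a[o, , drop = FALSE]
    rows[[role]] <- data.frame(
      role = role, chain = cid, resno = a$resno, eu = a$resno,
      aa = unname(.AA1[a$resid]), elety = trimws(a$elety),
      element = elem[sel][o], x = a$x, y = a$y, z = a$z,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  atoms$radius <- vdw_radius(atoms$element)

  model <- structure(list(atoms = atoms, chain_map = chain_map,
                          source_id = source_id),
                     class = "fc_complex")
  if (!quiet) {
    cnt <- vapply(split(atoms$eu, atoms$role),
                  function(v) length(unique(v)), integer(1))
    message("read_complex: residues per chain: ",
            paste(names(cnt), cnt, sep = "=", collapse = ", "))
  }
  model
}

.check_atom_lines <- function(lines) {
  idx <- grep("^ATOM  ", lines)
  for (i in idx) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords) || any(!is.finite(coords)))
      stop("unparseable ATOM record at line ", i)
  }
  invisible(TRUE)
}

#' Write a complex model as PDB text
#'
#' Emits fixed-column `ATOM` records (coordinates to 3 decimals), one `TER`
#' per chain and a final `END`.
#'
#' @param model an `fc_complex`.
#' @param path optional file path; if `NULL` the text is returned.
#' @return character scalar of PDB text (invisibly when `path` is given).
#' @export
write_complex <- function(model, path = NULL) {
  stopifnot(inherits(model, "fc_complex"))
  at <- model$atoms
  out <- character(0)
  serial <- 0L
  for (role in unique(at$role)) {
    a <- at[at$role == role, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      name <- a$elety[i]
      name_fmt <- if (nchar(name) >= 4L) substr(name, 1, 4) else
        sprintf(" %-3s", name)
      out <- c(out, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name_fmt, .AA3[[a$aa[i]]], a$chain[i], a$resno[i],
        a$x[i], a$y[i], a$z[i], 1.00, 0.00, a$element[i]))
    }
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d",
                          serial, .AA3[[a$aa[nrow(a)]]],
                          a$chain[nrow(a)], a$resno[nrow(a)]))
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' Apply EU numbering offsets
#'
#' Renumbers the Fc chain as `eu = author number + offset`; the FcRn alpha
#' chain and beta-2-microglobulin keep author numbering (positions on those
#' chains are conventionally cited in author numbering). Offsets are declared
#' in configuration, never inferred by alignment.
#'
#' @param model an `fc_complex`.
#' @param offsets named integer vector of per-role offsets (e.g.
#'   `c(FC = 6)`); roles not named keep their numbering.
#' @return the renumbered `fc_complex`.
#' @export
eu_renumber <- function(model, offsets = c(FC = 0L)) {
  stopifnot(inherits(model, "fc_complex"))
  bad <- setdiff(names(offsets), .CHAIN_ROLES)
  if (length(bad)) stop("unknown roles in offsets: ", paste(bad, collapse = ", "))
  at <- model$atoms
  for (role in names(offsets)) {
    sel <- at$role == role
    at$eu[sel] <- at$resno[sel] + as.integer(offsets[[role]])
  }
  ca <- at$elety == "CA"   # one CA per residue site
  if (anyDuplicated(paste(at$role, at$eu)[ca]))
    stop("EU renumbering collision: two sites share a role+eu_number")
  model$atoms <- at
  model
}

#' Residue-level view of a complex model
#'
#' @param model an `fc_complex`.
#' @return data.frame with one row per residue site: `role`, `eu`, `resno`,
#'   `aa`, `natoms`.
#' @export
complex_sites <- function(model) {
  stopifnot(inherits(model, "fc_complex"))
  at <- model$atoms
  key <- paste(at$role, at$eu, sep = "|")
  first <- !duplicated(key)
  data.frame(role = at$role[first], eu = at$eu[first],
             resno = at$resno[first], aa = at$aa[first],
             natoms = as.integer(table(key)[key[first]]),
             stringsAsFactors = FALSE)
}

#' @export
print.fc_complex <- function(x, ...) {
  s <- complex_sites(x)
  cat("fc_complex [", x$source_id, "]: ",
      nrow(x$atoms), " atoms, ", nrow(s), " residues (",
      paste(vapply(split(s$eu, s$role), length, integer(1)),
            names(table(s$role)), collapse = " + "),
      ")\n", sep = "")
  invisible(x)
}

# Internal: atom rows of one residue site.
.site_atoms <- function(model, role, eu) {
  sel <- model$atoms$role == role & model$atoms$eu == eu
  model$atoms[sel, , drop = FALSE]
}
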