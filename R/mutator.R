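# Mutation parsing and deterministic in silico side-chain replacement.

#' Parse a slash-separated mutation string
#'
#' Accepts strings like `"M252Y/S254T/T256E"` in EU numbering, or the
#' literal wild-type marker `"WT"` (empty mutation set). Token order is
#' irrelevant; the result is canonically ordered by position.
#'
#' @param text mutation string.
#' @param label optional free-text label (defaults to the canonical string).
#' @param max_mutations maximum number of mutations allowed (default 12,
#'   matching the most heavily engineered variants in curated datasets).
#' @return a `variant_spec` object.
#' @export
parse_mutations <- function(text, label = NULL, max_mutations = 12L) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty mutation string (use 'WT' for wild type)")
  if (toupper(text) %in% c("WT", "WILDTYPE", "WILD-TYPE")) {
    return(variant_spec(data.frame(wt = character(0), pos = integer(0),
                                   mut = character(0)),
                        label = if (is.null(label)) "WT" else label,
                        max_mutations = max_mutations))
  }
  toks <- strsplit(text, "/", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", toks))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed mutation token: ", toks[which(bad)[1]])
  wt <- toupper(vapply(m, `[`, "", 2))
  pos <- as.integer(vapply(m, `[`, "", 3))
  mut <- toupper(vapply(m, `[`, "", 4))
  noncanon <- !(wt %in% names(.AA3)) | !(mut %in% names(.AA3))
  if (any(noncanon)) stop("non-canonical amino acid in token: ",
                          toks[which(noncanon)[1]])
  same <- wt == mut
  if (any(same)) stop("wild-type equals mutant in token: ",
                      toks[which(same)[1]])
  if (anyDuplicated(pos)) stop("duplicate position in mutation string: ",
                               pos[duplicated(pos)][1])
  variant_spec(data.frame(wt = wt, pos = pos, mut = mut,
                          stringsAsFactors = FALSE),
               label = if (is.null(label)) NULL else label,
               max_mutations = max_mutations)
}

#' Construct a variant specification
#'
#' @param mutations data.frame with columns `wt`, `pos`, `mut`.
#' @param label free-text label.
#' @param max_mutations cap on the mutation count.
#' @return a `variant_spec`: mutation table canonically ordered by position.
#' @export
variant_spec <- function(mutations, label = NULL, max_mutations = 12L) {
  stopifnot(is.data.frame(mutations),
            all(c("wt", "pos", "mut") %in% names(mutations)))
  mutations <- mutations[order(mutations$pos), c("wt", "pos", "mut"),
                         drop = FALSE]
  rownames(mutations) <- NULL
  if (anyDuplicated(mutations$pos)) stop("duplicate position in variant")
  if (nrow(mutations) > max_mutations)
    stop("variant has ", nrow(mutations), " mutations; limit is ",
         max_mutations)
  if (is.null(label)) label <- mutation_string(mutations)
  structure(list(mutations = mutations, label = label),
            class = "variant_spec")
}

#' Canonical mutation string of a mutation table or variant
#' @param x a `variant_spec` or its mutation data.frame.
#' @return character scalar (`"WT"` for the empty set).
#' @export
mutation_string <- function(x) {
  m <- if (inherits(x, "variant_spec")) x$mutations else x
  if (!nrow(m)) return("WT")
  m <- m[order(m$pos), , drop = FALSE]
  paste0(m$wt, m$pos, m$mut, collapse = "/")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("variant_spec:", mutation_string(x), "\n")
  invisible(x)
}

#' @export
format.variant_spec <- function(x, ...) mutation_string(x)

#' Test equality of two variant specifications
#' @param a,b `variant_spec` objects.
#' @return logical.
#' @export
variant_equal <- function(a, b) {
  identical(mutation_string(a), mutation_string(b))
}

.CHI_GRID <- seq(-180, 150, by = 30)

#' Build the 3D model of an Fc variant
#'
#' Replaces, for each mutation, the side chain of the matching Fc residue by
#' ideal template geometry grafted on the backbone N-CA-C frame. The chi1
#' (and chi2, where the side chain has one) dihedral is scanned in
#' `chi_step`-degree increments and the rotamer minimizing a soft-sphere
#' clash score -- `sum over heavy-atom pairs of max(0, r_i + r_j - d)^2`
#' against every atom outside the mutated residue -- is kept, ties going to
#' the first rotamer in scan order (chi ascending). The backbone is never
#' moved, so all non-mutated atoms are bitwise unchanged and the procedure
#' is fully deterministic.
#'
#' @param model an `fc_complex`.
#' @param spec a `variant_spec` (or mutation string).
#' @param role chain role to mutate (default `"FC"`).
#' @param chi_step chi-scan granularity in degrees (default 30).
#' @return the mutated `fc_complex`.
#' @export
apply_mutations <- function(model, spec, role = "FC", chi_step = 30) {
  stopifnot(inherits(model, "fc_complex"))
  if (is.character(spec)) spec <- parse_mutations(spec)
  stopifnot(inherits(spec, "variant_spec"))
  muts <- spec$mutations
  for (i in seq_len(nrow(muts))) {
    model <- .apply_one_mutation(model, role, muts$pos[i], muts$wt[i],
                                 muts$mut[i], chi_step)
  }
  model$source_id <- paste0(model$source_id, "|", mutation_string(spec))
  model
}

.apply_one_mutation <- function(model, role, eu, wt, mut, chi_step) {
  at <- model$atoms
  sel <- at$role == role & at$eu == eu
  if (!any(sel))
    stop("no residue at EU position ", eu, " on chain role ", role)
  found <- at$aa[sel][1]
  if (found != wt)
    stop("wild-type mismatch at EU ", eu, ": expected ", wt,
         ", found ", found)

  bb <- c("N", "CA", "C", "O")
  res <- at[sel, , drop = FALSE]
  get_bb <- function(nm) {
    r <- res[res$elety == nm, , drop = FALSE]
    if (!nrow(r)) stop("residue at EU ", eu, " lacks backbone atom ", nm)
    c(r$x[1], r$y[1], r$z[1])
  }
  N <- get_bb("N"); CA <- get_bb("CA"); C <- get_bb("C")

  env <- at[!sel, , drop = FALSE]
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  env_r <- env$radius

  chis1 <- if (mut %in% c("G", "A")) 0 else seq(-180, 180 - chi_step,
                                                by = chi_step)
  chis2 <- if (mut %in% .HAS_CHI2) chis1 else 0
  best <- NULL
  best_score <- Inf
  for (c1 in chis1) {
    for (c2 in chis2) {
      sc <- .build_side_chain_mat(mut, N, CA, C, chi1 = c1, chi2 = c2)
      score <- if (nrow(sc$xyz)) {
        .clash_score_cpp(sc$xyz, vdw_radius(sc$elements), env_xyz, env_r)
      } else 0
      if (score < best_score - 1e-12) {
        best_score <- score
        best <- sc
      }
    }
  }

  keep <- res[res$elety %in% bb, , drop = FALSE]
  new_res <- keep
  if (!is.null(best) && nrow(best$xyz)) {
    side <- data.frame(role = role, chain = res$chain[1], resno = res$resno[1],
                       eu = eu, aa = mut, elety = best$names,
                       element = best$elements, x = best$xyz[, 1],
                       y = best$xyz[, 2], z = best$xyz[, 3],
                       radius = vdw_radius(best$elements),
                       stringsAsFactors = FALSE)
    new_res <- rbind(keep, side)
  }
  new_res$aa <- mut

  # splice back, preserving residue order within the chain
  idx <- which(sel)
  before <- at[seq_len(min(idx) - 1L), , drop = FALSE]
  after <- if (max(idx) < nrow(at)) at[(max(idx) + 1L):nrow(at), ,
                                       drop = FALSE] else at[0, ]
  model$atoms <- rbind(before, new_res, after)
  rownames(model$atoms) <- NULL
  model
}
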