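# In silico random variant libraries over the Fc interface positions.

.wildtype_at <- function(reference, positions) {
  sites <- complex_sites(reference)
  fc <- sites[sites$role == "FC", , drop = FALSE]
  wt <- stats::setNames(fc$aa[match(positions, fc$eu)],
                        as.character(positions))
  if (anyNA(wt))
    stop("reference lacks Fc positions: ",
         paste(positions[is.na(wt)], collapse = ", "))
  wt
}

#' Generate a random mutation library
#'
#' Each variant receives exactly `n_mutations` substitutions at distinct
#' positions drawn uniformly from `positions` (default: the 21 Fc
#' interface positions), each substituted by a uniformly drawn
#' non-wild-type amino acid (or one from the per-position `allowlist`).
#' Wild-type identities come from the reference complex. Variants are
#' unique by mutation signature; generation continues until `n_variants`
#' unique variants exist (guard: failure after `100 * n_variants`
#' attempts). Deterministic given `seed`.
#'
#' @param n_variants library size.
#' @param n_mutations substitutions per variant.
#' @param reference the reference `fc_complex` (wild-type source).
#' @param positions candidate EU positions.
#' @param allowlist optional named list: position -> allowed substitution
#'   amino acids (1-letter).
#' @param seed RNG seed.
#' @return list of `variant_spec`s.
#' @export
random_library <- function(n_variants, n_mutations, reference,
                           positions = .FC_CATALOG_POSITIONS,
                           allowlist = NULL, seed = 1L) {
  stopifnot(n_mutations >= 1, n_mutations <= length(positions))
  wt <- .wildtype_at(reference, positions)
  aa20 <- names(.AA3)
  choices <- lapply(as.character(positions), function(p) {
    opts <- if (!is.null(allowlist) && !is.null(allowlist[[p]]))
      setdiff(allowlist[[p]], wt[[p]]) else setdiff(aa20, wt[[p]])
    if (!length(opts)) stop("empty substitution allowlist at position ", p)
    opts
  })
  names(choices) <- as.character(positions)

  set.seed(seed)
  out <- list()
  seen <- character(0)
  attempts <- 0L
  while (length(out) < n_variants) {
    attempts <- attempts + 1L
    if (attempts > 100L * n_variants)
      stop("library generation did not terminate: requested diversity ",
           "exceeds the mutation space")
    pos <- sort(sample(positions, n_mutations))
    mut <- vapply(as.character(pos), function(p) {
      opts <- choices[[p]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, "")
    spec <- variant_spec(data.frame(wt = unname(wt[as.character(pos)]),
                                    pos = pos, mut = unname(mut),
                                    stringsAsFactors = FALSE),
                         max_mutations = length(positions))
    sig <- mutation_string(spec)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1L]] <- spec
  }
  out
}

#' Generate a constrained library of 6-8 mutations
#'
#' Builds the allowlist from per-mutation single-effect estimates: only
#' substitutions whose single effect on log10 KD is below `threshold`
#' (default +0.5 log units, i.e. not strongly affinity-decreasing) are
#' eligible. Variant sizes are drawn uniformly from `n_range`.
#'
#' @param n_variants library size.
#' @param reference reference `fc_complex`.
#' @param singles_table data.frame with columns `mutation` (e.g. "M252Y")
#'   and `effect` (log10 KD change of the single mutant vs wild type).
#' @param threshold maximal allowed single effect (log10 KD units).
#' @param n_range candidate mutation counts (default `6:8`).
#' @param positions candidate EU positions.
#' @param seed RNG seed.
#' @return list of `variant_spec`s.
#' @export
constrained_library <- function(n_variants, reference, singles_table,
                                threshold = 0.5, n_range = 6:8,
                                positions = .FC_CATALOG_POSITIONS,
                                seed = 1L) {
  stopifnot(all(c("mutation", "effect") %in% names(singles_table)))
  ok <- singles_table$effect < threshold
  allowed <- singles_table$mutation[ok]
  if (!length(allowed)) stop("allowlist is empty at threshold ", threshold)
  parsed <- lapply(allowed, function(s) parse_mutations(s)$mutations)
  tab <- do.call(rbind, parsed)
  tab <- tab[tab$pos %in% positions, , drop = FALSE]
  allow_by_pos <- split(tab$mut, tab$pos)
  if (length(allow_by_pos) < max(n_range))
    stop("allowlist covers only ", length(allow_by_pos),
         " positions; at least ", max(n_range), " required")
  wt <- .wildtype_at(reference, as.integer(names(allow_by_pos)))

  set.seed(seed)
  out <- list()
  seen <- character(0)
  attempts <- 0L
  pos_pool <- as.integer(names(allow_by_pos))
  while (length(out) < n_variants) {
    attempts <- attempts + 1L
    if (attempts > 100L * n_variants)
      stop("library generation did not terminate")
    nm <- if (length(n_range) == 1L) n_range else sample(n_range, 1L)
    pos <- sort(sample(pos_pool, nm))
    mut <- vapply(as.character(pos), function(p) {
      opts <- allow_by_pos[[p]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, "")
    spec <- variant_spec(data.frame(wt = unname(wt[as.character(pos)]),
                                    pos = pos, mut = unname(mut),
                                    stringsAsFactors = FALSE))
    sig <- mutation_string(spec)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1L]] <- spec
  }
  out
}

#' Summarize predicted log10 KD distributions per library
#'
#' @param predictions named list of numeric vectors (one per library).
#' @return data.frame with per-library `n`, `mean`, `sd`, `min`, `max`.
#' @export
distribution_summary <- function(predictions) {
  stopifnot(is.list(predictions), length(names(predictions)) ==
              length(predictions))
  out <- do.call(rbind, lapply(names(predictions), function(nm) {
    v <- predictions[[nm]]
    data.frame(library = nm, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
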