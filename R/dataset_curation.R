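# Curation of variant/affinity tables into harmonized learning sets.
#
# A raw variant table is a data.frame (or delimited text file) with columns
#   mutations   slash-separated mutation string, EU numbering ("WT" allowed)
#   kd_molar    equilibrium dissociation constant, molar
#   ph          assay pH, 6.0 or 7.0
#   method      SPR, ELISA or ALPHA
#   binder_flag "measured" or "non_binder"

#' Read / write a variant table
#'
#' Tab-delimited text with a header row; see the package overview for the
#' column dialect.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_variant_table(df)
  df
}

#' @rdname read_variant_table
#' @param table a variant table data.frame.
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.validate_variant_table <- function(df) {
  need <- c("mutations", "kd_molar", "ph", "method", "binder_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(df$ph %in% c(6, 7)))
    stop("assay pH must be 6.0 or 7.0")
  if (!all(df$binder_flag %in% c("measured", "non_binder")))
    stop("binder_flag must be 'measured' or 'non_binder'")
  measured <- df$binder_flag == "measured"
  if (any(!is.finite(df$kd_molar[measured]) | df$kd_molar[measured] <= 0))
    stop("measured kd_molar must be positive and finite")
  invisible(df)
}

#' pH harmonization factor from wild-type affinities
#'
#' The ratio of the wild-type Fc dissociation constants at pH 7.0 and
#' pH 6.0, rounded to an integer. With the configured defaults
#' (8.8e-5 M at pH 7.0 and 1.3e-6 M at pH 6.0) the factor is 68. The log
#' of KD being close to linear in pH over this range motivates a single
#' multiplicative correction.
#'
#' @param kd_wt_ph7,kd_wt_ph6 wild-type KD (molar) at the two pH values.
#' @return integer factor.
#' @export
harmonization_factor <- function(kd_wt_ph7 = 8.8e-5, kd_wt_ph6 = 1.3e-6) {
  stopifnot(kd_wt_ph7 > 0, kd_wt_ph6 > 0)
  round(kd_wt_ph7 / kd_wt_ph6)
}

#' Harmonize assay pH and log-transform affinities
#'
#' Records measured at pH 7.0 keep their KD; records at pH 6.0 are
#' multiplied by `factor` to approximate their pH 7.0 value. The response
#' returned is `log10(KD)`. Non-binder records carry no usable KD and are
#' excluded (their count is reported in the `removed_nonbinders`
#' attribute and via a message).
#'
#' @param table a variant table data.frame.
#' @param factor positive multiplicative pH correction
#'   (default [harmonization_factor()]).
#' @param quiet suppress the exclusion message.
#' @return the table restricted to measured records, with a `log10_kd`
#'   column at pH 7.0 scale; attribute `removed_nonbinders`.
#' @export
harmonize_ph <- function(table, factor = harmonization_factor(),
                         quiet = FALSE) {
  .validate_variant_table(table)
  stopifnot(is.numeric(factor), factor > 0)
  nb <- table$binder_flag == "non_binder"
  if (any(nb) && !quiet)
    message("harmonize_ph: excluding ", sum(nb), " non-binder record(s)")
  out <- table[!nb, , drop = FALSE]
  kd <- ifelse(out$ph == 6, out$kd_molar * factor, out$kd_molar)
  out$log10_kd <- log10(kd)
  rownames(out) <- NULL
  attr(out, "removed_nonbinders") <- sum(nb)
  out
}

#' Effective mutation signature of a variant
#'
#' The canonical string of the mutations whose EU position belongs to the
#' feature catalog's Fc position set; mutations at other positions are
#' invisible to the structural features and are dropped. An empty
#' signature (all mutations off-catalog, or wild type) is `"WT"`.
#'
#' @param spec a `variant_spec` or mutation string.
#' @param catalog_positions integer vector of Fc catalog positions
#'   (default the built-in 21).
#' @return character scalar signature.
#' @export
effective_signature <- function(spec, catalog_positions = .FC_CATALOG_POSITIONS) {
  if (is.character(spec)) spec <- parse_mutations(spec)
  m <- spec$mutations
  m <- m[m$pos %in% catalog_positions, , drop = FALSE]
  mutation_string(m)
}

#' Remove effective-signature duplicates
#'
#' Two records whose mutation sets agree on the catalog positions carry
#' identical feature vectors; keeping both would bias training. The first
#' occurrence (input order) is kept; alternatively the group is collapsed
#' to its geometric-mean KD (`conflict = "geomean"`).
#'
#' @param records harmonized variant table (needs `mutations`, `log10_kd`).
#' @param catalog_positions Fc catalog positions.
#' @param set_id identifier stored on the result (`"FLS"`, `"SLS"`, ...).
#' @param conflict `"first"` (default) or `"geomean"`.
#' @param removed_nonbinders count carried through from [harmonize_ph()].
#' @return a `curated_set`: list with `records` (including a `signature`
#'   column), `set_id`, `removed_duplicates`, `removed_nonbinders`.
#' @export
deduplicate <- function(records, catalog_positions = .FC_CATALOG_POSITIONS,
                        set_id = "FLS", conflict = c("first", "geomean"),
                        removed_nonbinders = NA_integer_) {
  conflict <- match.arg(conflict)
  stopifnot("log10_kd" %in% names(records))
  if (is.na(removed_nonbinders) &&
      !is.null(attr(records, "removed_nonbinders")))
    removed_nonbinders <- attr(records, "removed_nonbinders")
  sig <- vapply(records$mutations, effective_signature, "",
                catalog_positions = catalog_positions)
  records$signature <- unname(sig)
  dup <- duplicated(records$signature)
  if (conflict == "first") {
    kept <- records[!dup, , drop = FALSE]
  } else {
    kept <- records[!dup, , drop = FALSE]
    agg <- tapply(records$log10_kd, records$signature, mean)
    kept$log10_kd <- as.numeric(agg[kept$signature])
  }
  rownames(kept) <- NULL
  structure(list(records = kept, set_id = set_id,
                 removed_duplicates = sum(dup),
                 removed_nonbinders = removed_nonbinders),
            class = "curated_set")
}

#' @export
print.curated_set <- function(x, ...) {
  cat("curated_set ", x$set_id, ": ", nrow(x$records), " records (",
      x$removed_duplicates, " duplicates removed",
      if (!is.na(x$removed_nonbinders))
        paste0(", ", x$removed_nonbinders, " non-binders excluded"),
      ")\n", sep = "")
  invisible(x)
}

#' Build the two learning sets
#'
#' The first learning set (FLS) keeps only the homogeneous records:
#' pH 7.0, measured by SPR. The second learning set (SLS) adds the pH 6.0
#' records after multiplying their KD by the harmonization factor. Both
#' sets are deduplicated by effective signature.
#'
#' @param table raw variant table.
#' @param catalog_positions Fc catalog positions.
#' @param factor pH harmonization factor.
#' @param conflict duplicate-resolution rule, see [deduplicate()].
#' @param quiet suppress messages.
#' @return list with elements `FLS` and `SLS`, both `curated_set`s.
#' @export
build_learning_sets <- function(table,
                                catalog_positions = .FC_CATALOG_POSITIONS,
                                factor = harmonization_factor(),
                                conflict = "first", quiet = FALSE) {
  .validate_variant_table(table)
  harmonized <- harmonize_ph(table, factor, quiet = quiet)
  fls_rows <- harmonized[harmonized$ph == 7 & harmonized$method == "SPR", ,
                         drop = FALSE]
  if (!nrow(fls_rows) && !quiet)
    warning("no pH 7.0 SPR records: FLS is empty")
  fls <- deduplicate(fls_rows, catalog_positions, set_id = "FLS",
                     conflict = conflict,
                     removed_nonbinders = attr(harmonized,
                                               "removed_nonbinders"))
  sls_rows <- rbind(fls_rows, harmonized[harmonized$ph == 6, , drop = FALSE])
  sls <- deduplicate(sls_rows, catalog_positions, set_id = "SLS",
                     conflict = conflict,
                     removed_nonbinders = attr(harmonized,
                                               "removed_nonbinders"))
  list(FLS = fls, SLS = sls)
}
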