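#' Screen a family for the binding-pocket signature
#'
#' The core filter: for every row of the family alignment, read the
#' residues at the five signature columns (via the column map), count
#' matches to the reference signature, and flag rows with at least `k`
#' matches. Gaps and `X` count as mismatches; matching is strict residue
#' identity.
#'
#' @param family Alignment tibble (`id`, `aligned`).
#' @param cmap Column map from [build_column_map()]; must cover all
#'   signature positions.
#' @param ref A [reference_pocket_model()].
#' @param k Minimum number of matching signature positions to pass
#'   (default 5, i.e. all five; `k = 4` models the PctB/PctC-like
#'   four-of-five case).
#' @return A tibble in input row order with columns `id`,
#'   `signature_string`, `n_match`, `matched_positions` (list of integer)
#'   and `passes`.
#' @export
screen_family <- function(family, cmap, ref, k = 5L) {
  stopifnot(k >= 0, k <= nrow(ref$signature))
  pos <- ref$signature$position
  cols <- cmap$refpos_to_col[as.character(pos)]
  if (anyNA(cols)) {
    abort(sprintf("alignment does not span signature position(s): %s",
                  paste(pos[is.na(cols)], collapse = ", ")))
  }
  obs <- vapply(cols, function(cc) substring(family$aligned, cc, cc), character(nrow(family)))
  obs <- matrix(obs, nrow = nrow(family))
  hit <- sweep(obs, 2, ref$signature$residue, "==")
  n_match <- as.integer(rowSums(hit))
  tibble(
    id = family$id,
    signature_string = apply(obs, 1, paste, collapse = ""),
    n_match = n_match,
    matched_positions = purrr::map(seq_len(nrow(family)),
                                   function(i) pos[hit[i, ]]),
    passes = n_match >= k
  )
}

#' Tally screened sequences by match count
#' @param result A [screen_family()] result.
#' @return Tibble `n_match`, `n_seqs` covering 0..5.
#' @export
screen_counts <- function(result) {
  tb <- dplyr::count(result, .data$n_match, name = "n_seqs")
  full <- tibble(n_match = 0:5)
  out <- dplyr::left_join(full, tb, by = "n_match")
  out$n_seqs[is.na(out$n_seqs)] <- 0L
  out
}

#' Join screen results with protein metadata
#'
#' Adds the functional class (via [classify_protein()]) and phylum of each
#' screened sequence. Sequences without a metadata record are kept with
#' class and phylum `"unknown"` (and counted in the attached log).
#'
#' @param result A [screen_family()] result.
#' @param metadata Metadata tibble from [read_protein_table()] (or
#'   [generate_family()]); accessions must be unique.
#' @param rules Classification rule set (default [default_class_rules()]).
#' @return Tibble `id`, `signature_string`, `n_match`, `passes`, `class`,
#'   `phylum`, one row per screened sequence.
#' @export
summarize_screen <- function(result, metadata, rules = default_class_rules()) {
  if (anyDuplicated(metadata$accession)) {
    abort(paste0("duplicate accession in metadata: ",
                 metadata$accession[duplicated(metadata$accession)][1]))
  }
  cls <- classify_protein(metadata, rules)
  joined <- dplyr::left_join(
    dplyr::select(result, "id", "signature_string", "n_match", "passes"),
    dplyr::select(cls, "accession", "class", "phylum"),
    by = c(id = "accession"))
  missing <- sum(is.na(joined$class))
  if (missing > 0) {
    warn(sprintf("%d screened sequence(s) lack metadata; class set to 'unknown'",
                 missing))
  }
  joined$class[is.na(joined$class)] <- "unknown"
  joined$phylum[is.na(joined$phylum)] <- "unknown"
  joined
}
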