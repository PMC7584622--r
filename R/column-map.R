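#' Map alignment columns to reference numbering
#'
#' Walks the reference row of the family alignment left to right, assigning
#' each non-gap column the next reference residue number, and retains only
#' the columns that fall inside the reference domain span (columns outside
#' it are dropped, mirroring the removal of alignment columns not
#' represented in the reference domain). The reference row id may carry a
#' Stockholm-style `id/start-end` suffix giving its first residue number;
#' without one the domain start is assumed.
#'
#' @param family Alignment tibble (`id`, `aligned`).
#' @param ref A [reference_pocket_model()].
#' @return An object of class `column_map` with fields `col_to_refpos`,
#'   `refpos_to_col` (named integer vectors over retained columns /
#'   positions) and `retained_columns`.
#' @export
build_column_map <- function(family, ref) {
  hit <- find_reference_row(family, ref$reference_id)
  row <- family$aligned[hit$index]
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  if (length(nongap) == 0) abort("reference row is all gaps")
  start <- if (is.na(hit$start)) ref$domain_span[1] else hit$start
  positions <- start + seq_along(nongap) - 1L
  if (max(positions) > nchar(ref$reference_sequence)) {
    abort("reference row extends past the end of the reference sequence")
  }
  expect <- substring(ref$reference_sequence, positions, positions)
  got <- chars[nongap]
  ok <- got == expect
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf(paste0("reference row disagrees with reference sequence at ",
                         "position %d (column %d): row has '%s', reference '%s'"),
                  positions[i], nongap[i], got[i], expect[i]))
  }
  keep <- positions >= ref$domain_span[1] & positions <= ref$domain_span[2]
  retained <- nongap[keep]
  refpos <- positions[keep]
  structure(list(
    col_to_refpos = setNames(refpos, retained),
    refpos_to_col = setNames(retained, refpos),
    retained_columns = retained
  ), class = "column_map")
}

find_reference_row <- function(family, reference_id) {
  idx <- which(family$id == reference_id)
  start <- NA_integer_
  if (length(idx) == 0) {
    pat <- paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", reference_id),
                  "/(\\d+)-(\\d+)$")
    idx <- grep(pat, family$id)
    if (length(idx) == 1) {
      start <- as.integer(sub(pat, "\\1", family$id[idx]))
    }
  }
  if (length(idx) != 1) {
    abort(sprintf("reference row '%s' not found (exactly once) in the alignment",
                  reference_id))
  }
  list(index = idx, start = start)
}

#' @export
print.column_map <- function(x, ...) {
  cat("<column_map>", length(x$retained_columns), "retained columns, positions",
      min(x$col_to_refpos), "-", max(x$col_to_refpos), "\n")
  invisible(x)
}

#' Serialize / load a column map as JSON
#' @param cmap A `column_map`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_column_map()` returns the `column_map`.
#' @export
write_column_map <- function(cmap, path) {
  jsonlite::write_json(
    list(column = as.integer(names(cmap$col_to_refpos)),
         refpos = unname(cmap$col_to_refpos)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_column_map
#' @export
read_column_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    col_to_refpos = setNames(as.integer(x$refpos), x$column),
    refpos_to_col = setNames(as.integer(x$column), x$refpos),
    retained_columns = as.integer(x$column)
  ), class = "column_map")
}

#' Anchor a single sequence to reference numbering by pairwise alignment
#'
#' Global Needleman-Wunsch alignment against the full reference sequence
#' (BLOSUM62, affine gaps: open 11, extend 1). This is a convenience path
#' for sequences outside the family MSA; positions aligned to gaps are
#' unmapped.
#'
#' @param seq A single-row sequence tibble (or list) with `id` and
#'   `residues`.
#' @param ref A [reference_pocket_model()].
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A tibble with columns `target_pos`, `ref_pos`,
#'   `target_residue`, one row per aligned residue pair; `ref_pos` is
#'   strictly increasing in `target_pos`.
#' @export
align_to_reference <- function(seq, ref, gap_open = 11, gap_extend = 1) {
  residues <- if (is.data.frame(seq)) seq$residues[1] else seq$residues
  if (is.null(residues) || !nzchar(residues)) abort("empty sequence")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(residues),
    subject = Biostrings::AAString(ref$reference_sequence),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  tpos <- cumsum(pa != "-")
  rpos <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-"
  tibble(target_pos = tpos[keep], ref_pos = rpos[keep],
         target_residue = pa[keep])
}

#' Extract the pocket-signature residues of one family member
#'
#' Returns the five target residues at the signature positions of the
#' reference model, as a single string (e.g. `"RWYDD"` for the reference
#' itself); `-` marks positions that are gapped or unmapped.
#'
#' @param x Either a gapped alignment row (character scalar; requires
#'   `cmap`) or a position map from [align_to_reference()].
#' @param cmap A [build_column_map()] result (alignment-row path only).
#' @param ref A [reference_pocket_model()].
#' @return Character scalar of length `nrow(ref$signature)`.
#' @export
extract_signature <- function(x, cmap = NULL, ref) {
  pos <- ref$signature$position
  if (is.character(x) && length(x) == 1) {
    if (is.null(cmap)) abort("alignment-row extraction requires a column map")
    cols <- cmap$refpos_to_col[as.character(pos)]
    out <- ifelse(is.na(cols), "-", substring(x, cols, cols))
    out[out == ""] <- "-"
  } else if (is.data.frame(x)) {
    idx <- match(pos, x$ref_pos)
    out <- ifelse(is.na(idx), "-", x$target_residue[idx])
  } else {
    abort("x must be an alignment row or an align_to_reference() map")
  }
  paste(out, collapse = "")
}
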