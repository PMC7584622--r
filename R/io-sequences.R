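#' Read protein sequences from FASTA
#'
#' Sequences are validated against the 20 standard amino-acid letters plus
#' `X`; gap characters are forbidden in unaligned sequences. Lower-case
#' input is upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description` and `residues`, rows in
#'   file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aas <- Biostrings::readBStringSet(path)
  full <- names(aas)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  res <- toupper(as.character(aas))
  out <- tibble(id = id, description = desc, residues = unname(res))
  validate_sequences(out)
  out
}

validate_sequences <- function(seqs) {
  if (anyDuplicated(seqs$id)) {
    abort(paste0("duplicate sequence id: ",
                 seqs$id[duplicated(seqs$id)][1]))
  }
  if (any(seqs$id == "")) abort("empty sequence id")
  if (any(nchar(seqs$residues) < 1)) abort("zero-length sequence")
  bad <- gsub(paste0("[", paste(AA_OK, collapse = ""), "]"), "",
              seqs$residues)
  hit <- which(nchar(bad) > 0)
  if (length(hit)) {
    i <- hit[1]
    ch <- substr(bad[i], 1, 1)
    pos <- regexpr(ch, seqs$residues[i], fixed = TRUE)
    abort(sprintf("illegal residue character '%s' in sequence '%s' at position %d",
                  ch, seqs$id[i], pos))
  }
  invisible(seqs)
}

#' Write sequences to FASTA
#'
#' Deterministic serialization: 60-column wrapping, no trailing whitespace,
#' so write/read round trips are byte-stable.
#'
#' @param seqs Tibble with columns `id`, `description`, `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(purrr::pmap(seqs, function(id, description, residues, ...) {
    hdr <- if (nzchar(description)) paste0(">", id, " ", description) else paste0(">", id)
    c(hdr, wrap_seq(residues))
  }))
  writeLines(lines, path)
  invisible(path)
}

wrap_seq <- function(s, width = 60L) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Stockholm (sequence rows only; `#=GC`/`#=GS`
#' annotation lines are ignored). `.` gaps are normalized to `-`; the
#' alignment must be rectangular.
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"stockholm"`.
#' @return A tibble with columns `id` and `aligned` (gapped residue string);
#'   all rows have equal width.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (dialect == "aligned-fasta") {
    aas <- Biostrings::readBStringSet(path)
    aln <- tibble(id = sub("\\s.*$", "", names(aas)),
                  aligned = toupper(unname(as.character(aas))))
  } else {
    aln <- read_stockholm_rows(path)
  }
  aln$aligned <- gsub(".", "-", aln$aligned, fixed = TRUE)
  validate_alignment(aln)
  aln
}

read_stockholm_rows <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))
  rows <- lines[keep]
  m <- regmatches(rows, regexec("^(\\S+)\\s+(\\S+)\\s*$", rows))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) abort(sprintf("unparseable Stockholm row: '%s'", rows[bad][1]))
  id <- vapply(m, `[`, "", 2L)
  sq <- toupper(vapply(m, `[`, "", 3L))
  # multi-block Stockholm: concatenate per id, first-appearance order
  tb <- tibble(id = id, aligned = sq)
  tb <- dplyr::summarise(dplyr::group_by(tb, id = factor(id, unique(id))),
                         aligned = paste(.data$aligned, collapse = ""),
                         .groups = "drop")
  tb$id <- as.character(tb$id)
  tb
}

validate_alignment <- function(aln) {
  if (nrow(aln) == 0) abort("empty alignment")
  if (anyDuplicated(aln$id)) {
    abort(paste0("duplicate row id in alignment: ",
                 aln$id[duplicated(aln$id)][1]))
  }
  w <- nchar(aln$aligned)
  if (length(unique(w)) != 1L) {
    off <- aln$id[w != w[1]][1]
    abort(sprintf("ragged alignment: row '%s' has width %d, expected %d",
                  off, nchar(aln$aligned[aln$id == off][1]), w[1]))
  }
  bad <- gsub(paste0("[", paste(AA_OK, collapse = ""), "-]"), "", aln$aligned)
  hit <- which(nchar(bad) > 0)
  if (length(hit)) {
    i <- hit[1]
    ch <- substr(bad[i], 1, 1)
    abort(sprintf("illegal character '%s' in alignment row '%s'", ch, aln$id[i]))
  }
  invisible(aln)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln Alignment tibble (`id`, `aligned`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- unlist(purrr::map2(aln$id, aln$aligned,
                              function(i, s) c(paste0(">", i), wrap_seq(s))))
  writeLines(lines, path)
  invisible(path)
}

#' Number of columns in an alignment
#' @param aln Alignment tibble.
#' @return Integer column count.
#' @export
alignment_width <- function(aln) nchar(aln$aligned[1])
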