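#' Reference binding-pocket model
#'
#' Bundles a reference sequence with its dCache_1 domain span, the
#' five-residue pocket signature and the wider set of pocket-contact
#' positions, all in reference (PctA) numbering. The default signature is
#' R126, W128, Y144, D146, D173; the default domain span is residues
#' 36-261 and the logo region residues 100-175.
#'
#' @param reference_id Sequence identifier.
#' @param reference_sequence Full-length residue string.
#' @param domain_span Length-2 integer vector, 1-based inclusive.
#' @param signature Tibble with columns `position`, `residue`.
#' @param extended_pocket Integer vector of pocket-contact positions.
#' @param logo_region Length-2 integer vector for conservation profiling.
#' @return An object of class `ref_pocket_model`.
#' @export
reference_pocket_model <- function(reference_id,
                                   reference_sequence,
                                   domain_span = c(36L, 261L),
                                   signature = tibble(
                                     position = c(126L, 128L, 144L, 146L, 173L),
                                     residue = c("R", "W", "Y", "D", "D")),
                                   extended_pocket = c(101L, 111L, 121L, 126L,
                                                       128L, 144L, 146L, 147L,
                                                       173L),
                                   logo_region = c(100L, 175L)) {
  stopifnot(length(domain_span) == 2, domain_span[1] <= domain_span[2],
            all(c("position", "residue") %in% names(signature)))
  if (any(signature$position < domain_span[1] |
          signature$position > domain_span[2])) {
    abort("signature positions must lie within the domain span")
  }
  if (!all(signature$position %in% extended_pocket)) {
    abort("extended pocket must contain all signature positions")
  }
  at <- substring(reference_sequence, signature$position, signature$position)
  if (!all(at == signature$residue)) {
    i <- which(at != signature$residue)[1]
    abort(sprintf(
      "reference residue at position %d is '%s', signature expects '%s'",
      signature$position[i], at[i], signature$residue[i]))
  }
  structure(list(reference_id = reference_id,
                 reference_sequence = reference_sequence,
                 domain_span = as.integer(domain_span),
                 signature = signature,
                 extended_pocket = as.integer(extended_pocket),
                 logo_region = as.integer(logo_region)),
            class = "ref_pocket_model")
}

#' Packaged PctA reference surrogate
#'
#' Loads the synthetic PctA surrogate shipped with the package: a
#' deterministic 300-residue sequence that carries the experimentally
#' established pocket identities (Y101, M111, Y121, R126, W128, Y144, D146,
#' A147, D173) inside the 36-261 dCache_1 span. It is not the natural PctA
#' sequence; substitute the real protein via [reference_pocket_model()]
#' when available.
#'
#' @return A `ref_pocket_model`.
#' @export
pcta_reference <- function() {
  path <- system.file("extdata", "pcta_reference_synthetic.fasta",
                      package = "cachesense", mustWork = TRUE)
  seqs <- read_fasta(path)
  reference_pocket_model(reference_id = seqs$id[1],
                         reference_sequence = seqs$residues[1])
}

#' Reference signature as a string
#' @param ref A `ref_pocket_model`.
#' @return Character scalar, e.g. `"RWYDD"`.
#' @export
signature_string <- function(ref) paste(ref$signature$residue, collapse = "")

#' @export
print.ref_pocket_model <- function(x, ...) {
  cat("<ref_pocket_model>", x$reference_id, "\n")
  cat("  domain span:", x$domain_span[1], "-", x$domain_span[2], "\n")
  cat("  signature:", paste0(x$signature$residue, x$signature$position,
                             collapse = " "), "\n")
  invisible(x)
}
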