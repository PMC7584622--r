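#' Position frequency matrix over the pocket region
#'
#' Tallies residue counts at the retained alignment columns that map to a
#' window of reference positions (default 100-175, the active-pocket
#' region). `X` is tallied separately and excluded from frequencies, as are
#' gaps; the gap fraction is reported alongside.
#'
#' @param family Alignment tibble (`id`, `aligned`).
#' @param cmap Column map from [build_column_map()].
#' @param region Length-2 integer vector of reference positions.
#' @return An object of class `pfm`: list with `positions`, `counts`
#'   (positions x 20 residue matrix), `gap_counts`, `x_counts`, `n_rows`.
#' @export
compute_pfm <- function(family, cmap, region = c(100L, 175L)) {
  want <- seq(region[1], region[2])
  cols <- cmap$refpos_to_col[as.character(want)]
  present <- !is.na(cols)
  if (!any(present)) abort("region lies entirely outside the column map")
  want <- want[present]
  cols <- cols[present]
  counts <- matrix(0L, nrow = length(want), ncol = length(AA20),
                   dimnames = list(want, AA20))
  gap_counts <- integer(length(want))
  x_counts <- integer(length(want))
  for (j in seq_along(cols)) {
    ch <- substring(family$aligned, cols[j], cols[j])
    tb <- table(factor(ch, levels = c(AA20, "X", "-")))
    counts[j, ] <- as.integer(tb[AA20])
    x_counts[j] <- as.integer(tb[["X"]])
    gap_counts[j] <- as.integer(tb[["-"]])
  }
  structure(list(positions = want, counts = counts, gap_counts = gap_counts,
                 x_counts = x_counts, n_rows = nrow(family)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm>", length(x$positions), "positions x 20 residues,",
      x$n_rows, "rows\n")
  invisible(x)
}

#' Per-position residue frequencies
#' @param pfm A [compute_pfm()] result.
#' @return Matrix of frequencies (rows sum to 1 where any residue observed);
#'   gaps and `X` excluded from the denominator.
#' @export
pfm_frequencies <- function(pfm) {
  tot <- rowSums(pfm$counts)
  sweep(pfm$counts, 1, ifelse(tot == 0, 1, tot), "/")
}

#' Information content per position
#'
#' Sequence-logo heights: `IC = log2(20) - H` where `H` is the Shannon
#' entropy of the residue frequencies at the position (gaps and `X`
#' excluded). The optional small-sample correction subtracts
#' `e(n) = (20 - 1) / (2 ln 2 * n)` with `n` the number of residues
#' observed at the position. Positions with no observed residues (all gap)
#' have undefined IC, reported as `NA`.
#'
#' @param pfm A [compute_pfm()] result.
#' @param small_sample_correction Apply the correction term (default off;
#'   negligible at family sizes in the thousands).
#' @return Tibble `position`, `ic_bits`, `gap_fraction`, `top_residue`,
#'   `top_frequency`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  freq <- pfm_frequencies(pfm)
  tot <- rowSums(pfm$counts)
  h <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- log2(20) - h
  if (small_sample_correction) {
    ic <- ic - (length(AA20) - 1) / (2 * log(2) * tot)
  }
  ic[tot == 0] <- NA_real_
  ic <- pmax(ic, 0)
  top <- apply(freq, 1, which.max)
  tibble(
    position = pfm$positions,
    ic_bits = unname(ic),
    gap_fraction = (pfm$gap_counts + pfm$x_counts) / pfm$n_rows,
    top_residue = AA20[top],
    top_frequency = freq[cbind(seq_len(nrow(freq)), top)]
  )
}

#' Most conserved positions
#'
#' Ranks positions by the maximum single-residue frequency; ties are broken
#' by ascending position.
#'
#' @param pfm A [compute_pfm()] result.
#' @param m Number of positions to return.
#' @return Integer vector of `m` reference positions, most conserved first.
#' @export
top_conserved <- function(pfm, m) {
  freq <- pfm_frequencies(pfm)
  peak <- apply(freq, 1, max)
  ord <- order(-peak, pfm$positions)
  pfm$positions[head(ord, m)]
}

#' Write a PFM as a position x residue TSV
#' @param pfm A [compute_pfm()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = pfm$positions, pfm$counts,
                   gap = pfm$gap_counts, X = pfm$x_counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
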