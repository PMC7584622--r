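# Shared fixtures built in code.

ref_model <- pcta_reference()

AA_STD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Gapped alignment whose first row is the reference domain slice, with the
# given gap columns inserted into the reference row (other rows get random
# residues there).
toy_family <- function(extra_rows = 2, gap_cols = integer(), seed = 101) {
  set.seed(seed)
  span <- seq(ref_model$domain_span[1], ref_model$domain_span[2])
  refchars <- strsplit(substring(ref_model$reference_sequence,
                                 min(span), max(span)), "")[[1]]
  width <- length(refchars) + length(gap_cols)
  refrow <- character(width)
  refrow[gap_cols] <- "-"
  refrow[setdiff(seq_len(width), gap_cols)] <- refchars
  rows <- c(paste(refrow, collapse = ""))
  ids <- c(sprintf("%s/%d-%d", ref_model$reference_id, min(span), max(span)))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in seq_len(extra_rows)) {
    rows <- c(rows, paste(sample(aa, width, replace = TRUE), collapse = ""))
    ids <- c(ids, sprintf("row%02d", i))
  }
  tibble::tibble(id = ids, aligned = rows)
}

# Replace the character at reference position `pos` in an aligned row.
mutate_at_refpos <- function(row, cmap, pos, ch) {
  col <- cmap$refpos_to_col[[as.character(pos)]]
  substr(row, col, col) <- ch
  row
}

# Independent 1-D root-finder for the one-site complex concentration:
# solves (a - PL)(b - PL) = Kd * PL by bisection via uniroot.
oracle_complex <- function(nM, L, Kd) {
  if (nM == 0 || L == 0) return(0)
  f <- function(pl) (nM - pl) * (L - pl) - Kd * pl
  upper <- min(nM, L)
  stats::uniroot(f, c(0, upper), tol = upper * 1e-16)$root
}

# Mole-balance account of cumulative heat: tracks complex present in the
# cell and complex lost by displacement, independently of the simulator's
# per-injection increments.
oracle_cumulative_heat <- function(protocol, params) {
  m <- protocol$M0
  l <- 0
  pl <- 0
  displaced <- 0
  for (v in protocol$injections) {
    displaced <- displaced + pl * v
    f <- 1 - v / protocol$V0
    m <- m * f
    l <- l * f + protocol$Ls * v / protocol$V0
    pl <- oracle_complex(params$n * m, l, params$Kd)
  }
  params$dH * (protocol$V0 * pl + displaced) * 1e6
}
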