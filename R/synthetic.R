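#' Configuration for the synthetic family generator
#'
#' Describes a synthetic dCache_1-like aligned family: how many sequences,
#' what fraction carry the full five-residue pocket signature (and the
#' four-of-five partial signature), the background residue emission, the
#' per-cell gap rate, and the functional-class and phylum composition of
#' the cohort. Defaults emulate the screened family structure: a large
#' majority of non-matching domains, a small planted full-match subfamily,
#' MCP-dominated classes and Proteobacteria-dominated phyla.
#'
#' @param n_seqs Number of generated sequences (reference row excluded).
#' @param ref Reference model ([pcta_reference()] by default).
#' @param full_match_fraction Fraction carrying all five signature
#'   residues; exactly `round(f * n_seqs)` sequences are planted.
#' @param partial_match_fraction Fraction carrying exactly four of five.
#' @param background Length-20 emission probabilities over the standard
#'   residues (default uniform).
#' @param signature_fidelity Per-position probability that a planted
#'   signature residue is emitted intact (default 1; lower values blur the
#'   planted subfamily and the ground truth records what was emitted).
#' @param indel_rate Per-cell gap probability (never applied at signature
#'   columns of planted rows).
#' @param class_distribution Named probabilities over functional classes;
#'   names must be classes of `rules` or `"UNCHARACTERIZED"`.
#' @param phylum_distribution Named probabilities over phyla.
#' @param rules Classification rule set used to realize architectures, so
#'   that classifying the generated metadata returns the planted labels.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A list of class `family_gen_config`.
#' @export
family_gen_config <- function(n_seqs = 1000,
                              ref = pcta_reference(),
                              full_match_fraction = 0.08,
                              partial_match_fraction = 0.05,
                              background = rep(1 / 20, 20),
                              signature_fidelity = 1,
                              indel_rate = 0.01,
                              class_distribution = c(
                                MCP = 0.55, HK = 0.18, CSP = 0.12,
                                SP = 0.03, STK = 0.03, `AC/GC` = 0.02,
                                UNCHARACTERIZED = 0.07),
                              phylum_distribution = c(
                                Proteobacteria = 0.55, Firmicutes = 0.2,
                                Bacteroidetes = 0.1, Actinobacteria = 0.08,
                                Euryarchaeota = 0.07),
                              seed = 1L) {
  stopifnot(n_seqs >= 0,
            full_match_fraction >= 0, partial_match_fraction >= 0,
            full_match_fraction + partial_match_fraction <= 1,
            length(background) == 20, all(background >= 0),
            signature_fidelity >= 0, signature_fidelity <= 1,
            indel_rate >= 0, indel_rate < 1,
            all(class_distribution >= 0), all(phylum_distribution >= 0))
  structure(list(
    n_seqs = as.integer(n_seqs), ref = ref,
    full_match_fraction = full_match_fraction,
    partial_match_fraction = partial_match_fraction,
    background = background / sum(background),
    signature_fidelity = signature_fidelity,
    indel_rate = indel_rate,
    class_distribution = class_distribution / sum(class_distribution),
    phylum_distribution = phylum_distribution / sum(phylum_distribution),
    seed = as.integer(seed)
  ), class = "family_gen_config")
}

#' Generate a synthetic aligned family with ground truth
#'
#' Emits an alignment directly (no aligner involved): one column per
#' reference domain position, the reference domain as first row, and
#' `n_seqs` generated rows. Exactly `round(f * n_seqs)` generated rows
#' carry all five signature residues (at the default signature fidelity
#' of 1); a further `round(partial * n_seqs)` carry exactly four; the rest
#' are background and are re-drawn if they match all five by chance.
#' Domain architectures are realized from the classifier's own rule table,
#' so `classify_protein()` on the metadata returns the planted classes.
#'
#' @param cfg A [family_gen_config()].
#' @return A list with `family` (alignment tibble, reference row first),
#'   `metadata` (protein metadata tibble) and `truth` (tibble `id`,
#'   `n_match`, `class`, `phylum`, `is_reference`).
#' @export
generate_family <- function(cfg) {
  stopifnot(inherits(cfg, "family_gen_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  ref <- cfg$ref
  span <- seq(ref$domain_span[1], ref$domain_span[2])
  width <- length(span)
  sig_cols <- match(ref$signature$position, span)
  sig_res <- ref$signature$residue
  n <- cfg$n_seqs
  n_full <- round(cfg$full_match_fraction * n)
  n_part <- round(cfg$partial_match_fraction * n)

  kind <- c(rep("full", n_full), rep("partial", n_part),
            rep("background", n - n_full - n_part))
  kind <- sample(kind)

  mat <- matrix(sample(AA20, n * width, replace = TRUE, prob = cfg$background),
                nrow = n, ncol = width)
  if (cfg$indel_rate > 0 && n > 0) {
    gaps <- matrix(runif(n * width) < cfg$indel_rate, nrow = n)
    mat[gaps] <- "-"
  }
  draw_mismatch <- function(pos_idx) {
    # uniform over the 19 residues that differ from the signature residue
    vapply(pos_idx, function(j) sample(setdiff(AA20, sig_res[j]), 1), "")
  }
  idx_full <- which(kind == "full")
  if (length(idx_full)) {
    keep <- matrix(runif(length(idx_full) * 5) < cfg$signature_fidelity,
                   ncol = 5)
    plant <- matrix(sig_res, nrow = length(idx_full), ncol = 5, byrow = TRUE)
    if (any(!keep)) {
      mut <- which(!keep, arr.ind = TRUE)
      plant[mut] <- draw_mismatch(mut[, 2])
    }
    mat[cbind(rep(idx_full, 5), rep(sig_cols, each = length(idx_full)))] <-
      as.vector(plant)
  }
  idx_part <- which(kind == "partial")
  if (length(idx_part)) {
    mat[cbind(rep(idx_part, 5), rep(sig_cols, each = length(idx_part)))] <-
      rep(sig_res, each = length(idx_part))
    miss <- sample(5, length(idx_part), replace = TRUE)
    mat[cbind(idx_part, sig_cols[miss])] <- draw_mismatch(miss)
  }
  idx_bg <- which(kind == "background")
  if (length(idx_bg)) {
    sigm <- matrix(mat[cbind(rep(idx_bg, 5),
                             rep(sig_cols, each = length(idx_bg)))],
                   ncol = 5)
    accid <- idx_bg[rowSums(sweep(sigm, 2, sig_res, "==")) == 5L]
    for (i in accid) {
      j <- sample(5, 1)
      mat[i, sig_cols[j]] <- draw_mismatch(j)
    }
  }

  ids <- sprintf("SYN%05d", seq_len(n))
  ref_row_id <- sprintf("%s/%d-%d", ref$reference_id,
                        ref$domain_span[1], ref$domain_span[2])
  ref_row <- substring(ref$reference_sequence, ref$domain_span[1],
                       ref$domain_span[2])
  family <- tibble(
    id = c(ref_row_id, ids),
    aligned = c(ref_row,
                if (n > 0) do.call(paste0, asplit(mat, 2)) else character())
  )

  classes <- if (n > 0) sample(names(cfg$class_distribution), n, replace = TRUE,
                               prob = cfg$class_distribution) else character()
  phyla <- if (n > 0) sample(names(cfg$phylum_distribution), n, replace = TRUE,
                             prob = cfg$phylum_distribution) else character()
  rules <- default_class_rules()
  metadata <- dplyr::bind_rows(
    reference_metadata(ref_row_id),
    synthesize_metadata(ids, classes, phyla, rules)
  )

  n_match <- if (n > 0) {
    as.integer(rowSums(sweep(mat[, sig_cols, drop = FALSE], 2, sig_res, "==")))
  } else integer()
  truth <- tibble(
    id = c(ref_row_id, ids),
    n_match = c(5L, n_match),
    class = c("MCP", classes),
    phylum = c("Proteobacteria", phyla),
    is_reference = c(TRUE, rep(FALSE, n))
  )
  list(family = family, metadata = metadata, truth = truth)
}

reference_metadata <- function(ref_row_id) {
  tibble(
    accession = ref_row_id,
    architecture = list(tibble(domain = c("dCache_1", "MCPsignal"),
                               start = c(40L, 450L), end = c(260L, 520L),
                               evalue = c(1e-50, 1e-30))),
    output_domains = list("MCPsignal"),
    lineage = list(c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                     "Pseudomonadales")),
    phylum = "Proteobacteria"
  )
}

synthesize_metadata <- function(ids, classes, phyla, rules) {
  if (length(ids) == 0) {
    return(tibble(accession = character(), architecture = list(),
                  output_domains = list(), lineage = list(),
                  phylum = character()))
  }
  # one architecture prototype per class, shared across rows of that class
  proto_dom <- function(cl) {
    if (cl == "UNCHARACTERIZED") character()
    else rules$domains[[match(cl, rules$class)]][1]
  }
  proto_arch <- function(od) {
    base <- tibble(domain = "dCache_1", start = 40L, end = 260L, evalue = 1e-30)
    if (length(od)) {
      base <- dplyr::bind_rows(base, tibble(domain = od, start = 450L,
                                            end = 520L, evalue = 1e-20))
    }
    base
  }
  ucl <- unique(classes)
  dom_by_class <- setNames(purrr::map(ucl, proto_dom), ucl)
  arch_by_class <- setNames(purrr::map(dom_by_class, proto_arch), ucl)
  out_doms <- unname(dom_by_class[classes])
  arch <- unname(arch_by_class[classes])
  kingdom <- ifelse(phyla %in% c("Euryarchaeota", "Crenarchaeota"),
                    "Archaea", "Bacteria")
  tibble(
    accession = ids,
    architecture = arch,
    output_domains = out_doms,
    lineage = purrr::map2(kingdom, phyla, c),
    phylum = phyla
  )
}

#' Generate replicated synthetic ITC titrations with dilution controls
#'
#' Wraps [simulate_titration()]: each replicate draws a sample thermogram
#' (signal plus constant injection background plus noise) and a matching
#' buffer control (background plus noise only). Replicate seeds are derived
#' deterministically from the master seed.
#'
#' @param protocol A [titration_protocol()].
#' @param params A [one_site_params()] (ground truth).
#' @param noise_sd Gaussian noise sd in microjoules (see
#'   [noise_sd_for()] for the "percent of max heat" convention).
#' @param n_replicates Number of replicate titrations.
#' @param seed Master integer seed.
#' @return A list of `n_replicates` lists, each with `sample` and
#'   `control` thermogram tibbles and `seed_used`.
#' @export
generate_itc_dataset <- function(protocol, params, noise_sd = 0,
                                 n_replicates = 1, seed = 1) {
  stopifnot(n_replicates >= 1)
  control_params <- one_site_params(Kd = 1, n = 1, dH = 0,
                                    q_offset = params$q_offset)
  purrr::map(seq_len(n_replicates), function(i) {
    s_sample <- derive_seed(seed, 2L * i)
    s_control <- derive_seed(seed, 2L * i + 1L)
    list(
      sample = simulate_titration(protocol, params, noise_sd,
                                  seed = if (noise_sd > 0) s_sample else NULL),
      control = simulate_titration(protocol, control_params, noise_sd,
                                   seed = if (noise_sd > 0) s_control else NULL),
      seed_used = s_sample
    )
  })
}

derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

#' Noise level as a fraction of the maximum heat
#'
#' Computes the Gaussian noise standard deviation equal to `frac` of the
#' largest absolute noise-free injection heat for a protocol/parameter
#' pair.
#'
#' @param protocol A [titration_protocol()].
#' @param params A [one_site_params()].
#' @param frac Fraction (e.g. 0.02 for 2 percent).
#' @return Noise sd in microjoules.
#' @export
noise_sd_for <- function(protocol, params, frac = 0.02) {
  q <- ideal_heats(protocol, params)$heat_uJ
  frac * max(abs(q - params$q_offset))
}

#' Generate synthetic phenotype-assay tables
#'
#' Gradient-plate distances are Gaussian around configured means (floored
#' at a small positive value); capillary CFU counts are Poisson.
#'
#' @param d1_mean,d2_mean Mean distances toward/away from the attractant
#'   (mm).
#' @param dist_sd Distance standard deviation (mm).
#' @param n_plates Number of gradient plates.
#' @param treatment_rate,buffer_rate Poisson CFU rates for attractant and
#'   buffer capillaries.
#' @param n_capillaries Number of capillary pairs.
#' @param seed Integer seed.
#' @return List with `gradient` (tibble `plate`, `D1`, `D2`, `RI`) and
#'   `capillary` (tibble `capillary`, `treatment_cfu`, `buffer_cfu`).
#' @export
generate_assay_dataset <- function(d1_mean = 6.5, d2_mean = 3.5,
                                   dist_sd = 0.3, n_plates = 5,
                                   treatment_rate = 1000, buffer_rate = 200,
                                   n_capillaries = 5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d1 <- pmax(rnorm(n_plates, d1_mean, dist_sd), 0.01)
  d2 <- pmax(rnorm(n_plates, d2_mean, dist_sd), 0.01)
  gradient <- tibble(plate = seq_len(n_plates), D1 = d1, D2 = d2,
                     RI = response_index(d1, d2))
  capillary <- tibble(
    capillary = seq_len(n_capillaries),
    treatment_cfu = rpois(n_capillaries, treatment_rate),
    buffer_cfu = rpois(n_capillaries, buffer_rate)
  )
  list(gradient = gradient, capillary = capillary)
}
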