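#' Run the full signature-screen pipeline
#'
#' Reads (or accepts in-memory) a family alignment and protein metadata,
#' anchors columns to reference numbering, screens for the pocket
#' signature, classifies and rolls up by functional class and phylum, and
#' profiles conservation over the logo region. When `out_dir` is given,
#' writes `screen.tsv`, `rollup_class.tsv`, `rollup_phylum.tsv`, `pfm.tsv`
#' and a `manifest.json` with input checksums and parameters; reruns of the
#' same inputs produce identical bytes.
#'
#' @param alignment Alignment tibble, or path to an aligned FASTA file.
#' @param metadata Metadata tibble, or path to a protein table TSV.
#' @param ref Reference model (default [pcta_reference()]).
#' @param k Signature match threshold (default 5).
#' @param rules Classification rules (default [default_class_rules()]).
#' @param region Conservation region (default the reference logo region).
#' @param out_dir Optional output directory.
#' @return A list with `screen`, `summary`, `rollup_class`,
#'   `rollup_phylum`, `pfm`, `information` and `manifest`.
#' @export
run_scan <- function(alignment, metadata, ref = pcta_reference(), k = 5L,
                     rules = default_class_rules(),
                     region = NULL, out_dir = NULL) {
  aln_path <- NULL
  if (is.character(alignment)) {
    aln_path <- alignment
    alignment <- read_alignment(alignment)
  }
  meta_path <- NULL
  if (is.character(metadata)) {
    meta_path <- metadata
    metadata <- read_protein_table(metadata)
  }
  if (is.null(region)) region <- ref$logo_region
  cmap <- with_stage("column-map", build_column_map(alignment, ref))
  screen <- with_stage("screen", screen_family(alignment, cmap, ref, k = k))
  summary <- with_stage("summarize",
                        summarize_screen(screen, metadata, rules = rules))
  passing <- dplyr::filter(summary, .data$passes)
  pfm <- with_stage("conservation", compute_pfm(alignment, cmap, region))
  manifest <- list(
    parameters = list(k = k, region = as.integer(region),
                      reference_id = ref$reference_id,
                      n_rows = nrow(alignment)),
    checksums = list(
      alignment = if (!is.null(aln_path)) unname(tools::md5sum(aln_path)) else NA,
      metadata = if (!is.null(meta_path)) unname(tools::md5sum(meta_path)) else NA
    ),
    counts = list(screened = nrow(screen), passing = sum(screen$passes))
  )
  out <- list(screen = screen, summary = summary,
              rollup_class = rollup(passing, "class"),
              rollup_phylum = rollup(passing, "phylum"),
              pfm = pfm, information = information_content(pfm),
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(as.data.frame(dplyr::select(summary, -dplyr::any_of("evidence"))),
                 file.path(out_dir, "screen.tsv"), "tsv")
    write_report(as.data.frame(out$rollup_class),
                 file.path(out_dir, "rollup_class.tsv"), "tsv")
    write_report(as.data.frame(out$rollup_phylum),
                 file.path(out_dir, "rollup_phylum.tsv"), "tsv")
    write_pfm(pfm, file.path(out_dir, "pfm.tsv"))
    write_report(manifest, file.path(out_dir, "manifest.json"), "json")
  }
  out
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Fit one or more thermogram files
#'
#' Reads thermogram CSVs, applies the heat-of-dilution correction when a
#' control file is paired, fits the one-site model and (optionally) writes
#' one JSON fit report per input, in input order.
#'
#' @param paths Character vector of thermogram CSV paths.
#' @param control_paths Optional equal-length vector of control CSVs.
#' @param fix_n Optional fixed stoichiometry passed to [fit_one_site()].
#' @param seed Integer seed for optimizer starts.
#' @param out_dir Optional output directory for `<name>_fit.json` reports.
#' @return A list of `one_site_fit` objects named by file.
#' @export
run_itc <- function(paths, control_paths = NULL, fix_n = NULL, seed = 1,
                    out_dir = NULL) {
  if (!is.null(control_paths)) stopifnot(length(control_paths) == length(paths))
  fits <- purrr::map(seq_along(paths), function(i) {
    tg <- read_thermogram(paths[i])
    q <- tg$heats$heat_uJ
    if (!is.null(control_paths)) {
      ctl <- read_thermogram(control_paths[i])
      q <- subtract_dilution(q, ctl$heats$heat_uJ)
    }
    fit <- fit_one_site(q, tg$protocol, fix_n = fix_n, seed = seed)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      nm <- sub("\\.csv$", "", basename(paths[i]))
      write_report(c(as.list(tidy(fit) |> tidyr::pivot_wider(
        names_from = "term", values_from = c("estimate", "std.error"))),
        as.list(glance(fit))),
        file.path(out_dir, paste0(nm, "_fit.json")), "json")
    }
    fit
  })
  setNames(fits, basename(paths))
}

#' Generate and write a synthetic scan + ITC bundle
#'
#' Convenience wrapper over the generators: writes the synthetic family
#' alignment, metadata table, ground truth and one replicate set of ITC
#' thermograms into a directory. A seed is mandatory.
#'
#' @param out_dir Output directory.
#' @param cfg A [family_gen_config()].
#' @param protocol,params,noise_sd,n_replicates ITC generation settings.
#' @param seed Master seed (required).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, cfg = family_gen_config(),
                         protocol = titration_protocol(),
                         params = one_site_params(Kd = 0.14e-6),
                         noise_sd = 0, n_replicates = 1, seed) {
  if (missing(seed)) abort("a seed is mandatory for simulation runs")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$seed <- as.integer(seed)
  fam <- generate_family(cfg)
  paths <- list(
    alignment = file.path(out_dir, "family.afa"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_alignment(fam$family, paths$alignment)
  write_protein_table(fam$metadata, paths$metadata)
  write_report(as.data.frame(dplyr::select(fam$truth, -dplyr::any_of("evidence"))),
               paths$truth, "tsv")
  reps <- generate_itc_dataset(protocol, params, noise_sd, n_replicates,
                               seed = seed)
  for (i in seq_along(reps)) {
    sp <- file.path(out_dir, sprintf("itc_rep%02d.csv", i))
    cp <- file.path(out_dir, sprintf("itc_rep%02d_control.csv", i))
    write_thermogram(protocol, reps[[i]]$sample$heat_uJ, sp)
    write_thermogram(protocol, reps[[i]]$control$heat_uJ, cp)
    paths[[sprintf("itc_rep%02d", i)]] <- sp
    paths[[sprintf("itc_rep%02d_control", i)]] <- cp
  }
  invisible(paths)
}
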