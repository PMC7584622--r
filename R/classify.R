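#' Default functional-class rule set
#'
#' Maps Pfam-style output-domain names to the signal-transduction families
#' used for dCache_1-containing proteins: methyl-accepting chemotaxis
#' proteins (MCP), histidine kinases (HK), c-di-GMP synthases and
#' phosphodiesterases (CSP: GGDEF, EAL, HD-GYP), serine phosphatases (SP),
#' serine/threonine kinases (STK), adenylate/guanylate cyclases (AC/GC)
#' and proteins whose only extra domain is cyclic-nucleotide-binding
#' (CNB-only). Precedence (first match wins for multi-domain proteins):
#' MCP > CSP > HK > SP > STK > AC/GC > CNB-only.
#'
#' @return A tibble of class `class_rules` with columns `class` (in
#'   precedence order) and `domains` (list of character).
#' @export
default_class_rules <- function() {
  rules <- tibble(
    class = c("MCP", "CSP", "HK", "SP", "STK", "AC/GC", "CNB-only"),
    domains = list(
      c("MCPsignal", "MA"),
      c("GGDEF", "EAL", "HD-GYP", "HDc"),
      c("HisKA", "HisKA_2", "HisKA_3", "HATPase_c"),
      c("SpoIIE", "PP2C"),
      c("Pkinase"),
      c("Guanylate_cyc"),
      c("cNMP_binding")
    )
  )
  validate_class_rules(rules)
}

validate_class_rules <- function(rules) {
  stopifnot(all(c("class", "domains") %in% names(rules)))
  if (anyDuplicated(rules$class)) abort("duplicate class in rule set")
  if (any(purrr::map_int(rules$domains, length) == 0)) {
    abort("every class needs at least one qualifying domain name")
  }
  structure(rules, class = c("class_rules", class(tibble())))
}

#' Read / write a classification rule file (YAML)
#'
#' The YAML is an ordered mapping `class: [domain, ...]`; order defines
#' precedence.
#'
#' @param path YAML file path.
#' @return `read_class_rules()` returns a `class_rules` tibble;
#'   `write_class_rules()` returns `path` invisibly.
#' @export
read_class_rules <- function(path) {
  y <- yaml::read_yaml(path)
  validate_class_rules(tibble(class = names(y),
                              domains = unname(purrr::map(y, as.character))))
}

#' @rdname read_class_rules
#' @param rules A `class_rules` tibble.
#' @export
write_class_rules <- function(rules, path) {
  yaml::write_yaml(setNames(purrr::map(rules$domains, as.list), rules$class),
                   path)
  invisible(path)
}

#' Classify proteins by output-domain architecture
#'
#' Total classification: the first class in precedence order with at least
#' one qualifying output domain wins; `CNB-only` additionally requires that
#' no other output domain is present. Proteins with output domains but no
#' qualifying one are `"OTHER-annotated"`; proteins with no output domains
#' at all are `"UNCHARACTERIZED"`.
#'
#' @param metadata Metadata tibble ([read_protein_table()] columns).
#' @param rules A `class_rules` tibble (default [default_class_rules()]).
#' @return `metadata` with added columns `class` and `evidence` (list of
#'   matched domain names).
#' @export
classify_protein <- function(metadata, rules = default_class_rules()) {
  rules <- validate_class_rules(rules)
  res <- purrr::map(metadata$output_domains, classify_one, rules = rules)
  metadata$class <- purrr::map_chr(res, "class")
  metadata$evidence <- purrr::map(res, "evidence")
  metadata
}

classify_one <- function(out_domains, rules) {
  out_domains <- unique(out_domains)
  if (length(out_domains) == 0) {
    return(list(class = "UNCHARACTERIZED", evidence = character()))
  }
  for (i in seq_len(nrow(rules))) {
    hit <- intersect(out_domains, rules$domains[[i]])
    if (length(hit)) {
      if (rules$class[i] == "CNB-only" &&
          length(setdiff(out_domains, rules$domains[[i]])) > 0) next
      return(list(class = rules$class[i], evidence = hit))
    }
  }
  list(class = "OTHER-annotated", evidence = character())
}

#' Roll up classified screen results
#'
#' Counts records by class, phylum or their cross; counts always sum to the
#' number of input records. Sorted by descending count, then name, for
#' deterministic output.
#'
#' @param results Tibble with `class` and/or `phylum` columns (e.g. from
#'   [summarize_screen()] or [classify_protein()]).
#' @param by `"class"`, `"phylum"` or `"class_phylum"`.
#' @return Tibble of counts.
#' @export
rollup <- function(results, by = c("class", "phylum", "class_phylum")) {
  by <- match.arg(by)
  keys <- switch(by, class = "class", phylum = "phylum",
                 class_phylum = c("class", "phylum"))
  out <- dplyr::count(results, dplyr::across(dplyr::all_of(keys)), name = "n")
  dplyr::arrange(out, dplyr::desc(.data$n),
                 dplyr::across(dplyr::all_of(keys)))
}
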