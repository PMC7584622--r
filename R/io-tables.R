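#' Read a protein metadata table
#'
#' Tab-separated with header and columns `accession`, `architecture`
#' (semicolon-joined `domain:start-end:evalue` triples, 1-based inclusive
#' coordinates), `output_domains` (semicolon-joined names) and `lineage`
#' (semicolon-joined taxonomy from superkingdom downward). The phylum is
#' derived positionally: the second lineage element when the first is a
#' superkingdom, otherwise `"unresolved"`.
#'
#' Rows whose architecture fails to parse are skipped with a warning;
#' missing required columns are a hard error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `accession`, `architecture` (list of
#'   tibbles `domain`,`start`,`end`,`evalue`), `output_domains` (list of
#'   character), `lineage` (list of character) and `phylum`.
#' @export
read_protein_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE)
  need <- c("accession", "architecture", "output_domains", "lineage")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste0("missing required column(s): ",
                                 paste(miss, collapse = ", ")))
  arch <- purrr::map(raw$architecture, purrr::safely(parse_architecture))
  failed <- purrr::map_lgl(arch, ~ is.null(.x$result))
  if (any(failed)) {
    warn(sprintf("skipping %d record(s) with unparseable architecture: %s",
                 sum(failed), paste(raw$accession[failed], collapse = ", ")))
  }
  keep <- !failed
  lineage <- purrr::map(strsplit(raw$lineage[keep], ";", fixed = TRUE), trimws)
  out <- tibble(
    accession = raw$accession[keep],
    architecture = purrr::map(arch[keep], "result"),
    output_domains = purrr::map(strsplit(raw$output_domains[keep], ";", fixed = TRUE),
                                function(x) x[nzchar(trimws(x))]),
    lineage = lineage,
    phylum = purrr::map_chr(lineage, derive_phylum)
  )
  if (anyDuplicated(out$accession)) {
    abort(paste0("duplicate accession in metadata: ",
                 out$accession[duplicated(out$accession)][1]))
  }
  out
}

parse_architecture <- function(s) {
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  toks <- toks[nzchar(trimws(toks))]
  if (length(toks) == 0) {
    return(tibble(domain = character(), start = integer(),
                  end = integer(), evalue = double()))
  }
  m <- regmatches(toks, regexec("^\\s*([^:]+):(\\d+)-(\\d+):([0-9eE.+-]+)\\s*$", toks))
  if (any(vapply(m, length, 1L) != 5L)) {
    stop("unparseable architecture token: ",
         toks[vapply(m, length, 1L) != 5L][1])
  }
  out <- tibble(
    domain = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    evalue = as.numeric(vapply(m, `[`, "", 5L))
  )
  if (any(out$start > out$end) || any(out$evalue < 0) || anyNA(out$evalue)) {
    stop("invalid architecture interval or e-value in: ", s)
  }
  out
}

SUPERKINGDOMS <- c("Bacteria", "Archaea", "Eukaryota", "Viruses")

derive_phylum <- function(lineage) {
  if (length(lineage) >= 2 && lineage[1] %in% SUPERKINGDOMS) lineage[2] else "unresolved"
}

#' Write a protein metadata table
#'
#' Inverse of [read_protein_table()]; deterministic column and row order so
#' re-serialization is byte-stable.
#'
#' @param meta Metadata tibble as returned by [read_protein_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(meta, path) {
  arch <- purrr::map_chr(meta$architecture, function(a) {
    if (nrow(a) == 0) return("")
    paste(sprintf("%s:%d-%d:%s", a$domain, a$start, a$end,
                  format(a$evalue, scientific = TRUE, digits = 3)),
          collapse = ";")
  })
  df <- data.frame(
    accession = meta$accession,
    architecture = arch,
    output_domains = purrr::map_chr(meta$output_domains, paste, collapse = ";"),
    lineage = purrr::map_chr(meta$lineage, paste, collapse = ";"),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ITC thermogram file
#'
#' CSV with a protocol header block (`key,value` lines for `V0_L`, `Ls_M`,
#' `M0_M`, `T_K`) followed by a `injection,volume_L,heat_uJ` table. Units
#' are SI internally: litres, mol/L, microjoules for heats.
#'
#' @param path Path to the CSV file.
#' @return A list of class `thermogram_file` with elements `protocol`
#'   (a [titration_protocol()]) and `heats` (tibble `injection`,
#'   `volume_L`, `heat_uJ`).
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  hdr_end <- match("injection,volume_L,heat_uJ", lines)
  if (is.na(hdr_end)) abort("thermogram file lacks 'injection,volume_L,heat_uJ' header")
  kv <- strsplit(lines[seq_len(hdr_end - 1)], ",", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  need <- c("V0_L", "Ls_M", "M0_M", "T_K")
  miss <- setdiff(need, keys)
  if (length(miss)) abort(paste0("missing protocol field(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyNA(vals)) abort(sprintf("non-numeric protocol value for '%s'",
                                 keys[which(is.na(vals))[1]]))
  p <- setNames(vals, keys)
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, ",", fixed = TRUE)
  num <- suppressWarnings(lapply(cells, as.numeric))
  bad <- which(vapply(num, anyNA, TRUE))
  if (length(bad)) abort(sprintf("non-numeric thermogram entry at data row %d", bad[1]))
  heats <- tibble(
    injection = vapply(num, `[`, 0, 1L),
    volume_L = vapply(num, `[`, 0, 2L),
    heat_uJ = vapply(num, `[`, 0, 3L)
  )
  protocol <- titration_protocol(V0 = p[["V0_L"]], Ls = p[["Ls_M"]],
                                 M0 = p[["M0_M"]], injections = heats$volume_L,
                                 temperature = p[["T_K"]])
  structure(list(protocol = protocol, heats = heats), class = "thermogram_file")
}

#' Write an ITC thermogram file
#'
#' @param protocol A [titration_protocol()].
#' @param heats Numeric vector of per-injection heats (microjoules), one per
#'   injection in the protocol.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(protocol, heats, path) {
  stopifnot(length(heats) == length(protocol$injections))
  lines <- c(
    sprintf("V0_L,%.10g", protocol$V0),
    sprintf("Ls_M,%.10g", protocol$Ls),
    sprintf("M0_M,%.10g", protocol$M0),
    sprintf("T_K,%.10g", protocol$temperature),
    "injection,volume_L,heat_uJ",
    sprintf("%d,%.10g,%.10g", seq_along(heats), protocol$injections, heats)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a deterministic report
#'
#' Tables are written with fixed column order and a fixed float format so
#' identical inputs always serialize to identical bytes.
#'
#' @param tables A named list of data frames (or, for JSON, any
#'   jsonlite-serializable structure).
#' @param path Output path.
#' @param format `"tsv"` (single table) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(tables, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(tables, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stopifnot(is.data.frame(tables))
    df <- as.data.frame(tables)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return The deserialized structure.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
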