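test_that("FASTA read preserves order, ids and residues, and round trips byte-stably", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1 first record", "MKTAYIAK", ">seq2", "GWYDDLLX"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs$id, c("seq1", "seq2"))
  expect_equal(seqs$description, c("first record", ""))
  expect_equal(seqs$residues, c("MKTAYIAK", "GWYDDLLX"))

  out1 <- withr::local_tempfile(fileext = ".fasta")
  out2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, out1)
  write_fasta(read_fasta(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("FASTA parser rejects illegal residues with position, and gaps", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "MKTA", ">bad", "MKJA"), path)
  expect_error(read_fasta(path), "illegal residue.*'J'.*'bad'.*position 3")
  writeLines(c(">gapd", "MK-A"), path)
  expect_error(read_fasta(path), "illegal residue")
})

test_that("alignment reading normalizes '.' gaps, validates rectangularity, round trips", {
  path <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">a", "MK.A", ">b", "M-TA"), path)
  aln <- read_alignment(path)
  expect_equal(aln$aligned, c("MK-A", "M-TA"))
  expect_equal(alignment_width(aln), 4L)

  writeLines(c(">a", "MKTA", ">b", "MTA", ">c", "MKTA"), path)
  expect_error(read_alignment(path), "ragged alignment.*'b'")

  aln <- tibble::tibble(id = c("x", "y"), aligned = c("AC-DE", "A--DE"))
  out <- withr::local_tempfile()
  write_alignment(aln, out)
  expect_equal(read_alignment(out), aln)
  # single-character corruption of the residue alphabet must be rejected
  lines <- readLines(out)
  lines[2] <- sub("A", "1", lines[2])
  writeLines(lines, out)
  expect_error(read_alignment(out), "illegal character")
})

test_that("Stockholm rows parse with annotation lines ignored and blocks joined", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GS seq1 DE something",
               "seq1 MKT.A",
               "seq2 MK--A",
               "",
               "seq1 CD",
               "seq2 CD",
               "#=GC SS_cons ....",
               "//"), path)
  aln <- read_alignment(path, dialect = "stockholm")
  expect_equal(aln$id, c("seq1", "seq2"))
  expect_equal(aln$aligned, c("MKT-ACD", "MK--ACD"))
})

test_that("protein table parses architectures, output domains and phylum", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\tarchitecture\toutput_domains\tlineage",
    "A1\tdCache_1:40-260:1e-30;MCPsignal:500-560:1e-20\tMCPsignal\tBacteria;Proteobacteria;Gamma",
    "A2\tdCache_1:40-260:1e-30\t\tBacteria;Firmicutes",
    "A3\tdCache_1:40-260:1e-30\t\tsomething_odd"), path)
  meta <- read_protein_table(path)
  expect_equal(nrow(meta), 3)
  a1 <- meta$architecture[[1]]
  expect_equal(nrow(a1), 2)
  expect_equal(a1$domain, c("dCache_1", "MCPsignal"))
  expect_equal(a1$start, c(40L, 500L))
  expect_equal(a1$evalue, c(1e-30, 1e-20))
  expect_equal(meta$output_domains[[1]], "MCPsignal")
  expect_equal(meta$output_domains[[2]], character())
  expect_equal(meta$phylum, c("Proteobacteria", "Firmicutes", "unresolved"))
})

test_that("protein table reports missing columns hard and bad architectures softly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tarchitecture\toutput_domains",
               "A1\tx:1-2:0\t"), path)
  expect_error(read_protein_table(path), "missing required column")

  writeLines(c(
    "accession\tarchitecture\toutput_domains\tlineage",
    "A1\tdCache_1:40-260:1e-30\t\tBacteria;Proteobacteria",
    "A2\tnot_a_token\t\tBacteria;Firmicutes"), path)
  expect_warning(meta <- read_protein_table(path), "skipping 1 record.*A2")
  expect_equal(meta$accession, "A1")
})

test_that("protein table round trips through its own serializer", {
  fam <- generate_family(family_gen_config(n_seqs = 25, seed = 5))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(fam$metadata, p1)
  back <- read_protein_table(p1)
  expect_equal(back$accession, fam$metadata$accession)
  expect_equal(back$output_domains, fam$metadata$output_domains)
  expect_equal(back$phylum, fam$metadata$phylum)
  write_protein_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("thermogram files round trip with protocol echoed and reject bad entries", {
  prot <- titration_protocol()
  q <- seq(-40, -16, length.out = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermogram(prot, q, path)
  tg <- read_thermogram(path)
  expect_equal(length(tg$heats$heat_uJ), 25)
  expect_equal(tg$heats$heat_uJ, q)
  expect_equal(tg$protocol$Ls, prot$Ls)
  expect_equal(tg$protocol$M0, prot$M0)
  expect_equal(tg$protocol$injections, prot$injections)

  lines <- readLines(path)
  lines[8] <- sub(",-", ",x-", lines[8])  # corrupt a heat value
  writeLines(lines, path)
  expect_error(read_thermogram(path), "non-numeric thermogram entry at data row 3")

  writeLines(c("V0_L,0.001", "Ls_M,7e-4", "T_K,293.15",
               "injection,volume_L,heat_uJ", "1,1e-5,-40"), path)
  expect_error(read_thermogram(path), "missing protocol field.*M0_M")
})

test_that("JSON reports round trip", {
  x <- list(run = "demo", counts = list(screened = 10L, passing = 3L))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(x, path, "json")
  expect_equal(read_report(path), x)
})
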