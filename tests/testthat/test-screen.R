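test_that("reference row passes at k = 5; one substitution drops it to k = 4", {
  fam <- toy_family(extra_rows = 0)
  cmap <- build_column_map(fam, ref_model)
  res <- screen_family(fam, cmap, ref_model, k = 5)
  expect_equal(res$n_match, 5L)
  expect_true(res$passes)
  expect_equal(res$matched_positions[[1]], c(126L, 128L, 144L, 146L, 173L))

  # PctB/PctC-like: four of the five conserved residues
  fam4 <- fam
  fam4$id <- "pctb_like"
  fam4$aligned <- mutate_at_refpos(fam4$aligned, cmap, 146L, "E")
  fam4 <- dplyr::bind_rows(fam, fam4)
  at5 <- screen_family(fam4, cmap, ref_model, k = 5)
  expect_equal(at5$passes, c(TRUE, FALSE))
  at4 <- screen_family(fam4, cmap, ref_model, k = 4)
  expect_equal(at4$passes, c(TRUE, TRUE))
  expect_equal(at4$n_match, c(5L, 4L))
})

test_that("gap or X at a signature column counts as mismatch", {
  fam <- toy_family(extra_rows = 0)
  cmap <- build_column_map(fam, ref_model)
  gapped <- mutate_at_refpos(fam$aligned[1], cmap, 126L, "-")
  xed <- mutate_at_refpos(fam$aligned[1], cmap, 173L, "X")
  fam2 <- tibble::tibble(id = c("g", "x"), aligned = c(gapped, xed))
  res <- screen_family(fam2, cmap, ref_model)
  expect_equal(res$n_match, c(4L, 4L))
  expect_equal(res$signature_string, c("-WYDD", "RWYDX"))
})

test_that("screening a family whose alignment misses a pocket position fails hard", {
  fam <- toy_family(extra_rows = 1)
  cmap <- build_column_map(fam, ref_model)
  crippled <- cmap
  keep <- crippled$col_to_refpos != 144L
  crippled$col_to_refpos <- crippled$col_to_refpos[keep]
  crippled$refpos_to_col <- crippled$refpos_to_col[names(crippled$refpos_to_col) != "144"]
  expect_error(screen_family(fam, crippled, ref_model), "signature position.*144")
})

test_that("screen recovers generator truth exactly and respects k-monotonicity", {
  fam <- generate_family(family_gen_config(
    n_seqs = 400, full_match_fraction = 0.12, partial_match_fraction = 0.2,
    seed = 31))
  cmap <- build_column_map(fam$family, ref_model)
  res <- screen_family(fam$family, cmap, ref_model, k = 5)
  expect_equal(res$n_match, fam$truth$n_match)
  prev <- NULL
  for (k in 5:0) {
    rk <- screen_family(fam$family, cmap, ref_model, k = k)
    expect_equal(sum(rk$passes), sum(fam$truth$n_match >= k))
    if (!is.null(prev)) expect_true(all(rk$passes[prev]))
    prev <- rk$passes
  }
})

test_that("screen is invariant to row order and to unmapped extra columns", {
  fam <- generate_family(family_gen_config(n_seqs = 120, seed = 17))
  cmap <- build_column_map(fam$family, ref_model)
  base <- screen_family(fam$family, cmap, ref_model)

  set.seed(99)
  perm <- sample(nrow(fam$family))
  shuf <- fam$family[perm, ]
  res_shuf <- screen_family(shuf, build_column_map(shuf, ref_model), ref_model)
  expect_equal(res_shuf[order(perm), ]$n_match, base$n_match)

  # splice columns that are gapped in the reference row (hence unmapped)
  set.seed(100)
  width <- nchar(fam$family$aligned[1])
  at <- sort(sample(width, 3))
  spliced <- fam$family
  for (j in rev(at)) {
    ins <- ifelse(spliced$id == fam$family$id[1], "-",
                  sample(c("-", "A", "K"), nrow(spliced), replace = TRUE))
    spliced$aligned <- paste0(substring(spliced$aligned, 1, j), ins,
                              substring(spliced$aligned, j + 1))
  }
  res_spliced <- screen_family(spliced, build_column_map(spliced, ref_model),
                               ref_model)
  expect_equal(res_spliced$n_match, base$n_match)
  expect_equal(res_spliced$signature_string, base$signature_string)
})

test_that("summarize_screen joins class and phylum and logs missing metadata", {
  fam <- generate_family(family_gen_config(n_seqs = 50, seed = 23))
  cmap <- build_column_map(fam$family, ref_model)
  res <- screen_family(fam$family, cmap, ref_model)
  joined <- summarize_screen(res, fam$metadata)
  expect_equal(nrow(joined), nrow(res))
  expect_equal(joined$class[-1], fam$truth$class[-1])
  expect_equal(joined$phylum, fam$truth$phylum)

  expect_warning(j2 <- summarize_screen(res, fam$metadata[-2, ]), "unknown")
  expect_equal(j2$class[2], "unknown")

  dup <- dplyr::bind_rows(fam$metadata, fam$metadata[2, ])
  expect_error(summarize_screen(res, dup), "duplicate accession")
})

test_that("rollups of screened passes match generator truth and degenerate cases", {
  fam <- generate_family(family_gen_config(n_seqs = 300,
                                           full_match_fraction = 0.1,
                                           seed = 41))
  cmap <- build_column_map(fam$family, ref_model)
  res <- screen_family(fam$family, cmap, ref_model)
  joined <- summarize_screen(res, fam$metadata)
  passing <- dplyr::filter(joined, passes)
  truth_pass <- dplyr::filter(fam$truth, n_match == 5)
  expect_equal(nrow(passing), nrow(truth_pass))
  got <- rollup(passing, "phylum")
  want <- rollup(truth_pass, "phylum")
  expect_equal(got, want)

  none <- dplyr::filter(joined, n_match > 5)
  expect_equal(nrow(rollup(none, "class")), 0)

  all_rows <- rollup(joined, "class")
  expect_equal(sum(all_rows$n), nrow(joined))
})
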