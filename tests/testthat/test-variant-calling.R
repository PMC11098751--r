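model <- fixture_model(2, 1000)

counts <- function(A = 0L, C = 0L, G = 0L, T = 0L) {
  list(A = A, C = C, G = G, T = T)
}

test_that("candidates are emitted for significant cell types only", {
  mat <- make_matrix(
    make_matrix_row(pos = 100, ref = "A", cell_type = "typeA",
                    counts(A = 42L, C = 8L)),
    make_matrix_row(pos = 100, ref = "A", cell_type = "typeB",
                    counts(A = 40L)))
  cand <- detect_candidates(mat, model)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$target_cell_type, "typeA")
  expect_equal(cand$alt, "C")
  expect_equal(cand$p_value, oracle_bb_tail(8, 50, 2, 1000),
               tolerance = 1e-10)

  none <- make_matrix(make_matrix_row(pos = 1, ref = "A",
                                      cell_type = "typeA", counts(A = 50L)))
  expect_equal(nrow(detect_candidates(none, model)), 0)
})

test_that("two well-supported alternative alleles flag Multi_allelic", {
  mat <- make_matrix(
    make_matrix_row(pos = 5, ref = "A", cell_type = "typeA",
                    counts(A = 21L, C = 5L, T = 4L)))
  cand <- detect_candidates(mat, model)
  expect_true(any(grepl("Multi_allelic", cand$flags)))
  # a single supported alt does not
  mat2 <- make_matrix(
    make_matrix_row(pos = 5, ref = "A", cell_type = "typeA",
                    counts(A = 21L, C = 5L, T = 2L)))
  expect_false(any(grepl("Multi_allelic",
                         detect_candidates(mat2, model)$flags)))
})

test_that("exclusivity removes germline-like and pooled-significant sites", {
  # germline-like: alt in all cell types at ~50%
  germ <- make_matrix(
    make_matrix_row(pos = 10, ref = "C", cell_type = "typeA",
                    counts(C = 15L, T = 15L)),
    make_matrix_row(pos = 10, ref = "C", cell_type = "typeB",
                    counts(C = 16L, T = 14L)),
    make_matrix_row(pos = 10, ref = "C", cell_type = "typeC",
                    counts(C = 14L, T = 16L)))
  cand <- detect_candidates(germ, model)
  out <- exclusivity_filter(cand, germ, model)
  expect_true(all(grepl("Other_celltype_significant", out$flags)))

  # exclusive somatic: no flag
  som <- make_matrix(
    make_matrix_row(pos = 20, ref = "C", cell_type = "typeA",
                    counts(C = 20L, T = 10L)),
    make_matrix_row(pos = 20, ref = "C", cell_type = "typeB",
                    counts(C = 30L)),
    make_matrix_row(pos = 20, ref = "C", cell_type = "typeC",
                    counts(C = 30L)))
  cand2 <- detect_candidates(som, model)
  out2 <- exclusivity_filter(cand2, som, model)
  expect_false(any(grepl("Other_celltype_significant", out2$flags)))

  # each other type individually non-significant, but the aggregate is
  expect_gte(oracle_bb_tail(2, 30, 2, 1000), 0.001)
  expect_lt(oracle_bb_tail(4, 60, 2, 1000), 0.001)
  agg <- make_matrix(
    make_matrix_row(pos = 30, ref = "C", cell_type = "typeA",
                    counts(C = 20L, T = 10L)),
    make_matrix_row(pos = 30, ref = "C", cell_type = "typeB",
                    counts(C = 28L, T = 2L)),
    make_matrix_row(pos = 30, ref = "C", cell_type = "typeC",
                    counts(C = 28L, T = 2L)))
  cand3 <- detect_candidates(agg, model)
  cand3 <- cand3[target_cell_type == "typeA"]
  out3 <- exclusivity_filter(cand3, agg, model)
  expect_true(all(grepl("Other_celltype_significant", out3$flags)))
})

test_that("minimum support needs 3 reads, 2 cells and depth 5", {
  pass <- make_candidate(pos = 1, ref = "A", alt = "C", cell_type = "t",
                         depth = 6, alt_count = 3, n_cells_alt = 2)
  one_cell <- make_candidate(pos = 2, ref = "A", alt = "C", cell_type = "t",
                             depth = 6, alt_count = 3, n_cells_alt = 1)
  two_reads <- make_candidate(pos = 3, ref = "A", alt = "C", cell_type = "t",
                              depth = 6, alt_count = 2, n_cells_alt = 2)
  shallow <- make_candidate(pos = 4, ref = "A", alt = "C", cell_type = "t",
                            depth = 4, alt_count = 3, n_cells_alt = 2)
  out <- min_support_filter(rbind(pass, one_cell, two_reads, shallow))
  expect_equal(has_flag <- grepl("Min_support", out$flags),
               c(FALSE, TRUE, TRUE, TRUE))
})

test_that("homopolymer proximity flags at 4 bp but not 5 bp", {
  ref <- list(sequence = paste0(strrep("ACGT", 24), "AC",  # 98 bp lead-in
                                "AAAAAA",                  # tract 99..104
                                strrep("GTCA", 30)),
              chrom = "chr1")
  tr <- find_homopolymers(ref, 4)
  expect_equal(tr$start, 99L)
  expect_equal(tr$end, 104L)
  cands <- rbind(
    make_candidate(pos = 101, ref = "A", alt = "G", cell_type = "t"),
    make_candidate(pos = 107, ref = "C", alt = "T", cell_type = "t"),
    make_candidate(pos = 108, ref = "A", alt = "T", cell_type = "t"),
    make_candidate(pos = 109, ref = "G", alt = "A", cell_type = "t"))
  out <- homopolymer_filter(cands, ref, proximity = 4, min_tract_len = 4)
  # inside; distance 3; distance 4; distance 5
  expect_equal(grepl("Homopolymer", out$flags), c(TRUE, TRUE, TRUE, FALSE))
  far <- make_candidate(pos = 9999, ref = "A", alt = "C", cell_type = "t")
  expect_error(homopolymer_filter(far, ref), "beyond")
})

test_that("clustered variants are flagged except allow-listed doublets", {
  c1 <- make_candidate(pos = 200, ref = "A", alt = "G", cell_type = "t")
  c2 <- make_candidate(pos = 203, ref = "C", alt = "T", cell_type = "t")
  out <- clustered_filter(rbind(c1, c2))
  expect_true(all(grepl("Clustered", out$flags)))

  c3 <- make_candidate(pos = 205, ref = "C", alt = "T", cell_type = "t")
  out2 <- clustered_filter(rbind(c1, c3))
  expect_false(any(grepl("Clustered", out2$flags)))

  # adjacent CC>TT in the same cell type is exempt
  d1 <- make_candidate(pos = 300, ref = "C", alt = "T", cell_type = "t")
  d2 <- make_candidate(pos = 301, ref = "C", alt = "T", cell_type = "t")
  out3 <- clustered_filter(rbind(d1, d2))
  expect_false(any(grepl("Clustered", out3$flags)))
  # ... including on the purine strand (GG>AA == CC>TT)
  e1 <- make_candidate(pos = 400, ref = "G", alt = "A", cell_type = "t")
  e2 <- make_candidate(pos = 401, ref = "G", alt = "A", cell_type = "t")
  expect_false(any(grepl("Clustered", clustered_filter(rbind(e1, e2))$flags)))
  # but an adjacent non-allow-listed doublet is not exempt
  f1 <- make_candidate(pos = 500, ref = "A", alt = "G", cell_type = "t")
  f2 <- make_candidate(pos = 501, ref = "T", alt = "C", cell_type = "t")
  expect_true(all(grepl("Clustered", clustered_filter(rbind(f1, f2))$flags)))
})

test_that("doublet exemption demands shared barcode support when available", {
  d1 <- make_candidate(pos = 300, ref = "C", alt = "T", cell_type = "t")
  d2 <- make_candidate(pos = 301, ref = "C", alt = "T", cell_type = "t")
  shared <- rbind(
    data.table(chrom = "chr1", pos = 300L, ref = "C", cell_type = "t",
               barcode = "b1", A = 0L, C = 2L, G = 0L, T = 3L, other = 0L),
    data.table(chrom = "chr1", pos = 301L, ref = "C", cell_type = "t",
               barcode = "b1", A = 0L, C = 2L, G = 0L, T = 3L, other = 0L))
  out <- clustered_filter(rbind(d1, d2), cell_counts = shared)
  expect_false(any(grepl("Clustered", out$flags)))
  disjoint <- copy(shared)[pos == 301L, barcode := "b2"]
  out2 <- clustered_filter(rbind(d1, d2), cell_counts = disjoint)
  expect_true(all(grepl("Clustered", out2$flags)))
})

test_that("panel of normals stores and flags recurrent sites", {
  sig_row <- function(pos) make_matrix_row(pos = pos, ref = "A",
                                           cell_type = "typeA",
                                           counts(A = 40L, G = 10L))
  null_row <- function(pos) make_matrix_row(pos = pos, ref = "A",
                                            cell_type = "typeA",
                                            counts(A = 50L))
  normals <- list(
    make_matrix(sig_row(100), sig_row(200), null_row(300)),
    make_matrix(sig_row(100), null_row(200), null_row(300)),
    make_matrix(null_row(100), null_row(200), null_row(300)),
    make_matrix(null_row(100), null_row(200), null_row(300)),
    make_matrix(null_row(100), null_row(200), null_row(300)))
  pon <- build_pon(normals, model)
  expect_equal(pon[pos == 100, n_samples], 2L)
  expect_equal(pon[pos == 200, n_samples], 1L)
  expect_false(300L %in% pon$pos)

  cands <- rbind(
    make_candidate(pos = 100, ref = "A", alt = "G", cell_type = "t"),
    make_candidate(pos = 200, ref = "A", alt = "G", cell_type = "t"),
    make_candidate(pos = 300, ref = "A", alt = "G", cell_type = "t"))
  out <- pon_filter(cands, pon, min_samples = 2)
  expect_equal(grepl("PON", out$flags), c(TRUE, FALSE, FALSE))

  expect_warning(p1 <- build_pon(normals[1], model), "single")
  expect_identical(pon_filter(cands, p1)$flags, cands$flags)
})

test_that("PON round-trips through its TSV format", {
  sig_row <- make_matrix_row(pos = 7, ref = "A", cell_type = "typeA",
                             counts(A = 40L, G = 10L))
  pon <- suppressWarnings(build_pon(list(make_matrix(sig_row)), model))
  path <- tempfile(fileext = ".tsv")
  write_pon(pon, path)
  back <- read_pon(path)
  expect_equal(as.data.table(back)$pos, as.data.table(pon)$pos)
  expect_equal(attr(back, "n_panel_samples"), 1L)
})

test_that("the PASS set is independent of filter order", {
  sim <- small_sim()
  mat <- cell_counts_to_matrix(sim$cell_counts)
  cand0 <- detect_candidates(mat, model)
  a <- exclusivity_filter(cand0, mat, model)
  a <- min_support_filter(a)
  a <- homopolymer_filter(a, sim$reference)
  a <- clustered_filter(a)
  b <- clustered_filter(cand0)
  b <- homopolymer_filter(b, sim$reference)
  b <- min_support_filter(b)
  b <- exclusivity_filter(b, mat, model)
  pass_a <- a[!nzchar(flags), .(chrom, pos, alt, target_cell_type)]
  pass_b <- b[!nzchar(flags), .(chrom, pos, alt, target_cell_type)]
  setkey(pass_a, NULL); setkey(pass_b, NULL)
  expect_equal(pass_a[order(pos)], pass_b[order(pos)])
})

test_that("pure-null fixtures yield no PASS calls", {
  for (seed in 1:5) {
    cfg <- sim_config(n_cell_types = 3, cells_per_type = 50,
                      reference_length = 3000, germline_sites = 0,
                      somatic_sites_per_cell_type = 0, artefact_sites = 0,
                      seed = 1000 + seed)
    sim <- simulate_sample(cfg)
    mat <- cell_counts_to_matrix(sim$cell_counts)
    res <- call_mutations(mat, model, reference = sim$reference)
    expect_equal(nrow(res$pass), 0, info = paste("seed", seed))
  }
})

test_that("spiked truth is recovered end to end with clean precision", {
  sim <- small_sim(seed = 29)
  cfg <- small_cfg(seed = 29)
  mat <- cell_counts_to_matrix(sim$cell_counts)
  normals <- simulate_normal_panel(cfg, sim$reference, sim$truth,
                                   n_samples = 4)
  nmats <- lapply(normals, function(x) cell_counts_to_matrix(x$cell_counts))
  pon <- build_pon(nmats, model)
  res <- call_mutations(mat, model, reference = sim$reference, pon = pon,
                        cell_counts = sim$cell_counts)
  truth_keys <- sim$truth$somatic[, paste(pos, alt, cell_type)]
  pass_keys <- res$pass[, paste(pos, alt, target_cell_type)]
  expect_setequal(pass_keys, truth_keys)        # recall and precision 1
  # germline flagged, artefacts never PASS
  germ_cand <- res$calls[pos %in% sim$truth$germline$pos]
  expect_true(all(grepl("Other_celltype_significant", germ_cand$flags)))
  expect_false(any(res$pass$pos %in% sim$truth$artefact_sites$pos))
})

test_that("VCF output carries PASS and filter flags", {
  cand <- rbind(
    make_candidate(pos = 10, ref = "A", alt = "C", cell_type = "typeA"),
    make_candidate(pos = 20, ref = "G", alt = "T", cell_type = "typeB",
                   flags = "PON;Homopolymer"))
  cand[, filter := fifelse(nzchar(flags), flags, "PASS")]
  path <- tempfile(fileext = ".vcf")
  write_vcf(cand, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  expect_match(body[1], "\tPASS\t")
  expect_match(body[2], "PON;Homopolymer")
  expect_true(file.exists(sub("\\.vcf$", ".tsv", path)))
})
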