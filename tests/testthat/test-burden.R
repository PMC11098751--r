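test_that("callable sites follow the two-cell-type depth rule", {
  cc <- rbind(
    data.table(chrom = "chr1", pos = 10L, ref = "A", cell_type = "typeA",
               barcode = "a1", A = 6L, C = 0L, G = 0L, T = 0L, other = 0L),
    data.table(chrom = "chr1", pos = 10L, ref = "A", cell_type = "typeB",
               barcode = "b1", A = 5L, C = 0L, G = 0L, T = 0L, other = 0L),
    data.table(chrom = "chr1", pos = 20L, ref = "A", cell_type = "typeA",
               barcode = "a1", A = 6L, C = 0L, G = 0L, T = 0L, other = 0L),
    data.table(chrom = "chr1", pos = 20L, ref = "A", cell_type = "typeB",
               barcode = "b1", A = 4L, C = 0L, G = 0L, T = 0L, other = 0L),
    data.table(chrom = "chrX", pos = 30L, ref = "A", cell_type = "typeA",
               barcode = "a1", A = 9L, C = 0L, G = 0L, T = 0L, other = 0L),
    data.table(chrom = "chrX", pos = 30L, ref = "A", cell_type = "typeB",
               barcode = "b1", A = 9L, C = 0L, G = 0L, T = 0L, other = 0L))
  mat <- cell_counts_to_matrix(cc, apply_inclusion = FALSE)
  cs <- compute_callable_sites(mat, cell_counts = cc)
  # pos 10 callable for both; pos 20 for neither; chrX excluded
  expect_equal(cs$cell_type[cell_type == "typeA", callable_sites], 1L)
  expect_equal(cs$cell_type[cell_type == "typeB", callable_sites], 1L)
  expect_false(30L %in% cs$sites$pos)
  cs_all <- compute_callable_sites(mat, autosomes_only = FALSE)
  expect_true(30L %in% cs_all$sites$pos)
})

test_that("cell-type burden arithmetic and QC exclusion", {
  callable <- list(cell_type = data.table(
    cell_type = c("typeA", "typeB", "typeC"),
    callable_sites = c(2000000L, 400000L, 1000000L)))
  calls <- data.table(target_cell_type = c(rep("typeA", 12), "typeB"))
  b <- cell_type_burden(calls, callable)
  expect_equal(b[cell_type == "typeA", rate], 6.0)
  expect_true(b[cell_type == "typeB", qc_excluded])
  expect_true(is.na(b[cell_type == "typeB", rate]))
  expect_equal(b[cell_type == "typeC", rate], 0.0)
  # scale equivariance: doubling the denominator halves the rate
  callable2 <- list(cell_type = copy(callable$cell_type)[
    , callable_sites := callable_sites * 2L])
  b2 <- cell_type_burden(calls, callable2)
  expect_equal(b2[cell_type == "typeA", rate],
               b[cell_type == "typeA", rate] / 2)
})

test_that("per-cell burden attributes mutations by alt-supporting reads", {
  cc <- rbind(
    data.table(chrom = "chr1", pos = c(10L, 20L), ref = "A",
               cell_type = "typeA", barcode = "cell1",
               A = 3L, C = 0L, G = 0L, T = c(2L, 0L), other = 0L),
    data.table(chrom = "chr1", pos = c(10L, 20L), ref = "A",
               cell_type = "typeA", barcode = "cell2",
               A = 3L, C = 0L, G = 0L, T = 0L, other = 0L))
  calls <- data.table(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                      alt = "T", target_cell_type = "typeA")
  callable <- list(
    cell_type = data.table(cell_type = "typeA", callable_sites = 2L),
    sites = data.table(chrom = "chr1", pos = c(10L, 20L),
                       cell_type = "typeA"),
    per_cell = data.table(barcode = c("cell1", "cell2"),
                          cell_type = "typeA",
                          covered_callable_sites = c(500000L, 500000L)))
  pb <- per_cell_burden(calls, cc, callable, genome_size_bp = 2.8e9)
  # cell1 carries the pos-10 mutation only (no alt reads at pos 20)
  expect_equal(pb[barcode == "cell1", n_mutations], 1L)
  expect_equal(pb[barcode == "cell2", n_mutations], 0L)
  expect_equal(pb[barcode == "cell1", rate], 2.0)  # 1 / 5e5 * 1e6
  expect_equal(pb[barcode == "cell1", genome_extrapolation], 5600)
  expect_equal(pb[barcode == "cell2", genome_extrapolation], 0)
})

test_that("two mutations over half a megabase extrapolate to 11,200", {
  # worked arithmetic chain: 2 / 500,000 = 4e-6 per bp -> x 2.8e9
  rate_bp <- 2 / 500000
  expect_equal(rate_bp * 2.8e9, 11200)
  cc <- data.table(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                   cell_type = "typeA", barcode = "cell1",
                   A = 0L, C = 0L, G = 0L, T = 3L, other = 0L)
  calls <- data.table(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                      alt = "T", target_cell_type = "typeA")
  callable <- list(
    cell_type = data.table(cell_type = "typeA", callable_sites = 500000L),
    sites = data.table(chrom = "chr1", pos = c(10L, 20L),
                       cell_type = "typeA"),
    per_cell = data.table(barcode = "cell1", cell_type = "typeA",
                          covered_callable_sites = 500000L))
  pb <- per_cell_burden(calls, cc, callable, genome_size_bp = 2.8e9)
  expect_equal(pb$genome_extrapolation, 11200)
})

test_that("cell-type burden matches aggregated per-cell attribution", {
  sim <- small_sim()
  cfg <- small_cfg()
  mat <- cell_counts_to_matrix(sim$cell_counts, apply_inclusion = FALSE)
  callable <- compute_callable_sites(mat, cell_counts = sim$cell_counts)
  calls <- sim$truth$somatic[, .(chrom, pos, ref, alt,
                                 target_cell_type = cell_type)]
  bt <- cell_type_burden(calls, callable, min_callable = 100)
  pb <- per_cell_burden(calls, sim$cell_counts, callable,
                        genome_size_bp = 1e6)
  # every mutant cell covers its mutation by construction, so per-cell
  # attributions aggregate to at least the cell-type mutation count
  agg <- pb[, .(n = sum(n_mutations)), by = cell_type]
  truth <- copy(sim$truth$somatic)
  truth[, m := lengths(strsplit(mutant_cell_ids, ","))]
  want <- truth[, .(tot = sum(m)), by = cell_type]
  expect_equal(agg[order(cell_type), n], want[order(cell_type), tot])
})

test_that("autosomal genome size sums autosomes only", {
  lens <- c(chr1 = 1000, chr2 = 2000, chrX = 500, chrM = 16)
  expect_equal(autosomal_genome_size(lens), 3000)
  fai <- tempfile(fileext = ".fai")
  writeLines(c("chr1\t1000\t5\t60\t61", "chrX\t500\t1100\t60\t61"), fai)
  expect_equal(autosomal_genome_size(fai), 1000)
})
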