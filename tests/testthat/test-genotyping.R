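test_that("genotypes follow the ternary evidence rules", {
  calls <- data.table(chrom = "chr1", pos = 100L, ref = "C", alt = "T")
  cc <- rbind(
    data.table(chrom = "chr1", pos = 100L, ref = "C", cell_type = "typeA",
               barcode = "mutant_cell", A = 0L, C = 2L, G = 0L, T = 1L,
               other = 0L),
    data.table(chrom = "chr1", pos = 100L, ref = "C", cell_type = "typeA",
               barcode = "ref_cell", A = 0L, C = 3L, G = 0L, T = 0L,
               other = 0L),
    data.table(chrom = "chr1", pos = 999L, ref = "A", cell_type = "typeA",
               barcode = "uncovered_cell", A = 1L, C = 0L, G = 0L, T = 0L,
               other = 0L))
  gm <- genotype_cells(calls, cc)
  g <- setNames(gm$genotype, gm$barcode)
  expect_equal(g[["mutant_cell"]], "mutant")
  expect_equal(g[["ref_cell"]], "reference")
  expect_equal(g[["uncovered_cell"]], "missing")
  # entry-evidence invariants
  expect_true(all(gm[genotype == "mutant", alt_reads >= 1]))
  expect_true(all(gm[genotype == "reference",
                     total_reads >= 1 & alt_reads == 0]))
  expect_true(all(gm[genotype == "missing", total_reads == 0]))
})

test_that("genotyping invariants hold on simulated fixtures", {
  sim <- small_sim()
  calls <- sim$truth$somatic[, .(chrom, pos, ref, alt)]
  gm <- genotype_cells(calls, sim$cell_counts, sim$annotations)
  expect_true(all(gm[genotype == "mutant", alt_reads >= 1]))
  expect_true(all(gm[genotype == "reference",
                     total_reads >= 1 & alt_reads == 0]))
  expect_true(all(gm[genotype == "missing", total_reads == 0]))
  # every annotated cell appears once per mutation
  expect_equal(nrow(gm), nrow(calls) * nrow(sim$annotations))
})

test_that("mutant-cell fractions use covered cells as denominator", {
  m <- matrix("R", nrow = 30, ncol = 1,
              dimnames = list(paste0("c", 1:30), "m1"))
  m[1:5, 1] <- "M"
  m[21:30, 1] <- "."
  gm <- make_genotype_matrix(m)
  mcf <- mutant_cell_fraction(gm)
  expect_equal(mcf$n_mutant_cells, 5L)
  expect_equal(mcf$n_covered_cells, 20L)
  expect_equal(mcf$mutant_cell_fraction, 0.25)

  all_missing <- make_genotype_matrix(
    matrix(".", 5, 1, dimnames = list(paste0("c", 1:5), "m1")))
  expect_true(is.na(mutant_cell_fraction(all_missing)$mutant_cell_fraction))

  clonal <- make_genotype_matrix(
    matrix("M", 5, 1, dimnames = list(paste0("c", 1:5), "m1")))
  expect_equal(mutant_cell_fraction(clonal)$mutant_cell_fraction, 1.0)
})

test_that("clustering gates enforce 20 mutant cells and 10% genotyped", {
  cells <- paste0("c", 1:200)
  base <- matrix(".", 200, 3, dimnames = list(cells, c("m19", "m20", "m9pct")))
  base[1:19, "m19"] <- "M"; base[20:40, "m19"] <- "R"
  base[1:20, "m20"] <- "M"; base[21:60, "m20"] <- "R"
  base[1:18, "m9pct"] <- "M"                     # genotyped in 18/200 = 9%
  gm <- make_genotype_matrix(base)
  kept <- filter_for_clustering(gm, 20, 0.10)
  expect_setequal(unique(kept$mut_id), "m20")
  # boundary: exactly 20 cells and exactly 10% pass
  exact <- matrix(".", 200, 1, dimnames = list(cells, "m"))
  exact[1:20, 1] <- "M"
  kept2 <- filter_for_clustering(make_genotype_matrix(exact), 20, 0.10)
  expect_equal(unique(kept2$mut_id), "m")
  expect_warning(filter_for_clustering(make_genotype_matrix(base[, 3,
    drop = FALSE]), 20, 0.10), "no mutations")
})

two_clone_matrix <- function(missing_frac = 0) {
  cells <- c(paste0("cloneA_", 1:50), paste0("cloneB_", 1:50))
  muts <- paste0("m", 1:12)
  m <- matrix("R", 100, 12, dimnames = list(cells, muts))
  m[1:50, 1:6] <- "M"
  m[51:100, 7:12] <- "M"
  if (missing_frac > 0) {
    set.seed(77)
    idx <- sample(length(m), round(length(m) * missing_frac))
    m[idx] <- "."
  }
  m
}

test_that("planted two-clone structure is recovered exactly", {
  skip_if_not_installed("mclust")
  gm <- make_genotype_matrix(two_clone_matrix())
  cl <- hierarchical_cluster(gm, k = 2)
  truth <- ifelse(grepl("^cloneA", names(cl$clones)), 1, 2)
  expect_equal(mclust::adjustedRandIndex(cl$clones, truth), 1.0)
  # identical columns end up adjacent in the ordering
  ord <- match(names(cl$clones)[cl$clones == cl$clones[["cloneA_1"]]],
               cl$cell_order)
  expect_equal(sort(ord), min(ord):max(ord))

  # robust to 5% missing entries
  gm5 <- make_genotype_matrix(two_clone_matrix(0.05))
  cl5 <- hierarchical_cluster(gm5, k = 2)
  truth5 <- ifelse(grepl("^cloneA", names(cl5$clones)), 1, 2)
  expect_equal(mclust::adjustedRandIndex(cl5$clones, truth5), 1.0)
  # the gap criterion finds k = 2 on its own
  cl_auto <- hierarchical_cluster(gm)
  expect_equal(length(unique(cl_auto$clones)), 2)
})

test_that("clustering is invariant to input row order", {
  gm <- make_genotype_matrix(two_clone_matrix(0.03))
  set.seed(5)
  shuffled <- structure(as.data.table(gm)[sample(.N)],
                        class = class(gm))
  a <- hierarchical_cluster(gm, k = 2)
  b <- hierarchical_cluster(shuffled, k = 2)
  expect_identical(a$cell_order, b$cell_order)
  expect_identical(a$clones, b$clones)
})

test_that("degenerate inputs return trivial orderings", {
  single <- make_genotype_matrix(
    matrix("M", 5, 1, dimnames = list(paste0("c", 1:5), "m1")))
  cl <- hierarchical_cluster(single)
  expect_equal(length(unique(cl$clones)), 1)
  expect_null(cl$cell_hclust)
})

test_that("genotype matrices serialize with ternary codes", {
  gm <- make_genotype_matrix(two_clone_matrix())
  path <- tempfile(fileext = ".tsv")
  write_genotype_matrix(gm, path)
  wide <- fread(path)
  expect_equal(nrow(wide), 12)
  expect_true(all(unlist(wide[, -1]) %in% c("M", "R", ".")))
  expect_true(file.exists(paste0(path, ".evidence.tsv")))
})
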