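library(data.table)

# a small shared sample fixture, built once per test run
small_cfg <- function(seed = 3) {
  sim_config(n_cell_types = 3, cells_per_type = 50, reference_length = 1500,
             mean_depth_per_cell_type = 30, germline_sites = 5,
             somatic_sites_per_cell_type = 2, artefact_sites = 3,
             seed = seed)
}

.fixture_cache <- new.env()
small_sim <- function(seed = 3) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_sample(small_cfg(seed))
  }
  .fixture_cache[[key]]
}

# a reference model for tests that need fixed, known parameters
fixture_model <- function(alpha = 2, beta = 1000) {
  structure(list(alpha = alpha, beta = beta, n_training_sites = NA_integer_,
                 fit_log_likelihood = NA_real_, convergence = 0L,
                 technology_label = "fixture", valid = TRUE,
                 mean_error = alpha / (alpha + beta)), class = "bb_model")
}

# hand-rolled base-count-matrix rows for filter unit tests
make_matrix_row <- function(pos, ref, cell_type, counts,
                            chrom = "chr1", n_cells = NULL) {
  row <- data.table(chrom = chrom, pos = as.integer(pos), ref = ref,
                    cell_type = cell_type,
                    A = counts[["A"]], C = counts[["C"]],
                    G = counts[["G"]], T = counts[["T"]],
                    other = counts[["other"]] %||% 0L)
  if (is.null(n_cells)) {
    n_cells <- counts[["A"]] + counts[["C"]] + counts[["G"]] + counts[["T"]]
  }
  row[, `:=`(n_cells = n_cells,
             n_cells_A = pmin(A, n_cells), n_cells_C = pmin(C, n_cells),
             n_cells_G = pmin(G, n_cells), n_cells_T = pmin(T, n_cells))]
  row[, depth := A + C + G + T + other]
  row
}

make_matrix <- function(...) {
  mat <- rbindlist(list(...))
  structure(mat, class = c("base_count_matrix", class(mat)))
}

# candidate rows for filter unit tests
make_candidate <- function(chrom = "chr1", pos, ref, alt, cell_type,
                           depth = 30L, alt_count = 5L, n_cells_alt = 3L,
                           p_value = 1e-5, flags = "") {
  data.table(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             target_cell_type = cell_type, depth = as.integer(depth),
             alt_count = as.integer(alt_count),
             n_cells_alt = as.integer(n_cells_alt),
             p_value = p_value, flags = flags)
}

# long genotype matrix from a cells x mutations character matrix with
# entries "M", "R", "."
make_genotype_matrix <- function(mat_chr, cell_types = NULL) {
  muts <- colnames(mat_chr)
  cells <- rownames(mat_chr)
  if (is.null(cell_types)) cell_types <- rep("typeA", length(cells))
  gm <- CJ(barcode = cells, mut_id = muts, sorted = FALSE)
  gm <- merge(gm, data.table(barcode = cells, cell_type = cell_types),
              by = "barcode")
  code <- c(M = "mutant", R = "reference", "." = "missing")
  gm[, genotype := code[mat_chr[cbind(barcode, mut_id)]]]
  gm[, `:=`(chrom = "chr1", pos = match(mut_id, muts), ref = "C", alt = "T",
            alt_reads = fifelse(genotype == "mutant", 2L, 0L),
            total_reads = fifelse(genotype == "missing", 0L, 3L))]
  structure(gm, class = c("genotype_matrix", class(gm)))
}
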