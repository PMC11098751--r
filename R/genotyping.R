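# Single-cell genotyping, mutant-cell fractions and clonal clustering.
#
# Genotype semantics: mutant = at least one alt-supporting read; reference
# = covered (>= 1 read) with zero alt reads; missing = no coverage. Calls
# from any region of the same individual may be genotyped across all
# regions (region-aware calling, union genotyping).

#' Genotype every cell at every called mutation
#'
#' @param calls call table with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `target_cell_type`, `region`).
#' @param cell_counts per-cell count table (base-quality filtering is
#'   inherited from the counting stage).
#' @param annotations optional barcode annotation table; cells absent from
#'   it are skipped (their number is the `"n_skipped_barcodes"` attribute).
#' @return a `genotype_matrix`: long data.table `mut_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `barcode`, `cell_type`, `alt_reads`, `total_reads`,
#'   `genotype` in {"mutant", "reference", "missing"}.
#' @export
genotype_cells <- function(calls, cell_counts, annotations = NULL) {
  cl <- unique(as.data.table(calls)[, .(chrom, pos, ref, alt)])
  cl[, mut_id := sprintf("%s:%d:%s>%s", chrom, pos, ref, alt)]
  cc <- as.data.table(cell_counts)
  cells <- unique(cc[, .(barcode, cell_type)])
  n_skipped <- 0L
  if (!is.null(annotations)) {
    ann <- as.data.table(annotations)
    n_skipped <- sum(!cells$barcode %in% ann$barcode)
    if (n_skipped > 0) {
      message(n_skipped, " barcodes absent from annotations: skipped")
    }
    cells <- cells[barcode %in% ann$barcode]
  }
  grid <- cl[, as.list(cells), by = .(mut_id, chrom, pos, ref, alt)]
  ev <- cc[, .(chrom, pos, barcode,
               A, C, G, T, other)][grid, on = c("chrom", "pos", "barcode")]
  ev[is.na(A), `:=`(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L)]
  ev[, total_reads := A + C + G + T + other]
  ev[, alt_reads := as.matrix(.SD)[cbind(seq_len(.N), match(alt, BASES))],
     .SDcols = BASES]
  ev[, genotype := fifelse(alt_reads >= 1, "mutant",
                           fifelse(total_reads >= 1, "reference",
                                   "missing"))]
  out <- ev[, .(mut_id, chrom, pos, ref, alt, barcode, cell_type,
                alt_reads, total_reads, genotype)]
  setorder(out, mut_id, cell_type, barcode)
  structure(out[], class = c("genotype_matrix", class(out)),
            n_skipped_barcodes = n_skipped)
}

#' Mutant-cell fractions per mutation and group
#'
#' Fractions are computed over covered cells only (`missing` entries are
#' excluded from the denominator); a group with zero covered cells yields
#' `NA`.
#'
#' @param matrix a `genotype_matrix`.
#' @param grouping column to group cells by (default `"cell_type"`; use
#'   NULL for a single overall group).
#' @return data.table `mut_id`, group column, `n_mutant_cells`,
#'   `n_covered_cells`, `mutant_cell_fraction`.
#' @export
mutant_cell_fraction <- function(matrix, grouping = "cell_type") {
  gm <- as.data.table(matrix)
  by_cols <- c("mut_id", grouping)
  out <- gm[, .(n_mutant_cells = sum(genotype == "mutant"),
                n_covered_cells = sum(genotype != "missing")),
            by = by_cols]
  out[, mutant_cell_fraction := fifelse(n_covered_cells > 0,
                                        n_mutant_cells / n_covered_cells,
                                        NA_real_)]
  setorderv(out, by_cols)
  out[]
}

#' Gate mutations for clonal clustering
#'
#' Keeps mutations present in at least `min_mutant_cells` cells and
#' genotyped (covered) in at least `min_genotyped_fraction` of all cells.
#'
#' @param matrix a `genotype_matrix` built across all regions.
#' @param min_mutant_cells minimum mutant cells (default 20).
#' @param min_genotyped_fraction minimum genotyped fraction of all cells
#'   (default 0.10).
#' @return the filtered `genotype_matrix`; warns when empty.
#' @export
filter_for_clustering <- function(matrix, min_mutant_cells = 20,
                                  min_genotyped_fraction = 0.10) {
  gm <- as.data.table(matrix)
  stats <- gm[, .(n_mutant = sum(genotype == "mutant"),
                  genotyped_fraction = mean(genotype != "missing")),
              by = mut_id]
  keep_ids <- stats[n_mutant >= min_mutant_cells &
                      genotyped_fraction >= min_genotyped_fraction, mut_id]
  out <- gm[mut_id %in% keep_ids]
  if (nrow(out) == 0) warning("no mutations pass the clustering gates")
  structure(out[], class = c("genotype_matrix", class(out)))
}

#' Hierarchical clustering of cells by shared mutations
#'
#' Cells and mutations are clustered on the binary mutant-indicator matrix
#' (missing treated as 0 for distances, but retained in the genotype matrix
#' for display) with Jaccard distance and average linkage. Clone labels
#' come from cutting the cell dendrogram at `k` clusters, or, when `k` is
#' NULL, at the largest relative gap in merge heights (2 .. `max_k`).
#' Inputs are sorted lexicographically first, so the result is invariant to
#' input row order.
#'
#' @param matrix a (filtered) `genotype_matrix`.
#' @param k number of clones, or NULL for the gap criterion.
#' @param max_k largest k considered by the gap criterion.
#' @return list with `cell_order`, `mutation_order` (character vectors),
#'   `clones` (named integer vector of clone labels per barcode),
#'   `cell_hclust`, `mutation_hclust` (or NULL for degenerate inputs).
#' @export
hierarchical_cluster <- function(matrix, k = NULL, max_k = 10) {
  gm <- as.data.table(matrix)
  wide <- data.table::dcast(gm, barcode ~ mut_id,
                            value.var = "genotype",
                            fun.aggregate = function(x) x[1])
  setorder(wide, barcode)
  bin <- as.matrix(wide[, -1]) == "mutant"
  bin[is.na(bin)] <- FALSE
  mode(bin) <- "integer"
  rownames(bin) <- wide$barcode
  bin <- bin[, sort(colnames(bin)), drop = FALSE]
  if (nrow(bin) < 2 || ncol(bin) < 2) {
    return(list(cell_order = rownames(bin), mutation_order = colnames(bin),
                clones = setNames(rep(1L, nrow(bin)), rownames(bin)),
                cell_hclust = NULL, mutation_hclust = NULL))
  }
  dc <- stats::dist(bin, method = "binary")
  dc[is.na(dc)] <- 1
  hc_cells <- stats::hclust(dc, method = "average")
  dm <- stats::dist(t(bin), method = "binary")
  dm[is.na(dm)] <- 1
  hc_mut <- stats::hclust(dm, method = "average")
  if (is.null(k)) {
    h <- sort(hc_cells$height, decreasing = TRUE)
    kmax <- min(max_k, nrow(bin) - 1L)
    gaps <- h[seq_len(kmax - 1L)] - h[seq_len(kmax - 1L) + 1L]
    k <- which.max(gaps) + 1L
  }
  clones <- stats::cutree(hc_cells, k = min(k, nrow(bin)))
  list(cell_order = rownames(bin)[hc_cells$order],
       mutation_order = colnames(bin)[hc_mut$order],
       clones = clones, cell_hclust = hc_cells, mutation_hclust = hc_mut)
}

#' Write genotype and clonality outputs
#'
#' The genotype matrix is written wide (entries `M`/`R`/`.`) with an
#' evidence sidecar (`<path>.evidence.tsv`, the long table).
#'
#' @param matrix a `genotype_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(matrix, path) {
  gm <- as.data.table(matrix)
  code <- c(mutant = "M", reference = "R", missing = ".")
  gm[, label := code[genotype]]
  wide <- data.table::dcast(gm, mut_id ~ barcode, value.var = "label")
  fwrite(wide, path, sep = "\t")
  fwrite(gm[, -"label"], paste0(path, ".evidence.tsv"), sep = "\t")
  invisible(path)
}
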