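# Callable sites and mutational burdens.
#
# A site is callable for cell type c when its depth in c is at least
# min_depth and at least one other cell type also reaches min_depth —
# mirroring the calling requirement that evidence from a second cell type
# exists to test exclusivity against. Only autosomes enter burden
# denominators. Burdens are reported per haploid genome: single-cell assays
# mostly detect one allele per cell and position, and no ploidy correction
# is attempted.

#' Compute callable sites per cell type (and per cell)
#'
#' @param matrix a `base_count_matrix` (inclusion rule applied or not).
#' @param cell_counts optional per-cell count table; when given, per-cell
#'   covered-callable-site counts (>= 1 read within the cell type's
#'   callable set) are returned.
#' @param min_depth per-cell-type depth required for callability.
#' @param autosomes_only drop sex/organellar chromosomes (default TRUE).
#' @return list with `cell_type` (data.table `cell_type`,
#'   `callable_sites`), `sites` (long table of callable site/cell-type
#'   pairs) and `per_cell` (data.table `barcode`, `cell_type`,
#'   `covered_callable_sites`, or NULL).
#' @export
compute_callable_sites <- function(matrix, cell_counts = NULL,
                                   min_depth = 5, autosomes_only = TRUE) {
  mat <- as.data.table(matrix)
  if (autosomes_only) mat <- mat[is_autosome(chrom)]
  deep <- mat[depth >= min_depth, .(chrom, pos, cell_type)]
  n_deep <- deep[, .(n_celltypes_ge = .N), by = .(chrom, pos)]
  deep <- deep[n_deep[n_celltypes_ge >= 2], on = c("chrom", "pos")]
  deep[, n_celltypes_ge := NULL]
  per_type <- deep[, .(callable_sites = .N), by = cell_type]
  all_types <- unique(mat$cell_type)
  missing_types <- setdiff(all_types, per_type$cell_type)
  if (length(missing_types) > 0) {
    per_type <- rbind(per_type, data.table(cell_type = missing_types,
                                           callable_sites = 0L))
  }
  setorder(per_type, cell_type)
  per_cell <- NULL
  if (!is.null(cell_counts)) {
    cc <- as.data.table(cell_counts)
    if (autosomes_only) cc <- cc[is_autosome(chrom)]
    cc <- cc[A + C + G + T + other >= 1]
    cov <- cc[deep, on = c("chrom", "pos", "cell_type"), nomatch = NULL]
    per_cell <- cov[, .(covered_callable_sites = data.table::uniqueN(
      paste(chrom, pos))), by = .(barcode, cell_type)]
    setorder(per_cell, cell_type, barcode)
  }
  list(cell_type = per_type, sites = deep[], per_cell = per_cell)
}

#' Cell-type-level mutational burden
#'
#' Total PASS mutations per cell type divided by the cell type's callable
#' sites, reported per Mb. Cell types with fewer than `min_callable`
#' callable sites are marked `qc_excluded` and get no rate.
#'
#' @param calls PASS call table (with `target_cell_type`).
#' @param callable_summary from [compute_callable_sites()].
#' @param min_callable QC threshold on callable sites (default 500,000).
#' @return data.table `cell_type`, `n_mutations`, `callable_sites`, `rate`
#'   (mutations per Mb), `qc_excluded`.
#' @export
cell_type_burden <- function(calls, callable_summary,
                             min_callable = 500000) {
  ct <- copy(callable_summary$cell_type)
  cl <- as.data.table(calls)
  nm <- if (nrow(cl) > 0) {
    cl[, .(n_mutations = .N), by = .(cell_type = target_cell_type)]
  } else data.table(cell_type = character(), n_mutations = integer())
  out <- merge(ct, nm, by = "cell_type", all.x = TRUE)
  out[is.na(n_mutations), n_mutations := 0L]
  out[, qc_excluded := callable_sites < min_callable]
  out[, rate := fifelse(qc_excluded | callable_sites == 0, NA_real_,
                        n_mutations / callable_sites * 1e6)]
  setorder(out, cell_type)
  out[]
}

#' Single-cell mutational burden with genome extrapolation
#'
#' A mutation is attributed to a cell when that cell has at least one
#' alt-supporting read at the called site (consistent with genotyping);
#' each cell's denominator is the number of callable sites (for its cell
#' type) it covers with at least one read. The per-genome extrapolation
#' multiplies the per-bp rate by the haploid autosomal genome length.
#'
#' @param calls PASS call table (`chrom`, `pos`, `alt`,
#'   `target_cell_type`).
#' @param cell_counts per-cell count table.
#' @param callable_summary from [compute_callable_sites()] run with
#'   `cell_counts` so `per_cell` is available.
#' @param genome_size_bp haploid autosomal genome length in bp (see
#'   [autosomal_genome_size()]).
#' @return data.table `barcode`, `cell_type`, `n_mutations`,
#'   `covered_callable_sites`, `rate` (per Mb) and `genome_extrapolation`
#'   (mutations per haploid genome). Cells covering zero callable sites are
#'   excluded; their number is the `"n_excluded_cells"` attribute.
#' @export
per_cell_burden <- function(calls, cell_counts, callable_summary,
                            genome_size_bp) {
  check_that(!is.null(callable_summary$per_cell),
             "callable_summary must be computed with cell_counts")
  pc <- copy(callable_summary$per_cell)
  cl <- as.data.table(calls)
  cc <- as.data.table(cell_counts)
  if (nrow(cl) > 0) {
    ev <- cc[cl[, .(chrom, pos, alt, cell_type = target_cell_type)],
             on = c("chrom", "pos", "cell_type"), nomatch = NULL]
    ev[, alt_reads := as.matrix(.SD)[cbind(seq_len(.N), match(alt, BASES))],
       .SDcols = BASES]
    attributed <- ev[alt_reads >= 1,
                     .(n_mutations = .N), by = .(barcode, cell_type)]
  } else {
    attributed <- data.table(barcode = character(), cell_type = character(),
                             n_mutations = integer())
  }
  out <- merge(pc, attributed, by = c("barcode", "cell_type"), all.x = TRUE)
  out[is.na(n_mutations), n_mutations := 0L]
  n_excluded <- sum(out$covered_callable_sites == 0)
  out <- out[covered_callable_sites > 0]
  out[, rate := n_mutations / covered_callable_sites * 1e6]
  out[, genome_extrapolation :=
        n_mutations / covered_callable_sites * genome_size_bp]
  setorder(out, cell_type, barcode)
  structure(out[], n_excluded_cells = n_excluded)
}

#' Haploid autosomal genome length from a reference index
#'
#' Sums the lengths of autosomal sequences; accepts a reference list (from
#' [simulate_reference()]), a named character vector of sequences, a named
#' integer vector of lengths, or a `.fai` FASTA-index path.
#'
#' @param reference see description.
#' @return total autosomal length in bp.
#' @export
autosomal_genome_size <- function(reference) {
  lens <- if (is.character(reference) && length(reference) == 1 &&
              file.exists(reference)) {
    fai <- fread(reference, header = FALSE)
    setNames(as.numeric(fai[[2]]), fai[[1]])
  } else if (is.list(reference) && !is.null(reference$sequence)) {
    setNames(nchar(reference$sequence), reference$chrom)
  } else if (is.numeric(reference)) {
    reference
  } else {
    setNames(nchar(reference), names(reference))
  }
  sum(lens[is_autosome(names(lens))])
}
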