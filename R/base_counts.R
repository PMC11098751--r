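# Per-position, per-cell-type base counting and site-level pre-exclusions.
#
# All coordinates are 1-based inclusive; BED inputs are converted on read.
# Deletions and reference skips (splice N) contribute nothing; `N` bases in
# a read are tallied under `other` but never as allele evidence.

# parse a CIGAR string into (lengths, ops)
parse_cigar <- function(cig) {
  lens <- as.integer(regmatches(cig, gregexpr("\\d+", cig))[[1]])
  ops <- regmatches(cig, gregexpr("[MIDNSHP=X]", cig))[[1]]
  list(lens = lens, ops = ops)
}

# for one CIGAR: query indices and reference offsets of aligned bases
cigar_aligned <- function(cig) {
  pc <- parse_cigar(cig)
  q <- 0L; r <- 0L
  qidx <- integer(0); roff <- integer(0)
  for (i in seq_along(pc$ops)) {
    l <- pc$lens[i]
    switch(pc$ops[i],
           "M" = , "=" = , "X" = {
             qidx <- c(qidx, (q + 1L):(q + l))
             roff <- c(roff, r:(r + l - 1L))
             q <- q + l; r <- r + l
           },
           "I" = , "S" = { q <- q + l },
           "D" = , "N" = { r <- r + l },
           "H" = , "P" = NULL)
  }
  list(qidx = qidx, roff = roff)
}

#' Pile up reads into per-cell base observations
#'
#' Expands aligned read bases (CIGAR-aware) into per-site observations,
#' applies the base-quality cutoff, and keeps at most one base per read pair
#' and site (the mate with the higher base quality wins).
#'
#' @param reads read table with columns `qname`, `chrom`, `pos`, `cigar`,
#'   `seq`, `qual`, `barcode`, `cell_type`.
#' @param min_base_quality bases with phred quality below this are excluded.
#' @return data.table with one row per retained base: `chrom`, `pos`,
#'   `cell_type`, `barcode`, `base`.
#' @export
pileup_bases <- function(reads, min_base_quality = 30) {
  rd <- as.data.table(reads)
  if (nrow(rd) == 0) {
    return(data.table(chrom = character(), pos = integer(),
                      cell_type = character(), barcode = character(),
                      base = character()))
  }
  pieces <- vector("list", length(unique(rd$cigar)))
  i <- 0L
  for (cig in unique(rd$cigar)) {
    i <- i + 1L
    al <- cigar_aligned(cig)
    sub <- rd[cigar == cig]
    nb <- length(al$qidx)
    if (nb == 0) next
    idx <- rep(seq_len(nrow(sub)), each = nb)
    qi <- rep(al$qidx, nrow(sub))
    pieces[[i]] <- data.table(
      qname = sub$qname[idx], chrom = sub$chrom[idx],
      pos = sub$pos[idx] + rep(al$roff, nrow(sub)),
      cell_type = sub$cell_type[idx], barcode = sub$barcode[idx],
      base = substring(sub$seq[idx], qi, qi),
      bq = utf8ToInt(paste(substring(sub$qual[idx], qi, qi),
                           collapse = "")) - 33L)
  }
  obs <- rbindlist(pieces)
  obs <- obs[bq >= min_base_quality]
  # one base per read (pair) per site: keep the best-quality observation
  setorder(obs, chrom, pos, qname, -bq)
  obs <- obs[!duplicated(obs, by = c("chrom", "pos", "qname"))]
  obs[, .(chrom, pos, cell_type, barcode, base)]
}

#' Aggregate base observations into a per-cell count table
#'
#' @param bases from [pileup_bases()] (or an equivalent table).
#' @param reference a reference list (from [simulate_reference()]) or a
#'   named character vector of sequences, used to annotate the reference
#'   base.
#' @return per-cell count table: `chrom`, `pos`, `ref`, `cell_type`,
#'   `barcode`, `A`, `C`, `G`, `T`, `other`.
#' @export
bases_to_cell_counts <- function(bases, reference) {
  b <- as.data.table(bases)
  b[, base := fifelse(base %in% BASES, base, "other")]
  cc <- data.table::dcast(b[, .N, by = .(chrom, pos, cell_type, barcode,
                                         base)],
                          chrom + pos + cell_type + barcode ~ base,
                          value.var = "N", fill = 0L)
  for (col in c(BASES, "other")) if (!col %in% names(cc)) cc[, (col) := 0L]
  cc[, ref := reference_base(reference, chrom, pos)]
  setorder(cc, chrom, pos, cell_type, barcode)
  data.table::setcolorder(cc, c("chrom", "pos", "ref", "cell_type",
                                "barcode", BASES, "other"))
  cc[]
}

# look up reference bases for (chrom, pos) vectors
reference_base <- function(reference, chrom, pos) {
  seqs <- if (is.list(reference) && !is.null(reference$sequence)) {
    setNames(reference$sequence, reference$chrom)
  } else reference
  check_that(all(chrom %in% names(seqs)), "chromosome absent from reference")
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    check_that(all(pos[idx] >= 1 & pos[idx] <= nchar(seqs[[ch]])),
               "position outside reference bounds")
    out[idx] <- substring(seqs[[ch]], pos[idx], pos[idx])
  }
  out
}

#' Build the per-cell-type base-count matrix
#'
#' Aggregates a per-cell count table over cell types, tallying per-allele
#' supporting-cell counts, and applies the site inclusion rule: a site is
#' kept when its depth is at least `min_depth` in at least `min_cell_types`
#' cell types.
#'
#' @param cell_counts per-cell count table (`chrom`, `pos`, `ref`,
#'   `cell_type`, `barcode`, `A`, `C`, `G`, `T`, `other`).
#' @param min_depth,min_cell_types site inclusion rule (defaults 5 and 2).
#' @param apply_inclusion set `FALSE` to keep all covered sites.
#' @return a `base_count_matrix`: data.table keyed by site and cell type
#'   with per-base counts, `depth`, `n_cells`, and `n_cells_A` ..
#'   `n_cells_T` supporting-cell tallies.
#' @export
cell_counts_to_matrix <- function(cell_counts, min_depth = 5,
                                  min_cell_types = 2,
                                  apply_inclusion = TRUE) {
  cc <- as.data.table(cell_counts)
  mat <- cc[, c(lapply(.SD, sum),
                list(n_cells = .N,
                     n_cells_A = sum(A > 0), n_cells_C = sum(C > 0),
                     n_cells_G = sum(G > 0), n_cells_T = sum(T > 0))),
            by = .(chrom, pos, ref, cell_type),
            .SDcols = c(BASES, "other")]
  mat[, depth := A + C + G + T + other]
  if (apply_inclusion && nrow(mat) > 0) {
    ok <- mat[, .(n_celltypes_ge = sum(depth >= min_depth)),
              by = .(chrom, pos)][n_celltypes_ge >= min_cell_types]
    mat <- mat[ok[, .(chrom, pos)], on = c("chrom", "pos")]
  }
  setorder(mat, chrom, pos, cell_type)
  structure(mat[], class = c("base_count_matrix", class(mat)),
            min_depth = min_depth, min_cell_types = min_cell_types)
}

#' Base counts straight from a read table
#'
#' Convenience wrapper: pileup, per-cell aggregation and the site inclusion
#' rule in one step. Reads are expected to be already filtered and trimmed
#' (see [split_by_cell_type()] and [trim_terminal_qualities()]).
#'
#' @inheritParams pileup_bases
#' @inheritParams bases_to_cell_counts
#' @inheritParams cell_counts_to_matrix
#' @param region optional `c(chrom, start, end)` restriction (1-based
#'   inclusive).
#' @return list with `matrix` (a `base_count_matrix`) and `cell_counts`
#'   (the per-cell table).
#' @export
compute_base_counts <- function(reads, reference, region = NULL,
                                min_base_quality = 30, min_depth = 5,
                                min_cell_types = 2, apply_inclusion = TRUE) {
  bases <- pileup_bases(reads, min_base_quality = min_base_quality)
  if (!is.null(region)) {
    seqs <- if (is.list(reference)) setNames(reference$sequence,
                                             reference$chrom) else reference
    ch <- region[[1]]
    check_that(ch %in% names(seqs), "region outside reference")
    st <- as.integer(region[[2]]); en <- as.integer(region[[3]])
    check_that(st >= 1 && en <= nchar(seqs[[ch]]) && st <= en,
               "region outside reference")
    bases <- bases[chrom == ch & pos >= st & pos <= en]
  }
  if (nrow(bases) == 0) {
    cc <- data.table(chrom = character(), pos = integer(), ref = character(),
                     cell_type = character(), barcode = character(),
                     A = integer(), C = integer(), G = integer(),
                     T = integer(), other = integer())
  } else {
    cc <- bases_to_cell_counts(bases, reference)
  }
  list(matrix = cell_counts_to_matrix(cc, min_depth = min_depth,
                                      min_cell_types = min_cell_types,
                                      apply_inclusion = apply_inclusion),
       cell_counts = cc)
}

#' Read site-exclusion inputs
#'
#' `read_editing_sites()` reads a BED file (0-based half-open) of RNA
#' editing sites and returns 1-based positions; `read_common_snps()` reads a
#' TSV with columns `chrom pos ref alt af` and keeps polymorphisms whose
#' population allele frequency is strictly greater than `af_threshold`.
#'
#' @param path input path.
#' @param af_threshold allele-frequency cutoff (`> 0.01` removed by
#'   default).
#' @return data.table with columns `chrom`, `pos` (1-based).
#' @export
read_editing_sites <- function(path) {
  bed <- fread(path, header = FALSE)
  check_that(ncol(bed) >= 3, "BED needs at least 3 columns")
  setnames(bed, 1:3, c("chrom", "start", "end"))
  bed[, .(pos = (start + 1L):end), by = .(chrom, start, end)][
    , .(chrom, pos)]
}

#' @rdname read_editing_sites
#' @export
read_common_snps <- function(path, af_threshold = 0.01) {
  snp <- fread(path, header = TRUE)
  need <- c("chrom", "pos", "af")
  bad <- !complete.cases(snp[, intersect(need, names(snp)), with = FALSE])
  if (any(bad)) {
    warning(sum(bad), " malformed SNP records skipped")
    snp <- snp[!bad]
  }
  check_that(all(need %in% names(snp)), "SNP table needs chrom, pos, af")
  snp[af > af_threshold, .(chrom, pos)]
}

#' Remove excluded sites from a base-count matrix
#'
#' Drops sites overlapping RNA-editing positions or common polymorphisms;
#' removal counts per reason are attached as the `"removed"` attribute.
#'
#' @param matrix a `base_count_matrix`.
#' @param exclusions list with elements `editing_sites` and/or
#'   `common_snps`, each a data.table of `chrom`, `pos`.
#' @return the filtered `base_count_matrix`.
#' @export
apply_site_exclusions <- function(matrix, exclusions) {
  mat <- as.data.table(matrix)
  removed <- c(editing_sites = 0L, common_snps = 0L)
  for (nm in c("editing_sites", "common_snps")) {
    ex <- exclusions[[nm]]
    if (is.null(ex) || nrow(ex) == 0) next
    ex <- unique(as.data.table(ex)[, .(chrom, pos)])
    before <- data.table::uniqueN(mat, by = c("chrom", "pos"))
    mat <- mat[!ex, on = c("chrom", "pos")]
    removed[nm] <- before - data.table::uniqueN(mat, by = c("chrom", "pos"))
  }
  structure(mat[], class = c("base_count_matrix", class(mat)),
            min_depth = attr(matrix, "min_depth"),
            min_cell_types = attr(matrix, "min_cell_types"),
            removed = removed)
}

#' Write / read a base-count matrix as gzipped TSV
#'
#' @param matrix a `base_count_matrix`.
#' @param path output path (".tsv.gz" recommended).
#' @return `path` invisibly; `read_base_count_matrix()` returns the matrix.
#' @export
write_base_count_matrix <- function(matrix, path) {
  fwrite(as.data.table(matrix), path, sep = "\t", compress = "gzip")
  invisible(path)
}

#' @rdname write_base_count_matrix
#' @export
read_base_count_matrix <- function(path) {
  mat <- fread(path, sep = "\t")
  structure(mat, class = c("base_count_matrix", class(mat)))
}
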