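# Benchmarking single-cell call sets against a DNA truth set within
# jointly evaluable regions: category assignment (TP / TP with low DNA
# support / FN / FP), the printed precision / sensitivity / F1 formulas,
# and bootstrap confidence intervals.

#' Define the jointly evaluable region
#'
#' Positions satisfying all four depth criteria — DNA tumor, DNA matched
#' normal, single-cell malignant cell type(s), and at least
#' `min_other_celltypes` additional cell types at `sc_other_depth` — are
#' merged into intervals.
#'
#' @param dna_tumor_cov,dna_normal_cov data.tables `chrom`, `pos`, `depth`.
#' @param sc_cov_by_celltype data.table `chrom`, `pos`, `cell_type`,
#'   `depth`.
#' @param malignant_types character vector of malignant cell-type labels.
#' @param dna_tumor_depth,dna_normal_depth,sc_malignant_depth,sc_other_depth
#'   depth thresholds (50 / 10 / 10 / 5).
#' @param min_other_celltypes additional cell types required at
#'   `sc_other_depth` (default 2).
#' @return a `GRanges` of merged evaluable intervals (possibly empty, with
#'   a warning).
#' @export
define_evaluable_region <- function(dna_tumor_cov, dna_normal_cov,
                                    sc_cov_by_celltype, malignant_types,
                                    dna_tumor_depth = 50,
                                    dna_normal_depth = 10,
                                    sc_malignant_depth = 10,
                                    sc_other_depth = 5,
                                    min_other_celltypes = 2) {
  tum <- as.data.table(dna_tumor_cov)[depth >= dna_tumor_depth,
                                      .(chrom, pos)]
  nor <- as.data.table(dna_normal_cov)[depth >= dna_normal_depth,
                                       .(chrom, pos)]
  sc <- as.data.table(sc_cov_by_celltype)
  mal <- sc[cell_type %in% malignant_types & depth >= sc_malignant_depth,
            .(chrom, pos)]
  oth <- sc[!cell_type %in% malignant_types & depth >= sc_other_depth,
            .(n = data.table::uniqueN(cell_type)), by = .(chrom, pos)][
              n >= min_other_celltypes, .(chrom, pos)]
  ok <- Reduce(function(a, b) a[b, on = c("chrom", "pos"), nomatch = NULL],
               list(unique(tum), unique(nor), unique(mal), unique(oth)))
  if (nrow(ok) == 0) {
    warning("evaluable region is empty")
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(ok$chrom, IRanges::IRanges(ok$pos, ok$pos))
  GenomicRanges::reduce(sort(gr))
}

# TRUE for (chrom, pos) rows inside the region
in_region <- function(chrom, pos, region) {
  if (length(region) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, region) > 0
}

#' Restrict a DNA truth set to variants with single-cell evidence
#'
#' Keeps DNA-called variants with at least `min_reads` alt-supporting
#' reads in malignant cells (base-quality filtering is inherited from the
#' counting stage).
#'
#' @param dna_calls data.table `chrom`, `pos`, `ref`, `alt`.
#' @param sc_cell_counts per-cell count table.
#' @param malignant_types malignant cell-type labels.
#' @param min_reads minimum supporting reads (default 1).
#' @return the filtered truth table.
#' @export
filter_dna_truth <- function(dna_calls, sc_cell_counts, malignant_types,
                             min_reads = 1) {
  dc <- as.data.table(dna_calls)
  cc <- as.data.table(sc_cell_counts)[cell_type %in% malignant_types]
  agg <- cc[, lapply(.SD, sum), by = .(chrom, pos), .SDcols = BASES]
  ev <- agg[dc, on = c("chrom", "pos")]
  for (b in BASES) ev[is.na(get(b)), (b) := 0L]
  ev[, alt_reads := as.matrix(.SD)[cbind(seq_len(.N), match(alt, BASES))],
     .SDcols = BASES]
  ev[alt_reads >= min_reads, .(chrom, pos, ref, alt)]
}

#' Categorize benchmarked variants
#'
#' Within the evaluable region: TP = called in both single-cell and DNA;
#' TP_low_support = called in single-cell only, with at least one DNA alt
#' read (base quality already filtered into `dna_counts`) and no reads for
#' any other alternative allele; FP = called in single-cell only with zero
#' DNA alt reads, or with alt support in the matched normal DNA (germline
#' contamination), or with conflicting other-allele DNA reads; FN = called
#' in DNA only.
#'
#' @param sc_calls single-cell calls (`chrom`, `pos`, `ref`, `alt`).
#' @param dna_calls DNA truth calls (same columns; pre-filtered with
#'   [filter_dna_truth()]).
#' @param dna_counts per-site DNA allele counts: `chrom`, `pos`, `A`, `C`,
#'   `G`, `T` (bases counted at quality >= 30).
#' @param normal_counts matched-normal allele counts, same layout.
#' @param region a `GRanges` from [define_evaluable_region()].
#' @return a `benchmark_categories` list: `counts` (named TP,
#'   TP_low_support, FN, FP), `labels` (per-variant data.table with
#'   `category` and evidence), `n_outside_region`.
#' @export
categorize_calls <- function(sc_calls, dna_calls, dna_counts,
                             normal_counts, region) {
  sc <- unique(as.data.table(sc_calls)[, .(chrom, pos, ref, alt)])
  dna <- unique(as.data.table(dna_calls)[, .(chrom, pos, ref, alt)])
  n_outside <- sum(!in_region(sc$chrom, sc$pos, region)) +
    sum(!in_region(dna$chrom, dna$pos, region))
  sc <- sc[in_region(chrom, pos, region)]
  dna <- dna[in_region(chrom, pos, region)]

  allele_counts <- function(tbl, chrom_v, pos_v, alt_v, ref_v) {
    tb <- as.data.table(tbl)
    q <- data.table(chrom = chrom_v, pos = pos_v)
    m <- tb[q, on = c("chrom", "pos")]
    for (b in BASES) m[is.na(get(b)), (b) := 0L]
    cnt <- as.matrix(m[, BASES, with = FALSE])
    alt_n <- cnt[cbind(seq_len(nrow(m)), match(alt_v, BASES))]
    ref_n <- cnt[cbind(seq_len(nrow(m)), match(ref_v, BASES))]
    other_alt_n <- rowSums(cnt) - alt_n - ref_n
    list(alt = alt_n, other_alt = other_alt_n)
  }

  sc[, in_dna := paste(chrom, pos, alt) %in% paste(dna$chrom, dna$pos,
                                                   dna$alt)]
  dna[, in_sc := paste(chrom, pos, alt) %in% paste(sc$chrom, sc$pos,
                                                   sc$alt)]
  if (nrow(sc) > 0) {
    d_ev <- allele_counts(dna_counts, sc$chrom, sc$pos, sc$alt, sc$ref)
    n_ev <- allele_counts(normal_counts, sc$chrom, sc$pos, sc$alt, sc$ref)
    sc[, `:=`(dna_alt = d_ev$alt, dna_other_alt = d_ev$other_alt,
              normal_alt = n_ev$alt)]
    sc[, category := fifelse(
      in_dna, "TP",
      fifelse(normal_alt > 0, "FP",
              fifelse(dna_alt >= 1 & dna_other_alt == 0,
                      "TP_low_support", "FP")))]
  } else {
    sc[, `:=`(dna_alt = integer(), dna_other_alt = integer(),
              normal_alt = integer(), category = character())]
  }
  fn <- dna[in_sc == FALSE]
  labels <- rbind(
    sc[, .(chrom, pos, ref, alt, category)],
    if (nrow(fn) > 0) fn[, .(chrom, pos, ref, alt, category = "FN")])
  counts <- c(TP = sum(labels$category == "TP"),
              TP_low_support = sum(labels$category == "TP_low_support"),
              FN = sum(labels$category == "FN"),
              FP = sum(labels$category == "FP"))
  structure(list(counts = counts, labels = labels[],
                 n_outside_region = n_outside),
            class = "benchmark_categories")
}

#' Precision, sensitivity and F1 from benchmark categories
#'
#' Uses the printed formulas: precision counts TP and TP-with-low-support
#' in its numerator (`TP_prec`), sensitivity counts TP only (`TP_sens`),
#' and `F1 = 2 TP_prec / (2 TP_prec + FP + FN)`. Division by zero yields
#' `NA` (undefined), never 0.
#'
#' @param categories a `benchmark_categories` (or a named vector with
#'   `TP`, `TP_low_support`, `FN`, `FP`).
#' @return list with `precision`, `sensitivity`, `f1` and the counts.
#' @export
compute_metrics <- function(categories) {
  cnt <- if (inherits(categories, "benchmark_categories")) {
    categories$counts
  } else categories
  tp_prec <- cnt[["TP"]] + cnt[["TP_low_support"]]
  tp_sens <- cnt[["TP"]]
  fp <- cnt[["FP"]]; fn <- cnt[["FN"]]
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(precision = safe_div(tp_prec, tp_prec + fp),
       sensitivity = safe_div(tp_sens, tp_sens + fn),
       f1 = safe_div(2 * tp_prec, 2 * tp_prec + fp + fn),
       counts = cnt)
}

#' Bootstrap confidence intervals for the benchmark metrics
#'
#' Variants are resampled uniformly with replacement; metrics are
#' recomputed per resample and summarized by their mean and percentile 95%
#' interval. Resamples with an undefined metric are recorded as missing and
#' excluded from that metric's interval.
#'
#' @param categories a `benchmark_categories` with per-variant `labels`.
#' @param n_resamples number of bootstrap resamples (default 50).
#' @param seed integer seed (reproducible).
#' @return list with per-metric `point`, `mean`, `lower`, `upper`,
#'   `n_defined`, plus `n_resamples`.
#' @export
bootstrap_metrics <- function(categories, n_resamples = 50, seed = 1) {
  labels <- categories$labels
  check_that(nrow(labels) > 0, "no variants to resample")
  point <- compute_metrics(categories)
  draws <- with_seed(seed, {
    replicate(n_resamples, {
      cat_r <- labels$category[sample.int(nrow(labels), replace = TRUE)]
      cnt <- c(TP = sum(cat_r == "TP"),
               TP_low_support = sum(cat_r == "TP_low_support"),
               FN = sum(cat_r == "FN"), FP = sum(cat_r == "FP"))
      m <- compute_metrics(cnt)
      c(precision = m$precision, sensitivity = m$sensitivity, f1 = m$f1)
    })
  })
  summarize <- function(metric) {
    x <- draws[metric, ]
    ok <- !is.na(x)
    list(point = point[[metric]],
         mean = if (any(ok)) mean(x[ok]) else NA_real_,
         lower = if (any(ok)) unname(quantile(x[ok], 0.025)) else NA_real_,
         upper = if (any(ok)) unname(quantile(x[ok], 0.975)) else NA_real_,
         n_defined = sum(ok))
  }
  list(precision = summarize("precision"),
       sensitivity = summarize("sensitivity"),
       f1 = summarize("f1"),
       n_resamples = n_resamples)
}
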