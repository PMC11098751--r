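# Candidate somatic-SNV detection and the hard-filter cascade.
#
# Flags are conjunctive: a candidate is PASS iff it carries no flag. Every
# filter only adds flags, so the PASS set is independent of the order in
# which filters run.

FLAG_NAMES <- c("Multi_allelic", "Min_support", "Other_celltype_significant",
                "PON", "Homopolymer", "Clustered", "Editing_site", "SNP")

add_flag <- function(flags, which, flag_name) {
  flags[which] <- ifelse(nzchar(flags[which]),
                         paste(flags[which], flag_name, sep = ";"),
                         flag_name)
  flags
}

has_flag <- function(flags, flag_name) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) flag_name %in% f, logical(1))
}

# most-supported non-reference base per matrix row, with deterministic
# tie-breaking: read count, then supporting-cell count, then alphabetical
best_alt <- function(mat) {
  counts <- as.matrix(mat[, BASES, with = FALSE])
  cells <- as.matrix(mat[, paste0("n_cells_", BASES), with = FALSE])
  ridx <- match(mat$ref, BASES)
  counts[cbind(seq_len(nrow(mat)), ridx)] <- -1L
  # order of BASES is alphabetical; max.col("first") honours the tie-break
  # after ranking by count then cells
  score <- counts * (max(cells, 1L) + 1L) + cells
  score[counts < 0] <- -1
  j <- max.col(score, ties.method = "first")
  list(alt = BASES[j],
       alt_count = counts[cbind(seq_len(nrow(mat)), j)],
       n_cells_alt = cells[cbind(seq_len(nrow(mat)), j)])
}

#' Detect candidate somatic SNVs per cell type
#'
#' For each site and cell type the most-supported non-reference base is
#' tested against the beta-binomial background model; a candidate is
#' emitted when the one-sided tail p-value is below `alpha`. Sites where
#' two or more distinct non-reference bases each reach `min_reads` support
#' in the same cell type are flagged `Multi_allelic`.
#'
#' @param matrix a `base_count_matrix`.
#' @param model a `bb_model`.
#' @param alpha per-site significance threshold (default 0.001).
#' @param min_reads support threshold used for the multi-allelic flag.
#' @return data.table of candidates: site, `target_cell_type`, `alt`,
#'   `depth`, `alt_count`, `n_cells_alt`, `p_value`, `flags`.
#' @export
detect_candidates <- function(matrix, model, alpha = 0.001, min_reads = 3) {
  mat <- as.data.table(matrix)
  empty <- data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), target_cell_type = character(),
                      depth = integer(), alt_count = integer(),
                      n_cells_alt = integer(), p_value = numeric(),
                      flags = character())
  if (nrow(mat) == 0) return(empty)
  ba <- best_alt(mat)
  cand <- mat[, .(chrom, pos, ref, cell_type, depth)]
  cand[, `:=`(alt = ba$alt, alt_count = ba$alt_count,
              n_cells_alt = ba$n_cells_alt)]
  cand <- cand[alt_count > 0 & depth >= 1]
  if (nrow(cand) == 0) return(empty)
  cand[, p_value := bb_tail_pvalue(alt_count, depth, model)]
  cand <- cand[p_value < alpha]
  if (nrow(cand) == 0) return(empty)
  # multi-allelic: >= 2 distinct non-reference bases each with min_reads
  key <- mat[cand, on = c("chrom", "pos", "cell_type")]
  nonref_ge <- sapply(BASES, function(b)
    key[[b]] >= min_reads & key$ref != b)
  if (is.null(dim(nonref_ge))) nonref_ge <- matrix(nonref_ge, nrow = 1)
  multi <- rowSums(nonref_ge) >= 2
  cand[, flags := ""]
  cand[, flags := add_flag(flags, multi, "Multi_allelic")]
  setnames(cand, "cell_type", "target_cell_type")
  setorder(cand, chrom, pos, target_cell_type)
  cand[]
}

#' Cell-type-exclusivity filter
#'
#' A candidate is flagged `Other_celltype_significant` when the
#' beta-binomial test on the candidate allele is significant in any other
#' cell type individually, or on the base counts aggregated across all
#' other cell types. Germline variants (present in every cell type) are
#' removed by this rule. With a single cell type present, the test is
#' vacuous and the candidate is retained with a logged caveat.
#'
#' @param candidates from [detect_candidates()].
#' @param matrix the `base_count_matrix` the candidates came from.
#' @param model a `bb_model`.
#' @param alpha significance threshold (default 0.001).
#' @return candidates with updated `flags` (and per-candidate
#'   `other_max_p` evidence columns).
#' @export
exclusivity_filter <- function(candidates, matrix, model, alpha = 0.001) {
  cand <- copy(as.data.table(candidates))
  if (nrow(cand) == 0) return(cand)
  mat <- as.data.table(matrix)
  if (data.table::uniqueN(mat$cell_type) < 2) {
    message("only one cell type present: exclusivity test is vacuous")
    return(cand)
  }
  flagged <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    others <- mat[chrom == cand$chrom[i] & pos == cand$pos[i] &
                    cell_type != cand$target_cell_type[i]]
    if (nrow(others) == 0) next
    k_other <- others[[cand$alt[i]]]
    n_other <- others$depth
    keep <- n_other >= 1
    sig_each <- any(bb_tail_pvalue(k_other[keep], n_other[keep],
                                   model) < alpha)
    sig_agg <- sum(n_other) >= 1 &&
      bb_tail_pvalue(sum(k_other), sum(n_other), model) < alpha
    flagged[i] <- sig_each || sig_agg
  }
  cand[, flags := add_flag(flags, flagged, "Other_celltype_significant")]
  cand[]
}

#' Minimum-support filter
#'
#' A call requires at least `min_reads` alt reads from at least `min_cells`
#' distinct cells of the target cell type, and a depth of at least
#' `min_depth` in that cell type.
#'
#' @param candidates candidate table.
#' @param min_reads,min_cells,min_depth support thresholds (3 / 2 / 5).
#' @return candidates with updated `flags`.
#' @export
min_support_filter <- function(candidates, min_reads = 3, min_cells = 2,
                               min_depth = 5) {
  cand <- copy(as.data.table(candidates))
  if (nrow(cand) == 0) return(cand)
  fail <- !(cand$alt_count >= min_reads & cand$n_cells_alt >= min_cells &
              cand$depth >= min_depth)
  cand[, flags := add_flag(flags, fail, "Min_support")]
  cand[]
}

#' Locate mononucleotide tracts in a reference sequence
#'
#' @param reference reference list or named character vector of sequences.
#' @param min_tract_len minimum run length reported.
#' @return data.table `chrom`, `start`, `end`, `base`.
#' @export
find_homopolymers <- function(reference, min_tract_len = 4) {
  seqs <- if (is.list(reference) && !is.null(reference$sequence)) {
    setNames(reference$sequence, reference$chrom)
  } else reference
  out <- lapply(names(seqs), function(ch) {
    r <- rle(strsplit(seqs[[ch]], "", fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_tract_len
    data.table(chrom = ch, start = ends[keep] - r$lengths[keep] + 1L,
               end = ends[keep], base = r$values[keep])
  })
  rbindlist(out)
}

#' Homopolymer-proximity filter
#'
#' Candidates mapping to, or within `proximity` bp of, a mononucleotide
#' tract of length at least `min_tract_len` are flagged `Homopolymer`.
#'
#' @param candidates candidate table.
#' @param reference reference list or named character vector.
#' @param proximity flag window around tracts, in bp (default 4).
#' @param min_tract_len minimum tract length (default 4).
#' @return candidates with updated `flags`.
#' @export
homopolymer_filter <- function(candidates, reference, proximity = 4,
                               min_tract_len = 4) {
  cand <- copy(as.data.table(candidates))
  if (nrow(cand) == 0) return(cand)
  seqs <- if (is.list(reference) && !is.null(reference$sequence)) {
    setNames(reference$sequence, reference$chrom)
  } else reference
  for (ch in unique(cand$chrom)) {
    check_that(ch %in% names(seqs), "candidate chromosome not in reference")
    check_that(all(cand[chrom == ch, pos] <= nchar(seqs[[ch]])),
               "candidate position beyond reference end")
  }
  tracts <- find_homopolymers(seqs, min_tract_len = min_tract_len)
  flagged <- logical(nrow(cand))
  if (nrow(tracts) > 0) {
    for (i in seq_len(nrow(cand))) {
      t <- tracts[chrom == cand$chrom[i]]
      flagged[i] <- nrow(t) > 0 &&
        any(cand$pos[i] >= t$start - proximity &
              cand$pos[i] <= t$end + proximity)
    }
  }
  cand[, flags := add_flag(flags, flagged, "Homopolymer")]
  cand[]
}

#' Doublet-substitution allow list
#'
#' Canonical doublet classes exempt from the clustered-variant filter:
#' adjacent substitution pairs known to arise as single events from
#' specific mutational processes. The default covers the unambiguous
#' process-specific doublets (ultraviolet-light CC>TT and
#' tobacco/aldehyde-associated CC>AA); users analysing, for example,
#' mismatch-repair-deficient samples can extend it with further classes.
#'
#' @param extra additional classes as `"RR>AA"` strings (any orientation).
#' @return character vector of canonical doublet classes.
#' @export
dbs_allowlist <- function(extra = character()) {
  base_classes <- c("CC>TT", "CC>AA")
  all_cl <- c(base_classes, extra)
  parts <- strsplit(all_cl, ">", fixed = TRUE)
  unique(canonical_doublet(vapply(parts, `[`, character(1), 1),
                           vapply(parts, `[`, character(1), 2)))
}

#' Clustered-variant filter with doublet exemption
#'
#' Candidate pairs less than `window` bp apart (same chromosome and target
#' cell type) are flagged `Clustered`, unless the pair is adjacent
#' (distance 1), its canonical doublet class is in `allowlist`, and — when
#' per-cell evidence is supplied — the two variants share at least one
#' alt-supporting cell barcode (a true doublet arises on one haplotype in
#' the same cells).
#'
#' @param candidates candidate table.
#' @param allowlist from [dbs_allowlist()].
#' @param window pairs closer than this many bp are clustered (default 5).
#' @param cell_counts optional per-cell count table for the phased-support
#'   check.
#' @return candidates with updated `flags`.
#' @export
clustered_filter <- function(candidates, allowlist = dbs_allowlist(),
                             window = 5, cell_counts = NULL) {
  cand <- copy(as.data.table(candidates))
  if (nrow(cand) < 2) {
    if (nrow(cand) == 1 && !"flags" %in% names(cand)) cand[, flags := ""]
    return(cand)
  }
  cand[, site_id := seq_len(.N)]
  flagged <- logical(nrow(cand))
  groups <- split(seq_len(nrow(cand)),
                  paste(cand$chrom, cand$target_cell_type))
  for (g in groups) {
    if (length(g) < 2) next
    g <- g[order(cand$pos[g])]
    for (a in seq_along(g)) {
      for (b in seq_along(g)) {
        if (b <= a) next
        i <- g[a]; j <- g[b]
        d <- abs(cand$pos[j] - cand$pos[i])
        if (d == 0 || d >= window) next
        exempt <- FALSE
        if (d == 1) {
          lo <- if (cand$pos[i] < cand$pos[j]) i else j
          hi <- if (cand$pos[i] < cand$pos[j]) j else i
          cl <- canonical_doublet(paste0(cand$ref[lo], cand$ref[hi]),
                                  paste0(cand$alt[lo], cand$alt[hi]))
          if (cl %in% allowlist) {
            exempt <- TRUE
            if (!is.null(cell_counts)) {
              cc <- as.data.table(cell_counts)
              bcs <- function(k) cc[chrom == cand$chrom[k] &
                                      pos == cand$pos[k] &
                                      cell_type == cand$target_cell_type[k]][
                                        get(cand$alt[k]) > 0, barcode]
              exempt <- length(intersect(bcs(lo), bcs(hi))) >= 1
            }
          }
        }
        if (!exempt) {
          flagged[i] <- TRUE
          flagged[j] <- TRUE
        }
      }
    }
  }
  cand[, flags := add_flag(flags, flagged, "Clustered")]
  cand[, site_id := NULL]
  cand[]
}

#' Build a panel of normals
#'
#' Aggregates each unrelated non-neoplastic sample's counts across its cell
#' types per site, tests the most-supported non-reference allele against
#' the background model, and stores every site significant in at least one
#' sample with the number of samples in which it recurs and the maximum
#' observed alt fraction.
#'
#' @param normal_matrices list of `base_count_matrix` objects, one per
#'   unrelated sample.
#' @param model a `bb_model`.
#' @param alpha significance threshold.
#' @param min_samples recurrence threshold used downstream; a PON built
#'   from a single sample disables recurrence filtering with a warning.
#' @return a `panel_of_normals`: data.table `chrom`, `pos`, `ref`,
#'   `n_samples`, `max_alt_fraction`.
#' @export
build_pon <- function(normal_matrices, model, alpha = 0.001,
                      min_samples = 2) {
  check_that(length(normal_matrices) >= 1, "at least one normal required")
  if (length(normal_matrices) == 1) {
    warning("single normal sample: recurrence filtering is disabled")
  }
  per_sample <- lapply(normal_matrices, function(m) {
    mat <- as.data.table(m)
    agg <- mat[, c(lapply(.SD, sum),
                   list(n_cells_A = sum(n_cells_A), n_cells_C = sum(n_cells_C),
                        n_cells_G = sum(n_cells_G), n_cells_T = sum(n_cells_T))),
               by = .(chrom, pos, ref), .SDcols = c(BASES, "other")]
    agg[, depth := A + C + G + T + other]
    agg <- agg[depth >= 1]
    ba <- best_alt(agg)
    agg[, `:=`(alt_count = ba$alt_count)]
    agg <- agg[alt_count > 0]
    agg[, pval := bb_tail_pvalue(alt_count, depth, model)]
    agg[pval < alpha, .(chrom, pos, ref, alt_frac = alt_count / depth)]
  })
  sig <- rbindlist(per_sample)
  if (nrow(sig) == 0) {
    pon <- data.table(chrom = character(), pos = integer(),
                      ref = character(), n_samples = integer(),
                      max_alt_fraction = numeric())
  } else {
    pon <- sig[, .(n_samples = .N, max_alt_fraction = max(alt_frac)),
               by = .(chrom, pos, ref)]
  }
  structure(pon[], class = c("panel_of_normals", class(pon)),
            n_panel_samples = length(normal_matrices),
            min_samples = min_samples)
}

#' Flag candidates recurrent in the panel of normals
#'
#' @param candidates candidate table.
#' @param pon from [build_pon()].
#' @param min_samples candidates at sites significant in at least this many
#'   unrelated normals are flagged `PON`.
#' @return candidates with updated `flags`.
#' @export
pon_filter <- function(candidates, pon, min_samples = 2) {
  cand <- copy(as.data.table(candidates))
  if (nrow(cand) == 0 || is.null(pon) || nrow(pon) == 0) return(cand)
  if (isTRUE(attr(pon, "n_panel_samples") == 1)) return(cand)
  rec <- unique(as.data.table(pon)[n_samples >= min_samples,
                                   .(chrom, pos)])
  hit <- rec[cand, on = c("chrom", "pos"), which = TRUE]
  flagged <- !is.na(hit)
  cand[, flags := add_flag(flags, flagged, "PON")]
  cand[]
}

#' Flag candidates at excluded sites
#'
#' Adds `Editing_site` / `SNP` flags for candidates overlapping the
#' exclusion lists (used when exclusions were not already removed at the
#' base-count stage).
#'
#' @param candidates candidate table.
#' @param exclusions list with `editing_sites` / `common_snps` tables.
#' @return candidates with updated `flags`.
#' @export
exclusion_site_filter <- function(candidates, exclusions) {
  cand <- copy(as.data.table(candidates))
  if (nrow(cand) == 0) return(cand)
  flag_for <- c(editing_sites = "Editing_site", common_snps = "SNP")
  for (nm in names(flag_for)) {
    ex <- exclusions[[nm]]
    if (is.null(ex) || nrow(ex) == 0) next
    ex <- unique(as.data.table(ex)[, .(chrom, pos)])
    hit <- ex[cand, on = c("chrom", "pos"), which = TRUE]
    cand[, flags := add_flag(flags, !is.na(hit), flag_for[[nm]])]
  }
  cand[]
}

#' Call somatic mutations: candidate detection plus the full filter cascade
#'
#' Runs [detect_candidates()], then every filter whose inputs are
#' available: [exclusivity_filter()], [min_support_filter()],
#' [homopolymer_filter()], [clustered_filter()], [pon_filter()] and
#' [exclusion_site_filter()]. Flags are conjunctive, so the PASS set does
#' not depend on filter order. The full flagged candidate set is retained
#' as an audit trail.
#'
#' @param matrix a `base_count_matrix`.
#' @param model a `bb_model`.
#' @param reference reference (for the homopolymer filter); NULL skips it.
#' @param exclusions exclusion lists; NULL skips site flagging.
#' @param pon a `panel_of_normals`; NULL skips the PON filter.
#' @param cell_counts per-cell count table (doublet phasing evidence).
#' @param config a [pipeline_config()] (thresholds); defaults used if NULL.
#' @return list with `pass` (PASS calls) and `calls` (all candidates with
#'   flags; `filter` column is `"PASS"` or the `;`-joined flag names).
#' @export
call_mutations <- function(matrix, model, reference = NULL,
                           exclusions = NULL, pon = NULL,
                           cell_counts = NULL, config = pipeline_config()) {
  cand <- detect_candidates(matrix, model, alpha = config$alpha,
                            min_reads = config$min_reads)
  cand <- exclusivity_filter(cand, matrix, model, alpha = config$alpha)
  cand <- min_support_filter(cand, min_reads = config$min_reads,
                             min_cells = config$min_cells,
                             min_depth = config$min_depth)
  if (!is.null(reference)) {
    cand <- homopolymer_filter(cand, reference,
                               proximity = config$homopolymer_proximity,
                               min_tract_len = config$min_tract_len)
  }
  cand <- clustered_filter(cand, allowlist = config$dbs_allowlist,
                           window = config$cluster_window,
                           cell_counts = cell_counts)
  if (!is.null(pon)) {
    cand <- pon_filter(cand, pon, min_samples = config$pon_min_samples)
  }
  if (!is.null(exclusions)) {
    cand <- exclusion_site_filter(cand, exclusions)
  }
  cand[, filter := fifelse(nzchar(flags), flags, "PASS")]
  list(pass = cand[filter == "PASS"], calls = cand[])
}

#' Write calls as VCF 4.2 (plus a flat TSV mirror)
#'
#' The FILTER column carries PASS or the flag names; INFO records the
#' target cell type, depth, alt count, supporting cells and p-value.
#'
#' @param calls candidate table with `filter` column.
#' @param path output `.vcf` path; a `.tsv` mirror is written alongside.
#' @param sample_id sample label written in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = "sample") {
  cl <- as.data.table(calls)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=scmut %s",
                   as.character(utils::packageVersion("scmut"))),
           sprintf("##sample=%s", sample_id),
           "##INFO=<ID=CT,Number=1,Type=String,Description=\"Target cell type\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth in target cell type\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt read count in target cell type\">",
           "##INFO=<ID=CC,Number=1,Type=Integer,Description=\"Alt-supporting cells in target cell type\">",
           "##INFO=<ID=PV,Number=1,Type=Float,Description=\"Beta-binomial tail p-value\">",
           paste0("##FILTER=<ID=", FLAG_NAMES, ",Description=\"",
                  FLAG_NAMES, " filter\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(cl) == 0) character(0) else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tCT=%s;DP=%d;AC=%d;CC=%d;PV=%.3g",
    cl$chrom, cl$pos, cl$ref, cl$alt, cl$filter, cl$target_cell_type,
    cl$depth, cl$alt_count, cl$n_cells_alt, cl$p_value)
  writeLines(c(hdr, body), path)
  fwrite(cl, sub("\\.vcf$", ".tsv", path), sep = "\t")
  invisible(path)
}

#' Write / read a panel of normals as TSV
#'
#' @param pon a `panel_of_normals`.
#' @param path TSV path.
#' @return `path` invisibly; the reader returns a `panel_of_normals`.
#' @export
write_pon <- function(pon, path) {
  dt <- as.data.table(pon)
  writeLines(c(sprintf("#n_panel_samples=%d",
                       attr(pon, "n_panel_samples") %||% NA_integer_),
               paste(names(dt), collapse = "\t")), path)
  fwrite(dt, path, sep = "\t", append = TRUE)
  invisible(path)
}

#' @rdname write_pon
#' @export
read_pon <- function(path) {
  first <- readLines(path, n = 1)
  n_samples <- as.integer(sub("#n_panel_samples=", "", first, fixed = TRUE))
  pon <- fread(path, sep = "\t", skip = 1)
  structure(pon, class = c("panel_of_normals", class(pon)),
            n_panel_samples = n_samples, min_samples = 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
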