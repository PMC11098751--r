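# 96-class trinucleotide mutational spectra and genome-background
# renormalization.
#
# Classes follow the pyrimidine-strand convention: a substitution whose
# reference base is a purine is reverse-complemented together with its
# flanking context. The class layout is substitution-major
# (C>A ... T>G), then 5' base, then 3' base — the conventional ordering
# consumed by signature-fitting packages.

#' Build a raw 96-class mutational spectrum
#'
#' @param calls SNV table with `chrom`, `pos`, `ref`, `alt`.
#' @param reference reference list or named character vector of sequences.
#' @return a `spectrum96`: data.table `class96`, `context`, `count`,
#'   `raw_fraction`; attribute `normalization` is `"raw"`.
#' @export
build_spectrum <- function(calls, reference) {
  cl <- as.data.table(calls)
  template <- data.table(class96 = sbs96_classes())
  template[, context := paste0(substr(class96, 1, 1), substr(class96, 3, 3),
                               substr(class96, 7, 7))]
  if (nrow(cl) > 0) {
    seqs <- if (is.list(reference) && !is.null(reference$sequence)) {
      setNames(reference$sequence, reference$chrom)
    } else reference
    ref_obs <- reference_base(seqs, cl$chrom, cl$pos)
    if (any(ref_obs != cl$ref)) {
      stop("reference base mismatch between calls and FASTA at ",
           sum(ref_obs != cl$ref), " site(s)", call. = FALSE)
    }
    check_that(all(cl$pos >= 2), "site too close to the sequence start")
    tri <- character(nrow(cl))
    for (ch in unique(cl$chrom)) {
      idx <- which(cl$chrom == ch)
      check_that(all(cl$pos[idx] <= nchar(seqs[[ch]]) - 1L),
                 "site too close to the sequence end")
      tri[idx] <- substring(seqs[[ch]], cl$pos[idx] - 1L, cl$pos[idx] + 1L)
    }
    cls <- canonical_sbs96(tri, cl$alt)
    tab <- as.data.table(table(class96 = cls))
    template <- merge(template, tab, by = "class96", all.x = TRUE,
                      sort = FALSE)
    template[is.na(N), N := 0L]
    setnames(template, "N", "count")
  } else {
    template[, count := 0L]
  }
  total <- sum(template$count)
  template[, raw_fraction := if (total > 0) count / total else 0]
  structure(template[], class = c("spectrum96", class(template)),
            normalization = "raw")
}

#' Trinucleotide background frequencies of a region set
#'
#' Tallies all trinucleotide windows fully inside the given regions,
#' canonicalized to the 32 pyrimidine-centred contexts; windows containing
#' `N` are skipped. Frequencies sum to one.
#'
#' @param regions data.table/data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive), or NULL for whole sequences.
#' @param reference reference list or named character vector.
#' @return a `trinuc_background`: data.table `context`, `frequency`.
#' @export
compute_trinuc_background <- function(regions = NULL, reference) {
  seqs <- if (is.list(reference) && !is.null(reference$sequence)) {
    setNames(reference$sequence, reference$chrom)
  } else reference
  if (is.null(regions)) {
    regions <- data.table(chrom = names(seqs), start = 1L,
                          end = nchar(seqs))
  }
  rg <- as.data.table(regions)
  check_that(all(c("chrom", "start", "end") %in% names(rg)),
             "regions need chrom, start, end")
  counts <- setNames(numeric(32), trinuc32_contexts())
  for (i in seq_len(nrow(rg))) {
    ch <- rg$chrom[i]
    check_that(ch %in% names(seqs), "region chromosome not in reference")
    st <- max(rg$start[i], 1L)
    en <- min(rg$end[i], nchar(seqs[[ch]]))
    if (en - st + 1L < 3L) next
    s <- substring(seqs[[ch]], st, en)
    n <- nchar(s)
    tri <- substring(s, 1:(n - 2L), 3:n)
    tri <- canonical_trinuc(tri)
    tri <- tri[!is.na(tri)]
    if (length(tri) > 0) {
      tab <- table(tri)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  total <- sum(counts)
  check_that(total > 0, "no valid trinucleotide windows in the regions")
  bg <- data.table(context = trinuc32_contexts(),
                   frequency = as.numeric(counts) / total)
  structure(bg, class = c("trinuc_background", class(bg)))
}

#' Renormalize a spectrum against genome vs dataset trinucleotide content
#'
#' Each class's fraction is reweighted by the ratio of its context's
#' frequency in the whole genome to its frequency in the dataset's callable
#' regions (`direction = "genome_over_dataset"`, the default, which
#' up-weights contexts under-represented in the callable regions), then the
#' spectrum is renormalized to sum to one. The inverse orientation is
#' available behind `direction`. Idempotent once normalized.
#'
#' @param spectrum a raw `spectrum96` from [build_spectrum()].
#' @param genome_bg,dataset_bg `trinuc_background` tables.
#' @param direction `"genome_over_dataset"` or `"dataset_over_genome"`.
#' @return the spectrum with a `normalized_fraction` column; attribute
#'   `normalization` is `"genome-normalized"`.
#' @export
normalize_spectrum <- function(spectrum, genome_bg, dataset_bg,
                               direction = c("genome_over_dataset",
                                             "dataset_over_genome")) {
  direction <- match.arg(direction)
  if (identical(attr(spectrum, "normalization"), "genome-normalized")) {
    return(spectrum)
  }
  sp <- copy(as.data.table(spectrum))
  g <- setNames(genome_bg$frequency, genome_bg$context)
  d <- setNames(dataset_bg$frequency, dataset_bg$context)
  nonzero <- sp$raw_fraction > 0
  if (any(d[sp$context[nonzero]] == 0)) {
    stop("dataset context frequency is zero for a context with mutations",
         call. = FALSE)
  }
  w <- if (direction == "genome_over_dataset") {
    g[sp$context] / d[sp$context]
  } else {
    d[sp$context] / g[sp$context]
  }
  w[!is.finite(w)] <- 0
  x <- sp$raw_fraction * w
  total <- sum(x)
  sp[, normalized_fraction := if (total > 0) x / total else 0]
  structure(sp[], class = c("spectrum96", class(sp)),
            normalization = "genome-normalized")
}

#' Write a spectrum as TSV
#'
#' @param spectrum a `spectrum96`.
#' @param path output path; a `#` header line records the normalization
#'   state and class ordering convention.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  hdr <- sprintf(
    "# 96-class spectrum (%s); ordering: substitution-major, 5' base, 3' base",
    attr(spectrum, "normalization") %||% "raw")
  writeLines(hdr, path)
  fwrite(as.data.table(spectrum), path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}
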