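# Barcode-aware alignment handling: read BAM/SAM into a flat read table,
# filter on mapping quality / mismatches / alignment flags, partition by
# annotated cell type, and null out terminal base qualities.

#' Read-level filter configuration
#'
#' Defaults follow the technology: droplet scRNA-seq aligners emit 255 as
#' the unique-mapper sentinel, so `min_mapping_quality = 255` keeps unique
#' alignments only; sciATAC-seq uses a conventional threshold of 30.
#'
#' @param technology `"scrna"` or `"scatac"`.
#' @param min_mapping_quality reads with MAPQ strictly below this are
#'   dropped; `NULL` picks the technology default (255 / 30).
#' @param max_mismatches reads with more than this many mismatches (NM-style
#'   tag) are dropped.
#' @param trim_length bases at each read end whose quality is set to 0.
#' @param barcode_tag BAM tag holding the cell barcode.
#' @return a `read_filter_config` list.
#' @export
read_filter_config <- function(technology = c("scrna", "scatac"),
                               min_mapping_quality = NULL,
                               max_mismatches = 5, trim_length = 5,
                               barcode_tag = "CB") {
  technology <- match.arg(technology)
  if (is.null(min_mapping_quality)) {
    min_mapping_quality <- if (technology == "scrna") 255L else 30L
  }
  check_that(min_mapping_quality >= 0 && max_mismatches >= 0 &&
               trim_length >= 0, "thresholds must be >= 0")
  structure(list(technology = technology,
                 min_mapping_quality = as.integer(min_mapping_quality),
                 max_mismatches = as.integer(max_mismatches),
                 trim_length = as.integer(trim_length),
                 barcode_tag = barcode_tag),
            class = "read_filter_config")
}

#' Read a cell-barcode annotation table
#'
#' Expects a TSV with header `barcode<TAB>cell_type` (an optional third
#' `sample_id` column is kept).
#'
#' @param path TSV path.
#' @return data.table with columns `barcode`, `cell_type` (and `sample_id`).
#' @export
read_cell_annotations <- function(path) {
  ann <- tryCatch(fread(path, header = TRUE, sep = "\t"),
                  error = function(e) stop("unreadable annotation table: ",
                                           conditionMessage(e), call. = FALSE))
  check_that(all(c("barcode", "cell_type") %in% names(ann)),
             "annotation table needs columns barcode, cell_type")
  check_that(!anyDuplicated(ann$barcode),
             "barcodes must be unique within a sample")
  check_that(all(nzchar(ann$cell_type)), "cell_type labels must be non-empty")
  ann
}

#' Load barcoded alignments into a flat read table
#'
#' @param bam path to a coordinate-sorted BAM file.
#' @param barcode_tag tag holding the cell barcode (default `"CB"`).
#' @return data.table with columns `qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `barcode`, `nm` (NA when no NM/nM tag).
#' @export
read_alignments <- function(bam, barcode_tag = "CB") {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c(barcode_tag, "NM", "nM"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  nm <- res$tag$NM
  if (is.null(nm) || all(is.na(nm))) nm <- res$tag$nM
  if (is.null(nm)) nm <- rep(NA_integer_, length(res$qname))
  bc <- res$tag[[barcode_tag]]
  if (is.null(bc)) bc <- rep(NA_character_, length(res$qname))
  data.table(
    qname = res$qname, flag = res$flag,
    chrom = as.character(res$rname), pos = res$pos, mapq = res$mapq,
    cigar = res$cigar, seq = as.character(res$seq),
    qual = as.character(res$qual), barcode = bc, nm = as.integer(nm))
}

#' Partition reads by annotated cell type with read-level filtering
#'
#' Drops secondary, supplementary, duplicate and unmapped alignments, reads
#' below the mapping-quality threshold, reads with more than
#' `max_mismatches` mismatches, and reads whose barcode is absent or not in
#' the annotation table. Reads lacking an NM-style mismatch tag pass with a
#' warning counter.
#'
#' @param reads read table from [read_alignments()] (or a compatible
#'   data.table).
#' @param annotations from [read_cell_annotations()].
#' @param filter_config from [read_filter_config()].
#' @return list with `reads_by_type` (named list of data.tables, one per
#'   cell type, each carrying a `cell_type` column) and `dropped`
#'   (data.table `reason`, `n`).
#' @export
split_by_cell_type <- function(reads, annotations,
                               filter_config = read_filter_config()) {
  rd <- as.data.table(reads)
  n_in <- nrow(rd)
  if (n_in > 0 && mean(is.na(rd$barcode) | !nzchar(rd$barcode)) > 0.99) {
    stop("more than 99% of reads lack a barcode tag: wrong input type?",
         call. = FALSE)
  }
  drop <- data.table(reason = character(), n = integer())
  note <- function(reason, n) {
    if (n > 0) drop <<- rbind(drop, data.table(reason = reason, n = n))
  }

  bad_flag <- bitwAnd(rd$flag, 0x4L) > 0 | bitwAnd(rd$flag, 0x100L) > 0 |
    bitwAnd(rd$flag, 0x400L) > 0 | bitwAnd(rd$flag, 0x800L) > 0
  note("unmapped_secondary_dup_suppl", sum(bad_flag))
  rd <- rd[!bad_flag]

  low_mq <- rd$mapq < filter_config$min_mapping_quality
  note("low_mapping_quality", sum(low_mq))
  rd <- rd[!low_mq]

  nm_missing <- is.na(rd$nm)
  if (any(nm_missing)) {
    warning(sum(nm_missing), " reads lack a mismatch (NM) tag; passed through")
  }
  high_nm <- !nm_missing & rd$nm > filter_config$max_mismatches
  note("too_many_mismatches", sum(high_nm))
  rd <- rd[!high_nm]

  rd <- merge(rd, annotations[, .(barcode, cell_type)], by = "barcode",
              all.x = TRUE, sort = FALSE)
  unann <- is.na(rd$cell_type)
  note("unannotated_barcode", sum(unann))
  rd <- rd[!unann]

  by_type <- split(rd, by = "cell_type", sorted = TRUE)
  list(reads_by_type = by_type, dropped = drop)
}

#' Set terminal base qualities to zero
#'
#' The first and last `trim_length` base qualities of every read are set to
#' phred 0 (`"!"`); the sequence is untouched. Reads of length
#' `<= 2 * trim_length` end up with all-zero qualities and contribute
#' nothing downstream. Idempotent.
#'
#' @param reads read table with a `qual` column (phred+33 strings).
#' @param trim_length bases to null at each end.
#' @return the read table with modified `qual` (a copy).
#' @export
trim_terminal_qualities <- function(reads, trim_length = 5) {
  rd <- copy(as.data.table(reads))
  if (trim_length == 0 || nrow(rd) == 0) return(rd)
  rd[, qual := {
    len <- nchar(qual)
    t2 <- pmin(trim_length, len)
    left <- strrep("!", t2)
    mid_len <- pmax(len - 2L * trim_length, 0L)
    mid <- substr(qual, trim_length + 1L, trim_length + mid_len)
    right <- strrep("!", pmin(trim_length, pmax(len - trim_length, 0L)))
    paste0(left, mid, right)
  }]
  rd
}

#' Write a read table as SAM text
#'
#' Minimal single-end SAM 1.6 emitter used for cell-type outputs and
#' synthetic fixtures; CB and NM tags are carried when present.
#'
#' @param reads read table (columns as in [read_alignments()], plus
#'   optionally `barcode`, `nm`).
#' @param ref_lengths named integer vector of reference sequence lengths.
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref_lengths, path) {
  rd <- as.data.table(reads)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  setorder(rd, chrom, pos)
  tags <- character(nrow(rd))
  if ("barcode" %in% names(rd)) {
    tags <- ifelse(is.na(rd$barcode), tags,
                   paste0(tags, "\tCB:Z:", rd$barcode))
  }
  if ("nm" %in% names(rd)) {
    tags <- ifelse(is.na(rd$nm), tags, paste0(tags, "\tNM:i:", rd$nm))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                  rd$qname, rd$flag, rd$chrom, rd$pos, rd$mapq, rd$cigar,
                  rd$seq, rd$qual, tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Fabricate aligned reads over a synthetic reference
#'
#' Read-level counterpart of [simulate_pileups()] used to exercise the
#' BAM/SAM input path: fixed-length, pure-match (`<len>M`) reads with CB
#' barcodes, MAPQ 255 and computed NM tags. Germline and somatic variants
#' from `truth` are written into the read sequences (50% allele fraction;
#' somatic alleles only in the designated mutant cells). No background
#' errors are injected.
#'
#' @param config a [sim_config()] (small configurations intended).
#' @param reference from [simulate_reference()].
#' @param truth a truth set from [simulate_pileups()] (or NULL to spike
#'   nothing).
#' @param read_length read length in bp.
#' @param base_quality phred quality assigned to every base.
#' @param seed integer seed.
#' @return read table compatible with [read_alignments()].
#' @export
simulate_alignments <- function(config, reference, truth = NULL,
                                read_length = 30, base_quality = 37,
                                seed = config$seed) {
  L <- config$reference_length
  refbase <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  types <- paste0("type", LETTERS[seq_len(config$n_cell_types)])
  qch <- rawToChar(as.raw(base_quality + 33L))
  with_seed(child_seed(seed, 7L), {
    n_reads_per_type <- as.integer(round(
      L * config$mean_depth_per_cell_type / read_length))
    rd <- rbindlist(lapply(types, function(tt) {
      start <- sample.int(L - read_length + 1L, n_reads_per_type,
                          replace = TRUE)
      data.table(cell_type = tt, pos = start,
                 cell = sample.int(config$cells_per_type,
                                   n_reads_per_type, replace = TRUE))
    }))
    rd[, barcode := sprintf("BC_%s_%04d", cell_type, cell)]
    seqs <- vapply(rd$pos, function(p)
      paste(refbase[p:(p + read_length - 1L)], collapse = ""), character(1))
    nm <- integer(nrow(rd))
    if (!is.null(truth)) {
      apply_allele <- function(idx, site_pos, alt_base, prob) {
        hit <- idx[runif(length(idx)) < prob]
        for (j in hit) {
          off <- site_pos - rd$pos[j] + 1L
          s <- seqs[j]
          substr(s, off, off) <- alt_base
          seqs[j] <<- s
          nm[j] <<- nm[j] + 1L
        }
      }
      if (nrow(truth$germline) > 0) {
        for (i in seq_len(nrow(truth$germline))) {
          g <- truth$germline[i]
          idx <- which(rd$pos <= g$pos & rd$pos + read_length - 1L >= g$pos)
          apply_allele(idx, g$pos, g$alt, 0.5)
        }
      }
      if (nrow(truth$somatic) > 0) {
        for (i in seq_len(nrow(truth$somatic))) {
          s <- truth$somatic[i]
          mcells <- as.integer(strsplit(s$mutant_cell_ids, ",")[[1]])
          idx <- which(rd$pos <= s$pos & rd$pos + read_length - 1L >= s$pos &
                         rd$cell_type == s$cell_type & rd$cell %in% mcells)
          apply_allele(idx, s$pos, s$alt, 1)
        }
      }
    }
    rd[, `:=`(qname = sprintf("read%06d", seq_len(.N)), flag = 0L,
              chrom = reference$chrom, mapq = 255L,
              cigar = paste0(read_length, "M"), seq = seqs,
              qual = strrep(qch, read_length), nm = nm)]
    rd[, .(qname, flag, chrom, pos, mapq, cigar, seq, qual, barcode, nm,
           cell_type)]
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits `reference.fa`, `cells.sam`, `annotations.tsv` and `truth.tsv`
#' under `outdir`. The SAM file can be converted to BAM with
#' [Rsamtools::asBam()].
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisible named list of the file paths.
#' @export
write_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_sample(config)
  fa <- file.path(outdir, "reference.fa")
  dna <- Biostrings::DNAStringSet(setNames(sim$reference$sequence,
                                           sim$reference$chrom))
  Biostrings::writeXStringSet(dna, fa)
  reads <- simulate_alignments(config, sim$reference, sim$truth)
  sam <- file.path(outdir, "cells.sam")
  write_sam(reads, setNames(config$reference_length, sim$reference$chrom),
            sam)
  ann <- file.path(outdir, "annotations.tsv")
  fwrite(sim$annotations, ann, sep = "\t")
  tr <- file.path(outdir, "truth.tsv")
  truth_flat <- rbind(
    sim$truth$germline[, .(chrom, pos, ref, alt, class = "germline",
                           cell_type = NA_character_,
                           mutant_cell_ids = NA_character_)],
    if (nrow(sim$truth$somatic) > 0)
      sim$truth$somatic[, .(chrom, pos, ref, alt, class = "somatic",
                            cell_type, mutant_cell_ids)],
    if (nrow(sim$truth$artefact_sites) > 0)
      sim$truth$artefact_sites[, .(chrom, pos, ref, alt = NA_character_,
                                   class = "artefact",
                                   cell_type = NA_character_,
                                   mutant_cell_ids = NA_character_)])
  fwrite(truth_flat, tr, sep = "\t")
  invisible(list(reference = fa, sam = sam, annotations = ann, truth = tr))
}
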