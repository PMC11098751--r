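# Independent oracles, deliberately written with plain arithmetic and
# loops, never via the package's own code paths.

# beta-binomial upper tail by direct summation in linear space
oracle_bb_tail <- function(k, n, a, b) {
  if (k == 0) return(1)
  j <- k:n
  sum(choose(n, j) * beta(j + a, n - j + b) / beta(a, b))
}

# naive per-read-base pileup: loop over reads and positions (pure-match
# CIGARs only), returning per (pos, cell_type) base tallies
oracle_pileup <- function(reads, min_bq = 30) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    sq <- strsplit(reads$seq[i], "")[[1]]
    ql <- utf8ToInt(reads$qual[i]) - 33L
    for (j in seq_along(sq)) {
      if (ql[j] < min_bq) next
      key <- paste(reads$pos[i] + j - 1L, reads$cell_type[i], sq[j])
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force canonical trinucleotide tally over a sequence
oracle_trinuc_tally <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  counts <- new.env()
  ch <- strsplit(s, "")[[1]]
  for (i in 1:(length(ch) - 2)) {
    tri <- paste(ch[i:(i + 2)], collapse = "")
    if (grepl("N", tri)) next
    if (!ch[i + 1] %in% c("C", "T")) tri <- rc(tri)
    counts[[tri]] <- (counts[[tri]] %||% 0) + 1
  }
  v <- unlist(as.list(counts))
  v / sum(v)
}

# the printed metric formulas, straight arithmetic
oracle_metrics <- function(tp, tp_low, fp, fn) {
  tp_prec <- tp + tp_low
  list(
    precision = if (tp_prec + fp > 0) tp_prec / (tp_prec + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = if (2 * tp_prec + fp + fn > 0) {
      2 * tp_prec / (2 * tp_prec + fp + fn)
    } else NA_real_)
}
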