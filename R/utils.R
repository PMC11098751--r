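# Shared sequence/coordinate helpers. All coordinates are 1-based inclusive.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")

#' Reverse-complement a character vector of DNA strings
#'
#' Plain-character convenience used for trinucleotide and doublet
#' canonicalization; `N` maps to `N`.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACG", "TTT"))
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' The 96 pyrimidine-centred substitution classes
#'
#' Lexicographic layout: substitution major (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' base, then 3' base, e.g. `"A[C>A]A"`.
#'
#' @return character vector of length 96.
#' @export
sbs96_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (five in BASES) {
      for (three in BASES) {
        out <- c(out, paste0(five, "[", s, "]", three))
      }
    }
  }
  out
}

#' The 32 pyrimidine-centred trinucleotide contexts
#'
#' Ordered to match the context layout of [sbs96_classes()].
#'
#' @return character vector of length 32.
#' @export
trinuc32_contexts <- function() {
  out <- character(0)
  for (centre in PYRIMIDINES) {
    for (five in BASES) {
      for (three in BASES) {
        out <- c(out, paste0(five, centre, three))
      }
    }
  }
  out
}

# canonicalize a trinucleotide: centre base must be a pyrimidine, else
# reverse-complement. Returns NA for windows containing N.
canonical_trinuc <- function(tri) {
  bad <- grepl("N", tri, fixed = TRUE) | nchar(tri) != 3L
  centre <- substr(tri, 2L, 2L)
  out <- ifelse(centre %in% PYRIMIDINES, tri, revcomp(tri))
  out[bad] <- NA_character_
  out
}

# canonical substitution class "X[R>A]Y" from ref trinucleotide and alt base
canonical_sbs96 <- function(tri, alt) {
  centre <- substr(tri, 2L, 2L)
  flip <- !(centre %in% PYRIMIDINES)
  tri_c <- ifelse(flip, revcomp(tri), tri)
  alt_c <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  paste0(substr(tri_c, 1L, 1L), "[", substr(tri_c, 2L, 2L), ">", alt_c,
         "]", substr(tri_c, 3L, 3L))
}

# canonical doublet class, pyrimidine convention: a doublet REF>ALT and its
# reverse complement are the same event; keep the representation whose
# reference dinucleotide is lexicographically smaller between the two
# orientations (ties broken on the alt).
canonical_doublet <- function(ref2, alt2) {
  rc_ref <- revcomp(ref2)
  rc_alt <- revcomp(alt2)
  fwd <- paste0(ref2, ">", alt2)
  rev <- paste0(rc_ref, ">", rc_alt)
  ifelse(rc_ref < ref2 | (rc_ref == ref2 & rc_alt < alt2), rev, fwd)
}

# chromosome names treated as autosomes: anything that is not a sex
# chromosome or organellar contig under common naming conventions
is_autosome <- function(chrom) {
  !grepl("^(chr)?(X|Y|M|MT)$", chrom, ignore.case = TRUE)
}

# internal: stop unless condition holds
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# internal: derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483629L
}
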