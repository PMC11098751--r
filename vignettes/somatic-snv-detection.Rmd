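---
title: "Detecting somatic SNVs in barcoded single-cell data: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic SNVs in barcoded single-cell data: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmut)
library(data.table)
```

## The problem

High-throughput single-cell assays (droplet scRNA-seq, sciATAC-seq) carry
the sequence of expressed or accessible loci in every cell, so somatic
point mutations are in principle readable without any DNA sequencing of the
same sample. In practice the signal is buried: per-cell depth is usually a
single read per covered position, sequencing and alignment errors occur at
rates comparable to somatic mutation allele fractions, RNA editing mimics
A>G substitutions, and germline heterozygous polymorphisms outnumber
somatic mutations by orders of magnitude.

`scmut` resolves this by pooling reads **within annotated cell types**.
Three observations carry the method:

1. Pooling across the cells of a type restores testable depth at each
   site while retaining biological resolution — somatic mutations are
   expected to be confined to one differentiation lineage, while germline
   variants appear in every cell type.
2. Sequencing error is overdispersed across sites: a site's error rate is
   better treated as a random variable than as a constant. A beta-binomial
   captures this with two parameters.
3. Recurrent artefacts recur across unrelated individuals, so a panel of
   normals indexes them without any modelling of their mechanism.

## The error model

At a homozygous-reference site of depth $n$, the non-reference read count
$K$ is modelled as

$$K \mid P \sim \mathrm{Binomial}(n, P), \qquad P \sim
\mathrm{Beta}(\alpha, \beta),$$

so marginally $K$ is beta-binomial. The per-site test statistic is the
one-sided upper tail $\Pr(K \ge k)$, computed by exact summation of the
probability mass (log-space evaluation of each term, linear-space
accumulation). There is no normal approximation at any depth; the
summation is exact to floating-point precision and is verified in the test
suite against an independently coded oracle to ten significant digits.
$\Pr(K \ge 0)$ is exactly 1.

The test is one-sided by design: only an *excess* of non-reference reads is
evidence of a variant. No multiple-testing correction is applied; the
method fixes a per-site threshold (`alpha = 0.001`) and makes no
genome-wide FDR claim. The alt count tested is that of the single
most-supported non-reference base (ties broken by read count, then
supporting-cell count, then alphabetically, for determinism).

### Fitting

$(\alpha, \beta)$ are estimated by maximizing the beta-binomial
log-likelihood over training sites (Nelder–Mead on $\log\alpha,
\log\beta$, method-of-moments start, with the moment estimate kept if the
optimizer ever fails to improve on it — an explicit contract tested in the
suite). Identical $(n, k)$ pairs are collapsed to weighted unique
combinations first, which makes a million-site fit cost a few dozen
likelihood terms.

Training sites come from unrelated non-neoplastic samples and must be
homozygous-reference with no variant evidence beyond noise. Two one-sided
binomial screens implement this: sites whose alt count is not
significantly below a heterozygous 50% fraction are excluded
(germline-like), and sites whose alt count is significantly above a 1%
error ceiling are excluded (variant or recurrent-artefact-like). The
second screen matters more than it looks: recurrent artefact loci carry
error rates of several percent, and leaving them in the training pool
inflates the fitted overdispersion enough to blunt both candidate
detection and — more damagingly — the panel of normals, which relies on
the same test being sharply significant in each normal sample. Artefact
loci are the panel's concern, not the error model's.

Degenerate inputs are handled explicitly: an all-zero alt-count pool
returns a capped model ($\beta$ at a configured ceiling) with a warning
and `valid = FALSE`; a pool with half-alt counts everywhere fits a mean
error near 0.5 and is flagged invalid (the model's mean must lie in
$(0, 0.5)$).

## The filter cascade

All filters add flags; PASS means "no flags", so the PASS set is invariant
to filter order (a property test shuffles the order and compares).

* **Exclusivity.** For a candidate allele in cell type $c$, the same
  beta-binomial test is applied to that allele's counts in every other
  cell type individually *and* to the counts aggregated across all other
  cell types. Any significance flags the candidate. The aggregated test is
  what catches variants spread thinly across several other types — each
  individually below threshold — which is precisely the signature of a
  germline variant in shallow data. With only one annotated cell type the
  test is vacuous; the candidate is retained with a logged caveat.
* **Minimum support.** ≥ 3 alt reads, from ≥ 2 distinct cell barcodes, at
  depth ≥ 5 in the target cell type. Supporting-cell counts are first-class
  in the base-count matrix; they are not recomputable from totals.
* **Homopolymer.** Mononucleotide tracts of length ≥ 4 (configurable;
  the minimal tract length is a genuinely open parameter) plus a 4 bp
  proximity window.
* **Clustered.** Candidate pairs < 5 bp apart in the same chromosome and
  cell type are both flagged, unless the pair is adjacent and its
  canonical doublet class is allow-listed — true doublet substitutions
  (e.g. ultraviolet-induced CC>TT) arise as single events. When per-cell
  evidence is available the exemption additionally demands at least one
  shared alt-supporting barcode, since a real doublet lives on one
  haplotype in the same cells. The default allow list contains the
  unambiguous process-specific classes CC>TT and CC>AA; studies of, e.g.,
  mismatch-repair-deficient tumors should extend it
  (`dbs_allowlist(extra = ...)`), as several doublet-rich mutational
  processes have broader class membership than can be safely hard-coded.
* **Panel of normals.** Each unrelated normal's counts are aggregated
  across its cell types per site and tested; sites significant in ≥ 1
  sample are stored with their recurrence count, and candidates at sites
  recurrent in ≥ 2 samples are flagged. A single-normal panel disables
  recurrence filtering with a warning rather than silently over-filtering.
  Repeat-element-enriched artefacts are handled through this panel rather
  than a repeat mask.
* **Site exclusions.** RNA-editing site lists (BED, converted to 1-based)
  and common polymorphisms with population allele frequency strictly
  greater than 1%.

## Downstream analytics

**Callable sites and burdens.** A site is callable for cell type $c$ when
its depth in $c$ is ≥ 5 and at least one other cell type also reaches
depth 5 — the conjunction the exclusivity test needs to be meaningful.
Burdens are mutations per callable Mb, autosomes only; cell types under
500,000 callable sites are QC-excluded. Per-cell burdens divide the
mutations attributed to a cell (≥ 1 alt-supporting read, consistent with
genotyping) by the callable sites that cell covers with ≥ 1 read, and
extrapolate to a per-haploid-genome count using the autosomal reference
length computed from the FASTA index (never hard-coded). No ploidy
correction is attempted: at single-read depth essentially one allele is
observed per cell and position, so the estimate is intrinsically haploid.

**Spectra.** 96 pyrimidine-strand classes in the conventional
substitution-major ordering. Background trinucleotide frequencies are
tallied over callable regions and over the whole genome; the normalized
spectrum multiplies each class fraction by genome/dataset frequency of its
context and renormalizes. The direction of that ratio is ambiguous in
prose descriptions of the procedure; both orientations are implemented
(`direction =`), with genome-over-dataset — up-weighting contexts
under-represented in the callable territory — as the default, matching the
standard region-to-genome renormalization used before signature fitting.
Signature fitting itself (COSMIC decomposition, NMF extraction) is out of
scope; the emitted matrices are those tools' input.

**Genotyping and clonality.** Every cell × mutation entry is mutant
(≥ 1 alt read), reference (covered, 0 alt reads) or missing (no
coverage); these invariants are asserted on every output. Mutant-cell
fractions use covered cells as the denominator (undefined, not zero, when
no cell covers the site). For clonal clustering, mutations must be present
in ≥ 20 cells and genotyped in ≥ 10% of cells; cells are clustered on the
binary mutant indicator with Jaccard distance and average linkage —
missing is 0 for distances but stays visually distinct in outputs. The
tree is cut at a requested $k$ or at the largest relative gap in merge
heights. Inputs are sorted lexicographically before distance computation,
making the result invariant to input row order. Calling is intended to be
run per tumor region with the union of calls genotyped across all regions;
region-restricted subclonal mutations would otherwise dilute below the
detection threshold.

**Benchmarking.** Within regions jointly evaluable by DNA and single-cell
coverage (DNA tumor ≥ 50×, DNA normal ≥ 10×, malignant cell types ≥ 10
reads, ≥ 2 further cell types ≥ 5), variants are TP (called in both),
TP-with-low-DNA-support (single-cell-only but ≥ 1 high-quality DNA alt
read and no other alternative allele), FN (DNA-only) or FP (no DNA alt
reads, or alt support in the matched normal, indicating germline
contamination; a single-cell-only call with conflicting other-allele DNA
reads is also FP so that the categories partition). Precision uses
TP + TP-low in its numerator, sensitivity uses TP only, and
$F_1 = 2\,\mathrm{TP}_{\mathrm{prec}} / (2\,\mathrm{TP}_{\mathrm{prec}} +
\mathrm{FP} + \mathrm{FN})$; undefined ratios are reported as `NA`, never
0. Bootstrap intervals resample variants uniformly with replacement (50
resamples by default) and report mean and percentile 95% bounds.

## The synthetic-data generator

The generator emulates exactly the statistical structure the caller
assumes: every reference position is covered at Poisson depth per cell
type, reads land on cells uniformly, germline SNPs draw alt reads at 50%
allele fraction in all cell types, each somatic SNV is confined to
$\lceil f \cdot n_{\mathrm{cells}} \rceil$ designated cells of one type
(each guaranteed ≥ 1 alt read), and all other sites draw a per-site error
rate from Beta($\alpha$, $\beta$) with binomial alt reads, error bases
uniform over the three non-reference bases. Artefact-prone sites carry a
fixed inflated error rate shared across samples, emulating locus-intrinsic
mapping artefacts — this is what makes them recurrent in the normal panel.
Spiked variant positions keep ≥ 6 bp spacing from each other and 8 bp from
embedded homopolymer tracts, so planted truth never overlaps the proximity
filters by construction.

Default noise is Beta(2, 10000) (mean 2×10⁻⁴), a realistic residual error
after the base-quality ≥ 30 filter. The choice is a power analysis, fixed
up front: at the fixture scales used (≤ 10⁴ sites × 3 cell types, ≤ 25
runs), the expected number of chance candidates reaching 3 alt reads —
$\binom{n}{3}\,\alpha(\alpha+1)(\alpha+2)/\beta^{3}$ per site-type at
depth $n=30$, about $10^{-7}$ — stays well below one across the entire
suite, so the zero-false-positive invariants are statistically meaningful
rather than lucky. A mean error an order of magnitude higher would make
"precision 1.0" unattainable at these scales by arithmetic, not by any
defect of the caller.

What the generator does **not** model: transcript structure (coverage is
uniform, not exon-shaped), UMI collisions and PCR duplicates, allelic
imbalance and allele-specific expression, doublet cells, strand bias, and
RNA editing as a mechanism (editing sites are exercised through the
exclusion-list machinery instead). Passing tests therefore demonstrate the
statistical machinery — detection power, error calibration, filter logic —
not robustness to every artefact of real libraries; on real data the PON
and exclusion lists carry weight the fixtures cannot give them.

Fixtures are emitted both as in-memory count tables (fast unit tests) and
as minimal valid alignment files — SAM text with fabricated read names,
pure-match CIGARs, CB and NM tags — converted to BAM in tests so the real
Rsamtools-based reader path is exercised end to end.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; BED inputs are converted
  on read.
* Terminal-quality trimming zeroes the first and last 5 base qualities of
  each read. Because both ends are trimmed symmetrically, the result is
  identical in read and reference orientation; reads ≤ 10 bp are fully
  nulled and contribute nothing. Trimming is idempotent.
* The mapping-quality rule is `MQ < threshold ⇒ drop`, with 255 for
  scRNA-seq (the unique-mapper sentinel of the common aligners) and 30 for
  sciATAC-seq, as configuration rather than hard-code. Mismatch counts
  come from the NM-style tag; reads lacking one pass with a warning
  counter. Secondary, supplementary, duplicate and unmapped alignments are
  dropped.
* In the pileup a read contributes at most one base per site; when mates
  overlap, the higher-quality base wins. Deletions and reference skips
  (spliced `N` operations) contribute nothing to depth — RNA splicing
  would otherwise dominate an "other" category; `N` bases are tallied as
  `other` but are never allele evidence.
* A site with two distinct non-reference bases each at ≥ 3 reads in the
  same cell type is flagged `Multi_allelic` and excluded from PASS; such
  RNA sites are overwhelmingly artefactual.
* Test depths for the parameter-recovery experiments use 500× training
  sites. At shallow depth only the mean error $\alpha/(\alpha+\beta)$ is
  identified; resolving the two shapes separately requires per-site error
  rates to be individually resolvable, i.e. binomial noise
  $\sqrt{\mu/n}$ below the beta spread. This was verified by checking
  that shallow-depth misses have higher fitted than true likelihood —
  estimator variance, not an optimizer defect.
* Problem sizes in the test suite: tail-oracle checks at 1,000 random
  parameter triples; calibration and recovery at 10⁵ sites; the planted
  end-to-end fixture at 3 cell types × 200 cells × 5,000 sites with 50
  somatic, 200 germline and 20 artefact spikes across 5 seeds; pure-null
  false-positive checks at 3,000 sites × 5 seeds.

## Known limitations

* Indels, structural variants and copy-number inference are out of scope.
* The exclusivity principle removes true somatic mutations acquired before
  clonal diversification of the sampled lineages (early-embryonic or
  stem-cell mutations shared across cell types are indistinguishable from
  germline here).
* Burden estimates inherit expression bias: callable territory is whatever
  the assay covers, and the genome extrapolation assumes the covered
  territory's mutation rate is representative.
* The beta-binomial is a single global error model per technology; no
  site-specific (sequence-context or positional) error modelling, and no
  strand-bias test.
* With a single annotated cell type the germline/somatic distinction
  rests entirely on the exclusion lists and the PON.
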