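# End-to-end orchestration with one configuration object, structured
# per-filter logging and a reproducibility manifest.

#' Pipeline configuration
#'
#' Aggregates every calling threshold with its default: per-site
#' significance 0.001, minimum support of 3 reads from 2 cells at depth 5,
#' base quality 30, terminal trim 5 bp, homopolymer proximity 4 bp,
#' clustered-variant window 5 bp, PON recurrence 2 samples, burden QC at
#' 500,000 callable sites, and clustering gates of 20 mutant cells / 10%
#' genotyped.
#'
#' @param technology `"scrna"` or `"scatac"`.
#' @param alpha per-site beta-binomial significance threshold.
#' @param min_reads,min_cells,min_depth minimum-support rule.
#' @param min_base_quality base-quality cutoff for counting.
#' @param trim_length terminal bases whose quality is nulled.
#' @param homopolymer_proximity,min_tract_len homopolymer filter.
#' @param cluster_window clustered-variant window (bp).
#' @param pon_min_samples PON recurrence threshold.
#' @param burden_min_callable callable-site QC threshold for burdens.
#' @param clustering_min_mutant_cells,clustering_min_genotyped_fraction
#'   clonal-clustering gates.
#' @param dbs_allowlist doublet classes exempt from the clustered filter.
#' @param seed integer seed for stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(technology = c("scrna", "scatac"),
                            alpha = 0.001, min_reads = 3, min_cells = 2,
                            min_depth = 5, min_base_quality = 30,
                            trim_length = 5, homopolymer_proximity = 4,
                            min_tract_len = 4, cluster_window = 5,
                            pon_min_samples = 2,
                            burden_min_callable = 500000,
                            clustering_min_mutant_cells = 20,
                            clustering_min_genotyped_fraction = 0.10,
                            dbs_allowlist = scmut::dbs_allowlist(),
                            seed = 1) {
  technology <- match.arg(technology)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on a simulated sample
#'
#' Orchestrates every stage on synthetic inputs: reference + pileups,
#' error-model fitting on an unrelated normal panel, PON construction,
#' candidate detection and the filter cascade, burdens, the 96-class
#' spectrum (genome-normalized against the dataset's callable regions),
#' single-cell genotyping and mutant-cell fractions. Outputs are written
#' under `outdir` with a JSON manifest; reruns with the same inputs are
#' bit-identical.
#'
#' @param sim_cfg a [sim_config()] describing the sample.
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @param n_normals unrelated normal samples used for model training and
#'   the PON.
#' @return invisible list with all stage results (`model`, `pon`, `calls`,
#'   `burden_celltype`, `burden_cell`, `spectrum`, `genotypes`,
#'   `clonality`, `manifest`).
#' @export
run_pipeline <- function(sim_cfg, outdir, config = pipeline_config(),
                         n_normals = 5) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logit <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  sim <- simulate_sample(sim_cfg, min_tract_len = config$min_tract_len)
  logit("simulated sample: %d sites x %d cell types",
        sim_cfg$reference_length, sim_cfg$n_cell_types)

  normals <- simulate_normal_panel(sim_cfg, sim$reference, sim$truth,
                                   n_samples = n_normals)
  normal_mats <- lapply(normals, function(x)
    cell_counts_to_matrix(x$cell_counts))

  # training alt counts: depth minus reference-base and `other` reads,
  # aggregated across each normal sample's cell types
  training_pool <- rbindlist(lapply(normal_mats, function(m) {
    mm <- as.data.table(m)
    agg <- mm[, c(lapply(.SD, sum)), by = .(chrom, pos, ref),
              .SDcols = c(BASES, "other")]
    agg[, depth := A + C + G + T + other]
    refn <- as.matrix(agg[, BASES, with = FALSE])[
      cbind(seq_len(nrow(agg)), match(agg$ref, BASES))]
    agg[, alt_count := depth - other - refn]
    agg[, .(depth, alt_count)]
  }))
  training <- sample_training_sites(training_pool, n = 1e6,
                                    seed = config$seed)
  model <- fit_beta_binomial(training,
                             technology_label = config$technology)
  logit("fitted error model: alpha=%.4g beta=%.4g on %d sites",
        model$alpha, model$beta, model$n_training_sites)
  write_bb_model(model, file.path(outdir, "model.tsv"))

  pon <- build_pon(normal_mats, model, alpha = config$alpha,
                   min_samples = config$pon_min_samples)
  write_pon(pon, file.path(outdir, "pon.tsv"))
  logit("panel of normals: %d sites (%d samples)", nrow(pon), n_normals)

  mat <- cell_counts_to_matrix(sim$cell_counts,
                               min_depth = config$min_depth)
  res <- call_mutations(mat, model, reference = sim$reference,
                        pon = pon, cell_counts = sim$cell_counts,
                        config = config)
  n_flagged <- table(unlist(strsplit(res$calls$flags[
    nzchar(res$calls$flags)], ";")))
  for (nm in names(n_flagged)) logit("filter %s: %d candidates flagged",
                                     nm, n_flagged[[nm]])
  logit("calls: %d candidates, %d PASS", nrow(res$calls), nrow(res$pass))
  write_vcf(res$calls, file.path(outdir, "calls.vcf"))

  callable <- compute_callable_sites(mat, cell_counts = sim$cell_counts,
                                     min_depth = config$min_depth)
  bt <- cell_type_burden(res$pass, callable,
                         min_callable = config$burden_min_callable)
  fwrite(bt, file.path(outdir, "burden_celltype.tsv"), sep = "\t")
  genome_bp <- autosomal_genome_size(sim$reference)
  bc <- per_cell_burden(res$pass, sim$cell_counts, callable, genome_bp)
  fwrite(bc, file.path(outdir, "burden_cell.tsv"), sep = "\t")

  spec <- build_spectrum(res$pass, sim$reference)
  genome_bg <- compute_trinuc_background(NULL, sim$reference)
  callable_rg <- callable$sites[, .(chrom, start = pos, end = pos)]
  dataset_bg <- if (nrow(callable_rg) > 0) {
    compute_trinuc_background(
      unique(callable_rg)[, .(start = min(start), end = max(end)),
                          by = chrom][, .(chrom, start, end)],
      sim$reference)
  } else genome_bg
  spec <- normalize_spectrum(spec, genome_bg, dataset_bg)
  write_spectrum(spec, file.path(outdir, "spectrum.tsv"))

  gt <- genotype_cells(res$pass, sim$cell_counts, sim$annotations)
  write_genotype_matrix(gt, file.path(outdir, "genotypes.tsv"))
  mcf <- mutant_cell_fraction(gt)
  fwrite(mcf, file.path(outdir, "clonality.tsv"), sep = "\t")

  manifest <- list(
    package_version = as.character(utils::packageVersion("scmut")),
    config = config[setdiff(names(config), "dbs_allowlist")],
    dbs_allowlist = config$dbs_allowlist,
    sim_config = sim_cfg[!vapply(sim_cfg, is.null, logical(1))],
    n_normals = n_normals,
    outputs = c("model.tsv", "pon.tsv", "calls.vcf", "calls.tsv",
                "burden_celltype.tsv", "burden_cell.tsv", "spectrum.tsv",
                "genotypes.tsv", "clonality.tsv"),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  invisible(list(model = model, pon = pon, calls = res,
                 burden_celltype = bt, burden_cell = bc, spectrum = spec,
                 genotypes = gt, clonality = mcf, manifest = manifest))
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  check_that(length(bad) == 0,
             paste("unknown config keys:", paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}
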