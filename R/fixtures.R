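# Synthetic fixtures with the statistical structure the caller assumes:
# multi-cell-type pileups carrying germline SNPs (all cell types, ~50% allele
# fraction), cell-type-exclusive somatic SNVs (a chosen fraction of the cells
# of one type), recurrent artefact-prone sites (inflated error shared across
# samples) and background errors from a beta-binomial noise process
# (per-site error rate ~ Beta(alpha, beta), alt reads binomial).

#' Simulation configuration
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type cells per cell type.
#' @param reference_length reference length in bp (>= 1000); every position
#'   is a potentially covered site.
#' @param mean_depth_per_cell_type mean sequencing depth per cell type at a
#'   site (Poisson).
#' @param germline_sites number of spiked germline SNPs.
#' @param somatic_sites_per_cell_type somatic SNVs per cell type; a single
#'   integer or one integer per cell type.
#' @param somatic_cell_fraction fraction of cells of the target type carrying
#'   each somatic SNV, in (0, 1].
#' @param error_alpha,error_beta beta shape parameters of the background
#'   error process.
#' @param artefact_sites number of recurrent artefact-prone sites.
#' @param artefact_error fixed per-site error rate at artefact sites (shared
#'   across samples, emulating locus-intrinsic mapping artefacts).
#' @param homopolymer_tracts data.frame with columns `pos`, `len`, `base`
#'   (or NULL) of mononucleotide tracts to embed in the reference.
#' @param seed integer seed; identical seed implies bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cell_types = 3, cells_per_type = 200,
                       reference_length = 5000,
                       mean_depth_per_cell_type = 30,
                       germline_sites = 50,
                       somatic_sites_per_cell_type = 5,
                       somatic_cell_fraction = 0.3,
                       error_alpha = 2, error_beta = 10000,
                       artefact_sites = 0, artefact_error = 0.1,
                       homopolymer_tracts = NULL, seed = 1) {
  check_that(error_alpha > 0 && error_beta > 0,
             "error_alpha and error_beta must be > 0")
  check_that(somatic_cell_fraction > 0 && somatic_cell_fraction <= 1,
             "somatic_cell_fraction must be in (0, 1]")
  check_that(n_cell_types >= 1 && cells_per_type >= 1,
             "cell counts must be >= 1")
  check_that(germline_sites >= 0 && artefact_sites >= 0 &&
               all(somatic_sites_per_cell_type >= 0),
             "site counts must be >= 0")
  somatic <- rep_len(as.integer(somatic_sites_per_cell_type), n_cell_types)
  structure(list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(cells_per_type),
    reference_length = as.integer(reference_length),
    mean_depth_per_cell_type = mean_depth_per_cell_type,
    germline_sites = as.integer(germline_sites),
    somatic_sites_per_cell_type = somatic,
    somatic_cell_fraction = somatic_cell_fraction,
    error_alpha = error_alpha, error_beta = error_beta,
    artefact_sites = as.integer(artefact_sites),
    artefact_error = artefact_error,
    homopolymer_tracts = homopolymer_tracts,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a reference sequence with controlled homopolymer content
#'
#' Background bases are drawn uniformly, then rewritten so that no
#' mononucleotide run reaches `min_tract_len`; requested tracts are embedded
#' afterwards, with their flanks forced to a different base so the realized
#' tract length equals the requested one.
#'
#' @param config a [sim_config()].
#' @param min_tract_len homopolymer threshold: background runs are kept
#'   strictly shorter than this.
#' @return list with `sequence` (single character string), `chrom`
#'   (`"chrS"`), and `tracts` (data.table `pos`, `len`, `base`).
#' @export
simulate_reference <- function(config, min_tract_len = 4) {
  L <- config$reference_length
  check_that(L >= 1000, "reference_length must be >= 1000")
  tracts <- config$homopolymer_tracts
  if (!is.null(tracts)) {
    tracts <- as.data.table(tracts)
    check_that(all(c("pos", "len", "base") %in% names(tracts)),
               "homopolymer_tracts needs columns pos, len, base")
    setorder(tracts, pos)
    ends <- tracts$pos + tracts$len - 1L
    if (nrow(tracts) > 1 &&
        any(tracts$pos[-1] <= ends[-nrow(tracts)] + 1L)) {
      stop("requested homopolymer tracts overlap or touch", call. = FALSE)
    }
    check_that(all(tracts$pos >= 2) && all(ends <= L - 1L),
               "tracts must leave at least one flanking base inside the reference")
  }
  bases <- with_seed(child_seed(config$seed, 1L), {
    b <- sample(BASES, L, replace = TRUE)
    # break background runs >= min_tract_len
    repeat {
      r <- rle(b)
      if (all(r$lengths < min_tract_len)) break
      ends_r <- cumsum(r$lengths)
      for (i in which(r$lengths >= min_tract_len)) {
        run_pos <- (ends_r[i] - r$lengths[i] + 1L):ends_r[i]
        fix <- run_pos[seq(min_tract_len, length(run_pos), by = min_tract_len)]
        b[fix] <- vapply(b[fix], function(x)
          sample(setdiff(BASES, x), 1), character(1))
      }
    }
    b
  })
  if (!is.null(tracts) && nrow(tracts) > 0) {
    for (i in seq_len(nrow(tracts))) {
      p <- tracts$pos[i]; l <- tracts$len[i]; bb <- tracts$base[i]
      bases[p:(p + l - 1L)] <- bb
      for (fl in c(p - 1L, p + l)) {
        if (fl >= 1 && fl <= L && bases[fl] == bb) {
          bases[fl] <- setdiff(BASES, bb)[1]
        }
      }
    }
  } else {
    tracts <- data.table(pos = integer(), len = integer(),
                         base = character())
  }
  list(sequence = paste(bases, collapse = ""), chrom = "chrS",
       tracts = tracts)
}

# pick variant site positions keeping a minimum spacing from already-used
# positions (so spiked variants never trip the clustered filter) and
# avoiding filter neighbourhoods (homopolymer tracts +/- pad)
pick_positions <- function(n, L, used, avoid = integer(), spacing = 6L) {
  used_nbhd <- if (length(used) > 0) {
    as.vector(outer(used, (-spacing + 1L):(spacing - 1L), "+"))
  } else integer(0)
  free <- setdiff(seq_len(L), union(used_nbhd, avoid))
  picked <- integer(0)
  while (length(picked) < n && length(free) > 0) {
    p <- free[sample.int(length(free), 1)]
    picked <- c(picked, p)
    free <- free[abs(free - p) >= spacing]
  }
  check_that(length(picked) == n,
             "reference too short to place the requested variant sites")
  sort(picked)
}

#' Simulate per-cell pileup counts and the matching truth set
#'
#' Every reference position is a covered site: per cell type the site depth
#' is Poisson(`mean_depth_per_cell_type`), reads are assigned to cells
#' uniformly. Germline SNPs receive alt reads in all cell types at ~50%
#' allele fraction. Each somatic SNV is confined to
#' `ceil(somatic_cell_fraction * cells_per_type)` distinct cells of its
#' target cell type, each of which is guaranteed at least one alt read. All
#' other sites draw a per-site error rate from Beta(alpha, beta) (or the
#' fixed `artefact_error` at artefact sites) and alt reads binomially; error
#' reads pick one of the three non-reference bases uniformly.
#'
#' Variant positions are placed away from embedded homopolymer tracts and at
#' least 6 bp apart, so spiked truth does not overlap the proximity-based
#' artefact filters.
#'
#' @param config a [sim_config()].
#' @param reference from [simulate_reference()].
#' @param truth optional truth set from a previous call; when given, its
#'   artefact sites (with their inflated error rates) are reused and no
#'   germline/somatic variants are spiked. This generates an unrelated
#'   normal sample sharing only locus-intrinsic artefacts.
#' @param sample_id sample label recorded in the output.
#' @param seed overrides `config$seed` (used for unrelated samples).
#' @return list with `cell_counts` (data.table: chrom, pos, ref, cell_type,
#'   barcode, A, C, G, T, other), `truth` (list: germline, somatic,
#'   artefact_sites data.tables), `annotations` (barcode/cell_type/sample_id)
#'   and `config`.
#' @export
simulate_pileups <- function(config, reference, truth = NULL,
                             sample_id = "sample1", seed = config$seed) {
  L <- config$reference_length
  chrom <- reference$chrom
  refbase <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  types <- paste0("type", LETTERS[seq_len(config$n_cell_types)])
  ncell <- config$cells_per_type
  n_mut_cells <- as.integer(ceiling(config$somatic_cell_fraction * ncell))
  if (is.null(truth) && sum(config$somatic_sites_per_cell_type) > 0 &&
      n_mut_cells < 2) {
    warning("somatic_cell_fraction x cells_per_type < 2: such sites cannot ",
            "pass the 2-cell support rule; flagged in the truth set")
  }

  out <- with_seed(seed, {
    if (is.null(truth)) {
      # variant placement, avoiding tract neighbourhoods and each other
      avoid <- integer(0)
      if (nrow(reference$tracts) > 0) {
        avoid <- unlist(lapply(seq_len(nrow(reference$tracts)), function(i) {
          t <- reference$tracts[i]
          max(1L, t$pos - 8L):min(L, t$pos + t$len - 1L + 8L)
        }))
      }
      used <- integer(0)
      g_pos <- pick_positions(config$germline_sites, L, used, avoid)
      used <- union(used, g_pos)
      s_pos_by_type <- list()
      for (i in seq_along(types)) {
        sp <- pick_positions(config$somatic_sites_per_cell_type[i], L,
                             used, avoid)
        used <- union(used, sp)
        s_pos_by_type[[types[i]]] <- sp
      }
      a_pos <- pick_positions(config$artefact_sites, L, used, avoid)

      pick_alt <- function(p) vapply(refbase[p], function(r)
        sample(setdiff(BASES, r), 1), character(1), USE.NAMES = FALSE)
      germline <- data.table(chrom = chrom, pos = g_pos,
                             ref = refbase[g_pos], alt = pick_alt(g_pos))
      som_list <- lapply(seq_along(types), function(i) {
        sp <- s_pos_by_type[[types[i]]]
        if (length(sp) == 0) return(NULL)
        data.table(chrom = chrom, pos = sp, ref = refbase[sp],
                   alt = pick_alt(sp), cell_type = types[i],
                   mutant_cell_ids = vapply(sp, function(x) paste(
                     sort(sample.int(ncell, n_mut_cells)), collapse = ","),
                     character(1)),
                   recoverable = n_mut_cells >= 2)
      })
      somatic <- rbindlist(som_list)
      if (nrow(somatic) == 0) {
        somatic <- data.table(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              cell_type = character(),
                              mutant_cell_ids = character(),
                              recoverable = logical())
      }
      artefact <- data.table(chrom = chrom, pos = a_pos,
                             ref = refbase[a_pos],
                             error_rate = rep(config$artefact_error,
                                              length(a_pos)))
      truth <- list(germline = germline, somatic = somatic,
                    artefact_sites = artefact)
      spike <- TRUE
    } else {
      spike <- FALSE
    }

    # per-site error rates: beta draws, overridden at artefact sites
    p_site <- rbeta(L, config$error_alpha, config$error_beta)
    if (nrow(truth$artefact_sites) > 0) {
      p_site[truth$artefact_sites$pos] <- truth$artefact_sites$error_rate
    }

    # read-level table: one row per read
    grid <- data.table::CJ(cell_type = types, pos = seq_len(L))
    grid[, depth := rpois(.N, config$mean_depth_per_cell_type)]
    gpos <- grid[depth > 0]
    reads <- gpos[rep(seq_len(nrow(gpos)), gpos$depth)]
    reads[, depth := NULL]
    reads[, cell := sample.int(ncell, .N, replace = TRUE)]
    reads[, ref := refbase[pos]]
    reads[, base := ref]

    # background errors (variant sites excluded below by overwriting)
    err <- runif(nrow(reads)) < p_site[reads$pos]
    if (any(err)) {
      ei <- which(err)
      shift <- sample.int(3L, length(ei), replace = TRUE)
      # rotate away from the reference base
      bidx <- match(reads$ref[ei], BASES)
      reads$base[ei] <- BASES[((bidx - 1L + shift) %% 4L) + 1L]
    }

    if (spike && nrow(truth$germline) > 0) {
      gi <- which(reads$pos %in% truth$germline$pos)
      galt <- setNames(truth$germline$alt, truth$germline$pos)
      is_alt <- runif(length(gi)) < 0.5
      reads$base[gi] <- ifelse(is_alt, galt[as.character(reads$pos[gi])],
                               reads$ref[gi])
    }

    extra <- list()
    if (spike && nrow(truth$somatic) > 0) {
      for (i in seq_len(nrow(truth$somatic))) {
        s <- truth$somatic[i]
        mcells <- as.integer(strsplit(s$mutant_cell_ids, ",")[[1]])
        at_site <- which(reads$pos == s$pos)
        reads$base[at_site] <- reads$ref[at_site]   # wipe stray errors
        own <- at_site[reads$cell_type[at_site] == s$cell_type &
                         reads$cell[at_site] %in% mcells]
        if (length(own) > 0) {
          reads$base[own] <- ifelse(runif(length(own)) < 0.5, s$alt,
                                    reads$ref[own])
        }
        # guarantee >= 1 alt read in every designated mutant cell
        for (mc in mcells) {
          mine <- at_site[reads$cell_type[at_site] == s$cell_type &
                            reads$cell[at_site] == mc]
          if (length(mine) == 0) {
            extra[[length(extra) + 1L]] <- data.table(
              cell_type = s$cell_type, pos = s$pos, cell = mc,
              ref = s$ref, base = s$alt)
          } else if (!any(reads$base[mine] == s$alt)) {
            reads$base[mine[1]] <- s$alt
          }
        }
      }
      if (length(extra) > 0) reads <- rbindlist(c(list(reads), extra),
                                                use.names = TRUE)
    }

    # aggregate to per-cell counts
    reads[, barcode := sprintf("BC_%s_%04d", cell_type, cell)]
    cc <- data.table::dcast(
      reads[, .N, by = .(pos, ref, cell_type, barcode, base)],
      pos + ref + cell_type + barcode ~ base, value.var = "N", fill = 0L)
    for (b in BASES) if (!b %in% names(cc)) cc[, (b) := 0L]
    cc[, chrom := chrom]
    cc[, other := 0L]
    setorder(cc, pos, cell_type, barcode)
    data.table::setcolorder(cc, c("chrom", "pos", "ref", "cell_type",
                                  "barcode", BASES, "other"))
    list(cell_counts = cc[], truth = truth)
  })

  annotations <- data.table::CJ(cell_type = types, cell = seq_len(ncell))
  annotations[, barcode := sprintf("BC_%s_%04d", cell_type, cell)]
  annotations <- annotations[, .(barcode, cell_type,
                                 sample_id = sample_id)]
  list(cell_counts = out$cell_counts, truth = out$truth,
       annotations = annotations, config = config)
}

#' Simulate a sample end to end (reference + pileups)
#'
#' @inheritParams simulate_pileups
#' @param min_tract_len passed to [simulate_reference()].
#' @return list with `reference` plus all elements of [simulate_pileups()].
#' @export
simulate_sample <- function(config, min_tract_len = 4, sample_id = "sample1") {
  ref <- simulate_reference(config, min_tract_len = min_tract_len)
  sim <- simulate_pileups(config, ref, sample_id = sample_id)
  c(list(reference = ref), sim)
}

#' Simulate an unrelated normal panel sharing artefact loci
#'
#' Generates `n_samples` variant-free samples whose artefact-prone sites
#' (and their inflated error rates) coincide with those of `truth`,
#' emulating locus-intrinsic recurrent artefacts across unrelated
#' individuals.
#'
#' @param config a [sim_config()].
#' @param reference from [simulate_reference()].
#' @param truth truth set whose artefact sites are shared.
#' @param n_samples number of unrelated normal samples.
#' @param seed base seed; each sample uses an independent derived stream.
#' @return list of [simulate_pileups()] results.
#' @export
simulate_normal_panel <- function(config, reference, truth, n_samples = 5,
                                  seed = config$seed + 101L) {
  lapply(seq_len(n_samples), function(i) {
    simulate_pileups(config, reference, truth = truth,
                     sample_id = sprintf("normal%d", i),
                     seed = child_seed(seed, i))
  })
}

#' Draw beta-binomial (depth, alt) count pairs
#'
#' Exchangeable draws from the compound model: per-site error rate
#' `p ~ Beta(alpha, beta)`, alt count `~ Binomial(depth, p)`.
#'
#' @param alpha,beta beta shape parameters (> 0).
#' @param depths site depths (recycled to `n_sites`); all >= 1.
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return data.table with columns `depth`, `alt_count`.
#' @export
simulate_bb_counts <- function(alpha, beta, depths, n_sites = length(depths),
                               seed = 1) {
  check_that(alpha > 0 && beta > 0, "alpha and beta must be > 0")
  depths <- rep_len(as.integer(depths), n_sites)
  check_that(all(depths >= 1), "depths must be >= 1")
  with_seed(seed, {
    p <- rbeta(n_sites, alpha, beta)
    data.table(depth = depths, alt_count = rbinom(n_sites, depths, p))
  })
}
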