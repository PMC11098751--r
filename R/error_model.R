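# Beta-binomial background-error model.
#
# Non-reference counts k at homozygous-reference sites are modelled as
# Binomial(n, P) with the per-site error rate P ~ Beta(alpha, beta), i.e. k
# is beta-binomial. The one-sided upper tail of this distribution is the
# per-site significance test used for candidate detection.

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Beta-binomial log probability mass
#'
#' @param k non-reference (alt) counts.
#' @param n depths.
#' @param alpha,beta beta shape parameters, both > 0.
#' @return log P(K = k | n, alpha, beta), vectorized.
#' @export
bb_lpmf <- function(k, n, alpha, beta) {
  check_that(all(alpha > 0) && all(beta > 0), "alpha and beta must be > 0")
  lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

#' Beta-binomial probability mass
#' @inheritParams bb_lpmf
#' @return P(K = k | n, alpha, beta).
#' @export
bb_pmf <- function(k, n, alpha, beta) exp(bb_lpmf(k, n, alpha, beta))

#' One-sided upper-tail beta-binomial p-value
#'
#' Computes `P(K >= alt_count | depth, alpha, beta)` by exact summation of
#' the probability mass function; `bb_tail_pvalue(0, n, ...)` is exactly 1.
#' Summation runs from the largest mass terms downward in ordinary (linear)
#' space after a log-space mass evaluation, which keeps 12+ significant
#' digits at depths up to at least 1e5; there is no normal approximation.
#'
#' @param alt_count observed alt counts (vector), `0 <= alt_count <= depth`.
#' @param depth site depths (vector, recycled against `alt_count`).
#' @param model a `bb_model` from [fit_beta_binomial()], or `NULL` if
#'   `alpha`/`beta` are given directly.
#' @param alpha,beta shape parameters; ignored when `model` is supplied.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
#' @examples
#' bb_tail_pvalue(1, 1, alpha = 1, beta = 1)  # 0.5
bb_tail_pvalue <- function(alt_count, depth, model = NULL,
                           alpha = NULL, beta = NULL) {
  if (!is.null(model)) {
    alpha <- model$alpha
    beta <- model$beta
  }
  check_that(!is.null(alpha) && !is.null(beta),
             "supply either a model or alpha and beta")
  m <- max(length(alt_count), length(depth))
  alt_count <- rep_len(alt_count, m)
  depth <- rep_len(depth, m)
  check_that(all(depth >= 1), "depth must be >= 1")
  check_that(all(alt_count >= 0), "alt_count must be >= 0")
  if (any(alt_count > depth)) stop("alt_count exceeds depth", call. = FALSE)

  out <- numeric(m)
  # group by unique depth: one pmf evaluation per depth serves all its sites
  for (n in unique(depth)) {
    idx <- which(depth == n)
    pmf <- exp(bb_lpmf(0:n, n, alpha, beta))
    # tail[k+1] = P(K >= k); accumulate from the top for stability
    tail_p <- rev(cumsum(rev(pmf)))
    p <- tail_p[alt_count[idx] + 1L]
    p[alt_count[idx] == 0L] <- 1
    out[idx] <- pmin(p, 1)
  }
  out
}

# method-of-moments starting point for the likelihood fit
bb_moment_start <- function(k, n, w) {
  m <- sum(w * k) / sum(w * n)
  m <- min(max(m, 1e-8), 1 - 1e-8)
  f <- k / n
  mu_f <- sum(w * f) / sum(w)
  s2 <- sum(w * (f - mu_f)^2) / max(sum(w) - 1, 1)
  nbar <- sum(w * n) / sum(w)
  denom <- m * (1 - m) * (1 - 1 / nbar)
  rho <- if (denom > 0) (s2 - m * (1 - m) / nbar) / denom else 1e-4
  rho <- min(max(rho, 1e-6), 0.9)
  c(alpha = m * (1 - rho) / rho, beta = (1 - m) * (1 - rho) / rho)
}

#' Fit the beta-binomial background-error model
#'
#' Maximizes the beta-binomial log-likelihood over training (depth, alt)
#' pairs by Nelder-Mead on the log-parameter scale, starting from a
#' method-of-moments estimate. Identical (depth, alt) pairs are collapsed to
#' weighted unique combinations, so fitting a million shallow sites costs a
#' few dozen likelihood terms.
#'
#' @param training_counts a data.frame/data.table with columns `depth` and
#'   `alt_count` (one row per training site).
#' @param technology_label free-text label stored with the model.
#' @param beta_ceiling cap applied to `beta` when the fit degenerates (all
#'   alt counts zero).
#' @return an object of class `bb_model`: list with `alpha`, `beta`,
#'   `n_training_sites`, `fit_log_likelihood`, `convergence`,
#'   `technology_label`, `valid` and `mean_error`.
#' @export
fit_beta_binomial <- function(training_counts, technology_label = "generic",
                              beta_ceiling = 1e6) {
  tc <- as.data.table(training_counts)
  check_that(all(c("depth", "alt_count") %in% names(tc)),
             "training_counts needs columns depth, alt_count")
  tc <- tc[depth >= 1]
  check_that(nrow(tc) >= 1000,
             "at least 1000 training sites with depth >= 1 are required")
  agg <- tc[, .(w = .N), by = .(n = depth, k = alt_count)]

  if (sum(agg$k * agg$w) == 0) {
    warning("all training alt counts are zero; returning capped model")
    model <- structure(list(
      alpha = 1, beta = beta_ceiling, n_training_sites = nrow(tc),
      fit_log_likelihood = 0, convergence = NA_integer_,
      technology_label = technology_label, valid = FALSE,
      mean_error = 1 / (1 + beta_ceiling)), class = "bb_model")
    return(model)
  }

  start <- bb_moment_start(agg$k, agg$n, agg$w)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b)) return(1e18)
    -sum(agg$w * bb_lpmf(agg$k, agg$n, a, b))
  }
  fit <- optim(log(pmax(start, 1e-8)), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  alpha <- exp(fit$par[1]); beta <- exp(fit$par[2])
  ll <- -fit$value
  ll_start <- -nll(log(pmax(start, 1e-8)))
  if (ll < ll_start) {           # optimizer contract: never worse than start
    alpha <- start[["alpha"]]; beta <- start[["beta"]]; ll <- ll_start
  }
  mean_error <- alpha / (alpha + beta)
  valid <- is.finite(alpha) && is.finite(beta) && alpha > 0 && beta > 0 &&
    mean_error > 0 && mean_error < 0.5
  if (!valid) {
    warning(sprintf(
      "fitted mean error rate %.3g is outside (0, 0.5); model flagged invalid",
      mean_error))
  }
  structure(list(
    alpha = unname(alpha), beta = unname(beta),
    n_training_sites = nrow(tc), fit_log_likelihood = unname(ll),
    convergence = fit$convergence, technology_label = technology_label,
    valid = valid, mean_error = unname(mean_error)), class = "bb_model")
}

#' @export
print.bb_model <- function(x, ...) {
  cat(sprintf(
    "Beta-binomial error model [%s]\n  alpha = %.6g, beta = %.6g (mean error %.3g)\n  fitted on %d sites, logLik %.2f%s\n",
    x$technology_label, x$alpha, x$beta, x$mean_error,
    x$n_training_sites, x$fit_log_likelihood,
    if (isTRUE(x$valid)) "" else "  [INVALID]"))
  invisible(x)
}

#' Sample training sites from a panel of normals' counts
#'
#' Selects homozygous-reference-like sites for error-model training and
#' draws a uniform random subsample. Only sites with no variant evidence
#' beyond sequencing noise are eligible; two exclusion rules implement
#' this. A site is germline-variant-like when it has at least two alt
#' reads and its alt count is not significantly below a heterozygous (50%)
#' allele fraction (one-sided binomial test at `het_p`). A site carries
#' evidence beyond noise when its alt count is significantly above a
#' conservative error-rate ceiling (`error_ceiling`, one-sided binomial
#' test at `het_p`); this keeps recurrent-artefact loci out of the
#' background fit — they are the panel of normals' concern, not the error
#' model's.
#'
#' @param normal_panel_counts data.frame/data.table with columns `depth`,
#'   `alt_count` (one row per site).
#' @param n maximum number of training sites to return (all eligible sites
#'   if fewer).
#' @param seed integer seed; identical seed gives an identical sample.
#' @param het_p significance level for both eligibility tests.
#' @param error_ceiling upper bound on the plausible per-base error rate.
#' @return data.table with columns `depth`, `alt_count`.
#' @export
sample_training_sites <- function(normal_panel_counts, n = 1e6, seed = 1,
                                  het_p = 1e-3, error_ceiling = 0.01) {
  pc <- as.data.table(normal_panel_counts)
  check_that(nrow(pc) > 0, "empty panel")
  check_that(all(c("depth", "alt_count") %in% names(pc)),
             "panel counts need columns depth, alt_count")
  pc <- pc[depth >= 1]
  # keep a site when alt evidence is absent, or clearly below heterozygous
  below_het <- stats::pbinom(pc$alt_count, pc$depth, 0.5) < het_p
  # ... and not significantly above the noise ceiling
  beyond_noise <- stats::pbinom(pc$alt_count - 1L, pc$depth, error_ceiling,
                                lower.tail = FALSE) < het_p
  eligible <- pc[(alt_count < 2 | below_het) & !beyond_noise]
  if (nrow(eligible) <= n) return(eligible[, .(depth, alt_count)])
  idx <- with_seed(seed, sample.int(nrow(eligible), n))
  eligible[sort(idx), .(depth, alt_count)]
}

#' Write / read a fitted model as a plain-text parameter file
#'
#' The file is a 2-column TSV (`parameter`, `value`) preceded by `#` comment
#' lines recording provenance.
#'
#' @param model a `bb_model`.
#' @param path file path.
#' @return `write_bb_model()` returns `path` invisibly; `read_bb_model()`
#'   returns a `bb_model`.
#' @export
write_bb_model <- function(model, path) {
  lines <- c(
    sprintf("# beta-binomial error model (%s)", model$technology_label),
    sprintf("# n_training_sites=%d logLik=%.6f valid=%s",
            model$n_training_sites, model$fit_log_likelihood, model$valid),
    sprintf("alpha\t%.12g", model$alpha),
    sprintf("beta\t%.12g", model$beta))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bb_model
#' @export
read_bb_model <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  vals <- setNames(as.numeric(kv[, 2]), kv[, 1])
  structure(list(alpha = vals[["alpha"]], beta = vals[["beta"]],
                 n_training_sites = NA_integer_,
                 fit_log_likelihood = NA_real_, convergence = NA_integer_,
                 technology_label = "from_file",
                 valid = vals[["alpha"]] > 0 && vals[["beta"]] > 0,
                 mean_error = vals[["alpha"]] / (vals[["alpha"]] + vals[["beta"]])),
            class = "bb_model")
}
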