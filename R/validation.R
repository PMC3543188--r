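#' k-fold cross-validation of phenotype prediction
#'
#' Randomly splits the phenotyped individuals into `k` folds of as-equal-as
#' possible size.  For each fold the held-out phenotypes are masked (set to
#' `NA`) while the individuals stay in the pedigree and covariate blocks,
#' the complete model — including all variance parameters — is re-estimated
#' on the remaining folds, and the held-out phenotypes are predicted as
#' `mu_hat + X b_hat + Z u_hat + W a_hat + Q g_hat` from posterior means.
#' Pooled over all folds, the function reports the correlation `rho`
#' between predicted and actual phenotypes and the calibration slope
#' `beta`: the regression coefficient of actual phenotypes on the
#' predictions, `cov(y, yhat) / var(yhat)`.  For calibrated Bayesian
#' posterior-mean predictions this slope is 1 — predictions are neither
#' over- nor under-dispersed — which validates the assessed explained
#' variances.  (The transposed regression, predicted on actual, has
#' expectation `rho^2`, not 1, and is not a calibration check; both
#' slopes are returned, as `beta` and `beta_transposed`.)
#'
#' @param dataset an `ov_dataset` (or any list with `pedigree`,
#'   `genotypes`, `map`, `expressions`, `phenotypes`).
#' @param spec an [model_spec()]; per-fold chains reuse its settings and
#'   seed.
#' @param k number of folds.
#' @param fold_seed seed for the fold randomization, independent of the
#'   MCMC seed.
#' @param fitter optional override for testing: a
#'   `function(blocks, y_masked, spec)` returning a prediction vector over
#'   all individuals in `blocks`.
#' @return an object of class `ov_cv`: list with `predictions` (data.frame
#'   `id`, `fold`, `actual`, `predicted`), `rho`, `beta`, `folds`
#'   (per-fold rho), `k`.
#' @export
crossvalidate <- function(dataset, spec = model_spec(), k = 11L,
                          fold_seed = 1L, fitter = NULL) {
  stopifnot(k >= 2L)
  blocks <- design_blocks(dataset$phenotypes, dataset$pedigree,
                          dataset$genotypes, dataset$map,
                          dataset$expressions, components = spec$components)
  y <- blocks$y
  ph_idx <- which(!is.na(y))
  n <- length(ph_idx)
  if (n < k) stop("fewer phenotyped individuals than folds")
  set.seed(fold_seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  pred <- rep(NA_real_, length(y))
  if (is.null(fitter)) {
    fitter <- function(blocks, y_masked, spec) {
      fit <- if (spec$prior_snp == "mixture" || spec$prior_gex == "mixture") {
        run_bvs(y_masked, blocks, spec = spec)
      } else run_mixed_model(y_masked, blocks, spec = spec)
      predict(fit)
    }
  }
  for (f in seq_len(k)) {
    held <- ph_idx[fold == f]
    y_masked <- y
    y_masked[held] <- NA
    p <- fitter(blocks, y_masked, spec)
    pred[held] <- p[held]
  }
  actual <- y[ph_idx]; predicted <- pred[ph_idx]
  rho <- cor(predicted, actual)
  beta <- unname(coef(lm(actual ~ predicted))[2L])
  structure(list(
    predictions = data.frame(id = blocks$ids[ph_idx], fold = fold,
                             actual = actual, predicted = predicted),
    rho = rho, beta = beta,
    beta_transposed = unname(coef(lm(predicted ~ actual))[2L]), k = k,
    folds = vapply(seq_len(k), function(f) suppressWarnings(
      cor(predicted[fold == f], actual[fold == f])), 0)),
    class = "ov_cv")
}

#' @export
print.ov_cv <- function(x, ...) {
  cat(sprintf("ov_cv: %d-fold, n = %d\n  rho  = %.3f\n  beta = %.3f (calibration slope, actual on predicted)\n",
              x$k, nrow(x$predictions), x$rho, x$beta))
  invisible(x)
}

#' Effective sample size of a scalar MCMC trace
#'
#' Initial-positive-sequence estimator: autocovariances are summed in
#' adjacent pairs `(gamma_{2k} + gamma_{2k+1})` until a pair sum goes
#' negative, giving `ESS = N / (1 + 2 * sum(rho_k))`.  A constant
#' (degenerate) trace is reported as `ESS = N` with a `degenerate` flag.
#'
#' @param chain numeric trace of length >= 100.
#' @return ESS (numeric scalar) with attribute `degenerate`.
#' @export
ess <- function(chain) {
  N <- length(chain)
  if (N < 100L) stop("trace too short for an ESS estimate (need >= 100)")
  if (sd(chain) == 0) {
    return(structure(as.numeric(N), degenerate = TRUE))
  }
  ac <- stats::acf(chain, lag.max = N - 1L, plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  s <- 0
  k <- 1L
  while (k + 1L < length(ac)) {
    pair <- ac[k + 1L] + ac[k + 2L]   # rho_k + rho_{k+1} (ac[1] is lag 0)
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  structure(min(as.numeric(N), N / (1 + 2 * s)), degenerate = FALSE)
}

#' Monte-Carlo accuracy by repeated MCMC runs
#'
#' Runs the same model twice with different seeds and correlates the
#' posterior-mean effect vectors `u`, `a`, `g` between the runs; the chain
#' is considered accurate when every correlation exceeds 0.999.  Also
#' reports the effective sample sizes of the variance-component traces of
#' the first run.
#'
#' @param blocks an [design_blocks()] object.
#' @param spec an [model_spec()]; its seed slot is replaced by
#'   `seed1`/`seed2`.
#' @param seed1,seed2 two distinct chain seeds.
#' @param y optional phenotype override (defaults to `blocks$y`).
#' @return list with `correlations` (named, one per fitted effect vector),
#'   `pass` (all > 0.999), `ess` (per variance parameter, run 1), and the
#'   two fits.
#' @export
repeated_run_correlation <- function(blocks, spec = model_spec(),
                                     seed1 = 11L, seed2 = 12L, y = NULL) {
  if (seed1 == seed2) stop("seeds must differ")
  run <- function(sd) {
    sp <- spec; sp$seed <- as.integer(sd)
    if (sp$prior_snp == "mixture" || sp$prior_gex == "mixture") {
      run_bvs(y, blocks, spec = sp)
    } else run_mixed_model(y, blocks, spec = sp)
  }
  f1 <- run(seed1); f2 <- run(seed2)
  cors <- c(
    u = if (!is.null(f1$samples$u))
      cor(colMeans(f1$samples$u), colMeans(f2$samples$u)),
    a = if (!is.null(f1$samples$a))
      cor(colMeans(f1$samples$a), colMeans(f2$samples$a)),
    g = if (!is.null(f1$samples$g))
      cor(colMeans(f1$samples$g), colMeans(f2$samples$g)))
  if (!length(cors)) stop("no effect vectors fitted; nothing to correlate")
  list(correlations = cors, pass = all(cors > 0.999),
       ess = apply(f1$samples$variances, 2L, function(tr) as.numeric(ess(tr))),
       fit1 = f1, fit2 = f2)
}

#' Rank concordance of per-individual predictions across data layers
#'
#' Spearman rank-correlation matrix among the posterior-mean per-individual
#' values of the characteristic component of each fit (polygenic `Zu` for a
#' PED fit, `Wa` for SNP, `Qg` for GEX), computed over the shared
#' individuals.  Ties get average ranks (the default of the Spearman
#' correlation used).
#'
#' @param fits named list of `ov_fit` objects (typically single-component
#'   fits) sharing an individual set.
#' @return symmetric matrix of Spearman correlations with unit diagonal.
#' @export
component_concordance <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L, !is.null(names(fits)))
  vals <- lapply(fits, function(f) {
    s <- f$samples; bl <- f$blocks
    v <- if (!is.null(s$u)) colMeans(s$u)[bl$zmap + 1L]
    else if (!is.null(s$a)) drop(bl$W %*% colMeans(s$a))
    else if (!is.null(s$g)) drop(bl$Q %*% colMeans(s$g))
    else stop("fit has no random-effect component")
    setNames(v, bl$ids)
  })
  ids <- Reduce(intersect, lapply(vals, names))
  if (length(ids) < 3L) stop("fewer than 3 shared individuals across fits")
  M <- vapply(vals, function(v) v[ids], numeric(length(ids)))
  cor(M, method = "spearman")
}
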