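#' Chain settings for the Gibbs samplers
#'
#' Chain settings for the Gibbs samplers.  The defaults (100,000 cycles,
#' 10,000 burn-in, thinning 5) are calibrated so that repeated runs of the
#' full model on the bundled synthetic fixture reproduce the posterior-mean
#' effect vectors with correlation above 0.999
#' ([repeated_run_correlation()]); shorter exploratory chains are fine for
#' prototyping but [repeated_run_correlation()] should be consulted before
#' trusting their partitions.
#'
#' @param n_iter total MCMC cycles.
#' @param burn_in cycles discarded before storage.
#' @param thin storage interval; retained draws are
#'   `(n_iter - burn_in) / thin`.
#' @return a list of class `ov_chain`.
#' @export
chain_control <- function(n_iter = 100000L, burn_in = 10000L, thin = 5L) {
  stopifnot(n_iter > burn_in, burn_in >= 0L, thin >= 1L,
            (n_iter - burn_in) >= thin)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)), class = "ov_chain")
}

#' Model specification for the whole-omics regressions
#'
#' Describes which data layers enter the model
#' `y = 1 mu + X b + Z u + W a + Q g + e`, which prior family the SNP and
#' expression coefficient vectors get, the fixed inclusion probabilities of
#' the mixture priors, and the chain settings.
#'
#' Components: `"PED"` fits the polygenic vector `u ~ N(0, A sigma_u2)`
#' through the pedigree relationship matrix, `"SNP"` the marker coefficients
#' `a`, `"GEX"` the transcript coefficients `g`.  Under `"normal"` priors all
#' coefficients in a block share one variance (Bayesian mixed model); under
#' `"mixture"` each coefficient gets a two-component normal mixture with
#' inclusion indicator (Bayesian variable selection).  The mixture prior is
#' only available for the SNP and GEX blocks, never for `u`.  The inclusion
#' probabilities `pi_a`, `pi_g` are treated as known constants.
#'
#' @param components character subset of `c("PED", "SNP", "GEX")`.
#' @param prior_snp,prior_gex `"normal"` or `"mixture"`.
#' @param pi_a,pi_g prior inclusion probabilities, fixed, in (0, 1).
#' @param chain an [chain_control()] object.
#' @param seed integer seed making the chain bit-reproducible.
#' @param variance_prior `list(nu = 0, s2 = 0)` for the default flat prior on
#'   all variance components, or positive `nu`, `s2` for a proper
#'   scaled-inverse-chi-square prior.
#' @return a list of class `ov_spec`.
#' @export
model_spec <- function(components = c("PED", "SNP", "GEX"),
                       prior_snp = "normal", prior_gex = "normal",
                       pi_a = 0.05, pi_g = 0.05,
                       chain = chain_control(), seed = 1L,
                       variance_prior = list(nu = 0, s2 = 0)) {
  components <- match.arg(components, c("PED", "SNP", "GEX"),
                          several.ok = TRUE)
  prior_snp <- match.arg(prior_snp, c("normal", "mixture"))
  prior_gex <- match.arg(prior_gex, c("normal", "mixture"))
  stopifnot(pi_a > 0, pi_a <= 1, pi_g > 0, pi_g <= 1,
            inherits(chain, "ov_chain"))
  structure(list(components = components, prior_snp = prior_snp,
                 prior_gex = prior_gex, pi_a = pi_a, pi_g = pi_g,
                 chain = chain, seed = as.integer(seed),
                 variance_prior = variance_prior), class = "ov_spec")
}

#' Assemble aligned design blocks for a model fit
#'
#' Aligns phenotype, pedigree, genotype and expression inputs on shared
#' individual ids (intersection, reported), builds the cornerstone-coded
#' fixed-effect design for batch and sex (first level dropped), centers and
#' scales the covariate blocks, and records the pedigree incidence mapping.
#' Individuals with a missing trait value are kept in all matrices but
#' excluded from the likelihood (their polygenic value is still predicted
#' through the relationship matrix).
#'
#' @param phenotypes data.frame with columns `id`, `trait`, `batch`, `sex`
#'   (`trait` may contain `NA`).
#' @param pedigree an `ov_pedigree` (required when `"PED"` is requested).
#' @param genotypes numeric matrix of SNP dosages, rownames = individual ids.
#' @param map data.frame with columns `snp_id`, `chr`, `pos` matching the
#'   genotype columns in map order.
#' @param expressions numeric matrix of transcript abundances, rownames =
#'   individual ids.
#' @param components which of PED/SNP/GEX the blocks must support.
#' @param scale center and scale the covariate blocks to unit variance
#'   (the default, matching the models' prior scale).
#' @return a list of class `ov_blocks` with elements `y`, `obs` (logical
#'   likelihood mask), `X`, `zmap` (0-based pedigree index per row),
#'   `n_ped`, `ped_ids`, `Ainv`, `W`, `Q`, `map`, `ids`.
#' @export
design_blocks <- function(phenotypes, pedigree = NULL, genotypes = NULL,
                          map = NULL, expressions = NULL,
                          components = c("PED", "SNP", "GEX"),
                          scale = TRUE) {
  stopifnot(all(c("id", "trait") %in% names(phenotypes)))
  components <- intersect(components, c("PED", "SNP", "GEX"))
  ids <- as.character(phenotypes$id)
  if (anyDuplicated(ids)) stop("duplicate individual ids in phenotypes")
  n0 <- length(ids)
  if ("SNP" %in% components) {
    if (is.null(genotypes)) stop("SNP component requested without genotypes")
    ids <- intersect(ids, rownames(genotypes))
  }
  if ("GEX" %in% components) {
    if (is.null(expressions)) stop("GEX component requested without expressions")
    ids <- intersect(ids, rownames(expressions))
  }
  if ("PED" %in% components) {
    if (is.null(pedigree)) stop("PED component requested without a pedigree")
    ids <- intersect(ids, pedigree$id)
  }
  if (length(ids) < n0) {
    message("design_blocks: ", n0 - length(ids),
            " individual(s) dropped when intersecting input ids")
  }
  ph <- phenotypes[match(ids, as.character(phenotypes$id)), , drop = FALSE]
  y <- as.numeric(ph$trait)
  obs <- !is.na(y)

  fx <- list()
  if (!is.null(ph$batch) && length(unique(ph$batch)) > 1L) {
    fx$batch <- factor(ph$batch)
  }
  if (!is.null(ph$sex) && length(unique(ph$sex)) > 1L) fx$sex <- factor(ph$sex)
  X <- if (length(fx)) {
    stats::model.matrix(~., data = as.data.frame(fx))[, -1L, drop = FALSE]
  } else matrix(0, length(ids), 0L)
  rownames(X) <- ids

  zmap <- integer(0); n_ped <- 0L; ped_ids <- character(0); Ainv <- NULL
  if ("PED" %in% components) {
    n_ped <- nrow(pedigree)
    ped_ids <- pedigree$id
    zmap <- match(ids, ped_ids) - 1L
    Ainv <- a_inverse(pedigree)
  }
  W <- NULL; map_out <- NULL
  if ("SNP" %in% components) {
    W <- center_scale(genotypes[ids, , drop = FALSE], scale = scale)
    if (!is.null(map)) {
      map_out <- map[match(colnames(W), map$snp_id), , drop = FALSE]
      if (anyNA(map_out$chr)) {
        stop("SNP(s) missing from the map: ",
             paste(colnames(W)[is.na(map_out$chr)], collapse = ", "))
      }
    }
  }
  Q <- NULL
  if ("GEX" %in% components) {
    Q <- center_scale(expressions[ids, , drop = FALSE], scale = scale)
  }
  structure(list(y = y, obs = obs, X = X, zmap = zmap, n_ped = n_ped,
                 ped_ids = ped_ids, Ainv = Ainv, W = W, Q = Q,
                 map = map_out, ids = ids, components = components),
            class = "ov_blocks")
}

#' Fit the Bayesian mixed model (normal priors on u, a, g)
#'
#' Single-site Gibbs sampler for `y = 1 mu + X b + Z u + W a + Q g + e`
#' where every requested effect vector carries a normal prior
#' (`u ~ N(0, A sigma_u2)`, `a ~ N(0, I sigma_s2)`, `g ~ N(0, I sigma_g2)`,
#' `e ~ N(0, I sigma_e2)`), `mu` and `b` carry flat priors, and the four
#' variances carry flat priors (full conditionals drawn with
#' [sample_variance_flat()]'s inverse-gamma form).  The residual vector is
#' maintained incrementally and refreshed from scratch every 100 cycles.
#'
#' @param y phenotype vector; if `NULL`, taken from `blocks$y`.  `NA` entries
#'   are excluded from the likelihood but predicted.
#' @param blocks an [design_blocks()] object.
#' @param Ainv sparse inverse relationship matrix; if `NULL`, taken from
#'   `blocks$Ainv`.
#' @param spec an [model_spec()]; its `prior_snp`/`prior_gex` must be
#'   `"normal"`.
#' @param fixed_variances optional named list pinning any of `sigma_u2`,
#'   `sigma_s2`, `sigma_g2`, `sigma_e2` at a constant (used for
#'   conjugate-oracle checks).
#' @return an object of class `ov_fit` holding the retained posterior draws
#'   (see Details in [variance_partition()]).
#' @export
run_mixed_model <- function(y = NULL, blocks, Ainv = NULL,
                            spec = model_spec(), fixed_variances = NULL) {
  if (spec$prior_snp != "normal" || spec$prior_gex != "normal") {
    stop("run_mixed_model requires normal priors; use run_bvs for mixtures")
  }
  fit_gibbs(y, blocks, Ainv, spec, fixed_variances)
}

#' Fit the Bayesian variable-selection model (mixture priors on a and/or g)
#'
#' As [run_mixed_model()], but the SNP and/or expression coefficients carry
#' the two-component normal-mixture prior of [update_mixture_indicator()]:
#' per cycle the 0/1 indicators are Gibbs-updated, coefficients are drawn
#' with the slab or spike variance selected by their indicator, and the slab
#' and spike variances are drawn from the effects currently in each class
#' under flat priors with the identifiability constraint `tau1sq > tau0sq`
#' enforced by a rejection sampler (redraw both up to 100 attempts, then
#' carry the previous pair; rejections are counted in `fit$meta`).  An empty
#' mixture class carries its variance over unchanged that cycle.  The spike
#' variance is floored at `1e-10 * var(y)`.
#'
#' @inheritParams run_mixed_model
#' @export
run_bvs <- function(y = NULL, blocks, Ainv = NULL,
                    spec = model_spec(prior_snp = "mixture",
                                      prior_gex = "mixture"),
                    fixed_variances = NULL) {
  if (spec$prior_snp != "mixture" && spec$prior_gex != "mixture") {
    stop("run_bvs requires a mixture prior on the SNP and/or GEX block")
  }
  fit_gibbs(y, blocks, Ainv, spec, fixed_variances)
}

fit_gibbs <- function(y, blocks, Ainv, spec, fixed_variances = NULL) {
  stopifnot(inherits(blocks, "ov_blocks"), inherits(spec, "ov_spec"))
  if (is.null(y)) y <- blocks$y
  n_all <- length(blocks$ids)
  if (length(y) != n_all) stop("y length does not match the design blocks")
  obs <- !is.na(y)
  if (sum(obs) < 10L) stop("fewer than 10 observed phenotypes")

  use_ped <- "PED" %in% spec$components && blocks$n_ped > 0L
  use_snp <- "SNP" %in% spec$components && !is.null(blocks$W)
  use_gex <- "GEX" %in% spec$components && !is.null(blocks$Q)
  if ("PED" %in% spec$components && !use_ped) {
    stop("spec requests PED but blocks carry no pedigree")
  }
  if ("SNP" %in% spec$components && !use_snp) {
    stop("spec requests SNP but blocks carry no genotype block")
  }
  if ("GEX" %in% spec$components && !use_gex) {
    stop("spec requests GEX but blocks carry no expression block")
  }
  if (use_ped) {
    if (is.null(Ainv)) Ainv <- blocks$Ainv
    if (is.null(Ainv)) stop("PED component requires the sparse A-inverse")
    Ainv <- methods::as(methods::as(Ainv, "generalMatrix"), "CsparseMatrix")
    if (any(Matrix::diag(Ainv) <= 0)) {
      stop("A-inverse is not positive definite (non-positive diagonal)")
    }
  }

  Xo <- blocks$X[obs, , drop = FALSE]
  keep_x <- colSums(Xo^2) > 0
  if (!all(keep_x)) {
    warning("dropping fixed-effect level(s) unobserved in the training ",
            "phenotypes: ", paste(colnames(Xo)[!keep_x], collapse = ", "))
    Xo <- Xo[, keep_x, drop = FALSE]
  }
  Wo <- if (use_snp) blocks$W[obs, , drop = FALSE] else
    matrix(0, sum(obs), 0L)
  Qo <- if (use_gex) blocks$Q[obs, , drop = FALSE] else
    matrix(0, sum(obs), 0L)
  zo <- if (use_ped) blocks$zmap[obs] else integer(0)

  fv <- rep(NA_real_, 4L)
  if (!is.null(fixed_variances)) {
    nm <- c("sigma_u2", "sigma_s2", "sigma_g2", "sigma_e2")
    bad <- setdiff(names(fixed_variances), nm)
    if (length(bad)) stop("unknown fixed variance(s): ", paste(bad, collapse = ", "))
    fv[match(names(fixed_variances), nm)] <- unlist(fixed_variances)
  }

  mix_a <- use_snp && spec$prior_snp == "mixture"
  mix_g <- use_gex && spec$prior_gex == "mixture"
  ch <- spec$chain
  set.seed(spec$seed)
  raw <- gibbs_core(y[obs], Xo, zo, blocks$n_ped,
                    if (use_ped) Ainv@i else integer(0),
                    if (use_ped) Ainv@p else integer(1),
                    if (use_ped) Ainv@x else numeric(0),
                    Wo, Qo, mix_a, mix_g, spec$pi_a, spec$pi_g,
                    ch$n_iter, ch$burn_in, ch$thin,
                    spec$variance_prior$nu, spec$variance_prior$s2, fv)

  # re-embed fixed effects dropped for the training subset as zero columns
  b <- matrix(0, nrow(raw$b), ncol(blocks$X),
              dimnames = list(NULL, colnames(blocks$X)))
  if (ncol(Xo)) b[, colnames(Xo)] <- raw$b
  colnames(raw$variances) <- c("sigma_u2", "sigma_s2", "sigma_g2", "sigma_e2",
                               "tau_a1", "tau_a0", "tau_g1", "tau_g0")
  vkeep <- c("sigma_e2",
             if (use_ped) "sigma_u2",
             if (use_snp && !mix_a) "sigma_s2",
             if (mix_a) c("tau_a1", "tau_a0"),
             if (use_gex && !mix_g) "sigma_g2",
             if (mix_g) c("tau_g1", "tau_g0"))
  samples <- list(
    mu = raw$mu, b = b,
    u = if (use_ped) `colnames<-`(raw$u, blocks$ped_ids) else NULL,
    a = if (use_snp) `colnames<-`(raw$a, colnames(blocks$W)) else NULL,
    g = if (use_gex) `colnames<-`(raw$g, colnames(blocks$Q)) else NULL,
    gamma_a = if (mix_a) `colnames<-`(raw$gamma_a, colnames(blocks$W)) else NULL,
    gamma_g = if (mix_g) `colnames<-`(raw$gamma_g, colnames(blocks$Q)) else NULL,
    variances = raw$variances[, vkeep, drop = FALSE])
  structure(list(samples = samples, spec = spec, blocks = blocks, y = y,
                 obs = obs,
                 meta = list(seed = spec$seed, chain = unclass(ch),
                             components = spec$components,
                             mixture = c(snp = mix_a, gex = mix_g),
                             n_retained = length(raw$mu),
                             n_obs = sum(obs),
                             rejections = c(a = raw$n_reject_a,
                                            g = raw$n_reject_g),
                             empty_class_carryovers = raw$n_carry)),
            class = "ov_fit")
}

#' @export
print.ov_fit <- function(x, ...) {
  cat("ov_fit:", paste(x$meta$components, collapse = " + "),
      if (any(x$meta$mixture)) "(variable selection)" else "(mixed model)",
      "\n")
  cat(sprintf("  %d observed phenotypes, %d retained draws (chain %d/%d/thin %d, seed %d)\n",
              x$meta$n_obs, x$meta$n_retained, x$meta$chain$n_iter,
              x$meta$chain$burn_in, x$meta$chain$thin, x$meta$seed))
  vp <- variance_partition(x, by_chromosome = FALSE)
  print(vp$components, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Posterior-mean phenotype predictions
#'
#' `mu_hat + X b_hat + Z u_hat + W a_hat + Q g_hat` using posterior means of
#' all effects; rows without an observed phenotype are predicted through
#' their covariates and their pedigree-propagated polygenic value.
#'
#' @param object an `ov_fit`.
#' @param ... unused.
#' @return named numeric vector over all individuals in the fit's blocks.
#' @export
predict.ov_fit <- function(object, ...) {
  s <- object$samples; bl <- object$blocks
  pred <- rep(mean(s$mu), length(bl$ids))
  if (ncol(bl$X)) pred <- pred + drop(bl$X %*% colMeans(s$b))
  if (!is.null(s$u)) pred <- pred + colMeans(s$u)[bl$zmap + 1L]
  if (!is.null(s$a)) pred <- pred + drop(bl$W %*% colMeans(s$a))
  if (!is.null(s$g)) pred <- pred + drop(bl$Q %*% colMeans(s$g))
  setNames(pred, bl$ids)
}
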