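# helper: hand-built blocks for covariate-only models
bare_blocks <- function(y, W) {
  structure(list(y = y, obs = !is.na(y), X = matrix(0, length(y), 0L),
                 zmap = integer(0), n_ped = 0L, ped_ids = character(0),
                 Ainv = NULL, W = W, Q = NULL, map = NULL,
                 ids = as.character(seq_along(y)), components = "SNP"),
            class = "ov_blocks")
}

test_that("with fixed variances the Gibbs posterior matches the conjugate closed form", {
  set.seed(10)
  n <- 20L
  W <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("w1", "w2", "w3")))
  y <- 1 + W %*% c(0.8, -0.5, 0.2) + rnorm(n, sd = 1)
  y <- drop(y)
  se2 <- 1; tau2 <- 1
  fit <- run_mixed_model(y, bare_blocks(y, W),
                         spec = model_spec(components = "SNP",
                                           chain = chain_control(42000, 2000, 2),
                                           seed = 99),
                         fixed_variances = list(sigma_s2 = tau2, sigma_e2 = se2))
  # closed form over (mu, a) with flat prior on mu
  post <- conjugate_posterior(y, cbind(1, W), se2, c(0, rep(1 / tau2, 3)))
  draws <- cbind(fit$samples$mu, fit$samples$a)
  ess_i <- apply(draws, 2, function(tr) as.numeric(ess(tr)))
  mc_se <- apply(draws, 2, sd) / sqrt(ess_i)
  expect_true(all(abs(colMeans(draws) - post$mean) < 3 * mc_se))
  # posterior covariance of the coefficients within Monte-Carlo error
  emp_cov <- cov(draws)
  se_cov <- outer(apply(draws, 2, sd), apply(draws, 2, sd)) *
    sqrt(2 / min(ess_i))
  expect_true(all(abs(emp_cov - post$cov) < 4 * se_cov))
})

test_that("identical spec and seed give bit-identical posterior samples", {
  bl <- fixture_blocks()
  sp <- model_spec(chain = quick_chain(2000, 500, 5), seed = 123)
  f1 <- run_mixed_model(NULL, bl, spec = sp)
  f2 <- run_mixed_model(NULL, bl, spec = sp)
  expect_identical(f1$samples, f2$samples)
  spb <- model_spec(prior_snp = "mixture", prior_gex = "mixture",
                    chain = quick_chain(2000, 500, 5), seed = 123)
  b1 <- run_bvs(NULL, bl, spec = spb)
  b2 <- run_bvs(NULL, bl, spec = spb)
  expect_identical(b1$samples, b2$samples)
})

test_that("a pure-noise phenotype yields near-zero explained variance", {
  cfg <- sim_config(n_f2 = 300, snps_per_chr = 20, n_probes = 200,
                    fractions = c(polygenic = 0, direct_snp = 0, mediated = 0),
                    seed = 31)
  ds <- simulate_dataset(cfg)
  bl <- design_blocks(ds$phenotypes, ds$pedigree, ds$genotypes, ds$map,
                      ds$expressions)
  fit <- run_mixed_model(NULL, bl, spec = model_spec(chain = quick_chain(),
                                                     seed = 32))
  vp <- variance_partition(fit, by_chromosome = FALSE)$components
  genetic <- sum(vp$pm[vp$component %in% c("PED", "SNP", "GEX")])
  expect_lt(genetic / sum(vp$pm), 0.15)
  res <- vp$pm[vp$component == "residual"]
  expect_lt(abs(res - 1), 3 * vp$psd[vp$component == "residual"] + 0.1)
})

test_that("permuting SNP columns permutes the coefficient posterior accordingly", {
  set.seed(20)
  n <- 150L; m <- 30L
  W <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(NULL, paste0("s", 1:m)))
  y <- drop(scale(W[, 5]) * 0.6 + scale(W[, 20]) * 0.4 + rnorm(n, sd = 0.8))
  perm <- sample(m)
  ch <- chain_control(30000, 5000, 5)
  f1 <- run_mixed_model(y, bare_blocks(y, center_scale(W)),
                        spec = model_spec(components = "SNP", chain = ch, seed = 5))
  f2 <- run_mixed_model(y, bare_blocks(y, center_scale(W[, perm])),
                        spec = model_spec(components = "SNP", chain = ch, seed = 5))
  pm1 <- colMeans(f1$samples$a); pm2 <- colMeans(f2$samples$a)
  # single-site updates consume randomness in column order, so equality is
  # distributional: permuted posterior means agree within Monte-Carlo error
  expect_gt(cor(pm1[perm], pm2), 0.999)
  expect_lt(max(abs(pm1[perm] - pm2)), 0.02)
})

test_that("the BVS chain honours the slab/spike constraint and finds large effects", {
  set.seed(40)
  n <- 250L; m <- 200L
  W <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(NULL, paste0("s", 1:m)))
  Ws <- center_scale(W)
  true_idx <- c(10L, 50L, 90L, 130L, 170L)
  hits <- vapply(1:10, function(rep) {
    set.seed(40 + rep)
    y <- drop(Ws[, true_idx] %*% rep(0.45, 5) + rnorm(n))
    fit <- run_bvs(y, bare_blocks(y, Ws),
                   spec = model_spec(components = "SNP", prior_snp = "mixture",
                                     pi_a = 0.05, chain = quick_chain(),
                                     seed = 500 + rep))
    v <- fit$samples$variances
    expect_true(all(v[, "tau_a1"] > v[, "tau_a0"]))
    pip <- colMeans(fit$samples$gamma_a)
    mean(pip[true_idx]) > mean(pip[-true_idx])
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("a degenerate mixture (pi = 1) reproduces the mixed model's explained variance", {
  set.seed(50)
  n <- 200L; m <- 60L
  W <- center_scale(matrix(rbinom(n * m, 2, 0.5), n, m,
                           dimnames = list(NULL, paste0("s", 1:m))))
  y <- drop(W[, 1:6] %*% rep(0.3, 6) + rnorm(n))
  ch <- chain_control(20000, 5000, 5)
  fm <- run_mixed_model(y, bare_blocks(y, W),
                        spec = model_spec(components = "SNP", chain = ch, seed = 7))
  fb <- run_bvs(y, bare_blocks(y, W),
                spec = model_spec(components = "SNP", prior_snp = "mixture",
                                  pi_a = 1, chain = ch, seed = 8))
  expect_true(all(fb$samples$gamma_a == 1L))
  vm <- attr(explained_variance(fm$samples$a, W), "per_cycle")
  vb <- attr(explained_variance(fb$samples$a, W), "per_cycle")
  se <- sqrt(sd(vm)^2 / as.numeric(ess(vm)) + sd(vb)^2 / as.numeric(ess(vb)))
  expect_lt(abs(mean(vm) - mean(vb)), 3 * se + 0.01)
})

test_that("individuals with masked phenotypes stay in the model and get predictions", {
  ds <- fixture_ds()
  ph <- ds$phenotypes
  set.seed(60)
  masked <- sample(nrow(ph), 50L)
  ph$trait[masked] <- NA
  bl <- design_blocks(ph, ds$pedigree, ds$genotypes, ds$map, ds$expressions)
  fit <- run_mixed_model(NULL, bl, spec = model_spec(chain = quick_chain(),
                                                     seed = 61))
  expect_equal(fit$meta$n_obs, nrow(ph) - 50L)
  pred <- predict(fit)
  expect_equal(length(pred), nrow(ph))
  expect_false(anyNA(pred))
  # masked individuals' predictions correlate with their true trait values
  expect_gt(cor(pred[masked], ds$phenotypes$trait[masked]), 0.3)
})

test_that("requesting a component without its data block errors clearly", {
  ds <- fixture_ds()
  expect_error(design_blocks(ds$phenotypes, components = "SNP"), "genotypes")
  bl <- design_blocks(ds$phenotypes, ds$pedigree, components = "PED")
  expect_error(run_mixed_model(NULL, bl, spec = model_spec(chain = quick_chain())),
               "SNP")
  expect_error(run_bvs(NULL, bl, spec = model_spec(components = "PED")),
               "mixture")
})
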