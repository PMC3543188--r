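# fabricate a minimal ov_fit around given coefficient draws so partition
# operations can be exercised without running MCMC
stub_fit <- function(a_samples, W, map, n_retained = nrow(a_samples)) {
  n <- nrow(W)
  structure(list(
    samples = list(mu = rep(0, n_retained), b = matrix(0, n_retained, 0),
                   u = NULL, a = a_samples, g = NULL,
                   variances = matrix(1, n_retained, 1,
                                      dimnames = list(NULL, "sigma_e2"))),
    blocks = list(y = rep(0, n), obs = rep(TRUE, n),
                  X = matrix(0, n, 0), zmap = integer(0), n_ped = 0L,
                  W = W, Q = NULL, map = map,
                  ids = as.character(seq_len(n))),
    y = rep(0, n), obs = rep(TRUE, n),
    meta = list(n_retained = n_retained, components = "SNP",
                chain = list(n_iter = 1, burn_in = 0, thin = 1), seed = 1,
                mixture = c(snp = FALSE, gex = FALSE), n_obs = n)),
    class = "ov_fit")
}

test_that("explained variance reproduces closed forms for constant draws", {
  n <- 400L
  set.seed(1)
  x <- scale(rnorm(n))[, 1] * sqrt((n - 1) / n)  # exact unit variance below
  x <- (x - mean(x)) / sd(x)
  W1 <- matrix(x, ncol = 1, dimnames = list(NULL, "s1"))
  # zero draws -> (0, 0)
  ev0 <- explained_variance(matrix(0, 50, 1), W1)
  expect_equal(unname(ev0), c(0, 0), ignore_attr = TRUE)
  # constant draw beta on a unit-variance covariate -> PM = beta^2
  evb <- explained_variance(matrix(0.7, 50, 1), W1)
  expect_equal(evb[["pm"]], 0.49, tolerance = 1e-12)
  expect_equal(evb[["psd"]], 0)
  # two covariates, constant draws (1, 1) -> quadratic form a' S a with the
  # empirical covariance S
  set.seed(2)
  z <- rnorm(n)
  W2 <- cbind(s1 = x, s2 = 0.5 * x + sqrt(0.75) * scale(z)[, 1])
  ev2 <- explained_variance(matrix(1, 20, 2), W2)
  S <- cov(W2)
  expect_equal(ev2[["pm"]], sum(S), tolerance = 1e-12)
  expect_error(explained_variance(matrix(1, 5, 2), W2, integer(0)), "empty")
})

test_that("chromosome partition sums to the total up to the covariance remainder", {
  bl <- fixture_blocks()
  set.seed(3)
  a <- matrix(rnorm(40 * ncol(bl$W), sd = 0.05), 40, ncol(bl$W))
  fit <- stub_fit(a, bl$W, bl$map, 40)
  tab <- partition_by_chromosome(fit)
  expect_equal(sort(unique(tab$chr)), 1:5)
  expect_equal(sum(tab$pm) + attr(tab, "remainder"), attr(tab, "total_pm"),
               tolerance = 1e-10)
  # single-chromosome genome: the chromosome equals the total, remainder 0
  sub <- which(bl$map$chr == 1)
  fit1 <- stub_fit(a[, sub], bl$W[, sub], bl$map[sub, ], 40)
  tab1 <- partition_by_chromosome(fit1)
  expect_equal(nrow(tab1), 1L)
  expect_equal(attr(tab1, "remainder"), 0, tolerance = 1e-12)
  expect_equal(tab1$pm, attr(tab1, "total_pm"))
})

test_that("the chromosome remainder is the between-chromosome covariance", {
  bl <- fixture_blocks()
  set.seed(4)
  a <- matrix(rnorm(10 * ncol(bl$W), sd = 0.1), 10, ncol(bl$W))
  fit <- stub_fit(a, bl$W, bl$map, 10)
  tab <- partition_by_chromosome(fit)
  # oracle: per cycle, sum of off-diagonal covariances between the partial
  # predictors of the five chromosomes, averaged over cycles
  covrem <- mean(vapply(1:10, function(t) {
    P <- vapply(unique(bl$map$chr), function(ch) {
      ix <- which(bl$map$chr == ch)
      drop(bl$W[, ix] %*% a[t, ix])
    }, numeric(nrow(bl$W)))
    C <- cov(P)
    sum(C) - sum(diag(C))
  }, 0))
  expect_equal(attr(tab, "remainder"), covrem, tolerance = 1e-10)
})

test_that("window profile slides within chromosomes and reduces to the chromosome value", {
  bl <- fixture_blocks()
  set.seed(5)
  a <- matrix(rnorm(20 * ncol(bl$W), sd = 0.05), 20, ncol(bl$W))
  fit <- stub_fit(a, bl$W, bl$map, 20)
  wp <- window_profile(fit, window = 5)
  per_chr <- table(bl$map$chr)
  expect_equal(nrow(wp), sum(per_chr - 5 + 1))
  expect_true(all(bl$map$chr[wp$start] == bl$map$chr[wp$end]))
  # window = chromosome size: single value equal to the chromosome entry
  wp_full <- window_profile(fit, window = unname(per_chr[1]))
  chr_tab <- partition_by_chromosome(fit)
  expect_equal(wp_full$pm, chr_tab$pm, tolerance = 1e-12)
  # a chromosome smaller than the window falls back to one all-SNP window
  sub <- which(bl$map$chr == 1)[1:3]
  fit_small <- stub_fit(a[, sub], bl$W[, sub], bl$map[sub, ], 20)
  expect_message(wp_small <- window_profile(fit_small, window = 5), "single")
  expect_equal(nrow(wp_small), 1L)
})

test_that("window profile peaks at a simulated QTL and stays flat under the null", {
  set.seed(6)
  hits <- vapply(1:10, function(rep) {
    set.seed(600 + rep)
    n <- 250L
    cfg <- sim_config(n_f2 = n, n_chr = 1L, snps_per_chr = 100L, n_probes = 5L,
                      fractions = c(polygenic = 0, direct_snp = 0.4, mediated = 0),
                      architecture = list(
                        direct_qtl = data.frame(snp = 50L, weight = 1),
                        eqtl = data.frame(snp = 1L, probe = 1L, fraction = 0.1),
                        gex_effects = data.frame(probe = integer(0),
                                                 weight = numeric(0))),
                      seed = 600 + rep)
    ds <- simulate_dataset(cfg)
    bl <- design_blocks(ds$phenotypes, genotypes = ds$genotypes, map = ds$map,
                        components = "SNP")
    fit <- run_mixed_model(NULL, bl, spec = model_spec(components = "SNP",
                                                       chain = quick_chain(),
                                                       seed = rep))
    wp <- window_profile(fit, window = 5)
    peak <- wp[which.max(wp$pm), ]
    peak$start <= 52 && peak$end >= 48
  }, logical(1))
  expect_gte(sum(hits), 9L)
  # null: no QTL anywhere, profile low everywhere
  cfg0 <- sim_config(n_f2 = 250, n_chr = 1L, snps_per_chr = 100L, n_probes = 5L,
                     fractions = c(polygenic = 0, direct_snp = 0, mediated = 0),
                     architecture = list(
                       direct_qtl = data.frame(snp = 50L, weight = 1),
                       eqtl = data.frame(snp = 1L, probe = 1L, fraction = 0.1),
                       gex_effects = data.frame(probe = integer(0),
                                                weight = numeric(0))),
                     seed = 99)
  ds0 <- simulate_dataset(cfg0)
  bl0 <- design_blocks(ds0$phenotypes, genotypes = ds0$genotypes, map = ds0$map,
                       components = "SNP")
  fit0 <- run_mixed_model(NULL, bl0, spec = model_spec(components = "SNP",
                                                       chain = quick_chain(),
                                                       seed = 100))
  wp0 <- window_profile(fit0, window = 5)
  expect_lt(max(wp0$pm), 0.05 * var(bl0$y))
})

test_that("genomic values track the causal dosage and respect the variance bound", {
  set.seed(7)
  hitcors <- vapply(1:3, function(rep) {
    # a single isolated biallelic QTL on a sparse panel of unlinked markers
    cfg <- sim_config(n_f2 = 250, n_chr = 1L, snps_per_chr = 10L, n_probes = 5L,
                      fractions = c(polygenic = 0, direct_snp = 0.5, mediated = 0),
                      recomb = list(rep(0.5, 9)),
                      architecture = list(
                        direct_qtl = data.frame(snp = 5L, weight = 1),
                        eqtl = data.frame(snp = 1L, probe = 1L, fraction = 0.1),
                        gex_effects = data.frame(probe = integer(0),
                                                 weight = numeric(0))),
                      seed = 700 + rep)
    ds <- simulate_dataset(cfg)
    bl <- design_blocks(ds$phenotypes, genotypes = ds$genotypes, map = ds$map,
                        components = "SNP")
    fit <- run_mixed_model(NULL, bl, spec = model_spec(components = "SNP",
                                                       chain = quick_chain(),
                                                       seed = rep))
    gv <- genomic_values(fit, "SNP")
    # Jensen bound: variance of the posterior-mean predictor cannot exceed
    # the posterior-mean explained variance
    ev <- explained_variance(fit$samples$a, bl$W)
    expect_lte(var(gv), ev[["pm"]] + 1e-10)
    abs(cor(gv, ds$genotypes[, 5]))
  }, 0)
  expect_true(all(hitcors > 0.95))
  # zero draws -> all individuals zero
  bl <- fixture_blocks()
  fit0 <- stub_fit(matrix(0, 10, ncol(bl$W)), bl$W, bl$map, 10)
  expect_true(all(genomic_values(fit0, "SNP") == 0))
})

test_that("identical partitions contrast to zero drop labelled direct", {
  bl <- fixture_blocks()
  set.seed(8)
  a <- matrix(rnorm(20 * ncol(bl$W), sd = 0.1), 20, ncol(bl$W))
  fit <- stub_fit(a, bl$W, bl$map, 20)
  p <- variance_partition(fit, by_chromosome = TRUE, window = 5)
  ctr <- eqtl_contrast(p, p)
  expect_true(all(ctr$windows$drop == 0))
  expect_true(all(ctr$windows$label %in% c("direct", "negligible")))
  expect_true(all(ctr$chromosomes$label %in% c("direct", "negligible")))
  # mismatched maps must be refused
  sub <- which(bl$map$chr %in% 1:2)
  p2 <- variance_partition(stub_fit(a[, sub], bl$W[, sub], bl$map[sub, ], 20),
                           by_chromosome = TRUE, window = 5)
  expect_error(eqtl_contrast(p, p2), "identical|line up")
})
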