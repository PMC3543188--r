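test_that("simulated pedigree has the F0/F1/F2 structure with two founder lines", {
  cfg <- sim_config(n_f2 = 40, n_probes = 10)
  ped <- simulate_pedigree(cfg)
  gen <- attr(ped, "generation")
  expect_equal(unname(table(gen)[c("F0", "F1", "F2")]), c(20L, 40L, 40L),
               ignore_attr = TRUE)
  # 60 ancestral records at the default generation sizes
  expect_equal(sum(gen != "F2"), 60L)
  line <- attr(ped, "line")
  # every F1 has one parent from each line
  f1 <- ped[gen[ped$id] == "F1", ]
  expect_true(all(line[f1$sire] == 1L))
  expect_true(all(line[f1$dam] == 2L))
  # every F2's parents are F1, and its grandparents span both founder lines
  f2 <- ped[gen[ped$id] == "F2", ]
  expect_true(all(gen[f2$sire] == "F1"))
  expect_true(all(gen[f2$dam] == "F1"))
  idx <- attr(ped, "id_index")
  gp_lines <- apply(f2, 1, function(r) {
    gp <- c(ped$sire[idx[r[["sire"]]]], ped$dam[idx[r[["sire"]]]],
            ped$sire[idx[r[["dam"]]]], ped$dam[idx[r[["dam"]]]])
    sort(unique(line[gp]))
  })
  expect_true(all(apply(gp_lines, 2, identical, y = c(1L, 2L))))
  # minimal degenerate config: 2 founders, 1 F1, 2 F2 (selfing edge case)
  mini <- simulate_pedigree(sim_config(n_f0 = 2, n_f1 = 1, n_f2 = 2,
                                       n_probes = 5))
  expect_equal(nrow(mini), 5L)
  gm <- attr(mini, "generation")
  expect_true(all(gm[mini$sire[gm[mini$id] == "F2"]] == "F1"))
})

test_that("gene-dropped genotypes respect linkage extremes and 1:2:1 segregation", {
  cfg <- sim_config(n_f2 = 440, n_chr = 2, snps_per_chr = 10, n_probes = 5,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  # free recombination: adjacent R2 near zero
  cfg_free <- cfg; cfg_free$recomb <- replicate(2, rep(0.5, 9), simplify = FALSE)
  g_free <- simulate_f2_genotypes(ped, cfg_free, seed = 1)
  expect_lt(adjacent_r2(g_free$genotypes, g_free$map), 0.02)
  # complete linkage: all SNPs on a chromosome identical up to labeling
  cfg_tight <- cfg; cfg_tight$recomb <- replicate(2, rep(0, 9), simplify = FALSE)
  g_tight <- simulate_f2_genotypes(ped, cfg_tight, seed = 2)
  r2 <- adjacent_r2(g_tight$genotypes, g_tight$map)
  expect_equal(r2, 1, tolerance = 1e-12)
  # out-of-range recombination is refused
  expect_error(sim_config(recomb = replicate(5, rep(0.6, 39), simplify = FALSE)),
               "0.5")
  # 1:2:1 dosage segregation at n = 440
  g <- simulate_f2_genotypes(ped, cfg, seed = 3)
  pvals <- apply(g$genotypes, 2, function(x) {
    obs <- tabulate(x + 1L, 3L)
    suppressWarnings(chisq.test(obs, p = c(.25, .5, .25))$p.value)
  })
  expect_gte(mean(pvals > 0.001), 0.95)
})

test_that("default recombination pattern hits the target adjacent LD", {
  ds <- simulate_dataset(sim_config(seed = 11))
  r2a <- adjacent_r2(ds$genotypes, ds$map)
  r2b <- adjacent_r2(ds$genotypes, ds$map, gap = 2)
  expect_gt(r2a, 0.5); expect_lt(r2a, 0.6)
  # clustered spacings keep two-apart LD above the square of adjacent LD
  expect_gt(r2b, r2a^2)
})

test_that("transcriptome eQTL control produces the configured genetic fractions", {
  cfg <- sim_config(n_f2 = 440, snps_per_chr = 20, n_probes = 50,
                    eqtl_fraction = 0.5,
                    architecture = list(
                      direct_qtl = data.frame(snp = 30L, weight = 1),
                      eqtl = data.frame(snp = 10L, probe = 1L, fraction = 0.5),
                      gex_effects = data.frame(probe = 1L, weight = 1)),
                    seed = 21)
  ped <- simulate_pedigree(cfg)
  g <- simulate_f2_genotypes(ped, cfg, seed = 22)
  E <- simulate_transcriptome(g$genotypes, cfg, batch = rep(1L, 440), seed = 23)
  r2 <- cor(E[, 1], g$genotypes[, 10])^2
  expect_gt(r2, 0.4); expect_lt(r2, 0.6)
  # non-eQTL probes are independent of every SNP
  max_r <- max(abs(cor(E[, 2:20], g$genotypes)))
  expect_lt(max_r, 0.2)
})

test_that("phenotype components are rescaled to the target fractions exactly", {
  ds <- simulate_dataset(sim_config(n_f2 = 200, snps_per_chr = 20,
                                    n_probes = 100, seed = 31,
                                    fractions = c(polygenic = 0.42,
                                                  direct_snp = 0.1,
                                                  mediated = 0.3)))
  fr <- ds$truth$fractions_realized
  expect_equal(unname(fr["polygenic"]), 0.42, tolerance = 1e-10)
  expect_equal(unname(fr["direct_snp"]), 0.1, tolerance = 1e-10)
  expect_equal(unname(fr["mediated"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(fr["residual"]), 0.18, tolerance = 1e-10)
  # truth reassembles the phenotype exactly
  cmp <- ds$truth$components
  tr <- ds$phenotypes$trait
  rebuilt <- 10 + ds$truth$batch_effects[ds$phenotypes$batch] +
    ds$truth$sex_effect * (ds$phenotypes$sex == "M") +
    cmp$polygenic + cmp$direct + cmp$mediated + cmp$residual
  expect_equal(tr, unname(rebuilt), tolerance = 1e-10)
  # fractions summing above one are refused
  expect_error(sim_config(fractions = c(polygenic = 0.6, direct_snp = 0.3,
                                        mediated = 0.3)), "sum")
})

test_that("optional phenotype missingness masks the requested count", {
  ds <- simulate_dataset(sim_config(n_f2 = 440, snps_per_chr = 10,
                                    n_probes = 20, n_pheno = 337, seed = 41))
  expect_equal(sum(!is.na(ds$phenotypes$trait)), 337L)
  expect_equal(nrow(ds$phenotypes), 440L)
})

test_that("the polygenic vector has covariance A (regression of offspring on midparent)", {
  cfg <- sim_config(n_f2 = 400, snps_per_chr = 10, n_probes = 10, seed = 51,
                    fractions = c(polygenic = 0.9, direct_snp = 0, mediated = 0))
  ds <- simulate_dataset(cfg)
  u <- ds$truth$u_full
  ped <- ds$pedigree
  gen <- attr(ped, "generation")
  f2 <- ped[gen[ped$id] == "F2", ]
  mid <- (u[f2$sire] + u[f2$dam]) / 2
  off <- u[f2$id]
  # offspring deviations from midparent are mean-zero Mendelian noise
  b <- coef(lm(off ~ mid))[2]
  expect_equal(unname(b), 1, tolerance = 0.15)
  expect_equal(mean(off - mid), 0, tolerance = 3 * sd(off - mid) / sqrt(nrow(f2)))
})
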