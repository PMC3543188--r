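#' Configuration for the F2-cross simulator
#'
#' Describes a two-founder-line F2 intercross with linked tag SNPs, a
#' partially eQTL-controlled transcriptome, and a phenotype composed of
#' batch/sex effects, a pedigree polygenic effect, direct SNP effects,
#' expression-mediated SNP effects and residual noise with known variance
#' fractions.
#'
#' The default genome (5 chromosomes x 40 SNPs) uses per-interval
#' recombination fractions arranged in alternating runs of tight
#' (`c = 0.03`) and loose (`c = 0.2674`) spacings, calibrated so the mean
#' adjacent-SNP dosage R2 in the F2 is 0.55 in expectation while the
#' two-apart R2 stays well above 0.55^2 (clustered spacings mimic the
#' uneven tag-SNP density of a real panel).
#'
#' @param n_f0,n_f1,n_f2 generation sizes; founders are split into two
#'   lines fixed for alternate alleles.
#' @param n_chr,snps_per_chr genome layout.
#' @param n_probes number of expression probes.
#' @param fractions named numeric: target phenotype variance fractions for
#'   `polygenic`, `direct_snp` and `mediated`; the residual fraction is
#'   `1 - sum` and must be nonnegative.
#' @param n_batches,batch_sd number of batches and SD of their phenotype
#'   effects.
#' @param sex_effect additive phenotype effect of the second sex.
#' @param probe_batch_sd SD of per-probe batch effects on expressions.
#' @param eqtl_fraction genetic variance fraction of each eQTL-controlled
#'   probe (cis-heritability of the transcript).
#' @param eqtls_per_chr eQTL SNPs per eQTL-carrying chromosome, spread
#'   along the chromosome; each controls one probe.
#' @param n_mediator_probes total probes feeding the phenotype: the
#'   eQTL-controlled ones plus environment-responsive (non-genetic) probes,
#'   emulating a transcriptome that captures environmental as well as
#'   genetic variation.
#' @param tight_c,loose_c,run_length recombination-fraction pattern:
#'   alternating runs of `run_length` intervals at `tight_c` then `loose_c`.
#' @param recomb optional list (one numeric vector per chromosome, length
#'   `snps_per_chr - 1`) of per-interval recombination fractions overriding
#'   the pattern; all values must lie in [0, 0.5].
#' @param architecture optional list overriding [default_architecture()].
#' @param n_pheno number of F2 individuals with an observed phenotype
#'   (default: all).
#' @param seed simulation seed.
#' @return a list of class `ov_simconfig`.
#' @export
sim_config <- function(n_f0 = 20L, n_f1 = 40L, n_f2 = 440L,
                       n_chr = 5L, snps_per_chr = 40L, n_probes = 1000L,
                       fractions = c(polygenic = 0.2, direct_snp = 0.2,
                                     mediated = 0.4),
                       n_batches = 3L, batch_sd = 0.5, sex_effect = 0.5,
                       probe_batch_sd = 0.3, eqtl_fraction = 0.2,
                       eqtls_per_chr = 8L, n_mediator_probes = 120L,
                       tight_c = 0.03, loose_c = 0.2674, run_length = 4L,
                       recomb = NULL, architecture = NULL,
                       n_pheno = NULL, seed = 1L) {
  stopifnot(n_f0 >= 2L, n_f1 >= 1L, n_f2 >= 2L, n_chr >= 1L,
            snps_per_chr >= 2L, n_probes >= 1L)
  fr <- fractions[c("polygenic", "direct_snp", "mediated")]
  if (anyNA(fr)) stop("fractions must name polygenic, direct_snp, mediated")
  if (any(fr < 0) || sum(fr) > 1) {
    stop("variance fractions must be nonnegative and sum to at most 1")
  }
  if (is.null(recomb)) {
    recomb <- replicate(n_chr, {
      cls <- rep(rep(c(TRUE, FALSE), length.out = ceiling((snps_per_chr - 1) /
                                                            run_length)),
                 each = run_length)[seq_len(snps_per_chr - 1L)]
      ifelse(cls, tight_c, loose_c)
    }, simplify = FALSE)
  }
  if (any(unlist(recomb) < 0 | unlist(recomb) > 0.5)) {
    stop("recombination fractions must lie in [0, 0.5]")
  }
  cfg <- structure(list(n_f0 = as.integer(n_f0), n_f1 = as.integer(n_f1),
                        n_f2 = as.integer(n_f2), n_chr = as.integer(n_chr),
                        snps_per_chr = as.integer(snps_per_chr),
                        n_probes = as.integer(n_probes), fractions = fr,
                        residual = 1 - sum(fr),
                        n_batches = as.integer(n_batches),
                        batch_sd = batch_sd, sex_effect = sex_effect,
                        probe_batch_sd = probe_batch_sd,
                        eqtl_fraction = eqtl_fraction,
                        eqtls_per_chr = as.integer(eqtls_per_chr),
                        n_mediator_probes = as.integer(n_mediator_probes),
                        recomb = recomb, seed = as.integer(seed),
                        n_pheno = if (is.null(n_pheno)) NULL
                                  else as.integer(n_pheno)),
                   class = "ov_simconfig")
  cfg$architecture <- if (is.null(architecture)) default_architecture(cfg)
                      else architecture
  ok <- with(cfg$architecture, all(
    direct_qtl$snp >= 1, direct_qtl$snp <= n_chr * snps_per_chr,
    eqtl$snp >= 1, eqtl$snp <= n_chr * snps_per_chr,
    eqtl$probe >= 1, eqtl$probe <= n_probes,
    gex_effects$probe >= 1, gex_effects$probe <= n_probes))
  if (!ok) stop("architecture indices out of range for the configured ",
                "genome/transcriptome")
  cfg
}

#' Default trait architecture for a simulation config
#'
#' Places direct-effect QTLs mid-chromosome on the even-numbered
#' chromosomes (up to two) and `eqtls_per_chr` eQTL SNPs spread along each
#' odd-numbered chromosome (up to three), each controlling one probe with
#' genetic fraction `eqtl_fraction`.  The phenotype-feeding probe set
#' comprises these eQTL-controlled probes plus environment-responsive
#' probes up to `n_mediator_probes` in total, all with equal weight: the
#' transcriptome layer carries both SNP-mediated and purely environmental
#' phenotype variance, which is what lets it explain more than the genome
#' alone.
#'
#' @param cfg an `ov_simconfig` (architecture slot ignored).
#' @return list with data.frames `direct_qtl` (`snp`, `weight`), `eqtl`
#'   (`snp`, `probe`, `fraction`) and `gex_effects` (`probe`, `weight`).
#' @export
default_architecture <- function(cfg) {
  spc <- cfg$snps_per_chr
  mid <- function(chr) (chr - 1L) * spc + max(1L, spc %/% 2L)
  direct_chr <- head(seq(2L, cfg$n_chr, by = 2L), 2L)
  eqtl_chr <- head(seq(1L, cfg$n_chr, by = 2L), 3L)
  if (!length(direct_chr)) direct_chr <- cfg$n_chr
  direct <- data.frame(snp = mid(direct_chr), weight = 1)
  per_chr <- max(1L, min(cfg$eqtls_per_chr, spc))
  pos <- unique(pmax(1L, pmin(spc, round(seq(0.1, 0.9,
                                             length.out = per_chr) * spc))))
  snps <- unlist(lapply(eqtl_chr, function(ch) (ch - 1L) * spc + pos))
  eq <- data.frame(snp = snps, probe = seq_along(snps),
                   fraction = cfg$eqtl_fraction)
  eq <- eq[eq$probe <= cfg$n_probes, , drop = FALSE]
  n_med <- min(cfg$n_mediator_probes, cfg$n_probes)
  med <- seq_len(n_med)
  list(direct_qtl = direct, eqtl = eq,
       gex_effects = data.frame(probe = union(eq$probe, med), weight = 1))
}

#' Simulate an F0 -> F1 -> F2 pedigree
#'
#' Founders are split into two lines; F1 animals come from between-line
#' couples and F2 animals from F1 x F1 couples.  Couples are formed by a
#' deterministic pairing rule: the i-th animal of line 1 mates the i-th of
#' line 2, and F1 animal `j` mates F1 animal `j + floor(n_f1/2)` (so mates
#' come from different F0 couples); offspring are assigned to couples
#' round-robin, which resolves uneven counts.  With a single F1 animal the
#' design degenerates to selfing (structural edge case).
#'
#' @param cfg an `ov_simconfig`.
#' @return an `ov_pedigree` with a `generation` attribute
#'   (`"F0"`/`"F1"`/`"F2"`) and a `line` attribute for founders.
#' @export
simulate_pedigree <- function(cfg) {
  n1 <- cfg$n_f0 %/% 2L; n2 <- cfg$n_f0 - n1
  f0 <- sprintf("F0_%03d", seq_len(cfg$n_f0))
  line <- rep(c(1L, 2L), c(n1, n2))
  f1 <- sprintf("F1_%03d", seq_len(cfg$n_f1))
  f2 <- sprintf("F2_%04d", seq_len(cfg$n_f2))
  nc0 <- min(n1, n2)
  c0 <- ((seq_len(cfg$n_f1) - 1L) %% nc0) + 1L
  f1_sire <- f0[line == 1L][c0]
  f1_dam <- f0[line == 2L][c0]
  nc1 <- max(1L, cfg$n_f1 %/% 2L)
  c1 <- ((seq_len(cfg$n_f2) - 1L) %% nc1) + 1L
  f2_sire <- f1[c1]
  f2_dam <- if (cfg$n_f1 >= 2L) f1[c1 + nc1] else f1[c1]
  ped <- as_pedigree(c(f0, f1, f2),
                     c(rep(NA, cfg$n_f0), f1_sire, f2_sire),
                     c(rep(NA, cfg$n_f0), f1_dam, f2_dam))
  attr(ped, "generation") <- setNames(
    rep(c("F0", "F1", "F2"), c(cfg$n_f0, cfg$n_f1, cfg$n_f2))[
      match(ped$id, c(f0, f1, f2))], ped$id)
  attr(ped, "line") <- setNames(line, f0)
  ped
}

# one gamete per row: Markovian recombination along a chromosome whose F1
# parent carries one chromosome of each founder line (phase known)
sim_gametes <- function(n_gam, cvec) {
  m <- length(cvec) + 1L
  G <- matrix(0L, n_gam, m)
  G[, 1L] <- rbinom(n_gam, 1L, 0.5)
  for (j in seq_along(cvec)) {
    sw <- rbinom(n_gam, 1L, cvec[j])
    G[, j + 1L] <- ifelse(sw == 1L, 1L - G[, j], G[, j])
  }
  G
}

#' Gene-drop F2 genotypes over a linked SNP panel
#'
#' Founder lines are idealized as fully inbred and fixed for alternate
#' alleles at every tag SNP, so every F1 is heterozygous with known phase
#' and each F2 dosage is the sum of two independent recombinant gametes.
#' The expected adjacent-dosage correlation across an interval with
#' recombination fraction `c` is `1 - 2c`.
#'
#' @param ped pedigree from [simulate_pedigree()] (supplies the F2 ids).
#' @param cfg an `ov_simconfig`.
#' @param seed optional seed (otherwise the caller's RNG state is used).
#' @return list with `genotypes` (F2 x SNP dosage matrix, values 0/1/2) and
#'   `map` (data.frame `snp_id`, `chr`, `pos`, `order`).
#' @export
simulate_f2_genotypes <- function(ped, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gen <- attr(ped, "generation")
  f2 <- ped$id[gen[ped$id] == "F2"]
  n <- length(f2)
  blocks <- lapply(seq_len(cfg$n_chr), function(ch) {
    cvec <- cfg$recomb[[ch]]
    sim_gametes(n, cvec) + sim_gametes(n, cvec)
  })
  G <- do.call(cbind, blocks)
  map <- data.frame(
    snp_id = unlist(lapply(seq_len(cfg$n_chr), function(ch)
      sprintf("c%ds%02d", ch, seq_len(cfg$snps_per_chr)))),
    chr = rep(seq_len(cfg$n_chr), each = cfg$snps_per_chr),
    pos = rep(seq_len(cfg$snps_per_chr), cfg$n_chr))
  map$order <- seq_len(nrow(map))
  dimnames(G) <- list(f2, map$snp_id)
  list(genotypes = G, map = map)
}

#' Simulate a partially eQTL-controlled transcriptome
#'
#' Each probe listed in the eQTL architecture is built as
#' `sqrt(f) * scaled dosage + batch effect + sqrt(1 - f) * noise` (summed
#' over its eQTL SNPs), so its genetic variance fraction relative to the
#' genetic-plus-noise signal is `f` by construction; all other probes are
#' batch effect plus pure noise.
#'
#' @param genotypes F2 dosage matrix (from [simulate_f2_genotypes()]).
#' @param cfg an `ov_simconfig`.
#' @param batch integer batch assignment per individual; sampled uniformly
#'   from `cfg$n_batches` levels when `NULL`.
#' @param seed optional seed.
#' @return expression matrix (individuals x probes) with attributes `batch`
#'   and `truth` (per-probe realized genetic fraction and the eQTL table).
#' @export
simulate_transcriptome <- function(genotypes, cfg, batch = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  if (is.null(batch)) batch <- sample.int(cfg$n_batches, n, replace = TRUE)
  eq <- cfg$architecture$eqtl
  if (any(tapply(eq$fraction, eq$probe, sum) > 1)) {
    stop("total eQTL genetic fraction exceeds 1 for some probe")
  }
  E <- matrix(rnorm(n * cfg$n_probes), n, cfg$n_probes)
  realized <- numeric(cfg$n_probes)
  for (pr in unique(eq$probe)) {
    rows <- eq[eq$probe == pr, , drop = FALSE]
    gen <- rowSums(vapply(seq_len(nrow(rows)), function(k) {
      w <- genotypes[, rows$snp[k]]
      sqrt(rows$fraction[k]) * (w - mean(w)) / sd(w)
    }, numeric(n)))
    noise <- E[, pr] * sqrt(max(0, 1 - sum(rows$fraction)))
    realized[pr] <- var(gen) / var(gen + noise)
    E[, pr] <- gen + noise
  }
  if (cfg$probe_batch_sd > 0) {
    beff <- matrix(rnorm(cfg$n_batches * cfg$n_probes,
                         sd = cfg$probe_batch_sd),
                   cfg$n_batches, cfg$n_probes)
    E <- E + beff[batch, , drop = FALSE]
  }
  dimnames(E) <- list(rownames(genotypes),
                      sprintf("probe%04d", seq_len(cfg$n_probes)))
  structure(E, batch = batch,
            truth = list(eqtl = eq, realized_fraction = realized))
}

#' Compose the phenotype from its generative parts
#'
#' Builds `y = intercept + batch + sex + polygenic + direct SNP + mediated
#' (expression) + residual`.  The polygenic vector is drawn over the whole
#' pedigree by generation-wise Mendelian sampling (founders `N(0, 1)`,
#' offspring `0.5 (u_s + u_d) + N(0, 0.5 - 0.25 (F_s + F_d))`), so its
#' covariance is exactly `A`.  Each stochastic component is then centered
#' over the phenotyped generation and rescaled post hoc so its realized
#' variance equals the configured fraction exactly (total non-fixed
#' variance 1); the rescaling factors are recorded in the truth object so
#' parameter-recovery checks have a sharp target.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param genotypes,expressions matrices from the genotype and
#'   transcriptome simulators (aligned on F2 rows).
#' @param cfg an `ov_simconfig`.
#' @param batch,sex assignments per F2 individual; sampled when `NULL`.
#' @param seed optional seed.
#' @return list with `phenotypes` (data.frame `id`, `trait`, `batch`,
#'   `sex`; masked traits are `NA`) and `truth` (components, effect sizes,
#'   realized fractions, full polygenic vector).
#' @export
simulate_phenotype <- function(ped, genotypes, expressions, cfg,
                               batch = NULL, sex = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(genotypes)
  n <- length(ids)
  if (is.null(batch)) batch <- sample.int(cfg$n_batches, n, replace = TRUE)
  if (is.null(sex)) sex <- sample(c("F", "M"), n, replace = TRUE)
  fr <- cfg$fractions
  if (sum(fr) > 1) stop("variance fractions sum to more than 1")

  # polygenic effect by Mendelian sampling down the pedigree
  Fc <- inbreeding_coefficients(ped)
  idx <- attr(ped, "id_index")
  u <- numeric(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    if (is.na(s) && is.na(d)) {
      u[i] <- rnorm(1L)
    } else {
      us <- if (is.na(s)) 0 else u[s]
      ud <- if (is.na(d)) 0 else u[d]
      msv <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (Fc[s] + Fc[d]) else 0.75
      u[i] <- 0.5 * (us + ud) + rnorm(1L, sd = sqrt(msv))
    }
  }
  names(u) <- ped$id

  scale_to <- function(x, target_var) {
    x <- x - mean(x)
    s <- sd(x)
    if (target_var == 0 || s == 0) return(list(x = x * 0, factor = 0))
    f <- sqrt(target_var) / s
    list(x = x * f, factor = f)
  }
  poly <- scale_to(u[ids], fr[["polygenic"]])
  dq <- cfg$architecture$direct_qtl
  direct_raw <- drop(genotypes[, dq$snp, drop = FALSE] %*% dq$weight)
  direct <- scale_to(direct_raw, fr[["direct_snp"]])
  gx <- cfg$architecture$gex_effects
  med_raw <- drop(expressions[, gx$probe, drop = FALSE] %*% gx$weight)
  mediated <- scale_to(med_raw, fr[["mediated"]])
  resid <- scale_to(rnorm(n), cfg$residual)

  batch_eff <- c(0, rnorm(cfg$n_batches - 1L, sd = cfg$batch_sd))
  y <- 10 + batch_eff[batch] + cfg$sex_effect * (sex == "M") +
    poly$x + direct$x + mediated$x + resid$x
  trait <- y
  if (!is.null(cfg$n_pheno) && cfg$n_pheno < n) {
    trait[sample.int(n, n - cfg$n_pheno)] <- NA
  }
  list(
    phenotypes = data.frame(id = ids, trait = trait, batch = batch,
                            sex = sex, stringsAsFactors = FALSE),
    truth = list(
      fractions_target = c(fr, residual = cfg$residual),
      fractions_realized = c(polygenic = var(poly$x),
                             direct_snp = var(direct$x),
                             mediated = var(mediated$x),
                             residual = var(resid$x)),
      components = list(polygenic = poly$x, direct = direct$x,
                        mediated = mediated$x, residual = resid$x),
      u_full = u * poly$factor,
      direct_qtl = transform(dq, effect = weight * direct$factor),
      gex_effects = transform(gx, effect = weight * mediated$factor),
      eqtl = cfg$architecture$eqtl,
      batch_effects = batch_eff, sex_effect = cfg$sex_effect))
}

#' Simulate a complete F2 genome-transcriptome-phenotype dataset
#'
#' Orchestrates [simulate_pedigree()], [simulate_f2_genotypes()],
#' [simulate_transcriptome()] and [simulate_phenotype()] under one seed.
#'
#' @param cfg an `ov_simconfig`.
#' @return an object of class `ov_dataset`: list with `pedigree`,
#'   `genotypes`, `map`, `expressions`, `phenotypes`, `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_f2_genotypes(ped, cfg)
  n <- nrow(gt$genotypes)
  batch <- sample.int(cfg$n_batches, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  expr <- simulate_transcriptome(gt$genotypes, cfg, batch = batch)
  ph <- simulate_phenotype(ped, gt$genotypes, expr, cfg,
                           batch = batch, sex = sex)
  structure(list(pedigree = ped, genotypes = gt$genotypes, map = gt$map,
                 expressions = `attributes<-`(expr,
                   attributes(expr)[c("dim", "dimnames")]),
                 phenotypes = ph$phenotypes,
                 truth = c(ph$truth,
                           list(probe_genetic_fraction =
                                  attr(expr, "truth")$realized_fraction)),
                 cfg = cfg),
            class = "ov_dataset")
}

#' @export
print.ov_dataset <- function(x, ...) {
  cat(sprintf(
    "ov_dataset: %d pedigree records (%d F2), %d SNPs on %d chromosomes, %d probes\n",
    nrow(x$pedigree), nrow(x$genotypes), ncol(x$genotypes), x$cfg$n_chr,
    ncol(x$expressions)))
  cat(sprintf("  phenotyped: %d of %d; target fractions: %s; residual %.2f\n",
              sum(!is.na(x$phenotypes$trait)), nrow(x$phenotypes),
              paste(names(x$cfg$fractions), x$cfg$fractions, sep = "=",
                    collapse = ", "), x$cfg$residual))
  invisible(x)
}

#' The bundled small synthetic fixture
#'
#' A scaled-down standard dataset (200 F2, 5 chromosomes x 20 SNPs, 200
#' probes, default variance fractions and architecture) used throughout the
#' test suite and documentation; regenerated deterministically from its
#' seed rather than shipped as files.
#'
#' @param seed simulation seed.
#' @return an `ov_dataset`.
#' @export
simulate_fixture <- function(seed = 1L) {
  simulate_dataset(sim_config(n_f2 = 200L, snps_per_chr = 20L,
                              n_probes = 200L, seed = seed))
}

#' Mean adjacent-SNP dosage R2
#'
#' Average squared correlation between dosages of map-adjacent SNP pairs
#' within chromosomes — the panel's short-range linkage disequilibrium
#' summary used to judge the sliding-window width.
#'
#' @param genotypes dosage matrix, individuals in rows.
#' @param map marker map (`snp_id`, `chr`) in genotype column order.
#' @param gap map distance between the paired SNPs (1 = adjacent).
#' @return mean R2 over all within-chromosome pairs at the given gap.
#' @export
adjacent_r2 <- function(genotypes, map, gap = 1L) {
  r2 <- unlist(lapply(unique(map$chr), function(ch) {
    idx <- which(map$chr == ch)
    if (length(idx) <= gap) return(numeric(0))
    vapply(seq_len(length(idx) - gap), function(j) {
      suppressWarnings(
        cor(genotypes[, idx[j]], genotypes[, idx[j + gap]])^2)
    }, 0)
  }))
  mean(r2, na.rm = TRUE)  # zero-variance (monomorphic) pairs contribute NA
}
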