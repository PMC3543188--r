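col_vars <- function(M) {
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 rows for a variance")
  (colSums(M^2) - n * colMeans(M)^2) / (n - 1)
}

#' Posterior explained variance of a covariate subset
#'
#' For each retained MCMC cycle `t`, computes the empirical variance across
#' individuals (divisor `n - 1`) of the partial predictor
#' `M[, subset] %*% a_t[subset]`, and summarizes the per-cycle values by
#' their posterior mean (PM) and posterior standard deviation (PSD).
#'
#' @param samples matrix of coefficient draws, cycles in rows, covariates in
#'   columns.
#' @param M covariate block, individuals in rows; column count must match
#'   the coefficient dimension.
#' @param subset column indices (or names) of the covariates to include;
#'   defaults to all.
#' @return named numeric vector `c(pm = , psd = )` with attribute
#'   `per_cycle` (the per-cycle variance series).
#' @export
explained_variance <- function(samples, M, subset = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != ncol(M)) {
    stop("coefficient dimension (", ncol(samples),
         ") does not match covariate block (", ncol(M), ")")
  }
  if (is.null(subset)) subset <- seq_len(ncol(M))
  if (length(subset) == 0L) stop("empty covariate subset")
  P <- M[, subset, drop = FALSE] %*% t(samples[, subset, drop = FALSE])
  v <- col_vars(P)
  structure(c(pm = mean(v), psd = sd(v)), per_cycle = v)
}

# per-cycle explained-variance series for one model component of a fit,
# restricted to the likelihood rows
component_variance_series <- function(fit, component, subset = NULL) {
  s <- fit$samples; bl <- fit$blocks; obs <- fit$obs
  switch(component,
    E = {
      if (!ncol(bl$X)) return(rep(0, fit$meta$n_retained))
      col_vars(bl$X[obs, , drop = FALSE] %*% t(s$b))
    },
    PED = {
      U <- t(s$u)[bl$zmap[obs] + 1L, , drop = FALSE]
      col_vars(U)
    },
    SNP = attr(explained_variance(s$a, bl$W[obs, , drop = FALSE], subset),
               "per_cycle"),
    GEX = attr(explained_variance(s$g, bl$Q[obs, , drop = FALSE], subset),
               "per_cycle"),
    stop("unknown component: ", component))
}

#' Partition posterior explained variance by data layer
#'
#' Evaluates, per retained MCMC cycle, the empirical variance across the
#' phenotyped individuals of each partial predictor — batch/sex (`E`),
#' polygenic (`P`), SNP (`S`), expression (`G`) — plus the residual-variance
#' draws, and summarizes each as posterior mean (PM) and posterior SD (PSD).
#' Optionally adds the per-chromosome table (with the between-chromosome
#' covariance remainder) and the sliding-window genomic variance profile.
#'
#' Two proportion scales are reported: `prop_total` divides by the model's
#' total (sum of component PMs plus residual PM) and `prop_explained`
#' divides by the explained total only (batch/sex + genetic + transcriptome
#' layers, excluding the residual).
#'
#' @param fit an `ov_fit`.
#' @param by_chromosome add the per-chromosome partition (needs a SNP map).
#' @param window sliding-window width in SNPs for the genomic variance
#'   profile, or `NULL` to skip it.
#' @return an object of class `ov_partition` with elements `components`
#'   (data.frame), `total`, `explained_total`, and optionally `chromosomes`
#'   (+ attribute `remainder`) and `windows`.
#' @export
variance_partition <- function(fit, by_chromosome = TRUE, window = 5L) {
  stopifnot(inherits(fit, "ov_fit"))
  comps <- c(if (ncol(fit$blocks$X)) "E",
             if (!is.null(fit$samples$u)) "PED",
             if (!is.null(fit$samples$a)) "SNP",
             if (!is.null(fit$samples$g)) "GEX")
  series <- lapply(comps, function(cmp) component_variance_series(fit, cmp))
  names(series) <- comps
  pm <- vapply(series, mean, 0)
  psd <- vapply(series, sd, 0)
  res <- fit$samples$variances[, "sigma_e2"]
  tab <- data.frame(component = c(comps, "residual"),
                    pm = c(pm, mean(res)), psd = c(psd, sd(res)),
                    row.names = NULL)
  total <- sum(tab$pm)
  explained_total <- sum(tab$pm[tab$component != "residual"])
  tab$prop_total <- tab$pm / total
  tab$prop_explained <- ifelse(tab$component == "residual", NA,
                               tab$pm / explained_total)
  out <- list(components = tab, total = total,
              explained_total = explained_total,
              map = fit$blocks$map, n_retained = fit$meta$n_retained,
              model = paste(fit$meta$components, collapse = "+"))
  if (by_chromosome && !is.null(fit$samples$a) && !is.null(fit$blocks$map)) {
    out$chromosomes <- partition_by_chromosome(fit)
    if (!is.null(window)) out$windows <- window_profile(fit, window = window)
  }
  class(out) <- "ov_partition"
  out
}

#' @export
print.ov_partition <- function(x, ...) {
  cat("ov_partition (", x$model, " model, ", x$n_retained, " cycles)\n",
      sep = "")
  print(x$components, row.names = FALSE, digits = 3)
  cat(sprintf("total %.4g (explained %.4g)\n", x$total, x$explained_total))
  invisible(x)
}

#' Partition SNP explained variance by chromosome
#'
#' Computes [explained_variance()] for the SNP subset of every chromosome in
#' the marker map, and reports the between-chromosome covariance remainder
#' `PM(total SNP variance) - sum of per-chromosome PMs` (nonzero when
#' partial predictors of different chromosomes covary, as they do in an F2
#' family structure) as an attribute rather than silently absorbing it.
#'
#' @param fit an `ov_fit` with a SNP block and marker map.
#' @return data.frame (`chr`, `n_snp`, `pm`, `psd`) with attributes
#'   `remainder` and `total_pm`.
#' @export
partition_by_chromosome <- function(fit) {
  stopifnot(inherits(fit, "ov_fit"))
  map <- fit$blocks$map
  if (is.null(fit$samples$a)) stop("fit has no SNP component")
  if (is.null(map)) stop("fit carries no marker map")
  if (anyNA(map$chr)) {
    stop("SNP(s) without a chromosome assignment: ",
         paste(map$snp_id[is.na(map$chr)], collapse = ", "))
  }
  W <- fit$blocks$W[fit$obs, , drop = FALSE]
  chrs <- unique(map$chr)
  rows <- lapply(chrs, function(ch) {
    idx <- which(map$chr == ch)
    ev <- explained_variance(fit$samples$a, W, idx)
    data.frame(chr = ch, n_snp = length(idx), pm = ev[["pm"]],
               psd = ev[["psd"]])
  })
  tab <- do.call(rbind, rows)
  tot <- explained_variance(fit$samples$a, W)
  structure(tab, remainder = tot[["pm"]] - sum(tab$pm),
            total_pm = tot[["pm"]])
}

#' Sliding-window genomic variance profile
#'
#' Explained variance of every contiguous window of `window` SNPs, sliding
#' by one SNP in map order within each chromosome (windows never span a
#' chromosome boundary).  A chromosome with fewer SNPs than `window` yields
#' a single all-SNP window (with a message).
#'
#' @param fit an `ov_fit` with a SNP block and marker map.
#' @param window window width in SNPs (>= 2).
#' @return data.frame (`chr`, `start`, `end`, `start_snp`, `end_snp`, `pm`,
#'   `psd`), ordered by map order; `start`/`end` are global map indices.
#' @export
window_profile <- function(fit, window = 5L) {
  stopifnot(inherits(fit, "ov_fit"), window >= 2L)
  map <- fit$blocks$map
  if (is.null(fit$samples$a) || is.null(map)) {
    stop("fit has no SNP component with a marker map")
  }
  W <- fit$blocks$W[fit$obs, , drop = FALSE]
  out <- list()
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    if (length(idx) < window) {
      message("chromosome ", ch, " has ", length(idx), " < ", window,
              " SNPs; using a single all-SNP window")
      starts <- 1L; w <- length(idx)
    } else {
      starts <- seq_len(length(idx) - window + 1L); w <- window
    }
    for (s in starts) {
      sub <- idx[s:(s + w - 1L)]
      ev <- explained_variance(fit$samples$a, W, sub)
      out[[length(out) + 1L]] <- data.frame(
        chr = ch, start = sub[1L], end = sub[w],
        start_snp = map$snp_id[sub[1L]], end_snp = map$snp_id[sub[w]],
        pm = ev[["pm"]], psd = ev[["psd"]])
    }
  }
  do.call(rbind, out)
}

#' Per-individual posterior-mean genomic values
#'
#' Posterior mean over MCMC cycles of the partial predictor
#' `M[, subset] %*% a_t[subset]` for each individual — e.g. the chromosomal
#' genomic (breeding) values whose distribution turns tri-modal at a large
#' F2 QTL.  Covariates are centered, so the values are centered across
#' individuals up to Monte-Carlo error.
#'
#' @param fit an `ov_fit`.
#' @param component `"SNP"` or `"GEX"`.
#' @param subset covariate indices (e.g. one chromosome's SNPs); default all.
#' @param chr convenience: select all SNPs on this chromosome.
#' @return named numeric vector over the fit's individuals.
#' @export
genomic_values <- function(fit, component = "SNP", subset = NULL, chr = NULL) {
  stopifnot(inherits(fit, "ov_fit"))
  component <- match.arg(component, c("SNP", "GEX"))
  M <- if (component == "SNP") fit$blocks$W else fit$blocks$Q
  samples <- if (component == "SNP") fit$samples$a else fit$samples$g
  if (is.null(samples)) stop("fit has no ", component, " component")
  if (!is.null(chr)) {
    if (is.null(fit$blocks$map)) stop("fit carries no marker map")
    subset <- which(fit$blocks$map$chr == chr)
  }
  if (is.null(subset)) subset <- seq_len(ncol(M))
  if (!length(subset)) stop("empty covariate subset")
  pm <- colMeans(samples[, subset, drop = FALSE])
  setNames(drop(M[, subset, drop = FALSE] %*% pm), fit$blocks$ids)
}

#' Contrast SNP variance profiles with and without the transcriptome
#'
#' Compares per-chromosome and per-window SNP explained variances between a
#' marginal fit (SNP without expressions) and a conditional fit (SNP with
#' expressions in the model) built on the identical SNP block and map.  The
#' variance *drop* when transcripts enter the model localizes eQTL-type
#' signal: a window whose fractional drop is at least `mediated_threshold`
#' is labelled `"mediated/eQTL-like"`, at most `direct_threshold`
#' `"direct"`, otherwise `"intermediate"`.  Windows with negligible marginal
#' variance (below `min_pm` times the largest window) are labelled
#' `"negligible"`.
#'
#' @param partition_snp_only,partition_snp_gex `ov_partition` objects from
#'   the marginal and conditional fits (both with chromosome/window tables).
#' @param mediated_threshold,direct_threshold fractional-drop cutoffs
#'   (defaults 0.8 and 0.2).
#' @param min_pm fraction of the maximum marginal window PM below which a
#'   window is not classified.
#' @return list with data.frames `chromosomes` and `windows`, each holding
#'   `pm_marginal`, `pm_conditional`, `drop`, `frac_drop`, `label`.
#' @export
eqtl_contrast <- function(partition_snp_only, partition_snp_gex,
                          mediated_threshold = 0.8, direct_threshold = 0.2,
                          min_pm = 0.05) {
  p1 <- partition_snp_only; p2 <- partition_snp_gex
  stopifnot(inherits(p1, "ov_partition"), inherits(p2, "ov_partition"))
  if (is.null(p1$windows) || is.null(p2$windows)) {
    stop("both partitions need chromosome/window tables ",
         "(variance_partition(fit, by_chromosome = TRUE, window = ...))")
  }
  if (!identical(p1$map$snp_id, p2$map$snp_id) ||
      !identical(p1$map$chr, p2$map$chr)) {
    stop("the two partitions were not built on identical SNP maps")
  }
  classify <- function(pm1, pm2) {
    drop <- pm1 - pm2
    frac <- ifelse(pm1 > 0, drop / pm1, 0)
    label <- ifelse(frac >= mediated_threshold, "mediated/eQTL-like",
                    ifelse(frac <= direct_threshold, "direct",
                           "intermediate"))
    label[pm1 < min_pm * max(pm1)] <- "negligible"
    data.frame(pm_marginal = pm1, pm_conditional = pm2, drop = drop,
               frac_drop = frac, label = label)
  }
  chr_tab <- cbind(p1$chromosomes[, c("chr", "n_snp")],
                   classify(p1$chromosomes$pm, p2$chromosomes$pm))
  if (!identical(p1$windows[, c("chr", "start", "end")],
                 p2$windows[, c("chr", "start", "end")])) {
    stop("window tables of the two partitions do not line up")
  }
  win_tab <- cbind(p1$windows[, c("chr", "start", "end", "start_snp",
                                  "end_snp")],
                   classify(p1$windows$pm, p2$windows$pm))
  list(chromosomes = chr_tab, windows = win_tab,
       thresholds = c(mediated = mediated_threshold,
                      direct = direct_threshold))
}
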