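MODEL_GRID <- c("PED", "SNP", "GEX", "PED+SNP", "PED+GEX", "SNP+GEX",
                "PED+SNP+GEX")

grid_components <- function(model) {
  comps <- strsplit(model, "+", fixed = TRUE)[[1L]]
  bad <- setdiff(comps, c("PED", "SNP", "GEX"))
  if (length(bad) || !length(comps)) stop("unknown grid model: ", model)
  comps
}

#' Validate and summarize a set of model inputs
#'
#' Dimension and id-alignment report across pedigree, genotype, expression
#' and phenotype inputs: intersection sizes, missingness, monomorphic-SNP
#' and constant-probe counts, and the mean adjacent-SNP dosage R2 (so users
#' can judge the sliding-window width against the panel's LD).
#'
#' @param dataset an `ov_dataset` (or list of the same shape).
#' @return a list report of class `ov_input_report`.
#' @export
validate_inputs <- function(dataset) {
  ph <- dataset$phenotypes
  ids_ph <- as.character(ph$id)
  ids_gt <- rownames(dataset$genotypes)
  ids_ex <- rownames(dataset$expressions)
  shared <- Reduce(intersect, Filter(Negate(is.null),
                                     list(ids_ph, ids_gt, ids_ex)))
  mono <- sum(apply(dataset$genotypes, 2L, function(x) var(x, na.rm = TRUE)) == 0)
  const <- sum(apply(dataset$expressions, 2L, function(x) var(x, na.rm = TRUE)) == 0)
  unmapped <- setdiff(colnames(dataset$genotypes), dataset$map$snp_id)
  rep <- list(
    n_pedigree = if (!is.null(dataset$pedigree)) nrow(dataset$pedigree) else 0L,
    n_phenotype_rows = nrow(ph),
    n_phenotyped = sum(!is.na(ph$trait)),
    n_genotyped = length(ids_gt),
    n_expression = length(ids_ex),
    n_shared_ids = length(shared),
    ids_dropped_phenotypes = setdiff(ids_ph, shared),
    monomorphic_snps = mono,
    constant_probes = const,
    unmapped_snps = unmapped,
    missing_genotype_cells = sum(is.na(dataset$genotypes)),
    missing_expression_cells = sum(is.na(dataset$expressions)),
    mean_adjacent_r2 = adjacent_r2(dataset$genotypes, dataset$map),
    mean_two_apart_r2 = adjacent_r2(dataset$genotypes, dataset$map, gap = 2L))
  class(rep) <- "ov_input_report"
  rep
}

#' @export
print.ov_input_report <- function(x, ...) {
  cat("input report\n")
  cat(sprintf("  pedigree records : %d\n", x$n_pedigree))
  cat(sprintf("  phenotyped       : %d of %d rows\n", x$n_phenotyped,
              x$n_phenotype_rows))
  cat(sprintf("  genotyped        : %d (monomorphic SNPs: %d, unmapped: %d)\n",
              x$n_genotyped, x$monomorphic_snps, length(x$unmapped_snps)))
  cat(sprintf("  expression       : %d (constant probes: %d)\n",
              x$n_expression, x$constant_probes))
  cat(sprintf("  shared ids       : %d\n", x$n_shared_ids))
  cat(sprintf("  adjacent mean R2 : %.3f (two-apart %.3f)\n",
              x$mean_adjacent_r2, x$mean_two_apart_r2))
  invisible(x)
}

#' Fit the PED/SNP/GEX model grid and tabulate explained variances
#'
#' Fits any subset of the seven component combinations (PED, SNP, GEX,
#' PED+SNP, PED+GEX, SNP+GEX, PED+SNP+GEX; sex and batch always included as
#' fixed effects), computes the variance partition of every fit, and
#' assembles a master table with one row per component (E = batch/sex,
#' P = polygenic, S = SNP, G = expression, plus residual and totals) and
#' one column per model, each cell holding the posterior mean, posterior SD
#' and the percentage of the model's explained (non-residual) total.
#' Under mixture priors, SNP-carrying models additionally get chromosome
#' and window tables, and when both the marginal SNP and conditional
#' SNP+GEX models are in the grid, their [eqtl_contrast()] report.
#'
#' @param dataset an `ov_dataset`.
#' @param models character vector of grid model names.
#' @param prior `"normal"` (mixed model) or `"mixture"` (variable
#'   selection, applied to the SNP and GEX blocks).
#' @param chain an [chain_control()].
#' @param seed MCMC seed (shared across grid cells; results per model are
#'   reproducible independently).
#' @param pi_a,pi_g mixture inclusion probabilities.
#' @param window sliding-window width for the variance profiles.
#' @param cv also run [crossvalidate()] per model with `k` folds.
#' @param k CV fold count.
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV/JSON alongside a run manifest.
#' @return list of class `ov_grid`: `fits`, `partitions`, `master`
#'   (data.frame), `master_numeric`, optional `cv`, optional `contrast`.
#' @export
run_grid <- function(dataset, models = MODEL_GRID, prior = "normal",
                     chain = chain_control(), seed = 1L,
                     pi_a = 0.05, pi_g = 0.05, window = 5L,
                     cv = FALSE, k = 11L, out_dir = NULL) {
  models <- match.arg(models, MODEL_GRID, several.ok = TRUE)
  prior <- match.arg(prior, c("normal", "mixture"))
  fits <- list(); partitions <- list(); cvs <- list(); failures <- list()
  for (mdl in models) {
    comps <- grid_components(mdl)
    sp <- model_spec(
      components = comps,
      prior_snp = if (prior == "mixture" && "SNP" %in% comps) "mixture" else "normal",
      prior_gex = if (prior == "mixture" && "GEX" %in% comps) "mixture" else "normal",
      pi_a = pi_a, pi_g = pi_g, chain = chain, seed = seed)
    res <- tryCatch({
      blocks <- design_blocks(dataset$phenotypes, dataset$pedigree,
                              dataset$genotypes, dataset$map,
                              dataset$expressions, components = comps)
      if (sum(blocks$obs) < 30L) {
        stop("fewer than 30 aligned phenotyped individuals")
      }
      fit <- if (any(c(sp$prior_snp, sp$prior_gex) == "mixture")) {
        run_bvs(NULL, blocks, spec = sp)
      } else run_mixed_model(NULL, blocks, spec = sp)
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("model ", mdl, " failed: ", conditionMessage(res))
      failures[[mdl]] <- conditionMessage(res)
      next
    }
    fits[[mdl]] <- res
    partitions[[mdl]] <- variance_partition(res, by_chromosome = TRUE,
                                            window = window)
    if (cv) cvs[[mdl]] <- crossvalidate(dataset, spec = sp, k = k,
                                        fold_seed = seed + 1000L)
  }
  if (!length(fits)) stop("every requested grid model failed")

  rows <- c("E", "PED", "SNP", "GEX", "residual")
  master_num <- sapply(names(partitions), function(mdl) {
    tab <- partitions[[mdl]]$components
    setNames(tab$pm[match(rows, tab$component)], rows)
  })
  master_num <- rbind(master_num,
                      explained_total = vapply(partitions, function(p)
                        p$explained_total, 0),
                      total = vapply(partitions, function(p) p$total, 0))
  master <- sapply(names(partitions), function(mdl) {
    tab <- partitions[[mdl]]$components
    cell <- function(cmp) {
      i <- match(cmp, tab$component)
      if (is.na(i)) return("-")
      sprintf("%.3g(%.2g) %.0f%%", tab$pm[i], tab$psd[i],
              100 * tab$prop_explained[i])
    }
    c(E = cell("E"), P = cell("PED"), S = cell("SNP"), G = cell("GEX"),
      Residual = sprintf("%.3g", tab$pm[tab$component == "residual"]),
      Total = sprintf("%.3g", partitions[[mdl]]$explained_total))
  })
  master <- data.frame(component = rownames(master), master,
                       check.names = FALSE, row.names = NULL)

  contrast <- NULL
  if (all(c("SNP", "SNP+GEX") %in% names(partitions))) {
    contrast <- eqtl_contrast(partitions[["SNP"]], partitions[["SNP+GEX"]])
  }
  out <- structure(list(fits = fits, partitions = partitions,
                        master = master, master_numeric = master_num,
                        cv = if (cv) cvs else NULL, contrast = contrast,
                        failures = failures, prior = prior, seed = seed),
                   class = "ov_grid")
  if (!is.null(out_dir)) write_grid(out, out_dir, chain = chain)
  out
}

#' @export
print.ov_grid <- function(x, ...) {
  cat("ov_grid (", x$prior, " priors): ", length(x$fits), " model(s)\n",
      sep = "")
  print(x$master, row.names = FALSE)
  if (!is.null(x$cv)) {
    cat("\ncross-validation:\n")
    for (mdl in names(x$cv)) {
      cat(sprintf("  %-12s rho = %.3f  beta = %.3f\n", mdl,
                  x$cv[[mdl]]$rho, x$cv[[mdl]]$beta))
    }
  }
  invisible(x)
}

write_grid <- function(grid, out_dir, chain = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(grid$master, "master_table")
  wt(data.frame(component = rownames(grid$master_numeric),
                grid$master_numeric, check.names = FALSE), "master_numeric")
  for (mdl in names(grid$partitions)) {
    p <- grid$partitions[[mdl]]
    safe <- gsub("+", "_", mdl, fixed = TRUE)
    wt(p$components, paste0("partition_", safe))
    if (!is.null(p$chromosomes)) wt(p$chromosomes, paste0("chromosomes_", safe))
    if (!is.null(p$windows)) wt(p$windows, paste0("windows_", safe))
  }
  if (!is.null(grid$contrast)) {
    wt(grid$contrast$chromosomes, "eqtl_contrast_chromosomes")
    wt(grid$contrast$windows, "eqtl_contrast_windows")
  }
  if (!is.null(grid$cv)) {
    for (mdl in names(grid$cv)) {
      safe <- gsub("+", "_", mdl, fixed = TRUE)
      wt(grid$cv[[mdl]]$predictions, paste0("cv_predictions_", safe))
    }
    jsonlite::write_json(
      lapply(grid$cv, function(z) list(rho = z$rho, beta = z$beta, k = z$k)),
      file.path(out_dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(models = names(grid$fits), prior = grid$prior, seed = grid$seed,
         chain = if (!is.null(chain)) unclass(chain),
         failures = grid$failures,
         package_version = as.character(utils::packageVersion("omixvar"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a YAML run configuration
#'
#' Keys: `files` (pedigree/genotypes/map/expressions/phenotypes paths),
#' `models`, `prior`, `chain` (`n_iter`, `burn_in`, `thin`), `pi_a`,
#' `pi_g`, `cv` (`k` or false), `seed`, `out_dir`.  Missing keys fall back
#' to the package defaults.
#'
#' @param path YAML file.
#' @return a named list with a `files` element and fit options.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$models <- if (is.null(cfg$models)) MODEL_GRID else unlist(cfg$models)
  cfg$prior <- if (is.null(cfg$prior)) "normal" else cfg$prior
  ch <- cfg$chain
  cfg$chain <- chain_control(
    n_iter = if (is.null(ch$n_iter)) 100000L else ch$n_iter,
    burn_in = if (is.null(ch$burn_in)) 10000L else ch$burn_in,
    thin = if (is.null(ch$thin)) 5L else ch$thin)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}
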