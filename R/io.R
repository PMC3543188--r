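read_delim_auto <- function(path, header = TRUE, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  read.table(path, header = header, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", ...)
}

#' Read a genotype dosage matrix
#'
#' Delimited individuals x SNPs table (first column = individual id,
#' remaining columns = dosages, 0/1/2 or real-valued as in a PLINK-style
#' additive-coded `.raw` export).  Columns named `FID`, `PAT`, `MAT`,
#' `SEX`, `PHENOTYPE` (the PLINK raw preamble) are dropped if present, and
#' trailing allele suffixes (`snp_A`) can be stripped with
#' `strip_allele_suffix`.
#'
#' @param path delimited text file.
#' @param id_col name or index of the individual-id column (default: first;
#'   `IID` preferred when present).
#' @param strip_allele_suffix drop a trailing `_<allele>` from SNP names.
#' @return numeric matrix with individual-id rownames.
#' @export
read_genotypes <- function(path, id_col = NULL, strip_allele_suffix = FALSE) {
  df <- read_delim_auto(path)
  drop <- intersect(c("FID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
  if (is.null(id_col)) id_col <- if ("IID" %in% names(df)) "IID" else 1L
  ids <- as.character(df[[col_ref(df, id_col)]])
  df <- df[, setdiff(seq_along(df), c(col_ref(df, id_col),
                                      match(drop, names(df)))), drop = FALSE]
  M <- as.matrix(df)
  storage.mode(M) <- "double"
  rownames(M) <- ids
  if (strip_allele_suffix) colnames(M) <- sub("_[ACGT0-9]+$", "", colnames(M))
  M
}

#' Read a marker map
#'
#' Delimited text with columns `snp_id`, `chr`, `pos` (and optionally
#' `order`); rows are sorted into map order (chr, then pos).
#'
#' @param path delimited text file.
#' @return data.frame with `snp_id`, `chr`, `pos`, `order`.
#' @export
read_marker_map <- function(path) {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  need <- c("snp_id", "chr", "pos")
  if (!all(need %in% names(df))) {
    stop("marker map needs columns snp_id, chr, pos")
  }
  df <- df[order(df$chr, df$pos), , drop = FALSE]
  df$order <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Read an expression matrix
#'
#' Delimited individuals x probes real-valued table, first column (or
#' `id_col`) holding individual ids.
#'
#' @inheritParams read_genotypes
#' @return numeric matrix with individual-id rownames.
#' @export
read_expressions <- function(path, id_col = 1L) {
  df <- read_delim_auto(path)
  ids <- as.character(df[[col_ref(df, id_col)]])
  M <- as.matrix(df[, -col_ref(df, id_col), drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M
}

#' Read a phenotype table
#'
#' Delimited text with columns `id`, a trait column, and optional `batch`
#' and `sex`.
#'
#' @param path delimited text file.
#' @param trait name of the trait column (default: the first non-id,
#'   non-batch, non-sex column).
#' @param missing tokens read as a missing trait value.
#' @return data.frame with columns `id`, `trait`, `batch`, `sex`.
#' @export
read_phenotypes <- function(path, trait = NULL, missing = c("NA", ".", "")) {
  df <- read_delim_auto(path)
  names(df)[1L] <- "id"
  if (is.null(trait)) {
    trait <- setdiff(names(df), c("id", "batch", "sex"))[1L]
  }
  tv <- as.character(df[[trait]])
  tv[tv %in% missing] <- NA
  out <- data.frame(id = as.character(df$id), trait = as.numeric(tv),
                    stringsAsFactors = FALSE)
  out$batch <- if ("batch" %in% names(df)) df$batch else 1L
  out$sex <- if ("sex" %in% names(df)) df$sex else "U"
  out
}

#' Write a simulated dataset as the delimited files the readers consume
#'
#' Emits `pedigree.csv`, `genotypes.tsv`, `map.tsv`, `expressions.tsv`,
#' `phenotypes.tsv` and `truth.json` into a directory.
#'
#' @param dataset an `ov_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- as.data.frame(dataset$pedigree)
  ped[is.na(ped)] <- "0"
  write.table(ped, file.path(dir, "pedigree.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  gt <- data.frame(id = rownames(dataset$genotypes), dataset$genotypes,
                   check.names = FALSE)
  write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$map, file.path(dir, "map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ex <- data.frame(id = rownames(dataset$expressions),
                   round(dataset$expressions, 6L), check.names = FALSE)
  write.table(ex, file.path(dir, "expressions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$phenotypes, file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    tr$components <- NULL  # large vectors; reproducible from the seed
    for (nm in c("fractions_target", "fractions_realized", "u_full")) {
      if (!is.null(names(tr[[nm]]))) tr[[nm]] <- as.list(tr[[nm]])
    }
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory holding the delimited files.
#' @return an `ov_dataset` (without a truth record unless `truth.json`
#'   exists).
#' @export
read_dataset <- function(dir) {
  ds <- list(
    pedigree = read_pedigree(file.path(dir, "pedigree.csv")),
    genotypes = read_genotypes(file.path(dir, "genotypes.tsv")),
    map = read_marker_map(file.path(dir, "map.tsv")),
    expressions = read_expressions(file.path(dir, "expressions.tsv")),
    phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv")))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) ds$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  structure(ds, class = "ov_dataset")
}

#' Persist posterior samples as delimited files plus a run manifest
#'
#' Writes one TSV per parameter block (`mu`, `b`, `u`, `a`, `g`, indicator
#' means, variances) and a JSON manifest recording the seed, component set,
#' chain settings and package version.
#'
#' @param fit an `ov_fit`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    write.table(round(as.data.frame(x), 8L), file.path(dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  s <- fit$samples
  wt(data.frame(mu = s$mu), "mu")
  if (ncol(s$b)) wt(s$b, "b")
  for (nm in c("u", "a", "g", "gamma_a", "gamma_g")) {
    if (!is.null(s[[nm]])) wt(s[[nm]], nm)
  }
  wt(s$variances, "variances")
  jsonlite::write_json(
    c(fit$meta, list(package_version = as.character(utils::packageVersion("omixvar")))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
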