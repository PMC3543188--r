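#' Center and scale a covariate block
#'
#' Prepares a SNP-dosage or expression block for whole-omics regression:
#' missing entries are column-mean imputed, monomorphic (zero-variance)
#' columns are dropped with a warning, and every retained column is centered
#' to mean zero and scaled to unit variance (divisor `n - 1`).  Centering and
#' unit scaling put the per-column prior variances of the model on a common,
#' interpretable scale.
#'
#' @param M numeric matrix, individuals in rows, covariates in columns.
#' @param scale if `FALSE`, columns are centered only.
#' @return the transformed matrix, with attributes `dropped` (names/indices
#'   of removed zero-variance columns), `imputed` (count of imputed cells),
#'   `center` and `scale` (the statistics used, for applying the identical
#'   transform to new rows).
#' @export
center_scale <- function(M, scale = TRUE) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(ncol(M)))
  all_na <- colSums(!is.na(M)) == 0L
  if (any(all_na)) {
    stop("column(s) entirely missing: ",
         paste(colnames(M)[all_na], collapse = ", "))
  }
  n_imp <- sum(is.na(M))
  if (n_imp > 0L) {
    mns <- colMeans(M, na.rm = TRUE)
    nas <- which(is.na(M), arr.ind = TRUE)
    M[nas] <- mns[nas[, 2L]]
    message("center_scale: mean-imputed ", n_imp, " missing entries")
  }
  ctr <- colMeans(M)
  M <- sweep(M, 2L, ctr, "-")
  sds <- apply(M, 2L, sd)
  dropped <- colnames(M)[sds == 0]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " zero-variance column(s): ",
            paste(head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
    keep <- sds > 0
    M <- M[, keep, drop = FALSE]
    ctr <- ctr[keep]; sds <- sds[keep]
  }
  if (scale) M <- sweep(M, 2L, sds, "/")
  structure(M, dropped = dropped, imputed = n_imp, center = ctr,
            scale = if (scale) sds else rep(1, length(ctr)))
}
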