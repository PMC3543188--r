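# Independent oracles used by the test suite.  These deliberately avoid the
# package's own computational paths.

# Monte-Carlo gene dropping: kinship f_ij estimated by dropping founder
# alleles down the pedigree and scoring identity-by-descent; A = 2 * kinship
# for off-diagonals, diag = 1 + f(sire, dam).
gene_drop_A <- function(ped, n_drops = 1e5) {
  n <- nrow(ped)
  idx <- attr(ped, "id_index")
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  al1 <- matrix(0L, n_drops, n); al2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      al1[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick, al1[, si[i]], al2[, si[i]])
    }
    if (is.na(di[i])) {
      al2[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick, al1[, di[i]], al2[, di[i]])
    }
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      f <- mean((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
                  (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])) / 4
      if (i == j) {
        # f_ii = (1 + F_i)/2; A_ii = 2 f_ii
        A[i, i] <- 2 * f
      } else {
        A[i, j] <- 2 * f; A[j, i] <- 2 * f
      }
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# Exact REML for the animal model y = Xb + Zu + e, u ~ N(0, A su2):
# eigen-decomposition of the projected covariance, 1-D profile likelihood in
# lambda = su2/se2.
reml_animal <- function(y, X, Z, A) {
  n <- length(y); p <- qr(X)$rank
  Qx <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  M <- t(Qx) %*% (Z %*% A %*% t(Z)) %*% Qx
  e2 <- eigen(M, symmetric = TRUE)
  d <- e2$values; yt <- drop(t(e2$vectors) %*% t(Qx) %*% y)
  nll <- function(loglam) {
    lam <- exp(loglam); w <- lam * d + 1
    se2 <- sum(yt^2 / w) / (n - p)
    0.5 * (sum(log(w)) + (n - p) * log(se2))
  }
  o <- optimize(nll, c(-12, 12))
  lam <- exp(o$minimum)
  se2 <- sum(yt^2 / (lam * d + 1)) / (n - p)
  c(su2 = lam * se2, se2 = se2)
}

# Closed-form Bayesian linear regression with fixed noise and prior
# variances; prior precision 0 encodes a flat prior (e.g. the intercept).
conjugate_posterior <- function(y, X, sigma_e2, prior_prec) {
  P <- crossprod(X) / sigma_e2 + diag(prior_prec, nrow = ncol(X))
  S <- solve(P)
  list(mean = drop(S %*% crossprod(X, y)) / sigma_e2, cov = S)
}

# incidence matrix of phenotyped rows into pedigree entries
incidence_Z <- function(blocks) {
  Z <- matrix(0, length(blocks$y), blocks$n_ped)
  Z[cbind(seq_along(blocks$y), blocks$zmap + 1L)] <- 1
  Z
}
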