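# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# the bundled small synthetic dataset (200 F2, 100 SNPs, 200 probes)
fixture_ds <- function() cached("fixture", simulate_fixture(seed = 1))

fixture_blocks <- function() {
  cached("fixture_blocks", {
    ds <- fixture_ds()
    design_blocks(ds$phenotypes, ds$pedigree, ds$genotypes, ds$map,
                  ds$expressions)
  })
}

# short exploratory chain used where only rough posteriors are needed
quick_chain <- function(n_iter = 6000L, burn_in = 2000L, thin = 4L) {
  chain_control(n_iter, burn_in, thin)
}

# hand-built 6-member pedigree: founders s,d; full sibs x,y; z from the
# full-sib mating x * y; w an unrelated founder
hand_pedigree <- function() {
  as_pedigree(id = c("s", "d", "x", "y", "z", "w"),
              sire = c(NA, NA, "s", "s", "x", NA),
              dam = c(NA, NA, "d", "d", "y", NA))
}

# the exact A of hand_pedigree(), from the tabular recursion done by hand:
# A_xy = 0.5, A_zz = 1 + 0.5*A_xy = 1.25, A_zx = 0.5*(A_xx + A_xy) = 0.75,
# A_zs = 0.5*(A_xs + A_ys) = 0.5
hand_A <- function() {
  A <- matrix(0, 6, 6, dimnames = list(c("s","d","x","y","z","w"),
                                       c("s","d","x","y","z","w")))
  A["s","s"] <- 1; A["d","d"] <- 1; A["w","w"] <- 1
  A["x","x"] <- 1; A["y","y"] <- 1; A["z","z"] <- 1.25
  A["x","s"] <- A["s","x"] <- 0.5; A["x","d"] <- A["d","x"] <- 0.5
  A["y","s"] <- A["s","y"] <- 0.5; A["y","d"] <- A["d","y"] <- 0.5
  A["x","y"] <- A["y","x"] <- 0.5
  A["z","x"] <- A["x","z"] <- 0.75; A["z","y"] <- A["y","z"] <- 0.75
  A["z","s"] <- A["s","z"] <- 0.5; A["z","d"] <- A["d","z"] <- 0.5
  A
}

# random valid pedigree: founders plus animals whose parents are drawn from
# earlier animals (or unknown)
random_pedigree <- function(n, n_founders = max(4L, n %/% 10L), p_unknown = 0.1) {
  id <- paste0("a", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    if (runif(1) > p_unknown) sire[i] <- id[sample.int(i - 1L, 1L)]
    if (runif(1) > p_unknown) {
      repeat {
        cand <- sample.int(i - 1L, 1L)
        if (is.na(sire[i]) || id[cand] != sire[i]) break
      }
      dam[i] <- id[cand]
    }
  }
  as_pedigree(id, sire, dam)
}
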