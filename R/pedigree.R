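#' Read a pedigree from delimited text
#'
#' Reads a three-or-more column delimited file (CSV or TSV, autodetected) with
#' animal, sire and dam identifier columns, normalizes missing-parent tokens,
#' and returns a topologically ordered pedigree: every parent precedes its
#' offspring regardless of file order.
#'
#' Parents that are referenced but never declared as animals are auto-created
#' as founder records with a warning.  Duplicate animal ids and ancestry
#' cycles are hard errors.
#'
#' @param path path to a delimited text file.
#' @param id,sire,dam column names (or 1-based indices) of the animal, sire
#'   and dam columns.  Defaults are the first three columns.
#' @param missing character vector of tokens encoding an unknown parent.
#' @param sep field separator; `NULL` autodetects comma vs whitespace/tab.
#' @return an object of class `ov_pedigree`: a data.frame with character
#'   columns `id`, `sire`, `dam` (`NA` for unknown parents) in topological
#'   order, with an `id_index` attribute mapping id to row.
#' @seealso [numerator_relationship()], [a_inverse()]
#' @export
read_pedigree <- function(path, id = 1L, sire = 2L, dam = 3L,
                          missing = c("0", ".", "NA", ""), sep = NULL) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  }
  df <- read.table(path, header = looks_like_header(path, sep), sep = sep,
                   colClasses = "character", stringsAsFactors = FALSE,
                   strip.white = TRUE, comment.char = "")
  as_pedigree(df[[col_ref(df, id)]], df[[col_ref(df, sire)]],
              df[[col_ref(df, dam)]], missing = missing)
}

col_ref <- function(df, ref) {
  if (is.numeric(ref)) return(as.integer(ref))
  m <- match(tolower(ref), tolower(names(df)))
  if (is.na(m)) stop("column not found: ", ref)
  m
}

looks_like_header <- function(path, sep) {
  first <- strsplit(readLines(path, n = 1L), if (sep == "") "[ \t]+" else sep)[[1]]
  any(grepl("[A-Za-z]", first)) &&
    any(grepl("id|animal|sire|dam|sir|mother|father", tolower(first)))
}

#' Build a pedigree from id/sire/dam vectors
#'
#' Core constructor behind [read_pedigree()].  Applies the missing-parent
#' convention, auto-creates undeclared parents as founders (with a warning),
#' checks for duplicates and cycles, and topologically sorts the records.
#'
#' @param id,sire,dam character vectors of equal length.
#' @param missing tokens (besides `NA`) that encode an unknown parent.
#' @return an `ov_pedigree` object (see [read_pedigree()]).
#' @export
as_pedigree <- function(id, sire, dam, missing = c("0", ".", "NA", "")) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (anyDuplicated(id)) {
    stop("duplicate animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sire[sire %in% missing | is.na(sire)] <- NA_character_
  dam[dam %in% missing | is.na(dam)] <- NA_character_
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    warning("parent id(s) never declared as animals; added as founders: ",
            paste(parents, collapse = ", "))
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  ord <- ped_toposort(id, sire, dam)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  attr(ped, "id_index") <- setNames(seq_len(nrow(ped)), ped$id)
  class(ped) <- c("ov_pedigree", "data.frame")
  ped
}

# Kahn-style topological sort over the parent->offspring DAG; errors on a
# cycle and names one animal inside it.
ped_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  si <- unname(idx[sire]); di <- unname(idx[dam])
  indeg <- integer(n)
  indeg[!is.na(si)] <- indeg[!is.na(si)] + 1L
  indeg[!is.na(di)] <- indeg[!is.na(di)] + 1L
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    # keep file order among ready nodes for reproducibility
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- setdiff(seq_len(n), out)
    stop("pedigree contains an ancestry cycle involving: ",
         paste(id[bad], collapse = ", "))
  }
  out
}

#' @export
print.ov_pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("ov_pedigree: %d animals (%d founders)\n", nrow(x), nf))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Numerator relationship matrix from a pedigree
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' method: processing animals in topological order,
#' `A[i, j] = 0.5 * (A[sire(i), j] + A[dam(i), j])` for previously processed
#' `j`, and `A[i, i] = 1 + 0.5 * A[sire(i), dam(i)]`.  Unknown parents
#' contribute zero relationship, i.e. missing parents are treated as
#' unrelated, non-inbred base animals.
#'
#' A is twice the kinship matrix; diagonal entries are `1 + F_i` with `F_i`
#' the inbreeding coefficient.
#'
#' @param ped an `ov_pedigree` object.
#' @return a dense symmetric matrix with dimnames equal to the animal ids.
#' @export
numerator_relationship <- function(ped) {
  stopifnot(inherits(ped, "ov_pedigree"))
  n <- nrow(ped)
  idx <- attr(ped, "id_index")
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules with the
#' inbreeding correction: the Mendelian-sampling variance of animal `i` is
#' `d_i = 0.5 - 0.25 * (F_s + F_d)` when both parents are known,
#' `0.75 - 0.25 * F_p` with one known parent `p`, and `1` for founders, where
#' parental inbreeding coefficients `F` come from the tabular diagonal.
#' A dense inversion is never performed, so the construction scales to large
#' pedigrees.
#'
#' @param ped an `ov_pedigree` object.
#' @return a sparse symmetric `Matrix::dsCMatrix` with animal-id dimnames.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "ov_pedigree"))
  n <- nrow(ped)
  idx <- attr(ped, "id_index")
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  Fcoef <- inbreeding_coefficients(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- v
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    np <- sum(!is.na(c(s, d)))
    dI <- if (np == 2L) 0.5 - 0.25 * (Fcoef[s] + Fcoef[d])
          else if (np == 1L) 0.75 - 0.25 * Fcoef[c(s, d)[!is.na(c(s, d))]]
          else 1
    al <- 1 / dI
    add(i, i, al)
    for (p in c(s, d)[!is.na(c(s, d))]) {
      add(i, p, -al / 2); add(p, i, -al / 2)
    }
    ps <- c(s, d)[!is.na(c(s, d))]
    for (p in ps) for (q in ps) add(p, q, al / 4)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  methods::as(Matrix::forceSymmetric(M), "CsparseMatrix")
}

#' Inbreeding coefficients from the tabular method
#'
#' Runs the tabular recursion keeping only what is needed for the diagonal,
#' i.e. the full A of all ancestors (pedigrees here are small enough that the
#' dense tabular pass is cheap).
#'
#' @param ped an `ov_pedigree` object.
#' @return named numeric vector of inbreeding coefficients `F_i = A_ii - 1`.
#' @export
inbreeding_coefficients <- function(ped) {
  A <- numerator_relationship(ped)
  setNames(diag(A) - 1, ped$id)
}

#' Export a relationship matrix (or its inverse) as coordinate text
#'
#' Writes the non-zero entries of a symmetric matrix as `(i, j, value)`
#' triplets (upper triangle, 1-based indices, id labels included) for
#' inspection outside R.
#'
#' @param M dense or sparse symmetric matrix with dimnames.
#' @param path output file path (tab-separated text).
#' @export
write_coord_matrix <- function(M, path) {
  M <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  keep <- M@i <= M@j
  df <- data.frame(i = M@i[keep] + 1L, j = M@j[keep] + 1L,
                   id_i = rownames(M)[M@i[keep] + 1L],
                   id_j = colnames(M)[M@j[keep] + 1L],
                   value = M@x[keep])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
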