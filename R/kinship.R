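#' (Weighted) genomic relationship matrix
#'
#' G = Z D Z' * lambda, the VanRaden construction with an optional diagonal
#' matrix D of per-SNP variance weights (D = I gives the unweighted G).
#'
#' @param Z centered gene-content matrix from [gene_content_centered()].
#' @param lambda scaling constant 1 / sum(2 p (1 - p)).
#' @param weights optional per-marker weight vector d (default all 1).
#' @return Dense symmetric samples-by-samples matrix.
#' @export
genomic_matrix <- function(Z, lambda, weights = NULL) {
  d <- weights %||% rep(1, ncol(Z))
  assert_that(length(d) == ncol(Z), "weights length must equal marker count")
  G <- tcrossprod(sweep(Z, 2, d, `*`), Z) * lambda
  symmetrize(G)
}

#' Blend G with the pedigree submatrix for invertibility
#'
#' G* = tau G + (1 - tau) A22. A small pedigree admixture guarantees a
#' positive-definite, invertible genomic matrix even when G is singular
#' (duplicate samples, fewer markers than animals).
#'
#' @param G genomic matrix (genotyped animals).
#' @param A22 pedigree relationship matrix for the same animals, same order.
#' @param tau blending proportion on G (default 0.95).
#' @return Blended matrix G*.
#' @export
blend_grm <- function(G, A22, tau = 0.95) {
  assert_that(all(dim(G) == dim(A22)), "G and A22 dimensions differ")
  if (!is.null(dimnames(G)[[1]]) && !is.null(dimnames(A22)[[1]]) &&
      !identical(dimnames(G)[[1]], dimnames(A22)[[1]]))
    abort("G and A22 id ordering differs")
  tau * G + (1 - tau) * as.matrix(A22)
}

#' Single-step H inverse
#'
#' H^-1 = A^-1 + \[0 0; 0 G^-1 - A22^-1\] on the genotyped block: identical to
#' the pedigree inverse everywhere except among genotyped animals.
#'
#' @param Ainv sparse pedigree inverse for all animals (dimnames = ids).
#' @param Ginv inverse of the (blended) genomic matrix, genotyped animals.
#' @param A22inv inverse of the genotyped-subset pedigree matrix, same order
#'   as `Ginv`.
#' @param genotyped_ids animal ids of the genotyped block, in `Ginv` order;
#'   must all be present in `Ainv`.
#' @return Sparse symmetric H^-1 with the full animal ordering of `Ainv`.
#' @export
h_inverse <- function(Ainv, Ginv, A22inv, genotyped_ids) {
  ids <- rownames(Ainv)
  if (length(genotyped_ids) == 0) return(Ainv)
  idx <- match(genotyped_ids, ids)
  if (anyNA(idx))
    abort(paste("genotyped animals absent from pedigree:",
                paste(genotyped_ids[is.na(idx)], collapse = ", ")))
  assert_that(all(dim(Ginv) == length(idx)) && all(dim(A22inv) == length(idx)),
              "Ginv/A22inv not conformable with genotyped ids")
  Hinv <- as(Ainv, "CsparseMatrix")
  delta <- as.matrix(Ginv) - as.matrix(A22inv)
  Hinv[idx, idx] <- Hinv[idx, idx] + delta
  Matrix::forceSymmetric((Hinv + Matrix::t(Hinv)) / 2)
}

#' Write a relationship matrix as TSV
#'
#' Dense matrices are written id-indexed (first column `id`, one column per
#' animal); sparse matrices in coordinate form (`row_id`, `col_id`, `value`,
#' nonzeros only).
#'
#' @param M matrix (base or Matrix) with id dimnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(M, path) {
  assert_that(!is.null(rownames(M)), "matrix must carry id dimnames")
  if (methods::is(M, "sparseMatrix")) {
    tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
    df <- tibble(row_id = rownames(M)[tm@i + 1L],
                 col_id = colnames(M)[tm@j + 1L],
                 value = tm@x)
    readr::write_tsv(df, path)
  } else {
    df <- as_tibble(as.data.frame(as.matrix(M)))
    df <- dplyr::bind_cols(tibble(id = rownames(M)), df)
    readr::write_tsv(df, path)
  }
  invisible(path)
}

# symmetric Moore-Penrose pseudo-inverse by eigendecomposition; eigenvalues
# below rel_tol * max are treated as the null space
sym_pseudo_inverse <- function(M, rel_tol = 1e-9) {
  eg <- eigen(symmetrize(M), symmetric = TRUE)
  pos <- eg$values > rel_tol * max(abs(eg$values))
  V <- eg$vectors[, pos, drop = FALSE]
  V %*% (t(V) / eg$values[pos])
}

# x = G^+ b for a centered genomic G (null space = span(1)) and b with zero
# mean: solve (G + theta 11'/g) x = b by Cholesky — the rank-1 shift acts
# only on the null direction — then polish with iterative refinement; fall
# back to the eigen pseudo-inverse if G is rank-deficient beyond span(1).
g_pseudo_solve <- function(G, b, refine = 2L) {
  g <- nrow(G)
  theta <- mean(diag(G))
  Gs <- G + theta / g
  ch <- tryCatch(chol(Gs), error = function(e) NULL)
  if (!is.null(ch)) {
    x <- backsolve(ch, forwardsolve(t(ch), b))
    for (k in seq_len(refine)) {
      r <- b - as.numeric(G %*% x)
      r <- r - mean(r)
      x <- x + backsolve(ch, forwardsolve(t(ch), r))
      x <- x - mean(x)
    }
    rel <- sqrt(sum((as.numeric(G %*% x) - b)^2)) /
      max(sqrt(sum(b^2)), .Machine$double.eps)
    if (rel < 1e-8) return(x)
  }
  as.numeric(sym_pseudo_inverse(G) %*% b)
}

#' Assemble the full single-step kinship set
#'
#' Convenience wrapper building A^-1, A22 and its inverse, the (weighted,
#' blended) genomic matrix and H^-1 from a pedigree plus post-QC markers.
#'
#' @param ped ordered pedigree.
#' @param md post-QC [marker_data()] whose samples are the genotyped animals.
#' @param weights optional per-marker weights for G.
#' @param tau blending proportion passed to [blend_grm()].
#' @param use_inbreeding passed to [a_inverse()].
#' @return List: `Ainv`, `Hinv`, `G` (unblended), `Gstar`, `Ginv`, `A22`,
#'   `A22inv`, `genotyped_ids`, `Z`, `lambda`, `p`.
#' @export
kinship_set <- function(ped, md, weights = NULL, tau = 0.95,
                        use_inbreeding = TRUE) {
  geno_ids <- rownames(md$calls)
  missing <- setdiff(geno_ids, ped$animal)
  if (length(missing) > 0)
    abort(paste("genotyped animals absent from pedigree:",
                paste(missing, collapse = ", ")))
  Ainv <- a_inverse(ped, use_inbreeding = use_inbreeding)
  A22 <- numerator_matrix(ped, subset = geno_ids)
  A22inv <- solve(A22)
  gc <- gene_content_centered(md)
  G <- genomic_matrix(gc$Z, gc$lambda, weights = weights)
  dimnames(G) <- list(geno_ids, geno_ids)
  Gstar <- blend_grm(G, A22, tau = tau)
  Ginv <- solve(Gstar)
  Hinv <- h_inverse(Ainv, Ginv, A22inv, geno_ids)
  list(Ainv = Ainv, Hinv = Hinv, G = G, Gstar = Gstar, Ginv = Ginv,
       A22 = A22, A22inv = A22inv, genotyped_ids = geno_ids,
       Z = gc$Z, lambda = gc$lambda, p = gc$p)
}
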