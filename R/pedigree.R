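#' Coerce a data frame to a validated, ordered pedigree
#'
#' Takes a data frame with columns `animal`, `sire`, `dam` (any coercible to
#' character), maps the unknown-parent code to `NA`, adds parents that never
#' appear as animals as founders, checks for duplicate ids and cycles, and
#' topologically sorts the records so that parents always precede offspring.
#'
#' @param x data frame with columns `animal`, `sire`, `dam`.
#' @param unknown_code code used for unknown parents (default `"0"`).
#' @return A tibble of class `pedigree` with character columns `animal`,
#'   `sire`, `dam` (`NA` = unknown parent), ordered parents-first.
#' @export
as_pedigree <- function(x, unknown_code = "0") {
  assert_that(all(c("animal", "sire", "dam") %in% names(x)),
              "pedigree needs columns animal, sire, dam")
  ped <- tibble(
    animal = as.character(x$animal),
    sire   = as.character(x$sire),
    dam    = as.character(x$dam)
  )
  ped$sire[ped$sire %in% c(unknown_code, "", NA)] <- NA_character_
  ped$dam[ped$dam %in% c(unknown_code, "", NA)] <- NA_character_
  if (anyDuplicated(ped$animal))
    abort(paste("duplicate animal id(s):",
                paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", ")))
  if (any(ped$animal == ped$sire | ped$animal == ped$dam, na.rm = TRUE))
    abort("animal listed as its own parent")

  # parents never listed as animals become founders
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(parents) > 0) {
    ped <- dplyr::bind_rows(
      tibble(animal = parents, sire = NA_character_, dam = NA_character_), ped)
  }

  ord <- ped_topo_order(ped)
  ped <- ped[ord, ]
  class(ped) <- c("pedigree", class(tibble()))
  ped
}

# Kahn topological sort over parent -> offspring edges; errors on cycles
ped_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  indeg <- as.integer(!is.na(si)) + as.integer(!is.na(di))
  # children adjacency
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0) {
    i <- queue[[1]]; queue <- queue[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != n) abort("cyclic pedigree: an animal is its own ancestor")
  out
}

#' Read a pedigree CSV
#'
#' Expects a header `animal,sire,dam`; `unknown_code` (default "0") marks
#' unknown parents.
#'
#' @inheritParams as_pedigree
#' @param path path to the CSV file.
#' @return A [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path, unknown_code = "0") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  as_pedigree(df, unknown_code = unknown_code)
}

# internal: integer parent indices of an ordered pedigree (NA = unknown)
ped_parent_idx <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  list(s = unname(idx[ped$sire]), d = unname(idx[ped$dam]))
}

#' Inbreeding coefficients from a pedigree
#'
#' Computes Wright's inbreeding coefficient for every animal by the tabular
#' method (F is the parents' additive relationship halved). Founders and
#' animals with an unknown parent get F = 0.
#'
#' @param ped an ordered [as_pedigree()] pedigree.
#' @return Named numeric vector of F in pedigree order.
#' @export
inbreeding <- function(ped) {
  A <- numerator_matrix(ped)
  setNames(Matrix::diag(A) - 1, ped$animal)
}

#' Numerator (additive) relationship matrix A by the tabular method
#'
#' The recurrence a_ij = (a_{i,sire(j)} + a_{i,dam(j)})/2 with diagonal
#' 1 + F_j builds the full matrix in pedigree order; `subset` restricts the
#' result to a block such as the genotyped animals (A22).
#'
#' @param ped ordered pedigree.
#' @param subset optional character vector of animal ids; rows/cols of the
#'   returned matrix, in the given order.
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
numerator_matrix <- function(ped, subset = NULL) {
  n <- nrow(ped)
  p <- ped_parent_idx(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- p$s[i]; d <- p$d[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  if (!is.null(subset)) {
    missing <- setdiff(subset, ped$animal)
    if (length(missing) > 0)
      abort(paste("subset ids not in pedigree:", paste(missing, collapse = ", ")))
    A <- A[subset, subset, drop = FALSE]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules: each animal contributes 1/d_i to its own diagonal,
#' -1/(2 d_i) to animal-parent cells and 1/(4 d_i) to parent-parent cells,
#' where d_i is the Mendelian sampling variance. With `use_inbreeding = TRUE`
#' (the default) d_i = 0.5 - 0.25 (F_s + F_d) for two known parents,
#' 0.75 - 0.25 F_p for one, and 1 for founders.
#'
#' @param ped ordered pedigree.
#' @param use_inbreeding account for inbreeding in d_i (default TRUE).
#' @param F optional precomputed inbreeding coefficients in pedigree order
#'   (skips the tabular pass).
#' @return Sparse symmetric `dgCMatrix` with animal ids as dimnames.
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE, F = NULL) {
  n <- nrow(ped)
  p <- ped_parent_idx(ped)
  F <- if (!use_inbreeding) numeric(n) else unname(F %||% inbreeding(ped))
  assert_that(length(F) == n, "F length must match the pedigree")
  ii <- integer(9 * n); jj <- integer(9 * n); xx <- numeric(9 * n)
  k <- 0L
  add <- function(i, j, x) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- x
  }
  for (i in seq_len(n)) {
    s <- p$s[i]; d <- p$d[i]
    known <- c(s, d)[!is.na(c(s, d))]
    di <- switch(length(known) + 1L,
                 1,
                 0.75 - 0.25 * F[known],
                 0.5 - 0.25 * (F[s] + F[d]))
    w <- 1 / di
    add(i, i, w)
    for (q in known) {
      add(i, q, -w / 2); add(q, i, -w / 2)
      for (r in known) add(q, r, w / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$animal, ped$animal))
  Ainv
}
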