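#' WssGWAS configuration
#'
#' Defaults follow the litter-trait workflow: 0.52 Mb windows (the LD-decay
#' distance), three weight iterations, and a 1.56% significance threshold —
#' fifty times the variance an average window would explain (0.031% x 50).
#'
#' @param window_bp window span in base pairs.
#' @param n_iterations number of SNP-weight iterations.
#' @param sig_threshold_pct windows explaining at least this percentage of
#'   the additive genetic variance are significant; set `NULL` to derive it
#'   as `threshold_fold * 100 / n_windows`.
#' @param threshold_fold fold-enrichment used when `sig_threshold_pct` is
#'   `NULL`.
#' @param weight_floor lower bound on SNP weights, preventing a degenerate
#'   all-zero diagonal.
#' @return List of class `wssgwas_config`.
#' @export
wssgwas_config <- function(window_bp = 520000, n_iterations = 3,
                           sig_threshold_pct = 1.56, threshold_fold = 50,
                           weight_floor = 1e-8) {
  assert_that(window_bp > 0, "window_bp must be positive")
  assert_that(n_iterations >= 1, "need at least one iteration")
  structure(list(window_bp = window_bp, n_iterations = n_iterations,
                 sig_threshold_pct = sig_threshold_pct,
                 threshold_fold = threshold_fold,
                 weight_floor = weight_floor),
            class = "wssgwas_config")
}

#' Back-solve SNP effects from GEBVs
#'
#' u = lambda D Z' G^-1 a_g: distributes the genomic breeding values of the
#' genotyped animals over markers. When `Ginv` is the inverse of the same
#' (unblended) weighted G = Z D Z' lambda that relates the markers, Z u
#' reconstructs a_g exactly.
#'
#' @param a_hat_g GEBVs of the genotyped animals, in `Z` row order.
#' @param Z centered gene-content matrix.
#' @param weights per-marker weights d (diagonal of D).
#' @param Ginv inverse genomic relationship matrix.
#' @param lambda VanRaden scaling constant.
#' @return Named numeric vector of SNP effects.
#' @export
backsolve_snp_effects <- function(a_hat_g, Z, weights, Ginv, lambda) {
  assert_that(length(a_hat_g) == nrow(Z), "a_hat_g length != samples in Z")
  assert_that(length(weights) == ncol(Z), "weights length != markers in Z")
  u <- lambda * weights * as.numeric(crossprod(Z, Ginv %*% a_hat_g))
  setNames(u, colnames(Z))
}

#' Update SNP weights from estimated effects
#'
#' d_i = u_i^2 * 2 p_i (1 - p_i): each marker's weight is the additive
#' variance its estimated effect explains.
#'
#' @param u per-marker effects.
#' @param p counted-allele frequencies.
#' @return Raw (un-normalized) weights, all non-negative.
#' @export
update_weights <- function(u, p) {
  assert_that(length(u) == length(p), "u and p length mismatch")
  as.numeric(u)^2 * 2 * p * (1 - p)
}

#' Normalize SNP weights to a constant trace
#'
#' Rescales the weights so trace(D) equals the marker count (the trace of the
#' initial D = I), keeping the total genetic variance constant across
#' iterations while preserving relative proportions. Weights are floored at
#' `floor_eps` first; an all-zero vector is floored everywhere with a
#' warning.
#'
#' @param d_raw raw weights from [update_weights()].
#' @param trace_target target trace (default: number of markers).
#' @param floor_eps weight floor.
#' @return Normalized weight vector with `sum(d) == trace_target`.
#' @export
normalize_weights <- function(d_raw, trace_target = length(d_raw),
                              floor_eps = 1e-8) {
  if (sum(d_raw) <= 0) {
    warn("all SNP weights are zero; flooring before normalization")
  }
  d <- pmax(d_raw, floor_eps)
  d * (trace_target / sum(d))
}

#' Run the weighted single-step GWAS loop
#'
#' Iterates: build the weighted genomic matrix G(t) = Z D(t) Z' lambda and
#' its blended single-step H^-1; solve the MME for GEBVs; back-solve SNP
#' effects from the genotyped animals' GEBVs using the unblended G(t);
#' square the effects into new weights and renormalize their trace; repeat.
#' Iteration 1 (D = I) is plain ssGBLUP.
#'
#' @param data trait records.
#' @param md post-QC [marker_data()]; its samples are the genotyped animals
#'   and must all appear in the pedigree.
#' @param ped ordered pedigree.
#' @param vc variance components for the MME solves.
#' @param cfg a [wssgwas_config()].
#' @param tau blending proportion for the H^-1 build. The back-solve always
#'   uses the unblended weighted G: its pseudo-inverse applied to the
#'   mean-centered GEBVs keeps the reconstruction Z u = a_g - mean(a_g)
#'   exact (the centered G annihilates the ones vector, so only deviations
#'   from the genotyped-group mean are attributable to markers).
#' @param F optional named inbreeding coefficients for accuracies.
#' @return Object of class `wssgwas_run`: per-iteration list with the MME
#'   `fit`, `gebv` tibble, SNP effects `u_hat`, the `weights` used, and the
#'   reconstruction error; plus the shared `Z`, `lambda`, `p`, `map` and
#'   `genotyped_ids`.
#' @export
run_wssgwas <- function(data, md, ped, vc, cfg = wssgwas_config(),
                        tau = 0.95, F = NULL) {
  if (inherits(vc, "reml_fit")) vc <- vc$vc
  geno_ids <- rownames(md$calls)
  gc <- gene_content_centered(md)
  Z <- gc$Z; lambda <- gc$lambda; p <- gc$p
  M <- ncol(Z)
  if (is.null(F)) F <- inbreeding(ped)
  Ainv <- a_inverse(ped, F = unname(F))
  A22 <- numerator_matrix(ped, subset = geno_ids)
  A22inv <- solve(A22)

  d <- rep(1, M)
  iterations <- vector("list", cfg$n_iterations)
  for (t in seq_len(cfg$n_iterations)) {
    G <- genomic_matrix(Z, lambda, weights = d)
    dimnames(G) <- list(geno_ids, geno_ids)
    Gstar <- blend_grm(G, A22, tau = tau)
    Ginv_star <- solve(Gstar)
    Hinv <- h_inverse(Ainv, Ginv_star, A22inv, geno_ids)
    fit <- solve_mme(data, vc, Hinv, F = F)
    a_g <- setNames(fit$solutions$ebv, fit$solutions$animal)[geno_ids]

    # SNP effects carry differences among animals, not the group level:
    # back-solve the mean-centered GEBVs. The centered G has the ones vector
    # in its null space, so a symmetric pseudo-inverse replaces the plain
    # inverse; on the centered GEBVs the reconstruction Z u = a_c is exact.
    a_c <- a_g - mean(a_g)
    x <- g_pseudo_solve(G, a_c)
    u <- setNames(lambda * d * as.numeric(crossprod(Z, x)), colnames(Z))
    recon <- as.numeric(Z %*% u)
    recon_err <- sqrt(sum((recon - a_c)^2)) /
      max(sqrt(sum(a_c^2)), .Machine$double.eps)
    if (recon_err > 1e-6)
      warn(sprintf("iteration %d: GEBV reconstruction error %.2e (weighted G is rank-deficient beyond its intrinsic null space)",
                   t, recon_err))

    iterations[[t]] <- list(
      iteration = t,
      fit = fit,
      gebv = tibble(animal = geno_ids, gebv = unname(a_g),
                    gebv_centered = unname(a_c)),
      u_hat = u,
      weights = d,
      reconstruction_error = recon_err
    )
    d <- normalize_weights(update_weights(u, p), trace_target = M,
                           floor_eps = cfg$weight_floor)
  }
  structure(list(iterations = iterations, Z = Z, lambda = lambda, p = p,
                 map = md$map, genotyped_ids = geno_ids, cfg = cfg,
                 sigma_a2 = unlist(vc)[["sigma_a2"]]),
            class = "wssgwas_run")
}

#' @export
print.wssgwas_run <- function(x, ...) {
  cat(sprintf("<wssgwas_run> %d iteration(s), %d genotyped animals, %d markers\n",
              length(x$iterations), length(x$genotyped_ids), ncol(x$Z)))
  for (it in x$iterations)
    cat(sprintf("  iter %d: reconstruction error %.2e, trace(D) = %.6f\n",
                it$iteration, it$reconstruction_error, sum(it$weights)))
  invisible(x)
}
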