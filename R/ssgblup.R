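#' Solve the mixed-model equations at fixed variance components
#'
#' Henderson's MME for the repeatability animal model, with `Kinv` either the
#' pedigree inverse (PBLUP) or the single-step H inverse (ssGBLUP). Returns
#' breeding values for every animal in `Kinv`, prediction-error variances from
#' the inverse coefficient matrix, and PEV-based accuracies when inbreeding
#' coefficients are supplied.
#'
#' @param data trait records (`animal`, `value`, optional `year_season`,
#'   `parity`).
#' @param vc variance components: a [fit_reml()] object or a named vector
#'   with `sigma_a2`, `sigma_pe2`, `sigma_e2`.
#' @param Kinv relationship inverse with animal-id dimnames.
#' @param F optional named inbreeding coefficients (default 0) used for
#'   accuracies.
#' @param fit_pe include the permanent-environment effect (default TRUE when
#'   `sigma_pe2 > 0`).
#' @return Object of class `mme_fit`: `fixed` (term, estimate), `solutions`
#'   (animal, ebv, pev, accuracy), `pe` (animal, pe_hat), residual norm of
#'   the equations, and the components used.
#' @export
solve_mme <- function(data, vc, Kinv, F = NULL, fit_pe = NULL) {
  if (inherits(vc, "reml_fit")) vc <- vc$vc
  v <- unlist(vc)
  sa <- v[["sigma_a2"]]; spe <- v[["sigma_pe2"]]; se <- v[["sigma_e2"]]
  assert_that(se > 0, "residual variance must be strictly positive")
  assert_that(sa > 0, "additive variance must be strictly positive")
  fit_pe <- fit_pe %||% (spe > 0)
  data <- as_tibble(data)
  des <- mme_design(data, Kinv, fit_pe = fit_pe)
  eng <- mme_engine(des, Kinv, sa, if (fit_pe) spe else 0, se)

  pev <- pmax(eng$diagCuu * se, 0)
  Fv <- setNames(rep(0, des$q), des$ids)
  if (!is.null(F)) Fv[names(F)] <- F
  acc <- accuracy_from_pev(pev, sa, Fv)

  structure(list(
    fixed = tibble(term = colnames(des$X), estimate = eng$b),
    solutions = tibble(animal = des$ids, ebv = unname(eng$a),
                       pev = unname(pev), accuracy = unname(acc)),
    pe = if (eng$has_pe) tibble(animal = des$rec_ids, pe_hat = unname(eng$pe))
         else tibble(animal = character(), pe_hat = numeric()),
    mme_resid_rel = eng$mme_resid_rel,
    vc = c(sigma_a2 = sa, sigma_pe2 = if (fit_pe) spe else 0, sigma_e2 = se),
    recorded = unique(as.character(data$animal))
  ), class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat(sprintf("<mme_fit> %d animals, %d fixed-effect levels, rel. MME residual %.2e\n",
              nrow(x$solutions), nrow(x$fixed), x$mme_resid_rel))
  invisible(x)
}

accuracy_from_pev <- function(pev, sigma_a2, F) {
  denom <- (1 + F) * sigma_a2
  over <- pev > denom * (1 + 1e-8)
  if (any(over))
    warn(sprintf("%d PEV value(s) exceed (1+F) sigma_a2; accuracy clipped to 0",
                 sum(over)))
  sqrt(pmin(pmax(1 - pev / denom, 0), 1))
}

#' PEV-based accuracy of (G)EBVs
#'
#' r_i = sqrt(1 - PEV_i / ((1 + F_i) sigma_a2)), clipped to \[0, 1\]. The
#' summary accuracy is the mean over animals with phenotype records.
#'
#' @param sol an [solve_mme()] fit.
#' @param vc variance components (only `sigma_a2` is used).
#' @param F optional named inbreeding coefficients (default 0).
#' @return Tibble (animal, pev, accuracy) with attribute `mean_accuracy`
#'   (mean over recorded animals).
#' @export
ebv_accuracy <- function(sol, vc, F = NULL) {
  if (inherits(vc, "reml_fit")) vc <- vc$vc
  sa <- unlist(vc)[["sigma_a2"]]
  Fv <- setNames(rep(0, nrow(sol$solutions)), sol$solutions$animal)
  if (!is.null(F)) Fv[names(F)] <- F
  acc <- unname(accuracy_from_pev(unname(sol$solutions$pev), sa, unname(Fv)))
  out <- tibble(animal = sol$solutions$animal, pev = unname(sol$solutions$pev),
                accuracy = acc)
  attr(out, "mean_accuracy") <-
    mean(acc[out$animal %in% sol$recorded])
  out
}

#' Compare PBLUP with WssGBLUP iterations
#'
#' Fits PBLUP (pedigree inverse) and runs the weighted single-step loop for
#' `n_iter` iterations on the same records, reporting the mean PEV-based
#' accuracy over recorded animals per method, and — when the true breeding
#' values are known (simulated data) — the correlation between estimated and
#' true breeding values over genotyped animals.
#'
#' @param data trait records.
#' @param md post-QC [marker_data()] for the genotyped animals.
#' @param ped ordered pedigree.
#' @param vc variance components used for all solves.
#' @param n_iter number of WssGBLUP weight iterations (default 3).
#' @param truth optional named vector of true breeding values.
#' @param eval_ids animals over which the truth correlation is computed;
#'   default: genotyped animals without own records (the selection-candidate
#'   set, where prediction accuracy is the question), falling back to all
#'   genotyped animals when every genotyped animal has records.
#' @param tau blending proportion for G.
#' @return Tibble: method, iteration, mean_accuracy, truth_correlation.
#' @export
compare_methods <- function(data, md, ped, vc, n_iter = 3, truth = NULL,
                            eval_ids = NULL, tau = 0.95) {
  if (inherits(vc, "reml_fit")) vc <- vc$vc
  Fv <- inbreeding(ped)
  Ainv <- a_inverse(ped, F = unname(Fv))
  pblup <- solve_mme(data, vc, Ainv, F = Fv)
  if (is.null(eval_ids)) {
    eval_ids <- setdiff(rownames(md$calls), unique(as.character(data$animal)))
    if (length(eval_ids) < 2) eval_ids <- rownames(md$calls)
  }
  rows <- list()
  truth_cor <- function(sol) {
    if (is.null(truth)) return(NA_real_)
    ids <- intersect(intersect(names(truth), sol$solutions$animal), eval_ids)
    stats::cor(sol$solutions$ebv[match(ids, sol$solutions$animal)], truth[ids])
  }
  rows[[1]] <- tibble(method = "PBLUP", iteration = NA_integer_,
                      mean_accuracy = attr(ebv_accuracy(pblup, vc, Fv),
                                           "mean_accuracy"),
                      truth_correlation = truth_cor(pblup))
  run <- run_wssgwas(data, md, ped, vc,
                     cfg = wssgwas_config(n_iterations = n_iter), tau = tau,
                     F = Fv)
  for (t in seq_len(n_iter)) {
    sol <- run$iterations[[t]]$fit
    rows[[t + 1]] <- tibble(method = "WssGBLUP", iteration = t,
                            mean_accuracy = attr(ebv_accuracy(sol, vc, Fv),
                                                 "mean_accuracy"),
                            truth_correlation = truth_cor(sol))
  }
  dplyr::bind_rows(rows)
}
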