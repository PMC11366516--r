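#' Heritability of a repeatability-model trait
#'
#' h2 = sigma_a2 / (sigma_a2 + sigma_pe2 + sigma_e2): the additive fraction of
#' the phenotypic variance, with the permanent-environment variance counted in
#' the denominator.
#'
#' @param vc a [fit_reml()] object, or a numeric vector/list containing
#'   `sigma_a2`, `sigma_pe2`, `sigma_e2` (an unnamed numeric triple is taken
#'   in that order).
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(vc) {
  if (inherits(vc, "reml_fit")) vc <- vc$vc
  v <- unlist(vc)
  if (is.null(names(v)) || !all(c("sigma_a2", "sigma_pe2", "sigma_e2") %in% names(v))) {
    assert_that(length(v) == 3, "need sigma_a2, sigma_pe2, sigma_e2")
    names(v) <- c("sigma_a2", "sigma_pe2", "sigma_e2")
  }
  assert_that(all(v >= 0), "variance components must be non-negative")
  tot <- sum(v[c("sigma_a2", "sigma_pe2", "sigma_e2")])
  assert_that(tot > 0, "total variance is zero")
  unname(v["sigma_a2"] / tot)
}

#' REML variance components for the repeatability animal model
#'
#' Average-information REML with EM fallback: each round computes the
#' AI (Newton-type) update from the average-information matrix and accepts it
#' only if it stays in the parameter space and does not decrease the
#' restricted likelihood, otherwise the EM-REML update is taken. The recorded
#' likelihood trajectory is therefore monotone. Standard errors come from the
#' inverse AI matrix at convergence; the heritability SE uses the delta
#' method.
#'
#' @param data trait records: columns `animal`, `value` and optionally
#'   `year_season`, `parity` (modelled as categorical fixed effects).
#' @param Kinv relationship inverse (pedigree A^-1 for PBLUP, single-step
#'   H^-1 for ssGBLUP) with animal-id dimnames.
#' @param fit_pe include a permanent-environment effect per animal with
#'   records (default TRUE).
#' @param start optional starting values `c(sigma_a2, sigma_pe2, sigma_e2)`.
#' @param max_iter,tol convergence: stop when the maximum relative component
#'   change falls below `tol` (default 1e-8) or after `max_iter` rounds.
#' @param verbose print per-round progress.
#' @return Object of class `reml_fit`: variance components with SEs, `h2`
#'   and `h2_se`, the log-likelihood trajectory, convergence flags, and the
#'   AI matrix.
#' @export
fit_reml <- function(data, Kinv, fit_pe = TRUE, start = NULL,
                     max_iter = 200, tol = 1e-8, verbose = FALSE) {
  data <- as_tibble(data)
  des <- mme_design(data, Kinv, fit_pe = fit_pe)
  y <- des$y
  n <- des$n; p <- des$p; q <- des$q
  vy <- var_pop(y)
  flags <- character(0)

  if (vy < .Machine$double.eps) {
    flags <- c(flags, "degenerate")
    warn("response has zero variance; components at lower bound")
    vc <- c(sigma_a2 = 1e-10, sigma_pe2 = if (fit_pe) 1e-10 else 0,
            sigma_e2 = 1e-10)
    return(new_reml_fit(vc, se = rep(NA_real_, 3), h2 = NA_real_,
                        h2_se = NA_real_, loglik = NA_real_,
                        trajectory = tibble(), converged = FALSE,
                        flags = flags, ai = NULL, n = n, q = q, s = des$s))
  }

  floor_v <- 1e-10 * vy
  logdetK <- -as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)

  theta <- start %||% c(0.3, if (fit_pe) 0.2 else 0, 0.5) * vy
  if (!fit_pe) theta[2] <- 0
  theta <- pmax(theta, c(floor_v, if (fit_pe) floor_v else 0, floor_v))

  eval_engine <- function(th) {
    eng <- mme_engine(des, Kinv, th[1], th[2], th[3])
    ll <- reml_loglik_value(eng, des, logdetK, th[1], th[2], th[3])
    list(eng = eng, ll = ll)
  }

  cur <- eval_engine(theta)
  traj <- list()
  converged <- FALSE
  ai <- NULL
  step_used <- "start"

  for (iter in seq_len(max_iter)) {
    eng <- cur$eng
    s <- eng$s
    quad_a <- as.numeric(crossprod(eng$a, Kinv %*% eng$a))
    quad_pe <- if (eng$has_pe) sum(eng$pe^2) else 0
    ee <- sum(eng$ehat^2)
    alpha <- theta[3] / theta[1]
    gamma <- if (eng$has_pe) theta[3] / theta[2] else NA_real_

    traj[[iter]] <- tibble(iter = iter, loglik = cur$ll,
                           sigma_a2 = theta[1], sigma_pe2 = theta[2],
                           sigma_e2 = theta[3], step = step_used)
    if (verbose)
      message(sprintf("round %d [%s] logL=%.6f  sa2=%.5g spe2=%.5g se2=%.5g",
                      iter, step_used, cur$ll, theta[1], theta[2], theta[3]))

    # EM-REML updates
    em <- theta
    em[1] <- (quad_a + theta[3] * eng$trKinvCuu) / q
    if (eng$has_pe) em[2] <- (quad_pe + theta[3] * eng$trCpp) / s
    em[3] <- sum(y * eng$ehat) / (n - p)
    em <- pmax(em, c(floor_v, if (eng$has_pe) floor_v else 0, floor_v))

    # REML scores
    trPVa <- (q - alpha * eng$trKinvCuu) / theta[1]
    trPVpe <- if (eng$has_pe) (s - gamma * eng$trCpp) / theta[2] else NA_real_
    trP <- (n - p - (q - alpha * eng$trKinvCuu) -
              (if (eng$has_pe) (s - gamma * eng$trCpp) else 0)) / theta[3]
    score <- c(-0.5 * (trPVa - quad_a / theta[1]^2),
               if (eng$has_pe) -0.5 * (trPVpe - quad_pe / theta[2]^2) else NULL,
               -0.5 * (trP - ee / theta[3]^2))

    # AI matrix via projected data vectors
    fs <- list(as.numeric(des$Zi %*% eng$a) / theta[1],
               if (eng$has_pe) as.numeric(des$W %*% eng$pe) / theta[2] else NULL,
               eng$ehat / theta[3])
    fs <- fs[!vapply(fs, is.null, logical(1))]
    Pf <- lapply(fs, eng$project)
    k <- length(fs)
    ai <- matrix(0, k, k)
    for (i2 in seq_len(k)) for (j2 in i2:k) {
      ai[i2, j2] <- ai[j2, i2] <- 0.5 * sum(fs[[i2]] * Pf[[j2]])
    }

    active <- if (eng$has_pe) 1:3 else c(1, 3)
    cand <- NULL
    step_used <- "em"
    ok_ai <- FALSE
    delta <- tryCatch(solve(ai, score), error = function(e) NULL)
    if (!is.null(delta)) {
      # accept the AI (Newton) step only inside the parameter space and only
      # if the restricted likelihood does not decrease; halve it up to three
      # times before falling back to EM
      for (half in 0:3) {
        th_ai <- theta
        th_ai[active] <- theta[active] + delta / 2^half
        if (!all(th_ai[active] > floor_v)) next
        cand_try <- tryCatch(eval_engine(th_ai), error = function(e) NULL)
        if (!is.null(cand_try) && is.finite(cand_try$ll) &&
            cand_try$ll >= cur$ll - 1e-10) {
          ok_ai <- TRUE
          theta_new <- th_ai
          cand <- cand_try
          step_used <- if (half == 0) "ai" else sprintf("ai/%d", 2^half)
          break
        }
      }
    }
    if (!ok_ai) {
      theta_new <- em
      cand <- eval_engine(theta_new)
    }

    rel <- max(abs(theta_new[active] - theta[active]) /
                 pmax(theta[active], floor_v))
    theta <- theta_new
    cur <- cand
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    flags <- c(flags, "not_converged")
    warn(sprintf("REML did not converge in %d rounds (last relative change > %g)",
                 max_iter, tol))
  }

  # flat-likelihood / identifiability diagnostic from the final AI matrix
  se_vec <- rep(NA_real_, 3)
  h2_se <- NA_real_
  aiinv <- tryCatch(solve(ai), error = function(e) NULL)
  rc <- tryCatch(rcond(ai), error = function(e) 0)
  if (is.null(aiinv) || rc < 1e-10 || any(diag(aiinv) < 0)) {
    flags <- c(flags, "flat_likelihood")
    warn("average-information matrix is singular or near-singular: a variance component is not identifiable from these data")
  } else {
    active <- if (theta[2] > 0) 1:3 else c(1, 3)
    se_vec[active] <- sqrt(diag(aiinv))
    tot <- sum(theta)
    g <- c((tot - theta[1]) / tot^2, -theta[1] / tot^2, -theta[1] / tot^2)[active]
    h2_se <- sqrt(drop(t(g) %*% aiinv %*% g))
  }

  vc <- c(sigma_a2 = theta[1], sigma_pe2 = theta[2], sigma_e2 = theta[3])
  new_reml_fit(vc, se = se_vec, h2 = heritability(vc), h2_se = h2_se,
               loglik = cur$ll, trajectory = dplyr::bind_rows(traj),
               converged = converged, flags = flags, ai = ai,
               n = n, q = q, s = des$s)
}

new_reml_fit <- function(vc, se, h2, h2_se, loglik, trajectory, converged,
                         flags, ai, n, q, s) {
  structure(list(
    varcomp = tibble(component = c("sigma_a2", "sigma_pe2", "sigma_e2"),
                     estimate = unname(vc), se = se),
    vc = vc, h2 = h2, h2_se = h2_se, loglik = loglik,
    trajectory = trajectory, converged = converged, flags = flags,
    ai = ai, n = n, q = q, s = s
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> repeatability animal model\n")
  print(x$varcomp)
  cat(sprintf("h2 = %.4f (SE %.4f), logL = %.4f, %s\n", x$h2, x$h2_se,
              x$loglik, if (x$converged) "converged" else "NOT converged"))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit into one row per variance component
#'
#' @param x a `reml_fit`.
#' @param ... unused.
#' @return Tibble: component, estimate, se.
#' @export
tidy.reml_fit <- function(x, ...) x$varcomp

#' One-row model summary of a REML fit
#'
#' @param x a `reml_fit`.
#' @param ... unused.
#' @return Tibble with h2, h2_se, logLik, convergence and sizes.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(h2 = x$h2, h2_se = x$h2_se, logLik = x$loglik,
         converged = x$converged, n_records = x$n, n_animals = x$q,
         n_pe = x$s, flags = paste(x$flags, collapse = ";"))
}
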