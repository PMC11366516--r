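# Internal mixed-model-equation machinery for the repeatability animal model
#   y = X b + Z a + W pe + e,  a ~ N(0, K sigma_a2), pe ~ N(0, I sigma_pe2),
#   e ~ N(0, I sigma_e2)
# The coefficient matrix is used in Henderson's lambda-scaled form; the
# permanent-environment block is diagonal and is absorbed, leaving a dense
# Schur complement over fixed effects + animals whose Cholesky inverse yields
# the solutions, prediction-error variances, and the traces the REML updates
# need.

# Build design components from a trait data frame and a relationship inverse.
# Fixed effects: year_season and parity as factors when present (first level
# dropped via the usual treatment contrasts); aliased columns removed.
mme_design <- function(data, Kinv, fit_pe = TRUE) {
  assert_that(all(c("animal", "value") %in% names(data)),
              "trait data needs columns animal and value")
  ids <- rownames(Kinv)
  assert_that(!is.null(ids), "Kinv must carry animal ids as dimnames")
  data$animal <- as.character(data$animal)
  missing <- setdiff(data$animal, ids)
  if (length(missing) > 0)
    abort(paste("record animals absent from relationship matrix:",
                paste(utils::head(missing, 5), collapse = ", ")))

  n <- nrow(data)
  y <- as.numeric(data$value)

  fx <- "1"
  if ("year_season" %in% names(data) && length(unique(data$year_season)) > 1)
    fx <- c(fx, "factor(year_season)")
  if ("parity" %in% names(data) && length(unique(data$parity)) > 1)
    fx <- c(fx, "factor(parity)")
  X <- model.matrix(stats::as.formula(paste("~", paste(fx, collapse = "+"))),
                    data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  q <- length(ids)
  ai <- match(data$animal, ids)
  Zi <- sparseMatrix(i = seq_len(n), j = ai, x = 1, dims = c(q, n)[2:1],
                     dimnames = list(NULL, ids))
  rec_ids <- unique(data$animal)
  W <- NULL
  if (fit_pe) {
    pj <- match(data$animal, rec_ids)
    W <- sparseMatrix(i = seq_len(n), j = pj, x = 1,
                      dims = c(n, length(rec_ids)),
                      dimnames = list(NULL, rec_ids))
  }
  list(y = y, X = X, Zi = Zi, W = W, ids = ids, rec_ids = rec_ids,
       n = n, p = ncol(X), q = q, s = if (fit_pe) length(rec_ids) else 0L)
}

# Factorize and solve the absorbed MME at given variance components.
# Returns solutions, traces against Kinv, log|C|, and a closure for extra
# projections P f (used by the AI quadratic forms). `Kinv` may be the dense
# matrix cached by the caller to avoid repeated coercion.
mme_engine <- function(des, Kinv, sigma_a2, sigma_pe2, sigma_e2) {
  alpha <- sigma_e2 / sigma_a2
  has_pe <- !is.null(des$W) && sigma_pe2 > 0
  gamma <- if (has_pe) sigma_e2 / sigma_pe2 else NA_real_
  X <- des$X; Zi <- des$Zi; W <- des$W; y <- des$y
  p <- des$p; q <- des$q; n <- des$n

  XtX <- crossprod(X)
  XtZ <- as.matrix(crossprod(X, Zi))
  ZtZ_diag <- Matrix::colSums(Zi^2)
  C11 <- matrix(0, p + q, p + q)
  C11[1:p, 1:p] <- as.matrix(XtX)
  C11[1:p, p + 1:q] <- XtZ
  C11[p + 1:q, 1:p] <- t(XtZ)
  Kblock <- alpha * as.matrix(Kinv)
  diag(Kblock) <- diag(Kblock) + ZtZ_diag
  C11[p + 1:q, p + 1:q] <- Kblock

  rhs1 <- c(as.numeric(crossprod(X, y)), as.numeric(crossprod(Zi, y)))

  if (has_pe) {
    s <- ncol(W)
    Dpe <- Matrix::colSums(W^2) + gamma
    # (p+q) x s, kept sparse: each column touches a few fixed rows + 1 animal
    C12 <- rbind(as(as.matrix(crossprod(X, W)), "CsparseMatrix"),
                 crossprod(Zi, W))
    Msc <- C12 %*% Diagonal(x = 1 / Dpe)
    S <- C11 - as.matrix(Msc %*% Matrix::t(C12))
    rhs2 <- as.numeric(crossprod(W, y))
    rhs_s <- rhs1 - as.numeric(Msc %*% rhs2)
  } else {
    s <- 0L
    S <- C11
    rhs_s <- rhs1
  }
  S <- symmetrize(S)
  cholS <- tryCatch(chol(S), error = function(e)
    abort("singular mixed-model coefficient matrix"))
  Sinv <- chol2inv(cholS)

  solve_one <- function(f) {
    r1 <- c(as.numeric(crossprod(X, f)), as.numeric(crossprod(Zi, f)))
    if (has_pe) {
      r2 <- as.numeric(crossprod(W, f))
      x1 <- as.numeric(Sinv %*% (r1 - as.numeric(Msc %*% r2)))
      pe <- (r2 - as.numeric(Matrix::crossprod(C12, x1))) / Dpe
    } else {
      x1 <- as.numeric(Sinv %*% r1)
      pe <- numeric(0)
    }
    b <- x1[seq_len(p)]
    a <- x1[p + seq_len(q)]
    fit <- as.numeric(X %*% b) + as.numeric(Zi %*% a)
    if (has_pe) fit <- fit + as.numeric(W %*% pe)
    list(b = b, a = a, pe = pe, ehat = f - fit)
  }

  sol <- solve_one(y)
  yPy <- sum(y * sol$ehat) / sigma_e2

  Cuu <- Sinv[p + seq_len(q), p + seq_len(q), drop = FALSE]
  trKinvCuu <- if (methods::is(Kinv, "sparseMatrix")) {
    sum(Kinv * Cuu)
  } else {
    sum(as.matrix(Kinv) * Cuu)
  }
  diagCuu <- diag(Sinv)[p + seq_len(q)]
  logdetC <- 2 * sum(log(diag(cholS)))
  if (has_pe) {
    trCpp <- sum(1 / Dpe) + sum(Msc * (Sinv %*% Msc))
    logdetC <- logdetC + sum(log(Dpe))
  } else {
    trCpp <- 0
  }

  # residual of the full lambda-scaled MME, for the solution-quality contract
  mme_resid_rel <- {
    r1_chk <- as.numeric(C11 %*% c(sol$b, sol$a)) - rhs1
    if (has_pe) r1_chk <- r1_chk + as.numeric(C12 %*% sol$pe)
    sqrt(sum(r1_chk^2)) / max(sqrt(sum(rhs1^2)), .Machine$double.eps)
  }

  list(b = sol$b, a = setNames(sol$a, des$ids),
       pe = if (has_pe) setNames(sol$pe, des$rec_ids) else NULL,
       ehat = sol$ehat, yPy = yPy,
       trKinvCuu = trKinvCuu, trCpp = trCpp,
       diagCuu = setNames(diagCuu, des$ids),
       logdetC = logdetC, has_pe = has_pe, s = s,
       mme_resid_rel = mme_resid_rel,
       project = function(f) {
         sf <- solve_one(f)
         sf$ehat / sigma_e2
       })
}

# Restricted log-likelihood (up to an additive constant) from engine output
reml_loglik_value <- function(eng, des, logdetK, sigma_a2, sigma_pe2, sigma_e2) {
  q <- des$q; s <- eng$s; n <- des$n; p <- des$p
  pe_term <- if (eng$has_pe) s * log(sigma_pe2) else 0
  -0.5 * (eng$logdetC + logdetK + q * log(sigma_a2) + pe_term +
            (n - p - q - s) * log(sigma_e2) + eng$yPy)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood (up to an additive constant) of the
#' repeatability animal model at fixed variance components — useful for
#' convergence diagnostics and likelihood-surface exploration.
#'
#' @param data trait records: columns `animal`, `value`, optionally
#'   `year_season`, `parity`.
#' @param Kinv relationship inverse (A^-1 or H^-1) with animal-id dimnames.
#' @param components numeric vector/list with `sigma_a2`, `sigma_pe2`,
#'   `sigma_e2` (set `sigma_pe2 = 0` to drop the PE term).
#' @param fit_pe include the permanent-environment effect (default TRUE when
#'   `sigma_pe2 > 0`).
#' @return Scalar restricted log-likelihood.
#' @export
profile_loglik <- function(data, Kinv, components, fit_pe = NULL) {
  cmp <- as.list(components)
  sa <- cmp$sigma_a2; spe <- cmp$sigma_pe2 %||% 0; se <- cmp$sigma_e2
  assert_that(sa > 0 && se > 0, "sigma_a2 and sigma_e2 must be positive")
  fit_pe <- fit_pe %||% (spe > 0)
  des <- mme_design(as_tibble(data), Kinv, fit_pe = fit_pe)
  logdetK <- -as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)
  eng <- mme_engine(des, Kinv, sa, spe, se)
  reml_loglik_value(eng, des, logdetK, sa, spe, se)
}
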