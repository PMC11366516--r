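# shared fixture builders: everything is generated in code at test time

# random valid pedigree: founders plus animals with parents drawn from
# earlier animals (possibly unknown), guaranteeing acyclicity
random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1,
                            p_unknown = 0.1) {
  set.seed(seed)
  ids <- sprintf("a%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq.int(n_founders + 1, n)) {
    pool <- ids[seq_len(i - 1)]
    if (stats::runif(1) > p_unknown) sire[i] <- sample(pool, 1)
    if (stats::runif(1) > p_unknown) dam[i] <- sample(pool, 1)
    if (!is.na(sire[i]) && identical(sire[i], dam[i])) dam[i] <- NA_character_
  }
  df <- data.frame(animal = ids, sire = ifelse(is.na(sire), "0", sire),
                   dam = ifelse(is.na(dam), "0", dam))
  as_pedigree(df[sample(n), ])  # shuffled on purpose; as_pedigree reorders
}

# tiny marker_data from a plain matrix
toy_markers <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  marker_data(calls,
              data.frame(marker = paste0("m", seq_len(m)),
                         chrom = chrom %||% rep("1", m),
                         pos = pos %||% (seq_len(m) * 1000)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# direct enumeration oracle for the exact HWE test: conditional probability
# of each heterozygote count given allele counts, via the closed form
hwe_enum_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  na <- 2 * n - nA
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(h) {
    nAA <- (nA - h) / 2
    naa <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
          h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_het]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# repeated records simulated directly under the repeatability animal model,
# breeding values drawn with exact covariance A * sigma_a2
make_records <- function(ped, sigma = c(0.9, 0.7, 5.5), n_rec = 3, seed = 1,
                         recorded = NULL) {
  set.seed(seed)
  A <- numerator_matrix(ped)
  a <- as.numeric(t(chol(A + diag(1e-8, nrow(A)))) %*% rnorm(nrow(A))) *
    sqrt(sigma[1])
  names(a) <- ped$animal
  recorded <- recorded %||% ped$animal[!is.na(ped$sire)]
  pe <- stats::setNames(rnorm(length(recorded), 0, sqrt(sigma[2])), recorded)
  rec <- expand.grid(animal = recorded, parity = seq_len(n_rec),
                     stringsAsFactors = FALSE)
  rec$year_season <- sample(1:4, nrow(rec), replace = TRUE)
  rec$value <- 10 + 0.2 * rec$parity + a[rec$animal] + pe[rec$animal] +
    rnorm(nrow(rec), 0, sqrt(sigma[3]))
  attr(rec, "true_a") <- a
  tibble::as_tibble(rec)
}

# dense GLS / direct-V oracle pieces for the repeatability model
dense_model_pieces <- function(data, A, sigma_a2, sigma_pe2, sigma_e2) {
  ids <- rownames(A)
  n <- nrow(data)
  fx <- "1"
  if (length(unique(data$year_season)) > 1) fx <- c(fx, "factor(year_season)")
  if (length(unique(data$parity)) > 1) fx <- c(fx, "factor(parity)")
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(fx, collapse = "+"))), data)
  Zi <- matrix(0, n, length(ids)); Zi[cbind(seq_len(n), match(data$animal, ids))] <- 1
  recids <- unique(data$animal)
  W <- matrix(0, n, length(recids)); W[cbind(seq_len(n), match(data$animal, recids))] <- 1
  V <- Zi %*% A %*% t(Zi) * sigma_a2 + W %*% t(W) * sigma_pe2 + diag(n) * sigma_e2
  list(X = X, Zi = Zi, W = W, V = V, ids = ids, recids = recids)
}
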