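#' Construct a marker data set
#'
#' Bundles a samples-by-markers matrix of allele counts (0/1/2, `NA` missing)
#' with a marker map. Markers are sorted by chromosome then position; markers
#' with unknown position (`NA` or <= 0, or chromosome "0") keep their order at
#' the end of their chromosome block.
#'
#' @param calls integer/numeric matrix, samples in rows, markers in columns;
#'   values in {0, 1, 2, NA} counting copies of the counted allele.
#' @param map data frame with columns `marker`, `chrom`, `pos` (bp) and
#'   optionally `a1`, `a2` (counted and alternate allele).
#' @param sample_ids sample ids; defaults to `rownames(calls)`.
#' @return An object of class `marker_data`: list with `calls` (matrix) and
#'   `map` (tibble).
#' @export
marker_data <- function(calls, map, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  map <- as_tibble(map)
  assert_that(all(c("marker", "chrom", "pos") %in% names(map)),
              "map needs columns marker, chrom, pos")
  assert_that(ncol(calls) == nrow(map), "calls/map marker count mismatch")
  bad <- !(calls %in% c(0, 1, 2) | is.na(calls))
  if (any(bad)) abort("genotype calls must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(calls)))
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]
  calls <- calls[, ord, drop = FALSE]
  rownames(calls) <- sample_ids
  colnames(calls) <- map$marker
  structure(list(calls = calls, map = map), class = "marker_data")
}

#' @export
print.marker_data <- function(x, ...) {
  cat(sprintf("<marker_data> %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  invisible(x)
}

#' Counted-allele frequencies
#'
#' Frequency of the counted allele per marker, from non-missing calls only.
#'
#' @param md a [marker_data()] object.
#' @return Named numeric vector p in \[0, 1\].
#' @export
marker_freqs <- function(md) {
  colMeans(md$calls, na.rm = TRUE) / 2
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Whitespace-delimited PLINK text files. The counted allele of each marker is
#' the first non-missing allele listed in the file for that marker; "0 0"
#' genotypes become `NA`. Sex-chromosome and unknown-position markers are kept
#' at read time; filtering is [apply_qc()]'s job.
#'
#' @param ped_path path to the .ped file (6 leading columns, then two allele
#'   columns per marker).
#' @param map_path path to the .map file (chrom, marker, cM, bp).
#' @return A [marker_data()] object.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  assert_that(ncol(map) >= 4, ".map needs 4 columns: chrom, marker, cM, bp")
  map <- tibble(marker = map[[2]], chrom = map[[1]], pos = as.numeric(map[[4]]))
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    abort(sprintf(".ped has %d columns; expected %d for %d markers",
                  ncol(ped), 6 + 2 * m, m))
  sample_ids <- ped[[2]]
  calls <- matrix(NA_real_, nrow(ped), m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- ped[[6 + 2 * j - 1]]
    x2 <- ped[[6 + 2 * j]]
    seen <- c(rbind(x1, x2))
    alleles <- unique(seen[seen != "0"])
    if (length(alleles) > 2)
      abort(sprintf("marker %s has more than two alleles", map$marker[j]))
    A <- if (length(alleles) >= 1) alleles[1] else NA_character_
    B <- if (length(alleles) == 2) alleles[2] else NA_character_
    a1[j] <- A %||% NA_character_; a2[j] <- B %||% NA_character_
    miss <- x1 == "0" | x2 == "0"
    cj <- (x1 == A) + (x2 == A)
    cj[miss] <- NA_real_
    calls[, j] <- cj
  }
  map$a1 <- a1; map$a2 <- a2
  marker_data(calls, map, sample_ids = sample_ids)
}

#' Read genotypes from a sample-by-marker TSV plus a map TSV
#'
#' The genotype TSV has a `sample` id column and one column per marker with
#' values 0/1/2/NA; the map TSV has columns `marker`, `chrom`, `pos`.
#'
#' @param path genotype matrix TSV.
#' @param map_path marker map TSV.
#' @return A [marker_data()] object.
#' @export
read_matrix_tsv <- function(path, map_path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), .default = readr::col_double()))
  assert_that("sample" %in% names(g), "genotype TSV needs a 'sample' column")
  map <- readr::read_tsv(map_path, show_col_types = FALSE)
  calls <- as.matrix(g[, setdiff(names(g), "sample")])
  bad <- !(calls %in% c(0, 1, 2) | is.na(calls))
  if (any(bad)) abort("genotype TSV values must be 0, 1, 2 or NA")
  map <- map[match(colnames(calls), map$marker), ]
  if (anyNA(map$marker)) abort("markers in genotype TSV missing from map TSV")
  marker_data(calls, map, sample_ids = g$sample)
}

#' Quality-control configuration
#'
#' Thresholds mirror a standard PLINK litter-trait workflow: drop markers with
#' unknown position, on sex chromosomes, call rate < 0.90, minor allele
#' frequency < 0.01 or exact Hardy-Weinberg p < 1e-6; flag parent-offspring
#' pairs whose opposing-homozygote rate exceeds 10%.
#'
#' @param min_call_rate minimum per-marker call rate.
#' @param min_maf minimum minor allele frequency (monomorphic markers always
#'   fail this).
#' @param hwe_p_min markers with exact HWE p below this are removed.
#' @param drop_sex_chromosomes drop X/Y/XY/MT (and pig aliases 19/20).
#' @param drop_unknown_position drop markers with missing/zero position.
#' @param parentage_conflict_max opposing-homozygote rate above which a
#'   parent-offspring pair is flagged.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(min_call_rate = 0.90, min_maf = 0.01, hwe_p_min = 1e-6,
                      drop_sex_chromosomes = TRUE, drop_unknown_position = TRUE,
                      parentage_conflict_max = 0.10) {
  cfg <- list(min_call_rate = min_call_rate, min_maf = min_maf,
              hwe_p_min = hwe_p_min,
              drop_sex_chromosomes = drop_sex_chromosomes,
              drop_unknown_position = drop_unknown_position,
              parentage_conflict_max = parentage_conflict_max)
  ok <- vapply(cfg[1:3], function(v) v >= 0 && v <= 1, logical(1))
  assert_that(all(ok), "qc thresholds must lie in [0, 1]")
  structure(cfg, class = "qc_config")
}

sex_chrom_names <- c("X", "Y", "XY", "MT", "x", "y", "mt", "19", "20")

#' Two-sided exact Hardy-Weinberg test
#'
#' Conditional exact test on the observed allele counts: the p-value is the
#' total probability of heterozygote counts no more probable than the observed
#' one under the hypergeometric-type HWE null (the SNP-HWE construction used
#' by PLINK).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  assert_that(all(c(n_hom1, n_het, n_hom2) >= 0), "counts must be non-negative")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) abort("all genotype counts are zero")
  nA <- 2 * n_hom1 + n_het
  rare <- min(nA, 2 * n - nA)
  common <- 2 * n - rare
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, min(rare, common), by = 2)
  logp <- lfactorial(n) - lfactorial((rare - hs) / 2) - lfactorial(hs) -
    lfactorial(n - hs - (rare - hs) / 2) + hs * log(2) +
    lfactorial(rare) + lfactorial(common) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hs == n_het)
  if (length(obs) == 0) abort("heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Apply marker quality control
#'
#' Filters are applied in a fixed order so the report is reproducible:
#' unknown position, sex chromosome, call rate, MAF, exact HWE. Frequencies
#' are recomputed after any sample exclusion.
#'
#' @param md a [marker_data()] object.
#' @param cfg a [qc_config()].
#' @param exclude_samples optional sample ids to drop before marker filters
#'   (e.g. parentage-conflict animals).
#' @return List with `markers` (filtered `marker_data`) and `report`
#'   (class `qc_report`: per-rule removal counts).
#' @export
apply_qc <- function(md, cfg = qc_config(), exclude_samples = NULL) {
  calls <- md$calls
  map <- md$map
  samples_flagged <- intersect(exclude_samples %||% character(0), rownames(calls))
  if (length(samples_flagged) > 0)
    calls <- calls[setdiff(rownames(calls), samples_flagged), , drop = FALSE]
  n_in <- ncol(calls)
  keep <- rep(TRUE, n_in)
  removed <- c(unknown_position = 0L, sex_chromosome = 0L, call_rate = 0L,
               maf = 0L, hwe = 0L)

  if (isTRUE(cfg$drop_unknown_position)) {
    bad <- keep & (is.na(map$pos) | map$pos <= 0 | map$chrom %in% c("0", NA))
    removed["unknown_position"] <- sum(bad); keep[bad] <- FALSE
  }
  if (isTRUE(cfg$drop_sex_chromosomes)) {
    bad <- keep & map$chrom %in% sex_chrom_names
    removed["sex_chromosome"] <- sum(bad); keep[bad] <- FALSE
  }
  call_rate <- colMeans(!is.na(calls))
  bad <- keep & call_rate < cfg$min_call_rate
  removed["call_rate"] <- sum(bad); keep[bad] <- FALSE

  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad <- keep & (is.na(maf) | maf < cfg$min_maf)
  removed["maf"] <- sum(bad); keep[bad] <- FALSE

  if (cfg$hwe_p_min > 0) {
    idx <- which(keep)
    hwe_p <- vapply(idx, function(j) {
      g <- calls[, j]
      hwe_exact_p(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                  sum(g == 2, na.rm = TRUE))
    }, numeric(1))
    bad_idx <- idx[hwe_p < cfg$hwe_p_min]
    removed["hwe"] <- length(bad_idx); keep[bad_idx] <- FALSE
  }

  out <- marker_data(calls[, keep, drop = FALSE], map[keep, ])
  if (ncol(out$calls) == 0) warn("all markers removed by QC")
  report <- structure(list(
    removed = tibble(rule = names(removed), n_removed = unname(removed)),
    samples_flagged = samples_flagged,
    n_markers_in = n_in, n_markers_out = sum(keep),
    n_samples_in = nrow(md$calls), n_samples_out = nrow(calls)
  ), class = "qc_report")
  list(markers = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d -> %d markers, %d -> %d samples\n",
              x$n_markers_in, x$n_markers_out, x$n_samples_in, x$n_samples_out))
  print(x$removed)
  invisible(x)
}

#' Opposing-homozygote parentage conflict rate
#'
#' Fraction of jointly called markers where one member of a putative
#' parent-offspring pair is homozygous 0 and the other homozygous 2 — such
#' genotypes cannot be transmitted, so a high rate indicates a pedigree error.
#'
#' @param parent_calls,child_calls equal-length genotype vectors (0/1/2/NA).
#' @return The conflict fraction.
#' @export
parentage_conflict_rate <- function(parent_calls, child_calls) {
  assert_that(length(parent_calls) == length(child_calls),
              "call vectors must have equal length")
  ok <- !is.na(parent_calls) & !is.na(child_calls)
  if (!any(ok)) abort("no jointly non-missing markers")
  opp <- (parent_calls == 0 & child_calls == 2) |
         (parent_calls == 2 & child_calls == 0)
  sum(opp[ok]) / sum(ok)
}

#' Screen all genotyped parent-offspring pairs for conflicts
#'
#' @param md a [marker_data()] object.
#' @param ped an ordered pedigree.
#' @param cfg a [qc_config()]; pairs above `parentage_conflict_max` are flagged.
#' @return Tibble: animal, parent, relationship, conflict_rate, flagged.
#' @export
parentage_check <- function(md, ped, cfg = qc_config()) {
  geno <- rownames(md$calls)
  pairs <- dplyr::bind_rows(
    tibble(animal = ped$animal, parent = ped$sire, relationship = "sire"),
    tibble(animal = ped$animal, parent = ped$dam, relationship = "dam"))
  pairs <- dplyr::filter(pairs, .data$animal %in% geno, .data$parent %in% geno)
  if (nrow(pairs) == 0)
    return(tibble(animal = character(), parent = character(),
                  relationship = character(), conflict_rate = numeric(),
                  flagged = logical()))
  pairs$conflict_rate <- purrr::map2_dbl(pairs$parent, pairs$animal, function(p, a)
    parentage_conflict_rate(md$calls[p, ], md$calls[a, ]))
  pairs$flagged <- pairs$conflict_rate > cfg$parentage_conflict_max
  pairs
}

#' Centered gene-content matrix and the VanRaden scaling constant
#'
#' Z subtracts twice the counted-allele frequency from each genotype column;
#' residual missing calls are mean-imputed to 2p beforehand. The constant
#' lambda = 1 / sum(2 p_i (1 - p_i)) scales Z D Z' to a genomic relationship
#' matrix; 2p(1-p) is symmetric in allele labelling so lambda does not depend
#' on whether p is the minor-allele frequency.
#'
#' @param md post-QC [marker_data()]; monomorphic markers are an error.
#' @param freqs optional fixed frequencies (e.g. from a base population);
#'   default computed from `md`.
#' @return List with `Z` (samples x markers), `p`, and `lambda`.
#' @export
gene_content_centered <- function(md, freqs = NULL) {
  p <- freqs %||% marker_freqs(md)
  if (any(p <= 0 | p >= 1))
    abort("monomorphic marker present; run apply_qc() first")
  calls <- md$calls
  if (anyNA(calls)) {
    for (j in which(colSums(is.na(calls)) > 0)) {
      calls[is.na(calls[, j]), j] <- 2 * p[j]
    }
  }
  Z <- sweep(calls, 2, 2 * p)
  list(Z = Z, p = unname(p), lambda = 1 / sum(2 * p * (1 - p)))
}
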