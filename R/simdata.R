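#' Simulation configuration for a litter-trait breeding study
#'
#' Describes a closed multi-generation pig herd: discrete generations under a
#' nested mating design (each sire mated to `dams_per_sire` dams, each dam
#' producing `offspring_per_dam` piglets), biallelic SNPs on 18 autosomes
#' dropped through the pedigree with Haldane recombination at 1 cM/Mb, and
#' repeated litter-size records per sow generated under the repeatability
#' animal model with additive (QTL + polygenic), permanent-environment,
#' parity, year-season and residual components. Variance defaults
#' (0.9 / 0.68 / 5.49, h2 about 0.13) match a total-number-born-type trait.
#'
#' @param n_sires,dams_per_sire,offspring_per_dam nested mating design per
#'   generation.
#' @param n_generations number of generations bred after the founders.
#' @param n_chromosomes,chrom_length_bp genome layout. The default 18 x 6 Mb
#'   genome is a scaled-down stand-in chosen to preserve the SNPs-per-window
#'   geometry of a dense commercial chip (about 8-10 markers per 0.52 Mb
#'   window at the default marker count) rather than absolute genome length.
#' @param n_markers total marker count (spread evenly over chromosomes).
#' @param maf_range founder minor-allele-frequency range.
#' @param recomb_cM_per_Mb recombination rate (Haldane map).
#' @param n_qtl number of trait loci drawn from the markers.
#' @param qtl_maf_range minor-allele-frequency range QTL are drawn from
#'   (default 0.15-0.5: planted QTL are common variants, so their assigned
#'   variance fractions correspond to mappable signals).
#' @param n_background_loci number of additional small-effect marker loci
#'   carrying the additive variance not assigned to the named QTL, so the
#'   genetic background is marker-borne as in a real genome (each background
#'   locus explains far less than a significance-worthy window).
#' @param polygenic_fraction fraction of sigma_a2 bred through the pedigree
#'   without any marker association (untagged polygenic residual; default 0).
#' @param qtl_variance_fractions per-QTL fractions of sigma_a2 (summing to
#'   at most 1; the remainder is polygenic). A single number is recycled.
#' @param sigma_a2,sigma_pe2,sigma_e2 variance component targets.
#' @param mu trait mean.
#' @param n_parities records per sow.
#' @param n_year_seasons number of year-season levels.
#' @param parity_effect_sd,year_season_effect_sd fixed-effect magnitudes.
#' @param genotyping_fraction fraction of animals genotyped (recorded sows
#'   first, then other animals).
#' @param validation_generations number of final generations left without
#'   records (selection candidates): records go to the females of generation
#'   `n_generations - 1 - validation_generations`.
#' @param integerize_phenotypes round records to non-negative integers for
#'   litter-count realism (off by default: the trait is modelled as
#'   continuous).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_sires = 25, dams_per_sire = 6, offspring_per_dam = 10,
                       n_generations = 2,
                       n_chromosomes = 18, chrom_length_bp = 6e6,
                       n_markers = 1800, maf_range = c(0.05, 0.5),
                       recomb_cM_per_Mb = 1,
                       n_qtl = 50, qtl_variance_fractions = 0.01,
                       qtl_maf_range = c(0.15, 0.5),
                       n_background_loci = 200, polygenic_fraction = 0,
                       sigma_a2 = 0.9, sigma_pe2 = 0.68, sigma_e2 = 5.49,
                       mu = 10, n_parities = 3, n_year_seasons = 8,
                       parity_effect_sd = 0.3, year_season_effect_sd = 0.5,
                       genotyping_fraction = 0.25,
                       validation_generations = 0,
                       integerize_phenotypes = FALSE) {
  qf <- rep_len(qtl_variance_fractions, n_qtl)
  assert_that(sum(qf) + polygenic_fraction <= 1 + 1e-12,
              "QTL variance fractions plus polygenic_fraction must sum to <= 1")
  assert_that(genotyping_fraction >= 0 && genotyping_fraction <= 1,
              "genotyping_fraction must lie in [0, 1]")
  structure(list(
    n_sires = n_sires, dams_per_sire = dams_per_sire,
    offspring_per_dam = offspring_per_dam, n_generations = n_generations,
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    n_markers = n_markers, maf_range = maf_range,
    recomb_cM_per_Mb = recomb_cM_per_Mb,
    n_qtl = n_qtl, qtl_variance_fractions = qf,
    qtl_maf_range = qtl_maf_range,
    n_background_loci = n_background_loci,
    polygenic_fraction = polygenic_fraction,
    sigma_a2 = sigma_a2, sigma_pe2 = sigma_pe2, sigma_e2 = sigma_e2,
    mu = mu, n_parities = n_parities, n_year_seasons = n_year_seasons,
    parity_effect_sd = parity_effect_sd,
    year_season_effect_sd = year_season_effect_sd,
    genotyping_fraction = genotyping_fraction,
    validation_generations = validation_generations,
    integerize_phenotypes = integerize_phenotypes
  ), class = "sim_config")
}

#' Simulate a discrete-generation nested pedigree
#'
#' Founders (generation 0) are unrelated; each later generation mates
#' `n_sires` males with `dams_per_sire` females each (drawn from the previous
#' generation after generation 1), every dam producing `offspring_per_dam`
#' piglets with balanced sexes.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (mandatory for reproducibility).
#' @return An ordered [as_pedigree()] tibble with extra columns `sex`
#'   ("M"/"F") and `generation`.
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed) {
  assert_that(!missing(seed), "seed is required")
  set.seed(seed)
  n_dams <- cfg$n_sires * cfg$dams_per_sire
  founders <- tibble(
    animal = c(sprintf("G0_S%03d", seq_len(cfg$n_sires)),
               sprintf("G0_D%03d", seq_len(n_dams))),
    sire = NA_character_, dam = NA_character_,
    sex = c(rep("M", cfg$n_sires), rep("F", n_dams)),
    generation = 0L)
  gens <- list(founders)
  for (g in seq_len(cfg$n_generations - 1)) {
    prev <- gens[[g]]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    assert_that(length(males) >= cfg$n_sires && length(females) >= n_dams,
                "previous generation too small for the mating design")
    sires <- sample(males, cfg$n_sires)
    dams <- sample(females, n_dams)
    pair_sire <- rep(sires, each = cfg$dams_per_sire)
    n_off <- n_dams * cfg$offspring_per_dam
    sex <- sample(rep(c("M", "F"), length.out = n_off))
    gens[[g + 1]] <- tibble(
      animal = sprintf("G%d_%05d", g, seq_len(n_off)),
      sire = rep(pair_sire, each = cfg$offspring_per_dam),
      dam = rep(dams, each = cfg$offspring_per_dam),
      sex = sex, generation = g)
  }
  df <- dplyr::bind_rows(gens)
  ped <- as_pedigree(df)
  extra <- df[match(ped$animal, df$animal), c("sex", "generation")]
  ped$sex <- extra$sex
  ped$generation <- extra$generation
  ped
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotype alleles are drawn independently per marker at the
#' founder frequency (linkage disequilibrium then builds up through
#' co-transmission); gametes recombine under a Haldane map at
#' `recomb_cM_per_Mb`. Marker positions are uniform per chromosome.
#'
#' @param ped ordered pedigree (founders first).
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return A [marker_data()] object covering every pedigree animal.
#' @export
simulate_genotypes <- function(ped, cfg = sim_config(), seed) {
  assert_that(!missing(seed), "seed is required")
  set.seed(seed)
  per_chr <- rep(floor(cfg$n_markers / cfg$n_chromosomes), cfg$n_chromosomes)
  rem <- cfg$n_markers - sum(per_chr)
  if (rem > 0) per_chr[seq_len(rem)] <- per_chr[seq_len(rem)] + 1
  map <- dplyr::bind_rows(lapply(seq_len(cfg$n_chromosomes), function(ch) {
    pos <- sort(sample.int(cfg$chrom_length_bp, per_chr[ch]))
    tibble(chrom = as.character(ch), pos = as.numeric(pos))
  }))
  map$marker <- sprintf("snp%05d", seq_len(nrow(map)))
  map <- map[, c("marker", "chrom", "pos")]
  M <- nrow(map)
  p <- runif(M, cfg$maf_range[1], cfg$maf_range[2])

  # switch probability between adjacent markers; 0.5 across chromosome breaks
  morgan_per_bp <- cfg$recomb_cM_per_Mb * 1e-8
  d <- diff(map$pos) * morgan_per_bp
  r <- 0.5 * (1 - exp(-2 * d))
  new_chr <- diff(as.integer(factor(map$chrom, levels = unique(map$chrom)))) != 0
  r[new_chr] <- 0.5

  n <- nrow(ped)
  pid <- ped_parent_idx(ped)
  H1 <- matrix(0L, n, M)  # paternal haplotype
  H2 <- matrix(0L, n, M)  # maternal haplotype
  gamete <- function(parent_row) {
    start <- sample(0:1, 1)
    switches <- runif(M - 1) < r
    hap <- (start + cumsum(c(0L, as.integer(switches)))) %% 2L
    ifelse(hap == 0L, H1[parent_row, ], H2[parent_row, ])
  }
  for (i in seq_len(n)) {
    s <- pid$s[i]; dd <- pid$d[i]
    H1[i, ] <- if (is.na(s)) as.integer(runif(M) < p) else gamete(s)
    H2[i, ] <- if (is.na(dd)) as.integer(runif(M) < p) else gamete(dd)
  }
  calls <- H1 + H2
  marker_data(calls, map, sample_ids = ped$animal)
}

#' Simulate repeated litter-size records under the repeatability model
#'
#' True breeding values are a QTL part (marker gene content times sampled
#' effects, rescaled so the QTL fractions of `sigma_a2` are met exactly in
#' the recorded generation) plus a pedigree-bred polygenic remainder.
#' Recorded animals are the females of the last generation; each gets
#' `n_parities` records with parity and year-season fixed effects, a
#' permanent-environment deviation, and i.i.d. residuals.
#'
#' @param ped pedigree from [simulate_pedigree()] (needs `sex`,
#'   `generation`).
#' @param md all-animal [marker_data()] from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return List: `records` tibble (animal, parity, year_season, value),
#'   `truth` (true `a` per animal, `qtl` table, `pe`, fixed effects,
#'   `realized_h2` among recorded sows).
#' @export
simulate_phenotypes <- function(ped, md, cfg = sim_config(), seed) {
  assert_that(!missing(seed), "seed is required")
  assert_that(all(c("sex", "generation") %in% names(ped)),
              "pedigree must carry sex and generation (see simulate_pedigree)")
  assert_that(cfg$n_qtl <= ncol(md$calls), "more QTL than markers")
  set.seed(seed)
  n <- nrow(ped)
  rec_gen <- max(ped$generation) - (cfg$validation_generations %||% 0)
  assert_that(rec_gen >= 0, "validation_generations leaves no recorded generation")
  sows <- ped$animal[ped$sex == "F" & ped$generation == rec_gen]

  p <- marker_freqs(md)
  maf <- pmin(p, 1 - p)
  rng <- cfg$qtl_maf_range %||% c(0.15, 0.5)
  informative <- which(maf >= rng[1] & maf <= rng[2])
  if (length(informative) < cfg$n_qtl)
    informative <- order(maf, decreasing = TRUE)[seq_len(max(cfg$n_qtl, 1))]
  qtl_idx <- sort(sample(informative, cfg$n_qtl))
  qf <- cfg$qtl_variance_fractions

  # component scaled so its variance among the recorded sows is exact
  scaled_marker_component <- function(idx, effects, target_var) {
    Zc <- sweep(md$calls[, idx, drop = FALSE], 2, 2 * p[idx])
    a_raw <- as.numeric(Zc %*% effects)
    s <- sd(a_raw[match(sows, ped$animal)])
    scl <- if (target_var > 0 && s > 0) sqrt(target_var) / s else 0
    list(a = setNames(a_raw * scl, ped$animal), effects = effects * scl)
  }

  beta <- sample(c(-1, 1), cfg$n_qtl, replace = TRUE) *
    sqrt(qf * cfg$sigma_a2 / pmax(2 * p[qtl_idx] * (1 - p[qtl_idx]), 1e-6))
  qtl_cmp <- scaled_marker_component(qtl_idx, beta, sum(qf) * cfg$sigma_a2)
  a_qtl <- qtl_cmp$a
  beta <- qtl_cmp$effects

  # marker-borne additive background: many small-effect loci
  pg_frac <- cfg$polygenic_fraction %||% 0
  bg_frac <- max(1 - sum(qf) - pg_frac, 0)
  a_bg <- setNames(numeric(n), ped$animal)
  bg_idx <- integer(0)
  n_bg <- min(cfg$n_background_loci %||% 200, ncol(md$calls) - cfg$n_qtl)
  if (bg_frac > 0 && n_bg > 0) {
    pool <- setdiff(which(maf >= 0.05), qtl_idx)
    n_bg <- min(n_bg, length(pool))
    bg_idx <- sort(sample(pool, n_bg))
    bg_eff <- rnorm(n_bg) / sqrt(pmax(2 * p[bg_idx] * (1 - p[bg_idx]), 1e-6))
    bg_cmp <- scaled_marker_component(bg_idx, bg_eff, bg_frac * cfg$sigma_a2)
    a_bg <- bg_cmp$a
  }

  poly_var <- pg_frac * cfg$sigma_a2
  a_poly <- numeric(n)
  if (poly_var > 0) {
    pid <- ped_parent_idx(ped)
    Fv <- inbreeding(ped)
    for (i in seq_len(n)) {
      s <- pid$s[i]; dd <- pid$d[i]
      pa <- 0.5 * sum(c(if (!is.na(s)) a_poly[s], if (!is.na(dd)) a_poly[dd]))
      known <- sum(!is.na(c(s, dd)))
      msv <- switch(known + 1L, 1,
                    0.75 - 0.25 * Fv[c(s, dd)[!is.na(c(s, dd))]],
                    0.5 - 0.25 * (Fv[s] + Fv[dd]))
      a_poly[i] <- (if (known > 0) pa else 0) + rnorm(1, 0, sqrt(msv))
    }
    a_poly <- a_poly * sqrt(poly_var) / sd(a_poly[match(sows, ped$animal)])
  }
  a <- a_qtl + a_bg + setNames(a_poly, ped$animal)
  # finite-sample covariance between components perturbs the total: rescale
  # everything once more so Var(a) among recorded sows is sigma_a2 exactly
  scl_tot <- sqrt(cfg$sigma_a2) / sd(a[sows])
  a <- a * scl_tot
  beta <- beta * scl_tot

  pe <- setNames(rnorm(length(sows), 0, sqrt(cfg$sigma_pe2)), sows)
  parity_eff <- c(0, rnorm(cfg$n_parities - 1, 0, cfg$parity_effect_sd))
  ys_eff <- c(0, rnorm(cfg$n_year_seasons - 1, 0, cfg$year_season_effect_sd))

  rec <- tidyr::expand_grid(animal = sows, parity = seq_len(cfg$n_parities))
  rec$year_season <- sample.int(cfg$n_year_seasons, nrow(rec), replace = TRUE)
  rec$value <- cfg$mu + parity_eff[rec$parity] + ys_eff[rec$year_season] +
    a[rec$animal] + pe[rec$animal] +
    rnorm(nrow(rec), 0, sqrt(cfg$sigma_e2))
  if (isTRUE(cfg$integerize_phenotypes)) rec$value <- pmax(round(rec$value), 0)

  realized_h2 <- var_pop(unname(a[sows])) /
    (var_pop(unname(a[sows])) + cfg$sigma_pe2 + cfg$sigma_e2)
  list(
    records = rec,
    truth = list(
      a = a, pe = pe,
      qtl = tibble(marker = md$map$marker[qtl_idx],
                   chrom = md$map$chrom[qtl_idx],
                   pos = md$map$pos[qtl_idx],
                   effect = beta, variance_fraction = qf),
      parity_effects = parity_eff, year_season_effects = ys_eff,
      realized_h2 = realized_h2
    )
  )
}

#' Restrict a marker data set to a subset of samples
#'
#' @param md a [marker_data()] object.
#' @param ids sample ids to keep, in the given order.
#' @return A [marker_data()] object.
#' @export
subset_samples <- function(md, ids) {
  missing <- setdiff(ids, rownames(md$calls))
  if (length(missing) > 0)
    abort(paste("samples not present:", paste(missing, collapse = ", ")))
  marker_data(md$calls[ids, , drop = FALSE], md$map, sample_ids = ids)
}

#' Simulate a complete litter-trait study
#'
#' Chains [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under sub-seeds derived from `seed`, then marks a
#' `genotyping_fraction` of animals as genotyped (recorded sows first, then
#' random earlier animals).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return List: `ped`, `markers` (all animals), `geno` (genotyped-subset
#'   [marker_data()] for analysis), `records`, `truth`, `cfg`, `seed`.
#' @export
sim_litter_study <- function(cfg = sim_config(), seed) {
  assert_that(!missing(seed), "seed is required")
  ped <- simulate_pedigree(cfg, seed = seed)
  md <- simulate_genotypes(ped, cfg, seed = seed + 1000L)
  ph <- simulate_phenotypes(ped, md, cfg, seed = seed + 2000L)
  sows <- unique(ph$records$animal)
  n_geno <- round(cfg$genotyping_fraction * nrow(ped))
  set.seed(seed + 3000L)
  if (n_geno <= length(sows)) {
    geno_ids <- sample(sows, n_geno)
  } else {
    geno_ids <- c(sows, sample(setdiff(ped$animal, sows),
                               min(n_geno - length(sows),
                                   nrow(ped) - length(sows))))
  }
  geno_ids <- ped$animal[ped$animal %in% geno_ids]  # pedigree order
  list(ped = ped, markers = md, geno = subset_samples(md, geno_ids),
       records = ph$records, truth = ph$truth, cfg = cfg, seed = seed)
}

#' Write a simulated study to disk in the package's input formats
#'
#' Pedigree CSV (`animal,sire,dam`), PLINK .ped/.map for the genotyped
#' animals, phenotype CSV (`animal,parity,year_season,value`) and a truth
#' YAML.
#'
#' @param study result of [sim_litter_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             plink_ped = file.path(dir, "genotypes.ped"),
             plink_map = file.path(dir, "genotypes.map"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.yaml"))
  ped_out <- study$ped
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  readr::write_csv(ped_out[, c("animal", "sire", "dam")], paths["pedigree"])
  md <- study$geno
  al <- c("A", "G")
  geno_char <- matrix("0 0", nrow(md$calls), ncol(md$calls))
  for (v in 0:2) geno_char[which(md$calls == v)] <-
      paste(al[c(1, 1, 2)[v + 1]], al[c(1, 2, 2)[v + 1]])
  lines <- paste(rownames(md$calls), rownames(md$calls), "0 0 0 -9",
                 apply(geno_char, 1, paste, collapse = " "))
  writeLines(lines, paths["plink_ped"])
  readr::write_tsv(tibble(chrom = md$map$chrom, marker = md$map$marker,
                          cm = 0, pos = md$map$pos),
                   paths["plink_map"], col_names = FALSE)
  readr::write_csv(study$records, paths["phenotypes"])
  yaml::write_yaml(list(
    realized_h2 = study$truth$realized_h2,
    qtl = lapply(seq_len(nrow(study$truth$qtl)), function(i)
      as.list(study$truth$qtl[i, ])),
    seed = study$seed), paths["truth"])
  invisible(paths)
}
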