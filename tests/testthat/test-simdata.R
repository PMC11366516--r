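test_that("pedigree simulation obeys the mating design and is reproducible", {
  cfg <- sim_config(n_sires = 4, dams_per_sire = 3, offspring_per_dam = 5,
                    n_generations = 3)
  ped <- simulate_pedigree(cfg, seed = 1)
  # founders: 4 sires + 12 dams; two bred generations of 60 each
  expect_equal(sum(ped$generation == 0), 16)
  expect_equal(sum(ped$generation == 1), 60)
  expect_equal(sum(ped$generation == 2), 60)
  expect_equal(nrow(ped), 136)
  # parents precede offspring and all parents exist
  expect_true(all(is.na(ped$sire) | ped$sire %in% ped$animal))
  kids <- which(!is.na(ped$sire))
  expect_true(all(match(ped$sire[kids], ped$animal) < kids))
  # determinism
  expect_identical(simulate_pedigree(cfg, seed = 1), ped)
  expect_false(identical(simulate_pedigree(cfg, seed = 2)$sire, ped$sire))

  # founders-only degenerate config
  flat <- simulate_pedigree(sim_config(n_sires = 3, dams_per_sire = 2,
                                       n_generations = 1), seed = 1)
  expect_true(all(is.na(flat$sire)))
})

test_that("gene dropping reproduces founder HWE and chromosome-scale linkage", {
  cfg <- sim_config(n_sires = 30, dams_per_sire = 4, offspring_per_dam = 4,
                    n_generations = 2, n_chromosomes = 2,
                    chrom_length_bp = 5e7, n_markers = 60,
                    maf_range = c(0.3, 0.3))
  ped <- simulate_pedigree(cfg, seed = 5)
  md <- simulate_genotypes(ped, cfg, seed = 6)
  expect_identical(simulate_genotypes(ped, cfg, seed = 6)$calls, md$calls)
  # founder genotype frequencies match HWE at the stated MAF within
  # binomial error: p = 0.3, 150 founders x 60 markers
  founders <- ped$animal[ped$generation == 0]
  fc <- md$calls[founders, ]
  phat <- mean(fc) / 2
  se <- sqrt(0.3 * 0.7 / (2 * length(fc)))
  expect_lt(abs(phat - 0.3), 4 * se)
  het <- mean(fc == 1)
  expect_lt(abs(het - 2 * 0.3 * 0.7), 0.02)

  # zero recombination: offspring inherit whole-chromosome haplotypes, so
  # adjacent markers are in near-founder-level LD among close relatives
  cfg0 <- cfg; cfg0$recomb_cM_per_Mb <- 0
  md0 <- simulate_genotypes(ped, cfg0, seed = 6)
  off <- ped$animal[ped$generation == 1]
  chr1 <- which(md0$map$chrom == "1")
  r2_adj <- mean(vapply(seq_len(length(chr1) - 1), function(j)
    pair_r2(md0$calls[off, chr1[j]], md0$calls[off, chr1[j + 1]]),
    numeric(1)), na.rm = TRUE)
  cfg1 <- cfg; cfg1$recomb_cM_per_Mb <- 50
  md1 <- simulate_genotypes(ped, cfg1, seed = 6)
  r2_free <- mean(vapply(seq_len(length(chr1) - 1), function(j)
    pair_r2(md1$calls[off, chr1[j]], md1$calls[off, chr1[j + 1]]),
    numeric(1)), na.rm = TRUE)
  expect_gt(r2_adj, r2_free)
})

test_that("phenotypes follow the repeatability model structure", {
  cfg <- sim_config(n_sires = 10, dams_per_sire = 4, offspring_per_dam = 6,
                    n_markers = 180, n_qtl = 4, qtl_variance_fractions = 0.1,
                    n_background_loci = 50)
  ped <- simulate_pedigree(cfg, seed = 11)
  md <- simulate_genotypes(ped, cfg, seed = 12)
  ph <- simulate_phenotypes(ped, md, cfg, seed = 13)
  sows <- unique(ph$records$animal)
  expect_equal(nrow(ph$records), length(sows) * cfg$n_parities)
  # true additive variance among recorded sows hits the target exactly
  expect_equal(var(ph$truth$a[sows]), cfg$sigma_a2, tolerance = 1e-6)
  expect_identical(simulate_phenotypes(ped, md, cfg, seed = 13)$records,
                   ph$records)

  # no residual, no fixed effects: records within a sow identical up to pe
  cfg0 <- cfg
  cfg0$sigma_e2 <- 1e-12; cfg0$parity_effect_sd <- 0
  cfg0$year_season_effect_sd <- 0
  ph0 <- simulate_phenotypes(ped, md, cfg0, seed = 14)
  spread <- tapply(ph0$records$value, ph0$records$animal,
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-4)

  # integerized phenotypes are non-negative whole numbers
  cfgi <- cfg; cfgi$integerize_phenotypes <- TRUE
  phi <- simulate_phenotypes(ped, md, cfgi, seed = 15)
  expect_true(all(phi$records$value >= 0))
  expect_equal(phi$records$value, round(phi$records$value))

  expect_error(simulate_phenotypes(
    ped, md, sim_config(n_qtl = 1000, qtl_variance_fractions = 1e-4), seed = 1),
    "more QTL than markers")
})

test_that("a full simulated study is internally consistent and writable", {
  cfg <- sim_config(n_sires = 6, dams_per_sire = 3, offspring_per_dam = 4,
                    n_markers = 90, n_qtl = 2, qtl_variance_fractions = 0.1,
                    n_background_loci = 30, genotyping_fraction = 0.4)
  st <- sim_litter_study(cfg, seed = 21)
  expect_true(all(rownames(st$geno$calls) %in% st$ped$animal))
  expect_equal(nrow(st$geno$calls), round(0.4 * nrow(st$ped)))
  # genotyped set prioritizes recorded sows
  sows <- unique(st$records$animal)
  expect_true(all(rownames(st$geno$calls) %in% c(sows, st$ped$animal)))

  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  ped2 <- read_pedigree(paths["pedigree"])
  expect_setequal(ped2$animal, st$ped$animal)
  md2 <- read_plink_text(paths["plink_ped"], paths["plink_map"])
  expect_equal(dim(md2$calls), dim(st$geno$calls))
  # round-trip preserves genotype classes up to allele-counting orientation
  m <- md2$calls[rownames(st$geno$calls), 1]
  expect_true(all(m == st$geno$calls[, 1] | m == 2 - st$geno$calls[, 1]))
})

test_that("REML on simulated data recovers the generating heritability", {
  # pure pedigree-polygenic architecture: the exact model REML assumes
  cfg <- sim_config(n_sires = 20, dams_per_sire = 5, offspring_per_dam = 6,
                    n_markers = 90, n_qtl = 0,
                    qtl_variance_fractions = numeric(0),
                    n_background_loci = 0, polygenic_fraction = 1,
                    genotyping_fraction = 0)
  h2 <- numeric(3)
  for (k in 1:3) {
    st <- sim_litter_study(cfg, seed = 50 + k)
    fit <- fit_reml(st$records, a_inverse(st$ped), max_iter = 100)
    h2[k] <- fit$h2
  }
  target <- cfg$sigma_a2 / (cfg$sigma_a2 + cfg$sigma_pe2 + cfg$sigma_e2)
  expect_lt(abs(mean(h2) - target), 0.06)
})
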