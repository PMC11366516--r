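test_that("SNP effect back-solve matches dense algebra on a toy system", {
  # 3 samples, 2 markers, hand-computable
  Z <- matrix(c(-1, 0, 1, 0.5, -1, 0.5), 3, 2)
  d <- c(1, 2)
  lambda <- 0.8
  G <- Z %*% diag(d) %*% t(Z) * lambda + diag(1e-6, 3)  # regularized, invertible
  a_g <- c(0.3, -0.5, 0.2)
  Ginv <- solve(G)
  u <- backsolve_snp_effects(a_g, Z, d, Ginv, lambda)
  u_dense <- lambda * diag(d) %*% t(Z) %*% Ginv %*% a_g
  expect_equal(unname(u), drop(u_dense), tolerance = 1e-10)
  expect_equal(unname(backsolve_snp_effects(rep(0, 3), Z, d, Ginv, lambda)),
               c(0, 0), tolerance = 1e-12)
  expect_error(backsolve_snp_effects(1:2, Z, d, Ginv, lambda), "length")
})

test_that("weight updates square effects and scale by heterozygosity", {
  expect_equal(update_weights(c(1, 1), c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(update_weights(c(0, 2), c(0.5, 0.2)), c(0, 4 * 2 * 0.2 * 0.8))
  u <- c(0.3, -1.1, 0.7); p <- c(0.2, 0.4, 0.5)
  expect_equal(update_weights(3 * u, p), 9 * update_weights(u, p))
})

test_that("weight normalization preserves proportions and the trace exactly", {
  expect_equal(normalize_weights(c(0.5, 0.5), trace_target = 2), c(1, 1))
  expect_equal(normalize_weights(c(3, 1), trace_target = 2), c(1.5, 0.5))
  d0 <- c(0.4, 1.6)  # already traces to 2
  expect_equal(normalize_weights(d0, 2), d0)
  expect_warning(dz <- normalize_weights(c(0, 0), trace_target = 2), "zero")
  expect_equal(sum(dz), 2)
  set.seed(1)
  dr <- runif(50)
  dn <- normalize_weights(dr, 50)
  expect_equal(sum(dn), 50)
  expect_equal(dn / dn[1], dr / dr[1], tolerance = 1e-9)
})

test_that("the weighted loop keeps its invariants on simulated data", {
  cfg <- sim_config(n_sires = 8, dams_per_sire = 4, offspring_per_dam = 6,
                    n_markers = 270, n_qtl = 2, qtl_variance_fractions = 0.15,
                    n_background_loci = 60, genotyping_fraction = 0.6)
  st <- sim_litter_study(cfg, seed = 77)
  geno <- apply_qc(st$geno, qc_config())$markers
  vc <- c(sigma_a2 = cfg$sigma_a2, sigma_pe2 = cfg$sigma_pe2,
          sigma_e2 = cfg$sigma_e2)
  run <- suppressWarnings(run_wssgwas(st$records, geno, st$ped, vc,
                                      cfg = wssgwas_config(n_iterations = 3)))
  M <- ncol(run$Z)
  for (it in run$iterations) {
    # trace conservation, exact
    expect_equal(sum(it$weights), M)
    # reconstruction identity on the centered GEBVs
    expect_lt(it$reconstruction_error, 1e-6)
    a_c <- it$gebv$gebv_centered
    expect_equal(as.numeric(run$Z %*% it$u_hat), a_c, tolerance = 1e-6)
  }
  # iteration 1 is plain ssGBLUP: D = I
  expect_equal(run$iterations[[1]]$weights, rep(1, M))
  r1 <- run_wssgwas(st$records, geno, st$ped, vc,
                    cfg = wssgwas_config(n_iterations = 1))
  expect_equal(r1$iterations[[1]]$u_hat, run$iterations[[1]]$u_hat)
})

test_that("window scan matches hand calculations and label-flip invariance", {
  # 4 samples, 2 SNPs in one window
  Z <- matrix(c(-1, 0, 1, 0, 0.5, -0.5, 0.5, -0.5), 4, 2)
  u <- c(0.4, -0.2)
  map <- tibble::tibble(marker = c("m1", "m2"), chrom = "1",
                        pos = c(1e5, 2e5))
  scan <- window_scan(u, Z, map, sigma_a2 = 1)
  # a = Z u = (-0.5, 0.1, 0.3, 0.1); population variance 0.09 -> 9%
  expect_equal(scan$pct_var[1], 9)
  expect_equal(scan$n_snp, c(2L, 1L))
  # u = 0 -> all-zero scan
  scan0 <- window_scan(c(0, 0), Z, map, 1)
  expect_equal(scan0$pct_var, c(0, 0))
  # flipping a marker's labels (Z column and u sign) leaves the scan unchanged
  Zf <- Z; Zf[, 2] <- -Z[, 2]; uf <- u; uf[2] <- -u[2]
  expect_equal(window_scan(uf, Zf, map, 1)$pct_var, scan$pct_var)
  # whole-genome identity when every SNP shares one window
  set.seed(2)
  Zb <- matrix(rnorm(60), 10, 6)
  ub <- rnorm(6)
  mapb <- tibble::tibble(marker = paste0("s", 1:6), chrom = "1",
                         pos = seq(1000, 6000, by = 1000))
  sb <- window_scan(ub, Zb, mapb, sigma_a2 = 2, window_bp = 1e6)
  av <- Zb %*% ub
  expect_equal(sb$pct_var[1], mean((av - mean(av))^2) / 2 * 100)
  # unsorted map is an error
  expect_error(window_scan(ub, Zb, mapb[6:1, ], 2), "sorted")
})

test_that("significant windows merge into regions by overlap", {
  wv <- tibble::tibble(
    chrom = c("1", "1", "2", "2"),
    start_bp = c(1e6, 1.3e6, 5e6, 9e6),
    end_bp = c(1.5e6, 1.8e6, 5.4e6, 9.4e6),
    anchor = paste0("m", 1:4),
    n_snp = c(3L, 3L, 2L, 2L),
    pct_var = c(2.0, 1.6, 1.0, 1.6),
    idx_start = c(1L, 2L, 5L, 8L),
    idx_end = c(3L, 4L, 6L, 9L))
  class(wv) <- c("wssgwas_scan", class(tibble::tibble()))
  regions <- significant_windows(wv, wssgwas_config(sig_threshold_pct = 1.56))
  # overlapping chr1 windows merge; chr2 at 1.0 is below threshold
  expect_equal(nrow(regions), 2)
  expect_equal(regions$start_bp, c(1e6, 9e6))
  expect_equal(regions$end_bp, c(1.8e6, 9.4e6))
  expect_equal(regions$pct_var, c(2.0, 1.6))
  expect_equal(regions$n_snp, c(4L, 2L))
  # all below threshold -> empty
  none <- significant_windows(wv, wssgwas_config(sig_threshold_pct = 10))
  expect_equal(nrow(none), 0)
  # disjoint significant anchors stay separate regions
  wv2 <- wv; wv2$pct_var <- c(2.0, 1.0, 1.6, 1.6)
  r2 <- significant_windows(wv2, wssgwas_config(sig_threshold_pct = 1.56))
  expect_equal(nrow(r2), 3)
})

test_that("genotype class means summarize records by marker genotype", {
  calls <- rbind(a1 = 0, a2 = 0, a3 = 1, a4 = 1, a5 = 2, a6 = 2)
  md <- toy_markers(calls)
  rec <- tibble::tibble(animal = rep(paste0("a", 1:6), each = 2),
                        value = c(10, 11, 9, 10, 12, 13, 11, 12, 14, 15, 15, 16))
  cm <- genotype_class_means(rec, md, "m1")
  expect_equal(cm$genotype, c(0, 1, 2))
  expect_equal(cm$mean_value, c(10, 12, 15))
  expect_equal(cm$n_records, c(4L, 4L, 4L))
  expect_equal(attr(cm, "hom_difference"), 5)
  # absent class is absent, not zero
  cm2 <- genotype_class_means(rec[1:6, ], md, "m1")
  expect_equal(cm2$genotype, c(0, 1))
  # one class only -> single overall mean of those records
  cm3 <- genotype_class_means(rec[1:4, ], md, "m1")
  expect_equal(cm3$genotype, 0)
  expect_equal(cm3$mean_value, mean(c(10, 11, 9, 10)))
  expect_error(genotype_class_means(rec, md, "nope"), "not present")
})

test_that("gene annotation overlaps are half-open and report gaps", {
  ann <- tibble::tibble(
    chrom = c("1", "1", "1"),
    start = c(900, 2000, 5000),
    end = c(1100, 2500, 5600),
    gene = c("G1", "G2", "G3"))
  regions <- tibble::tibble(chrom = c("1", "1", "2"),
                            start_bp = c(1000, 2500, 100),
                            end_bp = c(2000, 3000, 200))
  expect_message(out <- annotate_windows(regions, ann), "absent")
  # G1 overlaps [1000,2000); G2 starts exactly at region end 2000 -> excluded
  expect_equal(out$genes[1], "G1")
  # G2 [2000,2500) abuts region [2500,3000) -> excluded; no gene
  expect_equal(out$genes[2], "-")
  expect_equal(out$genes[3], "-")

  # GFF3 file input
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t1500\t1800\t.\t+\t.\tID=gene:g10;Name=NANOG",
               "1\tsrc\tgene\t1900\t2600\t.\t+\t.\tID=gene:g11;Name=POU5F1",
               "1\tsrc\tgene\t9000\t9500\t.\t+\t.\tID=gene:g12;Name=FAR1"),
             gff)
  out2 <- annotate_windows(regions[1, ], gff)
  expect_equal(out2$genes, "NANOG, POU5F1")
})
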