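test_that("PLINK text genotypes are read with first-listed-allele counting", {
  ped_path <- withr::local_tempfile(fileext = ".ped")
  map_path <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 s1 0 0 2 -9 A A G G 0 0",
               "1 s2 0 0 2 -9 A G G G C C",
               "1 s3 0 0 2 -9 G G G A C C"),
             ped_path)
  writeLines(c("1\tm1\t0\t1000", "X\tm2\t0\t2000", "2\tm3\t0\t500"), map_path)
  md <- read_plink_text(ped_path, map_path)
  # m1: counted allele A (first listed): s1 AA=2, s2 AG=1, s3 GG=0
  expect_equal(unname(md$calls[, "m1"]), c(2, 1, 0))
  # "0 0" is missing (third genotype pair = m3)
  expect_true(is.na(md$calls["s1", "m3"]))
  expect_equal(unname(md$calls[c("s2", "s3"), "m3"]), c(2, 2))
  # X-chromosome marker retained at read time (QC filters later)
  expect_true("m2" %in% md$map$marker)
  # map sorted by chromosome then position
  expect_equal(md$map$chrom, c("1", "2", "X"))
  # ragged/mismatched input errors
  writeLines(c("1 s1 0 0 2 -9 A A"), ped_path)
  expect_error(read_plink_text(ped_path, map_path), "expected")
})

test_that("matrix TSV round-trips calls and rejects bad values", {
  g_path <- withr::local_tempfile(fileext = ".tsv")
  m_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tm1\tm2", "s1\t0\t2", "s2\tNA\t1"), g_path)
  writeLines(c("marker\tchrom\tpos", "m1\t1\t100", "m2\t1\t200"), m_path)
  md <- read_matrix_tsv(g_path, m_path)
  expect_equal(unname(md$calls[, "m1"]), c(0, NA))
  expect_equal(unname(md$calls[, "m2"]), c(2, 1))
  writeLines(c("sample\tm1\tm2", "s1\t0\t5", "s2\t1\t1"), g_path)
  expect_error(read_matrix_tsv(g_path, m_path), "0, 1, 2 or NA")
})

test_that("exact HWE p-values agree with the enumeration oracle", {
  expect_equal(hwe_exact_p(50, 0, 0), 1)  # monomorphic
  expect_equal(hwe_exact_p(25, 50, 25), hwe_enum_oracle(25, 50, 25))
  # all-homozygote split is wildly out of equilibrium
  expect_lt(hwe_exact_p(30, 0, 30), 1e-6)
  expect_error(hwe_exact_p(0, 0, 0), "zero")
  # random tables up to n = 200
  set.seed(7)
  for (k in 1:40) {
    n <- sample(5:200, 1)
    nA <- sample(0:(2 * n), 1)
    max_het <- min(nA, 2 * n - nA)
    het <- sample(seq(nA %% 2, max_het, by = 2), 1)
    tab <- c((nA - het) / 2, het, n - het - (nA - het) / 2)
    expect_equal(hwe_exact_p(tab[1], tab[2], tab[3]),
                 hwe_enum_oracle(tab[1], tab[2], tab[3]),
                 tolerance = 1e-12)
  }
})

test_that("QC filters apply in fixed order with a reconciling report", {
  set.seed(1)
  n <- 40
  calls <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  calls[, 4] <- rbinom(n, 2, 0.003)            # low MAF
  calls[1:round(0.2 * n), 5] <- NA             # low call rate
  calls[1:round(0.15 * n), 6] <- NA            # low call rate
  calls[, 7] <- rep(c(0, 2), each = n / 2)     # extreme HWE failure
  md <- toy_markers(calls,
                    chrom = c("1", "1", "X", "1", "1", "1", "1", "1", "0", "2"),
                    pos = c(1e3, 2e3, 3e3, 4e3, 5e3, 6e3, 7e3, 8e3, NA, 9e3))
  res <- apply_qc(md, qc_config())
  rem <- setNames(res$report$removed$n_removed, res$report$removed$rule)
  expect_equal(unname(rem["unknown_position"]), 1)
  expect_equal(unname(rem["sex_chromosome"]), 1)
  expect_equal(unname(rem["call_rate"]), 2)
  expect_equal(unname(rem["maf"]), 1)
  expect_equal(unname(rem["hwe"]), 1)
  expect_equal(res$report$n_markers_out + sum(rem), res$report$n_markers_in)
  expect_equal(ncol(res$markers$calls), 4)

  # disabled thresholds pass everything through
  off <- qc_config(min_call_rate = 0, min_maf = 0, hwe_p_min = 0,
                   drop_sex_chromosomes = FALSE, drop_unknown_position = FALSE)
  expect_equal(ncol(apply_qc(md, off)$markers$calls), ncol(md$calls))

  # idempotence
  res2 <- apply_qc(res$markers, qc_config())
  expect_equal(res2$markers$calls, res$markers$calls)
  expect_equal(sum(res2$report$removed$n_removed), 0)
})

test_that("opposing-homozygote conflict rate counts jointly called markers", {
  expect_equal(parentage_conflict_rate(c(0, 1, 2, 2), c(0, 1, 2, 2)), 0)
  expect_equal(parentage_conflict_rate(rep(0, 100), rep(2, 100)), 1)
  parent <- c(rep(0, 10), rep(2, 5), rep(NA, 5))
  child <- c(rep(2, 3), rep(0, 7), rep(2, 5), rep(1, 5))
  # 15 jointly called, 3 opposing homozygotes
  expect_equal(parentage_conflict_rate(parent, child), 0.2)
  expect_error(parentage_conflict_rate(c(NA, NA), c(1, 2)), "jointly")

  # flagging through a pedigree screen
  ped <- as_pedigree(data.frame(animal = c("p", "c"), sire = c("0", "p"),
                                dam = c("0", "0")))
  calls <- rbind(p = c(rep(0, 10), rep(1, 10)), c = c(rep(2, 3), rep(0, 7), rep(1, 10)))
  md <- toy_markers(calls)
  chk <- parentage_check(md, ped, qc_config())
  expect_equal(nrow(chk), 1)
  expect_equal(chk$conflict_rate, 0.15)
  expect_true(chk$flagged)
})

test_that("centered gene content and lambda follow the VanRaden scaling", {
  md <- toy_markers(matrix(c(0, 1, 2), 3, 1))
  gc <- gene_content_centered(md)
  expect_equal(unname(gc$Z[, 1]), c(-1, 0, 1))
  expect_equal(gc$lambda, 2)  # p = 0.5 -> 1 / (2 * 0.25)
  # all-heterozygote column has p = 0.5 and centers to zero
  md2 <- toy_markers(cbind(c(0, 1, 2), c(1, 1, 1)))
  expect_equal(unname(gene_content_centered(md2)$Z[, 2]), rep(0, 3))
  # a truly monomorphic marker breaks the lambda scaling and is an error
  expect_error(gene_content_centered(toy_markers(cbind(c(0, 1, 2), c(2, 2, 2)))),
               "monomorphic")
  gc2 <- gene_content_centered(md2, freqs = c(0.5, 0.45))
  expect_equal(unname(gc2$Z[, 2]), rep(0.1, 3))
  # column means are zero under own-sample frequencies
  set.seed(3)
  md3 <- toy_markers(matrix(rbinom(200, 2, 0.3), 20, 10))
  gc3 <- gene_content_centered(md3)
  expect_equal(unname(colMeans(gc3$Z)), rep(0, 10))
  # missing calls mean-imputed before centering
  calls <- matrix(rbinom(60, 2, 0.5), 20, 3)
  calls[1, 1] <- NA
  md4 <- toy_markers(calls)
  gc4 <- gene_content_centered(md4)
  expect_equal(gc4$Z[1, 1], 0)
})
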