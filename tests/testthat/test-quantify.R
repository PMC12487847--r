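test_that("channel apportionment splits MS1 proportionally and conserves it", {
  expect_equal(apportionChannels(1000, matrix(c(1, 1, 1, 1), 1))$apportioned,
               matrix(c(250, 250, 250, 250), 1))
  expect_equal(apportionChannels(1000, matrix(c(3, 1, 0, 0), 1))$apportioned,
               matrix(c(750, 250, 0, 0), 1))
  # all-zero reporters: flagged unquantifiable, not zeroed
  res <- apportionChannels(500, matrix(0, 1, 4))
  expect_true(res$unquantifiable)
  expect_true(all(is.na(res$apportioned)))

  # conservation property on random PSMs
  set.seed(7)
  ms1 <- runif(100, 1, 1e6)
  rep_mat <- matrix(rexp(400), 100, 4)
  out <- apportionChannels(ms1, rep_mat)
  expect_equal(rowSums(out$apportioned), ms1, tolerance = 1e-12)
  expect_error(apportionChannels(-1, matrix(1, 1, 1)), "non-negative")
})

test_that("absolute quantification sums unique PSMs and divides by peptide count", {
  # protein with 4 theoretical peptides (4 x 8-mers ending K)
  seq4 <- paste(rep("AAAAAAAK", 4), collapse = "")
  fm <- c(P1 = seq4)
  psm1 <- data.frame(peptide = "AAAAAAAK", proteins = "P1",
                     ms1_intensity = 1000,
                     reporter_c1 = 1, reporter_c2 = 1)
  psm1$accessions <- list("P1")
  pq <- proteinAbsoluteQuant(psm1, fm)
  expect_equal(unname(abundance(pq)["P1", ]), c(125, 125))

  # two PSMs: per-channel sums add before division
  # hand oracle: (1000*0.5 + 600*0.25)/4 = 162.5 ; (500 + 450)/4 = 237.5
  psm2 <- rbind(psm1[, 1:5],
                data.frame(peptide = "AAAAAAAK", proteins = "P1",
                           ms1_intensity = 600,
                           reporter_c1 = 1, reporter_c2 = 3))
  psm2$accessions <- list("P1", "P1")
  pq2 <- proteinAbsoluteQuant(psm2, fm)
  expect_equal(unname(abundance(pq2)["P1", ]), c(162.5, 237.5))

  # shared PSM contributes to neither accession
  psm3 <- rbind(psm2[, 1:5],
                data.frame(peptide = "AAAAAAAK", proteins = "P1;P2",
                           ms1_intensity = 1e6,
                           reporter_c1 = 1, reporter_c2 = 1))
  psm3$accessions <- list("P1", "P1", c("P1", "P2"))
  pq3 <- proteinAbsoluteQuant(psm3, c(fm, P2 = seq4))
  expect_equal(abundance(pq3)["P1", ], abundance(pq2)["P1", ])
  expect_false("P2" %in% rownames(pq3))  # zero unique PSMs -> missing row

  expect_error(proteinAbsoluteQuant(psm1, c(OTHER = seq4)),
               "absent from FASTA.*P1")
})

test_that("quantification is linear in MS1 intensity", {
  sim <- simulateDataset(syntheticConfig(
    n_background = 30L, n_groups = 5L, n_shifted = 2L, seed = 5))
  pq1 <- proteinAbsoluteQuant(sim$psms, sim$fasta_map,
                              samples = sim$design$sample)
  psms2 <- sim$psms
  psms2$ms1_intensity <- psms2$ms1_intensity * 3.5
  pq2 <- proteinAbsoluteQuant(psms2, sim$fasta_map,
                              samples = sim$design$sample)
  expect_equal(abundance(pq2), 3.5 * abundance(pq1), tolerance = 1e-12)
})

test_that("iBAQ estimates rank-correlate with true copy numbers", {
  sim <- simulateDataset(syntheticConfig(
    n_background = 300L, n_groups = 20L, n_shifted = 10L, cv = 0,
    interference = 0, seed = 11))
  pq <- proteinAbsoluteQuant(sim$psms, sim$fasta_map,
                             samples = sim$design$sample)
  est <- abundance(pq)
  tru <- sim$truth$abundance[rownames(est), colnames(est)]
  for (j in seq_len(ncol(est)))
    expect_gt(cor(est[, j], tru[, j], method = "spearman"), 0.95)
})

test_that("quant matrix round-trips through the TSV dialect", {
  pq <- tinyQuant(rbind(A = c(1.5, NA, 3, 4), B = c(0, 1, 2, 3)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeQuantMatrix(pq, tf)
  back <- readQuantMatrix(tf)
  expect_equal(abundance(back), abundance(pq))
})

test_that("sample correlation QC is symmetric with unit diagonal", {
  m <- matrix(10^runif(200, 1, 5), 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  m2 <- cbind(m, s5 = 2 * m[, 1])  # scaled copy: r = 1 in log space
  r <- qcCorrelation(m2, log_scale = TRUE)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r["s1", "s5"], 1)

  # textbook-formula oracle on a small hand table
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r2 <- qcCorrelation(cbind(a = x, b = y), log_scale = FALSE)
  expect_equal(r2["a", "b"], hand)

  expect_warning(qcCorrelation(cbind(a = c(1, NA, NA, NA), b = c(NA, 1, 2, 3)),
                               log_scale = FALSE),
                 "share only")
})
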