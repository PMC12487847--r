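test_that("ratio matrix entries are glog differences with missing propagation", {
  raw <- rbind(A = c(800, 800, 1600, 1600),
               B = c(400, 400, 400, NA),
               C = c(800, 800, 1600, 1600))
  colnames(raw) <- paste0("s", 1:4)
  pq <- glogNormalize(ProteinQuant(rbind(raw,
    matrix(10^runif(40, 2, 4), 10, 4,
           dimnames = list(paste0("bg", 1:10), colnames(raw))))))
  pairs <- IsoformPairs(c("A", "A"), c("B", "C"))
  rm_ <- computeRatioMatrix(pq, pairs)
  # identical members: all-zero row
  expect_equal(unname(rm_$ratios["A|C", ]), rep(0, 4))
  # missing member -> missing entry
  expect_true(is.na(rm_$ratios["A|B", "s4"]))
  # large-signal 2x ratio ~ 1 in log2
  expect_equal(unname(rm_$ratios["A|B", "s1"]), 1, tolerance = 0.05)
  # absent member -> pair dropped with warning
  expect_warning(computeRatioMatrix(pq, IsoformPairs("A", "ZZZ")),
                 "dropped")
})

test_that("minor isoform fraction averages min/(a+b) over complete samples", {
  raw <- rbind(A = c(70, 70, 70, 70), B = c(30, 30, 30, 30),
               C = c(70, 70, 70, 70), D = c(0, 0, 0, 0),
               E = c(50, 50, 50, 50))
  colnames(raw) <- paste0("s", 1:4)
  pq <- ProteinQuant(raw)
  pairs <- IsoformPairs(c("A", "A", "A", "D"), c("B", "C", "D", "E"))
  mif <- computeMif(pq, pairs)
  expect_equal(unname(mif["A|B"]), 0.30)   # 70:30 proportions
  expect_equal(unname(mif["A|C"]), 0.5)    # equal members
  expect_equal(unname(mif["A|D"]), 0.0)    # one member absent
  expect_true(all(mif <= 0.5, na.rm = TRUE))
})

test_that("row-wise OLS recovers contrasts, with and without a block covariate", {
  X <- twoGroupDesign(3)
  Y <- matrix(c(1, 1, 1, 2, 2, 2), 1, dimnames = list("r1", rownames(X)))
  fit <- fitLinearModel(Y, X)
  expect_equal(unname(fit@logFC), 1)
  expect_equal(unname(fit@sigma2), 0)
  expect_equal(unname(fit@df), 4)

  # normal-equations oracle on a 6-sample toy with an orthogonal block
  tab <- data.frame(sample = paste0("s", 1:6),
                    condition = rep(c("a", "b"), each = 3),
                    block = rep(c("x", "y", "x"), 2))
  Xb <- designMatrix(tab, "~ condition + block")
  set.seed(9)
  y <- c(1.1, 0.9, 1.0, 2.2, 1.8, 2.0)
  Ym <- matrix(y, 1, dimnames = list("r1", tab$sample))
  fitb <- fitLinearModel(Ym, Xb, contrast = "conditionb")
  beta_hat <- solve(crossprod(Xb), crossprod(Xb, y))
  expect_equal(unname(fitb@logFC), unname(beta_hat["conditionb", 1]))
  expect_equal(unname(fitb@stdevUnscaled),
               sqrt(solve(crossprod(Xb))["conditionb", "conditionb"]))

  # saturated row: flagged untestable
  X2 <- twoGroupDesign(1)
  Y2 <- matrix(rnorm(2), 1, dimnames = list("r1", rownames(X2)))
  fit2 <- eBayesSqueeze(fitLinearModel(Y2, X2), prior.df = 0)
  expect_true(is.na(fit2@t[1]))

  # rank-deficient design identifies aliased columns
  tab$dup <- tab$condition
  expect_error(designMatrix(tab, "~ condition + dup"), "aliased")
})

test_that("variance squeezing recovers the scaled inverse-chi-squared prior", {
  # limiting cases
  sq_const <- squeezeVariances(rep(2, 100), d = 50)
  expect_true(is.infinite(sq_const$d0))
  expect_equal(sq_const$postVar, rep(sq_const$s02, 100))

  # simulation oracle: s2 ~ s0^2 * F(d, d0), d0 = 4, s0^2 = 1
  set.seed(123)
  n <- 5000; d0 <- 4; s02 <- 1; d <- 8
  s2 <- s02 * (rchisq(n, d) / d) / (rchisq(n, d0) / d0)
  sq <- squeezeVariances(s2, d)
  expect_lt(abs(sq$d0 - d0) / d0, 0.25)
  expect_lt(abs(sq$s02 - s02) / s02, 0.10)
  # posterior lies between prior and observed variance
  expect_true(all(sq$postVar >= pmin(s2, sq$s02) - 1e-12))
  expect_true(all(sq$postVar <= pmax(s2, sq$s02) + 1e-12))

  expect_warning(squeezeVariances(rep(1, 5), d = 4), "fewer than")
})

test_that("variance squeezing agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(77)
  s2 <- 0.5 * (rchisq(300, 6) / 6) / (rchisq(300, 10) / 10)
  ours <- squeezeVariances(s2, d = 6)
  ref <- limma::squeezeVar(s2, df = 6)
  expect_equal(ours$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(ours$s02, ref$var.prior, tolerance = 1e-6)
  expect_equal(ours$postVar, ref$var.post, tolerance = 1e-8)
})

test_that("moderated t has the documented limiting behavior", {
  set.seed(21)
  X <- twoGroupDesign(4)
  Y <- matrix(rnorm(80), 10, 8, dimnames = list(paste0("r", 1:10),
                                                rownames(X)))
  Y[1, ] <- rep(c(1, 2, 3, 4), 2)  # balanced row: contrast estimate 0
  fit0 <- eBayesSqueeze(fitLinearModel(Y, X), prior.df = 0)
  expect_equal(unname(fit0@t[1]), 0)
  expect_equal(unname(fit0@p[1]), 1)

  # d0 = 0: identical to the ordinary per-row two-sample t-test
  for (i in 2:10) {
    tt <- t.test(Y[i, 5:8], Y[i, 1:4], var.equal = TRUE)
    expect_equal(unname(fit0@t[i]), unname(tt$statistic), tolerance = 1e-12)
    expect_equal(unname(fit0@p[i]), tt$p.value, tolerance = 1e-12)
  }

  # d0 = Inf with pooled variance: t = estimate/(s0*se), normal p
  fitInf <- eBayesSqueeze(fitLinearModel(Y, X), prior.df = Inf)
  s0 <- sqrt(fitInf@priorVar)
  expect_equal(fitInf@t, fitInf@logFC / (s0 * fitInf@stdevUnscaled))
  expect_equal(fitInf@p, 2 * pnorm(-abs(fitInf@t)))
})

test_that("moderated pipeline matches limma end to end", {
  skip_if_not_installed("limma")
  set.seed(33)
  X <- twoGroupDesign(5)
  Y <- matrix(rnorm(500, sd = rep(runif(50, 0.5, 2), 10)), 50, 10,
              dimnames = list(paste0("r", 1:50), rownames(X)))
  Y[1:10, 6:10] <- Y[1:10, 6:10] + 1
  ours <- eBayesSqueeze(fitLinearModel(Y, X))
  ref <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(unname(ours@t), unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(ours@p), unname(ref$p.value[, 2]), tolerance = 1e-8)
  expect_equal(ours@priorDf, ref$df.prior, tolerance = 1e-6)
})

test_that("BH adjustment matches p.adjust and rejects bad input", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("significance classification applies all three thresholds with reasons", {
  res <- data.frame(adj_p = c(0.005, 0.005, 0.02, 0.005),
                    logFC = c(0.6, 0.6, 0.6, 0.3),
                    mif = c(0.10, 0.01, 0.10, 0.10))
  out <- classifyPairs(res)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$reason, c("", "MIF", "adj_p", "logFC"))
})

test_that("swapping pair orientation negates logFC and t, leaves p and MIF", {
  set.seed(55)
  raw <- matrix(10^runif(120, 2, 5), 30, 4,
                dimnames = list(sprintf("P%02d", 1:30), paste0("s", 1:4)))
  pq <- glogNormalize(ProteinQuant(raw))
  gl <- glogAssay(pq)
  X <- twoGroupDesign(2)
  rownames(X) <- paste0("s", 1:4)
  fwd <- gl["P01", ] - gl["P02", ]
  rev <- gl["P02", ] - gl["P01", ]
  ff <- eBayesSqueeze(fitLinearModel(rbind(fwd, rev,
                                           gl[3:30, ] - gl[c(30, 3:29), ]),
                                     X), prior.df = 0)
  expect_equal(ff@logFC[1], -ff@logFC[2])
  expect_equal(ff@t[1], -ff@t[2])
  expect_equal(ff@p[1], ff@p[2])
})

test_that("ratio tests detect reciprocal shifts invisible to single-protein DE", {
  # pair members shift by -/+0.3 glog units (below the 0.5 single-protein
  # cutoff) while their ratio shifts by 0.6; a pair moving +1 together is
  # DE per protein but null as a ratio
  set.seed(88)
  n_bg <- 200; npc <- 5
  samples <- sprintf("s%02d", 1:(2 * npc))
  cond2 <- rep(c(0, 1), each = npc)
  mk <- function(base_log2, shift) {
    2^(base_log2 + shift * cond2 + rnorm(2 * npc, sd = 0.05))
  }
  raw <- rbind(
    RA = mk(10, -0.3), RB = mk(10, +0.3),    # reciprocal: ratio shift 0.6
    CA = mk(10, +1),  CB = mk(10, +1),       # common shift: ratio null
    matrix(2^(matrix(runif(n_bg, 8, 12), n_bg, 2 * npc) +
                rnorm(n_bg * 2 * npc, sd = 0.05)),
           n_bg, 2 * npc, dimnames = list(sprintf("BG%02d", 1:n_bg), NULL)))
  colnames(raw) <- samples
  pq <- glogNormalize(ProteinQuant(raw))
  X <- designMatrix(data.frame(sample = samples,
                               condition = rep(c("a", "b"), each = npc)),
                    "~ condition")
  pairs <- IsoformPairs(c("RA", "CA"), c("RB", "CB"))
  # two pairs only: the documented unmoderated fallback is expected
  tt <- suppressWarnings(ratioTest(pq, pairs, X))
  de <- singleProteinDE(pq, X, pair_results = tt$results)

  res <- tt$results
  expect_true(res$significant[res$pair_id == "RA|RB"])
  expect_false(res$significant[res$pair_id == "CA|CB"])
  prot <- de$proteins
  expect_false(any(prot$de[prot$accession %in% c("RA", "RB")]))
  expect_true(all(prot$de[prot$accession %in% c("CA", "CB")]))
  # the significant pair has zero individually-DE members
  expect_equal(unname(de$crosstab["0"]), 1)
  # constant protein is never DE
  expect_false(prot$de[prot$accession == "BG01"][1])
})

test_that("a global per-sample loading shift leaves every ratio test unchanged", {
  bench <- runBenchmark(syntheticConfig(n_background = 100L, n_groups = 20L,
                                        n_shifted = 10L, seed = 31))
  pq2 <- bench$pq
  gl <- SummarizedExperiment::assay(pq2, "glog")
  shift <- seq_len(ncol(gl))  # arbitrary per-sample constants
  SummarizedExperiment::assay(pq2, "glog", withDimnames = FALSE) <-
    sweep(gl, 2, shift, "+")
  tt2 <- ratioTest(pq2, bench$pairs, bench$design)
  expect_equal(tt2$results$logFC, bench$test$results$logFC,
               tolerance = 1e-10)
  expect_equal(tt2$results$t, bench$test$results$t, tolerance = 1e-10)
  expect_equal(tt2$results$p, bench$test$results$p, tolerance = 1e-10)
})
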