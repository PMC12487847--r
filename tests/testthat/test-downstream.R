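test_that("group proportions sum to one and renormalize over missing members", {
  raw <- rbind(A = c(2, 4, 70, 70), B = c(1, 2, 30, NA),
               C = c(1, 2, NA, 30))
  colnames(raw) <- paste0("s", 1:4)
  pq <- ProteinQuant(raw)
  gp <- groupProportions(pq, c("A", "B", "C"),
                         condition = c("x", "x", "y", "y"))
  expect_equal(unname(gp$proportions[, "s1"]), c(0.50, 0.25, 0.25))
  expect_equal(unname(colSums(gp$proportions, na.rm = TRUE)),
               rep(1, ncol(gp$proportions)), tolerance = 1e-9)
  expect_true(all(gp$renormalized[c("s3", "s4")]))
  # 70:30 two-member proportion consistent with the MIF definition
  expect_equal(unname(gp$proportions["B", "s3"]), 0.3)

  # degenerate sample skipped with warning
  raw2 <- raw; raw2[, 2] <- c(5, NA, NA)
  expect_warning(groupProportions(ProteinQuant(raw2), c("A", "B", "C")),
                 "skipped")
  expect_error(groupProportions(pq, "A"), ">= 2")
})

test_that("proportion shifts translate to relative-abundance fold changes", {
  expect_equal(proportionFoldChange(c(0.60, 0.40),
                                    c(0.40, 0.60))$fold_change, 2.25)
  expect_gt(proportionFoldChange(c(0.60, 0.40),
                                 c(0.40, 0.60))$fold_change, 2)
  expect_equal(proportionFoldChange(c(0.5, 0.5), c(0.5, 0.5))$fold_change, 1)
  expect_equal(proportionFoldChange(c(0.70, 0.30),
                                    c(0.30, 0.70))$fold_change, 49 / 9)
  expect_warning(out <- proportionFoldChange(c(0, 1), c(0.5, 0.5)),
                 "infinite")
  expect_true(out$infinite)
  # symmetry identity: (a,b)->(b,a) gives (a/b)^2
  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, 0.05, 0.95)
    fc <- proportionFoldChange(c(a, 1 - a), c(1 - a, a))$fold_change
    r <- (a / (1 - a))^2
    expect_equal(fc, max(r, 1 / r), tolerance = 1e-12)
  }
})

test_that("reversal screen keeps codirectional pairs at the relaxed disease FDR", {
  fet <- data.frame(pair_id = c("p1", "p2", "p3", "p4", "p5"),
                    logFC = c(1.2, 1.0, -0.8, 0.9, 2.0),
                    adj_p = rep(0.001, 5),
                    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  dis <- data.frame(pair_id = c("p1", "p2", "p3", "p4", "p5"),
                    logFC = c(0.3, -0.3, -0.2, 0.5, 1.9),
                    adj_p = c(0.04, 0.04, 0.09, 0.20, 0.01))
  out <- reversalAnalysis(fet, dis)
  # p1: codirectional, sig both -> kept, amplitude 0.25
  # p2: opposite direction -> dropped; p3: codirectional kept
  # p4: disease adjP 0.2 > 0.1 -> dropped; p5: not fetal-significant
  expect_identical(out$pair_id, c("p1", "p3"))
  expect_equal(out$amplitude_ratio, c(0.25, 0.25))
  expect_true(all(out$codirectional))

  # invariance to input row order
  out2 <- reversalAnalysis(fet[sample(5), ], dis[sample(5), ])
  expect_identical(out, out2)

  expect_warning(reversalAnalysis(fet, data.frame(pair_id = "zz",
                                                  logFC = 1, adj_p = 0.5)),
                 "no shared")
})

test_that("Fisher exact 2x2 matches enumeration and the stats reference", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  ext <- fisherExact2x2(matrix(c(0, 10, 10, 0), 2))
  expect_equal(ext$p, oracleFisher(0, 10, 10, 0))
  deg <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  # random tables vs enumeration oracle and fisher.test
  set.seed(6)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 6), 2)
    got <- fisherExact2x2(tab)
    expect_equal(got$p, oracleFisher(tab[1, 1], tab[1, 2],
                                     tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(got$p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("conservation enrichment detects depleted differential usage in ancient pairs", {
  set.seed(19)
  n <- 400
  ancient <- rep(c(TRUE, FALSE), each = n / 2)
  # ancient pairs differentially used at half the rate of recent ones
  de <- ifelse(ancient, runif(n) < 0.15, runif(n) < 0.30)
  pairs <- data.frame(ancestry_class = ifelse(ancient, "ancient", "recent"))
  enr <- conservationEnrichment(pairs, de)
  expect_identical(enr$category, "ancient_family")
  expect_lt(enr$odds_ratio, 1)
  expect_lt(enr$p, 0.05)
  # counts margin-consistent
  expect_equal(enr$de_in + enr$de_out + enr$not_de_in + enr$not_de_out, n)

  # single-category input skipped with warning
  expect_warning(
    out <- conservationEnrichment(
      data.frame(ancestry_class = rep("ancient", 10)), rep(TRUE, 10)),
    "empty level")
  expect_null(out)
})

test_that("null calibration: enrichment p-values are uniform when DE is independent", {
  set.seed(29)
  ps <- replicate(200, {
    anc <- sample(c("ancient", "recent"), 60, replace = TRUE)
    de <- runif(60) < 0.3
    suppressWarnings(
      conservationEnrichment(data.frame(ancestry_class = anc), de)$p)
  })
  ps <- unlist(Filter(Negate(is.null), ps))
  # exact-test p-values are conservative under the null; no excess of
  # small p beyond alpha
  expect_lt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("identity-vs-differential-usage t-test matches the closed form", {
  set.seed(41)
  x <- rnorm(50, 70, 5); y <- rnorm(50, 60, 5)
  got <- identityVsDeTest(c(x, y), c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_lt(got$p.value, 1e-6)
  # Welch statistic closed form
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / 50 + var(y) / 50)
  expect_equal(unname(got$statistic), tw)
  expect_error(identityVsDeTest(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "2 observations")
})

test_that("PCA separates duplicated sample groups and reconstructs the matrix", {
  set.seed(47)
  base1 <- rnorm(40); base2 <- base1 + rnorm(40, sd = 2)
  m <- cbind(a1 = base1, a2 = base1 + rnorm(40, sd = 0.05),
             b1 = base2, b2 = base2 + rnorm(40, sd = 0.05))
  pc <- pcaScores(m, 2)
  expect_true(sign(mean(pc$scores[c("a1", "a2"), 1])) !=
                sign(mean(pc$scores[c("b1", "b2"), 1])))
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)

  # reconstruction oracle on a 5x4 toy with all components kept
  toy <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  full <- prcomp(t(toy), center = TRUE)
  recon <- full$x %*% t(full$rotation) +
    matrix(full$center, 4, 5, byrow = TRUE)
  expect_equal(unname(t(recon)), unname(toy), tolerance = 1e-12)
  sc <- pcaScores(toy, n_components = 3)
  expect_equal(unname(sc$scores), unname(full$x[, 1:3]))

  expect_error(pcaScores(toy[1:2, ], 3), "fewer complete rows")
})
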