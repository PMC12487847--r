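# Shared in-code fixtures for the test suite.

# A tiny two-protein, four-sample quant object with known raw values.
tinyQuant <- function(values = NULL, samples = paste0("s", 1:4)) {
  if (is.null(values))
    values <- rbind(A = c(200, 220, 400, 440),
                    B = c(100, 110, 100, 110))
  colnames(values) <- samples
  ProteinQuant(values)
}

# Two-group design matrix: first half reference, second half treatment.
twoGroupDesign <- function(n_per_group, labels = c("ctl", "trt")) {
  samples <- sprintf("s%02d", seq_len(2 * n_per_group))
  tab <- data.frame(sample = samples,
                    condition = rep(labels, each = n_per_group))
  designMatrix(tab, "~ condition")
}

# Independent brute-force digestion oracle: scan the sequence position by
# position, cleaving after K/R unless the next residue is P.
oracleDigest <- function(s) {
  chars <- strsplit(s, "")[[1]]
  frags <- character(0)
  cur <- ""
  for (i in seq_along(chars)) {
    cur <- paste0(cur, chars[i])
    is_site <- chars[i] %in% c("K", "R") &&
      (i == length(chars) || chars[i + 1] != "P")
    if (is_site) {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  if (nzchar(cur)) frags <- c(frags, cur)
  frags
}

# Exhaustive-enumeration Fisher oracle: hypergeometric pmf via choose(),
# probability-mass ordering with the conventional relative tolerance.
oracleFisher <- function(a, b, c_, d_) {
  m <- a + b; n <- c_ + d_; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || (b + d_) == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  tot <- choose(m + n, k)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / tot, numeric(1))
  pobs <- choose(m, a) * choose(n, k - a) / tot
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Brute-force BH step-up oracle applied literally to the definition.
oracleBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  sorted <- p[ord]
  for (k in seq_len(n)) {
    adj[k] <- min(1, min(sorted[k:n] * n / (k:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# End-to-end helper: simulate -> quantify -> glog -> pairs -> ratio test.
runBenchmark <- function(config, prior.df = NULL, fdr = 0.01,
                         min_abs_lfc = 0.5, min_mif = 0.05) {
  sim <- simulateDataset(config)
  pq <- proteinAbsoluteQuant(sim$psms, sim$fasta_map,
                             samples = sim$design$sample,
                             colData = sim$design)
  if (any(sim$truth$missing_mask))
    pq <- applyMissingness(pq, sim$truth$missing_mask)
  pq <- glogNormalize(pq)
  gm <- geneMap(sim$fasta_map)
  ret <- filterParalogPairs(sim$homology, unique(gm[rownames(pq)]))
  groups <- buildGroups(ret, split(names(gm), gm))
  pairs <- enumeratePairs(groups)
  X <- designMatrix(sim$design, "~ condition")
  tt <- ratioTest(pq, pairs, X, prior.df = prior.df, fdr = fdr,
                  min_abs_lfc = min_abs_lfc, min_mif = min_mif)
  list(sim = sim, pq = pq, pairs = pairs, design = X, test = tt)
}
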