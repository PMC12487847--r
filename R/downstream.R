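#' Proportion of protein molecules within an isoform group
#'
#' Per sample, each member's raw abundance divided by the group total;
#' condition means and the SEM across biological replicates of the
#' cumulative (stacked) proportions, the error bars of stacked proportion
#' plots. Samples where fewer than two members are quantified (or the
#' group total is zero) are skipped with a warning; when a member is
#' missing in a sample, that sample's vector is renormalized over the
#' remaining members and flagged.
#'
#' @param pq a \linkS4class{ProteinQuant} (raw abundances used).
#' @param accessions group member accessions (>= 2).
#' @param condition factor/character of per-sample conditions (aligned to
#'   samples); NULL for a single pooled condition.
#' @param group_id label carried into the output.
#' @return list with \code{proportions} (members x samples matrix, columns
#'   summing to 1), \code{condition_means}, \code{sem_cumulative} (members
#'   x conditions), \code{renormalized} (logical per sample) and a tidy
#'   \code{table} (group_id, accession, condition, mean_proportion,
#'   sem_cumulative).
#' @examples
#' m <- matrix(c(2, 1, 1, 2, 1, 1), 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' groupProportions(ProteinQuant(m), c("A", "B", "C"))$proportions
#' @export
groupProportions <- function(pq, accessions, condition = NULL,
                             group_id = NA_character_) {
  if (length(accessions) < 2L) stop("a group needs >= 2 members")
  raw <- abundance(pq)
  missing_acc <- setdiff(accessions, rownames(raw))
  if (length(missing_acc))
    stop("accessions absent from matrix: ",
         paste(missing_acc, collapse = ", "))
  m <- raw[accessions, , drop = FALSE]
  tot <- colSums(m, na.rm = TRUE)
  n_quant <- colSums(!is.na(m))
  usable <- n_quant >= 2L & tot > 0
  if (any(!usable))
    warning("samples skipped (fewer than 2 quantified members or zero ",
            "total): ", paste(colnames(m)[!usable], collapse = ", "))
  prop <- sweep(m[, usable, drop = FALSE], 2, tot[usable], "/")
  renorm <- colSums(is.na(prop)) > 0
  prop[is.na(prop)] <- NA_real_

  if (is.null(condition)) condition <- rep("all", ncol(raw))
  condition <- as.character(condition)[usable]
  conds <- unique(condition)
  k <- length(accessions)
  cmean <- matrix(NA_real_, k, length(conds),
                  dimnames = list(accessions, conds))
  csem <- matrix(NA_real_, k, length(conds),
                 dimnames = list(accessions, conds))
  for (cn in conds) {
    sub <- prop[, condition == cn, drop = FALSE]
    cmean[, cn] <- rowMeans(sub, na.rm = TRUE)
    # cumulative stacked sums per sample, SEM across replicates
    cum <- apply(sub, 2, function(x) cumsum(ifelse(is.na(x), 0, x)))
    csem[, cn] <- apply(cum, 1, function(x)
      stats::sd(x) / sqrt(sum(!is.na(x))))
  }
  tab <- data.frame(
    group_id = group_id,
    accession = rep(accessions, times = length(conds)),
    condition = rep(conds, each = k),
    mean_proportion = as.vector(cmean),
    sem_cumulative = as.vector(csem),
    stringsAsFactors = FALSE)
  list(proportions = prop, condition_means = cmean,
       sem_cumulative = csem, renormalized = renorm, table = tab)
}

#' Fold change of relative abundance implied by a proportion shift
#'
#' For a two-member group moving from proportions \code{(a1, b1)} to
#' \code{(a2, b2)}, the ratio-of-ratios \code{(a1/b1) / (a2/b2)}, oriented
#' to be >= 1 with the direction reported separately. Even a modest
#' 60:40 to 40:60 shift already implies a 2.25-fold change in the two
#' proteins' relative abundance.
#'
#' @param p_before,p_after numeric length-2 proportion vectors, entries in
#'   (0, 1).
#' @return list with \code{fold_change} (>= 1; Inf flagged when a
#'   proportion is 0), \code{direction} ("toward_first", "toward_second"
#'   or "none") and \code{infinite} flag.
#' @examples
#' proportionFoldChange(c(0.6, 0.4), c(0.4, 0.6))$fold_change  # 2.25
#' @export
proportionFoldChange <- function(p_before, p_after) {
  if (length(p_before) != 2L || length(p_after) != 2L)
    stop("p_before and p_after must each have two proportions")
  pr <- c(p_before, p_after)
  if (any(pr < 0 | pr > 1)) stop("proportions must be in [0, 1]")
  if (any(pr == 0)) {
    warning("zero proportion: fold change is infinite")
    return(list(fold_change = Inf, direction = NA_character_,
                infinite = TRUE))
  }
  r1 <- p_before[1] / p_before[2]
  r2 <- p_after[1] / p_after[2]
  fc <- r1 / r2
  dir <- if (fc > 1) "toward_second" else if (fc < 1) "toward_first"
         else "none"
  list(fold_change = max(fc, 1 / fc), direction = dir, infinite = FALSE)
}

#' Screen for co-directional (fetal-like) isoform shifts in disease
#'
#' Retains isoform pairs that are significant in the fetal/postnatal
#' comparison (at the strict thresholds already flagged in
#' \code{fetal_results$significant}), reach the relaxed disease FDR
#' (default adjusted p <= 0.1), and shift in the same direction in disease
#' as in fetal hearts regardless of magnitude. The amplitude ratio
#' |disease logFC| / |fetal logFC| measures how complete the reversion
#' toward the fetal program is (< 1 = partial reversal).
#'
#' @param fetal_results,disease_results ratio-test results data.frames
#'   (\code{\link{ratioTest}}) sharing pair ids, with the same pair
#'   orientation.
#' @param disease_fdr adjusted-p threshold for the disease contrast
#'   (default 0.1).
#' @return data.frame of ReversalRecords: pair_id, fetal/disease logFC and
#'   adj_p, codirectional flag, amplitude_ratio; rows sorted by pair_id so
#'   the output is invariant to input row order.
#' @export
reversalAnalysis <- function(fetal_results, disease_results,
                             disease_fdr = 0.1) {
  shared <- intersect(fetal_results$pair_id, disease_results$pair_id)
  if (!length(shared)) {
    warning("no shared pair ids between result sets")
    return(data.frame(pair_id = character(0), fetal_logFC = numeric(0),
                      fetal_adj_p = numeric(0), disease_logFC = numeric(0),
                      disease_adj_p = numeric(0), codirectional = logical(0),
                      amplitude_ratio = numeric(0)))
  }
  shared <- sort(shared, method = "radix")
  f <- fetal_results[match(shared, fetal_results$pair_id), ]
  d <- disease_results[match(shared, disease_results$pair_id), ]
  rec <- data.frame(pair_id = shared,
                    fetal_logFC = f$logFC,
                    fetal_adj_p = f$adj_p,
                    disease_logFC = d$logFC,
                    disease_adj_p = d$adj_p,
                    codirectional = sign(f$logFC) == sign(d$logFC),
                    amplitude_ratio = abs(d$logFC) / abs(f$logFC),
                    stringsAsFactors = FALSE)
  keep <- f$significant & !is.na(d$adj_p) & d$adj_p <= disease_fdr &
    rec$codirectional
  rec <- rec[keep & !is.na(keep), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by probability-mass ordering: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's (within the
#' conventional (1 + 1e-7) relative tolerance). The odds ratio reported is
#' the sample (unconditional) odds ratio \code{(a d)/(b c)}. A zero row or
#' column margin makes the table degenerate: p = 1, odds ratio undefined.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return list with \code{odds_ratio}, \code{p}, \code{degenerate}.
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))  # p = 1
#' @export
fisherExact2x2 <- function(table) {
  x <- if (is.matrix(table)) table else matrix(table, 2, byrow = TRUE)
  if (!all(dim(x) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  a <- x[1, 1]; b <- x[1, 2]; cc <- x[2, 1]; dd <- x[2, 2]
  m <- a + b          # row-1 margin
  n <- cc + dd        # row-2 margin
  k <- a + cc         # column-1 margin
  if (m == 0 || n == 0 || k == 0 || (b + dd) == 0)
    return(list(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  dobs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= dobs * (1 + 1e-7)])
  or <- (a * dd) / (b * cc)
  list(odds_ratio = or, p = min(p, 1), degenerate = FALSE)
}

#' Ancestry / conservation enrichment among differentially used pairs
#'
#' For each binary categorization scheme of the pairs, builds the 2x2
#' table (significant vs not) x (in category vs not) and applies
#' \code{\link{fisherExact2x2}}. Built-in schemes: deep-clade
#' (ancient-vs-recent ancestry) membership; any extra logical columns in
#' \code{categories}.
#'
#' @param pairs an \linkS4class{IsoformPairs} (or data.frame with
#'   \code{ancestry_class}).
#' @param de_flags logical vector: pair differentially used (significant).
#' @param categories optional named list of logical vectors (extra binary
#'   categorizations, e.g. an Ensembl paralog-type split).
#' @return data.frame: category, counts a/b/c/d (DE&cat, DE&!cat, !DE&cat,
#'   !DE&!cat), odds_ratio, p. Categories with an empty level are skipped
#'   with a warning.
#' @export
conservationEnrichment <- function(pairs, de_flags, categories = NULL) {
  schemes <- list()
  anc <- pairs$ancestry_class
  cls <- !is.na(anc) & anc != "unclassified"
  if (any(cls))
    schemes$ancient_family <- ifelse(cls, anc == "ancient", NA)
  if (!is.null(categories)) schemes <- c(schemes, categories)
  out <- list()
  for (nm in names(schemes)) {
    cat_flag <- schemes[[nm]]
    ok <- !is.na(cat_flag) & !is.na(de_flags)
    cf <- cat_flag[ok]; de <- de_flags[ok]
    if (!any(cf) || all(cf)) {
      warning("category ", sQuote(nm), " has an empty level; skipped")
      next
    }
    tab <- matrix(c(sum(de & cf), sum(de & !cf),
                    sum(!de & cf), sum(!de & !cf)), 2, byrow = TRUE)
    ft <- fisherExact2x2(tab)
    out[[nm]] <- data.frame(category = nm,
                            de_in = tab[1, 1], de_out = tab[1, 2],
                            not_de_in = tab[2, 1], not_de_out = tab[2, 2],
                            odds_ratio = ft$odds_ratio, p = ft$p,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sequence identity vs differential usage
#'
#' Two-sided two-sample t-test (Welch by default) comparing mean pairwise
#' sequence identity between differentially used and unchanged pairs.
#'
#' @param mean_identities numeric percent identities.
#' @param de_flags logical differential-usage flags.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return \code{htest} object from \code{stats::t.test}.
#' @export
identityVsDeTest <- function(mean_identities, de_flags, var_equal = FALSE) {
  ok <- !is.na(mean_identities) & !is.na(de_flags)
  x <- mean_identities[ok][de_flags[ok]]
  y <- mean_identities[ok][!de_flags[ok]]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 observations per class")
  stats::t.test(x, y, var.equal = var_equal)
}

#' Principal component scores of a quantification or ratio matrix
#'
#' Rows with any missing value are dropped (count reported); samples are
#' the observations. Centering always; scaling optional (ratio matrices
#' are already on a common scale, so the default is unscaled).
#'
#' @param m numeric matrix features x samples (or a
#'   \linkS4class{ProteinQuant}, in which case the glog assay is used).
#' @param n_components number of components to return.
#' @param scale. scale features to unit variance.
#' @return list with \code{scores} (samples x components),
#'   \code{explained_variance} (fraction per component, non-increasing),
#'   \code{n_rows_used}, \code{n_rows_dropped}.
#' @export
pcaScores <- function(m, n_components = 2L, scale. = FALSE) {
  if (is(m, "ProteinQuant")) m <- glogAssay(m)
  m <- as.matrix(m)
  keep <- stats::complete.cases(m)
  dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (scale.) {
    sds <- apply(m, 1, stats::sd)
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) < n_components)
    stop("fewer complete rows (", nrow(m), ") than components requested")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  nc <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nc)],
       n_rows_used = nrow(m),
       n_rows_dropped = dropped)
}
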