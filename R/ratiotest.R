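#' Pairwise generalized-log ratio matrix
#'
#' One row per isoform pair, entries \code{glog(a) - glog(b)} per sample;
#' missing wherever either member is missing. Pairs with a member absent
#' from the matrix are dropped with a warning.
#'
#' @param pq a glog-normalized \linkS4class{ProteinQuant}.
#' @param pairs an \linkS4class{IsoformPairs}.
#' @return list with \code{ratios} (matrix, pairs x samples, rownames =
#'   pair ids) and \code{pairs} (the retained \code{IsoformPairs}).
#' @export
computeRatioMatrix <- function(pq, pairs) {
  gl <- glogAssay(pq)
  present <- pairs$accession_a %in% rownames(gl) &
    pairs$accession_b %in% rownames(gl)
  if (any(!present))
    warning(sum(!present), " pair(s) dropped: member absent from matrix")
  pairs <- pairs[present, , drop = FALSE]
  ratios <- gl[pairs$accession_a, , drop = FALSE] -
    gl[pairs$accession_b, , drop = FALSE]
  rownames(ratios) <- pairs$pair_id
  list(ratios = ratios, pairs = pairs)
}

#' Minor isoform fraction
#'
#' Per sample, \code{min(a, b) / (a + b)} on the raw (pre-log) abundance
#' scale; the returned value is the mean over all samples where both
#' members are quantified. Filters out pairs where one isoform is present
#' only at miniscule levels relative to the other.
#'
#' @param pq a \linkS4class{ProteinQuant} (raw abundances used).
#' @param pairs an \linkS4class{IsoformPairs}.
#' @return numeric vector in [0, 0.5] named by pair id; NA (undefined) when
#'   no sample has both members with positive total.
#' @export
computeMif <- function(pq, pairs) {
  raw <- abundance(pq)
  a <- raw[pairs$accession_a, , drop = FALSE]
  b <- raw[pairs$accession_b, , drop = FALSE]
  tot <- a + b
  frac <- pmin(a, b) / tot
  frac[!is.na(tot) & tot == 0] <- NA_real_
  out <- rowMeans(frac, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  stats::setNames(out, pairs$pair_id)
}

#' Build a design matrix from a sample table and formula
#'
#' Main-effects-only R-style formula (e.g. \code{~ age} or
#' \code{~ treatment + age + block}) applied to the design table with
#' treatment coding; the reference level of each factor is its first level
#' in the table (order of first appearance unless already a factor).
#'
#' @param design_table data.frame with one row per sample; a \code{sample}
#'   column (if present) provides row names.
#' @param formula model formula or string.
#' @return design matrix with rownames = samples.
#' @export
designMatrix <- function(design_table, formula) {
  dt <- as.data.frame(design_table)
  if ("sample" %in% names(dt)) {
    rownames(dt) <- dt$sample
  }
  f <- stats::as.formula(formula)
  vars <- all.vars(f)
  missing <- setdiff(vars, names(dt))
  if (length(missing))
    stop("design table lacks factor column(s): ",
         paste(missing, collapse = ", "))
  for (v in vars)
    if (!is.numeric(dt[[v]]) && !is.factor(dt[[v]]))
      dt[[v]] <- factor(dt[[v]], levels = unique(dt[[v]]))
  X <- stats::model.matrix(f, data = dt)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Row-wise ordinary least squares
#'
#' Fits the same linear model to every row of \code{Y} (a ratio matrix or
#' glog abundance matrix), complete-case per row: rows are fit on their
#' non-missing samples. Rows with residual degrees of freedom below 1 (or
#' a design that loses full rank after removing missing samples) are
#' flagged untestable (all-NA statistics).
#'
#' @param Y numeric matrix, features x samples.
#' @param design design matrix from \code{\link{designMatrix}} (columns =
#'   coefficients, rows = samples, matching \code{colnames(Y)}).
#' @param contrast name of the coefficient to test; default the last
#'   column.
#' @return a \linkS4class{RatioFit} (moderation slots empty until
#'   \code{\link{eBayesSqueeze}}).
#' @export
fitLinearModel <- function(Y, design, contrast = NULL) {
  Y <- as.matrix(Y)
  if (!is.null(colnames(Y)) && !is.null(rownames(design))) {
    if (!all(colnames(Y) %in% rownames(design)))
      stop("samples in Y missing from design: ",
           paste(setdiff(colnames(Y), rownames(design)), collapse = ", "))
    design <- design[colnames(Y), , drop = FALSE]
  }
  if (nrow(design) != ncol(Y))
    stop("design rows must match Y columns")
  if (is.null(contrast)) contrast <- colnames(design)[ncol(design)]
  if (!contrast %in% colnames(design))
    stop("contrast ", sQuote(contrast), " is not a design coefficient")
  p <- ncol(design)
  n <- nrow(Y)
  coefs <- matrix(NA_real_, n, p, dimnames = list(rownames(Y),
                                                  colnames(design)))
  se_uns <- rep(NA_real_, n)
  s2 <- rep(NA_real_, n)
  df <- rep(0, n)

  obs <- !is.na(Y)
  full <- rowSums(obs) == ncol(Y)
  ci <- match(contrast, colnames(design))

  fit_block <- function(idx, cols) {
    X <- design[cols, , drop = FALSE]
    if (qr(X)$rank < p || (length(cols) - p) < 1) return(invisible(NULL))
    fit <- stats::lm.fit(X, t(Y[idx, cols, drop = FALSE]))
    res <- as.matrix(fit$residuals)
    dfr <- length(cols) - p
    xtxi <- solve(crossprod(X))
    coefs[idx, ] <<- t(as.matrix(fit$coefficients))
    s2[idx] <<- colSums(res^2) / dfr
    df[idx] <<- dfr
    se_uns[idx] <<- sqrt(xtxi[ci, ci])
    invisible(NULL)
  }

  if (any(full)) fit_block(which(full), seq_len(ncol(Y)))
  partial <- which(!full)
  if (length(partial)) {
    pat <- apply(obs[partial, , drop = FALSE], 1, paste, collapse = "")
    for (pp in unique(pat)) {
      idx <- partial[pat == pp]
      cols <- which(strsplit(pp, "")[[1]] == "TRUE")
      fit_block(idx, cols)
    }
  }

  new("RatioFit",
      coefficients = coefs,
      stdevUnscaled = se_uns,
      sigma2 = s2,
      df = df,
      contrast = contrast,
      logFC = unname(coefs[, ci]),
      priorDf = NA_real_,
      priorVar = NA_real_,
      postVar = numeric(0),
      t = rep(NA_real_, n),
      p = rep(NA_real_, n),
      design = design)
}

#' Invert the trigamma function
#'
#' Monotone Newton iteration solving \code{trigamma(x) = y} for \code{x >
#' 0}, started from the asymptotic approximation \code{1/y}; tolerance
#' 1e-8 on the step, at most 50 iterations. Non-convergence returns
#' \code{Inf} with a warning (no excess dispersion detectable).
#'
#' @param y positive target value(s).
#' @return x with \code{trigamma(x) = y}.
#' @keywords internal
trigammaInverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))   # trigamma(x) ~ 1/x^2 for small x
    if (yy < 1e-6) return(1 / yy)        # trigamma(x) ~ 1/x for large x
    x <- 0.5 + 1 / yy
    for (i in seq_len(50L)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
      x <- x + dif
      if (x <= 0) x <- 1e-8
      if (abs(dif) < 1e-8 * x) return(x)
    }
    warning("trigamma inversion did not converge; returning Inf")
    Inf
  }, numeric(1))
}

#' Empirical-Bayes squeezing of row-wise variances
#'
#' Moment estimation of the scaled inverse-chi-squared prior on residual
#' variances: with \eqn{z_g = \log s_g^2}, the mean and excess variance of
#' \eqn{z_g - \psi(d_g/2) - \log(2/d_g)} identify the prior degrees of
#' freedom \eqn{d_0} (through a trigamma inversion) and the prior variance
#' \eqn{s_0^2}. Posterior variances are
#' \eqn{(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}; \eqn{d_0 = \infty} collapses
#' every posterior to \eqn{s_0^2}, \eqn{d_0 = 0} leaves variances
#' unmoderated.
#'
#' @param s2 numeric vector of residual variances (NA allowed).
#' @param d residual degrees of freedom (vector or scalar).
#' @param min_rows minimum finite variances required for moderation
#'   (default 20); below it, the unmoderated fallback \code{d0 = 0} is
#'   returned with a warning.
#' @return list with \code{d0}, \code{s02}, \code{postVar}.
#' @export
squeezeVariances <- function(s2, d, min_rows = 20L) {
  d <- rep_len(d, length(s2))
  ok <- is.finite(s2) & s2 > 0 & d >= 1
  if (sum(ok) < min_rows) {
    warning("fewer than ", min_rows,
            " usable variances; falling back to unmoderated test (d0 = 0)")
    return(list(d0 = 0, s02 = NA_real_, postVar = s2))
  }
  z <- log(s2[ok])
  e <- z - digamma(d[ok] / 2) + log(d[ok] / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L)
  evar_excess <- evar - mean(trigamma(d[ok] / 2))
  if (is.finite(evar_excess) && evar_excess > 0) {
    d0 <- 2 * trigammaInverse(evar_excess)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  postVar <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  postVar[!is.finite(s2)] <- NA_real_
  list(d0 = d0, s02 = s02, postVar = postVar)
}

#' Apply empirical-Bayes moderation and compute moderated t statistics
#'
#' Squeezes the fit's residual variances toward the estimated prior
#' (\code{\link{squeezeVariances}}) and computes per-row moderated
#' \eqn{t = \hat\beta / (\tilde s \, u)} with \eqn{d_0 + d_g} degrees of
#' freedom and two-sided p-values (standard normal when the total df is
#' infinite). \code{prior.df} overrides the estimated \eqn{d_0}: 0 gives
#' the ordinary row-wise t-test, \code{Inf} fully pooled variances.
#'
#' @param fit a \linkS4class{RatioFit} from \code{\link{fitLinearModel}}.
#' @param prior.df optional fixed prior degrees of freedom.
#' @param min_rows passed to \code{\link{squeezeVariances}}.
#' @return the fit with moderation slots, \code{t} and \code{p} filled.
#' @export
eBayesSqueeze <- function(fit, prior.df = NULL, min_rows = 20L) {
  s2 <- fit@sigma2
  d <- fit@df
  if (is.null(prior.df)) {
    sq <- squeezeVariances(s2, d, min_rows = min_rows)
  } else if (prior.df == 0) {
    sq <- list(d0 = 0, s02 = NA_real_, postVar = s2)
  } else if (is.infinite(prior.df)) {
    ok <- is.finite(s2) & d >= 1
    e <- log(s2[ok & s2 > 0]) - digamma(d[ok & s2 > 0] / 2) +
      log(d[ok & s2 > 0] / 2)
    s02 <- exp(mean(e))
    sq <- list(d0 = Inf, s02 = s02, postVar = rep(s02, length(s2)))
  } else {
    sq0 <- squeezeVariances(s2, d, min_rows = min_rows)
    s02 <- if (is.finite(sq0$s02)) sq0$s02 else mean(s2, na.rm = TRUE)
    sq <- list(d0 = prior.df, s02 = s02,
               postVar = (prior.df * s02 + d * s2) / (prior.df + d))
  }
  tstat <- fit@logFC / (sqrt(sq$postVar) * fit@stdevUnscaled)
  tot_df <- sq$d0 + d
  pval <- ifelse(is.infinite(tot_df),
                 2 * stats::pnorm(-abs(tstat)),
                 2 * stats::pt(-abs(tstat), df = tot_df))
  untestable <- d < 1 | !is.finite(fit@stdevUnscaled) |
    fit@stdevUnscaled == 0
  tstat[untestable] <- NA_real_
  pval[untestable] <- NA_real_
  fit@priorDf <- sq$d0
  fit@priorVar <- if (is.null(sq$s02) || is.na(sq$s02)) NA_real_ else sq$s02
  fit@postVar <- sq$postVar
  fit@t <- unname(tstat)
  fit@p <- unname(pval)
  fit
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1, original order
#' restored). NA p-values stay NA and do not enter the ranking.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full moderated ratio test for a set of isoform pairs
#'
#' Convenience wrapper: ratio matrix, complete-case filter, row-wise OLS,
#' empirical-Bayes moderation, BH adjustment, MIF computation and
#' significance classification with the standard thresholds (FDR < 0.01,
#' |logFC| >= 0.5, MIF >= 0.05).
#'
#' @param pq a glog-normalized \linkS4class{ProteinQuant}.
#' @param pairs an \linkS4class{IsoformPairs}.
#' @param design design matrix (\code{\link{designMatrix}}).
#' @param contrast coefficient to test (default last design column).
#' @param fdr,min_abs_lfc,min_mif significance thresholds.
#' @param complete_cases require pairs quantified in every sample (default
#'   TRUE); otherwise rows are fit on available samples.
#' @param prior.df optional fixed prior df (see
#'   \code{\link{eBayesSqueeze}}).
#' @return list with \code{results} (data.frame: pair_id, accession_a/b,
#'   pair_type, logFC, t, p, adj_p, mif, significant, reason), \code{fit}
#'   (the \linkS4class{RatioFit}) and \code{ratios}.
#' @export
ratioTest <- function(pq, pairs, design, contrast = NULL, fdr = 0.01,
                      min_abs_lfc = 0.5, min_mif = 0.05,
                      complete_cases = TRUE, prior.df = NULL) {
  rm_ <- computeRatioMatrix(pq, pairs)
  ratios <- rm_$ratios
  pairs <- rm_$pairs
  if (complete_cases) {
    keep <- stats::complete.cases(ratios)
    ratios <- ratios[keep, , drop = FALSE]
    pairs <- pairs[keep, , drop = FALSE]
  }
  fit <- fitLinearModel(ratios, design, contrast = contrast)
  fit <- eBayesSqueeze(fit, prior.df = prior.df)
  mif <- computeMif(pq, pairs)
  res <- classifyPairs(
    data.frame(pair_id = pairs$pair_id,
               accession_a = pairs$accession_a,
               accession_b = pairs$accession_b,
               pair_type = pairs$pair_type,
               logFC = fit@logFC,
               t = fit@t,
               p = fit@p,
               adj_p = bhAdjust(fit@p),
               mif = unname(mif),
               stringsAsFactors = FALSE),
    fdr = fdr, min_abs_lfc = min_abs_lfc, min_mif = min_mif)
  list(results = res, fit = fit, ratios = ratios, pairs = pairs)
}

#' Classify ratio-test results against the significance thresholds
#'
#' A pair is significant iff adjusted p < \code{fdr} AND |logFC| >=
#' \code{min_abs_lfc} AND MIF >= \code{min_mif}; each failed criterion is
#' recorded in a semicolon-delimited reason code.
#'
#' @param results data.frame with \code{adj_p}, \code{logFC}, \code{mif}.
#' @param fdr,min_abs_lfc,min_mif thresholds (defaults 0.01, 0.5, 0.05).
#' @return the data.frame with \code{significant} and \code{reason} added.
#' @export
classifyPairs <- function(results, fdr = 0.01, min_abs_lfc = 0.5,
                          min_mif = 0.05) {
  fail_p <- is.na(results$adj_p) | results$adj_p >= fdr
  fail_fc <- is.na(results$logFC) | abs(results$logFC) < min_abs_lfc
  fail_mif <- is.na(results$mif) | results$mif < min_mif
  reason <- mapply(function(a, b, c) {
    r <- c(if (a) "adj_p", if (b) "logFC", if (c) "MIF")
    if (length(r)) paste(r, collapse = ";") else ""
  }, fail_p, fail_fc, fail_mif)
  results$significant <- !(fail_p | fail_fc | fail_mif)
  results$reason <- unname(reason)
  results
}

#' Single-protein differential expression with the same moderated pipeline
#'
#' Runs the identical linear-model / empirical-Bayes / BH pipeline on the
#' per-protein glog abundances and, for each isoform pair, cross-tabulates
#' how many members (0, 1 or 2) are individually differentially expressed.
#' Ratio tests can flag pairs in which neither protein passes the
#' single-protein thresholds, because common shifts cancel in the ratio
#' while reciprocal shifts add.
#'
#' @param pq a glog-normalized \linkS4class{ProteinQuant}.
#' @param design design matrix.
#' @param contrast coefficient to test.
#' @param fdr,min_abs_lfc significance thresholds (defaults 0.01, 0.5).
#' @param pair_results optional ratio-test results data.frame to
#'   cross-tabulate against.
#' @param complete_cases as in \code{\link{ratioTest}}.
#' @return list with \code{proteins} (per-protein results incl.
#'   \code{de} flag) and, when \code{pair_results} is given,
#'   \code{pair_de_members} (data.frame pair_id, n_de_members) and
#'   \code{crosstab} (counts of significant pairs with 0/1/2 DE members).
#' @export
singleProteinDE <- function(pq, design, contrast = NULL, fdr = 0.01,
                            min_abs_lfc = 0.5, pair_results = NULL,
                            complete_cases = TRUE) {
  gl <- glogAssay(pq)
  if (complete_cases) gl <- gl[stats::complete.cases(gl), , drop = FALSE]
  fit <- eBayesSqueeze(fitLinearModel(gl, design, contrast = contrast))
  prot <- data.frame(accession = rownames(gl),
                     logFC = fit@logFC,
                     t = fit@t,
                     p = fit@p,
                     adj_p = bhAdjust(fit@p),
                     stringsAsFactors = FALSE)
  prot$de <- !is.na(prot$adj_p) & prot$adj_p < fdr &
    abs(prot$logFC) >= min_abs_lfc
  out <- list(proteins = prot)
  if (!is.null(pair_results)) {
    de_set <- prot$accession[prot$de]
    nde <- (pair_results$accession_a %in% de_set) +
      (pair_results$accession_b %in% de_set)
    out$pair_de_members <- data.frame(pair_id = pair_results$pair_id,
                                      n_de_members = nde)
    sig <- pair_results$significant
    out$crosstab <- table(factor(nde[sig], levels = 0:2))
  }
  out
}
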