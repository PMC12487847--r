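#' Read a PSM-level quantification table
#'
#' Tab-delimited with a mandatory header; required columns \code{peptide},
#' \code{proteins} (semicolon-delimited accessions), \code{ms1_intensity}
#' and one \code{reporter_<channel>} column per TMT channel; an optional
#' \code{run} column identifies the source acquisition.
#'
#' @param path file path.
#' @return a \code{data.table} with list-column \code{accessions} (parsed
#'   from \code{proteins}) and a \code{reporter_*} column per channel.
#' @export
readPsmTable <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  need <- c("peptide", "proteins", "ms1_intensity")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop("PSM table lacks required columns: ",
         paste(missing, collapse = ", "))
  rep_cols <- grep("^reporter_", names(dt), value = TRUE)
  if (!length(rep_cols))
    stop("PSM table has no reporter_<channel> columns")
  if (any(dt$ms1_intensity < 0, na.rm = TRUE))
    stop("negative ms1_intensity values")
  for (cc in rep_cols)
    if (any(dt[[cc]] < 0, na.rm = TRUE))
      stop("negative reporter intensities in ", cc)
  dt$accessions <- strsplit(dt$proteins, ";", fixed = TRUE)
  dt
}

#' Apportion MS1 precursor intensity across reporter channels
#'
#' Splits each PSM's MS1 precursor intensity proportionally to its MS2
#' reporter-ion intensities, producing per-channel composite MS1-MS2
#' quantities that sum exactly to the MS1 intensity. PSMs whose reporter
#' vector is all-zero cannot be apportioned and are flagged unquantifiable
#' (returned as all-NA rows), never silently zeroed.
#'
#' @param ms1_intensity numeric vector (one value per PSM) of non-negative
#'   precursor intensities.
#' @param reporter_intensities numeric matrix, PSMs x channels,
#'   non-negative.
#' @return list with \code{apportioned} (matrix, PSMs x channels; all-NA
#'   rows for unquantifiable PSMs) and \code{unquantifiable} (logical
#'   vector).
#' @examples
#' apportionChannels(1000, matrix(c(3, 1, 0, 0), 1))$apportioned
#' @export
apportionChannels <- function(ms1_intensity, reporter_intensities) {
  rep_mat <- as.matrix(reporter_intensities)
  if (length(ms1_intensity) != nrow(rep_mat))
    stop("ms1_intensity length must equal nrow(reporter_intensities)")
  if (any(ms1_intensity < 0, na.rm = TRUE) ||
      any(rep_mat < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  totals <- rowSums(rep_mat)
  bad <- !is.finite(totals) | totals <= 0 | !is.finite(ms1_intensity)
  out <- rep_mat * (ms1_intensity / totals)
  out[bad, ] <- NA_real_
  list(apportioned = out, unquantifiable = bad)
}

#' Absolute protein quantification from PSM-level composite MS1-MS2 data
#'
#' iBAQ-style estimator: for each protein and channel, the apportioned
#' channel intensities of that protein's isoform-unique PSMs are summed and
#' divided by the protein's theoretical tryptic peptide count
#' (\code{\link{trypticPeptideCount}}). PSMs whose peptide maps to more
#' than one accession are excluded (the only defensible rule when paralogs
#' share upward of 90\% identity); unquantifiable PSMs (all-zero reporters)
#' are excluded and counted. Proteins with no usable PSM in a channel are
#' \code{NA}, not zero.
#'
#' @param psms PSM table from \code{\link{readPsmTable}} (or an equivalent
#'   data.frame with \code{accessions} list-column, \code{ms1_intensity}
#'   and \code{reporter_*} columns).
#' @param fasta_map accession -> sequence map from
#'   \code{\link{readFastaMap}}.
#' @param samples character vector naming the samples in channel order; if
#'   NULL, the \code{reporter_*} suffixes are used.
#' @param min_len,max_len digestion length bounds passed to
#'   \code{\link{trypticPeptideCount}}.
#' @param colData optional per-sample annotation attached to the result.
#' @return a \linkS4class{ProteinQuant}; \code{metadata()$quant_log} records
#'   PSM counts in/out of each filter.
#' @export
proteinAbsoluteQuant <- function(psms, fasta_map, samples = NULL,
                                 min_len = 7L, max_len = 30L,
                                 colData = NULL) {
  psms <- data.table::as.data.table(psms)
  rep_cols <- grep("^reporter_", names(psms), value = TRUE)
  if (is.null(samples)) samples <- sub("^reporter_", "", rep_cols)
  if (length(samples) != length(rep_cols))
    stop("samples length must match the number of reporter columns")
  if (!"accessions" %in% names(psms))
    psms$accessions <- strsplit(psms$proteins, ";", fixed = TRUE)

  n_in <- nrow(psms)
  n_acc <- lengths(psms$accessions)
  unique_map <- n_acc == 1L
  app <- apportionChannels(psms$ms1_intensity,
                           as.matrix(psms[, rep_cols, with = FALSE]))
  usable <- unique_map & !app$unquantifiable
  quant_log <- list(psms_in = n_in,
                    psms_shared_excluded = sum(!unique_map),
                    psms_unquantifiable = sum(app$unquantifiable & unique_map),
                    psms_used = sum(usable))

  acc_used <- vapply(psms$accessions[usable], `[`, character(1), 1L)
  missing_acc <- setdiff(unique(acc_used), names(fasta_map))
  if (length(missing_acc))
    stop("accessions absent from FASTA: ",
         paste(missing_acc, collapse = ", "))

  mat <- app$apportioned[usable, , drop = FALSE]
  summed <- rowsum(mat, group = acc_used, na.rm = TRUE)
  # proteins with zero usable PSMs never appear -> missing, not zero
  counts <- vapply(rownames(summed), function(a)
    trypticPeptideCount(fasta_map[[a]], min_len, max_len), integer(1))
  zero_pep <- counts == 0L
  if (any(zero_pep)) {
    warning("proteins with no in-range tryptic peptide dropped: ",
            paste(rownames(summed)[zero_pep], collapse = ", "))
    summed <- summed[!zero_pep, , drop = FALSE]
    counts <- counts[!zero_pep]
  }
  values <- summed / counts
  colnames(values) <- samples
  pq <- ProteinQuant(values, colData = colData)
  metadata(pq)$quant_log <- quant_log
  pq
}

#' Write / read a protein quantification matrix
#'
#' Tab-delimited, rows = accessions (first column \code{accession}),
#' columns = samples, missing encoded as \code{NA}.
#'
#' @param pq a \linkS4class{ProteinQuant}.
#' @param path output file.
#' @param assay which assay to write.
#' @export
writeQuantMatrix <- function(pq, path, assay = "abundance") {
  m <- SummarizedExperiment::assay(pq, assay)
  dt <- data.table::data.table(accession = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname writeQuantMatrix
#' @return \code{readQuantMatrix}: a \linkS4class{ProteinQuant}.
#' @export
readQuantMatrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1L]]
  ProteinQuant(m)
}

#' Sample-sample correlation QC
#'
#' Pearson correlations between sample columns on shared (pairwise
#' non-missing) proteins, optionally after log10 transformation of positive
#' values — the standard agreement check for absolute abundance estimates
#' that span several orders of magnitude.
#'
#' @param pq a \linkS4class{ProteinQuant} or numeric matrix.
#' @param log_scale correlate log10 values (default TRUE); zeros and
#'   negatives are masked.
#' @param min_shared minimum pairwise-complete proteins required for a
#'   correlation (default 3); sparser cells are NA with a warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
qcCorrelation <- function(pq, log_scale = TRUE, min_shared = 3L) {
  m <- if (is(pq, "ProteinQuant")) abundance(pq) else as.matrix(pq)
  if (log_scale) {
    m[m <= 0] <- NA_real_
    m <- log10(m)
  }
  ns <- ncol(m)
  r <- matrix(NA_real_, ns, ns, dimnames = list(colnames(m), colnames(m)))
  diag(r) <- 1
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) < min_shared) {
      warning(sprintf("samples %s/%s share only %d proteins; correlation NA",
                      colnames(m)[i], colnames(m)[j], sum(ok)))
      next
    }
    r[i, j] <- r[j, i] <- stats::cor(m[ok, i], m[ok, j])
  }
  r
}
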