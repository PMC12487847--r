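#' @import methods
#' @importFrom data.table data.table as.data.table fread fwrite
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<-
NULL

#' ProteinQuant: absolute protein abundance estimates per sample
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' proteins-by-samples matrix of absolute abundance estimates on a common
#' (arbitrary) intensity scale in the \code{"abundance"} assay. After
#' \code{\link{glogNormalize}} a second assay \code{"glog"} holds the
#' variance-stabilized values and \code{metadata()$glog} the per-sample
#' calibration constants. Missing values are \code{NA}: a protein with no
#' isoform-unique PSMs in a sample is missing, never zero.
#'
#' @slot .  Inherits all slots from SummarizedExperiment.
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

.validProteinQuant <- function(object) {
  msg <- NULL
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- assay(object, "abundance")
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "abundance values must be non-negative")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample (column) names must be present and unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("ProteinQuant", .validProteinQuant)

#' Construct a ProteinQuant object
#'
#' @param abundance numeric matrix, proteins x samples, non-negative with
#'   \code{NA} for missing; rownames are protein accessions, colnames are
#'   sample names.
#' @param colData optional \code{DataFrame} (or data.frame) of sample
#'   annotations (the experimental design), one row per sample.
#' @param glog optional numeric matrix of glog-transformed values with the
#'   same dimensions.
#' @param glogParams optional list of per-sample glog calibration constants
#'   (see \code{\link{glogNormalize}}).
#' @return A \linkS4class{ProteinQuant} object.
#' @examples
#' m <- matrix(c(10, 20, NA, 5), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' ProteinQuant(m)
#' @export
ProteinQuant <- function(abundance, colData = NULL, glog = NULL,
                         glogParams = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sample_", seq_len(ncol(abundance)))
  assays <- list(abundance = abundance)
  if (!is.null(glog)) assays$glog <- as.matrix(glog)
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(abundance))
  else
    colData <- DataFrame(colData, row.names = colnames(abundance))
  se <- SummarizedExperiment(assays = assays, colData = colData)
  obj <- new("ProteinQuant", se)
  if (!is.null(glogParams)) metadata(obj)$glog <- glogParams
  validObject(obj)
  obj
}

#' @describeIn ProteinQuant-class the raw abundance matrix
#' @param object,x a \code{ProteinQuant}
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))

#' @rdname ProteinQuant-class
#' @export
setMethod("abundance", "ProteinQuant",
          function(object) assay(object, "abundance"))

#' @describeIn ProteinQuant-class the glog-transformed matrix (error if
#'   \code{glogNormalize} has not been run)
#' @export
setGeneric("glogAssay", function(object) standardGeneric("glogAssay"))

#' @rdname ProteinQuant-class
#' @export
setMethod("glogAssay", "ProteinQuant", function(object) {
  if (!"glog" %in% assayNames(object))
    stop("no 'glog' assay: run glogNormalize() first")
  assay(object, "glog")
})

setMethod("show", "ProteinQuant", function(object) {
  a <- assay(object, "abundance")
  cat("ProteinQuant:", nrow(a), "proteins x", ncol(a), "samples\n")
  cat("  missing:", sum(is.na(a)),
      sprintf("(%.1f%%)\n", 100 * mean(is.na(a))))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (ncol(colData(object)) > 0)
    cat("  colData:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

#' IsoformPairs: homology-defined protein pairs under comparison
#'
#' A \code{DataFrame} subclass with one row per ordered protein pair and
#' columns \code{pair_id}, \code{accession_a}, \code{accession_b},
#' \code{pair_type} ("paralog" or "spliceoform"), \code{mean_identity}
#' (percent, may be NA for spliceoforms), \code{group_id} and
#' \code{ancestry_class} ("ancient", "recent" or "unclassified").
#' \code{accession_a} is always the lexicographically smaller accession so
#' pair identity and reported log-fold-change signs are deterministic.
#'
#' @export
setClass("IsoformPairs", contains = "DFrame")

.pairCols <- c("pair_id", "accession_a", "accession_b", "pair_type",
               "mean_identity", "group_id", "ancestry_class")

.validIsoformPairs <- function(object) {
  msg <- NULL
  missing <- setdiff(.pairCols, colnames(object))
  if (length(missing))
    msg <- c(msg, paste("missing columns:",
                        paste(missing, collapse = ", ")))
  else {
    if (any(object$accession_a == object$accession_b))
      msg <- c(msg, "accession_a must differ from accession_b")
    if (any(object$accession_a > object$accession_b))
      msg <- c(msg, "accession_a must sort before accession_b")
    if (anyDuplicated(object$pair_id))
      msg <- c(msg, "pair_id must be unique")
    if (!all(object$pair_type %in% c("paralog", "spliceoform")))
      msg <- c(msg, "pair_type must be 'paralog' or 'spliceoform'")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("IsoformPairs", .validIsoformPairs)

#' Construct an IsoformPairs object
#'
#' Accessions within a pair are re-ordered so that \code{accession_a} is the
#' lexicographically smaller one (C-locale comparison) and a stable
#' \code{pair_id} of the form \code{"A|B"} is assigned. Rows are sorted by
#' \code{pair_id}, so the result is invariant to input order.
#'
#' @param accession_a,accession_b character vectors of protein accessions.
#' @param pair_type "paralog" or "spliceoform", recycled.
#' @param mean_identity percent identity (0-100) or NA, recycled.
#' @param group_id isoform-group identifier, recycled.
#' @param ancestry_class "ancient", "recent" or "unclassified", recycled.
#' @return An \linkS4class{IsoformPairs} object.
#' @examples
#' IsoformPairs(c("Q2", "P1"), c("Q1", "P2"))
#' @export
IsoformPairs <- function(accession_a, accession_b, pair_type = "paralog",
                         mean_identity = NA_real_, group_id = NA_character_,
                         ancestry_class = "unclassified") {
  a <- as.character(accession_a)
  b <- as.character(accession_b)
  if (length(a) != length(b))
    stop("accession_a and accession_b must have equal length")
  flip <- .cmpC(a, b) > 0
  lo <- a; lo[flip] <- b[flip]
  hi <- b; hi[flip] <- a[flip]
  pid <- paste(lo, hi, sep = "|")
  o <- order(pid, method = "radix")
  df <- DataFrame(
    pair_id = pid[o],
    accession_a = lo[o],
    accession_b = hi[o],
    pair_type = rep_len(as.character(pair_type), length(a))[o],
    mean_identity = rep_len(as.numeric(mean_identity), length(a))[o],
    group_id = rep_len(as.character(group_id), length(a))[o],
    ancestry_class = rep_len(as.character(ancestry_class), length(a))[o])
  obj <- new("IsoformPairs", df)
  validObject(obj)
  obj
}

# byte-order (C-locale) string comparison: -1, 0, 1 per element; radix sort
# order is locale-independent, which keeps pair orientation reproducible
.cmpC <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(try(Sys.setlocale("LC_COLLATE", old), silent = TRUE), add = TRUE)
  try(Sys.setlocale("LC_COLLATE", "C"), silent = TRUE)
  out <- integer(length(a))
  out[a < b] <- -1L
  out[a > b] <- 1L
  out
}

setMethod("show", "IsoformPairs", function(object) {
  cat("IsoformPairs:", nrow(object), "pairs",
      sprintf("(%d paralog, %d spliceoform)\n",
              sum(object$pair_type == "paralog"),
              sum(object$pair_type == "spliceoform")))
  cat("  groups:", length(unique(object$group_id)), "\n")
  if (nrow(object)) {
    idok <- !is.na(object$mean_identity)
    if (any(idok))
      cat(sprintf("  mean identity: %.1f%%\n",
                  mean(object$mean_identity[idok])))
  }
})

#' RatioFit: per-row linear model fits with empirical-Bayes moderation
#'
#' Holds the row-wise ordinary-least-squares fits of a ratio (or abundance)
#' matrix against a design matrix, plus the empirical-Bayes variance
#' moderation parameters. Slots follow the standard moderated-t
#' parameterization: posterior variance
#' \eqn{(d_0 s_0^2 + d s^2) / (d_0 + d)} and moderated
#' \eqn{t = \hat\beta / (\tilde s \cdot u)} on \eqn{d_0 + d} degrees of
#' freedom, where \eqn{u} is the unscaled standard error of the contrast.
#'
#' @slot coefficients numeric matrix of per-row coefficient estimates.
#' @slot stdevUnscaled numeric vector: unscaled SE of the tested contrast.
#' @slot sigma2 numeric vector of residual variances.
#' @slot df numeric vector of residual degrees of freedom.
#' @slot contrast character name of the tested coefficient.
#' @slot logFC numeric vector: contrast estimate per row.
#' @slot priorDf numeric scalar d0 (possibly Inf).
#' @slot priorVar numeric scalar s0^2.
#' @slot postVar numeric vector of posterior variances.
#' @slot t numeric vector of moderated t statistics.
#' @slot p numeric vector of two-sided p-values.
#' @slot design the design matrix used.
#' @export
setClass("RatioFit", representation(
  coefficients = "matrix",
  stdevUnscaled = "numeric",
  sigma2 = "numeric",
  df = "numeric",
  contrast = "character",
  logFC = "numeric",
  priorDf = "numeric",
  priorVar = "numeric",
  postVar = "numeric",
  t = "numeric",
  p = "numeric",
  design = "matrix"))

setValidity("RatioFit", function(object) {
  msg <- NULL
  n <- nrow(object@coefficients)
  if (length(object@sigma2) != n || length(object@df) != n)
    msg <- c(msg, "sigma2/df length must match number of rows")
  if (any(object@sigma2 < 0, na.rm = TRUE))
    msg <- c(msg, "residual variances must be non-negative")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RatioFit", function(object) {
  cat("RatioFit:", nrow(object@coefficients), "rows, contrast",
      sQuote(object@contrast), "\n")
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %.4g\n",
              format(object@priorDf), object@priorVar))
  cat("  tested:", sum(!is.na(object@t)), "rows\n")
})

#' @describeIn RatioFit-class moderated t statistics
#' @param object a \code{RatioFit}
#' @export
setGeneric("moderatedT", function(object) standardGeneric("moderatedT"))

#' @rdname RatioFit-class
#' @export
setMethod("moderatedT", "RatioFit", function(object) object@t)

#' @describeIn RatioFit-class prior degrees of freedom d0
#' @export
setGeneric("priorDf", function(object) standardGeneric("priorDf"))

#' @rdname RatioFit-class
#' @export
setMethod("priorDf", "RatioFit", function(object) object@priorDf)
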