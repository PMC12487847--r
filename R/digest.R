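#' Count theoretically observable tryptic peptides
#'
#' In-silico digest of a protein sequence used as the denominator of the
#' iBAQ-style absolute abundance estimate: fully tryptic cleavage C-terminal
#' to K or R, suppressed when the next residue is proline (KP/RP rule), zero
#' missed cleavages, counting fragments whose length falls in
#' \code{[min_len, max_len]}.
#'
#' @param protein_sequence single uppercase amino-acid string (standard
#'   20-letter alphabet plus U, O, B, Z, X, J; \code{*} terminators are
#'   stripped).
#' @param min_len,max_len inclusive peptide length bounds (defaults 7 and 30,
#'   the usual observable range for shotgun proteomics).
#' @return integer count of in-range fully tryptic peptides.
#' @examples
#' trypticPeptideCount("AAAAAAAK")            # 1
#' trypticPeptideCount("AAAAAAAKRCCCCCCC")    # 2 (R singlet too short)
#' trypticPeptideCount("AAAAAAAKPCCCCCC")     # 1 (no cleavage before P)
#' @export
trypticPeptideCount <- function(protein_sequence, min_len = 7L,
                                max_len = 30L) {
  if (length(protein_sequence) != 1L || is.na(protein_sequence))
    stop("protein_sequence must be a single string")
  s <- gsub("\\*$", "", protein_sequence)
  if (!nzchar(s)) stop("empty protein sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYUOBZXJ]", s))
    stop("illegal characters in protein sequence: ",
         gsub("[ACDEFGHIKLMNPQRSTVWYUOBZXJ]", "", s))
  frags <- digestTryptic(s)
  sum(nchar(frags) >= min_len & nchar(frags) <= max_len)
}

#' Fully tryptic fragments of a sequence (zero missed cleavages)
#'
#' @param s uppercase amino-acid string.
#' @return character vector of fragments in N- to C-terminal order.
#' @keywords internal
digestTryptic <- function(s) {
  # cleave after K/R not followed by P
  strsplit(gsub("(?<=[KR])(?!P)", "\n", s, perl = TRUE), "\n",
           fixed = TRUE)[[1L]]
}

#' Read a protein FASTA into an accession -> sequence map
#'
#' Accessions are parsed as the first whitespace-delimited token of the
#' header; UniProt-style \code{db|ACC|NAME} headers are recognized and the
#' central accession extracted, preserving isoform suffixes such as
#' \code{-2}.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences; an attribute
#'   \code{"gene"} carries the UniProt \code{GN=} gene symbol where present
#'   (NA otherwise), aligned with the sequences.
#' @export
readFastaMap <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  first <- sub("\\s.*$", "", headers)
  acc <- ifelse(grepl("^[^|]+\\|[^|]+\\|", first),
                sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", first),
                first)
  gene <- ifelse(grepl("\\bGN=([^ ]+)", headers),
                 sub(".*\\bGN=([^ ]+).*", "\\1", headers),
                 NA_character_)
  seqs <- toupper(as.character(aa))
  names(seqs) <- acc
  if (anyDuplicated(acc))
    warning("duplicate accessions in FASTA; keeping first occurrence: ",
            paste(unique(acc[duplicated(acc)]), collapse = ", "))
  keep <- !duplicated(acc)
  seqs <- seqs[keep]
  attr(seqs, "gene") <- stats::setNames(gene[keep], acc[keep])
  seqs
}

#' Map protein accessions to gene symbols
#'
#' Uses the \code{GN=} annotation captured by \code{\link{readFastaMap}},
#' falling back to the base accession (isoform suffix stripped) when no gene
#' symbol is present, so spliceoforms of one gene always share a label.
#'
#' @param fasta_map result of \code{\link{readFastaMap}}.
#' @return named character vector accession -> gene label.
#' @export
geneMap <- function(fasta_map) {
  gene <- attr(fasta_map, "gene")
  if (is.null(gene)) gene <- rep(NA_character_, length(fasta_map))
  base <- sub("-\\d+$", "", names(fasta_map))
  out <- ifelse(is.na(gene), base, gene)
  stats::setNames(out, names(fasta_map))
}
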