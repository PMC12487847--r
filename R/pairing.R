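#' Mean bidirectional sequence identity
#'
#' Arithmetic mean of the query-to-target and target-to-query percent
#' identities reported for a homolog pair (the two directions differ when
#' the sequences have different lengths).
#'
#' @param identity_ab,identity_ba percents in [0, 100].
#' @return mean percent identity.
#' @examples
#' meanIdentity(93, 93)   # e.g. mouse Myh7/Myh6
#' meanIdentity(40, 60)
#' @export
meanIdentity <- function(identity_ab, identity_ba) {
  if (any(identity_ab < 0 | identity_ab > 100 |
          identity_ba < 0 | identity_ba > 100, na.rm = TRUE))
    stop("identities must be in [0, 100]")
  (identity_ab + identity_ba) / 2
}

#' Read an Ensembl BioMart-style paralog homology table
#'
#' Tab-delimited with header; required columns \code{gene_id},
#' \code{paralog_gene_id}, \code{perc_id}, \code{perc_id_r1}; optional
#' \code{paralog_type} and \code{ancestor}; extra columns ignored.
#'
#' @param path file path.
#' @return data.table of homology records.
#' @export
readHomologyTable <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  need <- c("gene_id", "paralog_gene_id", "perc_id", "perc_id_r1")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop("homology table lacks columns: ", paste(missing, collapse = ", "))
  if (!"paralog_type" %in% names(dt)) dt$paralog_type <- NA_character_
  if (!"ancestor" %in% names(dt)) dt$ancestor <- NA_character_
  dt
}

#' Filter paralog gene pairs by sequence identity and quantification
#'
#' Retains homology records whose mean bidirectional identity is at or
#' above the threshold (inclusive at exactly the threshold) and whose two
#' genes both map to quantified proteins; reversed duplicates (b, a) of a
#' retained (a, b) are collapsed to one record.
#'
#' @param records homology table (\code{\link{readHomologyTable}}).
#' @param quantified_genes character set of gene ids with quantified
#'   protein products.
#' @param min_identity percent threshold, default 50.
#' @return data.table of retained unique gene pairs with
#'   \code{mean_identity}, \code{paralog_type}, \code{ancestor}.
#' @export
filterParalogPairs <- function(records, quantified_genes,
                               min_identity = 50) {
  if (min_identity < 0 || min_identity > 100)
    stop("min_identity must be in [0, 100]")
  dt <- data.table::as.data.table(records)
  dt$mean_identity <- meanIdentity(dt$perc_id, dt$perc_id_r1)
  keep <- !is.na(dt$mean_identity) & dt$mean_identity >= min_identity &
    dt$gene_id %in% quantified_genes &
    dt$paralog_gene_id %in% quantified_genes &
    dt$gene_id != dt$paralog_gene_id
  dt <- dt[keep]
  if (!nrow(dt))
    return(dt[, c("gene_id", "paralog_gene_id", "mean_identity",
                  "paralog_type", "ancestor"), with = FALSE])
  flip <- .cmpC(dt$gene_id, dt$paralog_gene_id) > 0
  tmp <- dt$gene_id[flip]
  dt$gene_id[flip] <- dt$paralog_gene_id[flip]
  dt$paralog_gene_id[flip] <- tmp
  dt <- dt[!duplicated(paste(dt$gene_id, dt$paralog_gene_id, sep = "|"))]
  dt[order(dt$gene_id, dt$paralog_gene_id, method = "radix"),
     c("gene_id", "paralog_gene_id", "mean_identity", "paralog_type",
       "ancestor"), with = FALSE]
}

#' Assemble isoform groups from retained gene pairs
#'
#' Groups are the connected components of the retained-pair graph,
#' projected onto quantified protein accessions through the gene-to-protein
#' map. Genes without a mapped accession are skipped with a warning.
#'
#' @param retained_pairs output of \code{\link{filterParalogPairs}}.
#' @param accession_map named list (or named character) gene ->
#'   accession(s) restricted to quantified proteins.
#' @return list of groups, each a list with \code{group_id},
#'   \code{genes}, \code{accessions}; attribute \code{"mean_size"} holds
#'   the mean number of member proteins.
#' @export
buildGroups <- function(retained_pairs, accession_map) {
  if (is.character(accession_map)) accession_map <- as.list(accession_map)
  rp <- data.table::as.data.table(retained_pairs)
  if (!nrow(rp)) {
    out <- list()
    attr(out, "mean_size") <- NA_real_
    return(out)
  }
  genes <- unique(c(rp$gene_id, rp$paralog_gene_id))
  unmapped <- genes[!genes %in% names(accession_map) |
                      lengths(accession_map[genes]) == 0]
  if (length(unmapped))
    warning("genes with no quantified accession skipped: ",
            paste(unmapped, collapse = ", "))
  ok <- !(rp$gene_id %in% unmapped) & !(rp$paralog_gene_id %in% unmapped)
  rp <- rp[ok]
  if (!nrow(rp)) {
    out <- list()
    attr(out, "mean_size") <- NA_real_
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    rp[, c("gene_id", "paralog_gene_id"), with = FALSE], directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  # stable group ids: number components by their smallest gene id
  by_comp <- split(names(membership), membership)
  ord <- order(vapply(by_comp, function(x) sort(x, method = "radix")[1],
                      character(1)), method = "radix")
  by_comp <- by_comp[ord]
  out <- lapply(seq_along(by_comp), function(i) {
    gg <- sort(by_comp[[i]], method = "radix")
    accs <- sort(unique(unlist(accession_map[gg], use.names = FALSE)),
                 method = "radix")
    list(group_id = sprintf("G%04d", i), genes = gg, accessions = accs)
  })
  sizes <- vapply(out, function(x) length(x$accessions), numeric(1))
  keep <- sizes >= 2
  out <- out[keep]
  attr(out, "mean_size") <- if (length(out)) mean(sizes[keep]) else NA_real_
  out
}

#' Enumerate all within-group pairs
#'
#' All n(n-1)/2 unordered member pairs of each isoform group, in canonical
#' orientation. Restricting the all-versus-all ratio comparison to
#' within-group pairs is what keeps the number of tests tractable (2,000
#' proteins compared all-to-all would need ~2 million tests).
#'
#' @param groups list of groups from \code{\link{buildGroups}}, or a single
#'   group.
#' @param identity_lookup optional function(acc_a, acc_b) -> mean identity
#'   used to annotate pairs.
#' @return an \linkS4class{IsoformPairs} object (pair_type "paralog").
#' @export
enumeratePairs <- function(groups, identity_lookup = NULL) {
  if (!is.null(groups$accessions)) groups <- list(groups)
  acc_a <- character(0); acc_b <- character(0); gid <- character(0)
  for (g in groups) {
    n <- length(g$accessions)
    if (n < 2L) next
    # vectorized upper-triangle index pairs (i < j)
    i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
    j <- sequence(rev(seq_len(n - 1L)), from = seq_len(n - 1L) + 1L)
    acc_a <- c(acc_a, g$accessions[i])
    acc_b <- c(acc_b, g$accessions[j])
    gid <- c(gid, rep(g$group_id, length(i)))
  }
  mi <- if (!is.null(identity_lookup) && length(acc_a))
    mapply(identity_lookup, acc_a, acc_b) else NA_real_
  IsoformPairs(acc_a, acc_b, pair_type = "paralog", mean_identity = mi,
               group_id = gid)
}

#' Pair UniProt canonical and isoform accessions (spliceoforms)
#'
#' Every pair of co-quantified accessions sharing the same UniProt base
#' accession (canonical \code{P12345}, isoforms \code{P12345-2}, ...) is a
#' spliceoform pair; a canonical entry with no quantified isoform yields no
#' pair. Accessions not matching the UniProt convention are skipped with a
#' warning.
#'
#' @param accessions character vector of quantified accessions.
#' @return an \linkS4class{IsoformPairs} object (pair_type "spliceoform");
#'   group ids are \code{"SP_<base accession>"}.
#' @examples
#' buildSpliceoformPairs(c("P52480", "P52480-2", "Q99999"))
#' @export
buildSpliceoformPairs <- function(accessions) {
  accessions <- unique(as.character(accessions))
  ok <- grepl("^[A-Z][A-Z0-9]{5,9}(-\\d+)?$", accessions)
  if (any(!ok))
    warning("accessions not matching the UniProt convention skipped: ",
            paste(accessions[!ok], collapse = ", "))
  accessions <- accessions[ok]
  base <- sub("-\\d+$", "", accessions)
  acc_a <- character(0); acc_b <- character(0); gid <- character(0)
  for (bs in unique(base)) {
    members <- sort(accessions[base == bs], method = "radix")
    if (length(members) < 2L) next
    idx <- utils::combn(length(members), 2L)
    acc_a <- c(acc_a, members[idx[1L, ]])
    acc_b <- c(acc_b, members[idx[2L, ]])
    gid <- c(gid, rep(paste0("SP_", bs), ncol(idx)))
  }
  IsoformPairs(acc_a, acc_b, pair_type = "spliceoform", group_id = gid)
}

#' Classify a pair's evolutionary ancestry
#'
#' Gene families whose last common ancestor is Bilateria or a configured
#' deeper clade are "ancient"; any other known taxon is "recent"; a missing
#' label is "unclassified".
#'
#' @param ancestor_taxon character vector of last-common-ancestor labels.
#' @param ancient_clades clade labels treated as at least as deep as
#'   Bilateria.
#' @param known_taxa optional vocabulary; labels outside it become
#'   "unclassified" with a warning. NULL (default) accepts any non-empty
#'   label as a valid taxon.
#' @return character vector: "ancient" / "recent" / "unclassified".
#' @examples
#' classifyAncestry(c("Opisthokonta", "Muroidea", ""))
#' @export
classifyAncestry <- function(ancestor_taxon,
                             ancient_clades = c("Bilateria", "Opisthokonta",
                                                "Eukaryota", "Metazoa",
                                                "Eumetazoa", "Fungi/Metazoa group",
                                                "Cellular organisms"),
                             known_taxa = NULL) {
  x <- as.character(ancestor_taxon)
  out <- ifelse(is.na(x) | !nzchar(x), "unclassified",
                ifelse(x %in% ancient_clades, "ancient", "recent"))
  if (!is.null(known_taxa)) {
    unknown <- nzchar(x) & !is.na(x) & !(x %in% known_taxa)
    if (any(unknown)) {
      warning("unknown ancestor taxa treated as unclassified: ",
              paste(unique(x[unknown]), collapse = ", "))
      out[unknown] <- "unclassified"
    }
  }
  out
}

#' Annotate isoform pairs with ancestry and identity from homology records
#'
#' Joins gene-level homology information onto protein-level pairs through a
#' gene map and fills \code{ancestry_class} (via
#' \code{\link{classifyAncestry}}) and \code{mean_identity} where missing.
#'
#' @param pairs an \linkS4class{IsoformPairs}.
#' @param records homology table with \code{gene_id},
#'   \code{paralog_gene_id}, \code{perc_id}, \code{perc_id_r1},
#'   \code{ancestor}.
#' @param gene_map named character accession -> gene id.
#' @param ... passed to \code{\link{classifyAncestry}}.
#' @return the annotated \linkS4class{IsoformPairs}.
#' @export
annotateAncestry <- function(pairs, records, gene_map, ...) {
  dt <- data.table::as.data.table(records)
  ga <- unname(gene_map[pairs$accession_a])
  gb <- unname(gene_map[pairs$accession_b])
  flip <- .cmpC(ga, gb) > 0
  lo <- ifelse(flip, gb, ga); hi <- ifelse(flip, ga, gb)
  key <- paste(lo, hi, sep = "|")
  rflip <- .cmpC(dt$gene_id, dt$paralog_gene_id) > 0
  rlo <- ifelse(rflip, dt$paralog_gene_id, dt$gene_id)
  rhi <- ifelse(rflip, dt$gene_id, dt$paralog_gene_id)
  rkey <- paste(rlo, rhi, sep = "|")
  idx <- match(key, rkey)
  anc <- rep(NA_character_, length(idx))
  anc[!is.na(idx)] <- as.character(dt$ancestor)[idx[!is.na(idx)]]
  mi_new <- pairs$mean_identity
  mi <- meanIdentity(dt$perc_id, dt$perc_id_r1)
  fill <- is.na(mi_new) & !is.na(idx)
  mi_new[fill] <- mi[idx[fill]]
  IsoformPairs(pairs$accession_a, pairs$accession_b,
               pair_type = pairs$pair_type,
               mean_identity = mi_new,
               group_id = pairs$group_id,
               ancestry_class = classifyAncestry(anc, ...))
}
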