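#' Configuration for the synthetic TMT experiment generator
#'
#' Defaults describe the standard benchmark: 1500 background proteins plus
#' 200 two-member paralog groups (100 null, 100 with a true glog2 ratio
#' shift of 1.0), one 10-plex with 5 fetal and 5 postnatal samples,
#' peptide-level lognormal noise at CV 0.2, no co-isolation interference,
#' no missingness.
#'
#' @param n_background background (singleton) proteins.
#' @param n_groups two-member isoform groups.
#' @param n_shifted groups with a true ratio shift between conditions;
#'   the remaining groups are null.
#' @param shift true between-condition shift of the pair log2 ratio.
#' @param n_per_condition samples per condition (plex size is twice this).
#' @param conditions length-2 character vector of condition labels.
#' @param log10_span orders of magnitude covered by protein copy numbers.
#' @param base_abundance intensity of the least-abundant protein stratum.
#' @param cv peptide-level coefficient of variation (lognormal).
#' @param interference co-isolation interference fraction in [0, 1): each
#'   reporter channel measures the true signal plus this fraction of the
#'   channel-mean background, compressing ratios toward 1:1.
#' @param missing_rate protein-x-sample missing-at-random rate applied
#'   after quantification (see \code{\link{applyMissingness}}).
#' @param peptides_mean mean of the Poisson number of in-range tryptic
#'   peptides per protein (at least 1 is enforced).
#' @param kp_rate fraction of proteins given an internal KP motif so the
#'   proline-suppression rule of the digest is exercised.
#' @param seed integer RNG seed (mandatory; no silent clock seeding).
#' @return a validated list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(n_background = 1500L, n_groups = 200L,
                            n_shifted = 100L, shift = 1.0,
                            n_per_condition = 5L,
                            conditions = c("fetal", "postnatal"),
                            log10_span = 5, base_abundance = 100,
                            cv = 0.2, interference = 0,
                            missing_rate = 0, peptides_mean = 10,
                            kp_rate = 0.05, seed) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  cfg <- list(n_background = as.integer(n_background),
              n_groups = as.integer(n_groups),
              n_shifted = as.integer(n_shifted),
              shift = shift,
              n_per_condition = as.integer(n_per_condition),
              conditions = conditions,
              log10_span = log10_span,
              base_abundance = base_abundance,
              cv = cv, interference = interference,
              missing_rate = missing_rate,
              peptides_mean = peptides_mean,
              kp_rate = kp_rate, seed = as.integer(seed))
  if (cfg$n_shifted > cfg$n_groups)
    stop("n_shifted cannot exceed n_groups")
  if (cfg$interference < 0 || cfg$interference >= 1)
    stop("interference must be in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1 ||
      cfg$cv < 0 || cfg$log10_span <= 0)
    stop("rates must be valid: cv >= 0, missing_rate in [0,1], span > 0")
  if (length(conditions) != 2L)
    stop("exactly two conditions are supported")
  class(cfg) <- "syntheticConfig"
  cfg
}

# random tryptic peptides: uniform body over an alphabet without K/R/P
# (so designed peptides are exactly the tryptic fragments), K/R terminus
.randomPeptides <- function(n, min_len = 7L, max_len = 25L) {
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                "Q", "S", "T", "V", "W", "Y")
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  body_len <- lens - 1L
  big <- paste(sample(alphabet, sum(body_len), replace = TRUE),
               collapse = "")
  ends <- cumsum(body_len)
  starts <- ends - body_len + 1L
  paste0(substring(big, starts, ends),
         sample(c("K", "R"), n, replace = TRUE))
}

#' Simulate a PSM-level TMT experiment with known ground truth
#'
#' Builds synthetic tryptic-digestible protein sequences, assigns copy
#' numbers spanning the configured orders of magnitude, gives isoform
#' groups condition-specific member proportions, and emits one PSM per
#' in-range tryptic peptide: MS1 intensity is the protein's summed channel
#' abundance times a lognormal peptide response, and reporter intensities
#' are the true channel abundances mixed with the configured interference
#' fraction of the channel-mean background (ratio compression), with
#' lognormal measurement noise per channel.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param out_dir optional directory; when given, the five artifacts are
#'   written in the package's standard dialects (\code{psms.tsv},
#'   \code{proteins.fasta}, \code{homology.tsv}, \code{design.csv},
#'   \code{ground_truth.tsv}).
#' @return list with \code{psms} (data.table), \code{fasta_map},
#'   \code{homology} (data.table), \code{design} (data.frame), and
#'   \code{truth}: true abundance matrix, per-condition proportions, pair
#'   table with \code{true_logFC} and \code{true_de}, and the
#'   missing-at-random mask.
#' @export
simulateDataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  n_cond <- 2L
  npc <- config$n_per_condition
  n_samples <- n_cond * npc
  samples <- sprintf("S%02d", seq_len(n_samples))
  channels <- sprintf("C%02d", seq_len(n_samples))
  condition <- rep(config$conditions, each = npc)

  n_members <- 2L * config$n_groups
  n_prot <- config$n_background + n_members
  acc <- sprintf("PR%05d", seq_len(n_prot))
  gene <- sprintf("GN%05d", seq_len(n_prot))

  # group structure: members are consecutive accession pairs at the front
  gidx <- if (config$n_groups)
    matrix(seq_len(n_members), nrow = config$n_groups, byrow = TRUE)
  else matrix(integer(0), 0, 2)
  shifted <- seq_len(config$n_groups) <= config$n_shifted

  # copy numbers: group totals and background log-uniform over the span
  totals <- config$base_abundance *
    10^stats::runif(config$n_groups + config$n_background, 0,
                    config$log10_span)
  group_tot <- totals[seq_len(config$n_groups)]
  bg_tot <- totals[-seq_len(config$n_groups)]

  # per-condition member-1 proportions
  p1_a <- stats::runif(config$n_groups, 0.35, 0.65)   # condition 1
  dir <- sample(c(-1, 1), config$n_groups, replace = TRUE)
  lr_a <- log2(p1_a / (1 - p1_a))
  lr_b <- lr_a + ifelse(shifted, dir * config$shift, 0)
  p1_b <- 2^lr_b / (1 + 2^lr_b)

  A <- matrix(0, n_prot, n_samples, dimnames = list(acc, samples))
  if (config$n_groups) {
    for (k in 1:2) {
      prop_a <- if (k == 1) p1_a else 1 - p1_a
      prop_b <- if (k == 1) p1_b else 1 - p1_b
      A[gidx[, k], condition == config$conditions[1]] <- group_tot * prop_a
      A[gidx[, k], condition == config$conditions[2]] <- group_tot * prop_b
    }
  }
  if (config$n_background)
    A[n_members + seq_len(config$n_background), ] <- bg_tot

  # sequences: designed in-range tryptic peptides (+ optional KP motif)
  npep <- pmax(1L, stats::rpois(n_prot, config$peptides_mean))
  peps <- .randomPeptides(sum(npep))
  pep_prot <- rep(seq_len(n_prot), npep)
  has_kp <- stats::runif(n_prot) < config$kp_rate
  kp_tail <- ifelse(has_kp, paste0("KP", strrep("A", 5)), "")
  seqs <- vapply(split(peps, pep_prot), paste, character(1), collapse = "")
  seqs <- paste0(seqs, kp_tail)
  names(seqs) <- acc
  # the KP tail is itself an in-range (length 7) fragment: emit a PSM too
  if (any(has_kp)) {
    peps <- c(peps, kp_tail[has_kp])
    pep_prot <- c(pep_prot, which(has_kp))
  }

  # PSM intensities
  n_psm <- length(peps)
  sdlog <- sqrt(log(1 + config$cv^2))
  resp <- stats::rlnorm(n_psm, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  ms1 <- rowSums(A)[pep_prot] * resp
  bg_mean <- colMeans(A)
  signal <- A[pep_prot, , drop = FALSE] +
    rep(config$interference * bg_mean, each = n_psm)
  eps <- matrix(stats::rlnorm(n_psm * n_samples, -sdlog^2 / 2, sdlog),
                n_psm, n_samples)
  reporters <- signal * eps
  colnames(reporters) <- paste0("reporter_", channels)

  psms <- data.table::data.table(peptide = peps,
                                 proteins = acc[pep_prot],
                                 ms1_intensity = ms1)
  psms <- cbind(psms, data.table::as.data.table(reporters))
  ord <- order(psms$proteins, psms$peptide, method = "radix")
  psms <- psms[ord]

  design <- data.frame(sample = samples, channel = channels,
                       condition = condition, stringsAsFactors = FALSE)

  homology <- if (config$n_groups) {
    idn <- stats::runif(config$n_groups, 55, 95)
    data.table::data.table(
      gene_id = gene[gidx[, 1]],
      paralog_gene_id = gene[gidx[, 2]],
      perc_id = round(idn + stats::runif(config$n_groups, -2, 2), 1),
      perc_id_r1 = round(idn + stats::runif(config$n_groups, -2, 2), 1),
      paralog_type = sample(c("within_species_paralog",
                              "other_paralog"),
                            config$n_groups, replace = TRUE,
                            prob = c(0.8, 0.2)),
      ancestor = sample(c("Bilateria", "Opisthokonta", "Muroidea",
                          "Euarchontoglires", "Rodentia"),
                        config$n_groups, replace = TRUE))
  } else data.table::data.table(gene_id = character(0),
                                paralog_gene_id = character(0),
                                perc_id = numeric(0),
                                perc_id_r1 = numeric(0),
                                paralog_type = character(0),
                                ancestor = character(0))

  missing_mask <- matrix(stats::runif(n_prot * n_samples) <
                           config$missing_rate,
                         n_prot, n_samples, dimnames = dimnames(A))

  pair_tab <- if (config$n_groups) data.frame(
    pair_id = paste(acc[gidx[, 1]], acc[gidx[, 2]], sep = "|"),
    accession_a = acc[gidx[, 1]],
    accession_b = acc[gidx[, 2]],
    group = seq_len(config$n_groups),
    true_logFC = lr_b - lr_a,
    true_de = shifted,
    stringsAsFactors = FALSE) else
      data.frame(pair_id = character(0), accession_a = character(0),
                 accession_b = character(0), group = integer(0),
                 true_logFC = numeric(0), true_de = logical(0))

  truth <- list(abundance = A,
                proportions = data.frame(group = seq_len(config$n_groups),
                                         p_member1_cond1 = p1_a,
                                         p_member1_cond2 = p1_b),
                pairs = pair_tab,
                missing_mask = missing_mask)

  fasta_map <- seqs
  attr(fasta_map, "gene") <- stats::setNames(gene, acc)

  out <- list(psms = psms, fasta_map = fasta_map, homology = homology,
              design = design, truth = truth, config = config)
  if (!is.null(out_dir)) writeSyntheticDataset(out, out_dir)
  out
}

#' Write a simulated dataset to the standard file dialects
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSyntheticDataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(psms = file.path(out_dir, "psms.tsv"),
             fasta = file.path(out_dir, "proteins.fasta"),
             homology = file.path(out_dir, "homology.tsv"),
             design = file.path(out_dir, "design.csv"),
             truth = file.path(out_dir, "ground_truth.tsv"))
  data.table::fwrite(sim$psms, paths["psms"], sep = "\t", quote = FALSE)
  gene <- attr(sim$fasta_map, "gene")
  writeLines(paste0(">", names(sim$fasta_map), " GN=",
                    gene[names(sim$fasta_map)], "\n",
                    unname(sim$fasta_map)),
             paths["fasta"])
  data.table::fwrite(sim$homology, paths["homology"], sep = "\t",
                     quote = FALSE)
  utils::write.csv(sim$design, paths["design"], row.names = FALSE,
                   quote = FALSE)
  data.table::fwrite(sim$truth$pairs, paths["truth"], sep = "\t",
                     quote = FALSE)
  invisible(paths)
}

#' Apply a missing-at-random mask to a quantification matrix
#'
#' @param pq a \linkS4class{ProteinQuant}.
#' @param mask logical matrix (TRUE = missing) with rownames matching
#'   accessions; rows absent from the matrix are ignored.
#' @return the masked \linkS4class{ProteinQuant}.
#' @export
applyMissingness <- function(pq, mask) {
  m <- abundance(pq)
  common <- intersect(rownames(m), rownames(mask))
  mm <- mask[common, colnames(m), drop = FALSE]
  m[common, ][mm] <- NA_real_
  SummarizedExperiment::assay(pq, "abundance", withDimnames = FALSE) <- m
  pq
}

#' Parameter-recovery report against simulation ground truth
#'
#' Compares estimated pair log-fold-changes and significance calls with
#' the simulator's truth: logFC bias and RMSE over true-shift pairs,
#' sensitivity at the applied thresholds, and the observed false discovery
#' rate among declared positives.
#'
#' @param results ratio-test results data.frame (\code{\link{ratioTest}})
#'   with \code{pair_id}, \code{logFC}, \code{significant}.
#' @param truth the \code{truth} element of \code{\link{simulateDataset}}
#'   (or its \code{pairs} data.frame).
#' @return list: \code{n_true_shift}, \code{n_called}, \code{bias},
#'   \code{rmse}, \code{sensitivity} (NA, flagged, when no true shifts),
#'   \code{observed_fdr} (NA when nothing is called).
#' @export
recoveryReport <- function(results, truth) {
  pairs <- if (!is.null(truth$pairs)) truth$pairs else truth
  idx <- match(results$pair_id, pairs$pair_id)
  if (anyNA(idx))
    stop("pair ids absent from ground truth: ",
         paste(utils::head(results$pair_id[is.na(idx)]), collapse = ", "))
  true_lfc <- pairs$true_logFC[idx]
  true_de <- pairs$true_de[idx]
  est <- results$logFC
  err <- (est - true_lfc)[true_de]
  called <- !is.na(results$significant) & results$significant
  list(n_true_shift = sum(true_de),
       n_called = sum(called),
       bias = if (any(true_de)) mean(err, na.rm = TRUE) else NA_real_,
       rmse = if (any(true_de)) sqrt(mean(err^2, na.rm = TRUE))
              else NA_real_,
       sensitivity = if (any(true_de)) mean(called[true_de]) else NA_real_,
       observed_fdr = if (any(called)) mean(!true_de[called]) else NA_real_)
}
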