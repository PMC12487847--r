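#' Load a run configuration
#'
#' YAML key-value file holding input paths, the threshold block and model
#' options; every value can be overridden through \code{overrides}
#' (flag-style named list, taking precedence). Defaults are the standard
#' thresholds: FDR 0.01, |logFC| 0.5, MIF 0.05, identity 50\%, disease FDR
#' 0.1.
#'
#' @param path YAML file (NULL for pure defaults).
#' @param overrides named list overriding config values.
#' @return validated config list of class \code{"runConfig"}.
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(psms = NULL, fasta = NULL, homology = NULL, design = NULL,
              out_dir = ".", formula = "~ condition", contrast = NULL,
              fdr = 0.01, min_abs_lfc = 0.5, min_mif = 0.05,
              min_identity = 50, disease_fdr = 0.1,
              min_len = 7L, max_len = 30L, c_quantile = 0.05,
              seed = NULL)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  with(cfg, {
    if (fdr <= 0 || fdr > 1 || disease_fdr <= 0 || disease_fdr > 1)
      stop("FDR thresholds must be in (0, 1]")
    if (min_mif < 0 || min_mif > 0.5)
      stop("min_mif must be in [0, 0.5]")
    if (min_identity < 0 || min_identity > 100)
      stop("min_identity must be in [0, 100]")
  })
  for (f in c("psms", "fasta", "homology", "design"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured input does not exist: ", cfg[[f]])
  class(cfg) <- "runConfig"
  cfg
}

.logStep <- function(verbose, ...) {
  if (verbose) message("[ratioform] ", ...)
}

#' Run the isoform-ratio workflow as composable stages
#'
#' Stages: \code{simulate} (synthetic inputs from \code{config$seed}),
#' \code{quantify} (PSMs -> absolute quantities -> glog),
#' \code{pair} (homology filter -> groups -> pair enumeration +
#' spliceoform pairs), \code{test} (moderated ratio test + single-protein
#' DE), \code{proportions}, \code{conservation}. Each stage writes its
#' standard artifact into \code{out_dir} plus a JSON run manifest with the
#' config, seed, input checksums and row counts in/out of every filter.
#'
#' @param config a \code{\link{loadRunConfig}} result (or named list of
#'   overrides).
#' @param stages character subset of
#'   \code{c("simulate", "quantify", "pair", "test", "proportions",
#'   "conservation")}.
#' @param out_dir output directory (overrides the config's).
#' @param verbose log progress to stderr.
#' @return invisibly, a list of in-memory stage results plus
#'   \code{manifest}.
#' @export
runPipeline <- function(config = loadRunConfig(),
                        stages = c("quantify", "pair", "test"),
                        out_dir = NULL, verbose = TRUE) {
  if (!inherits(config, "runConfig"))
    config <- loadRunConfig(overrides = config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  known <- c("simulate", "quantify", "pair", "test", "proportions",
             "conservation")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  state <- list()
  counts <- list()

  if ("simulate" %in% stages) {
    if (is.null(config$seed)) stop("stage 'simulate' requires config$seed")
    .logStep(verbose, "simulate: seed ", config$seed)
    sim <- simulateDataset(syntheticConfig(seed = config$seed),
                           out_dir = file.path(config$out_dir, "sim"))
    config$psms <- file.path(config$out_dir, "sim", "psms.tsv")
    config$fasta <- file.path(config$out_dir, "sim", "proteins.fasta")
    config$homology <- file.path(config$out_dir, "sim", "homology.tsv")
    config$design <- file.path(config$out_dir, "sim", "design.csv")
    state$sim <- sim
  }

  if ("quantify" %in% stages) {
    for (f in c("psms", "fasta", "design"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("stage 'quantify' needs input ", sQuote(f),
             "; run 'simulate' first or point the config at a file")
    psms <- readPsmTable(config$psms)
    fasta_map <- readFastaMap(config$fasta)
    design_tab <- utils::read.csv(config$design, stringsAsFactors = FALSE)
    rep_cols <- grep("^reporter_", names(psms), value = TRUE)
    chan <- sub("^reporter_", "", rep_cols)
    samples <- design_tab$sample[match(chan, design_tab$channel)]
    pq <- proteinAbsoluteQuant(psms, fasta_map, samples = samples,
                               min_len = config$min_len,
                               max_len = config$max_len,
                               colData = design_tab[
                                 match(samples, design_tab$sample), ,
                                 drop = FALSE])
    pq <- glogNormalize(pq, c_quantile = config$c_quantile)
    counts$quantify <- c(metadata(pq)$quant_log,
                         proteins_quantified = nrow(pq))
    .logStep(verbose, "quantify: ", counts$quantify$psms_in, " PSMs in, ",
             counts$quantify$psms_used, " used, ",
             nrow(pq), " proteins")
    writeQuantMatrix(pq, file.path(config$out_dir, "protein_quant.tsv"))
    state$pq <- pq
    state$fasta_map <- fasta_map
    state$design_tab <- design_tab
  }

  if ("pair" %in% stages) {
    if (is.null(state$pq)) stop("stage 'pair' needs the 'quantify' output")
    if (is.null(config$homology) || !file.exists(config$homology))
      stop("stage 'pair' needs input 'homology'")
    hom <- readHomologyTable(config$homology)
    gm <- geneMap(state$fasta_map)
    quant_gene <- unique(gm[rownames(state$pq)])
    retained <- filterParalogPairs(hom, quant_gene,
                                   min_identity = config$min_identity)
    amap <- split(names(gm)[names(gm) %in% rownames(state$pq)],
                  gm[names(gm) %in% rownames(state$pq)])
    groups <- buildGroups(retained, amap)
    pairs <- enumeratePairs(groups)
    pairs <- annotateAncestry(pairs, hom, gm)
    sp <- buildSpliceoformPairs(rownames(state$pq))
    if (nrow(sp)) pairs <- .bindPairs(pairs, sp)
    counts$pair <- list(homology_records_in = nrow(hom),
                        pairs_identity_retained = nrow(retained),
                        groups = length(groups),
                        mean_group_size = attr(groups, "mean_size"),
                        pairs_enumerated = nrow(pairs))
    .logStep(verbose, "pair: ", nrow(hom), " records -> ",
             nrow(retained), " retained -> ", nrow(pairs), " pairs")
    writePairTable(pairs, file.path(config$out_dir, "pairs.tsv"))
    state$pairs <- pairs
  }

  if ("test" %in% stages) {
    if (is.null(state$pq) || is.null(state$pairs))
      stop("stage 'test' needs the 'quantify' and 'pair' outputs")
    X <- designMatrix(state$design_tab, config$formula)
    tt <- ratioTest(state$pq, state$pairs, X, contrast = config$contrast,
                    fdr = config$fdr, min_abs_lfc = config$min_abs_lfc,
                    min_mif = config$min_mif)
    de <- singleProteinDE(state$pq, X, contrast = config$contrast,
                          fdr = config$fdr,
                          min_abs_lfc = config$min_abs_lfc,
                          pair_results = tt$results)
    counts$test <- list(pairs_in = nrow(state$pairs),
                        pairs_tested = nrow(tt$results),
                        pairs_significant = sum(tt$results$significant),
                        proteins_tested = nrow(de$proteins),
                        proteins_de = sum(de$proteins$de))
    .logStep(verbose, "test: ", counts$test$pairs_tested, " pairs tested, ",
             counts$test$pairs_significant, " significant; ",
             counts$test$proteins_de, " proteins DE")
    utils::write.table(tt$results,
                       file.path(config$out_dir, "ratio_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de$proteins,
                       file.path(config$out_dir, "protein_de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$test <- tt
    state$protein_de <- de
  }

  if ("proportions" %in% stages) {
    if (is.null(state$pq) || is.null(state$pairs))
      stop("stage 'proportions' needs the 'quantify' and 'pair' outputs")
    cond <- state$design_tab$condition[
      match(colnames(state$pq), state$design_tab$sample)]
    tabs <- list()
    for (g in unique(state$pairs$group_id)) {
      accs <- unique(c(state$pairs$accession_a[state$pairs$group_id == g],
                       state$pairs$accession_b[state$pairs$group_id == g]))
      accs <- accs[accs %in% rownames(state$pq)]
      if (length(accs) < 2) next
      gp <- tryCatch(groupProportions(state$pq, accs, condition = cond,
                                      group_id = g),
                     warning = function(w) NULL, error = function(e) NULL)
      if (!is.null(gp)) tabs[[g]] <- gp$table
    }
    prop_tab <- do.call(rbind, tabs)
    counts$proportions <- list(groups_profiled = length(tabs))
    utils::write.table(prop_tab,
                       file.path(config$out_dir, "proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$proportions <- prop_tab
  }

  if ("conservation" %in% stages) {
    if (is.null(state$test)) stop("stage 'conservation' needs 'test'")
    res <- state$test$results
    pr <- state$test$pairs
    enr <- conservationEnrichment(pr, res$significant)
    idt <- tryCatch(identityVsDeTest(pr$mean_identity, res$significant),
                    error = function(e) NULL)
    counts$conservation <- list(schemes = if (is.null(enr)) 0
                                else nrow(enr))
    if (!is.null(enr))
      utils::write.table(enr,
                         file.path(config$out_dir, "conservation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    state$conservation <- list(enrichment = enr, identity_test = idt)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ratioform")),
    timestamp = NA_character_,  # deterministic manifests hash identically
    stages = stages,
    seed = config$seed,
    config = unclass(config),
    input_checksums = .checksums(config),
    counts = counts)
  # hash excludes output location: the same analysis in a different
  # directory is the same run
  manifest$config_hash <-
    .hashObject(manifest$config[setdiff(names(manifest$config),
                                        c("out_dir", "psms", "fasta",
                                          "homology", "design"))])
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  state$manifest <- manifest
  invisible(state)
}

.checksums <- function(config) {
  files <- Filter(function(f) !is.null(f) && is.character(f) &&
                    file.exists(f),
                  config[c("psms", "fasta", "homology", "design")])
  lapply(files, function(f) unname(tools::md5sum(f)))
}

.hashObject <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # small stable polynomial hash; avoids a digest dependency
  h <- 17
  for (b in as.integer(raw[seq(1, length(raw), length.out =
                                 min(4096, length(raw)))])) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write / read an isoform pair table
#'
#' Tab-delimited with the IsoformPairs columns.
#'
#' @param pairs an \linkS4class{IsoformPairs}.
#' @param path file path.
#' @export
writePairTable <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- IsoformPairs(df$accession_a, df$accession_b,
                      pair_type = df$pair_type,
                      mean_identity = df$mean_identity,
                      group_id = df$group_id,
                      ancestry_class = df$ancestry_class)
  out
}

# concatenate two IsoformPairs objects, keeping canonical sort
.bindPairs <- function(a, b) {
  IsoformPairs(c(a$accession_a, b$accession_a),
               c(a$accession_b, b$accession_b),
               pair_type = c(a$pair_type, b$pair_type),
               mean_identity = c(a$mean_identity, b$mean_identity),
               group_id = c(a$group_id, b$group_id),
               ancestry_class = c(a$ancestry_class, b$ancestry_class))
}
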