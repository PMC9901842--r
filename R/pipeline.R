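#' Pipeline configuration with the study's default thresholds
#'
#' Collects every stage threshold in one manifest. The defaults are the
#' published operating points of the analysis: detection frequency 0.85,
#' linear fold-change gate (0.5, 2), adjusted-p cut-offs 0.01 (validated
#' proteome panel) and 0.05 (discovery/metabolome), genotype QC at 2%
#' missingness, 5% MAF and minor-allele counts of 10 per group, case
#' exclusion at 3 control SDs on PC1/PC2, 5 PC covariates, top-100
#' candidate nomination with soft threshold 1e-5, term-similarity 0.7,
#' and hub centrality thresholds 10/20.
#'
#' @param synthetic a [synthetic_config()] describing the simulated study.
#' @param seed master seed for the run (defaults to the synthetic seed).
#' @param ... named overrides of individual threshold entries.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), seed = NULL, ...) {
  cfg <- list(
    synthetic = synthetic,
    seed = as.integer(seed %||% synthetic$seed),
    proteome = list(alpha = 0.01, fc_linear_bounds = c(0.5, 2),
                    min_frequency = 0.85),
    metabolome = list(alpha = 0.05, fc_linear_bounds = c(0.5, 2),
                      min_frequency = 0.85, min_per_group = 2L,
                      n_perm = 499L),
    gwas = list(max_missing = 0.02, min_maf = 0.05, min_cu = 10L,
                min_ca = 10L, k_sd = 3, n_covariate_pcs = 5L,
                top_k = 100L, soft_p = 1e-5),
    multivariate = list(n_components = 2L, keepX = 50L,
                        ellipse_level = 0.95),
    integration = list(similarity_threshold = 0.7,
                       hub_thresholds = c(10L, 20L))
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- utils::modifyList(
    cfg[[nm]] %||% list(), overrides[[nm]])
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the tri-omics pipeline end to end on simulated data
#'
#' Simulates the three omics layers, then runs proteome quantification
#' (NSAF, unicity filter, differential test, spike-in calibration and
#' validation), metabolome cleaning and differential analysis, sPLS-DA
#' projection, the genotype QC / PCA / logistic-scan association stage,
#' and pathway-graph integration. Stage outputs are written as TSV/JSON
#' under `out_dir` together with a provenance manifest (config hash, seed,
#' per-stage record counts). Identical config and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; existing files overwritten).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config$synthetic
  counts <- list()

  # -- simulate -------------------------------------------------------
  sim <- run_stage("simulate", {
    prot <- generate_proteome(scfg)
    met <- generate_metabolome(scfg)
    gen <- generate_genotypes(scfg)
    write_proteome_tsv(prot, out_dir)
    write_metabolome_tsv(met, out_dir)
    write_genotypes_vcf(gen$genotypes, gen$variants,
                        file.path(out_dir, "genotypes.vcf"))
    utils::write.table(
      data.frame(sample = rownames(gen$genotypes),
                 phenotype = gen$phenotype),
      file.path(out_dir, "phenotype.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    list(proteome = prot, metabolome = met, genotypes = gen)
  })
  counts$simulate <- c(proteins = nrow(sim$proteome$spc),
                       metabolites = nrow(sim$metabolome$intensity),
                       variants = ncol(sim$genotypes$genotypes))

  # -- proteome -------------------------------------------------------
  proteome <- run_stage("proteome", {
    pr <- sim$proteome
    keep <- pr$features$unique_peptides > 1L
    spc <- pr$spc[keep, , drop = FALSE]
    lfq <- pr$lfq[keep, , drop = FALSE]
    nonzero <- colSums(spc) > 0
    nsaf <- compute_nsaf(spc[, nonzero, drop = FALSE],
                         pr$features$length[keep])
    res <- differential_test(nsaf, pr$groups[nonzero],
                             alpha = config$proteome$alpha,
                             fc_linear_bounds = config$proteome$fc_linear_bounds,
                             min_frequency = config$proteome$min_frequency)
    std <- spikein_standard()
    meas <- generate_spikein_measurements(std, slope = 1, intercept = 2,
                                          noise_sd = 0.05,
                                          seed = config$seed)
    cal <- fit_calibration(std, meas)
    sig <- res$feature_id[res$significant]
    conc <- do.call(rbind, lapply(sig, function(id) {
      est <- estimate_concentration(cal, lfq[id, ])
      cbind(protein_id = id,
            concentration_summary(est$concentration, pr$groups))
    }))
    if (!is.null(conc)) {
      conc$p_adj <- res$p_adj[match(conc$protein_id, res$feature_id)]
      conc$passes_validation <- validate_panel(
        conc, alpha = config$proteome$alpha,
        n_case = scfg$n_cases, n_control = scfg$n_controls)
    }
    utils::write.table(res, file.path(out_dir, "proteome_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(log2fc = res$log2fc,
                 neg_log10_p_adj = -log10(res$p_adj)),
      file.path(out_dir, "proteome_volcano.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(conc))
      utils::write.table(conc, file.path(out_dir, "proteome_panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    list(results = res, calibration = cal, panel = conc, nsaf = nsaf)
  })
  counts$proteome <- c(tested = nrow(proteome$results),
                       significant = sum(proteome$results$significant))

  # -- metabolome -----------------------------------------------------
  metabolome <- run_stage("metabolome", {
    mt <- sim$metabolome
    split <- exclude_contaminants(mt$features, mt$exclusion_list)
    x <- mt$intensity[split$retained$feature_id, , drop = FALSE]
    keep <- frequency_filter(x, mt$groups,
                             config$metabolome$min_per_group)
    x <- x[keep, , drop = FALSE]
    res <- differential_metabolites(
      x, mt$groups, alpha = config$metabolome$alpha,
      fc_linear_bounds = config$metabolome$fc_linear_bounds,
      min_frequency = config$metabolome$min_frequency)
    sig_ids <- res$feature_id[res$significant]
    perm <- if (length(sig_ids))
      permutation_validate(x[sig_ids, , drop = FALSE], mt$groups,
                           n_perm = config$metabolome$n_perm,
                           alpha = config$metabolome$alpha,
                           seed = config$seed)
    else NULL
    res$kegg_id <- mt$features$kegg_id[match(res$feature_id,
                                             mt$features$feature_id)]
    res$hmdb_id <- mt$features$hmdb_id[match(res$feature_id,
                                             mt$features$feature_id)]
    utils::write.table(res, file.path(out_dir, "metabolome_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(split$excluded))
      utils::write.table(split$excluded,
                         file.path(out_dir, "metabolome_exclusions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    list(results = res, excluded = split$excluded, permutation = perm,
         n_frequency_fail = sum(!keep))
  })
  counts$metabolome <- c(excluded = nrow(metabolome$excluded),
                         frequency_fail = metabolome$n_frequency_fail,
                         tested = nrow(metabolome$results),
                         significant = sum(metabolome$results$significant))

  # -- multivariate ---------------------------------------------------
  multivariate <- run_stage("multivariate", {
    grp <- sim$proteome$groups[match(colnames(proteome$nsaf),
                                     colnames(sim$proteome$spc))]
    detected <- !is.na(row_min_nonzero(proteome$nsaf))
    x <- t(log_impute(proteome$nsaf[detected, , drop = FALSE]))
    proj <- splsda(x, grp,
                   n_components = config$multivariate$n_components,
                   keepX = min(config$multivariate$keepX, ncol(x)))
    ell <- confidence_ellipse(proj$scores, proj$groups,
                              config$multivariate$ellipse_level)
    utils::write.table(
      data.frame(sample = rownames(proj$scores), proj$scores,
                 group = proj$groups),
      file.path(out_dir, "splsda_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ell, file.path(out_dir, "ellipses.json"),
                         dataframe = "rows", digits = NA)
    list(projection = proj, ellipses = ell)
  })
  counts$multivariate <- c(components = ncol(multivariate$projection$scores))

  # -- gwas -----------------------------------------------------------
  gwas <- run_stage("gwas", {
    panel <- read_genotype_vcf(file.path(out_dir, "genotypes.vcf"))
    pheno <- utils::read.delim(file.path(out_dir, "phenotype.tsv"))
    phenotype <- factor(pheno$phenotype[match(rownames(panel$genotypes),
                                              pheno$sample)],
                        levels = c("case", "control"))
    qc <- qc_filter(panel$genotypes, phenotype,
                    max_missing = config$gwas$max_missing,
                    min_maf = config$gwas$min_maf,
                    min_cu = config$gwas$min_cu,
                    min_ca = config$gwas$min_ca)
    pca <- genotype_pca(qc$genotypes)
    keep <- exclude_outlier_cases(pca$scores, phenotype,
                                  k_sd = config$gwas$k_sd)
    g2 <- qc$genotypes[keep, , drop = FALSE]
    pca2 <- genotype_pca(g2)
    hits <- logistic_scan(g2, phenotype[keep], pca2$scores,
                          n_covariate_pcs = config$gwas$n_covariate_pcs)
    meta <- sim$genotypes$variants
    hits <- cbind(hits, meta[match(hits$variant, meta$snp_id),
                             c("chrom", "pos", "gene", "coding_region")])
    cand <- nominate_candidates(hits, top_k = config$gwas$top_k,
                                soft_p = config$gwas$soft_p)
    utils::write.table(hits, file.path(out_dir, "gwas_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cand, file.path(out_dir, "gwas_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(qc = qc$report, hits = hits, candidates = cand,
         n_excluded_cases = sum(!keep))
  })
  counts$gwas <- c(qc_removed = sum(gwas$qc),
                   tested = nrow(gwas$hits),
                   candidates = nrow(gwas$candidates))

  # -- integrate ------------------------------------------------------
  integration <- run_stage("integrate", {
    prot_genes <- sim$proteome$features$gene[
      match(proteome$results$feature_id[proteome$results$significant],
            sim$proteome$features$protein_id)]
    met_ids <- metabolome$results$kegg_id[metabolome$results$significant]
    snp_ids <- gwas$candidates$variant
    snp_genes <- gwas$candidates$gene
    sets <- generate_pathways(
      genes = unique(c(prot_genes, snp_genes)),
      compounds = unique(met_ids),
      seed = config$seed)
    write_gmt(sets, file.path(out_dir, "pathways.gmt"))
    elements <- rbind(
      data.frame(element_id = prot_genes, layer = "proteome",
                 mapped_gene = NA_character_),
      data.frame(element_id = met_ids, layer = "metabolome",
                 mapped_gene = NA_character_),
      data.frame(element_id = snp_ids, layer = "gwas",
                 mapped_gene = snp_genes))
    mapped <- suppressWarnings(map_elements(elements, sets))
    graph <- build_graph(mapped)
    summ <- summarize_graph(graph, config$integration$hub_thresholds)
    rep <- intersection_report(mapped)
    igraph::write_graph(graph, file.path(out_dir, "connective_graph.graphml"),
                        format = "graphml")
    utils::write.table(rep$report,
                       file.path(out_dir, "intersection_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(size = summ$size, n_nodes = summ$n_nodes,
           n_self_loops = summ$n_self_loops,
           assortativity = summ$assortativity,
           hub_counts = as.list(summ$hub_counts),
           triple_layer_count = rep$triple_layer_count),
      file.path(out_dir, "graph_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(graph = graph, summary = summ, report = rep)
  })
  counts$integrate <- c(nodes = integration$summary$n_nodes,
                        edges = integration$summary$size,
                        triple_layer = integration$report$triple_layer_count)

  # -- manifest -------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    stages = names(counts),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("triomix")),
    record_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(simulate = sim, proteome = proteome,
                 metabolome = metabolome, multivariate = multivariate,
                 gwas = gwas, integration = integration,
                 manifest = manifest))
}
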