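#' Configuration for the synthetic tri-omics generator
#'
#' Bundles the cohort sizes, feature counts, planted effect sizes and noise
#' settings that the three generators ([generate_proteome()],
#' [generate_metabolome()], [generate_genotypes()]) share. The defaults
#' emulate the study conditions the pipeline targets: a ~50 vs ~50
#' case-control discovery cohort, a few hundred reliably detected serum
#' proteins with a planted panel of regulated ones, on the order of a
#' thousand metabolite features contaminated by medication-derived
#' compounds, and a modest genotyping panel with two latent subpopulations
#' and a handful of truly associated loci.
#'
#' @param n_cases,n_controls samples per group.
#' @param n_proteins detected proteins.
#' @param n_planted_proteins proteins given a true case/control shift.
#' @param planted_log2fc magnitude (log2 units) of the planted protein
#'   shift; sign per protein is recorded in the truth table (80 percent up,
#'   20 percent down, mirroring the typical up/down split of serum panels).
#' @param n_metabolites metabolite features.
#' @param n_contaminants drug-like/non-endogenous features planted
#'   predominantly in the case group.
#' @param n_snps,n_causal_snps genotyped variants and truly associated ones.
#' @param causal_odds_ratio per-allele odds ratio of the causal variants.
#' @param n_subpops latent subpopulations in the genotype panel.
#' @param fst_like_divergence Balding-Nichols divergence parameter in
#'   `[0, 1)`; 0 means no population structure.
#' @param missing_rate fraction of censored (zero) proteome/metabolome
#'   entries and of missing genotype calls.
#' @param seed integer master seed; fans out to per-generator substreams.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cases = 49L, n_controls = 50L,
                             n_proteins = 250L, n_planted_proteins = 20L,
                             planted_log2fc = 2.5,
                             n_metabolites = 1200L, n_contaminants = 226L,
                             n_snps = 500L, n_causal_snps = 5L,
                             causal_odds_ratio = 3,
                             n_subpops = 2L, fst_like_divergence = 0.1,
                             missing_rate = 0.02, seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_proteins = as.integer(n_proteins),
    n_planted_proteins = as.integer(n_planted_proteins),
    planted_log2fc = as.numeric(planted_log2fc),
    n_metabolites = as.integer(n_metabolites),
    n_contaminants = as.integer(n_contaminants),
    n_snps = as.integer(n_snps), n_causal_snps = as.integer(n_causal_snps),
    causal_odds_ratio = as.numeric(causal_odds_ratio),
    n_subpops = as.integer(n_subpops),
    fst_like_divergence = as.numeric(fst_like_divergence),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_cases", "n_controls", "n_proteins",
                  "n_planted_proteins", "n_metabolites", "n_contaminants",
                  "n_snps", "n_causal_snps")]
  if (any(unlist(counts) < 0L)) stop("all counts must be >= 0")
  if (cfg$n_planted_proteins > cfg$n_proteins)
    stop("n_planted_proteins must not exceed n_proteins")
  if (cfg$n_causal_snps > cfg$n_snps)
    stop("n_causal_snps must not exceed n_snps")
  if (cfg$n_contaminants > cfg$n_metabolites)
    stop("n_contaminants must not exceed n_metabolites")
  if (cfg$n_subpops < 1L) stop("n_subpops must be >= 1")
  if (cfg$fst_like_divergence < 0 || cfg$fst_like_divergence >= 1)
    stop("fst_like_divergence must be in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$causal_odds_ratio <= 0) stop("causal_odds_ratio must be > 0")
  structure(cfg, class = "synthetic_config")
}

group_factor <- function(cfg) {
  factor(rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
         levels = c("case", "control"))
}

#' Definition of a 48-protein spike-in calibration standard
#'
#' Mirrors the layout of the commercial UPS-2 dynamic-range standard:
#' 48 proteins in six abundance groups of eight, spanning 0.5 to 50,000
#' fmol (five orders of magnitude), measured in six replicates.
#'
#' @param amounts molar amount per abundance group (length-6 by default);
#'   recycled over groups of 8 proteins.
#' @param n_replicates replicate injections of the standard.
#' @return Object of class `spikein_standard` with `protein_ids`,
#'   `known_concentration` and `n_replicates`.
#' @export
spikein_standard <- function(amounts = c(50000, 5000, 500, 50, 5, 0.5),
                             n_replicates = 6L) {
  conc <- rep(amounts, each = 48L %/% length(amounts))
  if (length(conc) != 48L) stop("amounts must tile exactly 48 proteins")
  if (any(conc <= 0)) stop("known concentrations must be positive")
  if (max(conc) / min(conc) < 1e4)
    stop("standard must span at least 4 orders of magnitude")
  structure(list(
    protein_ids = sprintf("UPS%02d", seq_len(48L)),
    known_concentration = conc,
    n_replicates = as.integer(n_replicates)
  ), class = "spikein_standard")
}

#' Simulate a proteome with planted case/control effects
#'
#' Spectral counts are Poisson draws around a log-normal latent abundance
#' (so counts are integers while the matched LFQ intensity is the same
#' latent truth times a protein-specific response factor). Zeros are
#' structural: entries whose latent abundance falls below a global
#' detection threshold chosen at the configured `missing_rate` quantile are
#' censored in both the count and the intensity channel. A tenth of the
#' proteins are assigned a single unique peptide so the unicity filter has
#' something to remove.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `spc` (spectral counts, proteins x samples), `lfq`
#'   (intensities), `features` (protein_id, gene, length, unique_peptides),
#'   `groups`, and `truth` (planted flag, signed true log2 fold change).
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stream_seed(cfg$seed, "proteome"))
  p <- cfg$n_proteins
  n <- cfg$n_cases + cfg$n_controls
  groups <- group_factor(cfg)

  ids <- sprintf("P%04d", seq_len(p))
  genes <- sprintf("GENE%04d", seq_len(p))
  lengths <- sample(150:3000, p, replace = TRUE)
  unique_peptides <- 2L + stats::rpois(p, 3L)
  n_single <- max(0L, round(0.1 * p))
  if (n_single > 0L)
    unique_peptides[sample.int(p, n_single)] <- 1L

  truth_fc <- numeric(p)
  planted <- rep(FALSE, p)
  if (cfg$n_planted_proteins > 0L) {
    idx <- sample.int(p, cfg$n_planted_proteins)
    planted[idx] <- TRUE
    n_up <- ceiling(0.8 * cfg$n_planted_proteins)
    sign <- rep(c(1, -1), c(n_up, cfg$n_planted_proteins - n_up))
    truth_fc[idx] <- sign * cfg$planted_log2fc
  }

  mu <- stats::rnorm(p, mean = log(100), sd = 1.2)        # latent log scale
  sigma <- 0.5                                            # biological CV
  shift <- outer(truth_fc * log(2), as.numeric(groups == "case"))
  latent <- exp(mu + shift + matrix(stats::rnorm(p * n, 0, sigma), p, n))

  # structural censoring below a global detection threshold
  if (cfg$missing_rate > 0) {
    thr <- stats::quantile(latent, cfg$missing_rate)
    latent[latent < thr] <- 0
  }

  # counts large enough that Poisson zeros above the detection threshold
  # are rare: missingness is governed by the censoring, not the sampling
  count_scale <- 5 / min(latent[latent > 0])
  spc <- matrix(stats::rpois(p * n, latent * count_scale), p, n)
  spc[latent == 0] <- 0L
  response <- exp(stats::rnorm(p, log(1e4), 0.3))         # per-protein LFQ response
  lfq <- latent * response

  dimnames(spc) <- dimnames(lfq) <-
    list(ids, sprintf("S%03d", seq_len(n)))
  list(
    spc = spc, lfq = lfq,
    features = data.frame(protein_id = ids, gene = genes,
                          length = lengths,
                          unique_peptides = unique_peptides),
    groups = groups,
    truth = data.frame(protein_id = ids, planted = planted,
                       log2fc = truth_fc)
  )
}

#' Simulate replicate LFQ measurements of a spike-in standard
#'
#' Generates `log10(LFQ) = intercept + slope * log10(conc) + noise` for
#' every standard protein and replicate, the linear response on which the
#' calibration curve is fitted.
#'
#' @param std a [spikein_standard()].
#' @param slope,intercept response line in log10-log10 space.
#' @param noise_sd replicate noise (log10 units), `>= 0`.
#' @param seed integer seed.
#' @return numeric matrix, 48 proteins x `n_replicates`.
#' @export
generate_spikein_measurements <- function(std, slope = 1, intercept = 0,
                                          noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(std, "spikein_standard"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(std$known_concentration <= 0))
    stop("known concentrations must be positive")
  set.seed(stream_seed(seed, "spikein"))
  k <- length(std$protein_ids)
  r <- std$n_replicates
  log_mean <- intercept + slope * log10(std$known_concentration)
  lfq <- 10^(matrix(log_mean, k, r) + matrix(stats::rnorm(k * r, 0, noise_sd), k, r))
  dimnames(lfq) <- list(std$protein_ids, sprintf("rep%d", seq_len(r)))
  lfq
}

# Study-scale planted metabolite effects (log2): the magnitudes of the
# twelve group-specific compounds the pipeline is expected to recover.
default_metabolite_effects <- function() {
  c(-3.26, -2.30, -1.88, -1.86, -1.08, -0.35,
    0.67, 0.87, 1.04, 1.31, 2.44, 3.61)
}

#' Simulate an untargeted metabolome with planted effects and contaminants
#'
#' Endogenous features are log-normal with structural censoring as in
#' [generate_proteome()]. A planted subset carries the configured log2
#' fold changes. Contaminant features emulate medication-derived compounds:
#' they are detected predominantly in cases (85 percent of case samples vs
#' 5 percent of controls), which is what the exclusion stage must catch.
#'
#' @param cfg a [synthetic_config()].
#' @param planted_log2fc signed log2 effects for the planted endogenous
#'   features; defaults to the twelve study-scale magnitudes.
#' @return list with `intensity` (features x samples), `features`
#'   (feature_id, kegg_id, hmdb_id, is_contaminant), `groups`, `truth`,
#'   and `exclusion_list` (ids of the contaminant features, as a drug/non-
#'   endogenous reference list for the exclusion stage).
#' @export
generate_metabolome <- function(cfg, planted_log2fc = default_metabolite_effects()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stream_seed(cfg$seed, "metabolome"))
  m <- cfg$n_metabolites
  n <- cfg$n_cases + cfg$n_controls
  groups <- group_factor(cfg)
  n_planted <- length(planted_log2fc)
  if (n_planted + cfg$n_contaminants > m)
    stop("planted + contaminant features exceed n_metabolites")

  ids <- sprintf("M%05d", seq_len(m))
  kegg <- sprintf("C%05d", 90000L + seq_len(m))
  hmdb <- sprintf("HMDB%07d", 9000000L + seq_len(m))
  is_contaminant <- rep(FALSE, m)
  truth_fc <- numeric(m)
  planted <- rep(FALSE, m)

  idx_all <- sample.int(m, n_planted + cfg$n_contaminants)
  idx_planted <- idx_all[seq_len(n_planted)]
  idx_cont <- idx_all[-seq_len(n_planted)]
  planted[idx_planted] <- TRUE
  truth_fc[idx_planted] <- planted_log2fc
  is_contaminant[idx_cont] <- TRUE

  mu <- stats::rnorm(m, log(1e5), 1.5)
  shift <- outer(truth_fc * log(2), as.numeric(groups == "case"))
  intensity <- exp(mu + shift + matrix(stats::rnorm(m * n, 0, 0.5), m, n))
  if (cfg$missing_rate > 0) {
    thr <- stats::quantile(intensity, cfg$missing_rate)
    intensity[intensity < thr] <- 0
  }
  # contaminants: presence/absence dominated by group (medication artefact)
  if (length(idx_cont)) {
    p_detect <- ifelse(groups == "case", 0.85, 0.05)
    for (i in idx_cont) {
      present <- stats::rbinom(n, 1L, p_detect) == 1L
      intensity[i, ] <- ifelse(present, exp(stats::rnorm(n, log(5e4), 0.6)), 0)
    }
  }
  dimnames(intensity) <- list(ids, sprintf("S%03d", seq_len(n)))
  list(
    intensity = intensity,
    features = data.frame(feature_id = ids, kegg_id = kegg, hmdb_id = hmdb,
                          is_contaminant = is_contaminant),
    groups = groups,
    truth = data.frame(feature_id = ids, planted = planted, log2fc = truth_fc),
    exclusion_list = ids[is_contaminant]
  )
}

#' Simulate a case-control genotype panel with population structure
#'
#' Allele frequencies follow a Balding-Nichols model: an ancestral
#' frequency per variant, diverged per subpopulation with the configured
#' Fst-like parameter. Causal variants act multiplicatively on the odds of
#' being a case; the requested numbers of cases and controls are then
#' sampled from a larger simulated pool, as in a retrospective
#' case-control design. Genotype calls are set missing completely at
#' random at `missing_rate`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `genotypes` (samples x variants, 0/1/2/NA),
#'   `phenotype` (factor case/control), `subpop`, `variants`
#'   (snp_id, chrom, pos, gene, coding_region, causal, true_or) and
#'   `snp_gene_map`.
#' @export
generate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stream_seed(cfg$seed, "genotypes"))
  v <- cfg$n_snps
  n_target <- cfg$n_cases + cfg$n_controls
  f <- cfg$fst_like_divergence

  p0 <- stats::runif(v, 0.1, 0.9)
  pk <- matrix(p0, cfg$n_subpops, v, byrow = TRUE)
  if (f > 0 && cfg$n_subpops > 1L) {
    a <- p0 * (1 - f) / f
    b <- (1 - p0) * (1 - f) / f
    for (k in seq_len(cfg$n_subpops))
      pk[k, ] <- stats::rbeta(v, a, b)
  }

  causal <- rep(FALSE, v)
  if (cfg$n_causal_snps > 0L)
    causal[sample.int(v, cfg$n_causal_snps)] <- TRUE
  beta <- ifelse(causal, log(cfg$causal_odds_ratio), 0)

  pool <- 6L * n_target
  subpop_pool <- sample.int(cfg$n_subpops, pool, replace = TRUE)
  g_pool <- matrix(stats::rbinom(pool * v, 2L, pk[subpop_pool, ]), pool, v)
  eta <- drop(g_pool[, causal, drop = FALSE] %*% beta[causal])
  eta <- eta - mean(eta)                      # balanced baseline prevalence
  y_pool <- stats::rbinom(pool, 1L, stats::plogis(eta)) == 1L
  if (sum(y_pool) < cfg$n_cases || sum(!y_pool) < cfg$n_controls)
    stop("simulated pool too small for requested cohort sizes")
  take <- c(sample(which(y_pool), cfg$n_cases),
            sample(which(!y_pool), cfg$n_controls))
  genotypes <- g_pool[take, , drop = FALSE]
  subpop <- subpop_pool[take]
  phenotype <- factor(rep(c("case", "control"),
                          c(cfg$n_cases, cfg$n_controls)),
                      levels = c("case", "control"))

  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(genotypes)) < cfg$missing_rate
    genotypes[miss] <- NA_integer_
  }

  ids <- sprintf("rs%06d", seq_len(v))
  genes <- sprintf("SNPGENE%04d", seq_len(v))
  variants <- data.frame(
    snp_id = ids,
    chrom = sample(1:22, v, replace = TRUE),
    pos = sample.int(2e8, v),
    gene = genes,
    coding_region = stats::runif(v) < 0.4,
    causal = causal,
    true_or = ifelse(causal, cfg$causal_odds_ratio, 1)
  )
  dimnames(genotypes) <- list(sprintf("S%03d", seq_len(n_target)), ids)
  list(genotypes = genotypes, phenotype = phenotype, subpop = subpop,
       variants = variants,
       snp_gene_map = data.frame(snp_id = ids, gene = genes))
}

#' Simulate pathway-membership sets over synthetic identifiers
#'
#' Draws GMT-style pathway sets over the gene symbols and compound IDs of a
#' synthetic run so the integration stage can be exercised end to end.
#' Every identifier is placed in `1 + Poisson(0.6)` pathways, so
#' single-pathway elements (which become self-loops) occur alongside
#' multi-pathway ones.
#'
#' @param genes,compounds identifier vectors to distribute over pathways.
#' @param n_pathways number of pathway sets.
#' @param seed integer seed.
#' @return named list of member-id character vectors (a GMT in memory),
#'   with a `description` attribute.
#' @export
generate_pathways <- function(genes, compounds = character(),
                              n_pathways = 20L, seed = 1L) {
  set.seed(stream_seed(seed, "pathways"))
  ids <- c(genes, compounds)
  paths <- sprintf("path%03d", seq_len(n_pathways))
  sets <- stats::setNames(vector("list", n_pathways), paths)
  k <- pmin(1L + stats::rpois(length(ids), 0.6), n_pathways)
  for (i in seq_along(ids)) {
    for (p in sample(paths, k[i]))
      sets[[p]] <- c(sets[[p]], ids[i])
  }
  sets <- sets[vapply(sets, length, 1L) > 0L]
  attr(sets, "description") <- rep("synthetic pathway", length(sets))
  sets
}
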