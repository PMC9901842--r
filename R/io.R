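#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Emits a VCFv4.2 file with a single FORMAT field (`GT`), unphased
#' diploid calls and `./.` for missing genotypes — the minimal dialect the
#' association stage consumes.
#'
#' @param genotypes samples x variants 0/1/2 matrix with `NA` for missing.
#' @param variants data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param path output file.
#' @export
write_genotypes_vcf <- function(genotypes, variants, path) {
  g <- as.matrix(genotypes)
  stopifnot(nrow(variants) == ncol(g))
  samples <- rownames(g) %||% sprintf("S%03d", seq_len(nrow(g)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(g)), function(j) {
    calls <- ifelse(is.na(g[, j]), "./.", gt_code[as.character(g[, j])])
    paste(c(variants$chrom[j], variants$pos[j], variants$snp_id[j],
            "A", "G", ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read genotypes from a VCF into a dosage matrix
#'
#' Parses the GT field with \pkg{vcfR} and converts unphased or phased
#' diploid calls to 0/1/2 alternate-allele dosages (`NA` for missing).
#'
#' @param path VCF file.
#' @return list with `genotypes` (samples x variants) and `variants`
#'   (snp_id, chrom, pos).
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- function(s) {
    s <- gsub("|", "/", s, fixed = TRUE)
    ifelse(is.na(s) | s == "./.", NA_integer_,
           (substr(s, 1, 1) == "1") + (substr(s, 3, 3) == "1"))
  }
  g <- t(apply(gt, 1L, dose))
  g <- matrix(as.integer(g), nrow = nrow(gt),
              dimnames = list(rownames(gt), colnames(gt)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  list(genotypes = t(g),
       variants = data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                             pos = as.integer(fix$POS)))
}

# features-in-rows TSV with annotation columns first, sample columns after
write_feature_tsv <- function(values, annotations, path) {
  stopifnot(nrow(values) == nrow(annotations))
  utils::write.table(cbind(annotations, as.data.frame(values)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the synthetic proteome in the pipeline's TSV dialect
#' @param proteome a [generate_proteome()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_proteome_tsv <- function(proteome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("proteome_spc.tsv", "proteome_lfq.tsv",
                            "proteome_truth.tsv"))
  write_feature_tsv(proteome$spc, proteome$features, paths[1L])
  write_feature_tsv(proteome$lfq, proteome$features, paths[2L])
  utils::write.table(proteome$truth, paths[3L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write the synthetic metabolome in the pipeline's TSV dialect
#' @param metabolome a [generate_metabolome()] result.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_metabolome_tsv <- function(metabolome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("metabolome_intensity.tsv",
                            "metabolome_truth.tsv"))
  write_feature_tsv(metabolome$intensity, metabolome$features, paths[1L])
  utils::write.table(metabolome$truth, paths[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
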