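#' Simulate a biallelic SNP genotype panel
#'
#' Draws an individuals-by-SNPs matrix of additive genotype codes (0/1/2)
#' with every SNP guaranteed to have a realized minor allele frequency of at
#' least `maf_min`, mimicking the admissibility rule used for association
#' panels (analysis restricted to MAF >= 0.05). Optionally a k-subpopulation
#' allele-frequency divergence (F-model) is superimposed so that downstream
#' kinship/PC covariates have real structure to absorb.
#'
#' @param n_individuals number of lines (>= 2).
#' @param n_snps number of SNPs.
#' @param maf_min minimum realized minor allele frequency, in (0, 0.5).
#' @param n_chromosomes number of chromosomes positions are spread over.
#' @param n_subpops number of subpopulations (1 = unstructured panel).
#' @param fst divergence parameter of the F-model when `n_subpops > 1`.
#' @param chrom_length chromosome length in bp used to draw positions.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno` (n x m integer matrix, rows named by accession, columns by SNP id
#'   `chr<c>.s_<pos>`), `map` (data.frame with `snp`, `chrom`, `pos`),
#'   `maf` (realized minor allele frequencies), and `subpop` (assignment,
#'   when structured).
#' @examples
#' g <- simulate_genotypes(20, 50, maf_min = 0.1, seed = 1)
#' min(g$maf) >= 0.1
#' @export
simulate_genotypes <- function(n_individuals, n_snps, maf_min = 0.05,
                               n_chromosomes = 10, n_subpops = 1, fst = 0.1,
                               chrom_length = 3e8, seed = 1) {
  if (n_individuals < 2) stopf("'n_individuals' must be >= 2")
  if (n_snps < 1) stopf("'n_snps' must be >= 1")
  if (!is.numeric(maf_min) || maf_min <= 0 || maf_min >= 0.5)
    stopf("'maf_min' must lie strictly between 0 and 0.5")
  with_seed(seed, {
    subpop <- if (n_subpops > 1)
      sort(rep_len(seq_len(n_subpops), n_individuals)) else rep(1L, n_individuals)
    geno <- matrix(0L, n_individuals, n_snps)
    maf <- numeric(n_snps)
    for (j in seq_len(n_snps)) {
      repeat {
        p <- stats::runif(1, maf_min, 1 - maf_min)
        pk <- if (n_subpops > 1) {
          a <- p * (1 - fst) / fst
          b <- (1 - p) * (1 - fst) / fst
          stats::rbeta(n_subpops, a, b)
        } else p
        x <- stats::rbinom(n_individuals, 2L, pk[subpop])
        f <- mean(x) / 2
        m <- min(f, 1 - f)
        if (m >= maf_min && stats::var(x) > 0) break
      }
      geno[, j] <- x
      maf[j] <- m
    }
    # positions strictly increasing within chromosome
    chrom <- sort(rep_len(seq_len(n_chromosomes), n_snps))
    pos <- integer(n_snps)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      pos[idx] <- sort(sample.int(chrom_length, length(idx)))
    }
    snp <- sprintf("chr%d.s_%d", chrom, pos)
    dimnames(geno) <- list(sprintf("acc%03d", seq_len(n_individuals)), snp)
    structure(
      list(geno = geno,
           map = data.frame(snp = snp, chrom = chrom, pos = pos,
                            stringsAsFactors = FALSE),
           maf = stats::setNames(maf, snp),
           subpop = subpop,
           maf_min = maf_min, seed = seed),
      class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  cat(sprintf("  MAF range %.3f-%.3f (floor %.2f)\n",
              min(x$maf), max(x$maf), x$maf_min))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Write a genotype panel as plain-text VCF
#'
#' Minimal VCFv4.2 writer for simulated 0/1/2 panels (REF/ALT set to A/G,
#' unphased GT field only). Read back with [read_genotypes_vcf()].
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$geno; map <- genotypes$map
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(g)), function(j) {
    paste(c(map$chrom[j], map$pos[j], map$snp[j], "A", "G", ".", "PASS", ".",
            "GT", gt[g[, j] + 1L]), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=itrait",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a biallelic SNP VCF into a `genotype_matrix`
#'
#' Parsing is delegated to \pkg{vcfR}; genotypes are recoded to 0/1/2
#' alternate-allele dosage.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[] <- vapply(strsplit(gsub("\\|", "/", gt), "/"), function(a)
    sum(as.integer(a) > 0), integer(1))
  geno <- t(dose)
  f <- colMeans(geno) / 2
  map <- data.frame(snp = rownames(gt),
                    chrom = as.integer(v@fix[, "CHROM"]),
                    pos = as.integer(v@fix[, "POS"]),
                    stringsAsFactors = FALSE)
  structure(list(geno = geno, map = map,
                 maf = stats::setNames(pmin(f, 1 - f), rownames(gt)),
                 subpop = rep(1L, nrow(geno)), maf_min = 0, seed = NA),
            class = "genotype_matrix")
}

#' Write a genotype panel as HapMap-format text
#' @inheritParams write_genotypes_vcf
#' @return `path`, invisibly.
#' @export
write_genotypes_hapmap <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$geno; map <- genotypes$map
  code <- c("AA", "AG", "GG")
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 rownames(g)), collapse = "\t")
  body <- vapply(seq_len(ncol(g)), function(j) {
    paste(c(map$snp[j], "A/G", map$chrom[j], map$pos[j], "+", rep("NA", 6),
            code[g[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
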