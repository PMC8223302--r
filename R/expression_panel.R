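#' Simulate gene annotations along the genome of a genotype panel
#'
#' Places non-overlapping gene models on the chromosomes of an existing
#' panel so that local (within 10 kb) and distant eQTL geometries are both
#' available. About half of the genes are anchored near a SNP (guaranteeing
#' feasible local eQTLs); the rest are placed uniformly.
#'
#' @param genotypes a `genotype_matrix`.
#' @param n_genes number of genes.
#' @param gene_length gene span in bp.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_gene_annotations <- function(genotypes, n_genes = 50,
                                      gene_length = 3000, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  map <- genotypes$map
  with_seed(seed, {
    n_near <- ceiling(n_genes / 2)
    near_snp <- map[sample.int(nrow(map), min(n_near, nrow(map))), ]
    starts <- pmax(1L, near_snp$pos + sample(c(-1L, 1L), nrow(near_snp), TRUE) *
                     sample.int(8000L, nrow(near_snp), TRUE))
    chroms <- near_snp$chrom
    n_far <- n_genes - nrow(near_snp)
    if (n_far > 0) {
      chroms <- c(chroms, sample(unique(map$chrom), n_far, TRUE))
      starts <- c(starts, sample.int(max(map$pos), n_far, TRUE))
    }
    ann <- data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
                      chrom = chroms, start = starts,
                      end = starts + gene_length - 1L,
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      stringsAsFactors = FALSE)
    ann[order(ann$chrom, ann$start), ]
  })
}

#' Simulate an expression panel with planted local and distant eQTLs
#'
#' Expression of each gene is a baseline plus planted eQTL genotype effects
#' plus Gaussian noise, measured per accession under both WW and DS
#' conditions. A planted local eQTL SNP lies within the gene span plus a
#' 10-kb flank on either side; a distant eQTL SNP lies beyond it. Static
#' eQTLs are active under both conditions, dynamic ones under DS only.
#'
#' @param genotypes a `genotype_matrix`.
#' @param annotations gene table from [simulate_gene_annotations()] (columns
#'   `gene`, `chrom`, `start`, `end`).
#' @param n_local,n_distant number of planted local / distant eQTLs.
#' @param effect additive effect per alternate allele on expression.
#' @param prop_dynamic fraction of planted eQTLs active only under DS.
#' @param noise_sd residual standard deviation of expression.
#' @param flank_bp the local/distant boundary (default 10 kb, inclusive).
#' @param seed integer seed.
#' @return class `expression_panel`: list with `expression` (long data.frame:
#'   accession, gene, condition, value), `annotations`, `planted` (snp, gene,
#'   kind, active_ww, active_ds) and the geometry parameters.
#' @export
simulate_expression_panel <- function(genotypes, annotations, n_local = 2,
                                      n_distant = 2, effect = 2,
                                      prop_dynamic = 0, noise_sd = 1,
                                      flank_bp = 10000, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(annotations) == 0) stopf("'annotations' must be non-empty")
  map <- genotypes$map
  # geometry: candidate (snp, gene) pairs per kind
  pair_kind <- function(gene_row) {
    same <- map$chrom == gene_row$chrom
    inside <- same & map$pos >= gene_row$start - flank_bp &
      map$pos <= gene_row$end + flank_bp
    list(local = map$snp[inside], distant = map$snp[!inside])
  }
  with_seed(seed, {
    genes <- annotations[sample.int(nrow(annotations)), ]
    planted <- data.frame(snp = character(0), gene = character(0),
                          kind = character(0), stringsAsFactors = FALSE)
    used_genes <- character(0)
    take <- function(kind, n_want) {
      got <- 0L
      for (i in seq_len(nrow(genes))) {
        if (got == n_want) break
        gr <- genes[i, ]
        if (gr$gene %in% used_genes) next
        cand <- pair_kind(gr)[[kind]]
        if (length(cand) == 0) next
        planted <<- rbind(planted, data.frame(
          snp = cand[sample.int(length(cand), 1)], gene = gr$gene,
          kind = kind, stringsAsFactors = FALSE))
        used_genes <<- c(used_genes, gr$gene)
        got <- got + 1L
      }
      if (got < n_want)
        stopf("infeasible design: only %d of %d requested %s eQTLs have an admissible SNP/gene pair",
              got, n_want, kind)
    }
    if (n_local > 0) take("local", n_local)
    if (n_distant > 0) take("distant", n_distant)
    nq <- nrow(planted)
    dyn <- rep(FALSE, nq)
    if (nq > 0 && prop_dynamic > 0)
      dyn[sample.int(nq, round(prop_dynamic * nq))] <- TRUE
    planted$active_ww <- !dyn
    planted$active_ds <- TRUE

    acc <- rownames(genotypes$geno)
    baseline <- stats::setNames(stats::rnorm(nrow(annotations), 8, 1),
                                annotations$gene)
    grid <- expand.grid(accession = acc, gene = annotations$gene,
                        condition = c("WW", "DS"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$value <- baseline[grid$gene] + stats::rnorm(nrow(grid), sd = noise_sd)
    if (nq > 0) for (q in seq_len(nq)) {
      x <- genotypes$geno[, planted$snp[q]]
      for (cond in c("WW", "DS")) {
        if ((cond == "WW" && !planted$active_ww[q]) ||
            (cond == "DS" && !planted$active_ds[q])) next
        sel <- grid$gene == planted$gene[q] & grid$condition == cond
        grid$value[sel] <- grid$value[sel] + effect * x[match(grid$accession[sel], acc)]
      }
    }
    structure(list(expression = grid, annotations = annotations,
                   planted = planted, flank_bp = flank_bp,
                   genotypes = genotypes, effect = effect, seed = seed),
              class = "expression_panel")
  })
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d accessions x %d genes x WW/DS; %d planted eQTL(s)\n",
              length(unique(x$expression$accession)), nrow(x$annotations),
              nrow(x$planted)))
  invisible(x)
}

#' Write gene annotations as GFF3
#'
#' Serialization goes through \pkg{rtracklayer}.
#'
#' @param annotations data.frame with `gene`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(annotations, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stopf("writing GFF3 requires 'rtracklayer' and 'GenomicRanges'")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(annotations$chrom),
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand)
  gr$type <- "gene"
  gr$ID <- annotations$gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotations from GFF3
#' @param path path to a GFF3 file; `type == "gene"` rows are used.
#' @return data.frame with `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotations_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("reading GFF3 requires 'rtracklayer'")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  data.frame(gene = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
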