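#' Kinship matrix and population-structure covariates
#'
#' VanRaden centered-and-scaled cross-product kinship
#' `K = M M' / (2 * sum(p * (1 - p)))` with `M` the allele-frequency-centered
#' genotype matrix, plus the first `n_pcs` principal components of the
#' centered genotypes as structure covariates -- the Q and K of a Q+K mixed
#' linear model.
#'
#' @param genotypes a `genotype_matrix`.
#' @param n_pcs number of principal components (default 3).
#' @return list with `K` (n x n symmetric PSD matrix) and `Q`
#'   (n x n_pcs matrix of PCs).
#' @export
compute_kinship_and_pcs <- function(genotypes, n_pcs = 3) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$geno
  if (nrow(g) < 2 || ncol(g) < 1) stopf("need >= 2 individuals and >= 1 SNP")
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stopf("all SNPs are monomorphic")
  m <- sweep(g[, poly, drop = FALSE], 2, 2 * p[poly])
  K <- tcrossprod(m) / (2 * sum(p[poly] * (1 - p[poly])))
  K <- (K + t(K)) / 2
  n_pcs <- min(n_pcs, nrow(g) - 1, sum(poly))
  Q <- stats::prcomp(m, center = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  list(K = K, Q = Q)
}

## restricted log-likelihood of the single-random-effect model on rotated
## data; d = eigenvalues of K, delta = sigma2_e / sigma2_g
emma_reml_ll <- function(log_delta, d, yr, Xr) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xr, w * Xr)
  beta <- solve(XtWX, crossprod(Xr, w * yr))
  r <- yr - Xr %*% beta
  n <- length(yr); q <- ncol(Xr)
  rss <- sum(w * r^2)
  -0.5 * ((n - q) * log(rss) + sum(log(d + delta)) +
            determinant(XtWX, logarithm = TRUE)$modulus[1])
}

#' Mixed-linear-model association scan with P3D
#'
#' Q+K mixed model `y = Q alpha + x beta + u + e`, `u ~ N(0, sigma2_g K)`.
#' Variance components are estimated once by REML on the null (no-SNP)
#' model via the spectral decomposition of K (exact for a single random
#' effect) and then held fixed for every SNP test -- the uncompressed P3D
#' scheme. Each SNP is tested with a generalized-least-squares Wald t-test.
#' The significance threshold defaults to `1 / n_markers`. Phenotypic
#' variance explained is `beta^2 * var(x) / var(y) * 100`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param y named numeric phenotype vector (replicates pre-averaged per
#'   accession); names must match genotype rownames.
#' @param K,Q optional kinship and covariates from
#'   [compute_kinship_and_pcs()]; computed when omitted.
#' @param threshold significance threshold; default `1 / n_markers`.
#' @param n_pcs PCs used when `Q` is computed internally.
#' @return class `assoc_result`: data.frame with `snp`, `chrom`, `pos`,
#'   `beta`, `se`, `p`, `pve`, `significant`; attributes `threshold`,
#'   `vc` (delta, sigma2_g, sigma2_e), `skipped` (zero-variance SNP ids).
#' @export
mlm_scan <- function(genotypes, y, K = NULL, Q = NULL, threshold = NULL,
                     n_pcs = 3) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$geno
  if (is.null(names(y))) {
    if (length(y) != nrow(g)) stopf("y length does not match genotypes")
    names(y) <- rownames(g)
  }
  common <- intersect(rownames(g), names(y)[!is.na(y)])
  if (length(common) < 3) stopf("fewer than 3 phenotyped lines")
  g <- g[common, , drop = FALSE]
  y <- y[common]
  if (is.null(K) || is.null(Q)) {
    kq <- compute_kinship_and_pcs(genotypes, n_pcs)
    if (is.null(K)) K <- kq$K
    if (is.null(Q)) Q <- kq$Q
  }
  K <- K[common, common]
  Q <- Q[common, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = 1, Q)
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0))
    stopf("singular covariate configuration: covariate '%s' is redundant",
          colnames(X0)[qrX$pivot[qrX$rank + 1]])
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 1e-10)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X0)
  opt <- stats::optimize(emma_reml_ll, c(-12, 12), d = d, yr = yr, Xr = Xr,
                         maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  n <- length(y); q <- ncol(X0)
  XtWX <- crossprod(Xr, w * Xr)
  beta0 <- solve(XtWX, crossprod(Xr, w * yr))
  s2g <- sum(w * (yr - Xr %*% beta0)^2) / (n - q)
  vc <- list(delta = delta, sigma2_g = s2g, sigma2_e = s2g * delta)

  snp_var <- apply(g, 2, stats::var)
  keep <- snp_var > 0
  skipped <- colnames(g)[!keep]
  Gr <- crossprod(U, g[, keep, drop = FALSE])     # rotated SNPs
  WG <- w * Gr
  XtWG <- crossprod(Xr, WG)                        # q x m
  B <- solve(XtWX, XtWG)                           # q x m
  XtWy <- crossprod(Xr, w * yr)                    # q x 1
  gPg <- colSums(Gr * WG) - colSums(XtWG * B)
  gPy <- drop(crossprod(WG, yr)) - drop(crossprod(B, XtWy))
  yPy <- sum(w * yr^2) - drop(crossprod(XtWy, solve(XtWX, XtWy)))
  ok <- gPg > 1e-12
  beta <- se <- p <- rep(NA_real_, sum(keep))
  df <- n - q - 1
  beta[ok] <- gPy[ok] / gPg[ok]
  sigma2 <- pmax((yPy - beta^2 * gPg) / df, 0)
  se[ok] <- sqrt(sigma2[ok] / gPg[ok])
  tt <- beta / se
  p[ok] <- 2 * stats::pt(-abs(tt[ok]), df)
  p[ok] <- pmax(p[ok], .Machine$double.xmin)  # keep p in (0, 1]
  if (is.null(threshold)) threshold <- gwas_threshold(ncol(g))
  map <- genotypes$map[match(colnames(g)[keep], genotypes$map$snp), ]
  pve <- 100 * beta^2 * snp_var[keep] / stats::var(y)
  res <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                    beta = beta, se = se, p = p,
                    pve = pmin(pmax(pve, 0), 100),
                    significant = !is.na(p) & p <= threshold,
                    stringsAsFactors = FALSE)
  structure(res, class = c("assoc_result", "data.frame"),
            threshold = threshold, vc = vc, skipped = skipped, n = n)
}

#' @export
print.assoc_result <- function(x, ...) {
  vc <- attr(x, "vc")
  if (is.null(vc)) return(invisible(print.data.frame(x, ...)))
  cat(sprintf("assoc_result: %d SNPs tested on %d lines, threshold %.3g, %d significant\n",
              nrow(x), attr(x, "n"), attr(x, "threshold"),
              sum(x$significant)))
  cat(sprintf("  P3D components: sigma2_g = %.3g, sigma2_e = %.3g (delta = %.3g)\n",
              vc$sigma2_g, vc$sigma2_e, vc$delta))
  invisible(x)
}

#' Merge significant SNPs into QTL intervals
#'
#' Transitive closure of the "within `window` bp" adjacency relation per
#' chromosome: adjacent significant SNPs no more than 100 kb apart (by
#' default) are merged, repeatedly, until no more merging is possible; each
#' cluster is reported as `[min_pos - window, max_pos + window]` floored at
#' 1, with member SNPs and supporting traits unioned.
#'
#' @param snps data.frame with `snp`, `chrom`, `pos` (and optionally
#'   `trait`) -- typically the significant rows of an `assoc_result`.
#' @param window flank/merge distance in bp (default 100000).
#' @return data.frame of class `qtl_intervals`: `chrom`, `start`, `end`,
#'   `n_snps`, `snps` (comma-joined), `traits` (comma-joined union).
#' @export
merge_qtls <- function(snps, window = 100000) {
  if (nrow(snps) == 0)
    return(structure(data.frame(chrom = integer(0), start = integer(0),
                                end = integer(0), n_snps = integer(0),
                                snps = character(0), traits = character(0)),
                     class = c("qtl_intervals", "data.frame")))
  if (!"trait" %in% names(snps)) snps$trait <- NA_character_
  out <- list()
  for (cc in unique(snps$chrom)) {
    s <- snps[snps$chrom == cc, ]
    s <- s[order(s$pos), ]
    grp <- cumsum(c(1, diff(s$pos) > window))
    for (gg in unique(grp)) {
      m <- s[grp == gg, ]
      out[[length(out) + 1]] <- data.frame(
        chrom = cc, start = max(1, min(m$pos) - window),
        end = max(m$pos) + window, n_snps = nrow(m),
        snps = paste(unique(m$snp), collapse = ","),
        traits = paste(sort(unique(stats::na.omit(m$trait))), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  structure(res, class = c("qtl_intervals", "data.frame"))
}

#' Assign candidate genes to significant SNPs
#'
#' A gene is a candidate if and only if a significant SNP lies within its
#' span (1-based inclusive at both ends); a SNP overlapping several genes
#' yields all of them. Overlap is computed with \pkg{IRanges}.
#'
#' @param snps data.frame with `snp`, `chrom`, `pos`.
#' @param annotations gene table (`gene`, `chrom`, `start`, `end`) or a path
#'   to a GFF3 file. Rows with missing/invalid coordinates are skipped with
#'   a warning.
#' @return data.frame with `snp`, `chrom`, `pos`, `gene`.
#' @export
assign_candidate_genes <- function(snps, annotations) {
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- read_annotations_gff3(annotations)
  bad <- !is.finite(annotations$start) | !is.finite(annotations$end) |
    annotations$end < annotations$start
  if (any(bad)) {
    warnf("skipping %d malformed annotation row(s)", sum(bad))
    annotations <- annotations[!bad, ]
  }
  hits <- list()
  for (cc in unique(snps$chrom)) {
    s <- snps[snps$chrom == cc, ]
    a <- annotations[annotations$chrom == cc, ]
    if (nrow(s) == 0 || nrow(a) == 0) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(s$pos, s$pos),
                                IRanges::IRanges(a$start, a$end))
    if (length(ov) == 0) next
    hits[[length(hits) + 1]] <- data.frame(
      snp = s$snp[S4Vectors_from(ov)], chrom = cc,
      pos = s$pos[S4Vectors_from(ov)],
      gene = a$gene[S4Vectors_to(ov)], stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(snp = character(0), chrom = integer(0),
                      pos = integer(0), gene = character(0)))
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}

# Hits accessors live in S4Vectors (a hard dependency of IRanges)
S4Vectors_from <- function(ov) S4Vectors::from(ov)
S4Vectors_to <- function(ov) S4Vectors::to(ov)

#' Linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the additive genotype codings, with
#' pairwise deletion of missing values. Zero variance in either column
#' yields `NA`.
#'
#' @param snp_a,snp_b numeric genotype vectors on the same individuals.
#' @return `r^2` in `[0, 1]`, or `NA` when undefined.
#' @export
compute_ld_r2 <- function(snp_a, snp_b) {
  ok <- !is.na(snp_a) & !is.na(snp_b)
  a <- snp_a[ok]; b <- snp_b[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0)
    return(NA_real_)
  stats::cor(a, b)^2
}

#' Map expression QTLs and classify them local/distant, static/dynamic
#'
#' For every gene and condition (WW, DS) the expression values are scanned
#' with the P3D mixed model; SNPs at or below the threshold (default
#' `1 / n_markers`) are eQTLs. Per gene, the most significant SNP determines
#' the geometric label: local when it lies within the gene span plus a
#' 10-kb flank on either side (inclusive window boundary), distant
#' otherwise. A gene's eQTL is static when significant under both
#' conditions, dynamic when significant under exactly one.
#'
#' @param genotypes a `genotype_matrix`.
#' @param expression an `expression_panel` or long data.frame
#'   (`accession`, `gene`, `condition`, `value`).
#' @param annotations gene table; genes missing from it are skipped with a
#'   warning.
#' @param threshold significance threshold; default `1 / n_markers`.
#' @param flank_bp local/distant boundary (default 10000).
#' @param K,Q optional precomputed kinship/covariates.
#' @return data.frame of class `eqtl_records`: `gene`, `snp`, `chrom`,
#'   `pos`, `p_WW`, `p_DS`, `conditions`, `kind` (local/distant),
#'   `dynamics` (static/dynamic).
#' @export
map_eqtls <- function(genotypes, expression, annotations, threshold = NULL,
                      flank_bp = 10000, K = NULL, Q = NULL) {
  if (inherits(expression, "expression_panel")) {
    if (missing(annotations) || is.null(annotations))
      annotations <- expression$annotations
    expression <- expression$expression
  }
  if (is.null(threshold)) threshold <- gwas_threshold(ncol(genotypes$geno))
  if (is.null(K) || is.null(Q)) {
    kq <- compute_kinship_and_pcs(genotypes)
    K <- kq$K; Q <- kq$Q
  }
  recs <- list()
  for (gene in unique(expression$gene)) {
    ann <- annotations[annotations$gene == gene, ]
    if (nrow(ann) == 0) {
      warnf("gene '%s' absent from annotations: skipped", gene)
      next
    }
    per_cond <- list()
    for (cond in c("WW", "DS")) {
      e <- expression[expression$gene == gene & expression$condition == cond, ]
      if (nrow(e) == 0) next
      y <- tapply(e$value, e$accession, mean)
      scan <- mlm_scan(genotypes, y, K = K, Q = Q, threshold = threshold)
      hit <- scan[scan$significant, ]
      per_cond[[cond]] <- if (nrow(hit)) hit[which.min(hit$p), ] else NULL
    }
    sig_conds <- names(per_cond)[!vapply(per_cond, is.null, logical(1))]
    if (length(sig_conds) == 0) next
    best <- do.call(rbind, per_cond[sig_conds])
    top <- best[which.min(best$p), ]
    local <- top$chrom == ann$chrom &&
      top$pos >= ann$start - flank_bp && top$pos <= ann$end + flank_bp
    recs[[length(recs) + 1]] <- data.frame(
      gene = gene, snp = top$snp, chrom = top$chrom, pos = top$pos,
      p_WW = if ("WW" %in% sig_conds) per_cond$WW$p else NA_real_,
      p_DS = if ("DS" %in% sig_conds) per_cond$DS$p else NA_real_,
      conditions = paste(sig_conds, collapse = "+"),
      kind = if (local) "local" else "distant",
      dynamics = if (length(sig_conds) == 2) "static" else "dynamic",
      stringsAsFactors = FALSE)
  }
  res <- if (length(recs)) do.call(rbind, recs)
  else data.frame(gene = character(0), snp = character(0),
                  chrom = integer(0), pos = integer(0), p_WW = numeric(0),
                  p_DS = numeric(0), conditions = character(0),
                  kind = character(0), dynamics = character(0))
  structure(res, class = c("eqtl_records", "data.frame"),
            threshold = threshold, flank_bp = flank_bp)
}
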