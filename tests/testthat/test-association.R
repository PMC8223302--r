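test_that("kinship matches the hand-computed VanRaden cross-product", {
  mat <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 1, 1,
                  0, 2, 1), nrow = 3)
  g <- make_geno(mat)
  kq <- compute_kinship_and_pcs(g, n_pcs = 2)
  p <- colMeans(mat) / 2
  m <- sweep(mat, 2, 2 * p)
  K_oracle <- tcrossprod(m) / (2 * sum(p * (1 - p)))
  expect_equal(unname(kq$K), unname(K_oracle))
  expect_true(isSymmetric(kq$K))
  expect_true(all(eigen(kq$K, only.values = TRUE)$values > -1e-10))

  # duplicated individuals: off-diagonal equals their shared diagonal,
  # the maximal relatedness attainable for that genotype
  dup <- make_geno(rbind(mat, mat[1, ]))
  Kd <- compute_kinship_and_pcs(dup, n_pcs = 1)$K
  expect_equal(Kd[1, 4], Kd[1, 1])
  expect_equal(Kd[1, 4], Kd[4, 4])
  expect_equal(unname(Kd[1, 4]), max(Kd[1, ]))   # no one more related than the clone

  mono <- make_geno(matrix(2, 4, 3))
  expect_error(compute_kinship_and_pcs(mono), "monomorphic")
  expect_equal(formals(compute_kinship_and_pcs)$n_pcs, 3)
})

test_that("threshold arithmetic follows p = 1/n and prints as 1.8e-6", {
  expect_equal(gwas_threshold(558650) * 558650, 1)
  expect_equal(signif(gwas_threshold(558650), 2), 1.8e-6)
  for (n in c(100, 5000, 1250000))
    expect_equal(gwas_threshold(n) * n, 1)
})

test_that("the P3D scan detects a planted SNP and skips degenerate ones", {
  g <- fixture_geno()
  p <- simulate_trait_panel(g, h2 = 0.5, r = 2, n_causal = 1,
                            causal_share = 0.8, seed = 21)
  y <- accession_means(p, "WW")
  kq <- compute_kinship_and_pcs(g)
  scan <- mlm_scan(g, y, K = kq$K, Q = kq$Q)
  expect_equal(nrow(scan), 300)
  expect_true(all(scan$p > 0 & scan$p <= 1))
  expect_true(all(scan$pve >= 0 & scan$pve <= 100))
  expect_equal(attr(scan, "threshold"), 1 / 300)
  expect_equal(scan$snp[which.min(scan$p)], p$causal$snp)

  # zero-variance SNP is skipped and logged
  gm <- g$geno
  gm[, 5] <- 1L
  g2 <- make_geno(gm, g$map$chrom, g$map$pos)
  scan2 <- mlm_scan(g2, y, K = kq$K, Q = kq$Q)
  expect_equal(attr(scan2, "skipped"), colnames(gm)[5])
  expect_equal(nrow(scan2), 299)
})

test_that("singular covariates are rejected with a named error", {
  g <- fixture_geno()
  y <- rnorm(120)
  names(y) <- rownames(g$geno)
  kq <- compute_kinship_and_pcs(g)
  Qbad <- cbind(kq$Q, dupcol = kq$Q[, 1])
  expect_error(mlm_scan(g, y, K = kq$K, Q = Qbad), "singular covariate")
})

test_that("QTL merging applies the 100-kb rule transitively", {
  one <- data.frame(snp = "s1", chrom = 1L, pos = 1000000L)
  q1 <- merge_qtls(one)
  expect_equal(q1$start, 900000)
  expect_equal(q1$end, 1100000)

  two <- data.frame(snp = c("s1", "s2"), chrom = 1L,
                    pos = c(1000000L, 1050000L))
  q2 <- merge_qtls(two)
  expect_equal(nrow(q2), 1)
  expect_equal(c(q2$start, q2$end), c(900000, 1150000))

  chain <- data.frame(snp = paste0("s", 1:3), chrom = 1L,
                      pos = c(0, 90000, 180000) + 1L)
  expect_equal(nrow(merge_qtls(chain)), 1)      # transitive closure
  gap <- data.frame(snp = c("s1", "s2"), chrom = 1L, pos = c(1L, 101001L))
  expect_equal(nrow(merge_qtls(gap)), 2)
  # flooring at position 1
  expect_equal(merge_qtls(data.frame(snp = "s", chrom = 2L, pos = 50L))$start, 1)
})

test_that("QTL merging equals the brute-force union-find closure", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    snps <- data.frame(snp = paste0("s", 1:n),
                       chrom = sample(1:3, n, TRUE),
                       pos = sample.int(2e6, n))
    got <- merge_qtls(snps)
    oracle <- brute_merge_qtls(snps)
    expect_equal(got[, c("chrom", "start", "end", "n_snps")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("candidate genes require a SNP inside the inclusive gene span", {
  ann <- data.frame(gene = c("g1", "g2"), chrom = 1L,
                    start = c(1000L, 1800L), end = c(2000L, 2500L),
                    strand = "+")
  hits <- assign_candidate_genes(
    data.frame(snp = c("a", "b", "c"), chrom = 1L,
               pos = c(1500L, 2001L, 5000L)), ann)
  expect_setequal(hits$gene[hits$snp == "a"], "g1")
  expect_setequal(hits$gene[hits$snp == "b"], c("g2"))  # 2001 outside g1
  expect_false("c" %in% hits$snp)
  # multi-overlap yields all genes
  h2 <- assign_candidate_genes(
    data.frame(snp = "d", chrom = 1L, pos = 1900L), ann)
  expect_setequal(h2$gene, c("g1", "g2"))
  expect_warning(assign_candidate_genes(
    data.frame(snp = "a", chrom = 1L, pos = 10L),
    data.frame(gene = "bad", chrom = 1L, start = 100L, end = 50L,
               strand = "+")), "malformed")
})

test_that("gene assignment equals a brute-force interval lookup", {
  set.seed(31)
  ann <- data.frame(gene = paste0("g", 1:40), chrom = sample(1:2, 40, TRUE),
                    start = sample.int(1e6, 40), strand = "+")
  ann$end <- ann$start + sample.int(5000, 40)
  snps <- data.frame(snp = paste0("s", 1:200), chrom = sample(1:2, 200, TRUE),
                     pos = sample.int(1e6, 200))
  got <- assign_candidate_genes(snps, ann)
  oracle <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    sel <- ann$chrom == snps$chrom[i] & ann$start <= snps$pos[i] &
      ann$end >= snps$pos[i]
    if (!any(sel)) return(NULL)
    data.frame(snp = snps$snp[i], gene = ann$gene[sel])
  }))
  key <- function(d) sort(paste(d$snp, d$gene))
  expect_equal(key(got), key(oracle))
})

test_that("LD r2 is symmetric, coding-invariant, and guarded", {
  set.seed(17)
  a <- rbinom(200, 2, 0.4); b <- rbinom(200, 2, 0.3)
  expect_equal(compute_ld_r2(a, a), 1)
  expect_equal(compute_ld_r2(a, b), compute_ld_r2(b, a))
  expect_equal(compute_ld_r2(a, b), compute_ld_r2(2 - a, b))  # allele flip
  expect_equal(compute_ld_r2(a, b), cor(a, b)^2)
  expect_true(is.na(compute_ld_r2(a, rep(1, 200))))
  big_a <- rbinom(1e4, 2, 0.5); big_b <- rbinom(1e4, 2, 0.5)
  expect_lt(compute_ld_r2(big_a, big_b), 0.01)
})

test_that("eQTL mapping recovers planted geometry and dynamics", {
  g <- fixture_geno()
  ann <- simulate_gene_annotations(g, n_genes = 12, seed = 2)
  ep <- simulate_expression_panel(g, ann, n_local = 1, n_distant = 1,
                                  effect = 4, prop_dynamic = 0, seed = 3)
  eq <- map_eqtls(g, ep, threshold = 1e-8)
  loc <- ep$planted[ep$planted$kind == "local", ]
  dis <- ep$planted[ep$planted$kind == "distant", ]
  expect_true(loc$gene %in% eq$gene)
  expect_equal(eq$kind[eq$gene == loc$gene], "local")
  expect_equal(eq$dynamics[eq$gene == loc$gene], "static")
  expect_equal(eq$kind[eq$gene == dis$gene], "distant")

  ep2 <- simulate_expression_panel(g, ann, n_local = 0, n_distant = 1,
                                   effect = 4, prop_dynamic = 1, seed = 5)
  eq2 <- map_eqtls(g, ep2, threshold = 1e-8)
  dg <- ep2$planted$gene[1]
  expect_equal(eq2$dynamics[eq2$gene == dg], "dynamic")
  expect_equal(eq2$conditions[eq2$gene == dg], "DS")
})

test_that("the local window boundary at gene start minus 10 kb is inclusive", {
  set.seed(23)
  # target SNP at the window edge plus unlinked background SNPs, so the
  # kinship/PC covariates do not alias the tested marker
  mat <- cbind(rbinom(80, 2, 0.5),
               matrix(rbinom(80 * 30, 2, 0.5), 80, 30))
  g <- make_geno(mat, chrom = rep(1L, 31),
                 pos = c(40000L, seq(500000L, by = 10000L, length.out = 30)))
  ann <- data.frame(gene = "gX", chrom = 1L, start = 50000L, end = 53000L,
                    strand = "+")
  expr <- data.frame(accession = rep(rownames(g$geno), 2),
                     gene = "gX",
                     condition = rep(c("WW", "DS"), each = 80),
                     value = rep(5 + 3 * mat[, 1], 2) + rnorm(160, sd = 0.3))
  eq <- map_eqtls(g, expr, ann, threshold = 1e-4)
  expect_equal(nrow(eq), 1)
  expect_equal(eq$snp, g$map$snp[1])
  expect_equal(eq$kind, "local")   # pos 40000 == start - 10000, inclusive
})
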