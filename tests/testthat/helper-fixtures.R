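# shared fixtures, built once per test session

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default phantom scan triplet (also reconstructed slice), reused across
# the imaging tests
fixture_scan <- function() cached("scan", function() {
  make_image_phantoms(phantom_spec(seed = 5))
})

fixture_recon <- function() cached("recon", function() {
  reconstruct_slice(fixture_scan()$sinogram)
})

# small structured genotype panel shared by association/prediction tests
fixture_geno <- function() cached("geno", function() {
  simulate_genotypes(120, 300, maf_min = 0.05, n_chromosomes = 5, seed = 11)
})

# hand-built genotype_matrix for toy cases
make_geno <- function(mat, chrom = NULL, pos = NULL) {
  n <- nrow(mat); m <- ncol(mat)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  snp <- sprintf("chr%d.s_%d", chrom, pos)
  dimnames(mat) <- list(sprintf("acc%03d", seq_len(n)), snp)
  f <- colMeans(mat) / 2
  structure(list(geno = mat,
                 map = data.frame(snp = snp, chrom = chrom, pos = pos,
                                  stringsAsFactors = FALSE),
                 maf = stats::setNames(pmin(f, 1 - f), snp),
                 subpop = rep(1L, n), maf_min = 0, seed = NA),
            class = "genotype_matrix")
}

# solid-color test view (H x W x 3) with a rectangular green plant
green_rect_view <- function(h = 80, w = 60, top = 11, left = 21,
                            rect_h = 50, rect_w = 20) {
  img <- array(1, c(h, w, 3))
  img[top:(top + rect_h - 1), left:(left + rect_w - 1), 1] <- 0.1
  img[top:(top + rect_h - 1), left:(left + rect_w - 1), 2] <- 0.8
  img[top:(top + rect_h - 1), left:(left + rect_w - 1), 3] <- 0.1
  img
}

# long trait records for one simulated panel
panel_records <- function(panel, modality, trait, time) {
  r <- panel$traits
  r$modality <- modality; r$trait <- trait; r$time <- time
  r
}

# brute-force transitive-closure QTL merging oracle (union-find)
brute_merge_qtls <- function(snps, window = 100000) {
  out <- list()
  for (cc in unique(snps$chrom)) {
    s <- snps[snps$chrom == cc, ]
    n <- nrow(s)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n))
      if (abs(s$pos[i] - s$pos[j]) <= window)
        parent[find(i)] <- find(j)
    grp <- vapply(seq_len(n), find, integer(1))
    for (gg in unique(grp)) {
      m <- s[grp == gg, ]
      out[[length(out) + 1]] <- data.frame(
        chrom = cc, start = max(1, min(m$pos) - window),
        end = max(m$pos) + window, n_snps = nrow(m))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), c("chrom", "start", "end", "n_snps")]
}
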