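#' Simulate a replicated WW/DS trait panel with known heritability
#'
#' Builds i-trait-like phenotypes as genotype effect + treatment effect +
#' replicate noise. The trait value of accession i, replicate k is
#' `g_i + e_ik` under well-watered (WW) conditions and
#' `g_i + treatment_effect + d_i + e_ik` under drought stress (DS), where
#' `g_i` is the genetic value (a causal-SNP part plus a polygenic part),
#' `d_i` is a genotype-dependent drought response carried by the causal SNPs
#' (so that DS/WW ratio traits carry real signal), and `e_ik` is replicate
#' noise. Variances are set analytically, not estimated: the genetic values
#' are rescaled so that their realized variance is `sigma2_G` and the noise
#' variance solves `h2 = sigma2_G / (sigma2_G + sigma2_e / r)` exactly.
#' Broad-sense heritability on this construction is therefore `h2` by
#' identity, which downstream [estimate_heritability()] should recover.
#'
#' @param genotypes a [simulate_genotypes()] panel.
#' @param h2 target broad-sense heritability in `[0, 1]`. `h2 = 0` gives a
#'   pure-noise trait (all genetic deviations zero); `h2 = 1` gives zero
#'   replicate noise.
#' @param r number of replicates per accession x treatment (>= 1).
#' @param n_causal number of causal SNPs (0 = polygenic background only).
#' @param causal_share fraction of the genetic variance carried by the causal
#'   SNPs (the rest is an accession-level polygenic deviation). With
#'   `n_causal = 1` the planted SNP explains about `causal_share * h2` of the
#'   phenotypic variance of accession means.
#' @param treatment_effect mean shift of DS values relative to WW.
#' @param drought_effect_sd standard deviation of per-causal-SNP
#'   genotype-dependent drought effects (0 = none).
#' @param n_timepoints number of time points in the design.
#' @param noise `"gaussian"` (default) or `"heavy"` (t with 3 df, rescaled to
#'   the same variance) to exercise outlier filtering.
#' @param polygenic `"genomic"` (default) builds the non-causal genetic part
#'   as an infinitesimal sum of small effects over all SNPs, so it is fully
#'   borne by the kinship matrix; `"iid"` draws it as an independent
#'   accession-level deviation unrelated to the genotypes.
#' @param seed integer seed.
#' @return An object of class `simulated_panel`: list with `traits` (long
#'   data.frame: accession, replicate, treatment, time, value), `causal`
#'   (data.frame snp/beta/drought delta), `sigma2_G`, `sigma2_e`, `true_h2`,
#'   `r`, `genotypes` and the arguments.
#' @export
simulate_trait_panel <- function(genotypes, h2 = 0.4, r = 2, n_causal = 5,
                                 causal_share = 0.5, treatment_effect = 0,
                                 drought_effect_sd = 0, n_timepoints = 1,
                                 noise = c("gaussian", "heavy"),
                                 polygenic = c("genomic", "iid"), seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  noise <- match.arg(noise)
  polygenic <- match.arg(polygenic)
  if (h2 < 0 || h2 > 1) stopf("'h2' must lie in [0, 1]")
  if (r < 1) stopf("'r' must be >= 1")
  if (n_causal > ncol(genotypes$geno))
    stopf("n_causal (%d) exceeds the number of SNPs (%d)",
          n_causal, ncol(genotypes$geno))
  n <- nrow(genotypes$geno)
  with_seed(seed, {
    causal_idx <- if (n_causal > 0)
      sort(sample.int(ncol(genotypes$geno), n_causal)) else integer(0)
    beta <- if (n_causal > 0) stats::rnorm(n_causal) else numeric(0)
    g <- numeric(n)
    if (h2 > 0) {
      gc <- if (n_causal > 0) drop(genotypes$geno[, causal_idx, drop = FALSE] %*% beta)
            else numeric(n)
      if (n_causal > 0 && stats::var(gc) > 0)
        gc <- gc * sqrt(causal_share / stats::var(gc))
      gp <- if (polygenic == "genomic")
        drop(genotypes$geno %*% stats::rnorm(ncol(genotypes$geno)))
      else stats::rnorm(n)
      gp <- gp * sqrt(max(0, 1 - causal_share * (n_causal > 0)) / stats::var(gp))
      g <- gc + gp
      g <- (g - mean(g)) * sqrt(1 / stats::var(g))  # realized var exactly 1
    }
    sigma2_G <- if (h2 > 0) stats::var(g) else 0   # 1 by construction
    sigma2_e <- if (h2 == 0) 1 else r * sigma2_G * (1 - h2) / h2
    delta <- if (n_causal > 0 && drought_effect_sd > 0)
      stats::rnorm(n_causal, sd = drought_effect_sd) else rep(0, max(n_causal, 0))
    d <- if (n_causal > 0)
      drop(genotypes$geno[, causal_idx, drop = FALSE] %*% delta) else rep(0, n)

    acc <- rownames(genotypes$geno)
    grid <- expand.grid(accession = acc, replicate = seq_len(r),
                        treatment = c("WW", "DS"), time = seq_len(n_timepoints),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ne <- nrow(grid)
    e <- if (noise == "gaussian") stats::rnorm(ne, sd = sqrt(sigma2_e))
         else stats::rt(ne, df = 3) / sqrt(3) * sqrt(sigma2_e)
    gi <- g[match(grid$accession, acc)]
    di <- d[match(grid$accession, acc)]
    grid$value <- gi + e +
      ifelse(grid$treatment == "DS", treatment_effect + di, 0)
    structure(
      list(traits = grid,
           causal = data.frame(snp = colnames(genotypes$geno)[causal_idx],
                               beta = beta, drought_delta = delta,
                               stringsAsFactors = FALSE),
           genetic_values = stats::setNames(g, acc),
           sigma2_G = sigma2_G, sigma2_e = sigma2_e,
           true_h2 = if (sigma2_G == 0) 0 else
             sigma2_G / (sigma2_G + sigma2_e / r),
           r = r, treatment_effect = treatment_effect,
           genotypes = genotypes, seed = seed),
      class = "simulated_panel")
  })
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat(sprintf(paste0("simulated_panel: %d accessions x %d replicate(s) x ",
                     "WW/DS, H2 = %.3f (sigma2_G = %.3g, sigma2_e = %.3g)\n"),
              length(unique(x$traits$accession)), x$r, x$true_h2,
              x$sigma2_G, x$sigma2_e))
  invisible(x)
}

#' Accession means of a simulated panel
#'
#' Averages replicates per accession for one treatment arm (and optionally
#' one time point) -- the phenotype form consumed by [mlm_scan()].
#'
#' @param panel a `simulated_panel`.
#' @param treatment `"WW"`, `"DS"`, or `"ratio"` (DS mean / WW mean).
#' @param time time point (default 1).
#' @return named numeric vector, one entry per accession.
#' @export
accession_means <- function(panel, treatment = "WW", time = 1) {
  stopifnot(inherits(panel, "simulated_panel"))
  tr <- panel$traits[panel$traits$time == time, ]
  agg <- function(cond) {
    s <- tr[tr$treatment == cond, ]
    tapply(s$value, s$accession, mean)
  }
  out <- switch(treatment,
                WW = agg("WW"), DS = agg("DS"),
                ratio = agg("DS") / agg("WW"),
                stopf("unknown treatment '%s'", treatment))
  out[order(names(out))]
}
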