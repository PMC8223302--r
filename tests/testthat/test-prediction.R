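test_that("RR-BLUP with fixed lambda equals the closed-form ridge solution", {
  set.seed(1)
  Z <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50)
  y <- rnorm(20) + Z[, 3] - 0.5 * Z[, 10]
  for (lambda in c(0.5, 5, 50)) {
    fit <- fit_rrblup(Z, y, lambda = lambda)
    Zc <- sweep(Z, 2, colMeans(Z))
    V <- tcrossprod(Zc) + diag(lambda, 20)
    v1 <- solve(V, rep(1, 20))
    mu <- sum(v1 * y) / sum(v1)
    u_oracle <- solve(crossprod(Zc) + diag(lambda, 50),
                      crossprod(Zc, y - mu))
    expect_lt(max(abs(fit$effects - u_oracle)), 1e-8)
    expect_equal(fit$mu, mu, tolerance = 1e-10)
  }
})

test_that("RR-BLUP interpolates noiseless marker phenotypes", {
  set.seed(2)
  Z <- matrix(rbinom(40 * 15, 2, 0.4), 40, 15)
  beta <- rnorm(15)
  y <- 3 + drop(Z %*% beta)
  fit <- fit_rrblup(Z, y, lambda = 1e-8)
  expect_lt(max(abs(predict(fit, Z) - y)), 1e-6)

  # zero-variance marker gets effect exactly 0
  Z0 <- cbind(Z, const = 1)
  f0 <- fit_rrblup(Z0, y, lambda = 1)
  expect_equal(unname(f0$effects["const"]), 0)

  # constant phenotype degenerates to the mean
  fc <- fit_rrblup(Z, rep(4, 40))
  expect_equal(unname(predict(fc, Z)), rep(4, 40))
  expect_true(all(fc$effects == 0))
})

test_that("Bayes A is seed-reproducible and validates its priors", {
  set.seed(3)
  Z <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20)
  y <- drop(Z %*% rnorm(20, sd = 0.5)) + rnorm(50)
  a <- fit_bayes_a(Z, y, niter = 600, burnin = 200, seed = 11)
  b <- fit_bayes_a(Z, y, niter = 600, burnin = 200, seed = 11)
  expect_identical(a$effects, b$effects)
  expect_error(fit_bayes_a(Z, y, df_prior = -1), "positive")
  expect_error(fit_bayes_a(Z, y, scale_prior = 0), "positive")
  expect_error(fit_bayes_a(Z, y, niter = 100, burnin = 200), "burn-in")
})

test_that("Bayes A shrinks null effects and stays stationary", {
  set.seed(4)
  Z <- matrix(rbinom(60 * 25, 2, 0.4), 60, 25)
  y_sig <- drop(Z %*% rnorm(25, sd = 1.5)) + rnorm(60, sd = 0.25)
  y_null <- rnorm(60)
  f_sig <- fit_bayes_a(Z, y_sig, niter = 1500, burnin = 500, seed = 5)
  f_null <- fit_bayes_a(Z, y_null, niter = 1500, burnin = 500, seed = 5)
  expect_lt(mean(abs(f_null$effects)), 0.1 * mean(abs(f_sig$effects)))
  # Geweke-style stationarity on the residual-variance chain
  ch <- f_sig$sigma2_e_chain
  n <- length(ch)
  a <- ch[seq_len(floor(0.1 * n))]
  b <- ch[seq(floor(0.5 * n), n)]
  z <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(z), 4)
})

test_that("large-df Bayes A converges to RR-BLUP predictions", {
  # phenotype generated by the markers themselves, so the ridge model holds
  g <- fixture_geno()
  Z <- g$geno[, 1:40]
  set.seed(31)
  y <- 2 + drop(Z %*% rnorm(40, sd = 0.5)) + rnorm(nrow(Z), sd = 0.5)
  tr <- 1:100; te <- 101:120
  fr <- fit_rrblup(Z[tr, ], y[tr])
  fb <- fit_bayes_a(Z[tr, ], y[tr], niter = 4000, burnin = 1000,
                    df_prior = 1e6, scale_prior = max(fr$sigma2_u, 1e-6),
                    seed = 7)
  expect_gt(cor(predict(fb, Z[te, ]), predict(fr, Z[te, ])), 0.99)
})

test_that("genomic selection uses 50/50 splits and honors k truncation", {
  expect_equal(eval(formals(evaluate_genomic_selection)$train_fraction), 0.5)
  g <- fixture_geno()
  p <- simulate_trait_panel(g, h2 = 0.6, r = 2, n_causal = 8,
                            causal_share = 0.9, seed = 41)
  y <- accession_means(p, "WW")
  expect_warning(
    ev <- evaluate_genomic_selection(g, y, candidate_snps = p$causal$snp,
                                     k_values = 20, n_repeats = 4, seed = 2),
    "truncated")
  expect_true(all(ev$accuracy >= -1 & ev$accuracy <= 1))
  expect_equal(sort(unique(ev$set)), c("candidate", "random"))
})

test_that("candidate SNP sets outpredict random sets on a planted panel", {
  g <- fixture_geno()
  p <- simulate_trait_panel(g, h2 = 0.6, r = 2, n_causal = 8,
                            causal_share = 0.9, seed = 41)
  y <- accession_means(p, "WW")
  ev <- evaluate_genomic_selection(g, y, candidate_snps = p$causal$snp,
                                   k_values = 8, n_repeats = 25, seed = 3)
  s <- summary(ev)
  expect_gt(s$candidate_mean, s$random_mean)
  expect_lt(s$p_greater, 0.05)
})

test_that("stepwise selection recovers an exact predictor immediately", {
  set.seed(6)
  x <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  y <- x$b
  mp <- stepwise_trait_markers(x, y)
  expect_equal(mp$trait[1], "b")
  expect_equal(attr(mp, "final_r2"), 1, tolerance = 1e-12)
  expect_equal(nrow(mp), 1)   # perfect fit, nothing else enters
  # cumulative R2 path is non-decreasing
  set.seed(7)
  x2 <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  y2 <- rowSums(x2[, 1:4]) + rnorm(200, sd = 0.5)
  mp2 <- stepwise_trait_markers(x2, y2)
  expect_true(all(diff(mp2$cumulative_r2) >= -1e-12))
  expect_true(all(diff(attr(mp2, "r2_path")) >= -1e-12))
})

test_that("collinear predictors never enter and nulls enter at the alpha rate", {
  set.seed(8)
  x <- data.frame(a = rnorm(150))
  x$dup <- 2 * x$a          # exactly collinear once a is in
  y <- x$a + rnorm(150, sd = 0.1)
  mp <- stepwise_trait_markers(x, y)
  expect_false("dup" %in% mp$trait)

  false_entries <- vapply(1:20, function(i) {
    set.seed(100 + i)
    xn <- as.data.frame(matrix(rnorm(200 * 25), 200, 25))
    nrow(stepwise_trait_markers(xn, rnorm(200), max_steps = 5))
  }, numeric(1))
  # ~ entry_alpha * 25 tests at step one; allow a generous band
  expect_lt(mean(false_entries), 4)
})

test_that("spectral indexes respect flat spectra and chlorophyll direction", {
  flat <- structure(list(A = rep(0.3, 250),
                         wavelength = band_wavelength(1:250)),
                    class = "spectral_profile")
  si <- compute_spectral_indexes(flat)
  expect_equal(si$green_peak_reflectance, 0.3)
  expect_equal(si$red_valley_reflectance, 0.3)
  expect_equal(si$red_edge_area, 0, tolerance = 1e-12)

  leafy <- structure(list(A = leaf_spectrum(chlorophyll = 0.5),
                          wavelength = band_wavelength(1:250)),
                     class = "spectral_profile")
  s1 <- compute_spectral_indexes(leafy)
  expect_gt(s1$red_edge_area, 0)
  expect_gt(s1$green_peak_reflectance, s1$red_valley_reflectance)

  valleys <- vapply(c(0.1, 0.5, 0.9), function(chl)
    compute_spectral_indexes(structure(
      list(A = leaf_spectrum(chlorophyll = chl),
           wavelength = band_wavelength(1:250)),
      class = "spectral_profile"))$red_valley_reflectance, numeric(1))
  expect_true(all(diff(valleys) < 0))   # more chlorophyll, deeper valley

  # indexes are computed on averages: invariant to plant pixel count
  p1 <- structure(list(A = leaf_spectrum(), T = leaf_spectrum() * 10,
                       n_pixels = 10, wavelength = band_wavelength(1:250)),
                  class = "spectral_profile")
  p2 <- p1; p2$T <- p1$A * 5000; p2$n_pixels <- 5000
  expect_equal(compute_spectral_indexes(p1), compute_spectral_indexes(p2))
})
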