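test_that("trait tables form ratio columns with guarded division", {
  recs <- data.frame(
    accession = rep(c("a1", "a2"), each = 2),
    replicate = 1L,
    treatment = rep(c("WW", "DS"), 2),
    time = 40L, modality = "RGB", trait = "TPA",
    value = c(2, 4, 0, 7))
  tab <- assemble_trait_table(recs)
  expect_setequal(tab$info$column, c("TPA_D40_WW", "TPA_D40_DS", "TPA_D40_R"))
  d <- tab$data
  expect_equal(d$TPA_D40_R[d$accession == "a1"], 2)       # DS/WW = 4/2
  expect_true(is.na(d$TPA_D40_R[d$accession == "a2"]))    # WW = 0
})

test_that("a full factorial design yields the per-modality column counts", {
  # miniature design: counts follow n_traits x n_times x 3 views
  grid <- expand.grid(accession = c("a1", "a2"), replicate = 1:2,
                      treatment = c("WW", "DS"), time = c(25, 28),
                      trait = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
  grid$modality <- "RGB"
  grid$value <- rnorm(nrow(grid)) + 5
  tab <- assemble_trait_table(grid)
  expect_equal(nrow(tab$info), 3 * 2 * 3)
  expect_equal(nrow(tab$data), 4)
  # DS without a WW partner gets no ratio column
  solo <- data.frame(accession = "a1", replicate = 1L, treatment = "DS",
                     time = 1L, modality = "CT", trait = "x", value = 1)
  t2 <- assemble_trait_table(solo)
  expect_false(any(t2$info$view == "R"))
})

test_that("the 3-sigma filter is single-pass with column statistics", {
  # oracle by direct computation: mean 20, sd ~44.7, 100 < 20 + 3 * 44.7
  x <- c(0, 0, 0, 0, 100)
  out <- filter_outliers_3sigma(x)
  expect_equal(out$n_removed, 0L)
  expect_equal(out$values, x)

  within <- rnorm(50) * 0.1
  expect_equal(filter_outliers_3sigma(within)$n_removed, 0L)
  expect_equal(filter_outliers_3sigma(rep(3, 10))$n_removed, 0L)  # zero var

  y <- c(rnorm(1000), 50)
  out2 <- filter_outliers_3sigma(y)
  expect_equal(out2$n_removed, 1L)
  expect_true(is.na(out2$values[1001]))
})

test_that("the t-test stage keeps real WW/DS differences at alpha = 0.05", {
  same <- rep(c(1, 2, 3), 10)
  r <- ttest_filter(same, same)
  expect_gt(r$p, 0.99)
  expect_false(r$keep)

  set.seed(1)
  strong <- ttest_filter(rnorm(50), rnorm(50, mean = 5))
  expect_true(strong$keep)

  short <- ttest_filter(c(1), c(1, 2, 3))
  expect_false(short$keep)
  expect_equal(short$reason, "insufficient observations")

  # null calibration: keep fraction ~ alpha
  set.seed(7)
  kept <- vapply(1:400, function(i)
    ttest_filter(rnorm(20), rnorm(20))$keep, logical(1))
  ci <- qbinom(c(0.0005, 0.9995), 400, 0.05)
  expect_gte(sum(kept), ci[1])
  expect_lte(sum(kept), ci[2])
})

test_that("MLP importance ranks a perfect separator at 100%", {
  set.seed(3)
  n <- 60
  labels <- rep(c("WW", "DS"), each = n / 2)
  x <- cbind(sep = ifelse(labels == "DS", 1, 0) + rnorm(n, sd = 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  res <- mlp_importance_filter(x, labels, n_repeats = 5, hidden = 4, seed = 2)
  expect_equal(res$importance[res$trait == "sep"], 100)
  expect_true(res$keep[res$trait == "sep"])
  expect_false(attr(res, "low_separation"))
  expect_error(mlp_importance_filter(x, rep("WW", n)), "two classes")
})

test_that("pure-noise traits complete the MLP stage with a low-separation flag", {
  set.seed(9)
  x <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("n", 1:5)))
  res <- mlp_importance_filter(x, rep(c("WW", "DS"), 20), n_repeats = 3,
                               hidden = 3, maxit = 50, seed = 4)
  expect_equal(nrow(res), 5)
  expect_true(is.logical(res$keep))
})

test_that("heritability estimation honors the variance-component formula", {
  # sigma2_e = 0: replicates identical within accession -> H2 = 1
  acc <- rep(sprintf("a%02d", 1:30), each = 2)
  g <- rep(rnorm(30), each = 2)
  h <- estimate_heritability(g, acc, r = 2)
  expect_equal(h$H2, 1, tolerance = 1e-6)
  # formula arithmetic is applied to the estimated components
  set.seed(5)
  y <- g + rnorm(60)
  h2 <- estimate_heritability(y, acc, r = 2)
  expect_equal(h2$H2,
               h2$sigma2_G / (h2$sigma2_G + h2$sigma2_e / 2),
               tolerance = 1e-12)
  # ANOVA fallback agrees with REML on balanced data
  h3 <- estimate_heritability(y, acc, r = 2, method = "anova")
  expect_equal(h3$H2, h2$H2, tolerance = 0.02)
  expect_error(estimate_heritability(rnorm(5), letters[1:5], r = 1),
               "inestimable")
  expect_error(estimate_heritability(c(1, 2), c("a", "a"), r = 1),
               "2 accessions")
})

test_that("heritability recovery is consistent as the panel grows", {
  errs <- vapply(c(50, 368), function(n) {
    est <- vapply(1:8, function(i) {
      g <- simulate_genotypes(n, 40, seed = 100 + i)
      p <- simulate_trait_panel(g, h2 = 0.4, r = 2, seed = 200 + i)
      ww <- p$traits[p$traits$treatment == "WW", ]
      estimate_heritability(ww$value, ww$accession, r = 2)$H2
    }, numeric(1))
    abs(mean(est) - 0.4)
  }, numeric(1))
  expect_lt(errs[2], 0.1)
  expect_lte(errs[2], errs[1] + 0.05)   # bias shrinks with panel size
})

test_that("the four-stage selection keeps planted traits and drops noise", {
  g <- simulate_genotypes(60, 80, seed = 1)
  sig <- simulate_trait_panel(g, h2 = 0.6, r = 2, treatment_effect = 3,
                              seed = 4)
  noise <- simulate_trait_panel(g, h2 = 0, r = 2, seed = 9)
  recs <- rbind(panel_records(sig, "RGB", "planted", 40),
                panel_records(noise, "RGB", "noise", 40))
  tab <- assemble_trait_table(recs)
  rep <- run_selection(tab, mlp_hidden = 8, seed = 2)
  expect_true(rep$keep[rep$column == "planted_D40_WW"])
  expect_true(rep$keep[rep$column == "planted_D40_DS"])
  expect_false(any(rep$keep[rep$trait == "noise"]))
  # keep flag is the pure conjunction of the stage flags
  expect_equal(rep$keep,
               rep$t_keep & rep$mlp_keep & rep$h2_keep & !is.na(rep$t_keep))
})

test_that("the heritability cutoff is inclusive at H2 >= cutoff", {
  g <- simulate_genotypes(50, 30, seed = 3)
  p <- simulate_trait_panel(g, h2 = 0.5, r = 2, treatment_effect = 3, seed = 6)
  tab <- assemble_trait_table(panel_records(p, "HSI", "tr", 34))
  base <- run_selection(tab, run_mlp = FALSE, seed = 1)
  # the ratio column is judged on its own H2, so it probes the boundary
  h_r <- base$H2[base$column == "tr_D34_R"]
  at_cut <- run_selection(tab, run_mlp = FALSE, h2_cutoff = h_r, seed = 1)
  expect_true(at_cut$h2_keep[at_cut$column == "tr_D34_R"])   # H2 >= cutoff
  above <- run_selection(tab, run_mlp = FALSE, h2_cutoff = h_r + 1e-8,
                         seed = 1)
  expect_false(above$h2_keep[above$column == "tr_D34_R"])
  expect_equal(at_cut$H2, base$H2)
})

test_that("empty input produces an empty report without crashing", {
  empty <- assemble_trait_table(data.frame(
    accession = character(0), replicate = integer(0),
    treatment = character(0), time = integer(0), modality = character(0),
    trait = character(0), value = numeric(0)))
  rep <- run_selection(empty)
  expect_s3_class(rep, "selection_report")
  expect_equal(nrow(rep), 0)
})
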