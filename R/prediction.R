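#' Ridge-regression BLUP genomic prediction
#'
#' Fits `y = 1 mu + Z u + e` with `u ~ N(0, sigma2_u I)`,
#' `e ~ N(0, sigma2_e I)`. When `lambda` is not supplied the variance
#' components are estimated by REML through the spectral decomposition of
#' `Z Z'` (exact for a single random effect) and
#' `lambda = sigma2_e / sigma2_u`; marker effects are the BLUP solution of
#' the ridge system, `u = Z' (Z Z' + lambda I)^{-1} (y - mu)`, with `mu` the
#' GLS intercept. Markers are centered internally; a zero-variance marker
#' gets effect exactly 0. A constant phenotype degenerates to
#' prediction-by-mean with zero effects.
#'
#' @param Z training genotype matrix (lines x markers, 0/1/2 codes or a
#'   `genotype_matrix`).
#' @param y training phenotype vector.
#' @param lambda optional fixed ridge parameter (skips REML).
#' @return class `rrblup`: list with `mu`, `effects`, `lambda`, `sigma2_u`,
#'   `sigma2_e`, `centers`. Has `predict` and `print` methods.
#' @export
fit_rrblup <- function(Z, y, lambda = NULL) {
  if (inherits(Z, "genotype_matrix")) Z <- Z$geno
  Z <- as.matrix(Z)
  if (nrow(Z) < 2) stopf("need >= 2 training lines")
  if (nrow(Z) != length(y)) stopf("phenotype length does not match Z")
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)
  if (stats::var(y) == 0) {
    return(structure(list(mu = y[1], effects = rep(0, ncol(Z)),
                          lambda = Inf, sigma2_u = 0, sigma2_e = 0,
                          centers = centers), class = "rrblup"))
  }
  G <- tcrossprod(Zc)
  s2u <- NA_real_
  if (is.null(lambda)) {
    eig <- eigen(G, symmetric = TRUE)
    d <- pmax(eig$values, 1e-10)
    U <- eig$vectors
    yr <- drop(crossprod(U, y))
    Xr <- crossprod(U, matrix(1, length(y), 1))
    opt <- stats::optimize(emma_reml_ll, c(-18, 18), d = d, yr = yr, Xr = Xr,
                           maximum = TRUE)
    lambda <- exp(opt$maximum)
    # REML scale: sigma2_u is the marker-effect variance of the ridge model
    w <- 1 / (d + lambda)
    b0 <- sum(w * Xr * yr) / sum(w * Xr^2)
    s2u <- sum(w * (yr - Xr * b0)^2) / (length(y) - 1)
  }
  V <- G + diag(lambda, nrow(Zc))
  Vinv_1 <- solve(V, rep(1, nrow(Zc)))
  mu <- sum(Vinv_1 * y) / sum(Vinv_1)
  alpha <- solve(V, y - mu)
  u <- drop(crossprod(Zc, alpha))
  structure(list(mu = mu, effects = stats::setNames(u, colnames(Z)),
                 lambda = lambda, sigma2_u = if (is.finite(s2u)) s2u else NA_real_,
                 sigma2_e = if (is.finite(s2u)) s2u * lambda else NA_real_,
                 centers = centers),
            class = "rrblup")
}

#' @export
predict.rrblup <- function(object, newdata, ...) {
  if (inherits(newdata, "genotype_matrix")) newdata <- newdata$geno
  Zc <- sweep(as.matrix(newdata), 2, object$centers)
  drop(object$mu + Zc %*% object$effects)
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("rrblup: %d marker effects, lambda = %.4g, mu = %.4g\n",
              length(x$effects), x$lambda, x$mu))
  invisible(x)
}

#' Bayes A genomic prediction by Gibbs sampling
#'
#' Per-marker effect variances with scaled-inverse-chi-squared priors:
#' `u_j ~ N(0, sigma2_j)`, `sigma2_j ~ inv-chi2(df_prior, scale_prior)`, and
#' a matching prior on the residual variance. Gibbs updates cycle over the
#' intercept, each marker effect, each marker variance, and the residual
#' variance; posterior means are taken after burn-in with thinning. Runs are
#' reproducible given the seed. In the large-`df_prior` limit all marker
#' variances are shrunk to a common value and predictions approach RR-BLUP.
#'
#' @param Z training genotype matrix (lines x markers).
#' @param y training phenotype vector.
#' @param niter,burnin,thin chain settings (defaults 3000/1000/5).
#' @param df_prior prior degrees of freedom (> 0, default 5).
#' @param scale_prior prior scale; default calibrated from the sample
#'   variance of `y` so markers explain about half of it a priori.
#' @param seed integer seed.
#' @return class `bayes_a`: list with `mu`, `effects` (posterior means),
#'   `sigma2_e` (posterior mean), `sigma2_e_chain`, settings.
#' @export
fit_bayes_a <- function(Z, y, niter = 3000, burnin = 1000, thin = 5,
                        df_prior = 5, scale_prior = NULL, seed = 1) {
  if (inherits(Z, "genotype_matrix")) Z <- Z$geno
  Z <- as.matrix(Z)
  if (niter <= burnin) stopf("chain length must exceed burn-in")
  if (df_prior <= 0) stopf("'df_prior' must be positive")
  if (!is.null(scale_prior) && scale_prior <= 0)
    stopf("'scale_prior' must be positive")
  n <- nrow(Z); m <- ncol(Z)
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)
  zz <- colSums(Zc^2)
  vy <- stats::var(y)
  msx <- sum(apply(Zc, 2, stats::var))
  if (is.null(scale_prior))
    scale_prior <- vy * 0.5 / max(msx, 1e-8) * (df_prior + 2) / df_prior
  dfe <- 5
  Se <- vy * 0.5 * (dfe + 2) / dfe
  with_seed(seed, {
    mu <- mean(y)
    u <- rep(0, m)
    s2j <- rep(scale_prior, m)
    s2e <- vy / 2
    e <- y - mu
    keep <- seq(burnin + 1, niter)
    keep <- keep[(keep - burnin) %% thin == 0]
    mu_acc <- 0; u_acc <- rep(0, m); s2e_chain <- numeric(length(keep))
    ki <- 0L
    for (it in seq_len(niter)) {
      # intercept
      e <- e + mu
      mu <- stats::rnorm(1, mean(e), sqrt(s2e / n))
      e <- e - mu
      # marker effects and variances
      for (j in seq_len(m)) {
        if (zz[j] == 0) { u[j] <- 0; next }
        e <- e + Zc[, j] * u[j]
        cj <- zz[j] / s2e + 1 / s2j[j]
        mj <- sum(Zc[, j] * e) / s2e / cj
        u[j] <- stats::rnorm(1, mj, sqrt(1 / cj))
        e <- e - Zc[, j] * u[j]
        s2j[j] <- (scale_prior * df_prior + u[j]^2) /
          stats::rchisq(1, df_prior + 1)
      }
      s2e <- (sum(e^2) + Se * dfe) / stats::rchisq(1, n + dfe)
      if (it > burnin && (it - burnin) %% thin == 0) {
        ki <- ki + 1L
        mu_acc <- mu_acc + mu
        u_acc <- u_acc + u
        s2e_chain[ki] <- s2e
      }
    }
    structure(list(mu = mu_acc / ki,
                   effects = stats::setNames(u_acc / ki, colnames(Z)),
                   sigma2_e = mean(s2e_chain), sigma2_e_chain = s2e_chain,
                   centers = centers, niter = niter, burnin = burnin,
                   thin = thin, df_prior = df_prior,
                   scale_prior = scale_prior, seed = seed),
              class = "bayes_a")
  })
}

#' @export
predict.bayes_a <- function(object, newdata, ...) {
  if (inherits(newdata, "genotype_matrix")) newdata <- newdata$geno
  Zc <- sweep(as.matrix(newdata), 2, object$centers)
  drop(object$mu + Zc %*% object$effects)
}

#' @export
print.bayes_a <- function(x, ...) {
  cat(sprintf("bayes_a: %d marker effects, %d kept draws, sigma2_e = %.4g\n",
              length(x$effects), length(x$sigma2_e_chain), x$sigma2_e))
  invisible(x)
}

#' Candidate-vs-random genomic selection evaluation
#'
#' For each set size k, prediction accuracy (Pearson correlation between
#' predicted and observed phenotype on the held-out half) is measured over
#' repeated random 50/50 train/test splits using (a) the top-k candidate
#' SNPs (best SNP per candidate gene, ranked) and (b) size-matched SNP sets
#' drawn from the non-candidate pool, redrawn per repeat. A Welch t-test
#' compares the two accuracy distributions per k.
#'
#' @param genotypes a `genotype_matrix`.
#' @param phenotype named numeric vector (one value per line).
#' @param candidate_snps character vector of candidate SNP ids, ranked most
#'   significant first.
#' @param k_values set sizes; values exceeding the available candidates are
#'   truncated with a warning. Use `Inf` for "all genome".
#' @param n_repeats splits per arm and k (default 50).
#' @param model `"rrblup"` or `"bayesa"`.
#' @param train_fraction fraction of lines used for training (default 0.5).
#' @param seed integer seed.
#' @param ... passed to the model fitter.
#' @return class `gs_evaluation`: data.frame with `set`, `k`, `rep`,
#'   `accuracy`; `summary()` gives mean/sd per arm and the candidate vs
#'   random Welch test.
#' @export
evaluate_genomic_selection <- function(genotypes, phenotype, candidate_snps,
                                       k_values = c(1, 10, 20, 30, 40, 50,
                                                    100, Inf),
                                       n_repeats = 50,
                                       model = c("rrblup", "bayesa"),
                                       train_fraction = 0.5, seed = 1, ...) {
  model <- match.arg(model)
  g <- genotypes$geno
  if (is.null(names(phenotype))) names(phenotype) <- rownames(g)
  common <- intersect(rownames(g), names(phenotype)[!is.na(phenotype)])
  g <- g[common, , drop = FALSE]
  y <- phenotype[common]
  candidate_snps <- candidate_snps[candidate_snps %in% colnames(g)]
  pool <- setdiff(colnames(g), candidate_snps)
  fitfun <- function(Ztr, ytr, sd_seed)
    if (model == "rrblup") fit_rrblup(Ztr, ytr, ...)
    else fit_bayes_a(Ztr, ytr, seed = sd_seed, ...)
  out <- list()
  with_seed(seed, {
    for (k in k_values) {
      kk <- if (is.infinite(k)) ncol(g) else k
      if (kk > length(candidate_snps) && !is.infinite(k)) {
        warnf("k = %d exceeds the %d available candidate genes: truncated",
              kk, length(candidate_snps))
        kk <- length(candidate_snps)
      }
      cand_set <- if (is.infinite(k)) colnames(g)
                  else candidate_snps[seq_len(kk)]
      for (rep_i in seq_len(n_repeats)) {
        tr <- sample(length(y), round(train_fraction * length(y)))
        te <- setdiff(seq_along(y), tr)
        rand_set <- if (is.infinite(k)) colnames(g)
                    else sample(pool, min(kk, length(pool)))
        for (arm in c("candidate", "random")) {
          set <- if (arm == "candidate") cand_set else rand_set
          fit <- fitfun(g[tr, set, drop = FALSE], y[tr], sd_seed = rep_i)
          pred <- predict(fit, g[te, set, drop = FALSE])
          a <- suppressWarnings(stats::cor(pred, y[te]))
          out[[length(out) + 1]] <- data.frame(
            set = arm, k = if (is.infinite(k)) "all" else as.character(k),
            rep = rep_i, accuracy = if (is.na(a)) 0 else a,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  structure(do.call(rbind, out), class = c("gs_evaluation", "data.frame"),
            model = model)
}

#' @export
summary.gs_evaluation <- function(object, ...) {
  ks <- unique(object$k)
  do.call(rbind, lapply(ks, function(k) {
    ca <- object$accuracy[object$k == k & object$set == "candidate"]
    ra <- object$accuracy[object$k == k & object$set == "random"]
    p <- if (stats::sd(ca - mean(ca)) == 0 && stats::sd(ra) == 0) NA_real_
    else tryCatch(stats::t.test(ca, ra, alternative = "greater")$p.value,
                  error = function(e) NA_real_)
    data.frame(k = k, candidate_mean = mean(ca), candidate_sd = stats::sd(ca),
               random_mean = mean(ra), random_sd = stats::sd(ra),
               p_greater = p, stringsAsFactors = FALSE)
  }))
}

#' Stepwise selection of i-trait markers for a quantitative outcome
#'
#' Forward selection with backward elimination on a linear model: at each
#' step the candidate with the smallest partial-F p-value enters if
#' `p < entry_alpha`; after each entry, fitted predictors with partial-F
#' `p > removal_alpha` are dropped. Stops at `max_steps` entries or when no
#' candidate is admissible. Collinear candidates (residual tolerance below
#' 1e-8 given the current model) never enter.
#'
#' @param x data.frame or matrix of predictors (e.g. ratio i-traits).
#' @param y numeric outcome (e.g. survival rate).
#' @param entry_alpha,removal_alpha stepwise thresholds (defaults 0.05 and
#'   0.10, the classical stepwise convention).
#' @param max_steps maximum number of entries (default 20).
#' @return class `marker_panel`: data.frame with `step`, `trait`,
#'   `partial_r2`, `cumulative_r2` for the selected panel (in entry order,
#'   after removals); attributes `final_model` (lm) and `r2_path`.
#' @export
stepwise_trait_markers <- function(x, y, entry_alpha = 0.05,
                                   removal_alpha = 0.10, max_steps = 20) {
  x <- as.data.frame(x)
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  if (ncol(x) < 1) stopf("need at least one predictor")
  if (stats::var(y) == 0) stopf("outcome has zero variance")
  vars <- names(x)
  active <- character(0)
  r2_path <- numeric(0)
  steps <- list()
  tss <- sum((y - mean(y))^2)
  fit0 <- stats::lm(y ~ 1, data = x)
  current_r2 <- 0
  for (step in seq_len(max_steps)) {
    cands <- setdiff(vars, active)
    if (length(cands) == 0) break
    # residual tolerance screen against collinearity
    Xa <- if (length(active)) as.matrix(x[, active, drop = FALSE]) else NULL
    pvals <- vapply(cands, function(v) {
      xv <- x[[v]]
      if (stats::var(xv) == 0) return(NA_real_)
      if (!is.null(Xa)) {
        res <- stats::lm.fit(cbind(1, Xa), xv)$residuals
        if (sum(res^2) / sum((xv - mean(xv))^2) < 1e-8) return(NA_real_)
      }
      f1 <- stats::lm(stats::reformulate(c(active, v), "y"),
                      data = cbind(x, y = y))
      a <- suppressWarnings(stats::anova(fit0, f1))
      a$`Pr(>F)`[2]
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- names(which.min(pvals))
    if (pvals[best] >= entry_alpha || is.na(pvals[best])) break
    active <- c(active, best)
    fit0 <- stats::lm(stats::reformulate(active, "y"), data = cbind(x, y = y))
    # backward elimination
    repeat {
      if (length(active) == 0) break
      dr <- suppressWarnings(stats::drop1(fit0, test = "F"))
      pv <- dr$`Pr(>F)`[-1]
      names(pv) <- rownames(dr)[-1]
      worst <- names(which.max(pv))
      if (length(worst) == 0 || pv[worst] <= removal_alpha) break
      active <- setdiff(active, worst)
      fit0 <- stats::lm(stats::reformulate(c("1", active), "y"),
                        data = cbind(x, y = y))
    }
    current_r2 <- suppressWarnings(summary(fit0)$r.squared)
    r2_path <- c(r2_path, current_r2)
    steps[[step]] <- data.frame(step = step, entered = best,
                                active = paste(active, collapse = ","),
                                cumulative_r2 = current_r2,
                                stringsAsFactors = FALSE)
  }
  panel <- if (length(active)) {
    entry_order <- vapply(active, function(v)
      min(which(vapply(steps, function(s) s$entered == v, logical(1)))),
      numeric(1))
    r2_increments <- numeric(length(active))
    fit_seq <- stats::lm(y ~ 1, data = x)
    cum <- 0
    ordered <- active[order(entry_order)]
    for (i in seq_along(ordered)) {
      fit_seq <- stats::lm(stats::reformulate(ordered[seq_len(i)], "y"),
                           data = cbind(x, y = y))
      r2 <- suppressWarnings(summary(fit_seq)$r.squared)
      r2_increments[i] <- r2 - cum
      cum <- r2
    }
    data.frame(step = seq_along(ordered), trait = ordered,
               partial_r2 = r2_increments, cumulative_r2 = cumsum(r2_increments),
               stringsAsFactors = FALSE)
  } else data.frame(step = integer(0), trait = character(0),
                    partial_r2 = numeric(0), cumulative_r2 = numeric(0))
  structure(panel, class = c("marker_panel", "data.frame"),
            final_model = fit0, r2_path = r2_path,
            final_r2 = current_r2)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d i-trait markers, final R2 = %.3f\n",
              nrow(x), attr(x, "final_r2")))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Remote-sensing spectral indexes of a reflectance profile
#'
#' Four classical chlorophyll/water indicators computed on the average
#' reflectance spectrum: green peak reflectance (maximum over 500-590 nm),
#' red valley reflectance (minimum over 620-700 nm), green peak area
#' (trapezoidal integral of reflectance over 500-590 nm), and red edge area
#' (trapezoidal integral of the first derivative of reflectance with
#' respect to wavelength over 680-760 nm). Computed on averages, the
#' indexes are invariant to plant pixel count.
#'
#' @param profile a `spectral_profile` (or list with `A` and `wavelength`).
#' @return class `spectral_indexes`: named list with
#'   `red_valley_reflectance`, `green_peak_reflectance`, `green_peak_area`,
#'   `red_edge_area`.
#' @export
compute_spectral_indexes <- function(profile) {
  A <- profile$A; wl <- profile$wavelength
  if (is.null(A) || is.null(wl)) stopf("profile must carry A and wavelength")
  win <- function(lo, hi) {
    sel <- wl >= lo & wl <= hi
    if (sum(sel) < 2)
      stopf("window %g-%g nm falls outside the %g-%g nm grid",
            lo, hi, min(wl), max(wl))
    sel
  }
  gp <- win(500, 590); rv <- win(620, 700); re <- win(680, 760)
  dA <- diff(A) / diff(wl)
  wl_mid <- (wl[-1] + wl[-length(wl)]) / 2
  rem <- wl_mid >= 680 & wl_mid <= 760
  structure(list(
    red_valley_reflectance = min(A[rv]),
    green_peak_reflectance = max(A[gp]),
    green_peak_area = trapz(wl[gp], A[gp]),
    red_edge_area = trapz(wl_mid[rem], dA[rem])),
    class = "spectral_indexes")
}

#' @export
print.spectral_indexes <- function(x, ...) {
  cat(sprintf(paste0("spectral_indexes: red valley %.4f, green peak %.4f, ",
                     "green peak area %.2f, red edge area %.4f\n"),
              x$red_valley_reflectance, x$green_peak_reflectance,
              x$green_peak_area, x$red_edge_area))
  invisible(x)
}
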