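#' Assemble the accession x i-trait table with WW, DS and ratio views
#'
#' Takes per-scan trait records in long form and widens them to the table
#' consumed by the selection and association stages: one row per accession x
#' replicate, one column per (trait, time point, treatment view). For every
#' (trait, time) where both WW and DS columns exist a ratio column `_R` is
#' added, computed per accession-replicate as DS / WW; ratios with |WW|
#' below a machine-scaled epsilon are missing-coded. Column names follow the
#' `ddT200_D40_R` convention: trait, day, view.
#'
#' @param records long data.frame with columns `accession`, `replicate`,
#'   `treatment` (`"WW"`/`"DS"`), `time`, `modality`, `trait`, `value`.
#' @return class `trait_table`: list with `data` (wide data.frame, first two
#'   columns `accession` and `replicate`) and `info` (one row per trait
#'   column: `column`, `modality`, `trait`, `time`, `view`).
#' @export
assemble_trait_table <- function(records) {
  need <- c("accession", "replicate", "treatment", "time", "modality",
            "trait", "value")
  if (!all(need %in% names(records)))
    stopf("records must have columns: %s", paste(need, collapse = ", "))
  if (nrow(records) == 0)
    return(structure(list(data = data.frame(accession = character(0),
                                            replicate = integer(0)),
                          info = data.frame()), class = "trait_table"))
  records$treatment <- as.character(records$treatment)
  if (!all(records$treatment %in% c("WW", "DS")))
    stopf("treatment must be WW or DS")
  rid <- paste(records$accession, records$replicate, sep = "\r")
  key <- sprintf("%s_D%s_%s", records$trait, records$time,
                 ifelse(records$treatment == "WW", "WW", "DS"))
  wide <- tapply(records$value, list(rid, key), mean)
  rows <- do.call(rbind, strsplit(rownames(wide), "\r", fixed = TRUE))
  info_src <- records[!duplicated(key), c("modality", "trait", "time")]
  info_src$column <- key[!duplicated(key)]
  info_src$view <- ifelse(grepl("_WW$", info_src$column), "WW", "DS")

  # ratio columns where a WW/DS pair exists
  base <- unique(info_src[, c("modality", "trait", "time")])
  rat_cols <- list(); rat_info <- list()
  eps <- sqrt(.Machine$double.eps)
  for (i in seq_len(nrow(base))) {
    cw <- sprintf("%s_D%s_WW", base$trait[i], base$time[i])
    cd <- sprintf("%s_D%s_DS", base$trait[i], base$time[i])
    if (cw %in% colnames(wide) && cd %in% colnames(wide)) {
      ww <- wide[, cw]; ds <- wide[, cd]
      ratio <- ifelse(!is.na(ww) & abs(ww) > eps * pmax(1, abs(ww)) &
                        abs(ww) > .Machine$double.eps^0.5, ds / ww, NA_real_)
      ratio[!is.finite(ratio)] <- NA_real_
      cn <- sprintf("%s_D%s_R", base$trait[i], base$time[i])
      rat_cols[[cn]] <- ratio
      rat_info[[cn]] <- data.frame(modality = base$modality[i],
                                   trait = base$trait[i], time = base$time[i],
                                   column = cn, view = "R")
    }
  }
  dat <- data.frame(accession = rows[, 1],
                    replicate = as.integer(rows[, 2]),
                    wide, check.names = FALSE, stringsAsFactors = FALSE)
  if (length(rat_cols))
    dat <- cbind(dat, as.data.frame(rat_cols, check.names = FALSE))
  info <- rbind(info_src[, c("column", "modality", "trait", "time", "view")],
                if (length(rat_info))
                  do.call(rbind, rat_info)[, c("column", "modality", "trait",
                                               "time", "view")])
  rownames(info) <- NULL
  ord <- order(match(info$modality, unique(info$modality)), info$trait,
               info$time, match(info$view, c("WW", "DS", "R")))
  info <- info[ord, ]
  dat <- dat[, c("accession", "replicate", info$column)]
  structure(list(data = dat, info = info), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cnt <- table(x$info$modality)
  cat(sprintf("trait_table: %d rows x %d trait columns (%s)\n",
              nrow(x$data), nrow(x$info),
              paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", ")))
  invisible(x)
}

#' 3-sigma (PauTa) outlier removal for one trait column
#'
#' Values outside `[mean - 3*sd, mean + 3*sd]` are set missing, with mean
#' and sd computed once from the original column (single pass, not
#' iterated). Under normality this discards about 0.27% of the data, the
#' complement of the 99.7% coverage the criterion is built on. A
#' zero-variance column removes nothing.
#'
#' @param x numeric vector (missing values are passed through).
#' @return list with `values` (cleaned vector) and `n_removed`.
#' @export
filter_outliers_3sigma <- function(x) {
  obs <- !is.na(x)
  if (sum(obs) < 2) return(list(values = x, n_removed = 0L))
  m <- mean(x[obs]); s <- stats::sd(x[obs])
  if (!is.finite(s) || s == 0) return(list(values = x, n_removed = 0L))
  bad <- obs & (x < m - 3 * s | x > m + 3 * s)
  x[bad] <- NA_real_
  list(values = x, n_removed = sum(bad))
}

#' Welch t-test stage of the drought-trait selection
#'
#' Two-sided independent-samples t-test between the DS and WW groups;
#' a trait is kept when `p < alpha` (95% confidence by default). The
#' unequal-variance (Welch) form is used. Groups with fewer than two
#' non-missing observations drop the trait with reason
#' `"insufficient observations"`.
#'
#' @param ww,ds numeric vectors of the trait under the two treatments
#'   (typically accession means).
#' @param alpha significance level (default 0.05).
#' @return list with `p`, `keep`, and optionally `reason`.
#' @export
ttest_filter <- function(ww, ds, alpha = 0.05) {
  ww <- ww[!is.na(ww)]; ds <- ds[!is.na(ds)]
  if (length(ww) < 2 || length(ds) < 2 ||
      (stats::var(ww) == 0 && stats::var(ds) == 0 && mean(ww) == mean(ds)))
    return(list(p = NA_real_, keep = FALSE,
                reason = "insufficient observations"))
  p <- tryCatch(stats::t.test(ww, ds, var.equal = FALSE)$p.value,
                error = function(e) NA_real_)
  if (is.na(p)) return(list(p = NA_real_, keep = FALSE,
                            reason = "insufficient observations"))
  list(p = p, keep = p < alpha)
}

#' Multilayer-perceptron importance ranking of traits
#'
#' Trains a single-hidden-layer perceptron to classify WW vs DS rows,
#' repeats with `n_repeats` seeds, and scores each trait by permutation
#' importance (drop in training accuracy when the trait column is permuted),
#' normalized within each repeat so the most important trait scores 100%.
#' Traits whose mean normalized importance falls below `cutoff_pct` are
#' flagged for deletion, mirroring an SPSS-style normalized-importance
#' report with a 50% cut.
#'
#' @param x numeric matrix, rows = samples, columns = traits (standardized
#'   internally; missing values are mean-imputed per column).
#' @param labels factor/character of length `nrow(x)` with exactly two
#'   classes (WW/DS).
#' @param n_repeats number of training repeats (default 5).
#' @param cutoff_pct keep threshold on mean normalized importance
#'   (default 50).
#' @param hidden hidden-layer size (default 64).
#' @param maxit training iterations per repeat.
#' @param seed integer seed.
#' @return data.frame with `trait`, `importance` (mean normalized, %),
#'   `keep`; attribute `low_separation` flags near-chance classifiers.
#' @export
mlp_importance_filter <- function(x, labels, n_repeats = 5, cutoff_pct = 50,
                                  hidden = 64, maxit = 150, seed = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stopf("labels must contain exactly two classes (got %d)", nlevels(labels))
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
    if (all(is.na(x[, j]))) x[, j] <- 0
  }
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  xs <- scale(x, scale = sds)
  y <- as.integer(labels) - 1L
  n <- nrow(xs); p <- ncol(xs)
  acc <- function(fit, mat) mean((stats::predict(fit, mat) > 0.5) == y)
  imp <- matrix(0, n_repeats, p)
  base_acc <- numeric(n_repeats)
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      fit <- nnet::nnet(xs, y, size = hidden, decay = 0.05, maxit = maxit,
                        trace = FALSE, MaxNWts = (p + 2) * hidden + hidden + 10)
      base_acc[rep_i] <- acc(fit, xs)
      perm <- sample.int(n)
      raw <- vapply(seq_len(p), function(j) {
        xp <- xs
        xp[, j] <- xp[perm, j]
        max(base_acc[rep_i] - acc(fit, xp), 0)
      }, numeric(1))
      imp[rep_i, ] <- if (max(raw) > 0) raw / max(raw) * 100 else rep(0, p)
    }
  })
  res <- data.frame(trait = colnames(x) %||% paste0("V", seq_len(p)),
                    importance = colMeans(imp),
                    keep = colMeans(imp) >= cutoff_pct,
                    stringsAsFactors = FALSE)
  attr(res, "low_separation") <- mean(base_acc) < 0.6
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Broad-sense heritability of a replicated trait
#'
#' One-way random-effects model with accession as the random effect; the
#' variance components are estimated by REML (\pkg{lme4}), with a
#' method-of-moments ANOVA estimator as fallback, negative components
#' truncated at zero. Heritability follows
#' `H2 = sigma2_G / (sigma2_G + sigma2_e / r)` with `r` the number of
#' replicates.
#'
#' @param values numeric trait values.
#' @param accession accession id per value.
#' @param r replicate count used in the formula (default: mean number of
#'   observations per accession).
#' @param method `"reml"` (default) or `"anova"`.
#' @return class `h2_estimate`: list with `H2`, `sigma2_G`, `sigma2_e`, `r`,
#'   `method`.
#' @export
estimate_heritability <- function(values, accession, r = NULL,
                                  method = c("reml", "anova")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  values <- values[ok]; accession <- factor(as.character(accession)[ok])
  if (nlevels(accession) < 2) stopf("need at least 2 accessions")
  counts <- table(accession)
  if (is.null(r)) r <- mean(counts)
  if (all(counts < 2))
    stopf("error variance inestimable: all accessions have a single replicate")
  comp <- NULL
  if (method == "reml") {
    comp <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(values ~ (1 | accession),
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC("ignore", tol = 1e-4)))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      list(s2G = vc$vcov[vc$grp == "accession"],
           s2e = vc$vcov[vc$grp == "Residual"])
    }, error = function(e) NULL)
  }
  if (is.null(comp)) {  # ANOVA method-of-moments
    gm <- tapply(values, accession, mean)
    ni <- as.numeric(counts)
    n <- length(values)
    ssb <- sum(ni * (gm[names(counts)] - mean(values))^2)
    ssw <- sum((values - gm[accession])^2)
    msb <- ssb / (nlevels(accession) - 1)
    msw <- ssw / (n - nlevels(accession))
    n0 <- (n - sum(ni^2) / n) / (nlevels(accession) - 1)
    comp <- list(s2G = max((msb - msw) / n0, 0), s2e = msw)
    method <- "anova"
  }
  s2G <- max(comp$s2G, 0); s2e <- max(comp$s2e, 0)
  H2 <- if (s2G + s2e / r <= 0) 0 else s2G / (s2G + s2e / r)
  structure(list(H2 = H2, sigma2_G = s2G, sigma2_e = s2e, r = r,
                 method = method), class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("H2 = %.3f (sigma2_G = %.4g, sigma2_e = %.4g, r = %g, %s)\n",
              x$H2, x$sigma2_G, x$sigma2_e, x$r, x$method))
  invisible(x)
}

#' Run the four-step drought-trait selection
#'
#' Applies, in order: (1) single-pass 3-sigma outlier removal per column;
#' (2) Welch t-test of DS vs WW accession means per base trait (the verdict
#' propagates to that trait's WW, DS and ratio columns); (3) repeated-MLP
#' importance ranking of the base traits per modality x time block, WW vs DS
#' rows as classes; (4) broad-sense heritability, computed per treatment
#' view, a WW/DS pair passing if either condition reaches the cutoff (ratio
#' columns are assessed on their own values). The final keep flag is the
#' pure conjunction of the stage flags.
#'
#' @param table a [assemble_trait_table()] result.
#' @param alpha t-test significance level (default 0.05).
#' @param mlp_repeats,mlp_cutoff_pct,mlp_hidden MLP stage settings
#'   (defaults 5 repeats, 50% cutoff).
#' @param h2_cutoff heritability cutoff (default 0.2, kept when
#'   `H2 >= 0.2`).
#' @param r replicate count for the heritability formula (default: inferred
#'   from the table).
#' @param run_mlp set `FALSE` to skip the MLP stage (all traits pass it).
#' @param seed integer seed for the MLP stage.
#' @return class `selection_report`: data.frame with one row per trait
#'   column: stage statistics, per-stage keep flags, and `keep`.
#' @export
run_selection <- function(table, alpha = 0.05, mlp_repeats = 5,
                          mlp_cutoff_pct = 50, mlp_hidden = 64,
                          h2_cutoff = 0.2, r = NULL, run_mlp = TRUE,
                          seed = 1) {
  stopifnot(inherits(table, "trait_table"))
  info <- table$info
  if (nrow(info) == 0) {
    rep0 <- data.frame(column = character(0), keep = logical(0))
    return(structure(rep0, class = c("selection_report", "data.frame")))
  }
  dat <- table$data
  if (is.null(r)) r <- length(unique(dat$replicate))

  # stage 1: outliers, column-wise, single pass
  removed <- integer(nrow(info))
  for (i in seq_len(nrow(info))) {
    cl <- filter_outliers_3sigma(dat[[info$column[i]]])
    dat[[info$column[i]]] <- cl$values
    removed[i] <- cl$n_removed
  }

  base_key <- paste(info$modality, info$trait, info$time, sep = "\r")
  ub <- !duplicated(base_key)
  bases <- data.frame(modality = info$modality[ub], trait = info$trait[ub],
                      time = info$time[ub], key = base_key[ub],
                      stringsAsFactors = FALSE)

  # stage 2: t-test on accession means, WW vs DS, per base trait
  t_p <- stats::setNames(rep(NA_real_, nrow(bases)), bases$key)
  for (i in seq_len(nrow(bases))) {
    cw <- sprintf("%s_D%s_WW", bases$trait[i], bases$time[i])
    cd <- sprintf("%s_D%s_DS", bases$trait[i], bases$time[i])
    if (!cw %in% names(dat) || !cd %in% names(dat)) next
    mw <- tapply(dat[[cw]], dat$accession, mean, na.rm = TRUE)
    md <- tapply(dat[[cd]], dat$accession, mean, na.rm = TRUE)
    t_p[i] <- ttest_filter(mw, md, alpha)$p
  }
  t_keep <- !is.na(t_p) & t_p < alpha

  # stage 3: MLP importance per modality x time block
  mlp_imp <- stats::setNames(rep(NA_real_, nrow(bases)), bases$key)
  mlp_keep <- stats::setNames(rep(TRUE, nrow(bases)), bases$key)
  if (run_mlp) {
    blocks <- unique(bases[, c("modality", "time")])
    for (bi in seq_len(nrow(blocks))) {
      sel <- bases$modality == blocks$modality[bi] & bases$time == blocks$time[bi]
      traits <- bases$trait[sel]
      cw <- sprintf("%s_D%s_WW", traits, blocks$time[bi])
      cd <- sprintf("%s_D%s_DS", traits, blocks$time[bi])
      have <- cw %in% names(dat) & cd %in% names(dat)
      if (!any(have)) next
      xw <- as.matrix(dat[, cw[have], drop = FALSE])
      xd <- as.matrix(dat[, cd[have], drop = FALSE])
      colnames(xw) <- colnames(xd) <- traits[have]
      x <- rbind(xw, xd)
      lab <- rep(c("WW", "DS"), each = nrow(dat))
      res <- mlp_importance_filter(x, lab, n_repeats = mlp_repeats,
                                   cutoff_pct = mlp_cutoff_pct,
                                   hidden = mlp_hidden, seed = seed)
      k <- bases$key[sel][have]
      mlp_imp[k] <- res$importance
      mlp_keep[k] <- res$keep
    }
  }

  # stage 4: heritability per column; WW/DS pairs pass if either condition does
  h2 <- stats::setNames(rep(NA_real_, nrow(info)), info$column)
  for (i in seq_len(nrow(info))) {
    h2[i] <- tryCatch(
      estimate_heritability(dat[[info$column[i]]], dat$accession, r = r)$H2,
      error = function(e) NA_real_)
  }
  h2_self <- !is.na(h2) & h2 >= h2_cutoff
  h2_keep <- h2_self
  for (i in seq_len(nrow(info))) {
    if (info$view[i] %in% c("WW", "DS")) {
      sib <- sprintf("%s_D%s_%s", info$trait[i], info$time[i],
                     if (info$view[i] == "WW") "DS" else "WW")
      if (sib %in% names(h2_self)) h2_keep[i] <- h2_self[i] || h2_self[sib]
    }
  }

  key_of <- paste(info$modality, info$trait, info$time, sep = "\r")
  rep_df <- data.frame(
    column = info$column, modality = info$modality, trait = info$trait,
    time = info$time, view = info$view, n_outliers_removed = removed,
    t_p = as.numeric(t_p[key_of]), t_keep = as.logical(t_keep[key_of]),
    mlp_importance = as.numeric(mlp_imp[key_of]),
    mlp_keep = as.logical(mlp_keep[key_of]),
    H2 = as.numeric(h2), h2_keep = as.logical(h2_keep),
    stringsAsFactors = FALSE)
  rep_df$keep <- rep_df$t_keep & rep_df$mlp_keep & rep_df$h2_keep
  rep_df$keep[is.na(rep_df$keep)] <- FALSE
  structure(rep_df, class = c("selection_report", "data.frame"))
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report: %d trait columns, %d kept\n",
              nrow(x), sum(x$keep, na.rm = TRUE)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}
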