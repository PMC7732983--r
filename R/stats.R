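#' Differential expression, trend tests and QC for count matrices
#'
#' A self-contained negative-binomial testing stack: median-of-ratios size
#' factors, per-feature dispersion estimated by profile maximum likelihood
#' and shrunk toward a parametric mean-dispersion trend, a Wald test on
#' the two-condition contrast, and a likelihood-ratio test of one-mean vs
#' per-condition means across the ordered three-condition design, with
#' Benjamini-Hochberg correction across features.  Bit-exact concordance
#' with any particular external DE package is not a goal; calibration is
#' (type-I error of the raw tests is validated by simulation in the test
#' suite).
#'
#' @name stats-module
NULL

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over features with nonzero counts
#' in every sample, of the ratio of that sample's count to the feature's
#' geometric mean; log factors are then mean-centered.  When no feature is
#' nonzero in all samples, library-size scaling is used instead (with a
#' message).
#'
#' @param raw features x samples count matrix.
#' @return positive numeric vector, one factor per sample, mean-centered
#'   in log space.
#' @export
size_factors <- function(raw) {
  raw <- as.matrix(raw)
  ok <- rowSums(raw > 0) == ncol(raw)
  if (!any(ok)) {
    message("no feature nonzero in all samples; using library-size scaling")
    ls <- colSums(raw)
    sf <- ls / exp(mean(log(ls)))
    return(sf)
  }
  sub <- raw[ok, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2L, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stopifnot(all(sf > 0))
  sf
}

# Newton fit of a single NB log-mean with offsets: y_j ~ NB(mu_j, alpha),
# mu_j = q * s_j.  Returns log(q) (or -Inf for all-zero y).
.nb_fit_mean <- function(y, s, alpha) {
  if (all(y == 0)) return(-Inf)
  th <- log(sum(y) / sum(s))
  for (it in 1:50) {
    mu <- exp(th) * s
    U <- sum((y - mu) / (1 + alpha * mu))
    I <- sum(mu / (1 + alpha * mu))
    step <- U / I
    step <- max(min(step, 2), -2)
    th <- th + step
    if (abs(step) < 1e-10) break
  }
  th
}

.nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-12)
    sum(stats::dpois(y, lambda = pmax(mu, 1e-300), log = TRUE))
  else
    sum(stats::dnbinom(y, size = 1 / alpha, mu = pmax(mu, 1e-300), log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood of alpha for one feature under
# per-group means; the -0.5*log|I| adjustment removes most of the downward
# bias of the dispersion estimate at few replicates.
.nb_profile_ll <- function(y, s, group, alpha) {
  ll <- 0
  for (g in levels(group)) {
    i <- group == g
    th <- .nb_fit_mean(y[i], s[i], alpha)
    mu <- if (is.finite(th)) exp(th) * s[i] else rep(1e-300, sum(i))
    ll <- ll + .nb_loglik(y[i], mu, alpha)
    info <- sum(mu / (1 + alpha * mu))
    if (info > 0) ll <- ll - 0.5 * log(info)
  }
  ll
}

#' Estimate per-feature NB dispersions with trend shrinkage
#'
#' Per feature, the dispersion is estimated by maximizing the profile
#' likelihood (group means profiled out); a parametric mean-dispersion
#' trend `alpha(mu) = a0 + a1/mu` is then fit across features, and each
#' feature's log dispersion is shrunk toward the trend with a prior weight
#' of `prior_df` degrees of freedom against the feature's residual
#' degrees of freedom.  Floored at 1e-8.
#'
#' @param raw features x samples counts.
#' @param sf size factors.
#' @param group factor of sample conditions.
#' @param prior_df strength of shrinkage toward the trend (default 50:
#'   with 2-3 replicates per condition a feature contributes only a few
#'   residual degrees of freedom, so the trend dominates unless the
#'   feature's own estimate is strongly informative).
#' @return list with `alpha` (shrunk, used for testing), `alpha_mle`,
#'   `alpha_trend`, `base_mean` (mean of normalized counts).
#' @export
estimate_dispersions <- function(raw, sf, group, prior_df = 50) {
  raw <- as.matrix(raw)
  group <- droplevels(as.factor(group))
  norm <- sweep(raw, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  nuse <- base_mean > 0
  alpha_mle <- rep(NA_real_, nrow(raw))
  for (f in which(nuse)) {
    y <- raw[f, ]
    opt <- stats::optimize(function(la) .nb_profile_ll(y, sf, group, exp(la)),
                           interval = log(c(1e-8, 30)), maximum = TRUE,
                           tol = 1e-4)
    alpha_mle[f] <- exp(opt$maximum)
  }
  # parametric trend alpha = a0 + a1/mu, robust iterated least squares
  a0 <- stats::median(alpha_mle[nuse], na.rm = TRUE)
  a1 <- 0
  use <- which(nuse & alpha_mle > 2e-8)     # exclude boundary fits
  if (length(use) >= 10) {
    x <- 1 / base_mean[use]; yv <- alpha_mle[use]
    w <- rep(1, length(use))
    for (it in 1:5) {
      fit <- stats::lm.wfit(cbind(1, x), yv, w)
      co <- fit$coefficients
      pred <- pmax(co[1] + co[2] * x, 1e-8)
      res <- abs(yv - pred) / pred
      w <- 1 / pmax(res, 0.01)^2
    }
    a0 <- max(co[1], 1e-8); a1 <- max(co[2], 0)
  }
  alpha_trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), 1e-8)
  resid_df <- max(ncol(raw) - nlevels(group), 1L)
  la <- (resid_df * log(pmax(alpha_mle, 1e-8)) +
           prior_df * log(alpha_trend)) / (resid_df + prior_df)
  alpha <- pmax(exp(la), 1e-8)
  alpha[!nuse] <- NA_real_
  list(alpha = alpha, alpha_mle = alpha_mle, alpha_trend = alpha_trend,
       base_mean = base_mean)
}

#' Negative-binomial Wald test of differential expression
#'
#' Per feature, fits one NB mean per condition (size factors as offsets,
#' shrunk dispersion) and tests the log fold change `cond_b` vs `cond_a`
#' with a two-sided Wald test; BH correction across features.  A feature
#' is "called" when its FDR is below `alpha_fdr` and its absolute fold
#' change is at least `fc_threshold` (1.5, i.e. |log2 FC| >= 0.585).
#'
#' @param raw features x samples count matrix (rownames = feature ids).
#' @param conditions named vector sample -> condition (order matches
#'   columns when unnamed).
#' @param cond_a reference condition; `cond_b` the comparison (fold change
#'   is `cond_b` / `cond_a`).
#' @param cond_b comparison condition.
#' @param fc_threshold fold-change filter (default 1.5).
#' @param alpha_fdr FDR cut-off (default 0.05).
#' @param prior_df dispersion shrinkage strength.
#' @return data.frame: feature, baseMean, log2fc, se, p, fdr, called.
#'   All-zero features carry NA p and are excluded from the BH family.
#' @export
de_test <- function(raw, conditions, cond_a, cond_b, fc_threshold = 1.5,
                    alpha_fdr = 0.05, prior_df = 50) {
  raw <- as.matrix(raw)
  if (!is.null(names(conditions)) && !is.null(colnames(raw)))
    conditions <- conditions[colnames(raw)]
  sel <- conditions %in% c(cond_a, cond_b)
  raw2 <- raw[, sel, drop = FALSE]
  group <- factor(conditions[sel], levels = c(cond_a, cond_b))
  stopifnot(min(table(group)) >= 2)
  sf <- size_factors(raw2)
  disp <- estimate_dispersions(raw2, sf, group, prior_df = prior_df)
  n <- nrow(raw2)
  log2fc <- se <- p <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    a <- disp$alpha[f]
    if (is.na(a)) next
    y <- raw2[f, ]
    th <- info <- numeric(2)
    for (k in 1:2) {
      i <- group == levels(group)[k]
      th[k] <- .nb_fit_mean(y[i], sf[i], a)
      mu <- exp(th[k]) * sf[i]
      info[k] <- sum(mu / (1 + a * mu))
    }
    if (!all(is.finite(th))) {
      # one group all zero: infinite MLE fold change; report a large,
      # finite effect via a 0.5-pseudocount refit for direction only
      th <- vapply(1:2, function(k) {
        i <- group == levels(group)[k]
        log((sum(y[i]) + 0.5) / sum(sf[i]))
      }, numeric(1))
      info[info == 0] <- 0.5
    }
    beta <- th[2] - th[1]
    v <- 1 / info[1] + 1 / info[2]
    log2fc[f] <- beta / log(2)
    se[f] <- sqrt(v) / log(2)
    z <- beta / sqrt(v)
    p[f] <- 2 * stats::pnorm(-abs(z))
  }
  fdr <- rep(NA_real_, n)
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  called <- !is.na(fdr) & fdr < alpha_fdr & abs(log2fc) >= log2(fc_threshold)
  data.frame(feature = rownames(raw2) %||% as.character(seq_len(n)),
             baseMean = disp$base_mean, log2fc = log2fc, se = se,
             p = p, fdr = fdr, called = called,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Likelihood-ratio trend test across ordered conditions
#'
#' Per feature, compares the NB likelihood of one mean per condition
#' against a single common mean (size-factor offsets, shared shrunk
#' dispersion): statistic 2 * (llfull - llreduced), chi-square with
#' (n conditions - 1) degrees of freedom, BH across features.  Group
#' means are also returned on the log2(RPM-like + 1) normalized scale and
#' the trend shape classified via [classify_shape].
#'
#' @inheritParams de_test
#' @param conditions named vector sample -> condition; `cond_order` gives
#'   the ordered levels (default Young, SEN, SEN+M ordering = order of
#'   first appearance).
#' @param cond_order character vector of ordered condition levels.
#' @return data.frame: feature, means (one column per condition,
#'   normalized-count means), lrt_stat, p, fdr, shape.
#' @export
lrt_trend <- function(raw, conditions, cond_order = NULL, alpha_fdr = 0.05,
                      prior_df = 50) {
  raw <- as.matrix(raw)
  if (!is.null(names(conditions)) && !is.null(colnames(raw)))
    conditions <- conditions[colnames(raw)]
  if (is.null(cond_order)) cond_order <- unique(unname(conditions))
  group <- factor(conditions, levels = cond_order)
  stopifnot(nlevels(group) >= 2, min(table(group)) >= 2)
  sf <- size_factors(raw)
  disp <- estimate_dispersions(raw, sf, group, prior_df = prior_df)
  n <- nrow(raw)
  stat <- p <- rep(NA_real_, n)
  means <- matrix(NA_real_, n, nlevels(group),
                  dimnames = list(NULL, cond_order))
  for (f in seq_len(n)) {
    a <- disp$alpha[f]
    if (is.na(a)) next
    y <- raw[f, ]
    ll_full <- 0
    for (k in seq_len(nlevels(group))) {
      i <- group == cond_order[k]
      th <- .nb_fit_mean(y[i], sf[i], a)
      mu <- if (is.finite(th)) exp(th) * sf[i] else rep(1e-300, sum(i))
      means[f, k] <- mean(y[i] / sf[i])
      ll_full <- ll_full + .nb_loglik(y[i], mu, a)
    }
    th0 <- .nb_fit_mean(y, sf, a)
    mu0 <- exp(th0) * sf
    ll_red <- .nb_loglik(y, mu0, a)
    stat[f] <- max(2 * (ll_full - ll_red), 0)
    p[f] <- stats::pchisq(stat[f], df = nlevels(group) - 1L,
                          lower.tail = FALSE)
  }
  fdr <- rep(NA_real_, n)
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  shape <- if (nlevels(group) == 3L)
    classify_shape(means, fdr, alpha_fdr = alpha_fdr)
  else rep(NA_character_, n)
  out <- data.frame(feature = rownames(raw) %||% as.character(seq_len(n)),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_len(ncol(means))) out[[paste0("mean_", cond_order[k])]] <-
    means[, k]
  out$lrt_stat <- stat; out$p <- p; out$fdr <- fdr; out$shape <- shape
  out
}

#' Classify the trend shape of three ordered group means
#'
#' `flat` unless the trend test FDR is below `alpha_fdr`; otherwise
#' `linear-up` / `linear-down` when both transitions move in the same
#' direction (a zero transition inherits the other's direction), `U` for
#' down-then-up, `inverted-U` for up-then-down.  Invariant under any
#' strictly monotone rescaling of the means.
#'
#' @param means matrix (features x 3 ordered conditions) of group means.
#' @param fdr trend-test FDR per feature (NA treated as flat).
#' @param alpha_fdr significance cut-off (default 0.05).
#' @return character vector of shapes.
#' @export
classify_shape <- function(means, fdr, alpha_fdr = 0.05) {
  means <- as.matrix(means)
  stopifnot(ncol(means) == 3L)
  d1 <- means[, 2L] - means[, 1L]
  d2 <- means[, 3L] - means[, 2L]
  shape <- rep("flat", nrow(means))
  sig <- !is.na(fdr) & fdr < alpha_fdr
  up <- sig & ((d1 >= 0 & d2 >= 0) & (d1 + d2 > 0))
  dn <- sig & ((d1 <= 0 & d2 <= 0) & (d1 + d2 < 0))
  ush <- sig & d1 < 0 & d2 > 0
  ish <- sig & d1 > 0 & d2 < 0
  shape[up] <- "linear-up"; shape[dn] <- "linear-down"
  shape[ush] <- "U"; shape[ish] <- "inverted-U"
  shape
}

#' Pooled two-proportion z-test
#'
#' Two-sided normal test of H0: p1 == p2 with the pooled-variance z
#' statistic.  Degenerate tables (no successes, or no failures, in the
#' pooled sample) return p = 1.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return two-sided p-value.
#' @export
ztest_proportions <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  if (x1 + x2 == 0 || x1 + x2 == n1 + n2) return(1)
  p_pool <- (x1 + x2) / (n1 + n2)
  z <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-abs(z))
}

#' Homogeneity test of the global isomiR category distribution
#'
#' Tests whether the pooled six-way category distribution differs between
#' two conditions: chi-square test of homogeneity by default, or a
#' Monte-Carlo permutation test holding the table margins fixed.
#'
#' @param counts_a,counts_b named category count vectors (same categories).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo replicates for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return p-value.
#' @export
global_category_test <- function(counts_a, counts_b,
                                 method = c("chisq", "permutation"),
                                 n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  tab <- rbind(a = counts_a, b = counts_b)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) return(1)
  exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cnt < 5))
    message("expected cell count < 5; chi-square approximation may be crude")
  stat <- sum((tab - exp_cnt)^2 / exp_cnt)
  if (method == "chisq") {
    stats::pchisq(stat, df = ncol(tab) - 1L, lower.tail = FALSE)
  } else {
    set.seed(seed)
    null_tabs <- stats::r2dtable(n_perm, rowSums(tab), colSums(tab))
    null_stat <- vapply(null_tabs, function(tt)
      sum((tt - exp_cnt)^2 / exp_cnt), numeric(1))
    (1 + sum(null_stat >= stat - 1e-12)) / (1 + n_perm)
  }
}

#' Sample QC: pairwise Pearson correlation and PCA
#'
#' Both computed on log2(normalized + 1): the correlation matrix across
#' samples, and a PCA of samples (features centered; constant features
#' dropped with a message) with per-component variance fractions.
#'
#' @param rpm features x samples normalized matrix (e.g. RPM).
#' @return list: `correlation` (samples x samples), `pca` (scores matrix
#'   samples x components), `variance_fraction`.
#' @export
qc_summary <- function(rpm) {
  lg <- log2(as.matrix(rpm) + 1)
  cors <- stats::cor(lg, method = "pearson")
  v <- apply(lg, 1L, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " constant feature(s) dropped before PCA")
    lg <- lg[v > 0, , drop = FALSE]
  }
  if (!nrow(lg)) {
    message("all features constant across samples; PCA skipped")
    return(list(correlation = cors, pca = NULL, variance_fraction = NULL))
  }
  pc <- stats::prcomp(t(lg), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(correlation = cors, pca = pc$x, variance_fraction = vf)
}
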