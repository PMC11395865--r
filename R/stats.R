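#' Intraclass correlation ICC(2,k) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, average-measures intraclass
#' correlation (Shrout-Fleiss "ICC(2,k)" / McGraw-Wong ICC(A,k)) for a
#' complete targets-by-raters table of measurements. Mean squares come
#' from the two-way ANOVA decomposition (targets + raters):
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' with `MSR` the between-target, `MSC` the between-rater and `MSE` the
#' residual mean square. The confidence interval follows the
#' Satterthwaite-approximate F bounds for the single-measure ICC(2,1),
#' stepped up to average measures by the Spearman-Brown relation. The
#' qualitative band (poor / moderate / good / excellent at 0.5, 0.75, 0.9)
#' is reported alongside.
#'
#' @param ratings numeric matrix or data frame, rows = targets
#'   (lesions/cases), columns = raters; complete (no missing cells),
#'   at least 2 targets and 2 raters.
#' @param conf_level confidence level (default 0.95).
#' @return list: `icc`, `ci` (length-2), `interpretation`, `ms` (the three
#'   mean squares), `n`, `k`, `degenerate` (`TRUE` when the between-target
#'   variance is zero, making the coefficient unstable).
#' @export
icc2k <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("icc2k: table must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("icc2k: need at least 2 targets and 2 raters")
  long <- data.frame(value = as.vector(m),
                     target = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(value ~ target + rater, data = long)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- c("MSR", "MSC", "MSE")
  msr <- ms[["MSR"]]; msc <- ms[["MSC"]]; mse <- ms[["MSE"]]
  degenerate <- msr <= mse || isTRUE(all.equal(stats::var(rowMeans(m)), 0))
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  # single-measure ICC(2,1) F-based bounds (Shrout & Fleiss 1979)
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
  vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
    (n * (1 + (k - 1) * icc1) - k * icc1)^2
  v <- vn / vd
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)  # Spearman-Brown step-up
  ci <- sort(c(sb(l1), sb(u1)))  # step-up is non-monotone below r = -1/(k-1)
  band <- function(x) {
    if (!is.finite(x)) return(NA_character_)
    if (x < 0.5) "poor" else if (x < 0.75) "moderate"
    else if (x < 0.9) "good" else "excellent"
  }
  list(icc = icc, ci = ci, interpretation = band(icc), ms = ms,
       n = n, k = k, conf_level = conf_level, degenerate = degenerate)
}

#' Consistency-type average-measures ICC(3,k)
#'
#' Two-way mixed, consistency, average measures: `(MSR - MSE) / MSR`.
#' Unlike [icc2k()], a constant offset between raters does not lower it.
#'
#' @inheritParams icc2k
#' @return the coefficient (scalar).
#' @export
icc3k <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("icc3k: need at least 2 targets and 2 raters")
  long <- data.frame(value = as.vector(m),
                     target = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ target + rater, data = long))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / ms[1]
}

#' Pearson correlation with R-squared and p-value
#'
#' Product-moment correlation via [stats::cor.test()], reporting `r`,
#' `R^2 = r^2` and the two-sided p-value from the t transform.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list: `r`, `r_squared`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pearson_correlation: need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_correlation: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

#' Tukey HSD pairwise comparisons across groups
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test
#' (studentized-range family-wise adjustment, alpha = 0.05 convention).
#' The unadjusted pooled-variance pairwise p-value is reported next to the
#' adjusted one; the adjusted value is never smaller.
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @param conf_level family-wise confidence level.
#' @return data frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `p_unadj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("tukey_hsd: need >= 2 groups with n >= 2 each")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  long <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(names(groups), lengths(groups)),
                                    levels = names(groups)))
  fit <- stats::aov(value ~ group, data = long)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  dfe <- stats::df.residual(fit)
  cmp <- rownames(tk)
  p_unadj <- vapply(cmp, function(cc) {
    ab <- strsplit(cc, "-", fixed = TRUE)[[1]]
    na <- length(groups[[ab[1]]]); nb <- length(groups[[ab[2]]])
    tstat <- (mean(groups[[ab[1]]]) - mean(groups[[ab[2]]])) /
      sqrt(mse * (1 / na + 1 / nb))
    2 * stats::pt(-abs(tstat), dfe)
  }, 0)
  data.frame(comparison = cmp, diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], p_unadj = p_unadj,
             row.names = NULL)
}

#' Compare perfusion and wash-out volumes per subgroup
#'
#' Paired (default) or two-sample t-tests of perfusion versus wash-out
#' volume, overall and per subgroup, with mean +/- SD descriptives shaped
#' like a per-subgroup volumetric results table.
#'
#' @param perfusion_mm3,washout_mm3 numeric vectors of per-lesion volumes
#'   (equal length when `paired`).
#' @param subgroup optional factor/character of subgroup labels per lesion.
#' @param paired paired per lesion (`TRUE`, default) or independent.
#' @return data frame with one row per subgroup (plus `"all"`): n, means,
#'   SDs, `t`, `p`.
#' @export
compare_volumes <- function(perfusion_mm3, washout_mm3, subgroup = NULL,
                            paired = TRUE) {
  if (paired && length(perfusion_mm3) != length(washout_mm3))
    stop("compare_volumes: paired vectors must have equal length")
  groups <- if (is.null(subgroup)) list(all = seq_along(perfusion_mm3))
  else c(list(all = seq_along(perfusion_mm3)),
         split(seq_along(perfusion_mm3), subgroup))
  do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    p <- perfusion_mm3[i]; w <- washout_mm3[i]
    if (length(i) < 2) stop("compare_volumes: subgroup '", g,
                            "' has fewer than 2 pairs")
    sdd <- stats::sd(p - w)
    tt <- if (paired && sdd <= 1e-10 * (max(abs(c(p, w))) + 1)) {
      # degenerate paired case: (numerically) constant differences
      if (abs(mean(p - w)) <= 1e-10 * (max(abs(c(p, w))) + 1))
        list(statistic = 0, p.value = 1)
      else list(statistic = sign(mean(p - w)) * Inf, p.value = 0)
    } else stats::t.test(p, w, paired = paired)
    data.frame(subgroup = g, n = length(i),
               perfusion_mean = mean(p), perfusion_sd = stats::sd(p),
               washout_mean = mean(w), washout_sd = stats::sd(w),
               t = unname(tt$statistic), p = tt$p.value)
  }))
}

#' Summarize Likert agreement scores per subgroup on the 0-100% scale
#'
#' Scores on the 11-point 0-10 scale are multiplied by 10 to percent
#' agreement, then summarized as mean +/- SD per subgroup. Sample SD
#' (n - 1) is the default convention; population SD is available. A
#' single-observation subgroup reports SD 0 with a flag.
#'
#' @param scores integer vector of scores in 0..10.
#' @param subgroup factor/character of subgroup labels (one level for all
#'   rows if omitted).
#' @param sd `"sample"` (default) or `"population"`.
#' @return data frame: subgroup, n, `mean_pct`, `sd_pct`, `single_obs`.
#' @export
likert_agreement_summary <- function(scores, subgroup = NULL,
                                     sd = c("sample", "population")) {
  sd <- match.arg(sd)
  if (any(scores != round(scores)) || any(scores < 0 | scores > 10))
    stop("likert_agreement_summary: scores must be integers in 0..10")
  if (is.null(subgroup)) subgroup <- rep("all", length(scores))
  pct <- scores * 10
  out <- do.call(rbind, lapply(split(pct, subgroup), function(v) {
    s <- if (length(v) < 2) 0
    else if (sd == "sample") stats::sd(v)
    else sqrt(mean((v - mean(v))^2))
    data.frame(n = length(v), mean_pct = mean(v), sd_pct = s,
               single_obs = length(v) < 2)
  }))
  cbind(subgroup = rownames(out), out, row.names = NULL)
}
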