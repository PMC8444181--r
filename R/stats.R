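#' Mean-centre and scale values within groups
#'
#' Standardises each group to mean 0 and sd 1, then pools the groups. Mean
#' centring eliminates trend variation between groups; dividing by the
#' group standard deviation equalises group variances, so multiple groups
#' can be screened for normality together with a larger effective sample.
#'
#' @param values numeric measurements.
#' @param groups grouping vector, same length as `values`.
#' @return numeric vector of pooled standardised values (input order
#'   preserved).
#' @export
center_scale <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  out <- numeric(length(values))
  for (g in levels(groups)) {
    idx <- groups == g
    v <- values[idx]
    if (length(v) < 2L) {
      stop("group '", g, "' has fewer than 2 values", call. = FALSE)
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("group '", g, "' has zero spread: cannot scale", call. = FALSE)
    }
    out[idx] <- (v - mean(v)) / s
  }
  out
}

#' Kolmogorov-Smirnov screen for normality
#'
#' One-sample KS test of pooled standardised values against the standard
#' normal; the gatekeeper for applying the parametric ANOVA scheme.
#'
#' @param standardized values from [center_scale()] (>= 5 values).
#' @return list with `statistic` and `p.value`.
#' @export
ks_normality <- function(standardized) {
  if (length(standardized) < 5L || !all(is.finite(standardized))) {
    stop("need >= 5 finite standardised values", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(standardized, "pnorm"))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' N-way fixed-effects ANOVA (main effects)
#'
#' Tests each named factor's main effect on the response; no interaction
#' terms are fitted. With the balanced designs produced by the simulator the
#' factors are orthogonal, so the sums-of-squares decomposition does not
#' depend on factor order.
#'
#' @param values numeric response (e.g. MI or CC in bits, one per
#'   replicate-condition).
#' @param factors data.frame of factor columns (e.g. genotype, dose), same
#'   number of rows as `length(values)`.
#' @return data.frame with one row per factor: `factor`, `df`, `F`, `p`.
#' @export
anova_nway <- function(values, factors) {
  stopifnot(is.data.frame(factors), nrow(factors) == length(values))
  factors <- as.data.frame(lapply(factors, as.factor))
  for (nm in names(factors)) {
    if (nlevels(factors[[nm]]) < 2L) {
      stop("factor '", nm, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  dat <- cbind(.y = values, factors)
  fit <- stats::lm(.y ~ ., data = dat)
  at <- stats::anova(fit)
  keep <- rownames(at) != "Residuals"
  data.frame(
    factor = rownames(at)[keep],
    df = at$Df[keep],
    F = at$`F value`[keep],
    p = at$`Pr(>F)`[keep],
    stringsAsFactors = FALSE
  )
}

#' One-way ANOVA between two groups
#'
#' The direct pairwise comparison of the post-hoc scheme. For two groups
#' the F statistic equals the square of the pooled two-sample t statistic.
#'
#' @param A,B numeric vectors (>= 2 values each).
#' @return list with `F`, `p`, and degrees of freedom `df1`, `df2`.
#' @export
anova_1way <- function(A, B) {
  if (length(A) < 2L || length(B) < 2L) {
    stop("both groups need >= 2 values", call. = FALSE)
  }
  values <- c(A, B)
  # equal group means: between-group sum of squares is exactly zero
  if (stats::sd(values) == 0 || mean(A) == mean(B)) {
    return(list(F = 0, p = 1, df1 = 1L, df2 = length(values) - 2L))
  }
  grp <- factor(rep(c("A", "B"), c(length(A), length(B))))
  at <- stats::anova(stats::lm(values ~ grp))
  list(
    F = at$`F value`[1L], p = at$`Pr(>F)`[1L],
    df1 = at$Df[1L], df2 = at$Df[2L]
  )
}

#' Unbiased Cohen's d between two groups
#'
#' Standardised mean difference `d_unb = (m_A - m_B) / s_AB` with the
#' pooled scale `s_AB = sqrt((SS_A + SS_B) / (df_A + df_B))`, where `SS`
#' are within-group sums of squares and `df = n - 1` per group — the
#' substitution of the population sigma that accounts for unequal group
#' sizes and variances.
#'
#' @param A,B numeric vectors (>= 2 values each).
#' @return object of class `effect_size`: `d_unb`, `m_A`, `m_B`, `SS_A`,
#'   `SS_B`, `df_A`, `df_B`, `s_AB`, `category` (see [classify_effect()]).
#' @export
cohens_d_unbiased <- function(A, B) {
  if (length(A) < 2L || length(B) < 2L) {
    stop("both groups need >= 2 values", call. = FALSE)
  }
  m_A <- mean(A)
  m_B <- mean(B)
  SS_A <- sum((A - m_A)^2)
  SS_B <- sum((B - m_B)^2)
  df_A <- length(A) - 1L
  df_B <- length(B) - 1L
  s_AB <- sqrt((SS_A + SS_B) / (df_A + df_B))
  if (s_AB == 0) {
    stop("zero pooled scale: both groups are constant", call. = FALSE)
  }
  d <- (m_A - m_B) / s_AB
  structure(
    list(
      d_unb = d, m_A = m_A, m_B = m_B, SS_A = SS_A, SS_B = SS_B,
      df_A = df_A, df_B = df_B, s_AB = s_AB,
      category = classify_effect(d)
    ),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf(
    "d_unb = %.4f (%s effect; m_A = %.4g, m_B = %.4g, s_AB = %.4g)\n",
    x$d_unb, x$category, x$m_A, x$m_B, x$s_AB
  ))
  invisible(x)
}

#' Classify an effect size
#'
#' `|d| > 0.8`: large; `|d| > 0.5`: medium; `|d| > 0.2`: small; otherwise
#' negligible (exclusive lower bounds).
#'
#' @param d effect size (finite; an `effect_size` object is also accepted).
#' @return one of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
classify_effect <- function(d) {
  if (inherits(d, "effect_size")) d <- d$d_unb
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d))
  a <- abs(d)
  if (a > 0.8) "large" else if (a > 0.5) "medium" else if (a > 0.2) "small" else "negligible"
}

#' Two-stage significance decision
#'
#' A comparison is flagged (starred) only when the ANOVA p-value is at most
#' 0.05 AND the unbiased effect size exceeds 0.2 in magnitude — the
#' p-then-d post-hoc criterion. The effect category is attached either way.
#'
#' @param p p-value from [anova_1way()].
#' @param effect an `effect_size` from [cohens_d_unbiased()] (or a bare
#'   numeric d).
#' @return list with `flagged`, `p`, `d_unb`, `category`.
#' @export
significance_decision <- function(p, effect) {
  d <- if (inherits(effect, "effect_size")) effect$d_unb else effect
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1, is.finite(d))
  list(
    flagged = p <= 0.05 && abs(d) > 0.2,
    p = p, d_unb = d, category = classify_effect(d)
  )
}

#' Pearson correlation coefficient
#'
#' @param x,y equal-length numeric vectors (>= 3 values, nonzero variance).
#' @return the sample correlation `r`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Compare per-replicate correlation coefficients between two conditions
#'
#' Two-sample Student's t-test between the Pearson coefficients obtained
#' from independent biological replicates of two conditions (e.g.
#' saturating stimulation vs unstimulated). The reported `beta` is the
#' difference of group mean correlations, `mean(r_A) - mean(r_B)`.
#'
#' @param r_A,r_B numeric vectors of per-replicate correlations (>= 2
#'   each).
#' @param var_equal pooled-variance t-test (default TRUE, consistent with
#'   the pooled-scale convention of the effect-size formulas); FALSE for
#'   Welch.
#' @return list with `beta`, `t`, `p`, `df`.
#' @export
compare_replicate_correlations <- function(r_A, r_B, var_equal = TRUE) {
  if (length(r_A) < 2L || length(r_B) < 2L) {
    stop("each condition needs >= 2 replicate correlations", call. = FALSE)
  }
  beta <- mean(r_A) - mean(r_B)
  if (stats::sd(c(r_A, r_B)) == 0) {
    return(list(beta = beta, t = 0, p = 1, df = length(r_A) + length(r_B) - 2L))
  }
  tt <- stats::t.test(r_A, r_B, var.equal = var_equal)
  list(
    beta = beta, t = unname(tt$statistic), p = tt$p.value,
    df = unname(tt$parameter)
  )
}

#' All pairwise group comparisons under the p-then-d scheme
#'
#' Runs [anova_1way()] + [cohens_d_unbiased()] + [significance_decision()]
#' for every pair of groups.
#'
#' @param values numeric measurements.
#' @param groups grouping vector.
#' @return data.frame with one row per pair: `group_A`, `group_B`, `F`,
#'   `p`, `d_unb`, `category`, `flagged`.
#' @export
pairwise_comparisons <- function(values, groups) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    A <- values[groups == pr[1L]]
    B <- values[groups == pr[2L]]
    av <- anova_1way(A, B)
    ef <- cohens_d_unbiased(A, B)
    dec <- significance_decision(av$p, ef)
    data.frame(
      group_A = pr[1L], group_B = pr[2L], F = av$F, p = av$p,
      d_unb = ef$d_unb, category = ef$category, flagged = dec$flagged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
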