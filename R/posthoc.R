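#' Welch's two-sample t-test
#'
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value. If both samples have zero variance
#' and equal means the test degenerates to t = 0, df = n1 + n2 - 2, p = 1
#' (flagged).
#'
#' @param x1,x2 numeric samples with >= 2 values each.
#' @return A `stat_result` list: `statistic`, `df`, `p`, `kind`,
#'   `degenerate`.
#' @export
welch_t_test <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("both samples need >= 2 values")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    d <- mean(x1) - mean(x2)
    return(structure(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                          df = n1 + n2 - 2,
                          p = if (d == 0) 1 else 0,
                          kind = "welch_t", degenerate = TRUE),
                     class = "stat_result"))
  }
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  structure(list(statistic = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 kind = "welch_t", degenerate = FALSE),
            class = "stat_result")
}

#' Four-group analysis of variance
#'
#' One-way fixed-effects ANOVA across the four diagnosis-by-sex cells
#' (default; df = 3 and n - 4, matching the study design's F(3, 189) at
#' n = 193). `method = "welch"` gives the unequal-variance Welch ANOVA;
#' `method = "factorial"` gives the two-way diagnosis x sex interaction F.
#'
#' @param values numeric response.
#' @param groups factor with four non-empty cells.
#' @param method `"oneway"`, `"welch"` or `"factorial"`.
#' @return A `stat_result` with `statistic` (F), `df` (numerator,
#'   denominator), `p`.
#' @export
fourgroup_anova <- function(values, groups,
                            method = c("oneway", "welch", "factorial")) {
  method <- match.arg(method)
  # empty declared levels are an error, so do not drop them via factor()
  if (!is.factor(groups)) groups <- factor(groups)
  cnt <- table(groups)
  if (any(cnt == 0)) stop("empty cell: ", names(cnt)[cnt == 0][1])
  g <- nlevels(groups)
  n <- length(values)
  if (method == "factorial") {
    parts <- strsplit(levels(groups)[groups], "_", fixed = TRUE)
    dx <- factor(vapply(parts, `[`, "", 1))
    sx <- factor(vapply(parts, `[`, "", 2))
    a <- stats::anova(stats::lm(values ~ dx * sx))
    return(structure(list(statistic = a["dx:sx", "F value"],
                          df = c(a["dx:sx", "Df"], a["Residuals", "Df"]),
                          p = a["dx:sx", "Pr(>F)"],
                          kind = "anova_factorial", degenerate = FALSE),
                     class = "stat_result"))
  }
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  if (method == "oneway") {
    grand <- mean(values)
    ss_b <- sum(cnt * (means - grand)^2)
    ss_w <- sum((cnt - 1) * vars)
    df1 <- g - 1; df2 <- n - g
    if (ss_w == 0) {
      degenerate <- ss_b == 0
      return(structure(list(statistic = if (degenerate) 0 else Inf,
                            df = c(df1, df2),
                            p = if (degenerate) 1 else 0,
                            kind = "anova_oneway", degenerate = TRUE),
                       class = "stat_result"))
    }
    f <- (ss_b / df1) / (ss_w / df2)
    structure(list(statistic = f, df = c(df1, df2),
                   p = stats::pf(f, df1, df2, lower.tail = FALSE),
                   kind = "anova_oneway", degenerate = FALSE),
              class = "stat_result")
  } else {
    if (any(vars == 0)) {
      return(structure(list(statistic = NA_real_, df = c(g - 1, NA),
                            p = 1, kind = "anova_welch", degenerate = TRUE),
                       class = "stat_result"))
    }
    w <- cnt / vars
    mw <- sum(w * means) / sum(w)
    A <- sum(w * (means - mw)^2) / (g - 1)
    lambda <- sum((1 - w / sum(w))^2 / (cnt - 1))
    B <- 1 + 2 * (g - 2) / (g^2 - 1) * lambda
    f <- A / B
    df2 <- (g^2 - 1) / (3 * lambda)
    structure(list(statistic = f, df = c(g - 1, df2),
                   p = stats::pf(f, g - 1, df2, lower.tail = FALSE),
                   kind = "anova_welch", degenerate = FALSE),
              class = "stat_result")
  }
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: q_(i) = min over j >= i of m p_(j) / j, capped at 1;
#' hypotheses with q <= alpha are rejected (equivalently, all hypotheses up
#' to the largest i with p_(i) <= i alpha / m).
#'
#' @param p numeric p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return list with `q` (adjusted values, input order) and `reject`
#'   (logical).
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(list(q = numeric(0), reject = logical(0)))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, reject = q <= alpha)
}

#' Pearson chi-squared test on a 2 x 2 table
#'
#' Without continuity correction by default (Yates correction available).
#'
#' @param counts 2 x 2 non-negative count matrix with positive margins.
#' @param correct apply the Yates continuity correction.
#' @return A `stat_result` with `statistic` (chi-squared), `df` = 1, `p`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2) || any(counts < 0)) stop("need a 2 x 2 count table")
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  E <- outer(rs, cs) / n
  dev <- abs(counts - E)
  if (correct) dev <- pmax(0, dev - 0.5)
  x2 <- sum(dev^2 / E)
  structure(list(statistic = x2, df = 1,
                 p = stats::pchisq(x2, 1, lower.tail = FALSE),
                 kind = "chi_square", degenerate = FALSE),
            class = "stat_result")
}

#' A posteriori feature screen
#'
#' Residualizes age and site out of every feature (unless disabled), then
#' runs, per feature, Welch's t-test between diagnosis groups and the
#' four-group ANOVA across diagnosis-by-sex cells. Benjamini-Hochberg
#' correction is applied separately within each test family across all
#' features.
#'
#' @param features feature matrix with `<region>__<measure>` columns.
#' @param cohort matching `cohort_table`.
#' @param alpha FDR level.
#' @param residualize regress age/site out first (default `TRUE`).
#' @param anova_method passed to [fourgroup_anova()].
#' @return data.frame with one row per feature: `feature`, `region`,
#'   `measure`, Welch columns (`t`, `df_t`, `p_t`, `q_t`, `sig_t`) and
#'   ANOVA columns (`F`, `df1`, `df2`, `p_F`, `q_F`, `sig_F`), sorted by
#'   region then measure.
#' @export
screen_features <- function(features, cohort, alpha = 0.05,
                            residualize = TRUE, anova_method = "oneway") {
  if (ncol(features) == 0) {
    return(data.frame(feature = character(), region = character(),
                      measure = character(), t = numeric(), df_t = numeric(),
                      p_t = numeric(), q_t = numeric(), sig_t = logical(),
                      F = numeric(), df1 = numeric(), df2 = numeric(),
                      p_F = numeric(), q_F = numeric(), sig_F = logical()))
  }
  if (residualize) features <- residualize_covariates(features, cohort)
  meta <- parse_feature_names(colnames(features))
  asd <- cohort$diagnosis == "ASD"
  groups <- cohort_groups(cohort)
  tt <- apply(features, 2, function(v) {
    r <- welch_t_test(v[asd], v[!asd])
    c(r$statistic, r$df, r$p)
  })
  aa <- apply(features, 2, function(v) {
    r <- fourgroup_anova(v, groups, method = anova_method)
    c(r$statistic, r$df[1], r$df[2], r$p)
  })
  bh_t <- benjamini_hochberg(tt[3, ], alpha)
  bh_f <- benjamini_hochberg(aa[4, ], alpha)
  out <- data.frame(
    feature = colnames(features), region = meta$region,
    measure = meta$measure,
    t = tt[1, ], df_t = tt[2, ], p_t = tt[3, ], q_t = bh_t$q,
    sig_t = bh_t$reject,
    F = aa[1, ], df1 = aa[2, ], df2 = aa[3, ], p_F = aa[4, ], q_F = bh_f$q,
    sig_F = bh_f$reject,
    row.names = NULL
  )
  out[order(out$region, out$measure), ]
}
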