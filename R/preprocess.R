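#' Normalize regional measures by total intracranial volume
#'
#' Divides selected measure columns row-wise by each subject's TICV. The
#' default normalizes every measure (the literal protocol); restricting to
#' `c("area", "volume")` normalizes only the measures that scale with head
#' size.
#'
#' @param table feature matrix with `<region>__<measure>` column names.
#' @param cohort matching `cohort_table` (`ticv` > 0 for all subjects).
#' @param measures `"all"` or a character subset of the five measures.
#' @return normalized feature matrix.
#' @export
ticv_normalize <- function(table, cohort, measures = "all") {
  if (nrow(table) != nrow(cohort) ||
      !all(rownames(table) == cohort$subject_id)) {
    stop("subject mismatch between feature table and cohort")
  }
  if (any(cohort$ticv <= 0)) stop("all TICV values must be positive")
  meta <- parse_feature_names(colnames(table))
  sel <- if (identical(measures, "all")) rep(TRUE, ncol(table)) else
    meta$measure %in% measures
  table[, sel] <- table[, sel, drop = FALSE] / cohort$ticv
  table
}

#' Regress covariates out of every feature
#'
#' Replaces each feature column by the residuals of an ordinary least
#' squares fit on an intercept, age, and site indicator columns (S - 1
#' dummies). Redundant design columns (e.g. a single-site factor) are
#' dropped with a warning. Residuals have zero mean per feature.
#'
#' @param table feature matrix.
#' @param cohort matching `cohort_table`.
#' @param covariates subset of `c("age", "site")`.
#' @return residualized feature matrix.
#' @export
residualize_covariates <- function(table, cohort, covariates = c("age", "site")) {
  if (nrow(table) != nrow(cohort)) stop("subject mismatch")
  X <- matrix(1, nrow(cohort), 1)
  colnames(X) <- "(Intercept)"
  if ("age" %in% covariates) X <- cbind(X, age = cohort$age)
  if ("site" %in% covariates && nlevels(droplevels(cohort$site)) > 1) {
    s <- droplevels(cohort$site)
    dummies <- stats::model.matrix(~ s)[, -1, drop = FALSE]
    X <- cbind(X, dummies)
  } else if ("site" %in% covariates) {
    warning("single site is collinear with the intercept; dropped")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("rank-deficient design; dropping: ", paste(drop, collapse = ", "))
  }
  if (nrow(X) < qrX$rank + 2) stop("need >= 2 more subjects than parameters")
  res <- qr.resid(qrX, table)
  dimnames(res) <- dimnames(table)
  res
}

#' Center and scale columns to unit sample SD
#'
#' Columns are centered at their mean and divided by their sample standard
#' deviation (n - 1 denominator). Zero-variance columns are centered only,
#' given scale 1, and flagged.
#'
#' @param x numeric matrix with >= 2 rows.
#' @return list with `x` (standardized matrix), `center`, `scale` and
#'   `constant` (logical flag per column).
#' @export
standardize <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 rows")
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  constant <- sc == 0 | !is.finite(sc)
  sc[constant] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, sc, "/")
  list(x = xs, center = ctr, scale = sc, constant = constant)
}

#' Principal component analysis with a variance-retention rule
#'
#' Eigendecomposition of the sample covariance matrix of the (by default)
#' standardized features, via singular value decomposition of the centered
#' data. The retained component count k is the smallest number of leading
#' components whose cumulative explained-variance fraction reaches
#' `variance_threshold`.
#'
#' @param x numeric matrix (subjects x features), >= 2 rows.
#' @param variance_threshold cumulative explained-variance target in (0, 1\].
#' @param scale. standardize columns first (correlation PCA, default); set
#'   `FALSE` for raw-covariance PCA.
#' @return A `pca_model`: list with `center`, `scale`, `loadings`
#'   (orthonormal columns), `eigenvalues` (descending), `fractions`
#'   (explained-variance fractions summing to 1), `k` and `threshold`.
#' @export
fit_pca <- function(x, variance_threshold = 0.95, scale. = TRUE) {
  if (nrow(x) < 2) stop("need >= 2 rows")
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("`variance_threshold` must be in (0, 1]")
  }
  std <- standardize(x)
  xs <- if (scale.) std$x else sweep(x, 2, std$center)
  sv <- svd(xs)
  ev <- sv$d^2 / (nrow(x) - 1)
  tot <- sum(ev)
  fractions <- if (tot > 0) ev / tot else rep(0, length(ev))
  k <- which(cumsum(fractions) >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  structure(list(center = std$center,
                 scale = if (scale.) std$scale else rep(1, ncol(x)),
                 loadings = sv$v, eigenvalues = ev, fractions = fractions,
                 k = k, threshold = variance_threshold),
            class = "pca_model")
}

#' Project data onto retained principal components
#'
#' Applies the model's centering and scaling, then multiplies by the
#' retained loading vectors.
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param x matrix with the same columns as the training data.
#' @param k number of components (default: the model's retained count).
#' @return n x k score matrix.
#' @export
project <- function(model, x, k = model$k) {
  if (ncol(x) != length(model$center)) stop("column count mismatch")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  xs %*% model$loadings[, seq_len(k), drop = FALSE]
}
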