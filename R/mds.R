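#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds subjects from their pairwise Euclidean dissimilarities: squared
#' distances are double-centered into the Gram matrix B = -0.5 J D^2 J,
#' whose eigendecomposition yields the configuration Y = V sqrt(lambda)
#' over the positive-eigenvalue dimensions; coordinates for the leading
#' `n_dims` axes are returned. Dimensions with negative eigenvalues are
#' dropped with a warning (they cannot arise from exact Euclidean input).
#' Each eigenvector's first nonzero loading is made positive, fixing the
#' reflection ambiguity.
#'
#' @param x feature matrix (subjects x features) or a symmetric
#'   zero-diagonal distance matrix, per `input`.
#' @param n_dims embedding dimensions to report (default 3).
#' @param input `"features"` (Euclidean distances are computed) or
#'   `"distances"`.
#' @return An `mds_embedding`: list with `points` (n x n_dims), `config`
#'   (full positive-eigenvalue configuration), `eigenvalues` (descending)
#'   and `n_positive`.
#' @export
classical_mds <- function(x, n_dims = 3, input = c("features", "distances")) {
  input <- match.arg(input)
  if (n_dims < 1) stop("`n_dims` must be >= 1")
  D <- if (input == "features") {
    as.matrix(stats::dist(x))
  } else {
    d <- as.matrix(x)
    if (!isSymmetric(unname(d), tol = 1e-8) || any(abs(diag(d)) > 1e-12)) {
      stop("distance input must be symmetric with zero diagonal")
    }
    d
  }
  n <- nrow(D)
  D2 <- D^2
  # double centering: B = -0.5 * J D2 J
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  tolneg <- max(abs(ev)) * 1e-10
  if (any(ev < -tolneg)) {
    warning(sum(ev < -tolneg),
            " negative eigenvalue dimension(s) dropped (non-Euclidean input)")
  }
  pos <- which(ev > tolneg)
  V <- e$vectors[, pos, drop = FALSE]
  # reflection convention: first nonzero loading positive
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-12)[1]
    if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  config <- sweep(V, 2, sqrt(ev[pos]), "*")
  pts <- matrix(0, n, n_dims)
  keep <- seq_len(min(n_dims, ncol(config)))
  pts[, keep] <- config[, keep, drop = FALSE]
  rownames(pts) <- rownames(D)
  structure(list(points = pts, config = config, eigenvalues = ev,
                 n_positive = length(pos)),
            class = "mds_embedding")
}

#' Export an MDS embedding for external viewers
#'
#' Writes a TSV with columns `subject_id`, `x`, `y`, `z`, `diagnosis`,
#' `sex`, plus an eigenvalue scree TSV alongside (suffix `_scree.tsv`).
#'
#' @param embedding an `mds_embedding` with >= 3 reported dimensions.
#' @param path output TSV path.
#' @param cohort optional `cohort_table` supplying ids and group labels;
#'   defaults to rownames and empty labels.
#' @return invisible `path`.
#' @export
export_embedding <- function(embedding, path, cohort = NULL) {
  p <- embedding$points
  n <- nrow(p)
  ids <- if (!is.null(cohort)) cohort$subject_id else
    (rownames(p) %||% sprintf("sub-%04d", seq_len(n)))
  df <- data.frame(
    subject_id = if (n) ids else character(0),
    x = p[, 1], y = if (ncol(p) > 1) p[, 2] else 0,
    z = if (ncol(p) > 2) p[, 3] else 0,
    diagnosis = if (!is.null(cohort)) as.character(cohort$diagnosis) else
      rep("", n),
    sex = if (!is.null(cohort)) as.character(cohort$sex) else rep("", n))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  scree <- data.frame(component = seq_along(embedding$eigenvalues),
                      eigenvalue = embedding$eigenvalues)
  utils::write.table(scree, sub("\\.tsv$", "_scree.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
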