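#' Kernel specification
#'
#' @param kind `"linear"`, `"rbf"` or `"polynomial"`.
#' @param sigma RBF length scale (> 0): k(x, y) = exp(-|x - y|^2 / (2 sigma^2)).
#' @param degree,offset polynomial parameters: k(x, y) = (<x, y> + offset)^degree.
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("linear", "rbf", "polynomial"),
                        sigma = 1, degree = 2, offset = 1) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (degree < 1 || degree != round(degree)) stop("`degree` must be a positive integer")
  structure(list(kind = kind, sigma = sigma, degree = degree, offset = offset),
            class = "kernel_spec")
}

#' Kernel Gram matrix
#'
#' @param spec a [kernel_spec()].
#' @param x,y row-wise point matrices of equal column count (`y` defaults
#'   to `x`).
#' @return `nrow(x)` x `nrow(y)` kernel matrix.
#' @export
kernel_matrix <- function(spec, x, y = x) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("dimension mismatch between x and y")
  xp <- x %*% t(y)
  switch(spec$kind,
         linear = xp,
         polynomial = (xp + spec$offset)^spec$degree,
         rbf = {
           d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * xp
           exp(-pmax(d2, 0) / (2 * spec$sigma^2))
         })
}

#' Evaluate a kernel on a single pair of points
#' @inheritParams kernel_matrix
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, x, y) {
  if (length(x) != length(y)) stop("dimension mismatch between x and y")
  as.numeric(kernel_matrix(spec, matrix(x, 1), matrix(y, 1)))
}

#' Per-class box constraints for unbalanced designs
#'
#' With class sizes n1 and n2 and N = n1 + n2, the balanced scheme gives
#' each class the constraint C = N / (2 n_class), so the smaller class
#' receives the larger constraint and total constraint mass is equal across
#' classes. The literal scheme swaps the assignment (each class receives
#' N / (2 n_other)), reproducing the printed study configuration verbatim.
#'
#' @param n_first,n_second class sizes (>= 1).
#' @param scheme `"balanced"` (default) or `"literal"`.
#' @return named numeric: `first` and `second` box constraints.
#' @export
class_box_constraints <- function(n_first, n_second,
                                  scheme = c("balanced", "literal")) {
  scheme <- match.arg(scheme)
  if (n_first < 1 || n_second < 1) stop("class sizes must be >= 1")
  N <- n_first + n_second
  if (scheme == "balanced") {
    c(first = N / (2 * n_first), second = N / (2 * n_second))
  } else {
    c(first = N / (2 * n_second), second = N / (2 * n_first))
  }
}

#' Training configuration for the study's two classification modes
#'
#' Returns the default configuration used by the analysis: two-group
#' classification uses a linear kernel with KKT tolerance 0.001; four-group
#' one-vs-one classification uses a second-degree polynomial kernel with
#' KKT tolerance 2^-0.77, a misclassification penalty scale of 2^-16
#' applied multiplicatively to the pairwise box constraints, and gamma =
#' 0.25 (the RBF variance parameter, gamma = 1 / (2 sigma^2), used when an
#' RBF kernel is selected or grid-scanned).
#'
#' @param mode `"two_group"` or `"four_group"`.
#' @return list with `kernel`, `kkt_tol`, `penalty_scale`, `gamma`,
#'   `box_scheme` and `max_iter`.
#' @export
svm_config <- function(mode = c("two_group", "four_group")) {
  mode <- match.arg(mode)
  if (mode == "two_group") {
    list(kernel = kernel_spec("linear"), kkt_tol = 1e-3, penalty_scale = 1,
         gamma = NULL, box_scheme = "balanced", max_iter = 100000L)
  } else {
    list(kernel = kernel_spec("polynomial", degree = 2, offset = 1),
         kkt_tol = 2^-0.77, penalty_scale = 2^-16, gamma = 0.25,
         box_scheme = "balanced", max_iter = 100000L)
  }
}

#' Train a soft-margin kernel SVM by sequential minimal optimization
#'
#' Minimizes the dual 0.5 a' Q a - sum(a) subject to 0 <= a_i <= C_i and
#' sum(a_i y_i) = 0 (Q_ij = y_i y_j k(x_i, x_j)) with two-coordinate updates
#' selected by the maximal-violating-pair rule; convergence is declared when
#' the KKT duality gap m(a) - M(a) drops below `tol`. The algorithm is
#' deterministic (ties broken by lowest index); `seed` is accepted for
#' interface symmetry with the stochastic stages.
#'
#' @param x numeric score matrix (rows = subjects).
#' @param y labels in \{+1, -1\} (or a 2-level factor; the first level maps
#'   to +1).
#' @param C box constraint: scalar, length-2 `(positive, negative)` class
#'   constraints, or per-sample vector.
#' @param kernel a [kernel_spec()].
#' @param tol KKT tolerance (> 0).
#' @param max_iter maximum SMO pair updates.
#' @param seed unused; present for API uniformity.
#' @return An `svm_model`: support vectors `sv`, signed weights `weights`
#'   (a_i = alpha_i y_i), bias `b`, `kernel`, `labels` (first = +1 group),
#'   full `alpha`, `C`, training labels `y`, iteration count and final gap.
#' @export
train_binary_svm <- function(x, y, C = 1, kernel = kernel_spec("linear"),
                             tol = 1e-3, max_iter = 100000L, seed = NULL) {
  x <- as.matrix(x)
  lab <- c("+1", "-1")
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2) stop("exactly two classes required")
    lab <- levels(f)
    y <- ifelse(f == lab[1], 1, -1)
  }
  if (!all(y %in% c(-1, 1)) || length(unique(y)) != 2) {
    stop("both classes must be present with labels in {+1, -1}")
  }
  if (!all(is.finite(x))) stop("scores must be finite")
  n <- nrow(x)
  Ci <- if (length(C) == n && n != 2) C
        else if (length(C) == 2) ifelse(y > 0, C[1], C[2])
        else rep(C[1], n)
  if (any(Ci <= 0)) stop("box constraints must be positive")

  K <- kernel_matrix(kernel, x)
  Q <- (y %o% y) * K
  alpha <- numeric(n)
  G <- rep(-1, n)                      # gradient of the dual objective
  eps <- 1e-12
  it <- 0L
  gap <- Inf
  repeat {
    up <- (y > 0 & alpha < Ci - eps) | (y < 0 & alpha > eps)
    lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < Ci - eps)
    vals <- -y * G                     # y_i - f0(x_i)
    m <- max(vals[up]); M <- min(vals[lo])
    gap <- m - M
    if (gap <= tol) break
    if (it >= max_iter) {
      stop(sprintf("SMO failed to converge after %d iterations (KKT gap %.3g)",
                   it, gap))
    }
    i <- which(up)[which.max(vals[up])]
    j <- which(lo)[which.min(vals[lo])]
    h <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_star <- if (h > eps) gap / h else Inf
    # positive step bounded by both boxes
    t_max_i <- if (y[i] > 0) Ci[i] - alpha[i] else alpha[i]
    t_max_j <- if (y[j] > 0) alpha[j] else Ci[j] - alpha[j]
    t_step <- min(t_star, t_max_i, t_max_j)
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    G <- G + Q[, i] * (y[i] * t_step) - Q[, j] * (y[j] * t_step)
    it <- it + 1L
  }

  vals <- -y * G
  free <- alpha > eps & alpha < Ci - eps
  b <- if (any(free)) mean(vals[free]) else (m + M) / 2
  sv <- alpha > eps
  structure(list(sv = x[sv, , drop = FALSE], weights = (alpha * y)[sv],
                 b = b, kernel = kernel, labels = lab,
                 alpha = alpha, C = Ci, y = y, x = x,
                 iterations = it, kkt_gap = gap, tol = tol),
            class = "svm_model")
}

#' Dual objective of a trained (or candidate) SVM
#' @param model an `svm_model`.
#' @return value of sum(alpha) - 0.5 alpha' Q alpha.
#' @export
dual_objective <- function(model) {
  K <- kernel_matrix(model$kernel, model$x)
  a <- model$alpha
  ay <- a * model$y
  sum(a) - 0.5 * drop(ay %*% K %*% ay)
}

#' Verify the Karush-Kuhn-Tucker conditions of a trained model
#'
#' Case analysis at tolerance `tol`: alpha = 0 requires y f(x) >= 1 - tol;
#' 0 < alpha < C requires |y f(x) - 1| <= tol; alpha = C requires
#' y f(x) <= 1 + tol; and the equality constraint |sum(alpha_i y_i)| <= tol.
#'
#' @param model an `svm_model`.
#' @param x,y training data (default: stored in the model).
#' @param tol tolerance (default: the training tolerance).
#' @return list with `ok` (logical) and `worst` (largest violation, >= 0).
#' @export
check_kkt <- function(model, x = model$x, y = model$y, tol = model$tol) {
  f <- decision_value(model, x)$score
  yf <- y * f
  a <- model$alpha
  Ci <- model$C
  eps <- 1e-9
  viol <- numeric(length(a))
  zero <- a <= eps
  atC <- a >= Ci - eps
  free <- !zero & !atC
  viol[zero] <- pmax(0, (1 - tol) - yf[zero])
  viol[free] <- pmax(0, abs(yf[free] - 1) - tol)
  viol[atC] <- pmax(0, yf[atC] - (1 + tol))
  eq <- max(0, abs(sum(a * y)) - tol)
  worst <- max(c(viol, eq))
  list(ok = worst <= 0, worst = worst)
}

#' Evaluate the SVM decision function
#'
#' c(x) = sum_i a_i k(s_i, x) + b over the support vectors; x is assigned
#' to the first group iff c >= 0 (boundary inclusive).
#'
#' @param model an `svm_model`.
#' @param x matrix of points (rows) or a single point vector.
#' @return list with numeric `score` and character `label` vectors.
#' @export
decision_value <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  d <- ncol(model$sv)
  if (nrow(model$sv) > 0 && ncol(x) != d) stop("dimension mismatch")
  score <- if (nrow(model$sv) == 0) rep(model$b, nrow(x)) else
    as.numeric(kernel_matrix(model$kernel, x, model$sv) %*% model$weights) +
      model$b
  list(score = score,
       label = ifelse(score >= 0, model$labels[1], model$labels[2]))
}

#' Train a one-vs-one multiclass SVM ensemble
#'
#' One binary model per unordered class pair (C(m, 2) models; 6 for four
#' classes), each trained on that pair's subjects only, with pairwise
#' class box constraints recomputed from the pair's class sizes and scaled
#' by `config$penalty_scale`.
#'
#' @param x score matrix.
#' @param labels factor (or character) with >= 2 classes, each with >= 2
#'   members.
#' @param config list as from [svm_config()]; `config$kernel` is the shared
#'   kernel.
#' @param seed unused; API uniformity.
#' @return An `ovo_classifier`: list of `(pair, model)` entries plus the
#'   class level set.
#' @export
train_ovo <- function(x, labels, config = svm_config("four_group"),
                      seed = NULL) {
  f <- if (is.factor(labels)) labels else factor(labels)
  lev <- levels(f)
  cnt <- table(f)
  missing <- lev[cnt < 2]
  if (length(missing) > 0) {
    stop("classes with < 2 members: ", paste(missing, collapse = ", "))
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- f %in% pr
    sub <- droplevels(f[idx])
    bc <- class_box_constraints(sum(sub == pr[1]), sum(sub == pr[2]),
                                scheme = config$box_scheme) *
      config$penalty_scale
    m <- train_binary_svm(x[idx, , drop = FALSE],
                          factor(sub, levels = pr),
                          C = unname(bc), kernel = config$kernel,
                          tol = config$kkt_tol, max_iter = config$max_iter)
    list(pair = pr, model = m)
  })
  structure(list(models = models, levels = lev), class = "ovo_classifier")
}

#' Predict class labels by one-vs-one majority vote
#'
#' Each binary model votes for one class of its pair; the class with the
#' most votes wins. Ties are broken by the largest sum of absolute decision
#' values over the models that voted for each tied class, then by class
#' level order.
#'
#' @param classifier an `ovo_classifier`.
#' @param x matrix of points (rows) or a single point vector.
#' @return factor of predicted labels.
#' @export
predict_ovo <- function(classifier, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  lev <- classifier$levels
  n <- nrow(x)
  votes <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
  strength <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  for (entry in classifier$models) {
    dv <- decision_value(entry$model, x)
    won <- ifelse(dv$score >= 0, entry$pair[1], entry$pair[2])
    for (cl in entry$pair) {
      sel <- won == cl
      votes[sel, cl] <- votes[sel, cl] + 1L
      strength[sel, cl] <- strength[sel, cl] + abs(dv$score[sel])
    }
  }
  out <- character(n)
  for (r in seq_len(n)) {
    best <- which(votes[r, ] == max(votes[r, ]))
    if (length(best) > 1) {
      best <- best[strength[r, best] == max(strength[r, best])]
    }
    out[r] <- lev[best[1]]
  }
  factor(out, levels = lev)
}

#' Serialize / restore an SVM model as JSON
#' @param model an `svm_model`.
#' @param path file path.
#' @name svm_io
#' @export
write_svm_model <- function(model, path) {
  obj <- list(kernel = unclass(model$kernel), sv = model$sv,
              weights = model$weights, b = model$b, labels = model$labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname svm_io
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sv = as.matrix(obj$sv), weights = obj$weights, b = obj$b,
                 kernel = structure(obj$kernel, class = "kernel_spec"),
                 labels = obj$labels, alpha = NULL, C = NULL, y = NULL,
                 x = NULL),
            class = "svm_model")
}
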