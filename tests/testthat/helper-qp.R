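# Independent dense-QP oracle for the SVM dual, built on quadprog.
#
# Solves max sum(a) - 0.5 a' Q a  s.t.  y'a = 0, 0 <= a_i <= C_i
# with an interior-point-free active-set solver (quadprog::solve.QP) on a
# ridge-stabilized Q, then polishes the solution exactly on the recovered
# active set using the original (unridged) Q. Returns the best feasible
# dual objective found. Entirely independent of the package's SMO path.
qp_svm_dual <- function(x, y, C, kernel) {
  K <- kernel_matrix(kernel, x)
  n <- nrow(x)
  Q <- (y %o% y) * K
  obj <- function(a) sum(a) - 0.5 * drop((a * y) %*% K %*% (a * y))
  best <- -Inf
  for (rf in c(1e-8, 1e-6, 1e-4, 1e-3, 1e-2)) {
    ridge <- rf * max(1, mean(diag(Q)))
    sol <- tryCatch(
      quadprog::solve.QP(Q + diag(ridge, n), rep(1, n),
                         cbind(y, diag(n), -diag(n)),
                         c(0, rep(0, n), -C), meq = 1)$solution,
      error = function(e) NULL)
    if (is.null(sol)) next
    boxviol <- max(0, max(sol - C), max(-sol))
    a <- pmin(pmax(sol, 0), C)
    eps <- 1e-7 * max(C)
    free <- a > eps & a < C - eps
    cand <- list()
    if (any(free)) {
      Fi <- which(free)
      Bi <- which(!free)
      rhs <- c(1 - if (length(Bi)) drop(Q[Fi, Bi, drop = FALSE] %*% a[Bi]) else 0,
               -sum(y[Bi] * a[Bi]))
      M <- rbind(cbind(Q[Fi, Fi, drop = FALSE], y[Fi]), c(y[Fi], 0))
      s2 <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (!is.null(s2)) {
        a2 <- a
        a2[Fi] <- s2[seq_along(Fi)]
        if (all(a2 >= -1e-8 & a2 <= C + 1e-8) && abs(sum(a2 * y)) < 1e-8) {
          cand <- c(cand, list(pmin(pmax(a2, 0), C)))
        }
      }
    }
    if (boxviol < 1e-8 && abs(sum(a * y)) < 1e-8) cand <- c(cand, list(a))
    for (ac in cand) best <- max(best, obj(ac))
  }
  best
}

# Random binary SVM instance generator shared by the oracle suites.
random_svm_instance <- function(i) {
  n <- sample(6:30, 1)
  d <- sample(1:5, 1)
  x <- matrix(stats::rnorm(n * d), n, d)
  y <- c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))[sample(n)]
  kern <- list(kernel_spec("linear"),
               kernel_spec("rbf", sigma = 1.5),
               kernel_spec("polynomial"))[[(i %% 3) + 1]]
  Cc <- stats::runif(1, 0.5, 5)
  list(x = x, y = y,
       C = ifelse(y > 0, Cc, Cc * stats::runif(1, 0.5, 2)),
       kernel = kern)
}
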