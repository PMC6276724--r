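test_that("kernel evaluations match their closed forms", {
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_eval(kernel_spec("rbf", sigma = 2), c(1, 1), c(1, 1)), 1)
  expect_equal(kernel_eval(kernel_spec("rbf", sigma = 1), c(0, 0), c(1, 1)),
               exp(-1))
  # polynomial d = 2, offset 1, <x, y> = 2 -> 9
  expect_equal(kernel_eval(kernel_spec("polynomial"), c(1, 1), c(1, 1)), 9)
  expect_error(kernel_eval(kernel_spec("linear"), c(1, 2), c(1, 2, 3)),
               "mismatch")
})

test_that("class box constraints implement the balanced and literal schemes", {
  # study design: 110 ASD (first), 83 TD (second)
  bal <- class_box_constraints(110, 83, "balanced")
  expect_equal(unname(bal), c(193 / 220, 193 / 166))
  lit <- class_box_constraints(110, 83, "literal")
  expect_equal(unname(lit), c(193 / 166, 193 / 220))
  expect_equal(unname(class_box_constraints(50, 50)), c(1, 1))
})

test_that("SMO recovers the closed-form two-point solution", {
  x <- matrix(c(-1, 1), 2, 1)
  m <- train_binary_svm(x, c(-1, 1), C = 10)
  expect_equal(m$b, 0, tolerance = 1e-9)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(nrow(m$sv), 2)
  dv <- decision_value(m, x)
  expect_equal(dv$score, c(-1, 1), tolerance = 1e-9)
  expect_identical(dv$label, c("-1", "+1"))
  expect_true(check_kkt(m)$ok)
})

test_that("decision rule is boundary-inclusive and handles empty models", {
  no_sv <- structure(list(sv = matrix(0, 0, 2), weights = numeric(0),
                          b = 0.5, kernel = kernel_spec("linear"),
                          labels = c("ASD", "TD")),
                     class = "svm_model")
  dv <- decision_value(no_sv, c(1, 2))
  expect_equal(dv$score, 0.5)
  expect_identical(dv$label, "ASD")
  zero <- structure(no_sv, class = "svm_model")
  zero$b <- 0
  expect_identical(decision_value(zero, c(0, 0))$label, "ASD")  # c = 0
})

test_that("second-degree polynomial kernel separates XOR", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  m <- train_binary_svm(x, y, C = 100, kernel = kernel_spec("polynomial"),
                        tol = 1e-6)
  expect_equal(sign(decision_value(m, x)$score), y)
})

test_that("SMO matches the dense QP oracle on 50 random instances", {
  set.seed(42)
  for (i in 1:50) {
    inst <- random_svm_instance(i)
    m <- train_binary_svm(inst$x, inst$y, C = inst$C, kernel = inst$kernel,
                          tol = 1e-8, max_iter = 1e6)
    o_smo <- dual_objective(m)
    o_qp <- qp_svm_dual(inst$x, inst$y, inst$C, inst$kernel)
    expect_lt(abs(o_smo - o_qp) / max(1, abs(o_qp)), 1e-6)
    # dual feasibility after every training run
    expect_true(all(m$alpha >= -1e-12 & m$alpha <= m$C + 1e-12))
    expect_lt(abs(sum(m$alpha * m$y)), 1e-8)
    # labels agree with the margin sign on confidently classified points
    sc <- decision_value(m, inst$x)$score
    conf <- abs(sc) > 0.01
    expect_true(all(sign(sc[conf]) == (2 * (sc[conf] >= 0) - 1)))
  }
})

test_that("check_kkt detects perturbed models and honors the tolerance limit", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20), 10, 2),
             sweep(matrix(rnorm(20), 10, 2), 2, c(6, 6), "+"))
  y <- rep(c(-1, 1), each = 10)
  m <- train_binary_svm(x, y, C = 10, tol = 1e-6)
  expect_true(check_kkt(m)$ok)
  bad <- m
  bad$b <- bad$b + 1
  res <- check_kkt(bad)
  expect_false(res$ok)
  expect_gt(res$worst, 0)
  expect_true(check_kkt(bad, tol = Inf)$ok)
})

test_that("training errors on invalid input are informative", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(train_binary_svm(x, rep(1, 5)), "both classes")
  expect_error(train_binary_svm(x, c(1, 1, 1, -1, NA)), "both classes|finite")
  xx <- x; xx[1, 1] <- Inf
  expect_error(train_binary_svm(xx, c(1, 1, -1, -1, -1)), "finite")
})

test_that("one-vs-one builds C(m, 2) models and classifies separated clusters", {
  fix <- four_cluster_data(n_per = 10, sep = 10)
  ovo <- train_ovo(fix$x, fix$labels, svm_config("four_group"))
  expect_length(ovo$models, 6)
  pairs <- vapply(ovo$models, function(e) paste(e$pair, collapse = "|"), "")
  expect_equal(length(unique(pairs)), 6)
  expect_equal(mean(predict_ovo(ovo, fix$x) == fix$labels), 1)

  # a point deep inside one cluster wins all three of its pairwise votes
  deep <- fix$centers[2, ]
  expect_identical(as.character(predict_ovo(ovo, deep)), "ASD_F")

  # three classes give 3 classifiers
  sub <- fix$labels %in% c("ASD_M", "ASD_F", "TD_M")
  ovo3 <- train_ovo(fix$x[sub, ], droplevels(fix$labels[sub]),
                    svm_config("four_group"))
  expect_length(ovo3$models, 3)

  # missing class named in the error
  sub2 <- fix$labels != "TD_F"
  expect_error(train_ovo(fix$x[sub2, ], fix$labels[sub2],
                         svm_config("four_group")), "TD_F")
})

test_that("degenerate two-class OVO agrees with the binary decision rule", {
  set.seed(9)
  x <- rbind(matrix(rnorm(16), 8, 2),
             sweep(matrix(rnorm(16), 8, 2), 2, c(5, 0), "+"))
  lab <- factor(rep(c("ASD", "TD"), each = 8))
  cfg <- svm_config("two_group")
  ovo <- train_ovo(x, lab, cfg)
  expect_length(ovo$models, 1)
  probe <- matrix(rnorm(20), 10, 2)
  expect_identical(as.character(predict_ovo(ovo, probe)),
                   decision_value(ovo$models[[1]]$model, probe)$label)
})

test_that("OVO tie-breaking is deterministic across calls", {
  fix <- four_cluster_data(n_per = 8, sep = 10)
  ovo <- train_ovo(fix$x, fix$labels, svm_config("four_group"))
  center <- colMeans(fix$centers)  # equidistant from all clusters
  p1 <- predict_ovo(ovo, center)
  for (i in 1:5) expect_identical(predict_ovo(ovo, center), p1)
})

test_that("decision function is invariant to training-row permutation", {
  set.seed(10)
  x <- rbind(matrix(rnorm(30), 15, 2),
             sweep(matrix(rnorm(30), 15, 2), 2, c(3, 3), "+"))
  y <- rep(c(-1, 1), each = 15)
  kern <- kernel_spec("rbf", sigma = 1.5)
  m1 <- train_binary_svm(x, y, C = 2, kernel = kern, tol = 1e-10,
                         max_iter = 1e6)
  perm <- sample(30)
  m2 <- train_binary_svm(x[perm, ], y[perm], C = 2, kernel = kern,
                         tol = 1e-10, max_iter = 1e6)
  probes <- matrix(rnorm(200), 100, 2)
  expect_lt(max(abs(decision_value(m1, probes)$score -
                    decision_value(m2, probes)$score)), 1e-8)
})

test_that("training error is non-increasing in C on a noisy fixture", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40), 20, 2),
             sweep(matrix(rnorm(40), 20, 2), 2, c(1.5, 0), "+"))
  y <- rep(c(-1, 1), each = 20)
  errs <- vapply(c(0.05, 0.5, 5, 50), function(C) {
    m <- train_binary_svm(x, y, C = C, tol = 1e-6, max_iter = 1e6)
    mean(sign(decision_value(m, x)$score) != y)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("SVM models round-trip through JSON", {
  set.seed(12)
  x <- rbind(matrix(rnorm(12), 6, 2),
             sweep(matrix(rnorm(12), 6, 2), 2, c(4, 4), "+"))
  m <- train_binary_svm(x, rep(c(-1, 1), each = 6), C = 5,
                        kernel = kernel_spec("rbf", sigma = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_svm_model(m, f)
  m2 <- read_svm_model(f)
  probes <- matrix(rnorm(20), 10, 2)
  expect_equal(decision_value(m2, probes)$score,
               decision_value(m, probes)$score, tolerance = 1e-12)
})
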