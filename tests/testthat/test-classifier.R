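test_that("t_rank reproduces hand computations and orders by |t|", {
  X <- rbind(F1 = c(1, 1, 1, 5, 5, 5), F2 = c(2, 3, 2, 2, 3, 2))
  colnames(X) <- paste0("A", 1:6)
  y <- c(0, 0, 0, 1, 1, 1)
  rk <- t_rank(X, y)
  expect_identical(rk$feature[1], "F1")

  X2 <- rbind(F1 = c(1, 2, 3, 4, 5, 6))
  colnames(X2) <- paste0("A", 1:6)
  rk2 <- t_rank(X2, y)
  expect_equal(rk2$t[1], -3 * sqrt(3 / 2), tolerance = 1e-10)

  # zero pooled variance: infinite |t| when means differ, 0 when equal
  X3 <- rbind(F1 = c(1, 1, 1, 2, 2, 2), F2 = c(3, 3, 3, 3, 3, 3))
  colnames(X3) <- paste0("A", 1:6)
  rk3 <- t_rank(X3, y)
  expect_identical(rk3$feature, c("F1", "F2"))
  expect_true(is.infinite(rk3$t[1]))
  expect_identical(rk3$t[2], 0)
  expect_error(t_rank(X3, c(0, 0, 0, 0, 0, 1)), "n >= 2")
})

test_that("t_rank matches per-feature brute force on random data", {
  set.seed(30)
  X <- rand_expr(50, 16)
  y <- rep(c(0, 1), each = 8)
  rk <- t_rank(X, y)
  ref_t <- vapply(rownames(X), function(f) {
    oracle_pooled_t(X[f, y == 0], X[f, y == 1])$t
  }, 1)
  expect_equal(rk$t, unname(ref_t[rk$feature]), tolerance = 1e-8)
  expect_identical(rk$feature, rownames(X)[order(-abs(ref_t), rownames(X))])
})

test_that("training on a separable toy recovers its labels", {
  X <- rbind(F1 = c(0, 0, 10, 10), F2 = c(1, 0, 1, 0))
  colnames(X) <- paste0("A", 1:4)
  y <- c(0, 0, 1, 1)
  model <- train_prognostic(X, y, c("F1", "F2"))
  expect_equal(model$training_accuracy, 1)
  expect_identical(unname(predict(model, X)), as.integer(y))
  # duplicated sample gets the training sample's call
  Xd <- cbind(X, A5 = X[, 1])
  expect_identical(unname(predict(model, Xd)[5]), 0L)
  # extra non-model features do not change predictions
  Xe <- rbind(X, F3 = stats::rnorm(4))
  expect_identical(predict(model, Xe), predict(model, X))
  # missing features are named
  expect_error(predict(model, X[1, , drop = FALSE]), "F2")
  expect_error(train_prognostic(X, c(0, 0, 0, 0), c("F1", "F2")),
               "both classes")
})

test_that("training accuracy exceeds fresh-data accuracy on pure noise", {
  set.seed(31)
  gaps <- vapply(1:20, function(i) {
    X <- rand_expr(20, 40)
    y <- rep(c(0, 1), 20)
    model <- train_prognostic(X, y, rownames(X))
    Xnew <- rand_expr(20, 40)
    train_acc <- mean(predict(model, X) == y)
    test_acc <- mean(predict(model, Xnew) == y)
    train_acc - test_acc
  }, 1)
  expect_gt(mean(gaps), 0)
})

test_that("models survive a JSON round trip with identical predictions", {
  set.seed(32)
  X <- rand_expr(10, 20)
  y <- rep(c(0, 1), 10)
  model <- train_prognostic(X, y, rownames(X)[1:6], cost = 2)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model, path)
  back <- model_from_json(path)
  Xnew <- rand_expr(10, 100)
  expect_identical(predict(back, Xnew), predict(model, Xnew))
  expect_identical(back$features, model$features)
  expect_equal(back$cost, model$cost)
})

test_that("the leave-one-out consensus recovers planted features", {
  set.seed(33)
  X <- rand_expr(40, 20)
  y <- rep(c(0, 1), each = 10)
  X[1:3, y == 1] <- X[1:3, y == 1] + 10   # planted, perfectly separating
  cons <- inner_loocv_consensus(X, y, 3)
  expect_setequal(cons$consensus, rownames(X)[1:3])
  expect_true(all(cons$frequency$frequency[
    cons$frequency$feature %in% rownames(X)[1:3]] == 20))
})

test_that("a five-sample consensus equals the hand enumeration", {
  X <- rbind(F1 = c(0, 1, 10, 11, 12), F2 = c(5, 5, 5, 5, 6),
             F3 = c(2, 1, 2, 1, 2))
  colnames(X) <- paste0("A", 1:5)
  y <- c(0, 0, 1, 1, 1)
  cons <- inner_loocv_consensus(X, y, 1)
  # by hand: F1 separates the classes in every fold
  expect_identical(cons$consensus, "F1")
  expect_equal(cons$frequency$frequency[cons$frequency$feature == "F1"], 5L)
  # leaving out the only class-0 array empties that class
  expect_error(inner_loocv_consensus(X, c(0, 1, 1, 1, 1), 1), "degenerate")
})

test_that("consensus tie-breaking is deterministic", {
  X <- matrix(rep(c(1, 2, 1, 2, 1, 2), each = 4), 4, 6, byrow = FALSE,
              dimnames = list(paste0("F", 1:4), paste0("A", 1:6)))
  y <- c(0, 1, 0, 1, 0, 1)
  c1 <- inner_loocv_consensus(X, y, 2)
  c2 <- inner_loocv_consensus(X, y, 2)
  expect_identical(c1$consensus, c2$consensus)
  expect_identical(c1$consensus, c("F1", "F2"))  # id order under full ties
})

test_that("Monte-Carlo evaluation is seed-deterministic and recovers signal", {
  set.seed(34)
  X <- rand_expr(30, 24)
  y <- rep(c(0, 1), 12)
  X[1:4, y == 1] <- X[1:4, y == 1] + 6
  r1 <- monte_carlo_evaluate(X, y, R = 50, k = 4, seed = 7)
  r2 <- monte_carlo_evaluate(X, y, R = 50, k = 4, seed = 7)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_gte(r1$mean_accuracy, 0.95)
  expect_lte(r1$ci_low, r1$mean_accuracy)
  expect_gte(r1$ci_high, r1$mean_accuracy)
  # different seeds give different splits (visible on null data)
  Xn <- rand_expr(30, 24)
  n1 <- monte_carlo_evaluate(Xn, y, R = 50, k = 4, seed = 7)
  n2 <- monte_carlo_evaluate(Xn, y, R = 50, k = 4, seed = 8)
  expect_false(identical(n1$accuracies, n2$accuracies))
  expect_error(monte_carlo_evaluate(X, y, R = 1, k = 4), "R >= 2")
})

test_that("Monte-Carlo accuracy stays at chance under permuted labels", {
  set.seed(35)
  X <- rand_expr(60, 30)
  y <- sample(rep(c(0, 1), 15))
  r <- monte_carlo_evaluate(X, y, R = 50, k = 10, seed = 1)
  expect_gt(r$mean_accuracy, 0.3)
  expect_lt(r$mean_accuracy, 0.7)
})

test_that("compare_assays behaves at its boundaries and matches t.test", {
  a <- structure(list(accuracies = c(0.5, 0.6, 0.7)),
                 class = "monte_carlo_result")
  expect_equal(compare_assays(a, a)$p_value, 1)
  expect_equal(compare_assays(a, a)$t_stat, 0)

  same <- structure(list(accuracies = rep(0.5, 10)),
                    class = "monte_carlo_result")
  expect_equal(compare_assays(same, same)$p_value, 1)

  set.seed(36)
  b <- structure(list(accuracies = 0.9 + stats::rnorm(30, 0, 1e-4)),
                 class = "monte_carlo_result")
  c_ <- structure(list(accuracies = 0.5 + stats::rnorm(30, 0, 1e-4)),
                  class = "monte_carlo_result")
  expect_lt(compare_assays(b, c_)$p_value, 1e-6)

  x <- structure(list(accuracies = stats::rnorm(20, 0.6, 0.05)),
                 class = "monte_carlo_result")
  z <- structure(list(accuracies = stats::rnorm(25, 0.62, 0.05)),
                 class = "monte_carlo_result")
  got <- compare_assays(x, z)
  ref <- stats::t.test(x$accuracies, z$accuracies)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("nested LOOCV picks the smallest size on a separable toy", {
  X <- rbind(F1 = c(0, 1, 2, 10, 11, 12), F2 = stats::rnorm(6))
  colnames(X) <- paste0("A", 1:6)
  y <- c(0, 0, 0, 1, 1, 1)
  r <- nested_loocv(X, y, k_grid = c(1, 2))
  expect_equal(r$loocv_accuracy, 1)
  expect_equal(r$k_final, 1L)
  expect_identical(r$final_features, "F1")
})

test_that("nested LOOCV equals a naive triple-loop implementation exactly", {
  set.seed(37)
  X <- rand_expr(12, 8)
  y <- rep(c(0, 1), each = 4)
  X[1, y == 1] <- X[1, y == 1] + 1.5
  got <- nested_loocv(X, y, k_grid = c(1, 2))
  ref <- oracle_nested_loocv(X, y, k_grid = c(1, 2))
  expect_equal(got$folds$k_star, ref$k_star)
  expect_equal(got$folds$call, ref$call)
  expect_equal(got$loocv_accuracy, ref$accuracy)
  expect_equal(got$k_final, ref$k_final)
})

test_that("nested LOOCV shows no selection bias under null labels", {
  set.seed(38)
  accs <- vapply(1:3, function(i) {
    X <- rand_expr(80, 20)
    y <- sample(rep(c(0, 1), 10))
    nested_loocv(X, y, k_grid = c(2, 5, 10))$loocv_accuracy
  }, 1)
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.8)
})
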