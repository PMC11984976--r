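test_that("a symmetric 1-D two-class fit puts the boundary at zero", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- factor(c("a", "a", "b", "b"))
  fit <- fit_lda(x, y, lambda = 0)
  expect_equal(unname(predict(fit, matrix(c(-0.1, 0.1), ncol = 1))),
               factor(c("a", "b"), levels = c("a", "b")))
  # exact midpoint of equiprior classes: documented tie-break to the
  # earliest label in canonical order
  expect_equal(as.character(predict(fit, matrix(0, 1, 1))), "a")
})

test_that("duplicating every training sample leaves predictions unchanged", {
  fx <- gaussian_fixture(n_per_class = 20, k = 3, d = 4)
  fit1 <- fit_lda(fx$x, fx$y)
  fit2 <- fit_lda(rbind(fx$x, fx$x), factor(rep(fx$y, 2)))
  grid <- matrix(rnorm(50 * 4), 50, 4)
  expect_equal(predict(fit1, grid), predict(fit2, grid))
})

test_that("predictions equal the explicit Gaussian discriminant formula", {
  fx <- gaussian_fixture(n_per_class = 15, k = 3, d = 2, sep = 3)
  fit <- fit_lda(fx$x, fx$y, lambda = 1e-3)
  grid <- matrix(rnorm(200 * 2, sd = 3), 200, 2)
  # independent oracle: delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + ln pi_k
  oracle <- apply(grid, 1, function(x) {
    scores <- vapply(seq_along(fit$labels), function(k) {
      mu <- fit$means[k, ]
      as.numeric(x %*% fit$pooled_cov_inv %*% mu -
                   0.5 * mu %*% fit$pooled_cov_inv %*% mu +
                   log(fit$priors[k]))
    }, 0)
    fit$labels[which.max(scores)]
  })
  expect_equal(as.character(predict(fit, grid)), oracle)
})

test_that("predictions agree with an established LDA on a clean fixture", {
  skip_if_not_installed("MASS")
  fx <- gaussian_fixture(n_per_class = 25, k = 4, d = 3, sep = 4, seed = 7)
  fit <- fit_lda(fx$x, fx$y, lambda = 0)
  ref <- MASS::lda(fx$x, fx$y)
  grid <- matrix(rnorm(100 * 3, sd = 4), 100, 3)
  expect_equal(as.character(predict(fit, grid)),
               as.character(predict(ref, grid)$class))
})

test_that("batch predictions equal one-at-a-time predictions", {
  fx <- gaussian_fixture()
  fit <- fit_lda(fx$x, fx$y)
  grid <- matrix(rnorm(20 * 2), 20, 2)
  one_by_one <- vapply(seq_len(nrow(grid)),
                       function(i) as.character(predict(fit, grid[i, ])), "")
  expect_equal(as.character(predict(fit, grid)), one_by_one)
})

test_that("degenerate training sets and dimension mismatches are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fit_lda(x, factor(rep("a", 5))), "at least 2 classes")
  expect_error(fit_lda(x, factor(c("a", "a", "a", "a", "b"))), "< 2 samples")
  fx <- gaussian_fixture()
  fit <- fit_lda(fx$x, fx$y)
  expect_error(predict(fit, matrix(0, 1, 5)), "dimension")
})

test_that("predictions are invariant to invertible per-feature affine maps", {
  fx <- gaussian_fixture(n_per_class = 30, k = 3, d = 4, sep = 5, seed = 11)
  grid <- matrix(rnorm(80 * 4, sd = 5), 80, 4)
  fit <- fit_lda(fx$x, fx$y)                    # default shrinkage
  scale <- runif(4, 0.5, 2)
  shift <- rnorm(4)
  tf <- function(m) sweep(sweep(m, 2, scale, "*"), 2, shift, "+")
  fit2 <- fit_lda(tf(fx$x), fx$y)
  expect_equal(predict(fit, grid), predict(fit2, tf(grid)))
})

test_that("class means classify to their own class on separated fixtures", {
  fx <- gaussian_fixture(sep = 8, seed = 3)
  fit <- fit_lda(fx$x, fx$y)
  expect_equal(as.character(predict(fit, fit$means)), fit$labels)
})

test_that("accuracy is the mean of the row-normalized diagonal", {
  lab <- c("a", "b")
  m <- matrix(c(10L, 0L, 0L, 10L), 2, dimnames = list(lab, lab))
  class(m) <- c("confusion_matrix", class(m))
  expect_equal(accuracy(m), 100)
  u <- matrix(5L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  class(u) <- c("confusion_matrix", class(u))
  expect_equal(accuracy(u), 25)
  h <- matrix(c(8L, 1L, 2L, 4L), 2, dimnames = list(lab, lab))
  class(h) <- c("confusion_matrix", class(h))
  expect_equal(accuracy(h), 80)    # mean(80%, 80%)
  e <- matrix(c(0L, 2L, 0L, 3L), 2, dimnames = list(lab, lab))
  class(e) <- c("confusion_matrix", class(e))
  expect_error(accuracy(e), "empty row")
})

test_that("leave-one-repetition-out CV partitions the windows exactly", {
  set.seed(9)
  n <- 180
  df <- data.frame(repetition = rep(1:3, each = n / 3))
  df$cls <- rep(rep(c("a", "b"), each = n / 6), 3)
  mu <- ifelse(df$cls == "a", -4, 4)
  df$f1 <- rnorm(n) + mu
  df$f2 <- rnorm(n) + mu
  res <- loro_cv(df, c("f1", "f2"), df$cls)
  expect_equal(sum(res$confusion), n)      # each window tested exactly once
  expect_equal(unname(rowSums(res$confusion)), c(n / 2, n / 2))
  expect_equal(res$accuracy_pct, 100)      # far-separated, noise-free folds
  expect_equal(unname(diag(res$confusion)), c(n / 2, n / 2))
})

test_that("CV stops when a class is missing from a training fold", {
  set.seed(1)
  df <- data.frame(repetition = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3),
                   cls = c("a", "a", "a", "a", "a", "a", "a", "a",
                           "a", "a", "b", "b"),
                   f1 = rnorm(12))
  # class b exists only in repetition 3: the fold holding out repetition 3
  # must fail, naming the class and fold
  err <- expect_error(loro_cv(df, "f1", df$cls), "absent from training fold")
  expect_match(conditionMessage(err), "repetition 3")
  expect_match(conditionMessage(err), "b")
})
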