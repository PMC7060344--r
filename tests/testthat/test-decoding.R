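test_that("balancing reduces every cell to the minimum and equalizes classes", {
  labs <- rep(c("A", "B"), c(30, 20))
  idx <- balance_trials(labs, seed = 1)
  expect_equal(unname(table(labs[idx])), c(20L, 20L), ignore_attr = TRUE)

  labs2 <- rep(c("hit", "cr"), c(20, 20))
  cov2 <- data.frame(color = c(rep("o", 8), rep("c", 12),
                               rep("o", 10), rep("c", 10)))
  idx2 <- balance_trials(labs2, cov2, seed = 2)
  tab <- table(labs2[idx2], cov2$color[idx2])
  expect_true(all(tab == 8L))
  expect_equal(length(idx2), 32L)
})

test_that("balancing leaves the label independent of every covariate", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      labs <- sample(letters[1:3], 400, replace = TRUE)
      cov <- data.frame(x = sample(c("p", "q"), 400, replace = TRUE),
                        y = sample(c("u", "v", "w"), 400, replace = TRUE))
      idx <- balance_trials(labs, cov, seed = rep)
      for (v in names(cov)) {
        stat <- suppressWarnings(
          chisq.test(table(labs[idx], cov[[v]][idx]))$statistic)
        expect_equal(unname(stat), 0)
      }
    }
  })
})

test_that("empty cross-tab cells error by name unless dropped", {
  labs <- rep(c("hit", "cr"), c(10, 10))
  cov <- data.frame(color = c(rep("o", 10), rep("o", 5), rep("c", 5)))
  expect_error(balance_trials(labs, cov, seed = 1), "hit x c")
  idx <- balance_trials(labs, cov, seed = 1, drop_empty_cells = TRUE)
  expect_true(all(cov$color[idx] == "o"))
  # the surviving cell is reduced to the global minimum cell count
  expect_equal(unname(table(labs[idx])), c(5L, 5L), ignore_attr = TRUE)
})

test_that("splits partition trials with per-fold class balance", {
  labs <- rep(letters[1:4], each = 10)
  sp <- make_splits(labs, 20, seed = 4)
  test_sets <- lapply(sp$folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), seq_along(labs))  # union = all, disjoint
  expect_true(all(lengths(test_sets) == 2L))
  withr::with_seed(5, {
    for (rep in 1:5) {
      labs2 <- sample(c("x", "y", "z"), 120, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
      k <- sample(2:10, 1)
      if (min(table(labs2)) < k) next
      sp2 <- make_splits(labs2, k, seed = rep)
      expect_equal(sort(unlist(lapply(sp2$folds, `[[`, "test"))),
                   seq_along(labs2))
      per_fold <- sapply(sp2$folds, function(f)
        table(factor(labs2[f$test], levels = c("x", "y", "z"))))
      expect_true(all(apply(per_fold, 1, function(r) diff(range(r)) <= 1)))
    }
  })
  # 20 trials over 20 folds: legal one-trial test sets
  sp_small <- make_splits(rep(c("a", "b"), c(10, 10)), 20)
  expect_equal(sort(unlist(lapply(sp_small$folds, `[[`, "test"))), 1:20)
  expect_true(all(lengths(lapply(sp_small$folds, `[[`, "test")) == 1L))
  expect_error(make_splits(rep(c("a", "b"), 5), 20), "exceeds")
  expect_identical(make_splits(labs, 20, seed = 6),
                   make_splits(labs, 20, seed = 6))
})

test_that("window features equal a brute-force slice-and-concatenate oracle", {
  ep <- fake_epochs(7, 3, 10, rnorm(7 * 3 * 10))
  oracle <- function(bin, r) {
    lo <- max(1, bin - r); hi <- min(10, bin + r)
    do.call(cbind, lapply(lo:hi, function(b)
      matrix(ep$data[, , b], nrow = 7)))
  }
  for (bin in c(1, 2, 5, 9, 10))
    for (r in 0:3)
      expect_equal(window_features(ep, bin, r), oracle(bin, r),
                   ignore_attr = TRUE)
  # feature counts: interior = channels x full width, edges clipped
  expect_equal(ncol(window_features(ep, 5, 2)), 15L)
  expect_equal(ncol(window_features(ep, 1, 2)), 9L)
  expect_equal(ncol(window_features(ep, 5, 0)), 3L)
  expect_error(window_features(ep, 11, 2), "out of range")
})

test_that("pseudo-trial averaging follows the grouping and remainder rules", {
  X <- matrix(rnorm(50 * 4), 50)
  av <- average_pseudotrials(X, rep("a", 50), 5, seed = 1)
  expect_equal(nrow(av$features), 10L)
  av7 <- average_pseudotrials(matrix(1:14, 7), rep("a", 7), 5, seed = 1)
  expect_equal(nrow(av7$features), 2L)       # one group of 5 + remainder of 2
  same <- matrix(rep(c(1, 2, 3), each = 12), 12, byrow = FALSE)
  av_same <- average_pseudotrials(same, rep("a", 12), 5, seed = 2)
  expect_true(all(apply(av_same$features, 1, function(r)
    all(r == same[1, ]))))
  expect_error(average_pseudotrials(X, factor(rep("a", 50),
                                              levels = c("a", "b")), 5, 1),
               "empty class")
})

test_that("indistinguishable classes and shuffled labels decode at chance", {
  withr::with_seed(7, {
    ep <- fake_epochs(80, 4, 12, rnorm(80 * 4 * 12))
    labs <- factor(rep(c("p", "q"), 40))
  })
  ds <- labeled_dataset(ep, labs)
  tc <- decode_timecourse(ds, decoder_spec(n_folds = 10), seed = 8)
  expect_binomial_band(tc$mean_accuracy, 0.5, 80, level = 0.999)
  expect_true(all(tc$accuracy >= 0 & tc$accuracy <= 1))
  expect_equal(tc$mean_accuracy, colMeans(tc$accuracy))
})

test_that("a strong injected pattern is decoded only inside its window", {
  withr::with_seed(9, {
    n <- 80
    labs <- factor(rep(c("p", "q"), each = n / 2))
    ep <- fake_epochs(n, 4, 20, rnorm(n * 4 * 20))
    # pattern present from bin 11 onward, class-signed
    sgn <- ifelse(labs == "p", 1, -1)
    for (b in 11:20) ep$data[, , b] <- ep$data[, , b] + outer(sgn * 5, rep(1, 4))
  })
  ds <- labeled_dataset(ep, labs)
  tc <- decode_timecourse(ds, decoder_spec(n_folds = 10), seed = 10)
  expect_true(all(tc$mean_accuracy[14:20] > 0.9))
  expect_binomial_band(tc$mean_accuracy[1:8], 0.5, 80, level = 0.999)
})

test_that("accuracy is invariant to a consistent channel permutation", {
  withr::with_seed(11, {
    ep <- fake_epochs(40, 6, 8, rnorm(40 * 6 * 8))
    labs <- factor(rep(c("p", "q"), 20))
  })
  perm <- c(4, 2, 6, 1, 5, 3)
  ep2 <- ep
  ep2$data <- ep$data[, perm, , drop = FALSE]
  t1 <- decode_timecourse(labeled_dataset(ep, labs),
                          decoder_spec(n_folds = 5), seed = 12)
  t2 <- decode_timecourse(labeled_dataset(ep2, labs),
                          decoder_spec(n_folds = 5), seed = 12)
  expect_identical(t1$accuracy, t2$accuracy)
})

test_that("decoding is deterministic end to end", {
  withr::with_seed(13, {
    ep <- fake_epochs(40, 3, 6, rnorm(40 * 3 * 6))
    labs <- factor(rep(c("p", "q"), 20))
  })
  ds <- labeled_dataset(ep, labs)
  a <- decode_timecourse(ds, decoder_spec(n_folds = 5), seed = 14)
  b <- decode_timecourse(ds, decoder_spec(n_folds = 5), seed = 14)
  expect_identical(a, b)
  c2 <- decode_timecourse(ds, decoder_spec(n_folds = 5), seed = 15)
  expect_false(identical(a$accuracy, c2$accuracy))
})

test_that("the in-package classifier agrees with libSVM on held-out accuracy", {
  skip_if_not_installed("e1071")
  withr::with_seed(16, {
    n <- 96
    labs <- factor(rep(c("p", "q"), each = n / 2))
    ep <- fake_epochs(n, 5, 3, rnorm(n * 5 * 3))
    sgn <- ifelse(labs == "p", 1.2, -1.2)
    ep$data[, , 2] <- ep$data[, , 2] + outer(sgn, rep(1, 5))
  })
  spec <- decoder_spec(n_folds = 8, window_radius = 0)
  ds <- labeled_dataset(ep, labs)
  tc <- decode_timecourse(ds, spec, seed = 17, balance = FALSE)
  split <- make_splits(labs, 8, seed = mtsdecode:::derive_seeds(17, 3)[3])
  e_acc <- sapply(1:3, function(b) {
    X <- window_features(ep, b, 0)
    mean(sapply(1:8, function(k) {
      tr <- split$folds[[k]]$train; te <- split$folds[[k]]$test
      av <- average_pseudotrials(X[tr, ], labs[tr], 5, seed = k)
      m <- e1071::svm(av$features, av$labels, kernel = "linear", cost = 1,
                      scale = TRUE)
      mean(predict(m, X[te, , drop = FALSE]) == labs[te])
    }))
  })
  expect_lt(max(abs(tc$mean_accuracy - e_acc)), 0.12)
  expect_gt(tc$mean_accuracy[2], 0.75)
  expect_gt(e_acc[2], 0.75)
})

test_that("single-channel decoding localizes an effect to its carrier channels", {
  withr::with_seed(18, {
    n <- 64
    labs <- factor(rep(c("p", "q"), each = n / 2))
    ep <- fake_epochs(n, 6, 10, rnorm(n * 6 * 10))
    sgn <- ifelse(labs == "p", 4, -4)
    for (b in 5:10)  # effect on channels 1-2 only
      ep$data[, 1:2, b] <- ep$data[, 1:2, b] + outer(sgn, rep(1, 2))
  })
  ds <- labeled_dataset(ep, labs)
  sc <- single_channel_timecourses(ds, decoder_spec(n_folds = 8), seed = 19)
  eff <- rowMeans(sc$mean_accuracy[, 7:10])
  expect_true(all(eff[1:2] > 0.85))
  expect_true(all(eff[3:6] < 0.65))
  tc_all <- decode_timecourse(ds, decoder_spec(n_folds = 8), seed = 19)
  expect_gte(mean(tc_all$mean_accuracy[7:10]) + 0.02, max(eff))
})

test_that("dataset and spec constructors validate their inputs", {
  ep <- fake_epochs(10, 2, 3, 0)
  expect_error(labeled_dataset(ep, rep("a", 10)), "two label classes")
  expect_error(labeled_dataset(ep, rep(c("a", "b"), 3)), "one label per")
  expect_error(decoder_spec(cost = 0))
  expect_error(decoder_spec(n_folds = 1))
  expect_error(balance_trials(factor(character(0))))
})
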