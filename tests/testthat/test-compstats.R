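## Compositional statistics: log-ratio transforms, group tests, bootstrap CIs.

test_that("multiplicative zero replacement preserves closure", {
  x <- rbind(c(0.2, 0.3, 0.5), c(0.5, 0.5, 0))
  out <- zero_replace(x, delta = 0.01)
  expect_equal(out[1, ], x[1, ])   # no zeros -> unchanged
  expect_equal(rowSums(out), c(1, 1))
  ## hand computation of the multiplicative rule
  y <- zero_replace(rbind(c(0.5, 0.5, 0, 0)), delta = 0.01)
  expect_equal(as.numeric(y), c(0.49, 0.49, 0.01, 0.01))
  expect_error(zero_replace(rbind(c(0, 0, 0))), "entirely zero")
})

test_that("ilr is an isometry with the expected identities", {
  u <- matrix(1 / 8, 1, 8)
  expect_lt(max(abs(ilr(u))), 1e-12)
  set.seed(1)
  x <- matrix(stats::rgamma(20 * 8, 2), 20)
  x <- sweep(x, 1, rowSums(x), "/")
  y <- ilr(x)
  expect_equal(ncol(y), 7)
  back <- ilr_inverse(y)
  expect_lt(max(abs(back - x)), 1e-10)
  ## scale invariance
  y2 <- ilr(x * 7)
  expect_lt(max(abs(y2 - y)), 1e-10)
  expect_error(ilr(rbind(c(0.5, 0, 0.5))), "positive")
  ## the default basis is orthonormal in clr space
  V <- attr(y, "basis")
  expect_lt(max(abs(crossprod(V) - diag(7))), 1e-12)
})

test_that("the multivariate test validates inputs and detects shifts", {
  set.seed(2)
  base <- matrix(rnorm(30 * 7), 30)
  expect_error(multivariate_group_test(base, rep("a", 30)), "2 groups")
  expect_error(multivariate_group_test(base[1:5, ],
                                       c("a", "a", "a", "b", "b")), ">= 3")
  cst <- cbind(base, 1)
  colnames(cst) <- paste0("c", 1:8)
  expect_warning(multivariate_group_test(cst, rep(c("a", "b"), 15),
                                         n_perm = 50, seed = 1), "constant")
  ## power: 2-SD shift on one coordinate at n = 15/group
  rejections <- vapply(1:200, function(r) {
    x <- matrix(rnorm(30 * 7), 30)
    x[16:30, 3] <- x[16:30, 3] + 2
    g <- rep(c("a", "b"), each = 15)
    multivariate_group_test(x, g, n_perm = 99, seed = r)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("log-ratio differences recover constructed perturbations", {
  set.seed(3)
  x1 <- matrix(stats::rgamma(15 * 8, 20), 15)
  x1 <- sweep(x1, 1, rowSums(x1), "/")
  colnames(x1) <- of_states()
  ## identical groups: estimates ~0, CIs straddle 0
  ci0 <- logratio_difference_ci(rbind(x1, x1), rep(c("a", "b"), each = 15),
                                n_boot = 500, seed = 1)
  expect_lt(max(abs(ci0$estimate)), 1e-10)
  expect_true(all(ci0$lo <= 0 & ci0$hi >= 0))
  ## doubling one behavior makes its clr difference positive and largest;
  ## oracle: closed-form clr difference of the constructed compositions
  x2 <- x1
  x2[, "groom"] <- x2[, "groom"] * 2
  x2 <- sweep(x2, 1, rowSums(x2), "/")
  ci <- logratio_difference_ci(rbind(x2, x1), rep(c("a", "b"), each = 15),
                               n_boot = 500, seed = 2)
  groom_est <- ci$estimate[ci$behavior == "groom"]
  expect_gt(groom_est, 0)
  expect_equal(which.max(abs(ci$estimate)), which(ci$behavior == "groom"))
  clr_diff_oracle <- function(a, b) {
    g <- function(m) { lm <- colMeans(log(m)); lm - mean(lm) }
    g(a) - g(b)
  }
  expect_equal(ci$estimate, unname(clr_diff_oracle(x2, x1)), tolerance = 1e-10)
})

test_that("class relabeling permutes estimates and leaves the p-value unchanged", {
  set.seed(4)
  x <- matrix(stats::rgamma(24 * 6, 5), 24)
  x <- sweep(x, 1, rowSums(x), "/")
  colnames(x) <- paste0("b", 1:6)
  g <- rep(c("a", "b"), each = 12)
  x[g == "b", 2] <- x[g == "b", 2] * 1.5
  x <- sweep(x, 1, rowSums(x), "/")
  perm <- c(4, 1, 6, 2, 3, 5)
  ci1 <- logratio_difference_ci(x, g, n_boot = 300, seed = 5)
  ci2 <- logratio_difference_ci(x[, perm], g, n_boot = 300, seed = 5)
  expect_equal(ci2$estimate[match(ci1$behavior, ci2$behavior)], ci1$estimate,
               tolerance = 1e-12)
  p1 <- multivariate_group_test(ilr(x), g, n_perm = 199, seed = 6)$p_value
  ## a permutation of parts is an isometry: rank Wilks on any orthonormal
  ## ilr basis of the permuted table gives the same permutation null up to
  ## basis choice; test with the same basis construction
  p2 <- multivariate_group_test(ilr(x[, perm]), g, n_perm = 199, seed = 6)$p_value
  expect_lt(abs(p1 - p2), 0.05)
})

test_that("a constant dummy part leaves pairwise log-ratio contrasts intact", {
  set.seed(5)
  x <- matrix(stats::rgamma(20 * 5, 10), 20)
  x <- sweep(x, 1, rowSums(x), "/")
  colnames(x) <- paste0("b", 1:5)
  g <- rep(c("a", "b"), each = 10)
  ci1 <- logratio_difference_ci(x, g, n_boot = 200, seed = 7)
  xd <- cbind(x * 0.9, dummy = 0.1)
  ci2 <- logratio_difference_ci(xd, g, n_boot = 200, seed = 7)
  ## pairwise contrasts estimate_i - estimate_j are subcomposition-stable
  d1 <- outer(ci1$estimate, ci1$estimate, "-")
  e2 <- ci2$estimate[seq_len(5)]
  d2 <- outer(e2, e2, "-")
  expect_lt(max(abs(d1 - d2)), 1e-10)
})

test_that("compare_time_budgets wires usage tables through the full analysis", {
  set.seed(6)
  mk_usage <- function(shift) {
    x <- matrix(stats::rgamma(6 * 8, 30), 6)
    x[, 8] <- x[, 8] * shift
    x <- sweep(x, 1, rowSums(x), "/")
    colnames(x) <- of_states()
    x
  }
  ut <- tibble::as_tibble(rbind(mk_usage(1), mk_usage(4)))
  ut <- dplyr::bind_cols(tibble::tibble(mouse = paste0("m", 1:12)), ut)
  res <- compare_time_budgets(ut, rep(c("wt", "ko"), each = 6),
                              n_perm = 499, n_boot = 500, seed = 8)
  expect_lt(res$test$p_value, 0.05)
  expect_s3_class(res$log_ratios, "logratio_ci")
  ## group factor levels sort as ko < wt, so estimates are clr(ko) - clr(wt);
  ## the ko group was built with inflated locomotion
  loco <- res$log_ratios[res$log_ratios$behavior == "locomotion", ]
  expect_gt(loco$lo, 0)
})
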