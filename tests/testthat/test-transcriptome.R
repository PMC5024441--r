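test_that("lowess normalization removes intensity-dependent dye bias", {
  # equal channels: all corrected M exactly 0
  ch <- 2^runif(200, 6, 14)
  res <- lowess_normalize(ch, ch)
  expect_equal(res$M_corrected, rep(0, 200))

  # planted smooth bias M = 0.5 sin(A) is removed
  set.seed(9)
  A <- runif(2000, 6, 14)
  M <- 0.5 * sin(A)
  ch1 <- 2^(A + M / 2); ch2 <- 2^(A - M / 2)
  res <- lowess_normalize(ch1, ch2)
  expect_lt(max(abs(res$M_corrected)), 0.05)

  # renormalizing its own output leaves no residual trend
  ch1b <- 2^(res$A + res$M_corrected / 2)
  ch2b <- 2^(res$A - res$M_corrected / 2)
  res2 <- lowess_normalize(ch1b, ch2b)
  expect_lt(mean(abs(res2$M_corrected - res$M_corrected)), 2e-2)

  # dye swap: corrected M negates
  swap <- lowess_normalize(ch2, ch1)
  expect_equal(swap$M_corrected, -res$M_corrected, tolerance = 1e-10)

  expect_error(lowess_normalize(c(1, -2), c(1, 1)), "probe")
})

test_that("quantile normalization equalizes columns and is idempotent", {
  x <- cbind(a = c(1, 3, 5), b = c(2, 4, 6))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3.5, 5.5))

  set.seed(3)
  x <- matrix(rnorm(600, sd = rep(c(1, 2, 4), each = 200)), ncol = 3)
  qn <- quantile_normalize(x)
  # column distributions bit-identical
  expect_identical(sort(qn[, 1]), sort(qn[, 2]))
  expect_identical(sort(qn[, 2]), sort(qn[, 3]))
  # idempotent and rank-preserving
  expect_equal(quantile_normalize(qn), qn)
  for (j in 1:3) expect_identical(order(qn[, j]), order(x[, j]))

  # single column unchanged; identical columns unchanged
  expect_equal(quantile_normalize(x[, 1, drop = FALSE]),
               x[, 1, drop = FALSE])
  same <- cbind(x[, 1], x[, 1])
  expect_equal(quantile_normalize(same), same)

  # ties share the averaged reference value
  xt <- cbind(c(1, 1, 5), c(2, 4, 6))
  qt <- quantile_normalize(xt)
  expect_equal(qt[1, 1], qt[2, 1])
  expect_equal(qt[1, 1], mean(rowMeans(apply(xt, 2, sort))[1:2]))

  expect_error(quantile_normalize(matrix(c(1, NA), 1)), "missing")
})

test_that("moderated t reduces to the ordinary t when moderation is off", {
  set.seed(11)
  x <- matrix(rnorm(50 * 8), 50)
  grp <- rep(c("g1", "g2"), each = 4)
  res <- moderated_ttest(x, grp, moderation = FALSE)
  for (i in c(1, 17, 50)) {
    tt <- t.test(x[i, 5:8], x[i, 1:4], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(21)
  # heterogeneous true variances so moderation actually shrinks
  x <- matrix(rnorm(400 * 10, sd = rep(sqrt(1 / rgamma(400, 4, 4)), 10)),
              400)
  grp <- rep(c("g1", "g2"), each = 5)
  res <- moderated_ttest(x, grp)
  design <- cbind(1, grp == "g2")
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(res, "s0")^2, fit$s2.prior, tolerance = 0.01)
  expect_equal(res$t, fit$t[, 2], tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("posterior variance lies between the gene and prior variances", {
  set.seed(31)
  x <- matrix(rnorm(300 * 8, sd = rep(runif(300, 0.3, 3), 8)), 300)
  res <- moderated_ttest(x, rep(c("a", "b"), each = 4))
  d0 <- attr(res, "d0"); s0 <- attr(res, "s0")
  expect_true(d0 > 0)
  lo <- pmin(res$s^2, s0^2); hi <- pmax(res$s^2, s0^2)
  expect_true(all(res$s_post^2 >= lo - 1e-12))
  expect_true(all(res$s_post^2 <= hi + 1e-12))
})

test_that("null moderated p-values are uniform with nominal type-I error", {
  set.seed(77)
  x <- matrix(rnorm(10000 * 8), 10000)
  res <- moderated_ttest(x, rep(c("a", "b"), each = 4))
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
  rate <- mean(res$p < 0.01)
  expect_gt(rate, 0.007)
  expect_lt(rate, 0.013)
})

test_that("differential selection partitions by effect sign", {
  res <- data.frame(effect = c(2, -3, 0.5, 1), p = c(0.001, 0.005, 0.5, 0.02))
  rownames(res) <- paste0("g", 1:4)
  sel <- select_differential(res, 0.01)
  expect_identical(sel$selected, c("g1", "g2"))
  expect_identical(sel$up, "g1")
  expect_identical(sel$down, "g2")
  expect_identical(select_differential(res, 1)$n_selected, 4L)
  all_null <- data.frame(effect = rnorm(5), p = rep(0.5, 5))
  expect_identical(select_differential(all_null)$n_selected, 0L)
  expect_error(select_differential(res, 0), "alpha")
})

test_that("planted effects are recovered at high power", {
  set.seed(55)
  n <- 1000; n_true <- 50
  x <- matrix(rnorm(n * 8), n)
  x[seq_len(n_true), 5:8] <- x[seq_len(n_true), 5:8] + 4  # 4 sd shift
  res <- moderated_ttest(x, rep(c("a", "b"), each = 4))
  sel <- select_differential(res, 0.01)
  expect_gte(sum(sel$selected %in% as.character(seq_len(n_true))), 45)
})

test_that("correlation-distance clustering groups by profile shape", {
  # identical profiles merge at height 0
  prof <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4) * 2 + 5,
                g3 = c(4, 3, 2, 1))
  hc <- hierarchical_cluster(prof)
  expect_equal(min(hc$tree$height), 0, tolerance = 1e-12)
  # perfectly anti-correlated pair sits at distance 2
  expect_equal(max(as.matrix(hc$dist)), 2, tolerance = 1e-12)

  # 20 profiles from 2 orthogonal templates + small noise: exact recovery
  set.seed(8)
  t1 <- c(1, 1, 0, 0, 0); t2 <- c(0, 0, 1, 1, 1)
  prof <- rbind(t(replicate(10, t1 + rnorm(5, 0, 0.05))),
                t(replicate(10, t2 + rnorm(5, 0, 0.05))))
  cl <- hierarchical_cluster(prof, k = 2)$clusters
  expect_identical(unname(cl[1:10]), rep(cl[[1]], 10))
  expect_identical(unname(cl[11:20]), rep(cl[[11]], 10))
  expect_false(cl[[1]] == cl[[11]])

  # invariance to per-profile scaling and shifting
  scaled <- prof * 3.7 + 100
  expect_equal(hierarchical_cluster(scaled, k = 2)$clusters, cl)

  expect_error(hierarchical_cluster(rbind(a = rep(1, 4), b = 1:4)),
               "zero-variance.*a")
})

test_that("qPCR relative expression follows the 2^-dCt arithmetic", {
  res <- relative_expression(20, c(20, 20, 20))
  expect_equal(res$delta_ct, 0)
  expect_equal(res$relative_expression, 1)
  res <- relative_expression(23, c(20, 20, 20))
  expect_equal(res$delta_ct, 3)
  expect_equal(res$relative_expression, 0.125)
  # the normalization factor is the mean of the three reference Cts
  res <- relative_expression(22, c(19, 20, 21))
  expect_equal(res$ct_ref, 20)
  fc <- fold_change_ddct(2, 5)
  expect_equal(fc$delta_delta_ct, -3)
  expect_equal(fc$fold_change, 8)
  expect_error(relative_expression(50, c(20, 20, 20)), "Ct")
  expect_error(relative_expression(20, c(20, 20)), "three")
})
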