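# OPLS-DA: equivalence with the brute-force PLS1 oracle, orthogonality,
# invariances, VIP identities, cross-validated Q2 and permutation behavior.

test_that("with no orthogonal components the fit equals the PLS1 oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 25), 6)
    X[, 1:5] <- X[, 1:5] + outer(rep(c(-1, 1), each = 3), runif(5, 0.5, 2))
    y <- rep(c("A", "B"), each = 3)
    fit <- fit_opls(X, y, n_ortho = 0)
    ora <- pls1_oracle(X, y)
    expect_equal(unname(fit$w), ora$w, tolerance = 1e-10)
    expect_equal(unname(fit$t), ora$t, tolerance = 1e-10)
    expect_equal(unname(fit$p), ora$p, tolerance = 1e-10)
    expect_equal(fit$c, ora$c, tolerance = 1e-10)
  }
})

test_that("orthogonal scores are orthogonal to the predictive score", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 30), 12)
    X[, 1:6] <- X[, 1:6] + outer(rep(c(-1, 1), each = 6), runif(6, 0.5, 2))
    fit <- fit_opls(X, rep(c("A", "B"), each = 6), n_ortho = 2)
    for (a in 1:2) {
      cosang <- abs(sum(fit$t * fit$T_o[, a])) /
        (sqrt(sum(fit$t^2)) * sqrt(sum(fit$T_o[, a]^2)))
      expect_lt(cosang, 1e-8)
    }
  }
})

test_that("rank-1 y-predictive data is fitted and predicted perfectly", {
  sd0 <- separable_data(n_per_class = 3, J = 15, noise = 0, seed = 3)
  fit <- fit_opls(sd0$X, sd0$y, n_ortho = 0)
  expect_equal(fit$r2y, 1, tolerance = 1e-12)
  q2 <- cross_validate(sd0$X, sd0$y, K = 6, seed = 1)
  expect_equal(q2, 1, tolerance = 1e-6)
})

test_that("a planted y-orthogonal component is recovered by deflation", {
  set.seed(7)
  n <- 8
  y <- rep(c("A", "B"), each = 4)
  yc <- ifelse(y == "B", 1, -1)
  t_o <- c(rnorm(n))
  t_o <- t_o - mean(t_o)
  t_o <- t_o - yc * sum(t_o * yc) / sum(yc^2)  # exactly y-orthogonal
  v <- runif(20, 0.5, 2)
  p_o <- rnorm(20)
  X <- outer(yc, v) + 3 * outer(t_o, p_o)
  fit1 <- fit_opls(X, y, n_ortho = 1, scale. = FALSE)
  # oracle: project the planted component out by hand, then plain PLS
  Xc <- scale(X, scale = FALSE)
  t_hat <- drop(Xc %*% p_o) / sum(p_o^2)
  Xdefl <- Xc - outer(t_hat, p_o)
  ora <- fit_opls(Xdefl, y, n_ortho = 0, center = FALSE, scale. = FALSE)
  alignment <- abs(stats::cor(fit1$t, ora$t))
  expect_gt(alignment, 1 - 1e-8)
})

test_that("fitting pre-scaled data with scaling disabled reproduces the model", {
  set.seed(11)
  X <- matrix(rnorm(6 * 10), 6)
  X[, 1] <- X[, 1] + rep(c(-2, 2), each = 3)
  y <- rep(c("A", "B"), each = 3)
  ref <- fit_opls(X, y, n_ortho = 1)
  pre <- scale(X)
  again <- fit_opls(pre, y, n_ortho = 1, center = FALSE, scale. = FALSE)
  expect_equal(unname(again$w), unname(ref$w), tolerance = 1e-12)
  expect_equal(unname(again$t), unname(ref$t), tolerance = 1e-12)
  expect_equal(again$r2y, ref$r2y, tolerance = 1e-12)
})

test_that("relabeling the classes flips predictions but not fit quality", {
  set.seed(5)
  X <- matrix(rnorm(8 * 12), 8)
  X[, 1:3] <- X[, 1:3] + outer(rep(c(-1, 1), each = 4), c(1, 1.5, 2))
  y <- rep(c("A", "B"), each = 4)
  yswap <- ifelse(y == "A", "Z", "A")  # swaps which class codes +1
  f1 <- fit_opls(X, y)
  f2 <- fit_opls(X, yswap)
  expect_equal(f2$r2y, f1$r2y, tolerance = 1e-12)
  expect_equal(unname(compute_vip(f2)), unname(compute_vip(f1)),
               tolerance = 1e-12)
  expect_equal(predict(f2, X), -predict(f1, X), tolerance = 1e-12)
  q1 <- cross_validate(X, y, K = 4, seed = 2)
  q2_ <- cross_validate(X, yswap, K = 4, seed = 2)
  expect_equal(q2_, q1, tolerance = 1e-12)
})

test_that("VIP satisfies its normalization identities", {
  # one informative variable out of two: w = (1, 0), VIP = (sqrt(2), 0)
  y <- rep(c("A", "B"), each = 3)
  yc <- ifelse(y == "B", 1, -1)
  ortho <- c(1, -1, 0, 0, 1, -1)  # exactly orthogonal to yc
  X <- cbind(yc + 0, ortho)
  fit <- fit_opls(X, y, n_ortho = 0, scale. = FALSE)
  expect_equal(unname(compute_vip(fit)), c(sqrt(2), 0), tolerance = 1e-8)
  # mean of squared VIPs is exactly 1 on any fitted model
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 40), 6)
    X[, 1] <- X[, 1] + rep(c(-1, 1), each = 3)
    fit <- fit_opls(X, y)
    expect_equal(mean(compute_vip(fit)^2), 1, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(12), 4)
  expect_error(fit_opls(X, rep("A", 4)), "2 classes")
  expect_error(fit_opls(X, c("A", "A", "A", "B")), ">= 2 samples")
  Xz <- cbind(X, 0)
  expect_error(fit_opls(Xz, rep(c("A", "B"), each = 2)), "zero variance")
  expect_error(fit_opls(X, rep(c("A", "B"), each = 2), n_ortho = 10),
               "rank")
  # an oversized fold count is capped at leave-one-out
  set.seed(2)
  Xc <- matrix(rnorm(6 * 8), 6)
  Xc[, 1] <- Xc[, 1] + rep(c(-2, 2), each = 3)
  yc <- rep(c("A", "B"), each = 3)
  expect_equal(cross_validate(Xc, yc, K = 99, seed = 1),
               cross_validate(Xc, yc, K = 6, seed = 1))
})

test_that("Q2 does not exceed R2Y and collapses under label noise", {
  set.seed(31)
  q_vs_r <- replicate(15, {
    X <- matrix(rnorm(10 * 20), 10)
    X[, 1:4] <- X[, 1:4] + outer(rep(c(-1, 1), each = 5), runif(4, 0.3, 1.5))
    y <- rep(c("A", "B"), each = 5)
    c(cross_validate(X, y, K = 5), fit_opls(X, y)$r2y)
  })
  expect_true(all(q_vs_r[1, ] <= q_vs_r[2, ] + 1e-12))
  # pure-noise X with permuted labels: median Q2 is non-positive
  set.seed(17)
  null_q2 <- replicate(40, {
    X <- matrix(rnorm(10 * 20), 10)
    y <- sample(rep(c("A", "B"), each = 5))
    cross_validate(X, y, K = 5)
  })
  expect_lte(stats::median(null_q2), 0)
})

test_that("permutation p-values are deterministic and floor at 1/(n_perm+1)", {
  sd0 <- separable_data(n_per_class = 10, J = 15, noise = 0.05, seed = 2)
  pt1 <- permutation_test(sd0$X, sd0$y, n_perm = 99, seed = 4, K = 5)
  pt2 <- permutation_test(sd0$X, sd0$y, n_perm = 99, seed = 4, K = 5)
  expect_identical(pt1$p_q2, pt2$p_q2)
  expect_identical(pt1$q2_perm, pt2$q2_perm)
  # strongly separable data at n = 10 + 10: observed Q2 beats every permutation
  expect_equal(pt1$p_q2, 1 / 100)
  expect_gt(pt1$p_r2y, 0)
  expect_lte(pt1$p_r2y, 1)
})

test_that("S-plot covariance and correlation follow their definitions", {
  y <- rep(c("A", "B"), each = 4)
  yc <- ifelse(y == "B", 1, -1)
  ortho <- c(1, -1, 1, -1, -1, 1, -1, 1)  # exactly orthogonal to yc
  # exact construction: t equals the y pattern, so the identities are sharp
  X <- cbind(a = yc + 0, b = ortho, d = rep(0, 8))
  fit <- fit_opls(X, y, scale. = FALSE)
  sp <- s_plot(fit, X)
  expect_equal(sp$corr[sp$variable == "a"], 1, tolerance = 1e-12)
  expect_lt(abs(sp$cov[sp$variable == "b"]), 1e-12)
  # zero-variance column: correlation undefined, flagged NA, no error
  expect_true(is.na(sp$corr[sp$variable == "d"]))
  # noisy data: corr column matches the textbook Pearson correlation
  set.seed(9)
  Xn <- cbind(a = yc + rnorm(8, sd = 0.3), b = rnorm(8), c = rnorm(8))
  fitn <- fit_opls(Xn, y)
  spn <- s_plot(fitn, Xn)
  for (v in c("a", "b", "c")) {
    expect_equal(spn$corr[spn$variable == v],
                 unname(stats::cor(Xn[, v], fitn$t)), tolerance = 1e-12)
  }
})
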