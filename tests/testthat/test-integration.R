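# RDA, correlation network, entropy weights and TOPSIS.

test_that("RDA recovers exact linear structure and decomposes variance", {
  set.seed(3)
  n <- 12
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("e1", "e2", "e3")))
  B <- matrix(runif(3 * 4), 3)
  Y <- X %*% B
  colnames(Y) <- paste0("r", 1:4)
  res <- rda_analysis(Y, X)
  expect_equal(res$constrained_fraction, 1, tolerance = 1e-9)

  # noisy case: constrained + unconstrained eigenvalues sum to the total
  # variance of the scaled response
  Y2 <- Y + matrix(rnorm(n * 4), n)
  res2 <- rda_analysis(Y2, X)
  total <- sum(apply(scale(Y2), 2, var))
  expect_equal(sum(res2$constrained_eig) + sum(res2$unconstrained_eig),
               total, tolerance = 1e-9)
  expect_true(res2$constrained_fraction < 1)

  # independent least-squares + projection oracle for the fraction
  Ys <- scale(Y2); Xs <- scale(X)
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  oracle_frac <- sum((H %*% Ys)^2) / sum(Ys^2)
  expect_equal(res2$constrained_fraction, oracle_frac, tolerance = 1e-9)
})

test_that("RDA on an orthogonal explanatory gives zero constrained fraction", {
  x <- rep(c(-1, 1), 6)
  set.seed(4)
  y1 <- rnorm(12)
  y1 <- y1 - mean(y1)
  y1 <- y1 - x * sum(y1 * x) / sum(x^2)  # exactly uncorrelated with x
  Y <- cbind(r1 = y1)
  res <- rda_analysis(Y, cbind(e1 = x))
  expect_lt(res$constrained_fraction, 1e-9)
})

test_that("RDA is invariant to invertible recoding and rejects collinearity", {
  set.seed(6)
  X <- matrix(rnorm(10 * 3), 10, dimnames = list(NULL, c("a", "b", "c")))
  Y <- matrix(rnorm(10 * 2), 10, dimnames = list(NULL, c("y1", "y2")))
  A <- matrix(c(2, 1, 0, 0, 1, 1, 1, 0, 3), 3)
  res1 <- rda_analysis(Y, X)
  res2 <- rda_analysis(Y, X %*% A)
  expect_equal(res2$constrained_fraction, res1$constrained_fraction,
               tolerance = 1e-9)
  Xbad <- cbind(X, dup = X[, "a"] + X[, "b"])
  expect_error(rda_analysis(Y, Xbad), "dup")
  expect_error(rda_analysis(Y, matrix(rnorm(110), 10)), "more samples")
})

test_that("correlation network edges follow sign, threshold and the formula", {
  set.seed(8)
  v1 <- rnorm(10)
  x <- cbind(v1 = v1, neg = -v1, pos = v1 + rnorm(10, sd = 0.01),
             noise = rnorm(10))
  edges <- correlation_network(x, r_threshold = 0.8, p_threshold = 0.05)
  pick <- function(a, b) edges[edges$source == a & edges$target == b, ]
  expect_equal(pick("v1", "neg")$r, -1)
  expect_identical(pick("v1", "neg")$sign, "negative")
  expect_identical(pick("v1", "pos")$sign, "positive")
  expect_true(all(abs(edges$r) >= 0.8 & edges$p < 0.05))
  # r equals the textbook covariance / sd implementation
  r_hand <- sum((v1 - mean(v1)) * (x[, "pos"] - mean(x[, "pos"]))) /
    ((10 - 1) * sd(v1) * sd(x[, "pos"]))
  expect_equal(pick("v1", "pos")$r, r_hand, tolerance = 1e-12)
  # zero-variance variables are skipped with a warning, not an error
  expect_warning(e2 <- correlation_network(cbind(x, const = 1)),
                 "zero-variance")
  expect_false("const" %in% c(e2$source, e2$target))
})

test_that("entropy weights follow the dispersion formula", {
  # constant criterion gets entropy 1 and weight 0
  d <- cbind(varied = c(1, 2, 3), flat = c(4, 4, 4))
  w <- entropy_weights(d)
  expect_equal(unname(w["flat"]), 0)
  expect_equal(sum(w), 1)
  # identical columns share the weight equally
  d2 <- cbind(a = c(1, 5, 2), b = c(1, 5, 2))
  expect_equal(unname(entropy_weights(d2)), c(0.5, 0.5))
  # direct formula evaluation on a printed 3 x 2 fixture
  d3 <- cbind(c1 = c(1, 2, 3), c2 = c(2, 2, 4))
  p1 <- d3[, 1] / sum(d3[, 1]); p2 <- d3[, 2] / sum(d3[, 2])
  e <- c(-sum(p1 * log(p1)) / log(3), -sum(p2 * log(p2)) / log(3))
  expect_equal(unname(entropy_weights(d3)), (1 - e) / sum(1 - e),
               tolerance = 1e-12)
  expect_error(entropy_weights(cbind(a = c(1, 1), b = c(2, 2))), "constant")
})

test_that("TOPSIS closeness matches direct formula evaluation", {
  # symmetric two-criterion case: both alternatives score 0.5
  d <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  res <- topsis(d, weights = c(0.5, 0.5))
  expect_equal(unname(res$closeness), c(0.5, 0.5), tolerance = 1e-12)
  # an alternative that attains every per-criterion best has closeness 1
  d2 <- rbind(best = c(10, 1), mid = c(5, 5), worst = c(1, 10))
  colnames(d2) <- c("benefit1", "cost1")
  res2 <- topsis(d2, weights = c(0.6, 0.4), polarity = c("benefit", "cost"))
  expect_equal(unname(res2$closeness["best"]), 1)
  expect_equal(unname(res2$ranking["best"]), 1)
  # brute-force evaluation on a random matrix
  set.seed(12)
  d3 <- matrix(runif(12, 1, 10), 4, dimnames = list(NULL, c("x", "y", "z")))
  w <- c(0.2, 0.5, 0.3)
  res3 <- topsis(d3, weights = w)
  V <- sweep(sweep(d3, 2, sqrt(colSums(d3^2)), "/"), 2, w, "*")
  ideal <- apply(V, 2, max); anti <- apply(V, 2, min)
  dp <- sqrt(rowSums(sweep(V, 2, ideal)^2))
  dm <- sqrt(rowSums(sweep(V, 2, anti)^2))
  expect_equal(unname(res3$closeness), dm / (dp + dm), tolerance = 1e-12)
  expect_true(all(res3$closeness >= 0 & res3$closeness <= 1))
})

test_that("TOPSIS ranking is invariant to rescaling one criterion", {
  set.seed(14)
  d <- matrix(runif(15, 1, 9), 5, dimnames = list(NULL, c("a", "b", "c")))
  w <- c(0.3, 0.3, 0.4)
  base <- topsis(d, weights = w)
  d2 <- d; d2[, 2] <- d2[, 2] * 1e4
  rescaled <- topsis(d2, weights = w)
  expect_equal(unname(rescaled$closeness), unname(base$closeness),
               tolerance = 1e-12)
  expect_error(topsis(cbind(d, zero = 0), weights = c(w * 0.9, 0.1)),
               "zero-norm")
})

test_that("simulated physio tables reproduce the expected correlation signs", {
  d <- make_design(3)
  ph <- generate_physio(d, seed = 21)
  mg <- (as.integer(d$group) - 1) * 0.4
  x <- cbind(`Mg` = mg, t(ph))
  cm <- stats::cor(x)["Mg", ]
  pol <- attr(ph, "polarity")
  expect_true(all(cm[names(which(pol == "benefit"))] > 0))
  expect_true(all(cm[names(which(pol == "cost"))] < 0))
})
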