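# FPKM normalization, PCA contribution rates, differential expression and
# monotone trend classification.

test_that("FPKM matches the closed form and its algebraic identities", {
  counts <- matrix(c(100L, 1999900L), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  f <- compute_fpkm(counts, c(2000, 1000))
  # 100 / ((2000/1e3) * (2e6/1e6)) = 25
  expect_equal(f["a", "s1"], 25)
  expect_equal(compute_fpkm(matrix(0:3, 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))),
                            c(100, 100))[1, 1], 0)

  d <- make_design(2)
  sim <- generate_counts(d, 40, 4, 4, 1, 0.1, seed = 3)
  f <- compute_fpkm(sim$counts, sim$lengths)
  # column-sum identity: sum_g fpkm_gj = 1e9 * sum_g(counts/length) / total_j
  totals <- colSums(sim$counts)
  expect_equal(colSums(f),
               1e9 * colSums(sim$counts / sim$lengths) / totals)
  # per-sample depth scaling cancels
  doubled <- sim$counts
  doubled[, 1] <- doubled[, 1] * 2L
  expect_equal(compute_fpkm(doubled, sim$lengths)[, 1], f[, 1])
})

test_that("FPKM rejects empty libraries by name", {
  counts <- matrix(c(1L, 2L, 0L, 0L), 2,
                   dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(compute_fpkm(counts, c(100, 100)), "empty")
})

test_that("PCA contribution rates behave as eigenvalue fractions", {
  # rank-1 data: one component carries everything
  v <- rnorm(10)
  expr <- outer(v, c(1, 2, 3, 4))
  ps <- pca_summary(expr)
  expect_equal(ps$contribution[1], 1)
  # contributions always sum to 1
  set.seed(1)
  ps2 <- pca_summary(matrix(rnorm(200), 20))
  expect_equal(sum(ps2$contribution), 1)
  # isotropic 2-D Gaussian: symmetry forces a 50/50 split at large n
  set.seed(42)
  iso <- t(matrix(rnorm(2 * 5000), ncol = 2))
  ps3 <- pca_summary(iso)
  expect_true(all(abs(ps3$contribution - 0.5) < 0.03))
  expect_error(pca_summary(matrix(1, 3, 4)), "variance")
})

test_that("identical groups yield zero fold change and no call", {
  d <- make_design(2, groups = c("A", "B"))
  expr <- matrix(rep(c(5, 9, 2), 4), 3, 4,
                 dimnames = list(c("g1", "g2", "g3"), d$sample))
  de <- differential_expression(expr, d, "A", "B")
  expect_equal(de$log2fc, rep(0, 3))
  expect_true(all(de$call == "none"))
  expect_true(all(de$p == 1))
})

test_that("moderated t matches the limma oracle", {
  skip_if_not_installed("limma")
  d <- make_design(3, groups = c("A", "B"))
  sim <- generate_counts(d, 400, 40, 40, 1.5, 0.1, seed = 21)
  fpkm <- compute_fpkm(sim$counts, sim$lengths)
  de <- differential_expression(fpkm, d, "A", "B")
  lf <- log2(fpkm + 1)
  fit <- limma::eBayes(limma::lmFit(lf, cbind(1, d$group == "B")))
  expect_equal(attr(de, "df_prior"), unname(fit$df.prior), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("BH-adjusted q equals the independent step-up oracle", {
  # hand-checked case: p = (.01,.02,.03), m = 3 -> q = (.03,.03,.03)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  d <- make_design(3, groups = c("A", "B"))
  sim <- generate_counts(d, 300, 30, 30, 2, 0.1, seed = 8)
  de <- differential_expression(compute_fpkm(sim$counts, sim$lengths),
                                d, "A", "B")
  expect_identical(de$q, bh_oracle(de$p))
  expect_true(all(de$q >= de$p))
})

test_that("swapping the groups negates every fold change", {
  d <- make_design(3, groups = c("A", "B"))
  sim <- generate_counts(d, 150, 15, 15, 2, 0.1, seed = 13)
  fpkm <- compute_fpkm(sim$counts, sim$lengths)
  ab <- differential_expression(fpkm, d, "A", "B")
  ba <- differential_expression(fpkm, d, "B", "A")
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$p, ab$p)
})

test_that("both t methods keep type-I error near nominal under the null", {
  d <- make_design(3, groups = c("A", "B"))
  sim <- generate_counts(d, 1000, 0, 0, 0, 0.1, seed = 3)
  fpkm <- compute_fpkm(sim$counts, sim$lengths)
  for (m in c("welch", "moderated")) {
    de <- differential_expression(fpkm, d, "A", "B", method = m)
    rate <- mean(de$p < 0.05)
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
  }
})

test_that("trend classification follows strict monotonicity plus dual significance", {
  d <- make_design(2)
  expr <- rbind(
    g1 = c(2.0, 2.0, 5.1, 5.1, 9.8, 9.8),   # monotone up
    g2 = c(1.0, 1.0, 3.0, 3.0, 2.0, 2.0),   # not monotone
    g3 = c(9.0, 9.0, 5.0, 5.0, 1.0, 1.0))   # monotone down
  colnames(expr) <- d$sample
  fake_de <- function(calls) {
    data.frame(gene = rownames(expr), log2fc = 0, p = 0, q = 0,
               call = calls, stringsAsFactors = FALSE)
  }
  # both comparisons significant for all genes
  tr <- classify_trend(expr, d, fake_de(c("up", "up", "down")),
                       fake_de(c("up", "up", "down")))
  expect_identical(tr$trend, c("up", "none", "down"))
  # only one comparison significant: even a monotone gene drops to none
  tr2 <- classify_trend(expr, d, fake_de(c("up", "up", "down")),
                        fake_de(rep("none", 3)))
  expect_identical(tr2$trend, rep("none", 3))
  # ties break to none
  tied <- expr
  tied["g1", ] <- c(2, 2, 2, 2, 9, 9)
  tr3 <- classify_trend(tied, d, fake_de(rep("up", 3)), fake_de(rep("up", 3)))
  expect_identical(tr3$trend[1], "none")
  expect_error(classify_trend(expr, make_design(3, groups = c("A", "B")),
                              fake_de(rep("up", 3)), fake_de(rep("up", 3))),
               "3 ordered groups")
})

test_that("planted monotone genes are recovered in the study regime", {
  rec <- run_screen_recovery(seed = 502, n_genes = 1500, n_up = 75,
                             n_down = 75)
  tr <- rec$trends
  planted_trend <- tr$trend[match(rec$planted, tr$gene)]
  expect_gte(mean(planted_trend != "none"), 0.7)
  nulls <- !tr$gene %in% rec$planted
  expect_lte(mean(tr$trend[nulls] != "none"), 0.05)
  # recovered directions agree with the planted ones
  up_called <- tr$gene[tr$trend == "up"]
  expect_true(all(setdiff(up_called, rec$sim$truth$planted_up) %in%
                    tr$gene[!tr$gene %in% rec$planted]))
})
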