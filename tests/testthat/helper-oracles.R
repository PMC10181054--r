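# Independent oracles used to validate the package's implementations.
# These deliberately re-derive each quantity from first principles and share
# no code with the package internals they check.

# Single-component NIPALS PLS1 on autoscaled X and centered +/-1 y, with the
# same first-nonzero-weight-positive sign convention.
pls1_oracle <- function(X, y) {
  lv <- sort(unique(as.character(y)))
  yy <- ifelse(as.character(y) == lv[2], 1, -1)
  yc <- yy - mean(yy)
  Xs <- scale(X)
  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  nz <- which(abs(w) > 1e-12)[1]
  if (w[nz] < 0) w <- -w
  t_ <- drop(Xs %*% w)
  p <- drop(crossprod(Xs, t_)) / sum(t_^2)
  c_ <- sum(yc * t_) / sum(t_^2)
  list(w = w, t = t_, p = p, c = c_)
}

# Benjamini-Hochberg step-up, written as the textbook scan from the largest
# p downwards with running minimum.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, (m / i) * p[ord[i]])
    q[ord[i]] <- running
  }
  q
}

# Exact hypergeometric upper tail by direct summation of the mass function.
hyper_tail_oracle <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- max(k, 0):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small separable two-class dataset: rank-1 y-predictive structure plus
# optional noise; returns list(X, y).
separable_data <- function(n_per_class = 3, J = 20, noise = 0, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) .Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    y <- rep(c("A", "B"), each = n_per_class)
    v <- abs(stats::rnorm(J)) + 0.5
    X <- outer(ifelse(y == "B", 1, -1), v) +
      matrix(stats::rnorm(2 * n_per_class * J, sd = noise), 2 * n_per_class)
    list(X = X, y = y)
  })
}

# Generator-backed screening run shared by recovery tests: returns planted
# and recovered key-gene sets plus the intermediate tables.
run_screen_recovery <- function(seed, n_genes = 3000, n_up = 150,
                                n_down = 150, effect = 2, phi = 0.1) {
  design <- make_design(3)
  sim <- generate_counts(design, n_genes, n_up, n_down, effect, phi,
                         seed = seed)
  fpkm <- compute_fpkm(sim$counts, sim$lengths)
  lv <- levels(design$group)
  de12 <- differential_expression(fpkm, design, lv[1], lv[2])
  de23 <- differential_expression(fpkm, design, lv[2], lv[3])
  trends <- classify_trend(fpkm, design, de12, de23)
  lf <- log2(fpkm + 1)
  vip_of <- function(ga, gb) {
    samp <- c(design$sample[design$group == ga],
              design$sample[design$group == gb])
    X <- t(lf[, samp])
    keep <- apply(X, 2, stats::sd) > 0
    fit <- fit_opls(X[, keep, drop = FALSE],
                    as.character(design$group[match(samp, design$sample)]))
    v <- stats::setNames(rep(NA_real_, nrow(lf)), rownames(lf))
    v[colnames(X)[keep]] <- compute_vip(fit)
    v
  }
  keys <- select_key_genes(vip_of(lv[1], lv[2]), vip_of(lv[2], lv[3]),
                           trends)
  planted <- c(sim$truth$planted_up, sim$truth$planted_down)
  list(design = design, sim = sim, fpkm = fpkm, trends = trends,
       keys = keys, planted = planted,
       sensitivity = length(intersect(keys$key_common, planted)) /
         length(planted),
       contamination = if (length(keys$key_common) == 0) 0 else
         length(setdiff(keys$key_common, planted)) / length(keys$key_common))
}
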