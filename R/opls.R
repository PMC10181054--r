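# Two-class OPLS-DA implemented from scratch: orthogonal-signal-corrected
# NIPALS fit, R2Y, cross-validated Q2, permutation validation, VIP scores and
# S-plot coordinates. The predictive part is a single NIPALS PLS1 component
# (two classes need exactly one); orthogonal components are extracted and
# deflated before it.

# Map a two-class label vector to centered +/-1 coding. Class order follows
# sort(unique()), so the second level codes +1.
code_y <- function(y) {
  lv <- sort(unique(as.character(y)))
  if (length(lv) != 2) stop("y must contain exactly 2 classes, got ",
                            length(lv))
  yy <- ifelse(as.character(y) == lv[2], 1, -1)
  if (min(table(y)) < 2) stop("each class needs >= 2 samples")
  list(y = yy, levels = lv)
}

# Core fit on an already centered/scaled X and centered y. zero-variance
# columns must have been neutralized by the caller (all-zero columns are
# harmless: they get zero weight).
opls_core <- function(X, yc, n_ortho) {
  W_o <- matrix(0, ncol(X), 0)
  T_o <- matrix(0, nrow(X), 0)
  P_o <- matrix(0, ncol(X), 0)
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(X, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("X carries no y-covariance; cannot extract components")
    w <- w / nw
    t_ <- drop(X %*% w)
    p <- drop(crossprod(X, t_)) / sum(t_^2)
    w_o <- p - sum(w * p) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) {
      stop("no orthogonal variation left after ", a - 1,
           " component(s); reduce n_ortho")
    }
    w_o <- w_o / nwo
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    T_o <- cbind(T_o, t_o)
    P_o <- cbind(P_o, p_o)
  }
  # final predictive component: one NIPALS PLS1 round on the deflated X
  w <- drop(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("X carries no y-covariance; cannot fit predictive component")
  w <- w / nw
  # sign convention: first non-negligible weight entry forced positive
  nz <- which(abs(w) > 1e-12)[1]
  if (length(nz) && w[nz] < 0) w <- -w
  t_ <- drop(X %*% w)
  p <- drop(crossprod(X, t_)) / sum(t_^2)
  c_ <- sum(yc * t_) / sum(t_^2)
  list(w = w, t = t_, p = p, c = c_, W_o = W_o, T_o = T_o, P_o = P_o)
}

#' Fit a two-class OPLS-DA model
#'
#' X is mean-centered and (by default) unit-variance scaled; y is coded
#' centered +/-1. For each of `n_ortho` orthogonal components, the
#' y-orthogonal part of the provisional loading is extracted and deflated
#' from X; the predictive component is then a single NIPALS PLS1 round on the
#' deflated matrix. `r2y = 1 - ||y - t c||^2 / ||y||^2`.
#'
#' @param X numeric matrix, samples x variables.
#' @param y two-class label vector (factor, character or numeric), one entry
#'   per row of `X`; the lexicographically second class codes +1.
#' @param n_ortho number of orthogonal components (>= 0; must be below the
#'   rank of the centered X).
#' @param center,scale. center / autoscale columns of `X` (defaults `TRUE`).
#'   Variables with zero variance are rejected when `scale.` is `TRUE`.
#' @return object of class `opls`: list with `w`, `t`, `p`, `c` (predictive
#'   weightings/scores/loadings/y-loading), `W_o`, `T_o`, `P_o` (orthogonal
#'   counterparts), `x_means`, `x_scales`, `y_mean`, `y_levels`, `r2y`,
#'   `n_ortho`, `vip`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 6)
#' y <- rep(c("A", "B"), each = 3)
#' X[, 1] <- ifelse(y == "B", 1, -1) + rnorm(6, sd = 0.1)
#' m <- fit_opls(X, y, n_ortho = 0)
#' m$r2y
#' @export
fit_opls <- function(X, y, n_ortho = 0, center = TRUE, scale. = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_ortho >= 0)
  cy <- code_y(y)
  x_means <- if (center) colMeans(X) else rep(0, ncol(X))
  sds <- col_sds(sweep(X, 2, x_means))
  if (scale. && any(sds == 0)) {
    stop(sum(sds == 0), " variable(s) have zero variance; remove them before ",
         "autoscaled fitting")
  }
  x_scales <- if (scale.) sds else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, x_means), 2, x_scales, "/")
  rk <- qr(Xs)$rank
  if (n_ortho >= rk) {
    stop("n_ortho (", n_ortho, ") must be below rank(X) = ", rk)
  }
  y_mean <- mean(cy$y)
  yc <- cy$y - y_mean
  core <- opls_core(Xs, yc, n_ortho)
  r2y <- 1 - sum((yc - core$t * core$c)^2) / sum(yc^2)
  vip <- sqrt(length(core$w)) * abs(core$w)
  names(vip) <- colnames(X)
  structure(c(core, list(
    x_means = x_means, x_scales = x_scales, y_mean = y_mean,
    y_levels = cy$levels, r2y = r2y, n_ortho = n_ortho, vip = vip,
    center = center, scale. = scale., n = nrow(X)
  )), class = "opls")
}

#' @export
print.opls <- function(x, ...) {
  cat("Two-class OPLS-DA model\n")
  cat(sprintf("  samples: %d   variables: %d   orthogonal components: %d\n",
              x$n, length(x$w), x$n_ortho))
  cat(sprintf("  classes: %s (-1) vs %s (+1)\n", x$y_levels[1], x$y_levels[2]))
  cat(sprintf("  R2Y = %.4f\n", x$r2y))
  invisible(x)
}

#' Predict class scores for new samples
#'
#' Applies the stored centering/scaling, deflates the orthogonal components
#' sequentially, and returns the continuous prediction `t_new * c + mean(y)`
#' on the +/-1 coding scale.
#'
#' @param object fitted `opls` model.
#' @param newdata numeric matrix, samples x variables (same columns as the
#'   training X).
#' @param ... unused.
#' @return numeric vector of predicted y values.
#' @export
predict.opls <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == length(object$w))
  Xs <- sweep(sweep(X, 2, object$x_means), 2, object$x_scales, "/")
  for (a in seq_len(ncol(object$W_o))) {
    t_o <- drop(Xs %*% object$W_o[, a])
    Xs <- Xs - tcrossprod(t_o, object$P_o[, a])
  }
  drop(Xs %*% object$w) * object$c + object$y_mean
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so folds are as balanced as the counts allow.
make_folds <- function(y, K) {
  n <- length(y)
  if (K < 2) stop("K must be >= 2")
  if (K > n) stop("K (", K, ") exceeds the number of samples (", n, ")")
  fold <- integer(n)
  for (cl in unique(as.character(y))) {
    idx <- sample(which(as.character(y) == cl))
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' K-fold cross-validation with class-stratified, seed-deterministic fold
#' assignment. `q2 = 1 - PRESS / SS` where PRESS sums squared errors of
#' held-out predictions and SS is the total sum of squares of the coded y
#' about its overall mean. K is capped at the number of samples.
#'
#' @param X numeric matrix, samples x variables.
#' @param y two-class labels.
#' @param K number of folds (default 7, the common chemometrics choice);
#'   silently capped at the number of samples, so small two-class designs
#'   fall back to leave-one-out.
#' @param n_ortho orthogonal components for each training fit.
#' @param seed integer seed for the fold assignment; `NULL` uses the current
#'   RNG stream.
#' @param center,scale. passed to the internal fits.
#' @return single numeric Q2 (<= 1; <= 0 means no predictive power).
#' @export
cross_validate <- function(X, y, K = 7, n_ortho = 0, seed = NULL,
                           center = TRUE, scale. = TRUE) {
  X <- as.matrix(X)
  cy <- code_y(y)
  n <- nrow(X)
  K <- min(K, n)
  fold <- if (is.null(seed)) make_folds(y, K) else
    with_seed(seed, make_folds(y, K))
  press <- 0
  for (k in sort(unique(fold))) {
    tr <- fold != k
    Xtr <- X[tr, , drop = FALSE]
    ytr <- cy$y[tr]
    x_means <- if (center) colMeans(Xtr) else rep(0, ncol(Xtr))
    sds <- col_sds(sweep(Xtr, 2, x_means))
    # variables constant within a training fold are neutral: scale 1 leaves
    # their centered column ~0, so they get (near) zero weight
    x_scales <- if (scale.) ifelse(sds > 0, sds, 1) else rep(1, ncol(Xtr))
    Xs <- sweep(sweep(Xtr, 2, x_means), 2, x_scales, "/")
    y_mean <- mean(ytr)
    core <- opls_core(Xs, ytr - y_mean, n_ortho)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, x_means), 2, x_scales, "/")
    for (a in seq_len(ncol(core$W_o))) {
      t_o <- drop(Xte %*% core$W_o[, a])
      Xte <- Xte - tcrossprod(t_o, core$P_o[, a])
    }
    pred <- drop(Xte %*% core$w) * core$c + y_mean
    press <- press + sum((cy$y[!tr] - pred)^2)
  }
  1 - press / sum((cy$y - mean(cy$y))^2)
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Scans `0..max_ortho` (capped so every training fold keeps enough rank) and
#' returns the smallest count maximizing the K-fold Q2.
#'
#' @inheritParams cross_validate
#' @param max_ortho largest candidate (default 5).
#' @return list with `n_ortho`, `q2`, and the per-candidate `q2_by_ortho`.
#' @export
select_n_ortho <- function(X, y, max_ortho = 5, K = 7, seed = 1,
                           center = TRUE, scale. = TRUE) {
  n <- nrow(X)
  K <- min(K, n)
  # smallest training-fold size bounds the usable rank
  n_train_min <- n - ceiling(n / K)
  cap <- max(0, min(max_ortho, n_train_min - 2))
  q2s <- vapply(0:cap, function(a) {
    tryCatch(
      cross_validate(X, y, K = K, n_ortho = a, seed = seed,
                     center = center, scale. = scale.),
      error = function(e) -Inf)
  }, numeric(1))
  best <- which.max(q2s) - 1L
  list(n_ortho = best, q2 = q2s[best + 1L],
       q2_by_ortho = stats::setNames(q2s, 0:cap))
}

#' Permutation test for an OPLS-DA model
#'
#' Class labels are permuted uniformly at random `n_perm` times; the model is
#' refitted and cross-validated for each permutation. P-values use the add-one
#' rule `p = (1 + #{perm >= observed}) / (1 + n_perm)`, so with the default
#' 199 permutations the smallest attainable p is 0.005.
#'
#' @inheritParams cross_validate
#' @param n_perm number of permutations (default 199).
#' @param seed integer seed controlling permutations and fold draws.
#' @return object of class `opls_perm`: list with `n_perm`, observed `r2y`
#'   and `q2`, permutation vectors `r2y_perm` / `q2_perm`, and p-values
#'   `p_r2y` / `p_q2`.
#' @export
permutation_test <- function(X, y, n_perm = 199, seed = 1, K = 7,
                             n_ortho = 0, center = TRUE, scale. = TRUE) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(X)
  obs_fit <- fit_opls(X, y, n_ortho = n_ortho, center = center, scale. = scale.)
  with_seed(seed, {
    q2_obs <- cross_validate(X, y, K = K, n_ortho = n_ortho, seed = NULL,
                             center = center, scale. = scale.)
    r2y_perm <- numeric(n_perm)
    q2_perm <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      yp <- sample(y)
      r2y_perm[i] <- fit_opls(X, yp, n_ortho = n_ortho, center = center,
                              scale. = scale.)$r2y
      q2_perm[i] <- cross_validate(X, yp, K = K, n_ortho = n_ortho,
                                   seed = NULL, center = center,
                                   scale. = scale.)
    }
    structure(list(
      n_perm = n_perm,
      r2y = obs_fit$r2y, q2 = q2_obs,
      r2y_perm = r2y_perm, q2_perm = q2_perm,
      p_r2y = (1 + sum(r2y_perm >= obs_fit$r2y)) / (1 + n_perm),
      p_q2 = (1 + sum(q2_perm >= q2_obs)) / (1 + n_perm)
    ), class = "opls_perm")
  })
}

#' @export
print.opls_perm <- function(x, ...) {
  cat(sprintf("OPLS-DA permutation test (%d permutations)\n", x$n_perm))
  cat(sprintf("  R2Y = %.4f  (p = %.4g)\n", x$r2y, x$p_r2y))
  cat(sprintf("  Q2  = %.4f  (p = %.4g)\n", x$q2, x$p_q2))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' For the single predictive component of a two-class model the general
#' SSY-weighted formula reduces to `VIP_j = sqrt(J) |w_j|` with `||w|| = 1`,
#' so the mean of squared VIPs is exactly 1. Variables with VIP > 1 are the
#' conventional screening hits.
#'
#' @param model fitted `opls` model.
#' @return named numeric vector of VIP scores (>= 0).
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "opls"))
  ssy <- sum((model$t * model$c)^2)
  if (ssy == 0) stop("model explains no Y variance; VIP undefined")
  v <- sqrt(length(model$w)) * abs(model$w / sqrt(sum(model$w^2)))
  names(v) <- names(model$vip)
  v
}

#' S-plot coordinates
#'
#' Per variable: covariance and Pearson correlation of the (scaled) variable
#' with the predictive score vector t. High |covariance| with high
#' |correlation| marks reliable discriminating variables; VIP > 1 rows are
#' flagged.
#'
#' @param model fitted `opls` model.
#' @param X the training matrix (samples x variables) the model was fitted on.
#' @return data.frame with `variable`, `cov`, `corr` (NA for zero-variance
#'   variables), `vip`, `selected`.
#' @export
s_plot <- function(model, X) {
  stopifnot(inherits(model, "opls"))
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(model$w))
  Xs <- sweep(sweep(X, 2, model$x_means), 2, model$x_scales, "/")
  n <- nrow(Xs)
  t_ <- model$t
  cv <- drop(crossprod(Xs, t_)) / (n - 1)
  sdx <- col_sds(Xs)
  corr <- ifelse(sdx > 0, cv / (stats::sd(t_) * sdx), NA_real_)
  vip <- compute_vip(model)
  data.frame(variable = colnames(X) %||% seq_len(ncol(X)),
             cov = cv, corr = corr, vip = vip,
             selected = vip > 1, row.names = NULL,
             stringsAsFactors = FALSE)
}
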