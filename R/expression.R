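# Expression-level operations: FPKM normalization, PCA contribution rates,
# pairwise differential expression with BH correction, and monotone trend
# classification across the ordered dose groups.

#' FPKM normalization
#'
#' `fpkm_gj = counts_gj / ((length_g / 1e3) * (total_j / 1e6))`, i.e. fragments
#' per kilobase of transcript per million assigned fragments.
#'
#' @param counts non-negative matrix, genes x samples.
#' @param lengths gene lengths in bp (> 0), aligned with rows of `counts`.
#' @return numeric matrix of FPKM values, same dimnames as `counts`.
#' @examples
#' compute_fpkm(matrix(c(100, 1999900), 2, dimnames = list(c("a", "b"), "s1")),
#'              c(2000, 1000))  # gene a -> 25
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), length(lengths) == nrow(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0] %||% which(totals == 0)
    stop("zero library size in sample(s): ", paste(bad, collapse = ", "))
  }
  fpkm <- counts / outer(as.numeric(lengths) / 1e3, totals / 1e6)
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Per-component PCA contribution rates
#'
#' Principal component analysis of samples over genes (centered, unscaled by
#' default); the contribution rate of component k is its eigenvalue divided by
#' the total variance, so rates sum to 1.
#'
#' @param expr numeric matrix, genes x samples (samples are the observations).
#' @param scale. logical, autoscale genes before PCA (default `FALSE`).
#' @return data.frame with `component`, `eigenvalue`, `contribution` (fraction
#'   of total variance) and `cumulative`.
#' @export
pca_summary <- function(expr, scale. = FALSE) {
  x <- t(expr)
  if (scale.) {
    sds <- col_sds(x)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  if (sum(ev) == 0) stop("matrix has zero total variance; PCA undefined")
  data.frame(
    component = seq_along(ev),
    eigenvalue = ev,
    contribution = ev / sum(ev),
    cumulative = cumsum(ev) / sum(ev)
  )
}

# --- moderated t machinery -------------------------------------------------

# Inverse of the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf); converges in a handful of steps).
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# Empirical-Bayes variance shrinkage: given per-gene sample variances s2 on
# d degrees of freedom, estimate the scaled inverse chi-square prior (d0,
# s0^2) by matching moments of log(s2) and return the posterior variances
# (d0*s0^2 + d*s2)/(d0 + d). Genes with s2 == 0 borrow the prior entirely.
squeeze_var <- function(s2, d) {
  stopifnot(d >= 1)
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("need >= 2 genes with positive variance")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  rhs <- stats::var(e) - trigamma(d / 2)
  if (rhs <= 0) {
    d0 <- Inf
    s02 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * ifelse(ok, s2, 0)) / (d0 + d)
  list(var_post = post, df_prior = d0, var_prior = s02)
}

#' Pairwise differential expression between two dose groups
#'
#' Log2 fold changes are computed on group-mean FPKM with a pseudo-count:
#' `log2((mean_B + eps) / (mean_A + eps))`. P-values come from a two-sample
#' t-test on `log2(FPKM + 1)`; the default `"moderated"` method shrinks
#' per-gene variances toward an empirical-Bayes prior (pooled two-group
#' variance, scaled inverse chi-square prior fitted by moment matching on
#' log variances) and tests on `d0 + d` degrees of freedom, which restores
#' power at the 3-replicate design depth; `"welch"` gives the plain
#' unequal-variance t-test. P-values are Benjamini-Hochberg adjusted within
#' the comparison, and a gene is called up/down iff `q < q_threshold` and
#' `|log2fc| >= fc_threshold`.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param design design data.frame.
#' @param group_a,group_b group labels (A is the reference; fold changes are
#'   B over A).
#' @param fc_threshold minimum |log2 fold change| for a call (default 1).
#' @param q_threshold BH-adjusted p cutoff for a call (default 0.05).
#' @param method `"moderated"` (default) or `"welch"`.
#' @param eps pseudo-count for fold changes (default 1).
#' @return data.frame with `gene`, `mean_a`, `mean_b`, `log2fc`, `p`, `q`,
#'   `call` (`"up"`, `"down"`, `"none"`); attributes `comparison`, `method`,
#'   `df_prior`.
#' @export
differential_expression <- function(expr, design, group_a, group_b,
                                    fc_threshold = 1, q_threshold = 0.05,
                                    method = c("moderated", "welch"),
                                    eps = 1) {
  method <- match.arg(method)
  design <- validate_design(design)
  stopifnot(all(c(group_a, group_b) %in% group_levels(design)))
  sa <- samples_of(design, group_a)
  sb <- samples_of(design, group_b)
  if (length(sa) < 2 || length(sb) < 2) {
    stop("both groups need >= 2 replicates (variance undefined otherwise)")
  }
  stopifnot(all(c(sa, sb) %in% colnames(expr)))
  stop_if_not_scalar_prob(q_threshold, "q_threshold")

  A <- expr[, sa, drop = FALSE]
  B <- expr[, sb, drop = FALSE]
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  log2fc <- log2((mean_b + eps) / (mean_a + eps))

  la <- log2(A + 1)
  lb <- log2(B + 1)
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  ssa <- rowSums((la - ma)^2)
  ssb <- rowSums((lb - mb)^2)
  delta <- mb - ma

  if (method == "moderated") {
    d <- na + nb - 2
    s2 <- (ssa + ssb) / d
    if (sum(s2 > 0) < 2L) {
      # degenerate matrix (e.g. replicated columns): no prior can be fitted
      p <- ifelse(delta == 0, 1, 0)
      df_prior <- NA_real_
    } else {
      sq <- squeeze_var(s2, d)
      se <- sqrt(sq$var_post * (1 / na + 1 / nb))
      tt <- delta / se
      p <- 2 * stats::pt(-abs(tt), df = sq$df_prior + d)
      df_prior <- sq$df_prior
    }
  } else {
    va <- ssa / (na - 1)
    vb <- ssb / (nb - 1)
    se2 <- va / na + vb / nb
    tt <- delta / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- ifelse(se2 == 0, ifelse(delta == 0, 1, 0),
                2 * stats::pt(-abs(tt), df = df))
    df_prior <- NA_real_
  }
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  call <- ifelse(q < q_threshold & abs(log2fc) >= fc_threshold,
                 ifelse(log2fc > 0, "up", "down"), "none")
  out <- data.frame(gene = rownames(expr), mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, p = p, q = q, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "comparison") <- paste0(group_b, "_vs_", group_a)
  attr(out, "method") <- method
  attr(out, "df_prior") <- df_prior
  out
}

#' Classify monotone expression trends across three ordered dose groups
#'
#' A gene trends `"up"` iff its FPKM group means strictly increase
#' (mean M1 < mean M2 < mean M3) *and* it is significantly called in both
#' adjacent pairwise comparisons (M2 vs M1 and M3 vs M2); `"down"` is
#' mirrored; everything else (including ties) is `"none"`.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param design design with exactly 3 ordered groups.
#' @param de_12 differential expression table for group 2 vs group 1.
#' @param de_23 differential expression table for group 3 vs group 2.
#' @return data.frame with `gene`, the three group means, and
#'   `trend` (`"up"`, `"down"`, `"none"`).
#' @export
classify_trend <- function(expr, design, de_12, de_23) {
  design <- validate_design(design)
  lv <- group_levels(design)
  if (length(lv) != 3) stop("trend classification needs exactly 3 ordered groups")
  stopifnot(identical(de_12$gene, rownames(expr)),
            identical(de_23$gene, rownames(expr)))
  gm <- vapply(lv, function(g) rowMeans(expr[, samples_of(design, g),
                                             drop = FALSE]),
               numeric(nrow(expr)))
  sig_both <- de_12$call != "none" & de_23$call != "none"
  inc <- gm[, 1] < gm[, 2] & gm[, 2] < gm[, 3]
  dec <- gm[, 1] > gm[, 2] & gm[, 2] > gm[, 3]
  trend <- ifelse(inc & sig_both, "up", ifelse(dec & sig_both, "down", "none"))
  out <- data.frame(gene = rownames(expr), gm, trend = trend,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:4] <- paste0("mean_", lv)
  out
}
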