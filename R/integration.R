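# Integration of physiochemical indexes with pathway expression: redundancy
# analysis (constrained ordination), a thresholded Pearson correlation
# network, and entropy-weighted TOPSIS ranking.

#' Redundancy analysis of a response matrix on explanatory variables
#'
#' Both matrices are column-centered and (by default) unit-variance scaled
#' before the constrained ordination, since physiochemical indexes carry
#' heterogeneous units (SPAD, relative fluorescence, mg/g). The ordination
#' itself is delegated to [vegan::rda()]; constrained eigenvalues come from
#' the least-squares fit of the response on the explanatory variables,
#' unconstrained eigenvalues from the residuals, and the constrained fraction
#' is their share of the total response variance.
#'
#' @param response numeric matrix, samples x response variables.
#' @param explanatory numeric matrix, samples x explanatory variables; needs
#'   fewer columns than there are samples and full column rank.
#' @param scale. autoscale columns (default `TRUE`).
#' @return object of class `rda_result`: list with `constrained_eig`,
#'   `unconstrained_eig` (each sorted descending), `constrained_fraction`,
#'   `site_scores`, `response_scores`, `biplot_scores`, and the underlying
#'   vegan `ordination` object.
#' @export
rda_analysis <- function(response, explanatory, scale. = TRUE) {
  Y <- as.matrix(response)
  X <- as.matrix(explanatory)
  if (nrow(Y) != nrow(X)) stop("response and explanatory must be row-aligned")
  if (nrow(X) <= ncol(X)) {
    stop("need more samples (", nrow(X), ") than explanatory variables (",
         ncol(X), ")")
  }
  scale_cols <- function(m, what) {
    sds <- col_sds(m)
    if (any(sds == 0)) {
      stop("zero-variance ", what, " column(s): ",
           paste(colnames(m)[sds == 0] %||% which(sds == 0), collapse = ", "))
    }
    scale(m, center = TRUE, scale = scale.)
  }
  Ys <- scale_cols(Y, "response")
  Xs <- scale_cols(X, "explanatory")
  qx <- qr(scale(X, center = TRUE, scale = FALSE))
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]] %||%
      qx$pivot[-seq_len(qx$rank)]
    stop("explanatory matrix is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  ord <- vegan::rda(Ys, Xs)
  ce <- sort(as.numeric(ord$CCA$eig), decreasing = TRUE)
  ue <- sort(as.numeric(ord$CA$eig), decreasing = TRUE)
  sc <- tryCatch(
    vegan::scores(ord, display = c("sites", "species", "bp"),
                  choices = seq_len(max(1, length(ce))), scaling = 2),
    error = function(e) NULL)
  structure(list(
    constrained_eig = ce,
    unconstrained_eig = ue,
    constrained_fraction = sum(ce) / (sum(ce) + sum(ue)),
    site_scores = sc$sites,
    response_scores = sc$species,
    biplot_scores = sc$biplot,
    ordination = ord
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("Redundancy analysis\n")
  cat(sprintf("  constrained axes: %d (%.1f%% of response variance)\n",
              length(x$constrained_eig), 100 * x$constrained_fraction))
  invisible(x)
}

#' Thresholded Pearson correlation network
#'
#' Tests every pair of variables; edges with `|r| >= r_threshold` and
#' `p < p_threshold` are retained with their correlation sign. Two-sided
#' p-values come from the t transform of r on n - 2 degrees of freedom.
#'
#' @param x numeric matrix, samples x variables (named columns), e.g. Mg
#'   level, physio indexes and pathway totals side by side.
#' @param r_threshold minimum |r| (default 0.8).
#' @param p_threshold maximum p (default 0.05).
#' @param adjust BH-adjust p-values across all tested pairs before
#'   thresholding (default `FALSE`).
#' @return data.frame edge list: `source`, `target`, `r`, `p`, `sign`
#'   (`"positive"`/`"negative"`).
#' @export
correlation_network <- function(x, r_threshold = 0.8, p_threshold = 0.05,
                                adjust = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need >= 3 samples for correlation tests")
  sds <- col_sds(x)
  if (any(sds == 0)) {
    warning("skipping zero-variance variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p_vars <- ncol(x)
  if (p_vars < 2) {
    return(data.frame(source = character(), target = character(),
                      r = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(p_vars, 2)
  cm <- stats::cor(x)
  r <- cm[t(pairs)]
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  edges <- data.frame(
    source = colnames(x)[pairs[1, ]],
    target = colnames(x)[pairs[2, ]],
    r = r, p = p,
    sign = ifelse(r >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  edges[abs(edges$r) >= r_threshold & edges$p < p_threshold, , drop = FALSE]
}

#' Entropy weights for a decision matrix
#'
#' Objective criterion weights: columns are min-shifted to be non-negative
#' and normalized to proportions `p_ij`; the information entropy
#' `e_j = -(1/ln m) sum_i p_ij ln p_ij` (with `0 ln 0 := 0`) measures how
#' undispersed a criterion is, and `weight_j = (1 - e_j) / sum_k (1 - e_k)`.
#' A criterion constant across alternatives gets entropy 1 and weight 0.
#'
#' @param decision numeric matrix, alternatives x criteria (>= 2
#'   alternatives).
#' @return named numeric weight vector (>= 0, sums to 1).
#' @export
entropy_weights <- function(decision) {
  d <- as.matrix(decision)
  m <- nrow(d)
  if (m < 2) stop("need >= 2 alternatives")
  shift <- pmin(apply(d, 2, min), 0)
  d <- sweep(d, 2, shift)
  e <- apply(d, 2, function(col) {
    s <- sum(col)
    if (s == 0 || stats::sd(col) == 0) return(1)  # uninformative criterion
    p <- col / s
    p <- p[p > 0]
    -sum(p * log(p)) / log(m)
  })
  div <- 1 - e
  if (sum(div) <= 0) {
    stop("all criteria are constant; entropy weights undefined")
  }
  w <- div / sum(div)
  names(w) <- colnames(decision)
  w
}

#' TOPSIS ranking of alternatives
#'
#' Technique for Order Preference by Similarity to Ideal Solution: columns
#' are vector-normalized (divided by their Euclidean norm), weighted, and
#' each alternative's Euclidean distances to the ideal point (per-criterion
#' best respecting polarity) and anti-ideal point are converted into the
#' relative closeness `d_minus / (d_plus + d_minus)` in [0, 1]; alternatives
#' are ranked by descending closeness.
#'
#' @param decision numeric matrix, alternatives x criteria.
#' @param weights criterion weights (non-negative, summing to 1); default
#'   [entropy_weights()] of the decision matrix.
#' @param polarity per-criterion `"benefit"` (larger is better) or `"cost"`;
#'   a single value is recycled. Default all benefit.
#' @return object of class `topsis_result`: list with `weights`, `d_plus`,
#'   `d_minus`, `closeness`, `ranking` (1 = best), and the weighted
#'   normalized `matrix`.
#' @export
topsis <- function(decision, weights = NULL,
                   polarity = rep("benefit", ncol(decision))) {
  d <- as.matrix(decision)
  m <- nrow(d)
  if (m < 2) stop("need >= 2 alternatives")
  polarity <- rep_len(match.arg(polarity, c("benefit", "cost"),
                                several.ok = TRUE), ncol(d))
  if (is.null(weights)) weights <- entropy_weights(d)
  stopifnot(length(weights) == ncol(d), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  norms <- sqrt(colSums(d^2))
  if (any(norms == 0)) {
    stop("zero-norm criterion column(s): ",
         paste(colnames(d)[norms == 0] %||% which(norms == 0), collapse = ", "))
  }
  V <- sweep(sweep(d, 2, norms, "/"), 2, weights, "*")
  ideal <- ifelse(polarity == "benefit", apply(V, 2, max), apply(V, 2, min))
  anti <- ifelse(polarity == "benefit", apply(V, 2, min), apply(V, 2, max))
  d_plus <- sqrt(rowSums(sweep(V, 2, ideal)^2))
  d_minus <- sqrt(rowSums(sweep(V, 2, anti)^2))
  closeness <- ifelse(d_plus + d_minus == 0, 0.5,
                      d_minus / (d_plus + d_minus))
  names(closeness) <- rownames(d)
  structure(list(
    weights = weights,
    d_plus = d_plus, d_minus = d_minus,
    closeness = closeness,
    ranking = rank(-closeness, ties.method = "min"),
    ideal = ideal, anti_ideal = anti,
    matrix = V
  ), class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("Entropy-weighted TOPSIS\n")
  ord <- order(x$ranking)
  lab <- names(x$closeness) %||% seq_along(x$closeness)
  for (i in utils::head(ord, 5)) {
    cat(sprintf("  %s: closeness %.3f (rank %d)\n", lab[i], x$closeness[i],
                x$ranking[i]))
  }
  invisible(x)
}
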