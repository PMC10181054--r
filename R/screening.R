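# Key-gene and characteristic-gene screening: intersect the VIP > 1 hits of
# the two adjacent-dose OPLS-DA models with the monotone trend table, then
# reduce to the shortest expression-ranked prefix covering >= 90% of the key
# genes' total expression (the "bubble map" filter).

#' Select key genes from two OPLS-DA models and the trend table
#'
#' A gene is a key gene iff its VIP exceeds `vip_threshold` in *both* pairwise
#' models (M2 vs M1 and M3 vs M2) and its trend is not `"none"`. Key genes are
#' partitioned into up/down by the trend direction.
#'
#' @param vip_12,vip_23 named per-gene VIP vectors from the two models (same
#'   gene universe; genes absent from a model, e.g. removed as zero-variance,
#'   may carry `NA` and never pass).
#' @param trends trend table from [classify_trend()].
#' @param vip_threshold VIP cutoff (> 0, default 1).
#' @return object of class `screen_keys`: list with `key_12`, `key_23`
#'   (per-model hits), `key_common`, `key_up`, `key_down`, and the assembled
#'   per-gene `table`.
#' @export
select_key_genes <- function(vip_12, vip_23, trends, vip_threshold = 1) {
  stopifnot(vip_threshold > 0)
  if (!setequal(names(vip_12), names(vip_23)) ||
      !setequal(names(vip_12), trends$gene)) {
    stop("vip_12, vip_23 and trends must cover the same gene universe")
  }
  genes <- trends$gene
  v1 <- vip_12[genes]
  v2 <- vip_23[genes]
  trend <- trends$trend
  hit1 <- !is.na(v1) & v1 > vip_threshold
  hit2 <- !is.na(v2) & v2 > vip_threshold
  common <- hit1 & hit2 & trend != "none"
  tab <- data.frame(gene = genes, vip_12 = unname(v1), vip_23 = unname(v2),
                    trend = trend, key = common, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(
    key_12 = genes[hit1],
    key_23 = genes[hit2],
    key_common = genes[common],
    key_up = genes[common & trend == "up"],
    key_down = genes[common & trend == "down"],
    vip_threshold = vip_threshold,
    table = tab
  ), class = "screen_keys")
}

#' @export
print.screen_keys <- function(x, ...) {
  cat(sprintf("Key-gene screen (VIP > %g in both models, monotone trend)\n",
              x$vip_threshold))
  cat(sprintf("  per-model hits: %d / %d; common key genes: %d (%d up, %d down)\n",
              length(x$key_12), length(x$key_23), length(x$key_common),
              length(x$key_up), length(x$key_down)))
  invisible(x)
}

#' Select characteristic genes by cumulative expression coverage
#'
#' Key genes are ranked by their total FPKM over all samples (descending,
#' ties broken by gene id); the characteristic set is the shortest prefix
#' whose summed expression reaches `coverage_threshold` of the key genes'
#' total expression.
#'
#' @param key_genes character vector of key genes (non-empty).
#' @param expr FPKM matrix, genes x samples, covering `key_genes`.
#' @param coverage_threshold required cumulative fraction in (0, 1]
#'   (default 0.9).
#' @return object of class `screen_characteristic`: list with `genes` (the
#'   ordered characteristic prefix), `coverage` (achieved fraction), and
#'   `table` (per key gene: total expression, cumulative coverage, selected).
#' @export
select_characteristic_genes <- function(key_genes, expr,
                                        coverage_threshold = 0.9) {
  stop_if_not_scalar_prob(coverage_threshold, "coverage_threshold",
                          open_zero = TRUE)
  if (length(key_genes) == 0) stop("key gene set is empty")
  stopifnot(all(key_genes %in% rownames(expr)))
  totals <- rowSums(expr[key_genes, , drop = FALSE])
  if (sum(totals) == 0) stop("key genes have all-zero expression")
  ord <- order(-totals, key_genes)
  totals <- totals[ord]
  cum <- cumsum(totals) / sum(totals)
  n_sel <- which(cum >= coverage_threshold)[1]
  tab <- data.frame(gene = key_genes[ord], total_fpkm = unname(totals),
                    cum_coverage = cum,
                    characteristic = seq_along(cum) <= n_sel,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    genes = tab$gene[seq_len(n_sel)],
    coverage = unname(cum[n_sel]),
    coverage_threshold = coverage_threshold,
    table = tab
  ), class = "screen_characteristic")
}

#' @export
print.screen_characteristic <- function(x, ...) {
  cat(sprintf(
    "Characteristic genes: %d of %d key genes cover %.1f%% of expression (threshold %.0f%%)\n",
    length(x$genes), nrow(x$table), 100 * x$coverage,
    100 * x$coverage_threshold))
  invisible(x)
}
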