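# Synthetic-data generators. These emulate the statistical structure the
# downstream cascade assumes: a 3-dose x 3-replicate negative-binomial count
# matrix with planted monotone genes, GMT annotations with planted enriched
# terms, and physiochemical indexes with monotone dose-group structure.

#' Build a sample design table
#'
#' The design encodes the ordered treatment levels of the hydroponic Mg dose
#' series (by default M1 < M2 < M3 for 0, 0.4 and 0.8 mmol/L Mg) with a fixed
#' number of biological replicates per level.
#'
#' @param n_reps replicates per group (>= 2).
#' @param groups ordered character vector of group labels, lowest dose first.
#' @return data.frame with columns `sample`, `group` (ordered factor),
#'   `replicate`.
#' @examples
#' make_design(3)
#' @export
make_design <- function(n_reps = 3, groups = c("M1", "M2", "M3")) {
  stopifnot(n_reps >= 2, length(groups) >= 2, !anyDuplicated(groups))
  df <- data.frame(
    sample = paste0(rep(groups, each = n_reps), "_r", seq_len(n_reps)),
    group = factor(rep(groups, each = n_reps), levels = groups, ordered = TRUE),
    replicate = rep(seq_len(n_reps), length(groups)),
    stringsAsFactors = FALSE
  )
  validate_design(df)
}

#' @keywords internal
validate_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("sample", "group", "replicate") %in% names(design)))
  if (anyDuplicated(design$sample)) stop("duplicated sample ids in design")
  if (!is.ordered(design$group)) {
    design$group <- factor(design$group, levels = unique(design$group),
                           ordered = TRUE)
  }
  tab <- table(design$group)
  if (any(tab < 2)) {
    stop("every group needs >= 2 samples; offending group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  design
}

group_levels <- function(design) levels(design$group)

samples_of <- function(design, group) design$sample[design$group == group]

#' Simulate a negative-binomial count table with planted monotone genes
#'
#' Counts are drawn as NB(mean mu, dispersion phi) with `Var = mu + phi mu^2`
#' (`phi = 0` collapses to Poisson). Planted "up" genes have their log2 mean
#' increased by `effect_log2fc` per ordered group step; planted "down" genes
#' mirrored. Per-gene base means are log-normal(log 100, 1) unless supplied,
#' and gene lengths are uniform integers on 500..5000 bp so FPKM
#' normalization is non-trivial.
#'
#' @param design design data.frame from [make_design()].
#' @param n_genes total number of genes.
#' @param n_up,n_down numbers of planted monotone up / down genes
#'   (`n_up + n_down <= n_genes`).
#' @param effect_log2fc log2 fold change per group step for planted genes
#'   (>= 0).
#' @param dispersion NB dispersion phi (>= 0; 0 = Poisson).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param base_means optional per-gene expected base counts (length 1 or
#'   `n_genes`); default draws log-normal(log 100, 1).
#' @return list of class `sim_counts`:
#'   * `counts`: integer matrix genes x samples,
#'   * `lengths`: named gene lengths (bp),
#'   * `mu`: the expected-count matrix the draws came from,
#'   * `truth`: list with `planted_up`, `planted_down`, `effect_log2fc`,
#'     `dispersion`, `base_mean` (the `SimTruth` ground-truth labels).
#' @examples
#' d <- make_design(3)
#' sim <- generate_counts(d, n_genes = 100, n_up = 10, n_down = 10,
#'                        effect_log2fc = 2, dispersion = 0.1, seed = 1)
#' dim(sim$counts)
#' @export
generate_counts <- function(design, n_genes, n_up, n_down, effect_log2fc,
                            dispersion, seed, base_means = NULL) {
  design <- validate_design(design)
  stopifnot(n_genes >= 1)
  if (n_up + n_down > n_genes) stop("n_up + n_down must be <= n_genes")
  if (effect_log2fc < 0) stop("effect_log2fc must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")

  genes <- sprintf("g%05d", seq_len(n_genes))
  n_samp <- nrow(design)
  level <- as.integer(design$group) - 1L  # 0-based ordered dose level

  with_seed(seed, {
    base <- if (is.null(base_means)) {
      stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    } else rep_len(as.numeric(base_means), n_genes)
    lengths <- sample(500:5000, n_genes, replace = TRUE)
    planted <- sample(genes, n_up + n_down)
    up <- planted[seq_len(n_up)]
    down <- setdiff(planted, up)

    sign_g <- stats::setNames(numeric(n_genes), genes)
    sign_g[up] <- 1
    sign_g[down] <- -1
    # log2 mu_gj = log2 base_g + sign_g * effect * level_j
    mu <- outer(base, rep(1, n_samp)) *
      2^(outer(sign_g, level) * effect_log2fc)
    counts <- if (dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = n_genes)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_genes)
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genes, design$sample)
    dimnames(mu) <- dimnames(counts)

    structure(list(
      counts = counts,
      lengths = stats::setNames(lengths, genes),
      mu = mu,
      truth = list(planted_up = up, planted_down = down,
                   effect_log2fc = effect_log2fc, dispersion = dispersion,
                   base_mean = stats::setNames(base, genes))
    ), class = "sim_counts")
  })
}

#' Simulate a GMT annotation with planted enriched terms
#'
#' Builds `n_terms` gene sets over `genes`. Up to four of them are "planted":
#' they draw a fraction `enrich_frac` of their members from the planted up /
#' down genes recorded in `truth` (two terms per available direction) and the
#' remainder uniformly from the other genes; all other terms sample uniformly
#' from the whole universe. Planted terms are the ground truth for enrichment
#' recovery checks.
#'
#' @param genes character vector: the gene universe.
#' @param truth `truth` element of a [generate_counts()] result (or a list
#'   with `planted_up` / `planted_down`).
#' @param n_terms number of terms (>= 0).
#' @param term_size members per term (<= `length(genes)`).
#' @param enrich_frac fraction of a planted term drawn from planted genes,
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @return named list of gene vectors (GMT-serializable via [write_gmt()])
#'   with attributes `description` and `planted_terms` (named character:
#'   term -> "up"/"down").
#' @export
generate_annotation <- function(genes, truth, n_terms, term_size, enrich_frac,
                                seed) {
  stopifnot(n_terms >= 0, term_size >= 1)
  if (term_size > length(genes)) stop("term_size must be <= number of genes")
  if (enrich_frac < 0 || enrich_frac > 1) stop("enrich_frac must be in [0, 1]")

  terms <- sprintf("PW%04d", seq_len(n_terms))
  planted_pool <- list(up = intersect(truth$planted_up, genes),
                       down = intersect(truth$planted_down, genes))
  dirs <- rep(c("up", "down"), 2)
  dirs <- dirs[vapply(dirs, function(d) length(planted_pool[[d]]) > 0, TRUE)]
  n_planted <- min(length(dirs), n_terms)

  with_seed(seed, {
    sets <- vector("list", n_terms)
    planted_terms <- character(0)
    for (i in seq_len(n_terms)) {
      if (i <= n_planted) {
        dir <- dirs[i]
        pool <- planted_pool[[dir]]
        k_in <- min(round(enrich_frac * term_size), length(pool))
        inside <- sample(pool, k_in)
        outside <- sample(setdiff(genes, inside), term_size - k_in)
        sets[[i]] <- sort(c(inside, outside))
        planted_terms[terms[i]] <- dir
      } else {
        sets[[i]] <- sort(sample(genes, term_size))
      }
    }
    names(sets) <- terms
    attr(sets, "description") <- stats::setNames(
      ifelse(terms %in% names(planted_terms),
             "synthetic planted pathway", "synthetic background pathway"),
      terms)
    attr(sets, "planted_terms") <- planted_terms
    sets
  })
}

# Default physiochemical group-mean profiles over 3 ordered Mg levels.
# Units: chlorophyll in SPAD; F0/Fm in relative fluorescence; Fv/Fm and Y(II)
# dimensionless; contents in mg/g dry weight. Photosynthetic indexes,
# theanine and soluble sugar rise with dose; polyphenol, flavone and caffeine
# fall.
physio_profiles <- function(n_groups = 3) {
  prof <- list(
    "chlorophyll"    = c(45, 52, 60),
    "F0"             = c(300, 330, 365),
    "Fm"             = c(1200, 1400, 1600),
    "Fv/Fm"          = c(0.72, 0.77, 0.81),
    "Y(II)"          = c(0.55, 0.62, 0.70),
    "theanine"       = c(14, 17, 21),
    "soluble sugar"  = c(38, 45, 53),
    "tea polyphenol" = c(210, 185, 160),
    "flavone"        = c(12, 10, 8),
    "caffeine"       = c(36, 32, 28)
  )
  if (n_groups != 3) {
    prof <- lapply(prof, function(v) {
      stats::approx(seq_along(v), v, n = n_groups)$y
    })
  }
  prof
}

physio_polarity <- c(
  "chlorophyll" = "benefit", "F0" = "benefit", "Fm" = "benefit",
  "Fv/Fm" = "benefit", "Y(II)" = "benefit", "theanine" = "benefit",
  "soluble sugar" = "benefit", "tea polyphenol" = "cost",
  "flavone" = "cost", "caffeine" = "cost"
)

#' Simulate a physiochemical index table with monotone dose structure
#'
#' Photosynthetic indexes (chlorophyll, F0, Fm, Fv/Fm, Y(II)) plus theanine
#' and soluble sugar have strictly increasing group means across the ordered
#' Mg levels; tea polyphenol, flavone and caffeine strictly decrease.
#' Replicate values get multiplicative Gaussian noise with coefficient of
#' variation `cv`.
#'
#' @param design design data.frame.
#' @param seed integer seed.
#' @param cv per-replicate coefficient of variation (default 0.05).
#' @return numeric matrix indexes x samples with a `polarity` attribute
#'   (named character, `"benefit"` for indexes that rise with dose, `"cost"`
#'   for those that fall) and a `profiles` attribute with the noise-free
#'   group means.
#' @export
generate_physio <- function(design, seed, cv = 0.05) {
  design <- validate_design(design)
  stopifnot(cv >= 0)
  prof <- physio_profiles(nlevels(design$group))
  level <- as.integer(design$group)
  with_seed(seed, {
    m <- t(vapply(prof, function(v) v[level], numeric(nrow(design))))
    noise <- matrix(stats::rnorm(length(m), mean = 1, sd = cv), nrow(m))
    m <- m * noise
    dimnames(m) <- list(names(prof), design$sample)
    attr(m, "polarity") <- physio_polarity[rownames(m)]
    attr(m, "profiles") <- prof
    m
  })
}
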