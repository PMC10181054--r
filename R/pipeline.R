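# End-to-end orchestration: simulate (or load) -> FPKM -> DE/trend -> two
# adjacent-dose OPLS-DA models -> key/characteristic screening -> enrichment
# -> physio integration, from a single validated config, with deterministic
# seeding and a machine-readable run report.

#' Default pipeline configuration
#'
#' Returns the full nested config with every documented default: simulation
#' parameters mirror the hydroponic study design (3 ordered Mg levels x 3
#' replicates) with 3000 genes, 150 planted up + 150 planted down at
#' log2FC 2 per dose step and NB dispersion 0.1; thresholds are q < 0.05,
#' |log2FC| >= 1, VIP > 1, 90% cumulative coverage, enrichment q < 0.05 and
#' network |r| >= 0.8, p < 0.05; OPLS settings are 7-fold CV (capped at n),
#' 199 permutations, up to 5 orthogonal components.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "mgscreen_run",
    input = list(counts = NULL, design = NULL, gmt = NULL, physio = NULL),
    sim = list(n_genes = 3000L, n_up = 150L, n_down = 150L,
               effect_log2fc = 2, dispersion = 0.1, n_reps = 3L,
               n_terms = 20L, term_size = 40L, enrich_frac = 0.8,
               physio_cv = 0.05),
    thresholds = list(q = 0.05, fc = 1, vip = 1, coverage = 0.9,
                      enrich_q = 0.05, r = 0.8, cor_p = 0.05),
    opls = list(folds = 7L, n_perm = 199L, max_ortho = 5L),
    de_method = "moderated",
    integration = list(
      explanatory_indexes = c("tea polyphenol", "theanine", "caffeine",
                              "flavone", "soluble sugar"))
  )
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    c(path, k))
    } else {
      defaults[k] <- user[k]  # keeps explicit NULLs
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys, and checks every
#' threshold domain. Normalization is idempotent:
#' `validate_config(validate_config(x))` equals `validate_config(x)`.
#'
#' @param config partial config (named list); missing entries get defaults.
#' @return the normalized config.
#' @examples
#' cfg <- validate_config(list(sim = list(n_genes = 500)))
#' cfg$sim$n_genes
#' @export
validate_config <- function(config = list()) {
  cfg <- merge_config(default_config(), as.list(config))
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  simulate <- is.null(cfg$input$counts)
  chk(!simulate || (is.numeric(cfg$seed) && length(cfg$seed) == 1),
      "seed: mandatory single integer when simulating")
  with(cfg$sim, {
    chk(n_genes >= 1, "sim.n_genes >= 1")
    chk(n_up >= 0 && n_down >= 0 && n_up + n_down <= n_genes,
        "sim.n_up + sim.n_down must be <= sim.n_genes")
    chk(effect_log2fc >= 0, "sim.effect_log2fc >= 0")
    chk(dispersion >= 0, "sim.dispersion >= 0")
    chk(n_reps >= 2, "sim.n_reps >= 2")
    chk(enrich_frac >= 0 && enrich_frac <= 1, "sim.enrich_frac in [0, 1]")
    chk(physio_cv >= 0, "sim.physio_cv >= 0")
  })
  with(cfg$thresholds, {
    chk(q > 0 && q <= 1, "thresholds.q in (0, 1]")
    chk(fc >= 0, "thresholds.fc >= 0")
    chk(vip > 0, "thresholds.vip > 0")
    chk(coverage > 0 && coverage <= 1, "thresholds.coverage in (0, 1]")
    chk(enrich_q > 0 && enrich_q <= 1, "thresholds.enrich_q in (0, 1]")
    chk(r >= 0 && r <= 1, "thresholds.r in [0, 1]")
    chk(cor_p > 0 && cor_p <= 1, "thresholds.cor_p in (0, 1]")
  })
  with(cfg$opls, {
    chk(folds >= 2, "opls.folds >= 2")
    chk(n_perm >= 1, "opls.n_perm >= 1")
    chk(max_ortho >= 0, "opls.max_ortho >= 0")
  })
  chk(cfg$de_method %in% c("moderated", "welch"),
      "de_method must be 'moderated' or 'welch'")
  if (length(errs)) {
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  cfg
}

#' Read a pipeline configuration file
#'
#' Config files are YAML with the same nesting as [default_config()];
#' unknown keys are rejected and defaults filled in.
#'
#' @param path YAML file path.
#' @return normalized config list.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full screening cascade
#'
#' Executes simulate/load -> FPKM -> PCA -> pairwise DE -> trend -> two
#' OPLS-DA models (orthogonal-component selection, Q2, permutation test,
#' VIP, S-plot) -> key/characteristic gene screening -> hypergeometric
#' enrichment and pathway profiling -> RDA / correlation network / TOPSIS
#' integration. Every stage writes plain TSV artifacts under
#' `config$out_dir`; the funnel summary lands in `report.json`. A rerun with
#' the same config and seed reproduces byte-identical tables. A failing
#' stage leaves a `FAILED` marker naming the stage and rethrows.
#'
#' @param config pipeline config (validated via [validate_config()]).
#' @param quiet suppress progress messages (default `FALSE`).
#' @return object of class `mg_run`: list with `report` (the run report) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  cat("", file = logfile)
  say <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = logfile, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %s: done (%.1fs)", name, proc.time()[["elapsed"]] - t0)
    res
  }
  seed <- as.integer(cfg$seed)
  report <- list(config = cfg)
  simulate <- is.null(cfg$input$counts)

  dat <- stage("input", {
    if (simulate) {
      design <- make_design(cfg$sim$n_reps)
      sim <- generate_counts(design, cfg$sim$n_genes, cfg$sim$n_up,
                             cfg$sim$n_down, cfg$sim$effect_log2fc,
                             cfg$sim$dispersion, seed = seed)
      ann <- generate_annotation(rownames(sim$counts), sim$truth,
                                 cfg$sim$n_terms, cfg$sim$term_size,
                                 cfg$sim$enrich_frac,
                                 seed = derive_seed(seed, 1))
      physio <- generate_physio(design, seed = derive_seed(seed, 2),
                                cv = cfg$sim$physio_cv)
      write_counts(sim$counts, sim$lengths, file.path(out, "counts.tsv"))
      write_design(design, file.path(out, "design.tsv"))
      write_gmt(ann, file.path(out, "annotation.gmt"))
      write_physio(physio, file.path(out, "physio.tsv"))
      jsonlite::write_json(
        list(seed = seed, sim = cfg$sim,
             truth = list(planted_up = sim$truth$planted_up,
                          planted_down = sim$truth$planted_down,
                          planted_terms = as.list(attr(ann, "planted_terms")))),
        file.path(out, "simulation.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      list(counts = sim$counts, lengths = sim$lengths, design = design,
           annotation = ann, physio = physio, truth = sim$truth)
    } else {
      ct <- read_counts(cfg$input$counts)
      design <- read_design(cfg$input$design)
      ann <- if (!is.null(cfg$input$gmt)) read_gmt(cfg$input$gmt) else NULL
      physio <- if (!is.null(cfg$input$physio)) read_physio(cfg$input$physio)
      list(counts = ct$counts, lengths = ct$lengths, design = design,
           annotation = ann, physio = physio, truth = NULL)
    }
  })
  design <- dat$design
  lv <- group_levels(design)
  if (length(lv) != 3) stop("the cascade expects exactly 3 ordered groups")
  report$n_genes <- nrow(dat$counts)
  report$n_samples <- ncol(dat$counts)

  fpkm <- stage("normalize", {
    f <- compute_fpkm(dat$counts, dat$lengths)
    write_expression(f, file.path(out, "fpkm.tsv"))
    pca <- pca_summary(log2(f + 1))
    write_tsv_(pca, file.path(out, "pca.tsv"))
    report$pca_contribution_pc1 <- pca$contribution[1]
    report$pca_contribution_pc2 <- pca$contribution[2]
    f
  })

  de <- stage("de", {
    de12 <- differential_expression(fpkm, design, lv[1], lv[2],
                                    fc_threshold = cfg$thresholds$fc,
                                    q_threshold = cfg$thresholds$q,
                                    method = cfg$de_method)
    de23 <- differential_expression(fpkm, design, lv[2], lv[3],
                                    fc_threshold = cfg$thresholds$fc,
                                    q_threshold = cfg$thresholds$q,
                                    method = cfg$de_method)
    write_tsv_(de12, file.path(out, sprintf("de_%s_vs_%s.tsv", lv[2], lv[1])))
    write_tsv_(de23, file.path(out, sprintf("de_%s_vs_%s.tsv", lv[3], lv[2])))
    report$de <- list()
    for (d in list(de12, de23)) {
      report$de[[attr(d, "comparison")]] <- list(
        up = sum(d$call == "up"), down = sum(d$call == "down"))
    }
    list(de12 = de12, de23 = de23)
  })

  trends <- stage("trend", {
    tr <- classify_trend(fpkm, design, de$de12, de$de23)
    write_tsv_(tr, file.path(out, "trend.tsv"))
    report$trend <- list(up = sum(tr$trend == "up"),
                          down = sum(tr$trend == "down"))
    tr
  })

  opls <- stage("opls", {
    lf <- log2(fpkm + 1)
    fit_one <- function(ga, gb, tag, k) {
      samp <- c(samples_of(design, ga), samples_of(design, gb))
      X <- t(lf[, samp, drop = FALSE])
      y <- as.character(design$group[match(samp, design$sample)])
      keep <- col_sds(X) > 0
      Xk <- X[, keep, drop = FALSE]
      sel <- select_n_ortho(Xk, y, max_ortho = cfg$opls$max_ortho,
                            K = cfg$opls$folds,
                            seed = derive_seed(seed, 10 + k))
      fit <- fit_opls(Xk, y, n_ortho = sel$n_ortho)
      perm <- permutation_test(Xk, y, n_perm = cfg$opls$n_perm,
                               seed = derive_seed(seed, 20 + k),
                               K = cfg$opls$folds, n_ortho = sel$n_ortho)
      vip <- stats::setNames(rep(NA_real_, nrow(lf)), rownames(lf))
      vip[colnames(Xk)] <- compute_vip(fit)
      sp <- s_plot(fit, Xk)
      write_tsv_(data.frame(sample = samp, t = fit$t,
                            stringsAsFactors = FALSE),
                 file.path(out, sprintf("opls_scores_%s.tsv", tag)))
      write_tsv_(data.frame(gene = names(vip), vip = unname(vip),
                            stringsAsFactors = FALSE),
                 file.path(out, sprintf("opls_vip_%s.tsv", tag)))
      write_tsv_(sp, file.path(out, sprintf("opls_splot_%s.tsv", tag)))
      write_tsv_(data.frame(r2y_perm = perm$r2y_perm, q2_perm = perm$q2_perm),
                 file.path(out, sprintf("opls_perm_%s.tsv", tag)))
      list(fit = fit, perm = perm, vip = vip,
           summary = list(comparison = tag, n_ortho = sel$n_ortho,
                          r2y = fit$r2y, q2 = perm$q2,
                          p_r2y = perm$p_r2y, p_q2 = perm$p_q2,
                          n_vip_gt_threshold =
                            sum(vip > cfg$thresholds$vip, na.rm = TRUE)))
    }
    m12 <- fit_one(lv[1], lv[2], paste0(lv[2], "_vs_", lv[1]), 1)
    m23 <- fit_one(lv[2], lv[3], paste0(lv[3], "_vs_", lv[2]), 2)
    report$opls <- list(m12$summary, m23$summary)
    jsonlite::write_json(report$opls, file.path(out, "opls_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(m12 = m12, m23 = m23)
  })

  screen <- stage("screen", {
    keys <- select_key_genes(opls$m12$vip, opls$m23$vip, trends,
                             vip_threshold = cfg$thresholds$vip)
    if (length(keys$key_common) > 0) {
      chars <- select_characteristic_genes(keys$key_common, fpkm,
                                           cfg$thresholds$coverage)
      char_genes <- chars$genes
      coverage <- chars$coverage
      merged <- merge(keys$table,
                      chars$table[c("gene", "cum_coverage", "characteristic")],
                      by = "gene", all.x = TRUE, sort = TRUE)
      merged$characteristic[is.na(merged$characteristic)] <- FALSE
    } else {
      char_genes <- character(0)
      coverage <- NA_real_
      merged <- keys$table
      merged$cum_coverage <- NA_real_
      merged$characteristic <- FALSE
    }
    write_tsv_(merged, file.path(out, "screening.tsv"))
    report$screen <- list(
      key_12 = length(keys$key_12), key_23 = length(keys$key_23),
      key_common = length(keys$key_common),
      key_up = length(keys$key_up), key_down = length(keys$key_down),
      characteristic = length(char_genes), coverage = coverage)
    list(keys = keys, characteristic = char_genes)
  })

  enrich <- stage("enrich", {
    if (is.null(dat$annotation)) {
      report$enrichment <- list(n_terms_tested = 0, n_significant = 0)
      list(table = NULL, profile = NULL, sig_terms = character(0))
    } else {
      et <- hypergeometric_enrichment(screen$characteristic,
                                      rownames(dat$counts), dat$annotation,
                                      q_threshold = cfg$thresholds$enrich_q)
      write_tsv_(et, file.path(out, "enrichment.tsv"))
      sig <- et$term[et$significant]
      prof_terms <- if (length(sig) > 0) sig else names(dat$annotation)
      prof <- pathway_expression_profile(dat$annotation, prof_terms, fpkm,
                                         design)
      write_tsv_(prof$groups, file.path(out, "pathway_profile_groups.tsv"))
      write_tsv_(prof$terms, file.path(out, "pathway_profile_trends.tsv"))
      report$enrichment <- list(
        n_terms_tested = nrow(et), n_significant = length(sig),
        pathway_trends = as.list(table(prof$terms$trend)))
      list(table = et, profile = prof, sig_terms = sig)
    }
  })

  stage("integrate", if (is.null(dat$physio)) {
    report$integration <- list(skipped = "no physio table")
  } else {
    physio <- dat$physio
    pol <- attr(physio, "polarity") %||%
      stats::setNames(rep("benefit", nrow(physio)), rownames(physio))
    mg <- (as.integer(design$group) - 1) *
      (if (length(lv) == 3) 0.4 else 1)
    vars <- cbind(`Mg level` = mg, t(physio[, design$sample, drop = FALSE]))
    pathway_totals <- enrich$profile$sample_totals
    if (!is.null(pathway_totals) && nrow(pathway_totals) > 0) {
      vars <- cbind(vars, t(pathway_totals[, design$sample, drop = FALSE]))
    }
    edges <- correlation_network(vars, r_threshold = cfg$thresholds$r,
                                 p_threshold = cfg$thresholds$cor_p)
    write_tsv_(edges, file.path(out, "network_edges.tsv"))

    rda_frac <- NA_real_
    if (!is.null(pathway_totals) && nrow(pathway_totals) > 1) {
      expl_idx <- intersect(cfg$integration$explanatory_indexes,
                            rownames(physio))
      if (length(expl_idx) >= 1 && nrow(design) > length(expl_idx)) {
        rda <- rda_analysis(t(pathway_totals[, design$sample, drop = FALSE]),
                            t(physio[expl_idx, design$sample, drop = FALSE]))
        rda_frac <- rda$constrained_fraction
        write_tsv_(data.frame(
          axis = c(paste0("RDA", seq_along(rda$constrained_eig)),
                   paste0("PC", seq_along(rda$unconstrained_eig))),
          eigenvalue = c(rda$constrained_eig, rda$unconstrained_eig)),
          file.path(out, "rda_eigenvalues.tsv"))
        if (!is.null(rda$site_scores)) {
          write_tsv_(as.data.frame(rda$site_scores),
                     file.path(out, "rda_site_scores.tsv"), row_names = TRUE)
        }
      }
    }

    run_topsis <- function(idx, tag, polarity) {
      dm <- t(physio[idx, design$sample, drop = FALSE])
      tp <- topsis(dm, polarity = polarity)
      write_tsv_(data.frame(criterion = idx, weight = unname(tp$weights)),
                 file.path(out, sprintf("topsis_weights_%s.tsv", tag)))
      tp
    }
    photo <- intersect(c("chlorophyll", "F0", "Fm", "Fv/Fm", "Y(II)"),
                       rownames(physio))
    quality <- intersect(c("tea polyphenol", "theanine", "caffeine",
                           "flavone", "soluble sugar"), rownames(physio))
    tops <- list()
    if (length(photo) >= 2) {
      tops$photosynthetic <- run_topsis(photo, "photosynthetic", pol[photo])
    }
    if (length(quality) >= 2) {
      tops$quality <- run_topsis(quality, "quality", pol[quality])
    }
    if (!is.null(pathway_totals) && nrow(pathway_totals) >= 2) {
      dm <- t(pathway_totals[, design$sample, drop = FALSE])
      tops$pathways <- topsis(dm)
      write_tsv_(data.frame(criterion = rownames(pathway_totals),
                            weight = unname(tops$pathways$weights)),
                 file.path(out, "topsis_weights_pathways.tsv"))
    }
    report$integration <- list(
      n_edges = nrow(edges),
      rda_constrained_fraction = rda_frac,
      topsis_top = lapply(tops, function(tp)
        names(tp$weights)[which.max(tp$weights)]))
    invisible(NULL)
  })

  report$notes <- paste(
    "Differential expression uses the package-internal empirical-Bayes",
    "moderated t-test on log2(FPKM + 1) rather than DESeq2/edgeR;",
    "thresholds and seeds are echoed under $config.")
  stage("report", {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  say("pipeline complete: %s", out)
  structure(list(report = report, out_dir = out), class = "mg_run")
}

#' @export
print.mg_run <- function(x, ...) {
  r <- x$report
  cat("mgscreen pipeline run:", x$out_dir, "\n")
  cat(sprintf("  genes %d, samples %d\n", r$n_genes, r$n_samples))
  if (!is.null(r$trend)) {
    cat(sprintf("  trend: %d up / %d down\n", r$trend$up, r$trend$down))
  }
  if (!is.null(r$screen)) {
    cat(sprintf("  key genes: %d (%d up, %d down); characteristic: %d\n",
                r$screen$key_common, r$screen$key_up, r$screen$key_down,
                r$screen$characteristic))
  }
  if (!is.null(r$enrichment)) {
    cat(sprintf("  significant terms: %d\n", r$enrichment$n_significant))
  }
  invisible(x)
}
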