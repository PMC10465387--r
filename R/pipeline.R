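#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()] for synthetic mode) or `paths`
#' (named list with `expression`, `clinical`, and optionally `mutations`,
#' `gene_sets`, plus `unit` for the expression file) must be supplied.
#' The global `seed` is fanned out to one derived seed per stochastic stage,
#' so any stage is reproducible in isolation.
#'
#' @param sim optional [sim_config()].
#' @param paths optional named list of input files.
#' @param outdir output directory (created if missing).
#' @param seed global integer seed.
#' @param k_range,reps,p_item,consensus_threshold consensus-clustering knobs.
#' @param force_k optional manual override of the chosen cluster number.
#' @param ssgsea_alpha rank-weight exponent for enrichment scores.
#' @param deg_alpha adjusted-p cutoff for the DEG overlap rule.
#' @param cox_p raw-p cutoff for the prognostic gene screen.
#' @param cut_method score dichotomisation, `"median"` or `"logrank_opt"`.
#' @param tmb_classes optional variant-class filter for TMB.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, outdir = tempfile("run"),
                            seed = 1L, k_range = 2:9, reps = 100,
                            p_item = 0.8, consensus_threshold = 0.10,
                            force_k = NULL, ssgsea_alpha = 0.25,
                            deg_alpha = 0.001, cox_p = 0.05,
                            cut_method = "median", tmb_classes = NULL) {
  if (is.null(sim) == is.null(paths))
    stop("exactly one of `sim` (synthetic mode) or `paths` must be given")
  if (!is.null(paths)) {
    need <- c("expression", "clinical")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("paths missing: ", paste(miss, collapse = ", "))
    missing_files <- !vapply(unlist(paths[setdiff(names(paths), "unit")]),
                             file.exists, logical(1))
    if (any(missing_files)) stop("input file(s) not found")
  }
  structure(list(sim = sim, paths = paths, outdir = outdir,
                 seed = as.integer(seed), k_range = k_range, reps = reps,
                 p_item = p_item, consensus_threshold = consensus_threshold,
                 force_k = force_k, ssgsea_alpha = ssgsea_alpha,
                 deg_alpha = deg_alpha, cox_p = cox_p,
                 cut_method = cut_method, tmb_classes = tmb_classes),
            class = "pipeline_config")
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 131 * h) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Stage order: input (simulate or load) -> TPM conversion -> log2 ->
#' regulator consensus clusters -> immune ssGSEA -> pairwise moderated DE +
#' overlap -> univariate Cox prognostic screen -> gene-cluster consensus ->
#' PCA modification score + high/low groups -> score-stratified downstream
#' analyses. Every stage's outputs are written under `outdir` and recorded
#' in a manifest (file digests, timing, warnings); a failing stage aborts
#' after writing the manifest accumulated so far.
#'
#' @param config a [pipeline_config()].
#' @return list with `results` (per-stage R objects) and `manifest`
#'   (data.frame).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()

  record <- function(stage, params, files, warnings = character()) {
    digests <- if (length(files))
      paste(sprintf("%s:%s", basename(files),
                    unname(tools::md5sum(files))), collapse = ";")
    else ""
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage,
      parameters = params,
      outputs = paste(basename(files), collapse = ";"),
      md5 = digests,
      warnings = paste(warnings, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- function(...) file.path(config$outdir, sprintf(...))
  finish_manifest <- function() {
    mf <- do.call(rbind, manifest)
    utils::write.table(mf, file.path(config$outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mf
  }
  run_stage <- function(stage, expr) {
    ws <- character()
    val <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        finish_manifest()
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        ws <<- c(ws, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(value = val, warnings = ws)
  }

  ## --- input ---------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    st <- run_stage("input", {
      cohort <- generate_cohort(sim)
      mutations <- generate_mutations(sim, cohort$truth)
      immune_sets <- generate_immune_sets(
        rownames(cohort$expression), n_sets = 10, set_size = 25,
        seed = stage_seed(config$seed, "immune_sets"))
      list(cohort = cohort, mutations = mutations,
           immune_sets = immune_sets, unit = "TPM")
    })
    files <- c(out("expression.tsv"), out("clinical.tsv"),
               out("mutations.tsv"), out("immune_sets.gmt"),
               out("regulator_catalog.tsv"))
    write_expression(st$value$cohort$expression, files[1])
    write_clinical(st$value$cohort$clinical, files[2])
    write_mutations(st$value$mutations, files[3])
    write_gmt(st$value$immune_sets, files[4])
    utils::write.table(st$value$cohort$catalog, files[5], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("input", sprintf("mode=synthetic;seed=%d;n=%d", sim$seed,
                            sim$n_samples), files, st$warnings)
  } else {
    st <- run_stage("input", {
      unit <- if (is.null(config$paths$unit)) "TPM" else config$paths$unit
      expr <- read_expression(config$paths$expression, unit)
      clinical <- read_clinical(config$paths$clinical)
      mutations <- if (!is.null(config$paths$mutations))
        read_mutations(config$paths$mutations) else NULL
      immune_sets <- if (!is.null(config$paths$gene_sets))
        read_gmt(config$paths$gene_sets) else NULL
      list(cohort = list(expression = expr, clinical = clinical,
                         catalog = regulator_catalog(), truth = NULL),
           mutations = mutations, immune_sets = immune_sets, unit = unit)
    })
    record("input", sprintf("mode=files;unit=%s", st$value$unit),
           character(), st$warnings)
  }
  input <- st$value
  results$input <- input
  clinical <- input$cohort$clinical

  ## --- unit conversion + log2 ---------------------------------------
  st <- run_stage("normalise", {
    e <- input$cohort$expression
    if (expr_unit(e) == "FPKM") e <- fpkm_to_tpm(e)
    log2_transform(e)
  })
  log2e <- st$value
  record("normalise", sprintf("from=%s;pseudocount=1", input$unit),
         character(), st$warnings)
  results$log2 <- log2e

  ## --- regulator consensus clusters ---------------------------------
  st <- run_stage("regulator_clusters", {
    regs <- intersect(input$cohort$catalog$gene, rownames(log2e))
    if (length(regs) < 2) stop("regulator panel absent from expression")
    cp <- consensus_params(k_range = config$k_range, reps = config$reps,
                           p_item = config$p_item,
                           seed = stage_seed(config$seed, "regulator_clusters"))
    consensus_cluster(log2e[regs, ], cp,
                      threshold = config$consensus_threshold,
                      force_k = config$force_k)
  })
  regrun <- st$value
  f <- out("regulator_clusters.tsv")
  utils::write.table(
    data.frame(sample_id = names(regrun$chosen_labels),
               cluster = regrun$chosen_labels),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  record("regulator_clusters",
         sprintf("k_range=%s;reps=%d;p_item=%g;threshold=%g;chosen_k=%d",
                 paste(range(config$k_range), collapse = "-"), config$reps,
                 config$p_item, config$consensus_threshold, regrun$chosen_k),
         f, st$warnings)
  results$regulator_clusters <- regrun

  ## --- immune ssGSEA -------------------------------------------------
  if (!is.null(input$immune_sets)) {
    st <- run_stage("immune_ssgsea", {
      enr <- ssgsea_scores(log2e, input$immune_sets,
                           alpha = config$ssgsea_alpha)
      minmax_normalize(enr)
    })
    enr <- st$value
    f <- out("immune_ssgsea.tsv")
    utils::write.table(data.frame(set = rownames(enr$scores), enr$scores,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    record("immune_ssgsea", sprintf("alpha=%g;normalized=TRUE",
                                    config$ssgsea_alpha), f, st$warnings)
    results$immune_ssgsea <- enr
  }

  ## --- pairwise DE + overlap -----------------------------------------
  st <- run_stage("diffexpr", {
    de <- pairwise_contrasts(log2e, regrun$chosen_labels,
                             alpha = config$deg_alpha)
    list(contrasts = de, degs = overlap_degs(de, alpha = config$deg_alpha))
  })
  de <- st$value
  files <- c(vapply(names(de$contrasts), function(nm) {
    f <- out("de_%s.tsv", nm)
    utils::write.table(de$contrasts[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }, character(1)), out("overlap_degs.txt"))
  writeLines(de$degs, files[length(files)])
  record("diffexpr", sprintf("alpha=%g;n_overlap=%d", config$deg_alpha,
                             length(de$degs)), files, st$warnings)
  results$diffexpr <- de

  ## --- prognostic Cox screen -----------------------------------------
  st <- run_stage("prognostic_filter", {
    if (!length(de$degs)) stop("no overlap DEGs to screen")
    prognostic_filter(log2e, clinical, de$degs, p_threshold = config$cox_p)
  })
  prog <- st$value
  f <- out("prognostic_cox.tsv")
  utils::write.table(prog$table, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("prognostic_filter", sprintf("p_threshold=%g;n_prognostic=%d",
                                      config$cox_p, length(prog$genes)),
         f, st$warnings)
  results$prognostic <- prog

  ## --- gene-cluster consensus ----------------------------------------
  st <- run_stage("gene_clusters", {
    if (length(prog$genes) < 2) stop("fewer than 2 prognostic genes")
    cp <- consensus_params(k_range = config$k_range, reps = config$reps,
                           p_item = config$p_item,
                           seed = stage_seed(config$seed, "gene_clusters"))
    consensus_cluster(log2e[prog$genes, ], cp,
                      threshold = config$consensus_threshold)
  })
  generun <- st$value
  f <- out("gene_clusters.tsv")
  utils::write.table(
    data.frame(sample_id = names(generun$chosen_labels),
               gene_cluster = generun$chosen_labels),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  record("gene_clusters", sprintf("chosen_k=%d", generun$chosen_k), f,
         st$warnings)
  results$gene_clusters <- generun

  ## --- modification score --------------------------------------------
  st <- run_stage("modscore", {
    compute_score(log2e, prog$genes, clinical,
                  cut_method = config$cut_method)
  })
  score <- st$value
  f <- out("modscore.tsv")
  utils::write.table(
    data.frame(sample_id = names(score$score), pc1 = score$pc1,
               pc2 = score$pc2, score = score$score, group = score$group),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  record("modscore", sprintf("cut_method=%s;cutpoint=%.6g;explained=%.4f",
                             score$cut_method, score$cutpoint,
                             sum(score$explained)), f, st$warnings)
  results$score <- score

  ## --- downstream -----------------------------------------------------
  st <- run_stage("downstream", {
    ds <- list()
    grp <- score$group[clinical$sample_id]
    ds$score_km <- list(
      logrank = logrank_test(clinical$os_time, clinical$os_event, grp),
      curves = lapply(split(seq_along(grp), grp), function(ii)
        km_estimate(clinical$os_time[ii], clinical$os_event[ii])))
    if (!is.null(input$mutations) && nrow(input$mutations)) {
      ds$tmb <- compute_tmb(input$mutations, clinical$sample_id,
                            class_filter = config$tmb_classes)
      ds$mutation_summary <- mutation_summary(input$mutations, grp)
      tmbg <- stats::setNames(ds$tmb$tmb_group, ds$tmb$sample_id)
      ds$tmb_vs_score_km <- stratified_km(clinical, grp, tmbg)
      ds$tmb_by_group <- compare_groups(ds$tmb$tmb,
                                        grp[ds$tmb$sample_id],
                                        name = "tmb")
    }
    comp <- list()
    for (col in grep("^ips_", colnames(clinical), value = TRUE))
      comp[[col]] <- compare_groups(clinical[[col]], grp, name = col)
    if ("msi" %in% colnames(clinical)) {
      comp$score_by_msi <- compare_groups(score$score[clinical$sample_id],
                                          clinical$msi,
                                          name = "score_by_msi")
      comp$msi_by_group <- compare_groups(clinical$msi, grp,
                                          name = "msi_by_group")
    }
    comp$score_by_vital <- compare_groups(
      score$score[clinical$sample_id],
      factor(ifelse(clinical$os_event == 1, "dead", "alive")),
      name = "score_by_vital_status")
    ds$comparisons <- do.call(rbind, comp)
    if (!is.null(results$immune_ssgsea))
      ds$immune_correlation <- score_immune_correlation(
        score$score, results$immune_ssgsea)
    if (!is.null(input$immune_sets) && length(de$degs))
      ds$ora <- ora_hypergeometric(de$degs, input$immune_sets,
                                   rownames(log2e))
    ds
  })
  ds <- st$value
  files <- character()
  if (!is.null(ds$comparisons)) {
    files <- c(files, out("group_comparisons.tsv"))
    utils::write.table(ds$comparisons, files[length(files)], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ds$tmb)) {
    files <- c(files, out("tmb.tsv"))
    utils::write.table(ds$tmb, files[length(files)], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ds$immune_correlation)) {
    files <- c(files, out("immune_correlation.tsv"))
    utils::write.table(ds$immune_correlation, files[length(files)],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  record("downstream",
         sprintf("score_logrank_p=%.4g", ds$score_km$logrank$p),
         files, st$warnings)
  results$downstream <- ds

  manifest_df <- finish_manifest()
  list(results = results, manifest = manifest_df)
}

#' Validate a frozen score model on an external cohort
#'
#' Projects the new cohort through [apply_score()], dichotomises the
#' projected scores with the frozen cutpoint policy (recomputed on the new
#' cohort's score distribution) and reports the high-vs-low Kaplan-Meier
#' curves with a log-rank test.
#'
#' @param model a fitted `mod_score`.
#' @param x validation [expression_matrix()] (LOG2 scale).
#' @param clinical validation clinical table.
#' @return list (score, group, cutpoint, logrank, curves).
#' @export
validate_external <- function(model, x, clinical) {
  proj <- apply_score(model, x)
  cl <- clinical[match(colnames(x), clinical$sample_id), ]
  if (any(is.na(cl$sample_id))) stop("validation samples missing clinical rows")
  grp <- assign_groups(proj$score, cl, method = model$cut_method)
  lr <- logrank_test(cl$os_time, cl$os_event, grp$group)
  curves <- lapply(split(seq_along(grp$group), grp$group), function(ii)
    km_estimate(cl$os_time[ii], cl$os_event[ii]))
  list(score = proj$score, group = grp$group, cutpoint = grp$cutpoint,
       logrank = lr, curves = curves, genes_used = proj$genes_used)
}
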