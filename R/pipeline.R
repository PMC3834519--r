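#' Run the full relapse-signature pipeline
#'
#' End-to-end orchestration: per-type Welch prefilter, SVM-RFE panel
#' selection with Monte-Carlo CV, leave-one-out validation with bootstrap
#' ROC intervals, CIN matrix construction from segments, deleterious /
#' relapse-exclusive variant filtering with gene-level burden testing,
#' panel combination, random-forest artificial-contrast ranking, tiered
#' selection, Kendall association network, and coordinate mapping. Every
#' stage writes its outputs under `out_dir` and the consolidated report is
#' rendered as JSON and text. A fixed config seed makes the whole run
#' reproducible byte for byte (wall-clock timings are logged separately).
#'
#' @param inputs A [synthetic_spec()], a `cohort_bundle`, or a directory
#'   containing files written by [write_bundle()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory for stage artifacts.
#' @param gene_sets Optional named list of gene sets for pathway-level
#'   variant aggregation (see [read_gene_sets()]).
#' @return A `run_report` list (also serialized to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(inputs, cfg = pipeline_config(),
                         out_dir = tempfile("relapsig_run_"),
                         gene_sets = NULL) {
  t_start <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s seed=%d] %s", stage, cfg$seed, sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  bundle <- resolve_inputs(inputs)
  labels <- bundle$labels
  stage_fail <- function(stage, e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))

  matrices <- bundle$matrices
  if (cfg$normalize_metabolomics)
    for (ty in intersect(names(matrices),
                         c("serum_pos", "serum_neg", "urine_pos",
                           "urine_neg")))
      matrices[[ty]] <- normalize_chain(matrices[[ty]])
  if (!is.null(bundle$segments) && !is.null(bundle$cytobands)) {
    matrices$cin_cytoband <- tryCatch(
      cin_matrix(bundle$segments, bundle$cytobands, cfg$cin_gain,
                 cfg$cin_loss, level = "cytoband",
                 channel = cfg$cin_channel),
      error = function(e) stage_fail("cin", e))
    write_matrix(matrices$cin_cytoband,
                 file.path(out_dir, "cin_cytoband.tsv"))
    logf("cin", "CIN matrix: %d bands x %d samples (%s channel)",
         nrow(matrices$cin_cytoband$values),
         ncol(matrices$cin_cytoband$values), cfg$cin_channel)
  }

  per_type <- list()
  panels <- list()
  for (ty in names(matrices)) {
    fm <- impute_missing(matrices[[ty]])
    alpha <- prefilter_alpha_for(cfg, ty)
    wt <- tryCatch(welch_test(fm, labels),
                   error = function(e) stage_fail(paste0("prefilter/", ty), e))
    prefilter_table(wt, alpha,
                    path = file.path(out_dir, paste0("prefilter_", ty, ".tsv")))
    pass <- filter_significant(wt, alpha, cfg$adjust_bh)
    logf("prefilter", "%s: %d of %d features pass alpha=%g", ty,
         length(pass), nrow(fm$values), alpha)
    if (length(pass) < 1) {
      per_type[[ty]] <- list(n_features = nrow(fm$values),
                             n_prefilter = 0L, panel = character(0),
                             selected_k = 0L, cv_accuracy = NA_real_,
                             loo_accuracy = NA_real_, auc = NA_real_,
                             ci = c(low = NA_real_, high = NA_real_))
      next
    }
    sub <- fm_subset(fm, pass)
    res <- tryCatch(rfe(sub, labels, cfg, seed = derive_seed(cfg$seed,
                                                             type_offset(ty))),
                    error = function(e) stage_fail(paste0("rfe/", ty), e))
    utils::write.table(res$accuracy_curve,
                       file.path(out_dir, paste0("rfe_curve_", ty, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$selected_panel,
               file.path(out_dir, paste0("panel_", ty, ".txt")))
    writeLines(res$elimination_order,
               file.path(out_dir, paste0("elimination_", ty, ".txt")))
    loo <- loo_validate(fm_subset(fm, res$selected_panel), labels,
                        cost = cfg$svm_cost)
    roc <- roc_with_ci(loo$scores, labels, reps = cfg$boot_reps,
                       level = cfg$ci_level,
                       seed = derive_seed(cfg$seed, type_offset(ty) + 100L))
    utils::write.table(roc$points,
                       file.path(out_dir, paste0("roc_", ty, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("rfe", "%s: panel of %d, LOO accuracy %.3f, AUC %.3f", ty,
         res$selected_k, loo$accuracy, roc$auc)
    panels[[ty]] <- res$selected_panel
    per_type[[ty]] <- list(n_features = nrow(fm$values),
                           n_prefilter = length(pass),
                           panel = res$selected_panel,
                           selected_k = res$selected_k,
                           cv_accuracy = max(res$accuracy_curve$mean),
                           loo_accuracy = loo$accuracy, auc = roc$auc,
                           ci = roc$ci)
    matrices[[ty]] <- fm
  }

  variant_summary <- NULL
  if (!is.null(bundle$variants)) {
    vt <- bundle$variants
    deleterious <- tryCatch(filter_deleterious(vt),
                            error = function(e) stage_fail("variants", e))
    exclusive <- relapse_exclusive(deleterious, labels)
    write_vcf(exclusive, file.path(out_dir, "variants_filtered.vcf"))
    burden <- gene_burden(deleterious, labels, cfg$af_cutoff)
    utils::write.table(burden, file.path(out_dir, "burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sets <- NULL
    if (!is.null(gene_sets)) {
      sets <- set_aggregate(exclusive, labels, gene_sets,
                            background = unique(vt$variants$gene))
      utils::write.table(sets, file.path(out_dir, "set_aggregation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    variant_summary <- list(
      n_variants = nrow(vt$variants),
      n_deleterious = nrow(deleterious$variants),
      n_relapse_exclusive = nrow(exclusive$variants),
      n_burden_significant = sum(burden$p <= 0.05),
      top_burden = utils::head(burden, 10), sets = sets)
    logf("variants", "%d variants -> %d deleterious -> %d relapse-exclusive",
         nrow(vt$variants), nrow(deleterious$variants),
         nrow(exclusive$variants))
  }

  integration <- NULL
  if (length(panels) >= 2) {
    combined <- combine_panels(panels, matrices)
    write_matrix(combined, file.path(out_dir, "combined.tsv"))
    ranked <- tryCatch(
      ace_rank(combined, labels, forests = cfg$rface_forests,
               trees = cfg$rface_trees, quantile = cfg$rface_quantile,
               seed = derive_seed(cfg$seed, 900L)),
      error = function(e) stage_fail("integrate", e))
    utils::write.table(ranked, file.path(out_dir, "ranked_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tiers <- select_top(ranked, cfg$p_select, cfg$p_top)
    edges <- NULL
    if (nrow(tiers$selected) >= 2)
      edges <- kendall_network(fm_subset(combined, tiers$selected$feature),
                               cfg$alpha_edge)
    if (!is.null(edges))
      utils::write.table(edges, file.path(out_dir, "edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    coords <- map_coordinates(ranked, annotation = bundle$annotation,
                              bands = bundle$cytobands)
    utils::write.table(coords, file.path(out_dir, "coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    integration <- list(n_combined = nrow(combined$values),
                        n_selected = nrow(tiers$selected),
                        n_top = nrow(tiers$top),
                        composition = tiers$composition,
                        n_edges = if (is.null(edges)) 0L else nrow(edges))
    logf("integrate", "%d combined -> %d selected (p<=%g) -> %d top (p<=%g); %d edges",
         integration$n_combined, integration$n_selected, cfg$p_select,
         integration$n_top, cfg$p_top, integration$n_edges)
  }

  report <- structure(list(
    seed = cfg$seed, config = unclass(cfg),
    n_samples = length(labels),
    n_relapse = sum(labels == RELAPSE),
    per_type = per_type, variant_summary = variant_summary,
    integration = integration), class = "run_report")
  jsonlite::write_json(report_for_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  wall <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  logf("done", "wall clock %.1f s", wall)
  report$wall_clock <- wall
  report$out_dir <- out_dir
  report
}

type_offset <- function(ty) {
  10L * match(ty, c(DATA_TYPES, "cin_cytoband"))[1]
}

resolve_inputs <- function(inputs) {
  if (inherits(inputs, "synthetic_spec")) return(generate_cohort(inputs))
  if (inherits(inputs, "cohort_bundle")) return(inputs)
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs))
    return(read_bundle(inputs))
  stopf("inputs must be a synthetic_spec, a cohort_bundle, or a directory")
}

report_for_json <- function(report) {
  r <- unclass(report)
  r$per_type <- lapply(r$per_type, function(x) {
    x$ci <- as.list(x$ci); x
  })
  if (!is.null(r$variant_summary))
    r$variant_summary$top_burden <- NULL
  r
}

format_report <- function(report) {
  lines <- c(sprintf("relapse-signature pipeline report (seed %d)",
                     report$seed),
             sprintf("samples: %d (%d relapse / %d relapse-free)",
                     report$n_samples, report$n_relapse,
                     report$n_samples - report$n_relapse), "")
  for (ty in names(report$per_type)) {
    s <- report$per_type[[ty]]
    lines <- c(lines, sprintf(
      "%-14s %5d features | %4d prefilter | panel %3d | LOO %.3f | AUC %.3f (%.3f-%.3f)",
      ty, s$n_features, s$n_prefilter, s$selected_k,
      s$loo_accuracy, s$auc, s$ci[["low"]], s$ci[["high"]]))
  }
  if (!is.null(report$variant_summary)) {
    v <- report$variant_summary
    lines <- c(lines, "", sprintf(
      "variants: %d total, %d deleterious, %d relapse-exclusive, %d genes with burden p<=0.05",
      v$n_variants, v$n_deleterious, v$n_relapse_exclusive,
      v$n_burden_significant))
  }
  if (!is.null(report$integration)) {
    i <- report$integration
    comp <- paste(sprintf("%s=%d", i$composition$Var1, i$composition$n),
                  collapse = ", ")
    lines <- c(lines, "", sprintf(
      "integration: %d combined -> %d selected -> %d top; edges %d (%s)",
      i$n_combined, i$n_selected, i$n_top, i$n_edges, comp))
  }
  lines
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Cohort demographic summary
#'
#' Tabulates every categorical clinical characteristic as counts and
#' percentages (one decimal, denominator = cohort size), with a stage
#' roll-up combining stage II and IIA.
#'
#' @param labels Named label vector defining the cohort.
#' @param clinical A data.frame (or TSV path) whose first column is the
#'   sample id and remaining columns are categorical characteristics.
#' @return Named list of data.frames (`level`, `count`, `pct`), one per
#'   characteristic, plus `stage_combined` when a stage column is
#'   present.
#' @export
cohort_summary <- function(labels, clinical) {
  if (is.character(clinical) && length(clinical) == 1)
    clinical <- utils::read.delim(clinical, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  samples <- clinical[[1]]
  unknown <- setdiff(samples, names(labels))
  if (length(unknown) > 0)
    stopf("unknown sample(s) in clinical file: %s",
          paste(unknown, collapse = ", "))
  n <- length(labels)
  out <- list()
  for (col in names(clinical)[-1]) {
    x <- clinical[[col]]
    lev <- if (is.factor(x)) levels(x) else unique(as.character(x))
    counts <- table(factor(as.character(x), levels = lev))
    out[[col]] <- data.frame(level = names(counts),
                             count = as.integer(counts),
                             pct = round(100 * as.integer(counts) / n, 1),
                             stringsAsFactors = FALSE)
  }
  stage_col <- grep("stage", names(clinical), ignore.case = TRUE, value = TRUE)
  if (length(stage_col) == 1) {
    x <- as.character(clinical[[stage_col]])
    grp <- sub("^(II)[A-C]$", "\\1", x)
    counts <- table(factor(grp, levels = unique(grp)))
    out$stage_combined <- data.frame(level = names(counts),
                                     count = as.integer(counts),
                                     pct = round(100 * as.integer(counts) / n, 1),
                                     stringsAsFactors = FALSE)
  }
  out
}
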