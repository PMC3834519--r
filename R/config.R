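#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default. All
#' stages read their knobs from this object so a run is fully described by
#' one config plus one seed.
#'
#' @param alpha_prefilter Per-feature Welch-test significance threshold
#'   (raw p, no multiplicity correction by default).
#' @param alpha_per_type Optional named list overriding `alpha_prefilter`
#'   per data type (the workflow used both 0.05 and 0.01 cutoffs).
#' @param adjust_bh Apply Benjamini-Hochberg adjustment before
#'   thresholding (off by default; the reference workflow used raw p).
#' @param svm_cost Soft-margin cost C of the linear SVM.
#' @param rfe_step Features removed per elimination round (1 = classic RFE;
#'   larger values chunk the early rounds for very wide matrices).
#' @param mc_reps Monte-Carlo 2-fold CV repetitions per panel size.
#' @param boot_reps Bootstrap resamples for the ROC confidence interval.
#' @param ci_level Confidence level of the ROC interval.
#' @param cin_gain,cin_loss Log2-ratio thresholds a segment must exceed to
#'   count as gained (`>= cin_gain`) or lost (`<= -cin_loss`).
#' @param cin_channel CIN channel fed to selection: `"total"`, `"gain"` or
#'   `"loss"`.
#' @param af_cutoff Population allele-frequency cutoff defining a rare
#'   variant in the burden test.
#' @param rface_forests,rface_trees Number of forest repetitions and trees
#'   per forest in the artificial-contrast ranking.
#' @param rface_quantile Contrast-importance quantile each real feature is
#'   tested against.
#' @param p_select P-value threshold for the integrated selected set.
#' @param p_top P-value threshold for the top tier. The default mirrors the
#'   published workflow's extreme cutoff; on desk-scale data a practical
#'   value such as 1e-6 should be configured (see the methods vignette).
#' @param alpha_edge P-value threshold for Kendall association edges.
#' @param normalize_metabolomics Apply the total-intensity/log2/z-score
#'   normalization chain to raw metabolomics matrices at load time.
#' @param seed Integer seed fixing all randomness of a run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha_prefilter = 0.05,
                            alpha_per_type = list(),
                            adjust_bh = FALSE,
                            svm_cost = 1.0,
                            rfe_step = 1L,
                            mc_reps = 200L,
                            boot_reps = 2000L,
                            ci_level = 0.95,
                            cin_gain = 0.2,
                            cin_loss = 0.2,
                            cin_channel = "total",
                            af_cutoff = 0.05,
                            rface_forests = 20L,
                            rface_trees = 100L,
                            rface_quantile = 0.75,
                            p_select = 0.01,
                            p_top = 1e-30,
                            alpha_edge = 0.01,
                            normalize_metabolomics = FALSE,
                            seed = 1L) {
  cfg <- list(alpha_prefilter = alpha_prefilter,
              alpha_per_type = alpha_per_type, adjust_bh = isTRUE(adjust_bh),
              svm_cost = svm_cost, rfe_step = as.integer(rfe_step),
              mc_reps = as.integer(mc_reps),
              boot_reps = as.integer(boot_reps), ci_level = ci_level,
              cin_gain = cin_gain, cin_loss = cin_loss,
              cin_channel = match.arg(cin_channel,
                                      c("total", "gain", "loss")),
              af_cutoff = af_cutoff,
              rface_forests = as.integer(rface_forests),
              rface_trees = as.integer(rface_trees),
              rface_quantile = rface_quantile,
              p_select = p_select, p_top = p_top, alpha_edge = alpha_edge,
              normalize_metabolomics = isTRUE(normalize_metabolomics),
              seed = as.integer(seed))
  for (nm in c("alpha_prefilter", "ci_level", "af_cutoff", "rface_quantile",
               "p_select", "p_top", "alpha_edge"))
    if (!is_prob(cfg[[nm]])) stopf("%s must be in (0, 1]", nm)
  for (nm in names(cfg$alpha_per_type))
    if (!is_prob(cfg$alpha_per_type[[nm]]))
      stopf("alpha_per_type$%s must be in (0, 1]", nm)
  if (!(cfg$svm_cost > 0)) stopf("svm_cost must be positive")
  if (cfg$rfe_step < 1L) stopf("rfe_step must be >= 1")
  if (cfg$mc_reps < 1L) stopf("mc_reps must be >= 1")
  if (cfg$boot_reps < 100L) stopf("boot_reps must be >= 100")
  if (!(cfg$cin_gain > 0) || !(cfg$cin_loss > 0))
    stopf("cin_gain and cin_loss must be positive")
  if (cfg$rface_forests < 2L) stopf("rface_forests must be >= 2")
  if (cfg$rface_trees < 10L) stopf("rface_trees must be >= 10")
  structure(cfg, class = "pipeline_config")
}

prefilter_alpha_for <- function(cfg, data_type) {
  a <- cfg$alpha_per_type[[data_type]]
  if (is.null(a)) cfg$alpha_prefilter else a
}
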