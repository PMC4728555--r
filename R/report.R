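#' Run the full feature-association analysis and write a report bundle
#'
#' End-to-end pipeline over a validated dataset: per-position composition
#' table with raw and permutation-adjusted p-values, positive-minus-negative
#' frequency-delta matrix, GC feature summary and group comparison,
#' structure features, the dummy-coded logistic fit with full-data ROC/AUC
#' and cross-validated mean AUC, and (when intervals are supplied) the
#' promoter-TSS x open-chromatin association. All outputs are plain
#' TSV/JSON; a manifest records the seeds and configuration so a rerun with
#' the same inputs reproduces the bundle byte for byte.
#'
#' @param records Validated record data.frame (see [read_guides()]) with
#'   positive/negative outcomes.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed used for the permutation and CV stages.
#' @param n_perm Label permutations for the minP stage (0 skips it).
#' @param cv_k Cross-validation folds.
#' @param features Optional precomputed covariate data.frame (gc_normal +
#'   structure columns); computed from the records when `NULL`.
#' @param dhs Optional intervals (`GRanges`, BED path, or data.frame) of
#'   DNase-hypersensitive sites for the context association stage.
#' @param scaffold Scaffold sequence for structure features.
#' @param backend Folding backend.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_full_analysis <- function(records, outdir, seed, n_perm = 10000L,
                              cv_k = 20L, features = NULL, dhs = NULL,
                              scaffold = load_scaffold(),
                              backend = fold_backend()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out_tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  y <- as.integer(records$outcome == "positive")
  if (!any(y == 1) || !any(y == 0)) {
    stop("composition stage: both outcome groups must be present")
  }

  comp <- composition_summary(records, n_perm = n_perm, seed = seed)
  out_tsv(comp, "composition_table.tsv")

  tab_pos <- count_nucleotides(records, "positive")
  tab_neg <- count_nucleotides(records, "negative")
  delta <- frequency_delta(tab_pos, tab_neg)
  out_tsv(data.frame(position = seq_len(nrow(delta)), delta),
          "delta_matrix.tsv")

  gcf <- gc_features(records)
  gc_cmp <- compare_gc(gcf$gc_overall[y == 1], gcf$gc_overall[y == 0])
  out_tsv(cbind(id = records$id, gcf), "gc_features.tsv")
  gc_summary <- data.frame(
    mean_pos = mean(gcf$gc_overall[y == 1]),
    mean_neg = mean(gcf$gc_overall[y == 0]),
    welch_t = gc_cmp$welch$statistic, welch_p = gc_cmp$welch$p,
    ks_stat = gc_cmp$ks$statistic, ks_p = gc_cmp$ks$p)
  out_tsv(gc_summary, "gc_summary.tsv")

  if (is.null(features)) {
    sf <- structure_features(records, scaffold = scaffold,
                             backend = backend)
    features <- cbind(data.frame(gc_normal = gcf$gc_normal), sf)
  }
  out_tsv(cbind(id = records$id, features), "features.tsv")

  baselines <- choose_baselines(delta)
  X <- build_design(records, features, baselines)
  fit <- fit_logistic(X, y)
  out_tsv(as.data.frame(fit), "model_fit.tsv")
  roc <- roc_curve(predict_model(fit, X), y)
  out_tsv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                     tpr = roc$tpr), "roc_points.tsv")
  cv <- cv_auc(records, features, k = cv_k, seed = seed)
  auc <- list(auc_full = roc$auc, auc_cv_mean = as.numeric(cv),
              auc_cv_folds = as.numeric(attr(cv, "fold_auc")))
  jsonlite::write_json(auc, file.path(outdir, "auc.json"),
                       auto_unbox = TRUE, digits = NA)

  assoc <- NULL
  if (!is.null(dhs)) {
    if (is.character(dhs)) dhs <- read_bed(dhs)
    hits <- guide_overlaps(records, dhs)
    assoc <- context_dhs_association(records$context == "promoter-TSS",
                                     hits)
    jsonlite::write_json(
      list(n_overlapping = sum(hits), table = assoc$table,
           chisq_p = assoc$chisq_p, fisher_p = assoc$fisher_p,
           odds_ratio = assoc$odds_ratio),
      file.path(outdir, "dhs_association.json"), auto_unbox = TRUE,
      digits = NA)
  }

  manifest <- list(package = "crispreff",
                   version = as.character(utils::packageVersion("crispreff")),
                   n_records = nrow(records), seed = seed, n_perm = n_perm,
                   cv_k = cv_k, backend = backend$name,
                   baselines = unname(baselines),
                   stages = c("composition", "gc", "structure", "model",
                              if (!is.null(assoc)) "dhs_association"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(composition = comp, delta = delta, gc = gc_summary,
                 features = features, fit = fit, roc = roc, auc = auc,
                 dhs_association = assoc, manifest = manifest))
}
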