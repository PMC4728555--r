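#' @name synthetic_data
#' @title Synthetic sgRNA datasets with known ground truth
#'
#' @description
#' Generator of labelled sgRNA datasets carrying the statistical structure
#' the analysis assumes: i.i.d. per-position guide composition, a
#' genomic-context category, GC and secondary-structure covariates, and a
#' binary cleavage outcome drawn from a logistic model with configurable
#' effects. Defaults mirror the study conditions the pipeline targets:
#' 218 guides with about 59% positives and effect magnitudes of the order
#' reported for real Surveyor data (GC-normal about +3, adenine at the
#' PAM-adjacent position about -2.2, promoter-TSS about +3.9, seed
#' accessibility about -9 on the probability scale).
NULL

#' Configuration for the synthetic generator
#'
#' @param n_records Number of guides.
#' @param intercept Baseline log-odds of a positive outcome. The default is
#'   calibrated so that, with the default effects and covariate
#'   distributions, about 59% of outcomes are positive.
#' @param position_effects Named numeric vector of per-position nucleotide
#'   log-odds effects, names in design-column notation `Pos_{p}_{b}` with
#'   `p` in 1..21 (21 = PAM N base); unnamed positions/bases have effect 0.
#' @param context_probs Named probability vector over [context_levels()].
#' @param context_effects Named numeric vector of context log-odds effects
#'   (relative to the implicit 0 of unlisted categories).
#' @param gc_effect Log-odds effect of `gc_normal` (GC in 40-60%).
#' @param structure_effects Named numeric vector of log-odds effects for
#'   structure covariates (`seed_unpaired`, `mfe`,
#'   `tracr_interaction_avg`, `tracr_interaction_max`).
#' @param base_probs Per-base sampling probabilities for guide positions:
#'   a named numeric 4-vector, or `"uniform"` (default), or `"paperlike"`
#'   (pooled marginal base frequencies of the packaged occurrence-table
#'   fixture).
#' @param structure_mode `"noise"` (fast: covariates drawn from plausible
#'   distributions) or `"fold"` (covariates computed by actually folding
#'   the generated sequences, giving realistic collinearity; slow).
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 218L,
                             intercept = 2.74,
                             position_effects = c(Pos_20_A = -2.2),
                             context_probs = c("3'UTR" = 0.04,
                                               "promoter-TSS" = 0.10,
                                               "TTS" = 0.05,
                                               "5'UTR" = 0.04,
                                               "intron" = 0.35,
                                               "exon" = 0.12,
                                               "intergenic" = 0.30),
                             context_effects = c("promoter-TSS" = 3.9),
                             gc_effect = 3.1,
                             structure_effects = c(seed_unpaired = -9),
                             base_probs = "uniform",
                             structure_mode = c("noise", "fold"),
                             seed = 1L) {
  structure_mode <- match.arg(structure_mode)
  stopifnot(n_records >= 1)
  if (!setequal(names(context_probs), context_levels())) {
    stop("context_probs must cover exactly the seven context categories")
  }
  if (any(context_probs < 0) || sum(context_probs) <= 0) {
    stop("context_probs must be a nonnegative, non-degenerate distribution")
  }
  context_probs <- context_probs / sum(context_probs)
  if (is.character(base_probs)) {
    base_probs <- switch(match.arg(base_probs, c("uniform", "paperlike")),
                         uniform = stats::setNames(rep(0.25, 4),
                                                   nucleotides()),
                         paperlike = paperlike_base_probs())
  }
  stopifnot(setequal(names(base_probs), nucleotides()), all(base_probs > 0))
  base_probs <- base_probs[nucleotides()] / sum(base_probs)
  structure(list(n_records = as.integer(n_records), intercept = intercept,
                 position_effects = position_effects,
                 context_probs = context_probs[context_levels()],
                 context_effects = context_effects, gc_effect = gc_effect,
                 structure_effects = structure_effects,
                 base_probs = base_probs, structure_mode = structure_mode,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

paperlike_base_probs <- function() {
  fx <- load_table1_fixture()
  pooled <- colSums(fx$positive$counts[1:20, ]) +
    colSums(fx$negative$counts[1:20, ])
  pooled / sum(pooled)
}

draw_noise_structure <- function(n) {
  tr_max <- stats::rbeta(n, 4, 3)
  data.frame(mfe = -stats::rgamma(n, shape = 4, scale = 1.5),
             seed_unpaired = stats::rbeta(n, 2, 2),
             tracr_interaction_avg = tr_max * stats::rbeta(n, 2, 6),
             tracr_interaction_max = tr_max)
}

#' Generate a synthetic sgRNA dataset
#'
#' Guides are drawn i.i.d. per position from `base_probs`, the PAM N base
#' uniformly, contexts from `context_probs`; structure covariates come
#' either from real folding of the generated sequences (`"fold"`) or from
#' plausible noise distributions (`"noise"`); the outcome is Bernoulli
#' with success probability `plogis(linear predictor)`.
#'
#' @param config A [synthetic_config()].
#' @param backend Folding backend for `structure_mode = "fold"`.
#' @return List with `records` (validated record data.frame), `features`
#'   (gc_normal + structure covariates, as consumed by [build_design()])
#'   and `truth` (the config plus per-record linear predictors and
#'   probabilities).
#' @export
generate_dataset <- function(config = synthetic_config(),
                             backend = fold_backend()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_records
  m <- matrix(sample(nucleotides(), n * 20L, replace = TRUE,
                     prob = config$base_probs), n, 20L)
  guides <- apply(m, 1, paste, collapse = "")
  pam_n <- sample(nucleotides(), n, replace = TRUE)
  context <- sample(context_levels(), n, replace = TRUE,
                    prob = config$context_probs)
  start <- sample.int(2e6L, n) + 1e6L
  records <- data.frame(id = sprintf("sg%04d", seq_len(n)),
                        guide_seq = guides,
                        pam = paste0(pam_n, "GG"),
                        chrom = sample(paste0("chr", 1:19), n,
                                       replace = TRUE),
                        start = start, end = start + 23L,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        context = context, outcome = "unknown",
                        stringsAsFactors = FALSE)
  records$extended_seq <- paste0("G", records$guide_seq)

  gcf <- gc_features(records)
  sf <- if (config$structure_mode == "fold") {
    structure_features(records, backend = backend)
  } else {
    draw_noise_structure(n)
  }

  eta <- rep(config$intercept, n)
  sm <- cbind(m, pam_n)
  for (nm in names(config$position_effects)) {
    part <- strsplit(nm, "_")[[1]]
    p <- as.integer(part[2])
    b <- part[3]
    stopifnot(!is.na(p), p >= 1, p <= 21, b %in% nucleotides())
    eta <- eta + config$position_effects[[nm]] * (sm[, p] == b)
  }
  for (nm in names(config$context_effects)) {
    eta <- eta + config$context_effects[[nm]] * (context == nm)
  }
  eta <- eta + config$gc_effect * gcf$gc_normal
  for (nm in names(config$structure_effects)) {
    if (!nm %in% names(sf)) stop("unknown structure covariate: ", nm)
    eta <- eta + config$structure_effects[[nm]] * sf[[nm]]
  }
  prob <- stats::plogis(eta)
  records$outcome <- ifelse(stats::rbinom(n, 1, prob) == 1,
                            "positive", "negative")

  v <- validate_guides(records)
  stopifnot(nrow(v$rejects) == 0)
  features <- cbind(data.frame(gc_normal = gcf$gc_normal), sf)
  list(records = v$records, features = features,
       truth = list(config = config, eta = eta, prob = prob))
}

#' Load the packaged occurrence-table fixture
#'
#' Per-position nucleotide occurrence counts for the 129 cleavage-positive
#' and 89 cleavage-negative guides of the reference Surveyor dataset,
#' positions 1-21 (21 = PAM N base), shipped as plain TSV. Row sums are
#' validated against the group sizes on load.
#'
#' @return List with `positive` and `negative` [new_count_table()] objects.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_counts.tsv", package = "crispreff")
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(nrow(df) == 21, identical(df$position, 1:21))
  pos <- as.matrix(df[, paste0("pos_", nucleotides())])
  neg <- as.matrix(df[, paste0("neg_", nucleotides())])
  list(positive = new_count_table(pos, 129L),
       negative = new_count_table(neg, 89L))
}
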