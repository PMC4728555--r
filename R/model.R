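#' @name efficiency_model
#' @title Dummy-coded logistic model of cleavage efficiency
#'
#' @description
#' The efficiency model regresses the binary cleavage outcome on
#' position-wise nucleotide dummies (baseline = the base with the smallest
#' absolute positive-minus-negative frequency change at that position),
#' genomic-context dummies (baseline = intergenic), the binary GC-normal
#' indicator and the structure covariates. Evaluation follows two settings:
#' ROC/AUC of the full-data fit applied back to the training data, and the
#' mean AUC over stratified k-fold cross-validation (default k = 20).
NULL

#' Choose per-position baseline bases from a frequency-delta matrix
#'
#' At each position the baseline level is the base whose
#' positive-minus-negative frequency change is smallest in absolute value;
#' ties break alphabetically (A < C < G < T).
#'
#' @param delta Numeric matrix from [frequency_delta()].
#' @return Character vector of baseline bases, one per position.
#' @export
choose_baselines <- function(delta) {
  apply(delta, 1, function(row) nucleotides()[which.min(abs(row))])
}

#' Build the dummy-coded design matrix
#'
#' Columns: `Pos_{p}_{b}` indicators for every base `b` other than the
#' position's baseline (3 per position), `Context_*` indicators for the six
#' non-intergenic categories, and every column of `features` passed through
#' as numeric (logicals such as `gc_normal` become 0/1).
#'
#' @param records Validated record data.frame.
#' @param features Optional data.frame of numeric covariates (GC flag,
#'   structure features), one row per record.
#' @param baselines Character vector of per-position baseline bases, e.g.
#'   from [choose_baselines()].
#' @return Numeric data.frame with attribute `"baselines"`.
#' @export
build_design <- function(records, features = NULL, baselines) {
  m <- seq_matrix(records)
  npos <- ncol(m)
  if (length(baselines) != npos) {
    stop("need one baseline base per position (", npos, ")")
  }
  if (any(!records$context %in% context_levels())) {
    stop("unknown context category in records")
  }
  cols <- list()
  for (p in seq_len(npos)) {
    for (b in setdiff(nucleotides(), baselines[p])) {
      cols[[paste0("Pos_", p, "_", b)]] <- as.integer(m[, p] == b)
    }
  }
  for (cl in setdiff(context_levels(), "intergenic")) {
    cols[[paste0("Context_", context_token(cl))]] <-
      as.integer(records$context == cl)
  }
  if (!is.null(features)) {
    stopifnot(nrow(features) == nrow(records))
    for (nm in names(features)) cols[[nm]] <- as.numeric(features[[nm]])
  }
  X <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  rownames(X) <- NULL
  attr(X, "baselines") <- baselines
  X
}

#' Fit the logistic regression model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) with
#' Wald standard errors. Non-convergence, suspected separation and
#' rank-deficiency (dropped columns) are reported in attributes, never
#' silently ignored. A ridge fallback (L2-penalized fit via glmnet, no
#' standard errors) is available behind an explicit flag for separated
#' data.
#'
#' @param X Design data.frame from [build_design()] (numeric columns).
#' @param y Binary outcome vector (0/1 or logical), both classes present.
#' @param ridge Use the L2-penalized fallback instead of plain ML.
#' @param ridge_lambda Penalty for the ridge fallback.
#' @return data.frame of class `model_fit` with columns `term`, `estimate`,
#'   `std_error`, `z`, `p`; attributes `converged`, `iterations`, `loglik`,
#'   `dropped` (aliased columns), `separation` and (for prediction) the
#'   underlying fitted object.
#' @export
fit_logistic <- function(X, y, ridge = FALSE, ridge_lambda = 1e-2) {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("both outcome classes must be present")

  if (ridge) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("the ridge fallback requires the glmnet package")
    }
    gf <- glmnet::glmnet(as.matrix(X), y, family = "binomial", alpha = 0,
                         lambda = ridge_lambda)
    est <- as.numeric(stats::coef(gf))
    out <- data.frame(term = c("(Intercept)", colnames(X)),
                      estimate = est, std_error = NA_real_,
                      z = NA_real_, p = NA_real_)
    attr(out, "converged") <- TRUE
    attr(out, "fitted_object") <- gf
    attr(out, "method") <- "ridge"
    class(out) <- c("model_fit", "data.frame")
    return(out)
  }

  dat <- data.frame(.outcome = y, X, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", conditionMessage(w))) {
        # recorded in the converged attribute instead
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1],
                    std_error = co[, 2], z = co[, 3], p = co[, 4],
                    row.names = NULL)
  out$term <- gsub("^`|`$", "", out$term)
  attr(out, "converged") <- fit$converged
  attr(out, "iterations") <- fit$iter
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "dropped") <- gsub("^`|`$", "", names(which(sm$aliased)))
  attr(out, "separation") <- separation ||
    any(abs(out$estimate[is.finite(out$estimate)]) > 15)
  attr(out, "fitted_object") <- fit
  attr(out, "method") <- "ml"
  class(out) <- c("model_fit", "data.frame")
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Logistic model fit (", attr(x, "method"), "), ",
      nrow(x), " terms", sep = "")
  if (isTRUE(attr(x, "separation"))) cat(" [separation suspected]")
  if (!isTRUE(attr(x, "converged"))) cat(" [NOT converged]")
  cat("\n")
  print.data.frame(x, digits = 4, ...)
  dropped <- attr(x, "dropped")
  if (length(dropped) > 0) {
    cat("dropped (aliased):", paste(dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict cleavage probabilities from a fitted model
#'
#' @param fit A `model_fit` from [fit_logistic()].
#' @param X Design data.frame with the same columns used for fitting.
#' @return Numeric vector of predicted probabilities.
#' @export
predict_model <- function(fit, X) {
  obj <- attr(fit, "fitted_object")
  if (identical(attr(fit, "method"), "ridge")) {
    as.numeric(stats::predict(obj, newx = as.matrix(X), type = "response"))
  } else {
    suppressWarnings(
      as.numeric(stats::predict(obj, newdata = data.frame(X,
                                                          check.names = FALSE),
                                type = "response")))
  }
}

#' ROC curve and exact AUC
#'
#' ROC points over the distinct score thresholds (descending); the AUC is
#' the trapezoidal area under the curve, which equals the concordance
#' probability P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary outcome vector; both classes must be present.
#' @return List of class `roc_result` with `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  keep <- !duplicated(s, fromLast = TRUE) # last row of each tie block
  tpr <- c(0, cumsum(l)[keep] / n1)
  fpr <- c(0, cumsum(1L - l)[keep] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[keep]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_result")
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, labels) roc_curve(scores, labels)$auc

#' Mean AUC under stratified k-fold cross-validation
#'
#' Records are split into k folds stratified by outcome. For each fold the
#' model is refit on the remaining folds — including re-choosing the
#' per-position baselines from the training split's frequency deltas — and
#' the held-out fold is scored; the mean of the k fold AUCs is returned.
#' Folds whose held-out part lacks one of the classes are re-drawn (with a
#' warning); if that fails repeatedly the call errors.
#'
#' @param records Validated record data.frame with positive/negative
#'   outcomes.
#' @param features Covariate data.frame as for [build_design()].
#' @param k Number of folds (default 20).
#' @param seed RNG seed for the fold assignment.
#' @param max_redraws Attempts at drawing fold assignments in which every
#'   fold is scorable.
#' @return Mean fold AUC, with per-fold AUCs in attribute `"fold_auc"` and
#'   the fold assignment in `"folds"`.
#' @export
cv_auc <- function(records, features = NULL, k = 20L, seed,
                   max_redraws = 100L) {
  y <- as.integer(records$outcome == "positive")
  n <- length(y)
  if (n < k) stop("need at least k records")
  set.seed(seed)
  folds <- NULL
  for (try in seq_len(max_redraws)) {
    f <- integer(n)
    for (cls in 0:1) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(i) {
      any(y[f == i] == 1) && any(y[f == i] == 0) &&
        any(y[f != i] == 1) && any(y[f != i] == 0)
    }, logical(1)))
    if (ok) { folds <- f; break }
    if (try == 1) warning("re-drawing folds: a fold lacked one class")
  }
  if (is.null(folds)) stop("could not draw folds with both classes held out")

  fold_auc <- vapply(seq_len(k), function(i) {
    tr <- folds != i
    rec_tr <- records[tr, , drop = FALSE]
    delta <- frequency_delta(count_nucleotides(rec_tr, "positive"),
                             count_nucleotides(rec_tr, "negative"))
    bl <- choose_baselines(delta)
    ftr <- if (is.null(features)) NULL else features[tr, , drop = FALSE]
    fte <- if (is.null(features)) NULL else features[!tr, , drop = FALSE]
    fit <- fit_logistic(build_design(rec_tr, ftr, bl), y[tr])
    scores <- predict_model(fit, build_design(records[!tr, , drop = FALSE],
                                              fte, bl))
    roc_auc(scores, y[!tr])
  }, numeric(1))
  structure(mean(fold_auc), fold_auc = fold_auc, folds = folds)
}

#' Association between a context label and open-chromatin overlap
#'
#' 2 x 2 association test between two binary indicators — canonically,
#' "target is annotated promoter-TSS" against "target overlaps a
#' DNase-hypersensitive site". Reports the chi-square test (R's default
#' continuity correction for 2 x 2 tables) and Fisher's exact test; with a
#' degenerate margin only Fisher's test is returned.
#'
#' @param context_flags,dhs_flags Equal-length binary/logical vectors.
#' @return List with `table` (2 x 2, TRUE row/column first), `chisq_p`,
#'   `fisher_p`, `odds_ratio` (conditional MLE; `Inf` flags perfect
#'   association) and `expected_lt5`.
#' @export
context_dhs_association <- function(context_flags, dhs_flags) {
  stopifnot(length(context_flags) == length(dhs_flags))
  a <- factor(as.logical(context_flags), levels = c(TRUE, FALSE))
  b <- factor(as.logical(dhs_flags), levels = c(TRUE, FALSE))
  tab <- table(context = a, dhs = b)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  fis <- stats::fisher.test(tab)
  if (degenerate) {
    chisq_p <- NA_real_
    expected_lt5 <- NA
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab))
    chisq_p <- ht$p.value
    expected_lt5 <- any(ht$expected < 5)
  }
  list(table = unclass(tab), chisq_p = chisq_p, fisher_p = fis$p.value,
       odds_ratio = unname(fis$estimate), expected_lt5 = expected_lt5)
}
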