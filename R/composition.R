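#' @name composition
#' @title Position-wise nucleotide composition analysis
#'
#' @description
#' Per-position nucleotide counts for the cleavage-positive and -negative
#' groups, positive-minus-negative frequency deltas (the heatmap matrix),
#' per-position Pearson chi-square homogeneity tests, and the minP
#' permutation family-wise adjustment of the smallest p-value.
NULL

#' Construct a per-position count table
#'
#' @param counts Integer matrix, rows = positions, columns = A,C,G,T.
#' @param group_size Number of sequences in the group; each row must sum to
#'   it.
#' @return Object of class `count_table`: list with `counts` and
#'   `group_size`.
#' @export
new_count_table <- function(counts, group_size) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  colnames(counts) <- nucleotides()
  rownames(counts) <- paste0("pos", seq_len(nrow(counts)))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!all(rowSums(counts) == group_size)) {
    stop("each position's counts must sum to group_size")
  }
  structure(list(counts = counts, group_size = as.integer(group_size)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "positions, group size",
      x$group_size, "\n")
  print(x$counts)
  invisible(x)
}

#' Count nucleotides per position for one outcome group
#'
#' @param x Validated record data.frame or a character matrix from
#'   [seq_matrix()].
#' @param group Outcome label selecting the rows (`"positive"` or
#'   `"negative"`); ignored when `x` is already a matrix.
#' @return A [new_count_table()] object (positions x A,C,G,T).
#' @export
count_nucleotides <- function(x, group = NULL) {
  if (is.data.frame(x)) {
    if (is.null(group)) stop("'group' is required for a record data.frame")
    x <- seq_matrix(x[x$outcome == group, , drop = FALSE])
  }
  if (nrow(x) == 0) stop("empty group: no sequences to count")
  counts <- t(apply(x, 2, function(col) {
    tabulate(factor(col, levels = nucleotides()), nbins = 4)
  }))
  new_count_table(counts, nrow(x))
}

#' Positive-minus-negative frequency difference matrix
#'
#' The heatmap quantity: per position and base,
#' `freq_positive - freq_negative`, each frequency a within-group
#' proportion. Rows sum to zero.
#'
#' @param pos_table,neg_table [new_count_table()] objects over the same
#'   positions.
#' @return Numeric matrix (positions x A,C,G,T) of deltas in `[-1, 1]`.
#' @export
frequency_delta <- function(pos_table, neg_table) {
  stopifnot(inherits(pos_table, "count_table"),
            inherits(neg_table, "count_table"),
            nrow(pos_table$counts) == nrow(neg_table$counts))
  if (pos_table$group_size == 0 || neg_table$group_size == 0) {
    stop("group sizes must be positive")
  }
  pos_table$counts / pos_table$group_size -
    neg_table$counts / neg_table$group_size
}

#' Chi-square homogeneity test at one position
#'
#' Pearson chi-square on the 2 x 4 group-by-base table, no continuity
#' correction, df = 3. A base absent from both groups is dropped and the
#' degrees of freedom reduced accordingly (reported in the result).
#'
#' @param counts_pos,counts_neg Integer 4-vectors of A,C,G,T counts.
#' @return List with `chi2`, `df`, `p`, `dropped` (bases absent from both
#'   groups) and `expected_warning` (TRUE when any expected cell < 5).
#' @export
chisq_position <- function(counts_pos, counts_neg) {
  stopifnot(length(counts_pos) == 4, length(counts_neg) == 4,
            all(counts_pos >= 0), all(counts_neg >= 0),
            sum(counts_pos) > 0, sum(counts_neg) > 0)
  tab <- rbind(counts_pos, counts_neg)
  colnames(tab) <- nucleotides()
  keep <- colSums(tab) > 0
  dropped <- nucleotides()[!keep]
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) {
    # a single shared base: no heterogeneity testable
    return(list(chi2 = 0, df = 0L, p = 1, dropped = dropped,
                expected_warning = FALSE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), dropped = dropped,
       expected_warning = any(ht$expected < 5))
}

#' Per-position chi-square tests between outcome groups
#'
#' @param pos_table,neg_table [new_count_table()] objects over the same
#'   positions.
#' @return data.frame with one row per position: `position`, `chi2`, `df`,
#'   `p_raw`, `expected_warning`.
#' @export
composition_tests <- function(pos_table, neg_table) {
  stopifnot(nrow(pos_table$counts) == nrow(neg_table$counts))
  res <- lapply(seq_len(nrow(pos_table$counts)), function(p) {
    chisq_position(pos_table$counts[p, ], neg_table$counts[p, ])
  })
  data.frame(position = seq_along(res),
             chi2 = vapply(res, `[[`, numeric(1), "chi2"),
             df = vapply(res, `[[`, integer(1), "df"),
             p_raw = vapply(res, `[[`, numeric(1), "p"),
             expected_warning = vapply(res, `[[`, logical(1),
                                       "expected_warning"))
}

# vectorized chi-square p-values for all positions given group-1 counts;
# column totals are fixed under label permutation, so expected counts and
# testable degrees of freedom are precomputed once
chisq_p_from_counts1 <- function(counts1, totals, n1, n2) {
  n <- n1 + n2
  counts2 <- totals - counts1
  e1 <- totals * n1 / n
  e2 <- totals * n2 / n
  live <- totals > 0
  chi2num <- (counts1 - e1)^2 / ifelse(live, e1, 1) +
    (counts2 - e2)^2 / ifelse(live, e2, 1)
  chi2num[!live] <- 0
  chi2 <- rowSums(chi2num)
  df <- rowSums(live) - 1L
  p <- rep(1, length(chi2))
  testable <- df >= 1
  p[testable] <- stats::pchisq(chi2[testable], df[testable],
                               lower.tail = FALSE)
  p
}

#' minP permutation adjustment of per-position chi-square p-values
#'
#' Family-wise correction across the 21 positions: outcome labels are
#' randomly reassigned `n_perm` times preserving the observed group sizes;
#' in each permutation the chi-square test is run at every position and the
#' smallest p-value recorded, building the null distribution of the minimum.
#' Each observed raw p is then compared to that distribution.
#'
#' With `add_one = TRUE` (default) the estimator is `(r + 1) / (n_perm + 1)`
#' where `r` counts permutation minima at or below the observed p; this
#' avoids exact zeros. `add_one = FALSE` gives the plain `r / n_perm` tail
#' fraction.
#'
#' @param x Validated record data.frame or character matrix from
#'   [seq_matrix()].
#' @param labels Binary vector (1 = positive group) of length `nrow(x)`;
#'   when `x` is a record data.frame the default is taken from its
#'   `outcome` column.
#' @param n_perm Number of label randomizations (>= 1).
#' @param seed Integer RNG seed; required so runs are reproducible.
#' @param add_one Use the add-one tail estimator (default TRUE).
#' @return data.frame as [composition_tests()] plus `p_perm`, with the
#'   permutation minima in attribute `"perm_min_p"`.
#' @export
minp_permutation <- function(x, labels = NULL, n_perm = 10000L, seed,
                             add_one = TRUE) {
  if (is.data.frame(x)) {
    if (is.null(labels)) labels <- as.integer(x$outcome == "positive")
    x <- seq_matrix(x)
  }
  if (is.null(labels)) stop("'labels' is required for a matrix input")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  labels <- as.integer(labels)
  if (length(labels) != nrow(x) || !all(labels %in% 0:1)) {
    stop("labels must be a 0/1 vector matching the number of records")
  }
  n1 <- sum(labels == 1L)
  n2 <- sum(labels == 0L)
  if (n1 == 0 || n2 == 0) stop("both outcome groups must be non-empty")

  n_pos <- ncol(x)
  # one-hot encoding: n x (positions * 4)
  ind <- matrix(0L, nrow(x), n_pos * 4L)
  for (p in seq_len(n_pos)) {
    ind[, (p - 1L) * 4L + seq_len(4L)] <-
      outer(x[, p], nucleotides(), "==") + 0L
  }
  totals <- matrix(colSums(ind), n_pos, 4L, byrow = TRUE)
  obs1 <- matrix(colSums(ind[labels == 1L, , drop = FALSE]), n_pos, 4L,
                 byrow = TRUE)
  p_raw <- chisq_p_from_counts1(obs1, totals, n1, n2)

  set.seed(seed)
  min_p <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(nrow(x), n1)
    c1 <- matrix(colSums(ind[idx, , drop = FALSE]), n_pos, 4L, byrow = TRUE)
    min(chisq_p_from_counts1(c1, totals, n1, n2))
  }, numeric(1))

  r <- vapply(p_raw, function(p) sum(min_p <= p + 1e-12), numeric(1))
  p_perm <- if (add_one) (r + 1) / (n_perm + 1) else r / n_perm

  out <- data.frame(position = seq_len(n_pos),
                    p_raw = p_raw, p_perm = p_perm)
  attr(out, "perm_min_p") <- min_p
  out
}

#' Composition summary in the layout of the published occurrence table
#'
#' One row per position with per-base occurrence counts and within-group
#' percentages for both outcome groups, the raw chi-square p-value and
#' (optionally) the permutation-adjusted p-value.
#'
#' @param records Validated record data.frame with positive and negative
#'   outcomes.
#' @param n_perm Permutations for the minP adjustment; 0 skips it.
#' @param seed RNG seed for the permutation stage (required if `n_perm` > 0).
#' @return data.frame with count/percent columns per group and base, plus
#'   `p_raw` and `p_perm`.
#' @export
composition_summary <- function(records, n_perm = 10000L, seed = NULL) {
  tab_pos <- count_nucleotides(records, "positive")
  tab_neg <- count_nucleotides(records, "negative")
  tests <- composition_tests(tab_pos, tab_neg)
  out <- data.frame(position = tests$position)
  for (grp in c("pos", "neg")) {
    tb <- if (grp == "pos") tab_pos else tab_neg
    for (b in nucleotides()) {
      out[[paste0(grp, "_", b)]] <- tb$counts[, b]
      out[[paste0(grp, "_", b, "_pct")]] <-
        round(100 * tb$counts[, b] / tb$group_size, 1)
    }
  }
  out$p_raw <- tests$p_raw
  if (n_perm > 0) {
    if (is.null(seed)) stop("a seed is required for the permutation stage")
    out$p_perm <- minp_permutation(records, n_perm = n_perm,
                                   seed = seed)$p_perm
  }
  out
}
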