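#' GC-content features of guide sequences
#'
#' Computes GC percentages on the 20-nt guide (the transcribed extra 5' G
#' and the PAM are excluded): overall, and over the windows 1-6 (PAM-distal),
#' 7-14 and 15-20 (PAM-proximal). `gc_normal` flags guides whose overall GC
#' lies in the inclusive 40-60% band; outside that band the guide is "GC
#' abnormal".
#'
#' @param guides Character vector of 20-nt guide sequences, or a validated
#'   record data.frame (its `guide_seq` column is used).
#' @return data.frame with columns `gc_overall`, `gc_1_6`, `gc_7_14`,
#'   `gc_15_20` (percent) and logical `gc_normal`.
#' @export
gc_features <- function(guides) {
  if (is.data.frame(guides)) guides <- guides$guide_seq
  guides <- normalize_seq(guides)
  if (any(nchar(guides) != 20)) stop("guides must be 20 nt")
  gc_window <- function(from, to) {
    sub <- substr(guides, from, to)
    100 * (nchar(gsub("[AT]", "", sub)) / (to - from + 1))
  }
  overall <- gc_window(1, 20)
  data.frame(gc_overall = overall,
             gc_1_6 = gc_window(1, 6),
             gc_7_14 = gc_window(7, 14),
             gc_15_20 = gc_window(15, 20),
             gc_normal = overall >= 40 & overall <= 60)
}

#' Compare GC percentages between outcome groups
#'
#' Welch unequal-variance two-sample t-test and two-sample
#' Kolmogorov-Smirnov test of the GC distributions in the cleavage-positive
#' vs -negative groups.
#'
#' @param values_pos,values_neg Numeric vectors of GC percentages.
#' @return List with `welch` (`statistic`, `df`, `p`, `degenerate` flag set
#'   when a group has fewer than 2 values or zero pooled variance) and `ks`
#'   (`statistic`, `p`).
#' @export
compare_gc <- function(values_pos, values_neg) {
  if (length(values_pos) == 0 || length(values_neg) == 0) {
    stop("both groups must be non-empty")
  }
  ks <- suppressWarnings(stats::ks.test(values_pos, values_neg))
  degenerate <- length(values_pos) < 2 || length(values_neg) < 2 ||
    (stats::var(values_pos) == 0 && stats::var(values_neg) == 0)
  welch <- if (degenerate) {
    list(statistic = NA_real_, df = NA_real_, p = NA_real_)
  } else {
    tt <- stats::t.test(values_pos, values_neg, var.equal = FALSE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  }
  welch$degenerate <- degenerate
  list(welch = welch,
       ks = list(statistic = unname(ks$statistic), p = ks$p.value))
}

#' @importFrom stats var
NULL
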