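# build a valid record data.frame from guide sequences
make_records <- function(guides, pam = "AGG", context = "intron",
                         outcome = "positive", chrom = "chr1",
                         start = NULL) {
  n <- length(guides)
  if (is.null(start)) start <- seq(100, by = 1000, length.out = n)
  df <- data.frame(id = paste0("g", seq_len(n)), guide_seq = guides,
                   pam = rep_len(pam, n), chrom = rep_len(chrom, n),
                   start = start, end = start + 23L,
                   strand = rep_len("+", n),
                   context = rep_len(context, n),
                   outcome = rep_len(outcome, n),
                   stringsAsFactors = FALSE)
  validate_guides(df)$records
}

random_guides <- function(n, len = 20L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# brute-force all-pairs interval overlap oracle (0-based half-open)
overlap_oracle <- function(records, intervals) {
  vapply(seq_len(nrow(records)), function(i) {
    any(intervals$chrom == records$chrom[i] &
          intervals$start < records$end[i] &
          intervals$end > records$start[i])
  }, logical(1))
}
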