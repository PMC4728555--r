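#' @name dataset_io
#' @title Reading, validating and writing sgRNA datasets
#'
#' @description
#' An sgRNA dataset is a plain data.frame with one row per guide and columns
#' `id`, `guide_seq` (20 nt over A/C/G/T), `pam` (3 nt, NGG), `chrom`,
#' `start`, `end` (0-based half-open), `strand` (+/-), `context` (one of the
#' seven genomic-context categories, see [context_levels()]) and `outcome`
#' (`"positive"`, `"negative"` or `"unknown"`). A derived column
#' `extended_seq` holds the transcribed GN20 sequence (extra 5' G required by
#' the U6 promoter). Coordinates are BED-convention internally; 1-based
#' closed input is converted at parse time.
NULL

#' Nucleotide alphabet used throughout
#' @return Character vector `c("A","C","G","T")`.
#' @export
nucleotides <- function() c("A", "C", "G", "T")

#' Genomic-context categories
#'
#' The seven annotation categories used to label the genomic context of each
#' target site (as produced by standard peak annotators).
#' @return Character vector of the seven category labels; `"intergenic"` is
#'   the conventional baseline level in the regression model.
#' @export
context_levels <- function() {
  c("3'UTR", "promoter-TSS", "TTS", "5'UTR", "intron", "exon", "intergenic")
}

# safe column-name fragment for a context label
context_token <- function(x) {
  map <- c("3'UTR" = "UTR3", "promoter-TSS" = "promoter_TSS", "TTS" = "TTS",
           "5'UTR" = "UTR5", "intron" = "intron", "exon" = "exon",
           "intergenic" = "intergenic")
  unname(map[x])
}

guide_columns <- function() {
  c("id", "guide_seq", "pam", "chrom", "start", "end", "strand",
    "context", "outcome")
}

normalize_seq <- function(x) {
  x <- toupper(trimws(x))
  gsub("U", "T", x, fixed = TRUE)
}

#' Validate sgRNA records
#'
#' Checks every row against the record invariants: 20-nt guide over A/C/G/T,
#' NGG PAM, start < end, known strand, known context category and outcome
#' label. Sequences are normalized (upper case, U -> T) and the GN20
#' `extended_seq` column is (re)computed.
#'
#' @param df data.frame with the columns of [guide_columns()].
#' @return List with `records` (validated, normalized data.frame) and
#'   `rejects` (data.frame of `row`, `id`, `reason` for each rejected row).
#' @export
validate_guides <- function(df) {
  missing_cols <- setdiff(guide_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$guide_seq <- normalize_seq(df$guide_seq)
  df$pam <- normalize_seq(df$pam)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)

  reasons <- character(nrow(df))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- msg
  }
  bad(nchar(df$guide_seq) != 20L, "guide_seq is not 20 nt")
  bad(grepl("[^ACGT]", df$guide_seq), "guide_seq has non-ACGT characters")
  bad(nchar(df$pam) != 3L | substr(df$pam, 2, 3) != "GG" |
        grepl("[^ACGT]", df$pam), "pam does not match NGG")
  bad(!(df$strand %in% c("+", "-")), "strand must be + or -")
  bad(!(df$context %in% context_levels()), "unknown context category")
  bad(!(df$outcome %in% c("positive", "negative", "unknown")),
      "outcome must be positive/negative/unknown")
  bad(df$start >= df$end, "start must be < end (0-based half-open)")

  ok <- reasons == ""
  rejects <- data.frame(row = which(!ok),
                        id = as.character(df$id[!ok]),
                        reason = reasons[!ok],
                        stringsAsFactors = FALSE)
  records <- df[ok, , drop = FALSE]
  records$extended_seq <- paste0("G", records$guide_seq)
  rownames(records) <- NULL
  list(records = records, rejects = rejects)
}

#' Read an sgRNA dataset from delimited text
#'
#' @param path Path to a TSV/CSV file with header naming the columns of
#'   [guide_columns()].
#' @param sep Field separator; `NULL` (default) guesses TSV for `.tsv`/`.txt`
#'   and CSV for `.csv`.
#' @param coords `"bed"` (0-based half-open, default) or `"one_based"`
#'   (1-based closed, converted on read).
#' @param on_reject `"warn"` (default) keeps valid rows and warns with the
#'   rejected row numbers; `"error"` fails if any row is invalid.
#' @return data.frame of validated records with attribute `"rejects"`.
#' @export
read_guides <- function(path, sep = NULL, coords = c("bed", "one_based"),
                        on_reject = c("warn", "error")) {
  coords <- match.arg(coords)
  on_reject <- match.arg(on_reject)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  if (coords == "one_based") {
    df$start <- as.integer(df$start) - 1L
  }
  v <- validate_guides(df)
  if (nrow(v$rejects) > 0) {
    msg <- paste0("rejected ", nrow(v$rejects), " row(s): ",
                  paste0("line ", v$rejects$row + 1L, " (", v$rejects$reason,
                         ")", collapse = "; "))
    if (on_reject == "error") stop(msg) else warning(msg)
  }
  structure(v$records, rejects = v$rejects)
}

#' Write an sgRNA dataset as TSV
#'
#' Inverse of [read_guides()]: `read_guides(write_guides(df, p))` is the
#' identity on valid records.
#'
#' @param records Validated record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides <- function(records, path) {
  utils::write.table(records[, c(guide_columns(), "extended_seq")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' @param path BED file; only the first three columns are used.
#' @return A `GRanges` of the intervals.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Test which records overlap a set of genomic intervals
#'
#' A record overlaps if its half-open target interval `[start, end)`
#' intersects any interval on the same chromosome. Strand is ignored:
#' chromatin accessibility (the intended use, DNase-hypersensitive sites)
#' is strand-agnostic.
#'
#' @param records Validated record data.frame.
#' @param intervals A `GRanges` (e.g. from [read_bed()]) or a data.frame with
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return Logical vector, one element per record.
#' @export
guide_overlaps <- function(records, intervals) {
  if (is.data.frame(intervals)) {
    if (nrow(intervals) == 0) return(rep(FALSE, nrow(records)))
    stopifnot(all(intervals$start < intervals$end))
    intervals <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  }
  if (length(intervals) == 0 || nrow(records) == 0) {
    return(rep(FALSE, nrow(records)))
  }
  gr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(start = records$start + 1L, end = records$end))
  # disjoint chromosome sets between query and subject are a legitimate
  # no-overlap case, not a user error
  suppressWarnings(
    GenomicRanges::countOverlaps(gr, intervals, ignore.strand = TRUE) > 0)
}

#' Per-position sequence matrix for composition analysis
#'
#' Builds the n x 21 character matrix analysed position by position:
#' columns 1..20 are the guide 5'->3' (position 20 is PAM-proximal) and
#' column 21 is the variable N base of the PAM.
#'
#' @param records Validated record data.frame.
#' @return Character matrix with one row per record, columns `pos1..pos21`.
#' @export
seq_matrix <- function(records) {
  m <- t(vapply(strsplit(records$guide_seq, ""), identity, character(20)))
  m <- cbind(m, substr(records$pam, 1, 1))
  dimnames(m) <- list(records$id, paste0("pos", seq_len(21)))
  m
}
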