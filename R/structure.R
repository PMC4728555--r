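#' @name structure_features_module
#' @title Secondary-structure features of sgRNAs
#'
#' @description
#' Equilibrium secondary-structure features used as covariates in the
#' efficiency model: the base-pair probability matrix and minimum free
#' energy (MFE) of the full sgRNA, the windowed probability that the seed
#' region is entirely unpaired (sliding window of width `W = 21`, seed span
#' `U = 12`), and the average/maximum probability that scaffold (tracrRNA)
#' bases pair with guide bases.
#'
#' Two folding backends are available. The internal backend is an exact
#' McCaskill-style partition function over nested structures with
#' Watson-Crick + GU pairs, additive per-pair energies and a minimum
#' hairpin loop of 3 — deliberately simple so that every number it produces
#' can be checked against exhaustive structure enumeration. The external
#' backend shells out to `RNAfold` (ViennaRNA) for Turner-parameter
#' energies; feature aggregation is identical for both.
NULL

#' Configure a folding backend
#'
#' @param name `"internal"` (exact simple-energy partition function) or
#'   `"external"` (ViennaRNA `RNAfold` on the PATH).
#' @param energies Named vector of pair energies in kcal/mol for the
#'   internal backend (`GC`, `AU`, `GU`; more negative = more stable).
#' @param temperature Temperature in degrees Celsius used for the Boltzmann
#'   factor (internal backend).
#' @param max_length Maximum sequence length accepted by the internal
#'   backend.
#' @return List of class `fold_backend`.
#' @export
fold_backend <- function(name = c("internal", "external"),
                         energies = c(GC = -3, AU = -2, GU = -1),
                         temperature = 37, max_length = 200L) {
  name <- match.arg(name)
  stopifnot(all(c("GC", "AU", "GU") %in% names(energies)))
  if (name == "external" && Sys.which("RNAfold") == "") {
    stop("external folding backend unavailable: RNAfold not found on PATH; ",
         "use fold_backend(\"internal\")")
  }
  structure(list(name = name,
                 energies = energies[c("GC", "AU", "GU")],
                 temperature = temperature,
                 RT = 0.0019872 * (273.15 + temperature),
                 max_length = as.integer(max_length)),
            class = "fold_backend")
}

encode_rna <- function(seq) {
  seq <- toupper(seq)
  seq <- gsub("T", "U", seq, fixed = TRUE)
  chars <- strsplit(seq, "")[[1]]
  code <- match(chars, c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) {
    stop("invalid RNA alphabet character(s): ",
         paste(unique(chars[is.na(code)]), collapse = ", "))
  }
  code
}

check_len <- function(code, backend) {
  if (backend$name == "internal" && length(code) > backend$max_length) {
    stop("sequence longer than internal backend max_length (",
         backend$max_length, ")")
  }
}

#' Base-pair probability matrix
#'
#' Equilibrium probability that bases i and j are paired, under the
#' backend's energy model. The matrix is symmetric, entries lie in
#' `[0, 1]`, row sums are at most 1, and `p[i, j] = 0` whenever
#' `|i - j| < 4` (minimum hairpin loop of 3).
#'
#' @param seq RNA (or DNA; T is read as U) sequence string.
#' @param backend A [fold_backend()].
#' @return Numeric n x n matrix of pair probabilities.
#' @export
pair_probabilities <- function(seq, backend = fold_backend()) {
  code <- encode_rna(seq)
  if (backend$name == "internal") {
    check_len(code, backend)
    fold_bpp_cpp(code, unname(backend$energies), backend$RT)$p
  } else {
    rnafold_bpp(seq)
  }
}

#' Minimum free energy of the nested-structure ensemble
#'
#' @inheritParams pair_probabilities
#' @return MFE in the backend's energy units (kcal/mol); 0 for sequences
#'   that cannot form any pair (the empty structure is always admissible,
#'   so the internal MFE is never positive).
#' @export
mfe <- function(seq, backend = fold_backend()) {
  code <- encode_rna(seq)
  if (backend$name == "internal") {
    check_len(code, backend)
    fold_mfe_cpp(code, unname(backend$energies))
  } else {
    rnafold_mfe(seq)
  }
}

#' Probability that a span of bases is simultaneously unpaired
#'
#' Ratio of the constrained partition function (all bases in `span`
#' forbidden from pairing) to the unconstrained one.
#'
#' @inheritParams pair_probabilities
#' @param span Integer vector `c(first, last)`, 1-based inclusive.
#' @return Probability in `[0, 1]`.
#' @export
unpaired_probability <- function(seq, span, backend = fold_backend()) {
  code <- encode_rna(seq)
  stopifnot(length(span) == 2, span[1] >= 1, span[2] <= length(code),
            span[1] <= span[2])
  if (backend$name == "internal") {
    check_len(code, backend)
    blocked <- rep(FALSE, length(code))
    blocked[span[1]:span[2]] <- TRUE
    zc <- fold_Z_cpp(code, unname(backend$energies), backend$RT, blocked)
    z <- fold_Z_cpp(code, unname(backend$energies), backend$RT,
                    rep(FALSE, length(code)))
    zc / z
  } else {
    rnafold_unpaired(seq, span)
  }
}

#' Windowed seed accessibility
#'
#' Sliding-window estimate of the probability that the entire seed region
#' is unpaired: every length-`W` window of `full_seq` that contains the
#' seed span is folded in isolation, the probability that all seed bases
#' are simultaneously unpaired is computed within each window, and the
#' mean over windows is returned. Defaults follow the sgRNA convention
#' `W = 21` (the GN20 transcript length) with a 12-nt seed.
#'
#' @param full_seq Full sequence to scan (typically GN20 + scaffold).
#' @param seed_span Integer `c(first, last)` of the seed within `full_seq`,
#'   1-based inclusive.
#' @param W Window width; must satisfy `U <= W <= nchar(full_seq)` where
#'   `U` is the seed length.
#' @param backend A [fold_backend()].
#' @return Mean over windows of the all-seed-bases-unpaired probability.
#' @export
seed_unpaired_probability <- function(full_seq, seed_span, W = 21L,
                                      backend = fold_backend()) {
  n <- nchar(full_seq)
  U <- seed_span[2] - seed_span[1] + 1L
  if (U > W || W > n) stop("need seed length <= W <= sequence length")
  starts <- seq.int(max(1L, seed_span[2] - W + 1L),
                    min(seed_span[1], n - W + 1L))
  if (length(starts) == 0 || starts[1] > min(seed_span[1], n - W + 1L)) {
    stop("no length-W window contains the seed span")
  }
  probs <- vapply(starts, function(s0) {
    win <- substr(full_seq, s0, s0 + W - 1L)
    unpaired_probability(win, seed_span - s0 + 1L, backend)
  }, numeric(1))
  mean(probs)
}

#' Guide-tracrRNA interaction probabilities
#'
#' Folds the concatenated guide + scaffold molecule and summarizes, from
#' its base-pair probability matrix, how strongly scaffold (tracrRNA)
#' bases pair with guide bases: for each scaffold base the maximum and the
#' average pairing probability across guide bases, both then averaged over
#' scaffold bases.
#'
#' @param guide Guide-side sequence (typically the GN20 transcript).
#' @param scaffold Scaffold/tracrRNA sequence.
#' @param backend A [fold_backend()].
#' @return List with `tracr_interaction_avg` and `tracr_interaction_max`;
#'   the pair matrix of the concatenated molecule is attached as attribute
#'   `"pair_matrix"`.
#' @export
tracr_interaction <- function(guide, scaffold, backend = fold_backend()) {
  stopifnot(nchar(guide) > 0, nchar(scaffold) > 0)
  p <- pair_probabilities(paste0(guide, scaffold), backend)
  ng <- nchar(guide)
  cross <- p[(ng + 1):nrow(p), 1:ng, drop = FALSE] # scaffold rows x guide cols
  out <- list(tracr_interaction_avg = mean(rowMeans(cross)),
              tracr_interaction_max = mean(apply(cross, 1, max)))
  attr(out, "pair_matrix") <- p
  out
}

#' Structure feature block for a dataset
#'
#' Per record: MFE of the full sgRNA (GN20 + scaffold), windowed seed
#' accessibility (`W = 21`, seed = the 12 PAM-proximal guide bases scanned
#' over the full sgRNA), and the tracrRNA interaction summaries.
#'
#' @param records Validated record data.frame.
#' @param scaffold Scaffold sequence string; default [load_scaffold()].
#' @param backend A [fold_backend()].
#' @param U Seed length in nt (PAM-proximal); default 12.
#' @param W Accessibility window width; default 21 (GN20 length).
#' @return data.frame with columns `mfe`, `seed_unpaired`,
#'   `tracr_interaction_avg`, `tracr_interaction_max`.
#' @export
structure_features <- function(records, scaffold = load_scaffold(),
                               backend = fold_backend(), U = 12L, W = 21L) {
  res <- lapply(records$extended_seq, function(ext) {
    full <- paste0(ext, scaffold)
    # guide occupies positions 2..21 of GN20; seed = last U guide bases
    seed <- c(21L - U + 1L, 21L)
    ti <- tracr_interaction(ext, scaffold, backend)
    data.frame(mfe = mfe(full, backend),
               seed_unpaired = seed_unpaired_probability(full, seed, W,
                                                         backend),
               tracr_interaction_avg = ti$tracr_interaction_avg,
               tracr_interaction_max = ti$tracr_interaction_max)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Load the packaged sgRNA scaffold sequence
#'
#' The chimeric crRNA-tracrRNA scaffold of the standard SpCas9 expression
#' construct (pX330-style), shipped as a FASTA file.
#'
#' @param path Optional FASTA path overriding the packaged default.
#' @return Scaffold sequence string (DNA alphabet).
#' @export
load_scaffold <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scaffold_px330.fa", package = "crispreff")
  }
  lines <- readLines(path)
  normalize_seq(paste(lines[!grepl("^>", lines)], collapse = ""))
}

# ---- external (ViennaRNA) backend helpers -------------------------------

run_rnafold <- function(input, args = character()) {
  out <- tryCatch(
    system2("RNAfold", args = c(args, "--noPS"), input = input,
            stdout = TRUE, stderr = FALSE),
    error = function(e) stop("external folding backend unavailable: ",
                             conditionMessage(e)))
  out
}

parse_energy <- function(lines, open = "(", close = ")") {
  ln <- lines[grepl(paste0("\\", open, " *-?[0-9.]+ *\\", close, "$"),
                    lines)][1]
  as.numeric(sub(paste0(".*\\", open, " *(-?[0-9.]+) *\\", close, "$"),
                 "\\1", ln))
}

rnafold_mfe <- function(seq) {
  parse_energy(run_rnafold(seq))
}

rnafold_bpp <- function(seq) {
  dir <- tempfile("rnafold")
  dir.create(dir)
  old <- setwd(dir)
  on.exit({setwd(old); unlink(dir, recursive = TRUE)})
  run_rnafold(paste0(">q\n", seq), args = "-p")
  ps <- readLines("q_dp.ps")
  ub <- grep(" ubox$", ps, value = TRUE)
  ub <- ub[grepl("^[0-9]", ub)]
  n <- nchar(seq)
  p <- matrix(0, n, n)
  if (length(ub) > 0) {
    f <- do.call(rbind, lapply(strsplit(ub, " +"), function(x) {
      as.numeric(x[1:3])
    }))
    p[f[, 1:2, drop = FALSE]] <- f[, 3]^2
    p[f[, 2:1, drop = FALSE]] <- f[, 3]^2
  }
  p
}

rnafold_unpaired <- function(seq, span) {
  # free-energy route: p(unpaired) = exp(-(F_constrained - F) / RT)
  n <- nchar(seq)
  cons <- rep(".", n)
  cons[span[1]:span[2]] <- "x"
  f_free <- parse_energy(run_rnafold(seq, args = "-p0"), "[", "]")
  f_cons <- parse_energy(
    run_rnafold(paste0(seq, "\n", paste(cons, collapse = "")),
                args = c("-p0", "-C")), "[", "]")
  RT <- 0.0019872 * (273.15 + 37)
  exp(-(f_cons - f_free) / RT)
}
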