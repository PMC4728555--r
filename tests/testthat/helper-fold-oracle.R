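# Exhaustive-enumeration oracle for the nested-structure thermodynamic
# model: every valid nested structure (Watson-Crick + GU pairs, minimum
# hairpin loop 3) is listed explicitly and Boltzmann-weighted. Feasible to
# sequence length ~18. Independent of the package's DP engine.

oracle_pair_energy <- function(a, b, en) {
  key <- paste0(sort(c(a, b)), collapse = "")
  switch(key, "CG" = en[["GC"]], "AU" = en[["AU"]], "GU" = en[["GU"]],
         NA_real_)
}

# all structures over chars[i..j] as 2-column pair matrices
oracle_structures <- function(chars, en) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j) # i unpaired
    for (k in (i + 4):j) {
      if (is.na(oracle_pair_energy(chars[i], chars[k], en))) next
      left <- rec(i + 1, k - 1)
      right <- if (k + 1 <= j) rec(k + 1, j) else
        list(matrix(integer(0), 0, 2))
      for (L in left) for (R in right) {
        out <- c(out, list(rbind(c(i, k), L, R)))
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, length(chars))
}

# Boltzmann-exact ensemble quantities by direct summation
oracle_ensemble <- function(seq, en = c(GC = -3, AU = -2, GU = -1),
                            temperature = 37) {
  RT <- 0.0019872 * (273.15 + temperature)
  chars <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  n <- length(chars)
  structs <- oracle_structures(chars, en)
  energies <- vapply(structs, function(s) {
    if (nrow(s) == 0) return(0)
    sum(vapply(seq_len(nrow(s)), function(r) {
      oracle_pair_energy(chars[s[r, 1]], chars[s[r, 2]], en)
    }, numeric(1)))
  }, numeric(1))
  w <- exp(-energies / RT)
  Z <- sum(w)
  P <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    m <- structs[[s]]
    if (nrow(m) > 0) {
      P[m] <- P[m] + w[s]
      P[m[, 2:1, drop = FALSE]] <- P[m[, 2:1, drop = FALSE]] + w[s]
    }
  }
  list(Z = Z, P = P / Z, mfe = min(energies), structures = structs,
       weights = w,
       unpaired = function(span) {
       keep <- vapply(structs, function(m) {
         nrow(m) == 0 || !any(m %in% span[1]:span[2])
       }, logical(1))
       sum(w[keep]) / Z
     })
}
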