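# exact minP adjustment by enumerating every label assignment
minp_exhaustive <- function(m, n1) {
  n <- nrow(m)
  combos <- utils::combn(n, n1)
  pos_p <- function(idx) {
    vapply(seq_len(ncol(m)), function(p) {
      c1 <- tabulate(factor(m[idx, p], levels = nucleotides()), 4)
      c2 <- tabulate(factor(m[-idx, p], levels = nucleotides()), 4)
      chisq_position(c1, c2)$p
    }, numeric(1))
  }
  obs_p <- pos_p(seq_len(n1))
  min_p <- apply(combos, 2, function(idx) min(pos_p(idx)))
  list(p_raw = obs_p,
       p_exact = vapply(obs_p, function(p) mean(min_p <= p + 1e-12),
                        numeric(1)))
}
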