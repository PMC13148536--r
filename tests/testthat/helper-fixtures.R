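# shared fixtures built in code

# paste codons into a CDS string, appending a stop
make_cds <- function(...) paste0(paste0(c(...), collapse = ""), "TAA")

# a deterministic full classification whose optimal codons are the
# generator's designated ones (delta +0.5 on the optimal codon, the
# remainder spread evenly over its sisters so per-aa deltas sum to zero)
fixture_classification <- function(trna = NULL) {
  des <- designate_codons()
  delta <- dplyr::filter(codon_table(), degenerate) |>
    dplyr::left_join(des, by = "aa") |>
    dplyr::mutate(delta = ifelse(codon == optimal,
                                 0.5, -0.5 / (degeneracy - 1))) |>
    dplyr::select(codon, aa, degeneracy, delta)
  cls <- assign_optimal(delta)
  if (!is.null(trna)) cls <- trna_status(cls, trna)
  cls
}

# independent brute-force RSCU for one amino acid's codon counts
oracle_rscu <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(rep(NA_real_, length(counts)))
  unname(length(counts) * counts / total)
}

# independent brute-force tau
oracle_tau <- function(x) {
  s <- 0
  for (v in x) s <- s + (1 - v / max(x))
  s / (length(x) - 1)
}

# independent Mann-Whitney U for the first sample: count pairs a > b,
# ties as one half
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    if (ai > bj) u <- u + 1 else if (ai == bj) u <- u + 0.5
  }
  u
}
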