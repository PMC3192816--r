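# shared fixtures and small utilities for the suite

toy_trna <- function(g = c(3L, 1L)) {
  data.frame(id = seq_along(g),
             label = paste0("sp", seq_along(g)),
             anticodon = NA_character_,
             amino_acid = rep("X", length(g)),
             gene_copy_number = g)
}

# a minimal finite-recharging system fully under test control
toy_system <- function(L = 20, copies = 2, S = 2, T_counts = c(30L, 10L),
                       V = c(15, 5), K = 5, kappa = 0.2, w = 3,
                       alpha = 0.5, beta = 20, species = NULL) {
  if (is.null(species)) {
    species <- rep(seq_len(S), length.out = L)
  }
  make_system_manual(
    list(list(name = "toy", species = as.integer(species),
              copies = as.integer(copies))),
    T_counts = T_counts, V = V, K = K, kappa = kappa, w = w,
    alpha = alpha, beta = beta)
}

total_variation <- function(emp, pi) {
  keys <- union(names(emp), names(pi))
  gv <- function(v) ifelse(is.na(v[keys]), 0, v[keys])
  0.5 * sum(abs(gv(emp) - gv(pi)))
}

# mean reader density upstream vs downstream of a bottleneck position
lr_imbalance <- function(profile, center, gap = 1) {
  left <- mean(profile$reader_density[seq_len(center - gap)])
  right <- mean(profile$reader_density[(center + gap):nrow(profile)])
  left / right
}

# check the extended-particle exclusion invariant on a final configuration
gaps_ok <- function(pos_list, w) {
  all(vapply(pos_list, function(p) {
    length(p) < 2 || all(diff(sort(p)) >= w)
  }, logical(1)))
}

extdata_trna <- function() load_trna_table(rt_extdata("trna_synthetic.tsv"))
extdata_map <- function(trna = extdata_trna())
  load_codon_map(rt_extdata("codon_map_synthetic.tsv"), trna)
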