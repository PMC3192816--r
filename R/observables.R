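#' Assemble steady-state observables from raw engine accumulators
#'
#' Turns the engine's time-weighted integrals into the measured quantities:
#' per-mRNA currents (terminations per mRNA copy per second), reader and
#' coverage density profiles, per-tRNA charging levels, per-site hop rates,
#' and the global ribosomes-per-codon. Densities are time-weighted (dwell
#' integrals), matching CTMC stationary expectations. Standard errors are
#' block averages over the measurement window.
#'
#' @param raw list returned by the compiled engine.
#' @param system the `rt_system` that was simulated.
#' @param burn_in burn-in used (for the record).
#' @param seed seed used (for the record).
#' @return an `rt_observables` list with elements `species` (per-mRNA
#'   summary), `profiles` (per-mRNA data.frames with `position`,
#'   `reader_density`, `coverage_density`, `hop_rate`), `charging` (per-tRNA
#'   `c` and `c_se`), `ribosomes_per_codon`, `measure`, `n_events`, and the
#'   final microstate.
#' @export
assemble_observables <- function(raw, system, burn_in = NA, seed = NA) {
  measure <- raw$measure
  nb <- raw$n_blocks
  w <- system$w
  R <- length(system$mrnas)
  names_r <- vapply(system$mrnas, function(m) m$name, character(1))
  copies <- vapply(system$mrnas, function(m) m$copies, numeric(1))
  block_len <- measure / nb

  profiles <- vector("list", R)
  J <- J_se <- rho <- rho_cov <- numeric(R)
  terms <- numeric(R)
  for (r in seq_len(R)) {
    L <- length(system$mrnas[[r]]$species)
    occ <- raw$occupancy[[r]] / (measure * copies[r])  # reader density per site
    cov <- coverage_from_reader(occ, w)
    hop <- raw$hops[[r]] / (measure * copies[r])
    profiles[[r]] <- data.frame(position = seq_len(L),
                                reader_density = occ,
                                coverage_density = cov,
                                hop_rate = hop)
    terms[r] <- sum(raw$term_blocks[r, ])
    J[r] <- terms[r] / (measure * copies[r])
    jb <- raw$term_blocks[r, ] / (block_len * copies[r])
    J_se[r] <- stats::sd(jb) / sqrt(nb)
    rho[r] <- mean(occ)
    rho_cov[r] <- mean(cov)
  }
  names(profiles) <- names_r

  Tc <- system$trna$T
  c_mean <- rowSums(raw$a_int_blocks) / (measure * Tc)
  cb <- sweep(raw$a_int_blocks / block_len, 1, Tc, "/")
  c_se <- apply(cb, 1, stats::sd) / sqrt(nb)
  charging <- data.frame(species_id = system$trna$id,
                         label = system$trna$label,
                         T = Tc, c = c_mean, c_se = c_se)

  rib_total_blocks <- colSums(raw$rib_blocks) / block_len  # mean bound ribosomes per block
  rpc_blocks <- rib_total_blocks / system$N
  structure(list(
    species = data.frame(name = names_r,
                         L = vapply(system$mrnas, function(m) length(m$species), numeric(1)),
                         copies = copies,
                         terminations = terms,
                         J = J, J_se = J_se,
                         reader_density = rho,
                         coverage_density = rho_cov),
    profiles = profiles,
    charging = charging,
    ribosomes_per_codon = mean(rpc_blocks),
    ribosomes_per_codon_se = stats::sd(rpc_blocks) / sqrt(nb),
    measure = measure,
    burn_in = burn_in,
    seed = seed,
    n_events = raw$n_events,
    final = list(a = raw$final_a, b = raw$final_b, pos = raw$final_pos),
    state_time = raw$state_time
  ), class = "rt_observables")
}

#' Coverage density profile from a reader density profile
#'
#' A ribosome reading codon `k` covers codons `k - w + 1 ... k` (reader =
#' rightmost covered codon, body overhanging leftward on entry), so site `j`
#' is covered whenever a reader sits in `j ... j + w - 1`:
#' `rho_cov(j) = sum_{k=j}^{min(j+w-1, L)} rho(k)`.
#'
#' @param reader per-site reader density.
#' @param w ribosome width in codons.
#' @return per-site coverage density.
#' @export
coverage_from_reader <- function(reader, w) {
  L <- length(reader)
  vapply(seq_len(L), function(j)
    sum(reader[j:min(j + w - 1, L)]), numeric(1))
}

#' Current from termination counts
#'
#' `J_r = terminations / (measure_time * m_r)`: proteins per mRNA copy per
#' second, equal in steady state to the mean hop rate past any site of the
#' lattice.
#'
#' @param terminations number of termination events for the mRNA species.
#' @param measure_time measurement window (s).
#' @param copies number of mRNA copies `m_r`.
#' @return the current (1/s).
#' @export
current_from_terminations <- function(terminations, measure_time, copies) {
  if (measure_time <= 0) stop("measurement window must be positive")
  terminations / (measure_time * copies)
}

#' Charging levels from charged-pool time integrals
#'
#' `c_i = <a_i>_t / T_i`, the time-averaged fraction of species-i tRNAs that
#' are aminoacylated.
#'
#' @param a_integral per-species integral of `a_i` over the window.
#' @param measure_time window length (s).
#' @param T_counts per-species totals.
#' @return numeric vector of charging levels in `[0, 1]`.
#' @export
charging_levels <- function(a_integral, measure_time, T_counts) {
  if (measure_time <= 0) stop("measurement window must be positive")
  a_integral / (measure_time * T_counts)
}

#' @method print rt_observables
#' @export
print.rt_observables <- function(x, ...) {
  cat("ribotraffic observables (measure =", x$measure, "s,",
      format(x$n_events, big.mark = ","), "events)\n")
  df <- x$species
  df$J <- signif(df$J, 4); df$J_se <- signif(df$J_se, 2)
  df$reader_density <- signif(df$reader_density, 3)
  df$coverage_density <- signif(df$coverage_density, 3)
  print(df, row.names = FALSE)
  cat("ribosomes per codon:", signif(x$ribosomes_per_codon, 3),
      "+/-", signif(x$ribosomes_per_codon_se, 2), "\n")
  cat("min charging level:",
      signif(min(x$charging$c), 3), "(",
      x$charging$label[which.min(x$charging$c)], ")\n")
  invisible(x)
}
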