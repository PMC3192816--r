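#' Default simulation configuration
#'
#' Literature-derived defaults for a budding-yeast-proportioned system. The
#' simulation is a scaled-down cell: the ratio of total tRNAs to total codons,
#' the enzymes-per-tRNA ratio and the effective volume are matched to the cell
#' so that all intensive quantities (hopping rates, charging rates per tRNA,
#' critical initiation rates) are unchanged by the reduction.
#'
#' Values and provenance:
#' \describe{
#'   \item{w = 10}{ribosome footprint in codons (~30 nt protected).}
#'   \item{k_mean_target = 10 /s}{mean codon translation rate; fixes the
#'     proportionality constant kappa of the hopping rate k_i = kappa * a_i.}
#'   \item{cell_codons = 4e6, cell_trnas = 3e6}{total ORF codons on the
#'     transcriptome and total tRNA molecules of a typical yeast cell; their
#'     ratio (0.75 tRNAs per codon) is what the simulation preserves.}
#'   \item{cell_volume_L = 4.2e-14}{42 fL cell volume; the effective volume of
#'     a simulation with N codons is cell_volume * N / cell_codons.}
#'   \item{kcat = 5 /s, km_conc_M = 3e-7}{uniform synthetase turnover number
#'     and Michaelis constant (an average over measured synthetases; all
#'     enzymes are assumed identical).}
#'   \item{enzymes_per_trna = 0.1}{synthetase molecules per tRNA molecule,
#'     from proteome-wide abundance estimates.}
#'   \item{burn_in = 200 s, measure = 400 s}{default schedule; long enough
#'     that the first and second half of the measurement window agree for the
#'     packaged fixtures.}
#' }
#'
#' @param ... named overrides for any field.
#' @return a named list of configuration values.
#' @export
#' @examples
#' cfg <- default_config(k_mean_target = 8)
#' cfg$k_mean_target
default_config <- function(...) {
  cfg <- list(
    w = 10L,
    k_mean_target = 10,
    trna_per_codon_ratio = 3e6 / 4e6,
    cell_codons = 4e6,
    cell_trnas = 3e6,
    cell_volume_L = 4.2e-14,
    kcat = 5,
    km_conc_M = 3e-7,
    enzymes_per_trna = 0.1,
    beta = NULL,                 # default: 2 * max fully-charged hop rate
    kappa_weighting = "species", # "species" (unweighted) or "usage"
    burn_in = 200,
    measure = 400,
    n_blocks = 5L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

AVOGADRO <- 6.02214076e23

#' Allocate a tRNA total across species proportionally to gene copy number
#'
#' Splits `T_tot` molecules over species with weights `g` (gene copy numbers)
#' using largest-remainder rounding, so that the total is met exactly and
#' every species receives at least one molecule.
#'
#' @param g positive per-species gene copy numbers.
#' @param T_tot total number of tRNA molecules to distribute.
#' @return integer vector of per-species counts summing to `T_tot`.
#' @export
#' @examples
#' allocate_trna_counts(c(3, 1), 100)   # 75, 25
allocate_trna_counts <- function(g, T_tot) {
  if (any(g <= 0)) stop("gene copy numbers must be positive")
  T_tot <- as.integer(round(T_tot))
  if (T_tot <= 0) stop("T_tot must be positive")
  S <- length(g)
  if (T_tot < S) stop("T_tot (", T_tot, ") is smaller than the number of species (",
                      S, "); cannot give each species one molecule")
  share <- g / sum(g) * T_tot
  base <- floor(share)
  rem <- T_tot - sum(base)
  if (rem > 0) {
    # stable largest-remainder: ties broken by species order
    idx <- order(-(share - base), seq_len(S))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  counts <- as.integer(base)
  # enforce the >= 1 floor by taking from the most abundant species
  while (any(counts == 0)) {
    donor <- which.max(counts)
    recip <- which(counts == 0)[1]
    counts[donor] <- counts[donor] - 1L
    counts[recip] <- 1L
    if (counts[donor] <= 0) stop("cannot satisfy the one-molecule floor")
  }
  stopifnot(sum(counts) == T_tot)
  counts
}

#' Calibrate the hopping-rate constant
#'
#' The hopping rate of a codon of species i is `kappa * a_i`, with `a_i` the
#' current charged count. `kappa` is fixed such that at full charging
#' (`a_i = T_i`) the mean hopping rate equals `k_mean_target`. By default the
#' mean is the unweighted mean over tRNA species; with `usage` weights (a
#' probability vector over species, e.g. the codon usage `f`) the mean is
#' taken over codon positions instead.
#'
#' @param T_counts per-species tRNA totals.
#' @param k_mean_target target mean hopping rate (codons/s).
#' @param usage optional per-species usage weights summing to 1.
#' @return the scalar rate constant kappa (1/s per molecule).
#' @export
#' @examples
#' calibrate_kappa(c(50, 150), 10)  # mean count 100 -> kappa = 0.1
calibrate_kappa <- function(T_counts, k_mean_target, usage = NULL) {
  if (k_mean_target <= 0) stop("k_mean_target must be positive")
  if (sum(T_counts) <= 0) stop("total tRNA count must be positive")
  if (is.null(usage)) {
    k_mean_target * length(T_counts) / sum(T_counts)
  } else {
    if (abs(sum(usage) - 1) > 1e-8) stop("usage weights must sum to 1")
    k_mean_target / sum(usage * T_counts)
  }
}

#' Synthetase kinetics from cell-proportioned ratios
#'
#' Computes, per tRNA species, the enzyme copy number `E_i` (at least one
#' molecule), the maximum recharging rate `V_i = kcat * E_i`, and the
#' Michaelis constant in molecule units `K_i = km_conc * N_A * v_eff`. A
#' single `kcat` and `km_conc` are used for all species (uniform-synthetase
#' assumption).
#'
#' @param kcat synthetase turnover number (1/s).
#' @param enzymes_per_trna enzyme molecules per tRNA molecule.
#' @param T_counts per-species tRNA totals.
#' @param km_conc Michaelis constant as a molar concentration (mol/L).
#' @param v_eff_L effective simulation volume in litres.
#' @return list with integer `E`, numeric `V` and `K` (same `K` for all).
#' @export
#' @examples
#' enzyme_kinetics(1, 0.1, c(100, 200), 1e-6, 1e-15)
enzyme_kinetics <- function(kcat, enzymes_per_trna, T_counts, km_conc, v_eff_L) {
  if (kcat <= 0 || enzymes_per_trna <= 0 || km_conc <= 0 || v_eff_L <= 0)
    stop("all kinetic inputs must be positive")
  E <- pmax(1L, as.integer(round(enzymes_per_trna * T_counts)))
  V <- kcat * E
  K <- rep(km_conc * AVOGADRO * v_eff_L, length(T_counts))
  list(E = E, V = V, K = K)
}

#' Assemble a simulation system
#'
#' Combines a set of mRNA species with a tRNA table and a configuration into
#' a fully parameterized system: per-species tRNA totals allocated from gene
#' copy numbers, the hopping constant kappa calibrated to the target mean
#' rate, and synthetase kinetics scaled through the effective volume. The
#' tRNA total is `round(trna_per_codon_ratio * N)` with `N` the total number
#' of codons actually present (sum over mRNA copies), so doubling the system
#' size doubles all extensive quantities and leaves the intensive physics
#' unchanged.
#'
#' @param mrnas list of mRNA species; each a list with `name`, `species`
#'   (integer vector of tRNA species ids per codon), `copies`, and optionally
#'   `codons` (character codons) and per-species `alpha`/`beta`.
#' @param trna tRNA table as returned by [load_trna_table()] (columns `id`,
#'   `label`, `amino_acid`, `gene_copy_number`).
#' @param alpha initiation rate (1/s), applied to every mRNA species that
#'   does not carry its own.
#' @param config configuration list from [default_config()].
#' @param n_codons_ref optional reference codon count used for the
#'   tRNA-total, enzyme and volume scaling instead of the actual `N`; used
#'   when several systems (e.g. two cell-cycle phases) must share one tRNA
#'   pool sized on their average.
#' @return an object of class `rt_system`.
#' @export
build_system <- function(mrnas, trna, alpha, config = default_config(),
                         n_codons_ref = NULL) {
  stopifnot(is.list(mrnas), length(mrnas) >= 1)
  w <- as.integer(config$w)
  for (m in mrnas) {
    if (is.null(m$name) || is.null(m$species) || is.null(m$copies))
      stop("each mRNA needs fields name, species, copies")
    if (length(m$species) < w)
      stop("mRNA ", m$name, " is shorter (", length(m$species),
           " codons) than the ribosome width w = ", w)
    if (m$copies < 1) stop("mRNA ", m$name, " has copy number < 1")
    if (any(m$species < 1) || any(m$species > nrow(trna)))
      stop("mRNA ", m$name, " references an unknown tRNA species id")
  }
  N <- sum(vapply(mrnas, function(m) m$copies * length(m$species), numeric(1)))
  N_ref <- if (is.null(n_codons_ref)) N else n_codons_ref
  T_tot <- as.integer(round(config$trna_per_codon_ratio * N_ref))
  T_counts <- allocate_trna_counts(trna$gene_copy_number, T_tot)

  usage <- NULL
  if (identical(config$kappa_weighting, "usage")) {
    cnt <- codon_counts(mrnas, nrow(trna))
    usage <- cnt / sum(cnt)
  }
  kappa <- calibrate_kappa(T_counts, config$k_mean_target, usage = usage)

  v_eff <- config$cell_volume_L * N_ref / config$cell_codons
  kin <- enzyme_kinetics(config$kcat, config$enzymes_per_trna, T_counts,
                         config$km_conc_M, v_eff)

  beta <- config$beta
  if (is.null(beta)) beta <- 2 * max(kappa * T_counts)
  if (beta <= alpha)
    warning("termination rate beta (", signif(beta, 3),
            ") is not larger than alpha; termination may become limiting")

  mrnas <- lapply(mrnas, function(m) {
    if (is.null(m$alpha)) m$alpha <- alpha
    if (is.null(m$beta)) m$beta <- beta
    m
  })

  trna$T <- T_counts
  trna$E <- kin$E
  trna$V <- kin$V
  trna$K <- kin$K

  structure(list(
    mrnas = mrnas,
    trna = trna,
    kappa = kappa,
    w = w,
    N = N,
    T_tot = T_tot,
    v_eff_L = v_eff,
    config = config
  ), class = "rt_system")
}

# total number of codons of each tRNA species over all mRNA copies
codon_counts <- function(mrnas, S) {
  cnt <- numeric(S)
  for (m in mrnas) {
    tab <- tabulate(m$species, nbins = S)
    cnt <- cnt + m$copies * tab
  }
  cnt
}

#' @method print rt_system
#' @export
print.rt_system <- function(x, ...) {
  cat("ribotraffic system:", length(x$mrnas), "mRNA species,",
      x$N, "codons,", x$T_tot, "tRNAs over", nrow(x$trna), "species\n")
  cat("  kappa =", signif(x$kappa, 4), "/s per molecule; w =", x$w, "codons\n")
  for (m in x$mrnas)
    cat("  ", m$name, ": L =", length(m$species), ", copies =", m$copies,
        ", alpha =", signif(m$alpha, 3), ", beta =", signif(m$beta, 3), "\n")
  invisible(x)
}
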