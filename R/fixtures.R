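# Synthetic packaged fixtures: surrogate yeast-like ORFs and preset systems.
# The real supplementary sequences are not redistributable here, so these
# transcripts are synthetic constructions that reproduce the documented
# structure of the study systems: lengths, one dominant high-demand codon
# type with clusters around site ~80 (mRNA A), rare slow codons at wide
# separations (mRNA B), and the cell-cycle High/Low abundance pattern.

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# one representative codon per tRNA species (first codon mapped to it)
representative_codons <- function(map) {
  S <- max(map$species_id)
  vapply(seq_len(S), function(i) map$codon[map$species_id == i][1], character(1))
}

# place `at` positions of species `special` in a background drawn from
# `pool` ids weighted by gene copy number
compose_orf <- function(name, L, special, at, trna, pool, seed) {
  sp <- integer(L)
  bg <- with_seed(seed, sample(pool, L, replace = TRUE,
                               prob = trna$gene_copy_number[pool]))
  sp[] <- bg
  sp[at] <- special
  list(name = name, species = sp)
}

#' Synthetic surrogate ORFs for the four single-species study transcripts
#'
#' Four transcripts named after the yeast genes whose roles they stand in
#' for, with the same lengths (110, 480, 87, 560 codons) and the documented
#' codon-usage structure, but synthetic sequences:
#' \describe{
#'   \item{YDR382W (A, 110)}{ribosomal-protein-like; no rare codons; one
#'     dominant codon type (a fifth of the sequence) with clusters around
#'     site 80 -- the type whose charged pool depletes first.}
#'   \item{YLR378C (B, 480)}{six copies of a rare (lowest gene-copy) codon
#'     type spread > w apart; bulk codon usage roughly supply-proportional.}
#'   \item{YJL136C (C, 87)}{like A with a different dominant type.}
#'   \item{YMR307W (D, 560)}{a few rare codons near the start and a large
#'     cluster of C's dominant type near the end.}
#' }
#'
#' @param trna,map synthetic tRNA table and codon map.
#' @return list of 4 records with `name`, `species`, `codons`.
#' @export
synthetic_orfs <- function(trna = synthetic_trna_table(),
                           map = synthetic_codon_map(trna)) {
  g <- trna$gene_copy_number
  abundant <- which(g >= 6)
  common <- which(g >= 2)
  dom_a <- which(trna$label == "Glu1")   # abundant, heavily used in A
  slow_b <- which(trna$label == "Leu5")  # rare (single gene copy)
  dom_c <- which(trna$label == "Lys2")
  rare_d <- which(trna$label == "Gln2")

  a <- compose_orf("YDR382W", 110, dom_a,
                   at = c(12, 25, 38, 51, 60, 97, 103, 108,
                          70:74, 78:82, 86:89),
                   trna, setdiff(abundant, dom_a), seed = 20111L)
  b <- compose_orf("YLR378C", 480, slow_b,
                   at = c(60, 140, 221, 300, 380, 432),
                   trna, setdiff(common, slow_b), seed = 20112L)
  cc <- compose_orf("YJL136C", 87, dom_c,
                    at = c(8, 19, 30, 41, 50, 78, 83, 55:60, 63:64),
                    trna, setdiff(abundant, dom_c), seed = 20113L)
  d0 <- compose_orf("YMR307W", 560, rare_d,
                    at = c(25, 32, 40, 48, 55, 62),
                    trna, setdiff(common, c(rare_d, dom_c)), seed = 20114L)
  d0$species[c(520:535, 200, 260, 320)] <- dom_c
  orfs <- list(a, b, cc, d0)
  rep_codon <- representative_codons(map)
  lapply(orfs, function(m) { m$codons <- rep_codon[m$species]; m })
}

#' Synthetic cell-cycle gene panel (scaled down)
#'
#' Ten "group I" genes whose abundance switches between the G1 and G2 phases
#' (High = 3 copies, Low = 1) plus twelve constitutive "group II" genes. The
#' group I length pattern and High/Low switching pattern follow the
#' cell-cycle regulator panel of the full-scale study (Cln3, Cdh1, Cdc20,
#' Clb1, Clb6, Sic1, Cln1, Cln2, Clb2, Clb5) with lengths scaled down
#' tenfold; group II abundances span a high-to-medium range so that group I
#' makes up ~15% of all codons.
#'
#' @param trna,map synthetic tables.
#' @return list with `genes` (records with `name`, `species`, `codons`),
#'   `copies_G1`, `copies_G2` (named integer vectors).
#' @export
synthetic_cellcycle_panel <- function(trna = synthetic_trna_table(),
                                      map = synthetic_codon_map(trna)) {
  g1_names <- c("Cln3", "Cdh1", "Cdc20", "Clb1", "Clb6",
                "Sic1", "Cln1", "Cln2", "Clb2", "Clb5")
  g1_len <- c(58, 57, 61, 47, 38, 29, 55, 55, 49, 44)  # Table lengths / 10
  g1_high_in_G1 <- c(TRUE, TRUE, FALSE, FALSE, TRUE,
                     TRUE, TRUE, TRUE, FALSE, TRUE)
  g2_names <- sprintf("const%02d", 1:12)
  g2_len <- rep(50L, 12)
  g2_copies <- c(20L, 18L, 16L, 14L, 12L, 10L, 8L, 6L, 5L, 4L, 3L, 2L)

  # background usage avoids the rarest tRNAs (gene copy < 3) so that the
  # phase-dependent demand, not a shared rare-codon bottleneck, sets the
  # leading critical initiation rate
  pool <- which(trna$gene_copy_number >= 3)
  heavy_species <- which(trna$label == "Glu1")
  heavy_genes <- c("Cln3", "Cdh1", "Cln1", "Cln2")  # High in G1
  genes <- with_seed(20115L, {
    mk <- function(name, L) {
      bg <- sample(pool, L, replace = TRUE,
                   prob = trna$gene_copy_number[pool])
      sp <- bg
      if (name %in% heavy_genes) {
        # cyclin-like transcripts lean heavily on one abundant codon type,
        # clustered mid-ORF, so their abundance switch moves its demand
        n_heavy <- round(0.3 * L)
        start <- floor(L / 3)
        sp[seq(start, start + n_heavy - 1)] <- heavy_species
      }
      list(name = name, species = sp,
           codons = representative_codons(map)[sp])
    }
    c(Map(mk, g1_names, g1_len), Map(mk, g2_names, g2_len))
  })
  high <- 3L; low <- 1L
  copies_G1 <- c(ifelse(g1_high_in_G1, high, low), g2_copies)
  copies_G2 <- c(ifelse(g1_high_in_G1, low, high), g2_copies)
  names(copies_G1) <- names(copies_G2) <- c(g1_names, g2_names)
  list(genes = genes, copies_G1 = copies_G1, copies_G2 = copies_G2)
}

#' Path to a packaged fixture file
#' @param ... path components under the package's extdata directory.
#' @export
rt_extdata <- function(...) {
  system.file("extdata", ..., package = "ribotraffic", mustWork = TRUE)
}

#' Preset study systems
#'
#' Ready-made `rt_system`s mirroring the study designs:
#' \describe{
#'   \item{"mrna_A" / "mrna_B" / "mrna_C" / "mrna_D"}{many copies of a
#'     single surrogate transcript, sized to ~`n_codons_target` codons with
#'     yeast-proportioned tRNA pools.}
#'   \item{"mix_AB_50", "mix_AB_20", "mix_AB_80"}{A/B mixtures at 50:50,
#'     20:80, 80:20 shares by codon count.}
#'   \item{"mix_CD_50", "mix_CD_20", "mix_CD_80"}{likewise for C/D.}
#'   \item{"cellcycle_G1" / "cellcycle_G2"}{the scaled-down 22-gene panel in
#'     either phase, sharing one tRNA pool sized on the phase-average codon
#'     count.}
#' }
#'
#' @param name preset name.
#' @param alpha initiation rate (1/s).
#' @param n_codons_target approximate total codons (single species and
#'   mixtures).
#' @param config configuration overrides.
#' @return an `rt_system`.
#' @export
fixture_system <- function(name, alpha,
                           n_codons_target = 5000,
                           config = default_config()) {
  trna <- synthetic_trna_table()
  map <- synthetic_codon_map(trna)
  orfs <- synthetic_orfs(trna, map)
  names(orfs) <- c("A", "B", "C", "D")
  single <- c(mrna_A = "A", mrna_B = "B", mrna_C = "C", mrna_D = "D")
  if (name %in% names(single)) {
    m <- orfs[[single[[name]]]]
    m$copies <- max(1L, as.integer(round(n_codons_target / length(m$species))))
    return(build_system(list(m), trna, alpha = alpha, config = config))
  }
  if (grepl("^mix_", name)) {
    parts <- strsplit(name, "_")[[1]]
    pair <- strsplit(parts[2], "")[[1]]
    share1 <- as.numeric(parts[3]) / 100
    mix <- make_mixture(orfs[pair], c(share1, 1 - share1), n_codons_target)
    return(build_system(mix, trna, alpha = alpha, config = config))
  }
  if (name %in% c("cellcycle_G1", "cellcycle_G2")) {
    panel <- synthetic_cellcycle_panel(trna, map)
    copies <- if (name == "cellcycle_G1") panel$copies_G1 else panel$copies_G2
    genes <- Map(function(g, k) { g$copies <- k; g },
                 panel$genes, copies[vapply(panel$genes, `[[`, "", "name")])
    len <- vapply(panel$genes, function(g) length(g$species), numeric(1))
    n_avg <- mean(c(sum(len * panel$copies_G1), sum(len * panel$copies_G2)))
    return(build_system(genes, trna, alpha = alpha, config = config,
                        n_codons_ref = n_avg))
  }
  stop("unknown preset: ", name)
}

#' Uniform mono-codon preset
#'
#' A single-tRNA-species system (every codon identical): the exactly
#' analysable base case. Thirty copies of a 150-codon transcript (4500
#' codons), tRNA pool at the cell ratio (T = 3375), kappa set so the
#' fully-charged hopping rate is 10 codons/s, synthetase kinetics from the
#' default ratios. Its LD current and density follow the uniform-lattice
#' closed forms, and its depletion onset follows the mono-codon critical
#' initiation rate.
#'
#' @param alpha initiation rate (1/s).
#' @return an `rt_system`.
#' @export
fixture_mono <- function(alpha) {
  cfg <- default_config()
  L <- 150L; m <- 30L
  N <- L * m
  T1 <- as.integer(round(cfg$trna_per_codon_ratio * N))
  v_eff <- cfg$cell_volume_L * N / cfg$cell_codons
  kin <- enzyme_kinetics(cfg$kcat, cfg$enzymes_per_trna, T1,
                         cfg$km_conc_M, v_eff)
  k <- cfg$k_mean_target
  make_system_manual(
    list(list(name = "mono", species = rep(1L, L), copies = m)),
    T_counts = T1, V = kin$V, K = kin$K, kappa = k / T1, w = cfg$w,
    alpha = alpha, beta = 2 * k)
}

#' Designer-transcript presets for the three queueing regimes
#'
#' Two-codon-species systems built so that a different route to queueing has
#' the smallest threshold in each: depletion of the central species' charged
#' pool ("LR1", slow central synthetase), the fixed-rate queueing phase
#' behind the central site ("QP", fast synthetases, rare central tRNA), or
#' depletion of the bulk species with no queueing ("LR2", the bulk codons
#' are the slow ones). `alpha_probe` is an initiation rate above the
#' regime's threshold but below the competing ones, suitable for exhibiting
#' the regime in simulation.
#'
#' @param regime one of "LR1", "QP", "LR2".
#' @return list with `system` (at `alpha = alpha_probe`), `alpha_probe`, and
#'   the classifier output `classification`.
#' @export
fixture_designer <- function(regime = c("LR1", "QP", "LR2")) {
  regime <- match.arg(regime)
  L <- 51L; m <- 40L; w <- 10L
  mk <- function(T_counts, V, alpha) {
    mr <- make_designer_mrna(L, 1L, 2L, copies = m, w = w)
    make_system_manual(list(mr), T_counts = T_counts, V = V, K = 10,
                       kappa = 0.01, w = w, alpha = alpha,
                       beta = 2 * 0.01 * max(T_counts))
  }
  sys <- switch(regime,
    # central pool depletes first: tiny V for species 2
    LR1 = mk(c(1500L, 40L), V = c(750, 0.3), alpha = 0.012),
    # fixed-rate bottleneck first: generous V everywhere, rare central tRNA
    QP  = mk(c(1500L, 40L), V = c(750, 50), alpha = 0.45),
    # bulk pool depletes first: bulk tRNA rare and slow to recharge
    LR2 = mk(c(200L, 1840L), V = c(3, 920), alpha = 0.003))
  list(system = sys, alpha_probe = sys$mrnas[[1]]$alpha,
       classification = classify_designer_regime(sys))
}
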