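#' Supply, demand and the queueing propensity Q
#'
#' For each tRNA species i: the supply `sigma_i = T_i / T_tot` (the species'
#' share of the tRNA pool, i.e. the intrinsic relative speed of its codons at
#' full charging), the demand `f_i = sum_r m_r n_{i,r} / sum_r m_r L_r` (the
#' species' share of all codons on all mRNA copies), and their ratio
#' `Q_i = f_i / sigma_i` -- a codon type's propensity to deplete its charged
#' pool and cause queueing. Both sigma and f sum to 1; unused species have
#' `f_i = 0`.
#'
#' @param system an `rt_system`.
#' @return data.frame with `species_id`, `label`, `T`, `counts` (total codons
#'   of the species over all copies), `sigma`, `f`, `Q`.
#' @export
supply_demand <- function(system) {
  Tc <- system$trna$T
  cnt <- codon_counts(system$mrnas, nrow(system$trna))
  sigma <- Tc / sum(Tc)
  f <- cnt / sum(cnt)
  data.frame(species_id = system$trna$id,
             label = system$trna$label,
             T = Tc,
             counts = cnt,
             sigma = sigma,
             f = f,
             Q = f / sigma)
}

#' Low-density closed forms for a uniform lattice of extended particles
#'
#' For a uniform (single hopping rate `k`) lattice with entry rate `alpha`
#' and particles of width `w`, the entry-limited (LD) steady state has
#' current `J = alpha (k - alpha) / (k + (w - 1) alpha)` and reader density
#' `rho = alpha / (k + (w - 1) alpha)`; the coverage density is `w * rho`.
#' The LD branch holds for `alpha <= k / (1 + sqrt(w))`, beyond which the
#' system is in the maximal-current phase with `J_MC = k / (1 + sqrt(w))^2`.
#'
#' @param alpha initiation rate (1/s).
#' @param k uniform hopping rate (1/s).
#' @param w particle width (codons).
#' @return list with `J`, `rho`, `rho_cov`, `ld_valid` (is alpha on the LD
#'   branch), `alpha_max_ld`, `J_mc`.
#' @export
#' @examples
#' ld_theory(0.1, 10, 10)$J
ld_theory <- function(alpha, k, w) {
  stopifnot(k > 0, w >= 1)
  J <- alpha * (k - alpha) / (k + (w - 1) * alpha)
  rho <- alpha / (k + (w - 1) * alpha)
  alpha_max <- k / (1 + sqrt(w))
  list(J = J, rho = rho, rho_cov = w * rho,
       ld_valid = alpha <= alpha_max,
       alpha_max_ld = alpha_max,
       J_mc = k / (1 + sqrt(w))^2)
}

# smaller root of alpha^2 - (k - (w-1) Jt) alpha + Jt k = 0, i.e. the alpha
# at which the LD current equals Jt; NA if the LD branch never reaches Jt
ld_alpha_for_current <- function(Jt, k, w) {
  B <- k - (w - 1) * Jt
  disc <- B^2 - 4 * Jt * k
  if (disc < 0) return(NA_real_)
  (B - sqrt(disc)) / 2
}

#' Critical initiation rates for charged-tRNA depletion
#'
#' In the LD regime all pools are nearly fully charged and the current
#' through every mRNA is approximated by the uniform-lattice closed form
#' evaluated at the position-averaged supply: `kbar = kappa * T_tot *
#' <sigma_s(j)>` (arithmetic mean over codon positions; a harmonic variant is
#' available). The use rate of species i is then `U_i(alpha) = J(alpha) *
#' C_i` with `C_i = sum_r m_r n_{i,r}` the total number of its codons, and
#' the maximum recharging rate is `R_i = V_i T_i / (K_i + T_i)` (the
#' Michaelis-Menten rate with the whole pool bare). The critical initiation
#' rate `alpha_c,i` solves `U_i = R_i` in closed form (the smaller quadratic
#' root); species whose use rate never reaches `R_i` anywhere on the LD
#' branch can never be depleted there and get `alpha_c,i = Inf`. The overall
#' `alpha_c = min_i alpha_c,i`, attained by the predicted bottleneck species.
#' To first order in small alpha, `alpha_c,i ~ R_i / C_i`, which with
#' enzyme numbers proportional to tRNA numbers is proportional to `1/Q_i`.
#'
#' @param system an `rt_system` with populated kinetics.
#' @param averaging `"arithmetic"` (default) or `"harmonic"` site-average of
#'   the supply.
#' @return data.frame per tRNA species with `sigma`, `f`, `Q`, `U_slope`
#'   (`C_i`), `R_max`, `alpha_c` and `alpha_c_first_order`; attributes
#'   `alpha_c` (the minimum), `bottleneck` (label), `k_bar`, `alpha_max_ld`.
#' @export
critical_alphas <- function(system, averaging = c("arithmetic", "harmonic")) {
  averaging <- match.arg(averaging)
  sd <- supply_demand(system)
  used <- sd$f > 0
  mean_sigma <- if (averaging == "arithmetic") {
    sum(sd$f[used] * sd$sigma[used])
  } else {
    1 / sum(sd$f[used] / sd$sigma[used])
  }
  kbar <- system$kappa * system$T_tot * mean_sigma
  w <- system$w
  Jmax <- kbar / (1 + sqrt(w))^2
  R_max <- system$trna$V * sd$T / (system$trna$K + sd$T)
  C <- sd$counts
  alpha_c <- rep(Inf, nrow(sd))
  first <- rep(Inf, nrow(sd))
  for (i in which(used)) {
    Jt <- R_max[i] / C[i]
    first[i] <- Jt
    if (Jt < Jmax) {
      root <- ld_alpha_for_current(Jt, kbar, w)
      if (!is.na(root)) alpha_c[i] <- root
    }
  }
  out <- data.frame(species_id = sd$species_id, label = sd$label,
                    sigma = sd$sigma, f = sd$f, Q = sd$Q,
                    U_slope = C, R_max = R_max,
                    alpha_c = alpha_c, alpha_c_first_order = first)
  amin <- min(alpha_c)
  attr(out, "alpha_c") <- amin
  attr(out, "bottleneck") <-
    if (is.finite(amin)) sd$label[which.min(alpha_c)] else NA_character_
  attr(out, "k_bar") <- kbar
  attr(out, "alpha_max_ld") <- kbar / (1 + sqrt(w))
  out
}

#' Queueing-phase threshold for a single fixed slow site
#'
#' For the fixed-rate exclusion process (no recharging) with bulk hopping
#' rate `k`, particle width `w` and one interior defect site with rate
#' `q <= k`, ribosomes queue behind the defect once the entry-limited current
#' exceeds the maximal current the defect can carry. That capacity is
#' estimated from the jammed renewal cycle -- the waiting ribosome hops out
#' of the defect at rate `q` and its follower then needs `w` bulk hops at
#' rate `k` to reach it -- giving `J_q = 1 / (1/q + w/k) = qk / (k + wq)`,
#' capped by the lattice's maximal current `k / (1 + sqrt(w))^2` (a weak
#' defect cannot carry more than the uniform lattice). The threshold
#' `alpha_QP` is the initiation rate at which the LD current reaches `J_q`;
#' at `q = k` the cap applies and `alpha_QP` reduces exactly to the
#' uniform-lattice LD boundary `k / (1 + sqrt(w))`.
#'
#' @param q defect-site hopping rate (1/s).
#' @param k bulk hopping rate (1/s).
#' @param w particle width.
#' @return `alpha_QP` (1/s); `Inf` when `q > k` (the site is not a
#'   bottleneck).
#' @export
qp_threshold <- function(q, k, w) {
  stopifnot(k > 0, q >= 0, w >= 1)
  if (q > k) return(Inf)
  if (q == 0) return(0)
  Jcycle <- q * k / (k + w * q)
  Jmc <- k / (1 + sqrt(w))^2
  # a weak defect cannot carry more than the uniform lattice: the threshold
  # is then the LD/MC boundary itself (returned in closed form to avoid the
  # cancellation in the quadratic root at the boundary)
  if (Jcycle >= Jmc) return(k / (1 + sqrt(w)))
  a <- ld_alpha_for_current(Jcycle, k, w)
  if (is.na(a)) Inf else min(a, k / (1 + sqrt(w)))
}

#' Classify the queueing regime of a two-codon designer mRNA
#'
#' For a designer transcript whose codons are all of a bulk tRNA species
#' except one central codon of a second species, three routes compete as the
#' initiation rate grows, each with its own threshold: depletion of the
#' central species' charged pool (`alpha_c` of the central species ->
#' smooth-onset limited-resources queueing, "LR1_queueing"), the fixed-rate
#' queueing-phase transition behind the central site (`alpha_QP` with
#' `q = kappa * T_center`, `k = kappa * T_bulk` -> sharp transition, "QP"),
#' or depletion of the bulk species (`alpha_c` of the bulk species -> a
#' limited-resources regime with no queueing, since the slow codons are the
#' bulk, "LR2_no_queueing"). The smallest threshold determines the regime.
#'
#' @param system an `rt_system` containing one designer mRNA (see
#'   [make_designer_mrna()]).
#' @return list with `region`, `alpha_c_bulk`, `alpha_c_center`, `alpha_qp`,
#'   `bulk_species`, `center_species`.
#' @export
classify_designer_regime <- function(system) {
  stopifnot(length(system$mrnas) == 1)
  sp <- system$mrnas[[1]]$species
  tab <- table(sp)
  if (length(tab) != 2)
    stop("designer classification needs exactly two codon species")
  bulk <- as.integer(names(tab)[which.max(tab)])
  center <- as.integer(names(tab)[which.min(tab)])
  ca <- critical_alphas(system)
  a_bulk <- ca$alpha_c[ca$species_id == bulk]
  a_center <- ca$alpha_c[ca$species_id == center]
  q <- system$kappa * system$trna$T[center]
  k <- system$kappa * system$trna$T[bulk]
  a_qp <- qp_threshold(q, k, system$w)
  thresholds <- c(LR1_queueing = a_center, QP = a_qp, LR2_no_queueing = a_bulk)
  region <- names(thresholds)[which.min(thresholds)]
  list(region = region,
       alpha_c_bulk = a_bulk, alpha_c_center = a_center, alpha_qp = a_qp,
       bulk_species = bulk, center_species = center)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Queueing likelihood index (QLI)
#'
#' The geometric mean, over the codon positions of an ORF, of the
#' demand/supply ratio `Q` of each codon's tRNA species. High-QLI transcripts
#' are enriched in codons whose charged pools are prone to depletion, so QLI
#' anti-correlates with adaptation indices such as CAI. Zero or undefined Q
#' values are replaced by half the smallest positive Q (logged via a
#' message).
#'
#' @param species integer vector of tRNA species ids along the ORF.
#' @param Q per-species Q values (position i of the vector = species id i),
#'   e.g. column `Q` of [supply_demand()].
#' @return the QLI (dimensionless).
#' @export
qli <- function(species, Q) {
  qs <- Q[species]
  if (anyNA(qs) || any(qs <= 0)) {
    pseudo <- 0.5 * min(Q[Q > 0], na.rm = TRUE)
    n_bad <- sum(is.na(qs) | qs <= 0)
    message("qli: ", n_bad, " codon(s) with zero/undefined Q replaced by ",
            "pseudocount ", signif(pseudo, 3))
    qs[is.na(qs) | qs <= 0] <- pseudo
  }
  geometric_mean(qs)
}

#' Relative synonymous codon usage (RSCU) and adaptiveness weights
#'
#' `RSCU_j = X_j / mean(X over the codon's synonymous family)`, with `X_j`
#' the count of codon j in a reference (highly expressed) gene set; the
#' adaptiveness weight is `RSCU_j / max(RSCU over the family)`. Zero counts
#' are replaced by a 0.5 pseudocount (logged via a message).
#'
#' @param reference_counts named numeric vector of codon counts (names are
#'   codons, DNA or RNA alphabet); sense codons missing from the vector count
#'   as zero.
#' @return data.frame with `codon`, `amino_acid`, `count`, `rscu`, `weight`.
#' @export
#' @examples
#' rscu_weights(c(GCU = 30, GCC = 10))[1:2, ]
rscu_weights <- function(reference_counts) {
  sc <- sense_codons()
  names(reference_counts) <- normalize_codons(names(reference_counts))
  x <- setNames(rep(0, nrow(sc)), sc$codon)
  known <- intersect(names(reference_counts), sc$codon)
  x[known] <- reference_counts[known]
  if (any(x == 0)) {
    message("rscu_weights: ", sum(x == 0),
            " sense codon(s) with zero reference count given pseudocount 0.5")
    x[x == 0] <- 0.5
  }
  rscu <- numeric(nrow(sc))
  weight <- numeric(nrow(sc))
  for (aa in unique(sc$amino_acid)) {
    idx <- which(sc$amino_acid == aa)
    rscu[idx] <- x[idx] / mean(x[idx])
    weight[idx] <- rscu[idx] / max(rscu[idx])
  }
  data.frame(codon = sc$codon, amino_acid = sc$amino_acid,
             count = unname(x[sc$codon]), rscu = rscu, weight = weight)
}

#' Codon adaptation index (CAI)
#'
#' The geometric mean over codon positions of the RSCU-based adaptiveness
#' weight of each codon (Sharp-Li). Codons of single-codon families (Met,
#' Trp), whose weight is identically 1, are excluded from the mean.
#'
#' @param codons character vector of codons along the ORF (DNA or RNA).
#' @param reference_counts named codon counts of a highly expressed reference
#'   gene set, or a precomputed table from [rscu_weights()].
#' @return the CAI in `(0, 1]`.
#' @export
cai <- function(codons, reference_counts) {
  wtab <- if (is.data.frame(reference_counts)) reference_counts
          else rscu_weights(reference_counts)
  codons <- normalize_codons(codons)
  fam_size <- table(wtab$amino_acid)
  multi <- wtab$amino_acid[match(codons, wtab$codon)]
  keep <- !is.na(multi) & fam_size[multi] > 1
  if (anyNA(multi)) stop("cai: codon(s) not in the sense-codon table: ",
                         paste(unique(codons[is.na(multi)]), collapse = ", "))
  w <- wtab$weight[match(codons[keep], wtab$codon)]
  if (!length(w)) stop("cai: no codons from multi-codon families")
  geometric_mean(w)
}
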