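#' Assemble a system with explicit tRNA pools and kinetics
#'
#' Low-level constructor used by the oracle micro-instances and tests:
#' instead of deriving pools and kinetics from gene copy numbers and
#' cell-proportioned ratios (as [build_system()] does), every quantity is
#' given explicitly.
#'
#' @param mrnas list of mRNA species (`name`, `species`, `copies`, and
#'   optionally `alpha`, `beta`).
#' @param T_counts per-tRNA-species totals.
#' @param V,K per-species maximum recharging rates and Michaelis constants
#'   (molecules); recycled to length S.
#' @param kappa hopping-rate constant (1/s per molecule).
#' @param w ribosome width (codons).
#' @param alpha,beta default initiation/termination rates for mRNAs that do
#'   not carry their own.
#' @return an `rt_system`.
#' @export
make_system_manual <- function(mrnas, T_counts, V, K, kappa, w,
                               alpha = NULL, beta = NULL) {
  S <- length(T_counts)
  V <- rep_len(V, S); K <- rep_len(K, S)
  mrnas <- lapply(mrnas, function(m) {
    if (is.null(m$copies)) m$copies <- 1L
    if (is.null(m$alpha)) {
      if (is.null(alpha)) stop("mRNA ", m$name, " has no alpha")
      m$alpha <- alpha
    }
    if (is.null(m$beta)) {
      if (is.null(beta)) stop("mRNA ", m$name, " has no beta")
      m$beta <- beta
    }
    m
  })
  trna <- data.frame(id = seq_len(S),
                     label = paste0("sp", seq_len(S)),
                     amino_acid = rep("X", S),
                     gene_copy_number = as.integer(pmax(1, T_counts)),
                     T = as.integer(T_counts),
                     E = NA_integer_, V = V, K = K)
  N <- sum(vapply(mrnas, function(m) m$copies * length(m$species), numeric(1)))
  structure(list(mrnas = mrnas, trna = trna, kappa = kappa, w = as.integer(w),
                 N = N, T_tot = sum(T_counts), v_eff_L = NA_real_,
                 config = default_config()),
            class = "rt_system")
}

#' Designer mRNA: uniform bulk with one distinct central codon
#'
#' A transcript of `L` codons, all of `bulk_species` except the central
#' position `ceiling(L / 2)`, which is `center_species`. With `L = 1` the
#' single codon is the central one.
#'
#' @param L length in codons.
#' @param bulk_species,center_species tRNA species ids (must differ unless
#'   `L = 1`).
#' @param copies copy number.
#' @param w if given, `L < w` is rejected (the transcript must hold at least
#'   one ribosome).
#' @param name transcript name.
#' @return an mRNA record (list with `name`, `species`, `copies`).
#' @export
#' @examples
#' make_designer_mrna(5, 1, 2)$species  # 1 1 2 1 1
make_designer_mrna <- function(L, bulk_species, center_species, copies = 1L,
                               w = NULL, name = "designer") {
  if (!is.null(w) && L < w)
    stop("designer mRNA of length ", L, " is shorter than the ribosome width ", w)
  if (L < 1) stop("L must be at least 1")
  sp <- rep(as.integer(bulk_species), L)
  sp[ceiling(L / 2)] <- as.integer(center_species)
  list(name = name, species = sp, copies = as.integer(copies))
}

#' Copy numbers for an mRNA mixture with prescribed codon shares
#'
#' Given mRNA species and target shares of the total codon count, chooses
#' integer copy numbers `m_r = share_r * N_target / L_r` (nearest rounding)
#' and reports the achieved shares.
#'
#' @param mrnas list of mRNA records (each with `species`).
#' @param shares numeric shares by codon count, summing to 1.
#' @param n_codons_target total codons aimed for.
#' @return the mRNA list with `copies` set; attributes `achieved_shares` and
#'   `n_codons`.
#' @export
#' @examples
#' a <- list(name = "A", species = rep(1, 100))
#' b <- list(name = "B", species = rep(1, 400))
#' m <- make_mixture(list(a, b), c(0.5, 0.5), 4000)
#' vapply(m, `[[`, numeric(1), "copies")  # 20 5
make_mixture <- function(mrnas, shares, n_codons_target) {
  if (abs(sum(shares) - 1) > 1e-8) stop("shares must sum to 1")
  if (length(shares) != length(mrnas)) stop("one share per mRNA species")
  L <- vapply(mrnas, function(m) length(m$species), numeric(1))
  m_r <- round(shares * n_codons_target / L)
  if (any(m_r < 1)) {
    bad <- which(m_r < 1)[1]
    stop("share ", shares[bad], " of ", n_codons_target,
         " codons gives no full copy of mRNA ", mrnas[[bad]]$name,
         " (L = ", L[bad], "); increase the share or n_codons_target to at least ",
         ceiling(L[bad] / shares[bad]))
  }
  out <- Map(function(m, k) { m$copies <- as.integer(k); m }, mrnas, m_r)
  codons <- m_r * L
  attr(out, "achieved_shares") <- codons / sum(codons)
  attr(out, "n_codons") <- sum(codons)
  out
}

#' Random gene set with tunable codon usage bias
#'
#' Generates `n_genes` ORFs whose codons are drawn from a distribution that
#' interpolates between uniform over the 61 sense codons (`bias = 0`) and
#' supply-proportional (`bias = 1`: a codon's probability is its tRNA
#' species' supply share, split evenly over the species' codons). With a
#' vector `bias`, gene g uses `bias[g]`, so one call can span the whole
#' biased-to-unbiased range. Pure function of its arguments and `seed`.
#'
#' @param n_genes number of genes.
#' @param length_range integer range of gene lengths (codons).
#' @param bias scalar or per-gene vector in `[0, 1]`.
#' @param seed RNG seed.
#' @param trna,map tRNA table and codon map (synthetic defaults).
#' @return list of gene records (`name`, `codons`, `species`, `bias`).
#' @export
make_random_gene_set <- function(n_genes, length_range = c(100, 500),
                                 bias = 0.5, seed = 1L,
                                 trna = synthetic_trna_table(),
                                 map = synthetic_codon_map(trna)) {
  stopifnot(all(bias >= 0), all(bias <= 1))
  bias <- rep_len(bias, n_genes)
  set.seed(as.integer(seed))
  sigma <- trna$gene_copy_number / sum(trna$gene_copy_number)
  sp_of_codon <- map$species_id
  codons_per_species <- tabulate(sp_of_codon, nbins = nrow(trna))
  p_supply <- sigma[sp_of_codon] / codons_per_species[sp_of_codon]
  p_supply <- p_supply / sum(p_supply)
  p_unif <- rep(1 / nrow(map), nrow(map))
  lapply(seq_len(n_genes), function(g) {
    L <- sample(length_range[1]:length_range[2], 1)
    p <- (1 - bias[g]) * p_unif + bias[g] * p_supply
    idx <- sample.int(nrow(map), L, replace = TRUE, prob = p)
    list(name = sprintf("gene%03d", g),
         codons = map$codon[idx],
         species = map$species_id[idx],
         bias = bias[g])
  })
}

# ---------------------------------------------------------------------------
# Exact CTMC enumeration oracle
# ---------------------------------------------------------------------------

# number of reader configurations on one lattice (computed before
# enumeration so oversized state spaces are rejected cheaply):
# N(start) = N(start+1) + N(start+w), N(start > L) = 1
count_configs <- function(L, w) {
  n <- rep(1, L + w + 1)
  for (start in L:1) {
    nxt <- if (start + 1 > L) 1 else n[start + 1]
    jmp <- if (start + w > L) 1 else n[start + w]
    n[start] <- nxt + jmp
  }
  n[1]
}

# all reader configurations on one lattice of length L with gaps >= w
enumerate_configs <- function(L, w) {
  memo <- vector("list", L + w + 1)
  rec <- function(start) {
    if (start > L) return(list(integer(0)))
    if (!is.null(memo[[start]])) return(memo[[start]])
    out <- list(integer(0))
    for (p in start:L) {
      for (tl in rec(p + w)) out[[length(out) + 1]] <- c(p, tl)
    }
    memo[[start]] <<- out
    out
  }
  rec(1)
}

state_key_r <- function(pos_list, a, fixed_rates) {
  join <- function(v) if (length(v)) paste0(paste(v, collapse = ","), ",") else ""
  key <- paste0(vapply(pos_list, function(p) paste0("L", join(p)),
                       character(1)), collapse = "")
  if (!fixed_rates) key <- paste0(key, "|", join(a))
  key
}

#' Exact stationary solution of a small system by state enumeration
#'
#' Enumerates every microstate (ribosome configurations on all lattices x
#' charged counts per tRNA species), builds the CTMC generator with exactly
#' the event rules of the simulator, and solves the stationary linear system.
#' Intended for micro-instances (state space up to ~1e5).
#'
#' @param system an `rt_system` (small!).
#' @param fixed_rates,charge_on_termination as in [run_simulation()].
#' @param max_states guard on the state-space size.
#' @return list with `pi` (stationary probabilities named by state key, the
#'   same keys the engine's `track_states` mode emits), `J` (exact current
#'   per mRNA species, per copy), `reader_profile` (list per mRNA species),
#'   `c` (exact charging levels), `n_states`.
#' @export
exact_stationary <- function(system, fixed_rates = FALSE,
                             charge_on_termination = TRUE,
                             max_states = 2e5) {
  w <- system$w
  mr <- system$mrnas
  lat_species <- unlist(lapply(seq_along(mr), function(r) rep(r, mr[[r]]$copies)))
  n_lat <- length(lat_species)
  Tc <- system$trna$T
  S <- length(Tc)

  # size guard before any enumeration
  n_cfg <- vapply(lat_species, function(r)
    count_configs(length(mr[[r]]$species), w), numeric(1))
  n_a <- if (fixed_rates) 1 else prod(Tc + 1)
  n_states <- prod(n_cfg) * n_a
  if (!is.finite(n_states) || n_states > max_states)
    stop("state space too large: ", format(n_states, big.mark = ","),
         " states (max ", format(max_states, big.mark = ","), ")")

  cfgs <- lapply(lat_species, function(r)
    enumerate_configs(length(mr[[r]]$species), w))
  dims <- vapply(cfgs, length, numeric(1))

  # index arithmetic: state = (cfg indices per lattice, a vector)
  idx_grid <- do.call(expand.grid, c(lapply(dims, seq_len),
                                     if (!fixed_rates) lapply(Tc, function(t) 0:t)))
  n_states <- nrow(idx_grid)
  get_state <- function(i) {
    row <- as.integer(idx_grid[i, ])
    pos <- lapply(seq_len(n_lat), function(l) cfgs[[l]][[row[l]]])
    a <- if (fixed_rates) Tc else row[(n_lat + 1):(n_lat + S)]
    list(pos = pos, a = a)
  }
  # reverse lookup: key -> index
  keys <- vapply(seq_len(n_states), function(i) {
    st <- get_state(i)
    state_key_r(st$pos, st$a, fixed_rates)
  }, character(1))
  lookup <- setNames(seq_len(n_states), keys)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, rate) {
    ii[[length(ii) + 1]] <<- from
    jj[[length(jj) + 1]] <<- to
    xx[[length(xx) + 1]] <<- rate
  }
  for (i in seq_len(n_states)) {
    st <- get_state(i)
    for (l in seq_len(n_lat)) {
      r <- lat_species[l]
      sp_seq <- mr[[r]]$species
      L <- length(sp_seq)
      p <- st$pos[[l]]
      if (length(p) == 0 || p[1] > w) {
        nx <- st; nx$pos[[l]] <- c(1L, p)
        add(i, lookup[[state_key_r(nx$pos, nx$a, fixed_rates)]], mr[[r]]$alpha)
      }
      for (k in seq_along(p)) {
        sp <- sp_seq[p[k]]
        if (p[k] == L) {
          ok <- fixed_rates || !charge_on_termination || st$a[sp] > 0
          if (ok && mr[[r]]$beta > 0) {
            nx <- st; nx$pos[[l]] <- p[-length(p)]
            if (!fixed_rates && charge_on_termination) nx$a[sp] <- nx$a[sp] - 1L
            add(i, lookup[[state_key_r(nx$pos, nx$a, fixed_rates)]], mr[[r]]$beta)
          }
        } else {
          free <- (k == length(p)) || (p[k + 1] >= p[k] + 1 + w)
          avail <- if (fixed_rates) Tc[sp] else st$a[sp]
          if (free && avail > 0) {
            nx <- st; nx$pos[[l]][k] <- p[k] + 1L
            if (!fixed_rates) nx$a[sp] <- nx$a[sp] - 1L
            add(i, lookup[[state_key_r(nx$pos, nx$a, fixed_rates)]],
                system$kappa * avail)
          }
        }
      }
    }
    if (!fixed_rates) {
      for (sp in seq_len(S)) {
        b <- Tc[sp] - st$a[sp]
        if (b > 0) {
          rt <- system$trna$V[sp] * b / (system$trna$K[sp] + b)
          if (rt > 0) {
            nx <- st; nx$a[sp] <- nx$a[sp] + 1L
            add(i, lookup[[state_key_r(nx$pos, nx$a, fixed_rates)]], rt)
          }
        }
      }
    }
  }

  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_states, n_states))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # stationary distribution: pi^T Q = 0, sum(pi) = 1
  A <- Matrix::t(Q)
  A[n_states, ] <- 1
  rhs <- c(rep(0, n_states - 1), 1)
  pi_hat <- as.numeric(Matrix::solve(A, rhs))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- keys

  # exact observables
  R <- length(mr)
  J <- numeric(R)
  reader_profile <- lapply(mr, function(m) numeric(length(m$species)))
  c_exact <- numeric(S)
  for (i in seq_len(n_states)) {
    st <- get_state(i)
    p_i <- pi_hat[i]
    if (p_i == 0) next
    for (l in seq_len(n_lat)) {
      r <- lat_species[l]
      sp_seq <- mr[[r]]$species
      L <- length(sp_seq)
      p <- st$pos[[l]]
      for (k in seq_along(p)) {
        reader_profile[[r]][p[k]] <- reader_profile[[r]][p[k]] + p_i
        if (p[k] == L) {
          ok <- fixed_rates || !charge_on_termination || st$a[sp_seq[L]] > 0
          if (ok) J[r] <- J[r] + p_i * mr[[r]]$beta
        }
      }
    }
    c_exact <- c_exact + p_i * st$a / Tc
  }
  copies <- vapply(mr, function(m) m$copies, numeric(1))
  J <- J / copies
  reader_profile <- Map(function(pr, m) pr / m, reader_profile, copies)
  list(pi = pi_hat, J = J, reader_profile = reader_profile,
       c = c_exact, n_states = n_states, generator = Q)
}

#' Catalogued exactly solvable micro-instances
#'
#' Tiny systems bundled with their exact stationary solution from
#' [exact_stationary()], used to validate the stochastic engine.
#'
#' \describe{
#'   \item{"two_site"}{L = 2, w = 1, one copy, one tRNA species with T = 1
#'     and finite recharging: the smallest system in which depletion,
#'     exclusion and recharging all interact (8 reachable states).}
#'   \item{"two_site_alpha0"}{the same with alpha = 0 (empty absorbing
#'     lattice, J = 0).}
#'   \item{"uniform_small"}{L = 12, w = 3, one copy, mono-codon, generous
#'     pool (T = 40) with fast recharging: approximates the LD phase at
#'     small alpha.}
#'   \item{"fixed_small"}{L = 12, w = 3 with infinite recharging (fixed-rate
#'     extended-particle TASEP).}
#' }
#'
#' @param preset one of the names above.
#' @return list with `system`, `fixed_rates`, and `exact` (the oracle
#'   solution).
#' @export
make_oracle_instance <- function(preset = c("two_site", "two_site_alpha0",
                                            "uniform_small", "fixed_small")) {
  preset <- match.arg(preset)
  if (preset %in% c("two_site", "two_site_alpha0")) {
    alpha <- if (preset == "two_site_alpha0") 0 else 1
    sys <- make_system_manual(
      mrnas = list(list(name = "toy", species = c(1L, 1L), copies = 1L)),
      T_counts = 1L, V = 2, K = 1, kappa = 1, w = 1,
      alpha = alpha, beta = 2)
    fixed <- FALSE
  } else {
    fixed <- preset == "fixed_small"
    sys <- make_system_manual(
      mrnas = list(list(name = "uni", species = rep(1L, 12), copies = 1L)),
      T_counts = 40L, V = 400, K = 5, kappa = 0.25, w = 3,
      alpha = 0.8, beta = 20)
  }
  exact <- exact_stationary(sys, fixed_rates = fixed)
  list(system = sys, fixed_rates = fixed, exact = exact)
}
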