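#' Initialize a simulation state
#'
#' All lattices start empty, every tRNA is charged (`a_i = T_i`,
#' `b_i = 0`) and the clock is at zero.
#'
#' @param system an `rt_system` from [build_system()].
#' @return an `rt_state`: list with `pos` (one sorted integer vector of
#'   1-based reader positions per lattice), `lattice_species` (mRNA species
#'   index per lattice), `a`, `b`, `t`.
#' @export
init_state <- function(system) {
  lat <- unlist(lapply(seq_along(system$mrnas), function(r)
    rep(r, system$mrnas[[r]]$copies)))
  structure(list(
    pos = rep(list(integer(0)), length(lat)),
    lattice_species = lat,
    a = as.integer(system$trna$T),
    b = rep(0L, nrow(system$trna)),
    t = 0
  ), class = "rt_state")
}

#' Catalogue the enabled events of a state
#'
#' Pure-R reference implementation of the event semantics shared with the
#' compiled engine: initiation on a lattice is enabled iff no reader sits at
#' a position `<= w` (an entering ribosome reads codon 1 with its body
#' overhanging leftward); a ribosome reading codon `j < L` can advance iff
#' the next reader ahead is at `>= j + 1 + w` and a charged tRNA of the
#' codon's species is available, with rate `kappa * a_s(j)`; a reader at `L`
#' terminates with rate `beta` (consuming a charged tRNA of species `s(L)`
#' unless `charge_on_termination` is off); each tRNA species has one
#' aggregated recharge channel with rate `V_i b_i / (K_i + b_i)`.
#'
#' @param state an `rt_state`.
#' @param system the `rt_system` it belongs to.
#' @param fixed_rates if `TRUE`, infinite-recharging mode: `a_i` is pinned at
#'   `T_i` and recharge channels are absent (the fixed-rate extended-particle
#'   TASEP).
#' @param charge_on_termination whether the terminal hop consumes a charged
#'   tRNA of the last codon's species.
#' @return data.frame with columns `type` ("init", "elong", "term",
#'   "recharge"), `lattice`, `ribosome`, `species`, `rate` (only events with
#'   positive rate are listed).
#' @export
enabled_events <- function(state, system, fixed_rates = FALSE,
                           charge_on_termination = TRUE) {
  w <- system$w
  kappa <- system$kappa
  Tc <- system$trna$T
  rows <- list()
  for (l in seq_along(state$pos)) {
    r <- state$lattice_species[l]
    m <- system$mrnas[[r]]
    L <- length(m$species)
    p <- state$pos[[l]]
    if (length(p) == 0 || p[1] > w)
      rows[[length(rows) + 1]] <- data.frame(
        type = "init", lattice = l, ribosome = NA_integer_,
        species = NA_integer_, rate = m$alpha)
    for (i in seq_along(p)) {
      sp <- m$species[p[i]]
      if (p[i] == L) {
        ok <- fixed_rates || !charge_on_termination || state$a[sp] > 0
        if (ok && m$beta > 0)
          rows[[length(rows) + 1]] <- data.frame(
            type = "term", lattice = l, ribosome = i, species = sp,
            rate = m$beta)
      } else {
        free <- (i == length(p)) || (p[i + 1] >= p[i] + 1 + w)
        avail <- if (fixed_rates) Tc[sp] else state$a[sp]
        if (free && avail > 0)
          rows[[length(rows) + 1]] <- data.frame(
            type = "elong", lattice = l, ribosome = i, species = sp,
            rate = kappa * avail)
      }
    }
  }
  if (!fixed_rates) {
    for (i in seq_along(Tc)) {
      if (state$b[i] > 0) {
        rt <- system$trna$V[i] * state$b[i] / (system$trna$K[i] + state$b[i])
        if (rt > 0)
          rows[[length(rows) + 1]] <- data.frame(
            type = "recharge", lattice = NA_integer_, ribosome = NA_integer_,
            species = i, rate = rt)
      }
    }
  }
  if (!length(rows))
    return(data.frame(type = character(0), lattice = integer(0),
                      ribosome = integer(0), species = integer(0),
                      rate = numeric(0)))
  do.call(rbind, rows)
}

#' Advance the state by one Gillespie step (reference engine)
#'
#' Samples an exponential waiting time with the total enabled rate and one
#' event proportional to its rate, applies it, and returns the new state.
#' Uses R's global RNG stream.
#'
#' @inheritParams enabled_events
#' @return list with `state` (after the event), `dt`, and `event` (the row of
#'   the catalogue that fired).
#' @export
step_state <- function(state, system, fixed_rates = FALSE,
                       charge_on_termination = TRUE) {
  ev <- enabled_events(state, system, fixed_rates, charge_on_termination)
  total <- sum(ev$rate)
  if (total <= 0) stop("no enabled events: total rate is zero")
  dt <- rexp(1, total)
  k <- sample.int(nrow(ev), 1, prob = ev$rate)
  e <- ev[k, ]
  if (e$type == "init") {
    state$pos[[e$lattice]] <- c(1L, state$pos[[e$lattice]])
  } else if (e$type == "elong") {
    state$pos[[e$lattice]][e$ribosome] <- state$pos[[e$lattice]][e$ribosome] + 1L
    if (!fixed_rates) {
      state$a[e$species] <- state$a[e$species] - 1L
      state$b[e$species] <- state$b[e$species] + 1L
    }
  } else if (e$type == "term") {
    n <- length(state$pos[[e$lattice]])
    state$pos[[e$lattice]] <- state$pos[[e$lattice]][-n]
    if (!fixed_rates && charge_on_termination) {
      state$a[e$species] <- state$a[e$species] - 1L
      state$b[e$species] <- state$b[e$species] + 1L
    }
  } else { # recharge
    state$b[e$species] <- state$b[e$species] - 1L
    state$a[e$species] <- state$a[e$species] + 1L
  }
  state$t <- state$t + dt
  list(state = state, dt = dt, event = e)
}

#' Run a steady-state simulation
#'
#' Runs the compiled continuous-time Monte Carlo engine for `burn_in`
#' simulated seconds, then accumulates time-weighted observables over a
#' further `measure` seconds: terminations (currents), per-site reader dwell
#' times (density profiles), charged-pool integrals (charging levels), and
#' per-site hop counts (flux checks). Standard errors come from splitting the
#' measurement window into `n_blocks` equal blocks. The same seed yields a
#' bit-identical trajectory.
#'
#' @param system an `rt_system`.
#' @param burn_in,measure simulated seconds; defaults from the system config.
#' @param seed integer RNG seed.
#' @param n_blocks number of blocks for standard errors.
#' @param fixed_rates infinite-recharging mode (see [enabled_events()]).
#' @param charge_on_termination see [enabled_events()].
#' @param track_states if `TRUE`, also accumulate the time spent in every
#'   distinct microstate (tiny systems only; used against the enumeration
#'   oracle).
#' @param max_events hard cap on the number of events.
#' @return an `rt_observables` object; see [assemble_observables()].
#' @export
run_simulation <- function(system, burn_in = NULL, measure = NULL, seed = 1L,
                           n_blocks = NULL, fixed_rates = FALSE,
                           charge_on_termination = TRUE,
                           track_states = FALSE, max_events = 5e8) {
  if (is.null(burn_in)) burn_in <- system$config$burn_in
  if (is.null(measure)) measure <- system$config$measure
  if (is.null(n_blocks)) n_blocks <- system$config$n_blocks
  if (measure <= 0) stop("measure time must be positive")
  if (burn_in < 0) stop("burn-in time must be non-negative")
  set.seed(as.integer(seed))
  raw <- sim_run_cpp(
    mrna_codons = lapply(system$mrnas, function(m) as.integer(m$species)),
    mrna_copies = vapply(system$mrnas, function(m) as.integer(m$copies), integer(1)),
    mrna_alpha = vapply(system$mrnas, function(m) m$alpha, numeric(1)),
    mrna_beta = vapply(system$mrnas, function(m) m$beta, numeric(1)),
    T_counts = as.integer(system$trna$T),
    Vmax = as.numeric(system$trna$V),
    Km = as.numeric(system$trna$K),
    kappa = system$kappa,
    w = as.integer(system$w),
    burn_in = burn_in,
    measure = measure,
    n_blocks = as.integer(n_blocks),
    fixed_rates = fixed_rates,
    charge_on_termination = charge_on_termination,
    track_states = track_states,
    max_events = max_events)
  if (isTRUE(raw$max_events_hit))
    warning("event cap reached before the end of the schedule; ",
            "observables cover a shortened window")
  # conservation invariant at the end of the run
  if (!fixed_rates &&
      !all(raw$final_a + raw$final_b == as.integer(system$trna$T)))
    stop("tRNA conservation violated (a_i + b_i != T_i)")
  assemble_observables(raw, system, burn_in = burn_in, seed = seed)
}
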