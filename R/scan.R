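#' Sweep the initiation rate and record steady-state observables
#'
#' Runs one steady-state simulation per (alpha, seed) combination and
#' collects, for every mRNA species, the current `J`, mean reader and
#' coverage densities, and, for every tRNA species, the charging level
#' `c_i`. The analytic depletion thresholds from [critical_alphas()] are
#' attached so the simulated onset can be compared with the prediction.
#'
#' @param system an `rt_system`; its mRNAs' initiation rates are overridden
#'   by the grid values (all species get the same alpha, as in the study
#'   design).
#' @param alpha_grid increasing vector of initiation rates (1/s).
#' @param seeds integer vector of replica seeds.
#' @param burn_in,measure schedule per run (defaults from the system config).
#' @param ... further arguments passed to [run_simulation()].
#' @return list of class `rt_scan` with data.frames `species` (alpha, seed,
#'   name, J, J_se, reader_density, coverage_density, ribosomes_per_codon)
#'   and `charging` (alpha, seed, species_id, label, c, c_se); attribute
#'   `predicted` holds the [critical_alphas()] table.
#' @export
scan_alpha <- function(system, alpha_grid, seeds = 1L,
                       burn_in = NULL, measure = NULL, ...) {
  if (!length(alpha_grid)) stop("alpha_grid must not be empty")
  if (is.unsorted(alpha_grid)) stop("alpha_grid must be sorted ascending")
  sp_rows <- list()
  ch_rows <- list()
  for (a in alpha_grid) {
    sys_a <- system
    sys_a$mrnas <- lapply(sys_a$mrnas, function(m) { m$alpha <- a; m })
    for (s in seeds) {
      obs <- run_simulation(sys_a, burn_in = burn_in, measure = measure,
                            seed = s, ...)
      d <- obs$species
      d$alpha <- a; d$seed <- s
      d$ribosomes_per_codon <- obs$ribosomes_per_codon
      sp_rows[[length(sp_rows) + 1]] <- d
      ch <- obs$charging
      ch$alpha <- a; ch$seed <- s
      ch_rows[[length(ch_rows) + 1]] <- ch
    }
  }
  out <- list(species = do.call(rbind, sp_rows),
              charging = do.call(rbind, ch_rows))
  attr(out, "predicted") <- tryCatch(critical_alphas(system),
                                     error = function(e) NULL)
  class(out) <- "rt_scan"
  out
}

#' @method print rt_scan
#' @export
print.rt_scan <- function(x, ...) {
  cat("ribotraffic alpha scan:", length(unique(x$species$alpha)),
      "alpha values x", length(unique(x$species$seed)), "seed(s)\n")
  agg <- aggregate(J ~ alpha + name, data = x$species, FUN = mean)
  print(utils::head(agg[order(agg$name, agg$alpha), ], 20), row.names = FALSE)
  pred <- attr(x, "predicted")
  if (!is.null(pred) && is.finite(attr(pred, "alpha_c")))
    cat("predicted alpha_c =", signif(attr(pred, "alpha_c"), 3),
        "(bottleneck:", attr(pred, "bottleneck"), ")\n")
  invisible(x)
}

#' Simulated depletion onset from a charging scan
#'
#' The smallest grid alpha at which the minimum charging level over tRNA
#' species (averaged over seeds) drops below `threshold`; used to compare
#' the simulated onset of the limited-resources regime with the analytic
#' critical initiation rate.
#'
#' @param scan an `rt_scan`.
#' @param threshold charging level defining depletion (default 0.9).
#' @param species_id optionally restrict to one tRNA species.
#' @return the onset alpha, or `NA` if no grid point crosses the threshold.
#' @export
depletion_onset <- function(scan, threshold = 0.9, species_id = NULL) {
  ch <- scan$charging
  if (!is.null(species_id)) ch <- ch[ch$species_id %in% species_id, ]
  agg <- aggregate(c ~ alpha + species_id, data = ch, FUN = mean)
  mins <- aggregate(c ~ alpha, data = agg, FUN = min)
  mins <- mins[order(mins$alpha), ]
  hit <- which(mins$c < threshold)
  if (!length(hit)) return(NA_real_)
  mins$alpha[hit[1]]
}
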