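#' Simulation parameters
#'
#' Builds and validates the full parameter set of the two-species ribosome
#' traffic model.  The lattice has `L1` codons upstream of the uORF start,
#' `L2` codons of uORF (start and stop included) and `L3` codons downstream,
#' the last of which is the exit site whose scanning-ribosome arrivals
#' define `r_out`.
#'
#' Probabilities are per tact (one discrete time step).  With an elongation
#' movement probability of 0.3 and a physiological elongation speed of
#' five codons per second, one tact corresponds to 0.06 s (see
#' [tact_seconds()]).
#'
#' @param L1 Codons upstream of the uORF start site. Must be at least
#'   `D_sigma` so a freshly loaded ribosome fits upstream of the start.
#' @param L2 uORF length in codons, start and stop sites included.
#'   Minimum 2 (distinct start and stop).
#' @param L3 Codons downstream of the uORF stop, including the final exit
#'   site.
#' @param D_sigma Footprint of a scanning ribosome, in codons.
#' @param D_eps Footprint of an elongating ribosome, in codons.
#' @param m_sigma Probability per tact that a scanning ribosome advances
#'   one site when the site ahead is empty.
#' @param m_eps Probability per tact that an elongating ribosome advances.
#' @param t_init Probability that a scanning ribosome fronting the start
#'   site converts to an elongating ribosome (initiation efficiency;
#'   1 - t_init is the leakiness of the start codon).
#' @param t_reinit Probability that an elongating ribosome fronting the
#'   stop site resumes scanning (reinitiation) instead of terminating.
#' @param lambda_load Per-tact probability of loading a scanning ribosome
#'   when the first `D_sigma` sites are free. This is the model's `r_in`.
#'   The default 0.075 corresponds to one loading event per 0.8 s at a
#'   0.06 s tact (see [per_tact_probability()]).
#' @param delta_eps Movement multiplier for a newly converted elongating
#'   ribosome: while paused it moves with probability `delta_eps * m_eps`,
#'   and the pause clears on its first successful move. `delta_eps = 1`
#'   means no initiation delay.
#' @param P_sigma_spont Per-tact spontaneous dissociation probability of a
#'   scanning ribosome.
#' @param P_eps_spont Per-tact spontaneous drop-off probability of an
#'   elongating ribosome.
#' @param collision_dissociation When `TRUE` (default) a scanning ribosome
#'   hit from behind by an elongating ribosome is knocked off the mRNA;
#'   when `FALSE` the elongating ribosome is simply blocked.
#' @param n_tacts Number of tacts per run.
#' @param burn_in Initial tacts excluded from rate estimation.
#' @param seed Integer seed; every run is bit-reproducible given the seed.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(L2 = 100, lambda_load = 0.02, n_tacts = 1e4)
#' p$stop_site - p$start_site + 1  # uORF length
#' @export
sim_params <- function(L1 = 100, L2 = 100, L3 = 100,
                       D_sigma = 10, D_eps = 10,
                       m_sigma = 0.3, m_eps = 0.3,
                       t_init = 0.8, t_reinit = 0,
                       lambda_load = 0.075, delta_eps = 1,
                       P_sigma_spont = 0, P_eps_spont = 0,
                       collision_dissociation = TRUE,
                       n_tacts = 1e5, burn_in = 0, seed = 1L) {
  p <- list(L1 = L1, L2 = L2, L3 = L3, D_sigma = D_sigma, D_eps = D_eps,
            m_sigma = m_sigma, m_eps = m_eps, t_init = t_init,
            t_reinit = t_reinit, lambda_load = lambda_load,
            delta_eps = delta_eps, P_sigma_spont = P_sigma_spont,
            P_eps_spont = P_eps_spont,
            collision_dissociation = isTRUE(collision_dissociation),
            n_tacts = n_tacts, burn_in = burn_in, seed = as.integer(seed))
  validate_params(p)
}

#' Validate a simulation parameter list
#'
#' Checks all structural constraints and returns the parameter object with
#' derived lattice indices (`start_site`, `stop_site`, `exit_site`) filled
#' in. Called by [sim_params()]; exported so configurations assembled by
#' hand or parsed from files can be checked too.
#'
#' @param p A named list with the fields of [sim_params()].
#' @return A validated `sim_params` object.
#' @export
validate_params <- function(p) {
  need <- c("L1", "L2", "L3", "D_sigma", "D_eps", "m_sigma", "m_eps",
            "t_init", "t_reinit", "lambda_load", "delta_eps",
            "P_sigma_spont", "P_eps_spont", "collision_dissociation",
            "n_tacts", "burn_in", "seed")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))

  pos_int <- function(field, x) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x))
      stop(sprintf("%s must be a positive integer (got %s)", field,
                   paste(x, collapse = ",")))
  }
  prob <- function(field, x) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("%s must be a probability in [0, 1] (got %s)", field,
                   paste(x, collapse = ",")))
  }
  for (f in c("L1", "L2", "L3", "D_sigma", "D_eps", "n_tacts"))
    pos_int(f, p[[f]])
  for (f in c("m_sigma", "m_eps", "t_init", "t_reinit", "lambda_load",
              "delta_eps", "P_sigma_spont", "P_eps_spont"))
    prob(f, p[[f]])
  if (length(p$burn_in) != 1 || !is.finite(p$burn_in) || p$burn_in < 0 ||
      p$burn_in != round(p$burn_in))
    stop("burn_in must be a non-negative integer")
  if (p$burn_in >= p$n_tacts)
    stop("burn_in must be smaller than n_tacts")
  if (p$L2 < 2)
    stop("L2 must be at least 2: the uORF start and stop must be distinct sites")
  if (p$L1 < p$D_sigma)
    stop(sprintf("L1 (%d) must be at least D_sigma (%d) so a loaded ribosome fits upstream of the start site",
                 p$L1, p$D_sigma))
  if (p$L1 + 1 < p$D_eps)
    stop(sprintf("L1 + 1 (%d) must be at least D_eps (%d) so an initiating ribosome fits on the lattice",
                 p$L1 + 1, p$D_eps))
  if (!is.logical(p$collision_dissociation))
    stop("collision_dissociation must be TRUE or FALSE")

  p$start_site <- p$L1 + 1
  p$stop_site <- p$L1 + p$L2
  p$exit_site <- p$L1 + p$L2 + p$L3
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Ribosome traffic simulation parameters\n")
  cat(sprintf("  lattice: L1=%d | uORF L2=%d | L3=%d (total %d sites)\n",
              x$L1, x$L2, x$L3, x$exit_site))
  cat(sprintf("  footprints: scanning %d, elongating %d\n",
              x$D_sigma, x$D_eps))
  cat(sprintf("  movement: m_sigma=%g, m_eps=%g, initiation delay delta_eps=%g\n",
              x$m_sigma, x$m_eps, x$delta_eps))
  cat(sprintf("  conversion: t_init=%g, t_reinit=%g\n", x$t_init, x$t_reinit))
  cat(sprintf("  loading r_in=%g; drop-off P_sigma=%g, P_eps=%g; collision dissociation %s\n",
              x$lambda_load, x$P_sigma_spont, x$P_eps_spont,
              if (x$collision_dissociation) "on" else "off"))
  cat(sprintf("  run: %g tacts (burn-in %g), seed %d\n",
              x$n_tacts, x$burn_in, x$seed))
  invisible(x)
}

#' Real-time duration of one simulation tact
#'
#' Converts the elongation movement probability into seconds per tact,
#' given a physiological elongation speed. With `m_eps = 0.3` and a speed
#' of 5 codons per second a tact lasts 0.3 / 5 = 0.06 s.
#'
#' @param m_eps Per-tact elongation movement probability.
#' @param codons_per_second Elongation speed of a mammalian ribosome.
#' @return Seconds per tact.
#' @examples
#' tact_seconds() # 0.06
#' @export
tact_seconds <- function(m_eps = 0.3, codons_per_second = 5) {
  stopifnot(m_eps > 0, codons_per_second > 0)
  m_eps / codons_per_second
}

#' Per-tact probability of a recurring event
#'
#' Converts a mean waiting time between events (in seconds) into a
#' per-tact probability. A ribosome loading once every 0.8 s at a 0.06 s
#' tact corresponds to a loading probability of 0.075 per tact.
#'
#' @param interval_seconds Mean time between events.
#' @param tact_duration Seconds per tact, see [tact_seconds()].
#' @return Probability per tact.
#' @examples
#' per_tact_probability(0.8) # 0.075
#' @export
per_tact_probability <- function(interval_seconds,
                                 tact_duration = tact_seconds()) {
  stopifnot(interval_seconds > 0, tact_duration > 0)
  tact_duration / interval_seconds
}
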