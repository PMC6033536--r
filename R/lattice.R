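#' Create an empty lattice state
#'
#' The lattice is a string of `L1 + L2 + L3` sites over the alphabet
#' 0 (empty), 1 (scanning ribosome) and 2 (elongating ribosome), together
#' with a particle registry. A particle's `front` is its leading (3'-most)
#' edge; it covers the sites `front - D + 1` to `front` where `D` is its
#' kind's footprint.
#'
#' @param params A [sim_params()] object.
#' @return A `lattice_state`: list with `sites` (integer vector),
#'   `particles` (data frame with columns `id`, `kind` (0 scanning /
#'   1 elongating), `front`, `paused` (initiation pause not yet
#'   released), `leaky` (scanning ribosome that failed its one
#'   initiation draw)), cumulative `counters`, and the derived
#'   `start_site`, `stop_site`, `exit_site`.
#' @examples
#' st <- new_lattice(sim_params(L1 = 50, L2 = 100, L3 = 50))
#' length(st$sites)  # 200
#' @export
new_lattice <- function(params) {
  params <- validate_params(params)
  L <- params$exit_site
  structure(list(
    sites = integer(L),
    particles = data.frame(id = integer(), kind = integer(),
                           front = integer(), paused = logical(),
                           leaky = logical()),
    counters = empty_counters(),
    next_id = 1L,
    start_site = params$start_site,
    stop_site = params$stop_site,
    exit_site = params$exit_site
  ), class = "lattice_state")
}

counter_names <- c("loaded", "exited", "initiated", "terminated",
                   "reinitiated", "collision_dissociated",
                   "sigma_spont_dissociated", "eps_spont_dissociated")

empty_counters <- function() {
  stats::setNames(numeric(length(counter_names)), counter_names)
}

routine_bits <- c(load = 1L, initiate = 2L, terminate = 4L, exit = 8L,
                  move = 16L, dissociate = 32L)

advance_state <- function(state, params, n = 1L, routines = names(routine_bits),
                          checks = FALSE) {
  stopifnot(inherits(state, "lattice_state"))
  params <- validate_params(params)
  bad <- setdiff(routines, names(routine_bits))
  if (length(bad)) stop("unknown routine(s): ", paste(bad, collapse = ", "))
  mask <- sum(routine_bits[routines])
  out <- cpp_advance(unclass(state), params, as.integer(n), as.integer(mask),
                     checks)
  new <- state
  new$sites <- out$sites
  new$particles <- out$particles
  new$counters <- unlist(out$counters)[counter_names]
  new$next_id <- out$next_id
  attr(new, "exits") <- out$exits
  new
}

#' Apply one full tact to a lattice state
#'
#' One tact applies, in this fixed order: scanning-ribosome loading,
#' initiation at the uORF start, termination/reinitiation at the stop,
#' exit registration at the last site, one movement attempt per particle
#' in decreasing front order, and spontaneous dissociation. Randomness is
#' drawn from R's RNG, so wrap calls in `set.seed()` for reproducibility.
#'
#' @param state A `lattice_state`.
#' @param params A [sim_params()] object.
#' @param n Number of tacts to apply.
#' @param checks Verify structural invariants after every tact.
#' @return The successor `lattice_state`; cumulative event counts in
#'   `$counters`, exits during this call in `attr(, "exits")`.
#' @examples
#' p <- sim_params(L1 = 20, L2 = 10, L3 = 20, lambda_load = 1)
#' set.seed(1)
#' st <- tact(new_lattice(p), p)
#' st$counters[["loaded"]]  # 1: loading is certain on an empty lattice
#' @export
tact <- function(state, params, n = 1L, checks = FALSE) {
  advance_state(state, params, n = n, checks = checks)
}

#' Individual update routines
#'
#' Each function applies exactly one of the six per-tact routines to a
#' lattice state, which is mainly useful for testing the update rules in
#' isolation. See [tact()] for the composite step and the routine order.
#'
#' @param state A `lattice_state`.
#' @param params A [sim_params()] object.
#' @return The successor `lattice_state`.
#' @name routines
NULL

#' @rdname routines
#' @export
attempt_load <- function(state, params)
  advance_state(state, params, routines = "load")

#' @rdname routines
#' @export
attempt_initiation <- function(state, params)
  advance_state(state, params, routines = "initiate")

#' @rdname routines
#' @export
attempt_termination <- function(state, params)
  advance_state(state, params, routines = "terminate")

#' @rdname routines
#' @export
register_exits <- function(state, params)
  advance_state(state, params, routines = "exit")

#' @rdname routines
#' @export
movement_step <- function(state, params)
  advance_state(state, params, routines = "move")

#' @rdname routines
#' @export
spontaneous_dissociation_step <- function(state, params)
  advance_state(state, params, routines = "dissociate")

#' Serialize a lattice state to its site string
#'
#' @param state A `lattice_state`.
#' @return A single string over \{0,1,2\}, one character per site.
#' @examples
#' format_lattice(new_lattice(sim_params(L1 = 10, L2 = 2, L3 = 3)))
#' @export
format_lattice <- function(state) {
  paste(state$sites, collapse = "")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("Lattice state: %d sites, %d particle(s)\n",
              length(x$sites), nrow(x$particles)))
  cat(sprintf("  start %d | stop %d | exit %d\n",
              x$start_site, x$stop_site, x$exit_site))
  s <- format_lattice(x)
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat("  ", s, "\n", sep = "")
  invisible(x)
}
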