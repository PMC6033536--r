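# Exact validation oracle for small single-site-footprint instances.
#
# With unit footprints (D = 1) and no initiation pause the lattice string
# is almost the complete Markov state; the one extra bit — whether the
# scanning ribosome currently at the start site has already failed its
# single initiation draw — is encoded as a fourth site symbol (3) that
# can only occur at the start position. The per-tact transition kernel is
# then enumerated exactly by branching over every Bernoulli draw of the
# update routines. The stationary exit rate obtained from the resulting
# transition matrix is an independent check on the stochastic engine;
# this code deliberately shares nothing with the C++ implementation.

assert_exact_spec <- function(params, max_length = 12) {
  params <- validate_params(params)
  if (params$D_sigma != 1 || params$D_eps != 1)
    stop("exact enumeration requires unit footprints (D_sigma = D_eps = 1)")
  if (params$delta_eps != 1)
    stop("exact enumeration requires delta_eps = 1 (no initiation pause state)")
  if (params$exit_site > max_length)
    stop(sprintf("lattice length %d exceeds the enumerability cap of %d sites",
                 params$exit_site, max_length))
  params
}

# Full successor distribution of one tact from `sites` (integer vector
# over {0,1,2}). Returns probs keyed by successor site-string plus the
# expected number of exits during the tact.
oracle_transitions <- function(sites, params) {
  p <- assert_exact_spec(params)
  L <- p$exit_site
  start <- p$start_site
  stp <- p$stop_site
  succ <- new.env(parent = emptyenv())
  pexit <- 0

  emit <- function(s, pr, ex) {
    key <- paste(s, collapse = "")
    succ[[key]] <- (if (is.null(succ[[key]])) 0 else succ[[key]]) + pr
    pexit <<- pexit + pr * ex
  }
  branch <- function(pr, pyes, yes, no) {
    if (pyes >= 1) yes(pr)
    else if (pyes <= 0) no(pr)
    else { yes(pr * pyes); no(pr * (1 - pyes)) }
  }

  # routine 6: spontaneous dissociation, highest position first
  stage_spont <- function(s, pr, ex, pos, k) {
    if (k > length(pos)) { emit(s, pr, ex); return(invisible()) }
    q <- pos[k]
    pdrop <- if (s[q] == 2) p$P_eps_spont else p$P_sigma_spont
    branch(pr, pdrop,
           yes = function(w) { s2 <- s; s2[q] <- 0
             stage_spont(s2, w, ex, pos, k + 1) },
           no = function(w) stage_spont(s, w, ex, pos, k + 1))
  }
  enter_spont <- function(s, pr, ex) {
    stage_spont(s, pr, ex, rev(which(s > 0)), 1)
  }

  # routine 5: one movement attempt per particle, decreasing position
  stage_move <- function(s, pr, ex, pos, k) {
    if (k > length(pos)) { enter_spont(s, pr, ex); return(invisible()) }
    nxt <- function(s2, w) stage_move(s2, w, ex, pos, k + 1)
    q <- pos[k]
    if (s[q] != 2) {                    # scanning (3 = leaky, at start only)
      if (q < L && s[q + 1] == 0) {
        branch(pr, p$m_sigma,
               yes = function(w) { s2 <- s; s2[q] <- 0; s2[q + 1] <- 1
                 nxt(s2, w) },          # a leaky scanner is plain past the start
               no = function(w) nxt(s, w))
      } else nxt(s, pr)
    } else {                            # elongating
      if (q >= stp || s[q + 1] == 2) { nxt(s, pr); return(invisible()) }
      ahead <- s[q + 1]
      blocked <- ahead == 1 && !p$collision_dissociation
      if (blocked) { nxt(s, pr); return(invisible()) }
      branch(pr, p$m_eps,
             yes = function(w) { s2 <- s; s2[q] <- 0; s2[q + 1] <- 2
               nxt(s2, w) },            # ahead == 1 removes that scanner
             no = function(w) nxt(s, w))
    }
  }
  enter_move <- function(s, pr, ex) {
    stage_move(s, pr, ex, rev(which(s > 0)), 1)
  }

  # routine 4: exit registration at the last site
  stage_exit <- function(s, pr) {
    ex <- 0
    if (s[L] == 1) { s[L] <- 0; ex <- 1 }
    enter_move(s, pr, ex)
  }

  # routine 3: termination / reinitiation at the stop site
  stage_term <- function(s, pr) {
    if (s[stp] == 2) {
      branch(pr, p$t_reinit,
             yes = function(w) { s2 <- s; s2[stp] <- 1; stage_exit(s2, w) },
             no = function(w) { s2 <- s; s2[stp] <- 0; stage_exit(s2, w) })
    } else stage_exit(s, pr)
  }

  # routine 2: one initiation draw per arriving scanning ribosome; a
  # failed ribosome is marked (symbol 3) and never redrawn
  stage_init <- function(s, pr) {
    if (s[start] == 1) {
      branch(pr, p$t_init,
             yes = function(w) { s2 <- s; s2[start] <- 2; stage_term(s2, w) },
             no = function(w) { s2 <- s; s2[start] <- 3; stage_term(s2, w) })
    } else stage_term(s, pr)
  }

  # routine 1: loading at the 5' end
  if (sites[1] == 0) {
    branch(1, p$lambda_load,
           yes = function(w) { s2 <- sites; s2[1] <- 1; stage_init(s2, w) },
           no = function(w) stage_init(sites, w))
  } else stage_init(sites, 1)

  keys <- ls(succ)
  list(states = keys,
       probs = vapply(keys, function(k) succ[[k]], numeric(1)),
       expected_exits = pexit)
}

#' Exact transition matrix of a small instance
#'
#' Enumerates the reachable state space of the model from the empty
#' lattice and the exact one-tact transition probabilities, for instances
#' with unit ribosome footprints, no initiation pause, and a short
#' lattice. The enumeration branches over every Bernoulli draw of the six
#' update routines in their fixed order, including the decreasing-position
#' movement sweep, and is implemented independently of the simulation
#' engine.
#'
#' @param params A [sim_params()] with `D_sigma = D_eps = 1`,
#'   `delta_eps = 1` and total lattice length at most `max_length`.
#' @param max_length Enumerability cap on the lattice length.
#' @param max_states Cap on the reachable state count.
#' @return List with `states` (site strings), row-stochastic matrix `P`,
#'   and `expected_exits` (per-state expected exits in one tact).
#' @export
transition_matrix <- function(params, max_length = 12, max_states = 20000) {
  p <- assert_exact_spec(params, max_length = max_length)
  L <- p$exit_site
  empty <- paste(integer(L), collapse = "")
  index <- new.env(parent = emptyenv())
  states <- character()
  trans <- list()
  exits <- numeric()
  queue <- empty
  index[[empty]] <- 1L
  states[1] <- empty

  while (length(queue)) {
    key <- queue[1]
    queue <- queue[-1]
    sites <- as.integer(strsplit(key, "")[[1]])
    tr <- oracle_transitions(sites, p)
    i <- index[[key]]
    trans[[i]] <- tr
    exits[i] <- tr$expected_exits
    for (k in tr$states) {
      if (is.null(index[[k]])) {
        if (length(states) >= max_states)
          stop(sprintf("reachable state space exceeds the cap of %d states",
                       max_states))
        index[[k]] <- length(states) + 1L
        states[length(states) + 1L] <- k
        queue <- c(queue, k)
      }
    }
  }

  n <- length(states)
  P <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(n)) {
    tr <- trans[[i]]
    P[i, vapply(tr$states, function(k) index[[k]], integer(1))] <- tr$probs
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12))
    stop("internal error: transition matrix rows do not sum to 1")
  list(states = states, P = P, expected_exits = exits)
}

cesaro_stationary <- function(P, iters = 20000) {
  # lazy chain removes periodicity; running average gives the Cesaro limit
  n <- nrow(P)
  Q <- (P + diag(n)) / 2
  mu <- c(1, numeric(n - 1))
  acc <- numeric(n)
  for (i in seq_len(iters)) {
    mu <- as.numeric(mu %*% Q)
    if (i > iters / 2) acc <- acc + mu
  }
  acc / sum(acc)
}

#' Exact stationary output flux of a small instance
#'
#' Solves the stationary distribution of the exact transition matrix from
#' [transition_matrix()] by dense linear algebra and returns the
#' stationary expected exit rate — the exact `r_out` that an infinitely
#' long simulation of the same instance would estimate. Falls back to a
#' Cesaro (time-average) limit when the linear system is degenerate.
#'
#' @inheritParams transition_matrix
#' @return Exact `r_out` (expected scanning-ribosome exits per tact).
#' @examples
#' p <- sim_params(L1 = 2, L2 = 2, L3 = 2, D_sigma = 1, D_eps = 1,
#'                 m_sigma = 0.5, m_eps = 0.5, t_init = 0.5,
#'                 lambda_load = 0.3)
#' stationary_flux(p)
#' @export
stationary_flux <- function(params, max_length = 12, max_states = 20000) {
  tm <- transition_matrix(params, max_length = max_length,
                          max_states = max_states)
  n <- length(tm$states)
  pi_hat <- tryCatch({
    A <- t(tm$P) - diag(n)
    A[n, ] <- 1
    b <- c(numeric(n - 1), 1)
    x <- solve(A, b)
    if (any(x < -1e-8) || abs(sum(x) - 1) > 1e-6)
      stop("linear solve returned an invalid distribution")
    x <- pmax(x, 0)
    x / sum(x)
  }, error = function(e) {
    warning("stationary linear solve degenerate (", conditionMessage(e),
            "); using the Cesaro time-average instead")
    cesaro_stationary(tm$P)
  })
  sum(pi_hat * tm$expected_exits)
}

#' Closed-form passage probability of an isolated scanning ribosome
#'
#' In the collision-free limit (vanishing loading rate) and without
#' spontaneous dissociation, a scanning ribosome reaches the exit site iff
#' it leaks past the uORF start (probability `1 - t_init`; each ribosome
#' faces exactly one initiation draw per arrival) or initiates and then
#' reinitiates at the stop (probability `t_init * t_reinit`; termination
#' is resolved within a single tact).
#'
#' @param params A [sim_params()] with zero spontaneous dissociation.
#' @return The passage probability `(1 - t_init) + t_init * t_reinit`.
#' @examples
#' single_particle_passage(sim_params(t_init = 0.8, t_reinit = 0)) # 0.2
#' @export
single_particle_passage <- function(params) {
  params <- validate_params(params)
  if (params$P_sigma_spont > 0 || params$P_eps_spont > 0)
    stop("closed form only valid without spontaneous dissociation ",
         "(P_sigma_spont = P_eps_spont = 0)")
  (1 - params$t_init) + params$t_init * params$t_reinit
}

#' Compare simulated and exact fluxes on small instances
#'
#' Runs the stochastic engine on each instance and compares its `r_out`
#' against the exact stationary flux, reporting the z-score of the
#' discrepancy in units of the simulation's batch-means standard error.
#'
#' @param specs List of [sim_params()] objects satisfying the exact-oracle
#'   restrictions.
#' @return Data frame with columns `spec`, `exact`, `simulated`, `se`,
#'   `z`.
#' @export
oracle_check <- function(specs = default_oracle_specs()) {
  rows <- lapply(seq_along(specs), function(i) {
    p <- validate_params(specs[[i]])
    exact <- stationary_flux(p)
    sim <- run_simulation(p)
    se <- sim$r_out_se
    data.frame(spec = i, exact = exact, simulated = sim$r_out, se = se,
               z = (sim$r_out - exact) / se)
  })
  do.call(rbind, rows)
}

#' Default small instances for oracle validation
#'
#' Five unit-footprint instances spanning initiation efficiencies 0, 0.5
#' and 1, reinitiation 0 and 0.5, and both collision-dissociation modes.
#'
#' @param n_tacts Tacts per simulated comparison run.
#' @return List of [sim_params()] objects.
#' @export
default_oracle_specs <- function(n_tacts = 2e5) {
  base <- function(...) {
    sim_params(L1 = 2, L2 = 2, L3 = 2, D_sigma = 1, D_eps = 1,
               m_sigma = 0.5, m_eps = 0.5, lambda_load = 0.3,
               n_tacts = n_tacts, ...)
  }
  list(base(t_init = 0, seed = 11L),
       base(t_init = 0.5, seed = 12L),
       base(t_init = 1, seed = 13L),
       base(t_init = 0.5, t_reinit = 0.5, seed = 14L),
       base(t_init = 0.8, collision_dissociation = FALSE, seed = 15L))
}
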