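# Small shared fixtures; everything is generated in code.

# a compact lattice that still has distinct flanks and a multi-codon uORF
tiny_params <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(L1 = 20, L2 = 10, L3 = 20, n_tacts = 1e3), list(...)))
}

# unit-footprint instance small enough for exact enumeration
unit_params <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(L1 = 2, L2 = 2, L3 = 2, D_sigma = 1, D_eps = 1,
         m_sigma = 0.5, m_eps = 0.5, lambda_load = 0.3,
         n_tacts = 1e5), list(...)))
}

# place a particle by hand on an empty lattice (front = leading edge)
place_particle <- function(state, params, kind, front, paused = FALSE,
                           leaky = FALSE) {
  D <- if (kind == 0) params$D_sigma else params$D_eps
  stopifnot(front - D + 1 >= 1, all(state$sites[(front - D + 1):front] == 0))
  state$sites[(front - D + 1):front] <- kind + 1L
  state$particles <- rbind(state$particles,
                           data.frame(id = state$next_id, kind = kind,
                                      front = front, paused = paused,
                                      leaky = leaky))
  state$particles <- state$particles[order(state$particles$front), ,
                                     drop = FALSE]
  state$next_id <- state$next_id + 1L
  state
}

# independent reconstruction of the site string from the registry
project_particles <- function(state, params) {
  sites <- integer(length(state$sites))
  for (i in seq_len(nrow(state$particles))) {
    p <- state$particles[i, ]
    D <- if (p$kind == 0) params$D_sigma else params$D_eps
    span <- (p$front - D + 1):p$front
    if (any(sites[span] != 0)) stop("overlapping particles")
    sites[span] <- p$kind + 1L
  }
  sites
}

expect_valid_state <- function(state, params) {
  expect_identical(state$sites, project_particles(state, params))
  el <- state$particles[state$particles$kind == 1, ]
  if (nrow(el)) {
    expect_true(all(el$front >= params$start_site))
    expect_true(all(el$front <= params$stop_site))
  }
}

# scanning-ribosome conservation ledger (exact integer closure)
expect_ledger_closes <- function(state) {
  cnt <- state$counters
  n_scan <- sum(state$particles$kind == 0)
  n_elong <- sum(state$particles$kind == 1)
  expect_identical(
    cnt[["loaded"]],
    cnt[["exited"]] + cnt[["collision_dissociated"]] +
      cnt[["sigma_spont_dissociated"]] +
      (cnt[["initiated"]] - cnt[["reinitiated"]]) + n_scan)
  expect_identical(
    cnt[["initiated"]],
    cnt[["terminated"]] + cnt[["reinitiated"]] +
      cnt[["eps_spont_dissociated"]] + n_elong)
}
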