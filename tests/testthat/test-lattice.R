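test_that("an empty lattice has the documented shape", {
  p <- sim_params(L1 = 50, L2 = 100, L3 = 50)
  st <- new_lattice(p)
  expect_length(st$sites, 200)
  expect_true(all(st$sites == 0))
  expect_equal(nrow(st$particles), 0)
  expect_equal(format_lattice(st), strrep("0", 200))
})

test_that("loading adds a scanning ribosome on the first D_sigma sites", {
  p <- tiny_params(lambda_load = 1)
  set.seed(1)
  st <- attempt_load(new_lattice(p), p)
  expect_equal(nrow(st$particles), 1)
  expect_equal(st$particles$front, p$D_sigma)
  expect_equal(sum(st$sites == 1), p$D_sigma)
  expect_equal(st$counters[["loaded"]], 1)

  # zero probability never loads
  p0 <- tiny_params(lambda_load = 0)
  st0 <- attempt_load(new_lattice(p0), p0)
  expect_equal(nrow(st0$particles), 0)

  # a blocked 5' end never loads, even at lambda = 1
  blocked <- place_particle(new_lattice(p), p, kind = 0, front = p$D_sigma)
  set.seed(1)
  still <- attempt_load(blocked, p)
  expect_equal(nrow(still$particles), 1)
  expect_equal(still$counters[["loaded"]], 0)
})

test_that("initiation converts in place, once per arriving ribosome", {
  p <- tiny_params(t_init = 1)
  st <- place_particle(new_lattice(p), p, kind = 0, front = p$start_site)
  out <- attempt_initiation(st, p)
  expect_equal(out$particles$kind, 1)
  expect_equal(out$particles$front, p$start_site)
  expect_equal(out$counters[["initiated"]], 1)
  expect_equal(sum(out$sites == 2), p$D_eps)

  # t_init = 0: the ribosome stays scanning and is marked leaky,
  # so it faces no further draws on later tacts
  p0 <- tiny_params(t_init = 0)
  st0 <- attempt_initiation(st, p0)
  expect_equal(st0$particles$kind, 0)
  expect_true(st0$particles$leaky)
  p1 <- p0; p1$t_init <- 1
  again <- attempt_initiation(st0, validate_params(p1))
  expect_equal(again$particles$kind, 0)  # no redraw for a leaky ribosome
})

test_that("initiation efficiency matches t_init over independent arrivals", {
  # many independent single-ribosome arrivals at the start site
  p <- tiny_params(t_init = 0.8)
  n <- 4000
  set.seed(42)
  st0 <- place_particle(new_lattice(p), p, kind = 0, front = p$start_site)
  conv <- replicate(n, {
    attempt_initiation(st0, p)$particles$kind == 1
  })
  frac <- mean(conv)
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("termination removes or reinitiates at the stop site", {
  p <- tiny_params(t_reinit = 0)
  st <- place_particle(new_lattice(p), p, kind = 1, front = p$stop_site)
  out <- attempt_termination(st, p)
  expect_equal(nrow(out$particles), 0)
  expect_equal(out$counters[["terminated"]], 1)

  p1 <- tiny_params(t_reinit = 1)
  out1 <- attempt_termination(st, p1)
  expect_equal(out1$particles$kind, 0)
  expect_equal(out1$particles$front, p1$stop_site)
  expect_equal(out1$counters[["reinitiated"]], 1)

  # no particle at the stop: a no-op
  empty <- attempt_termination(new_lattice(p), p)
  expect_equal(nrow(empty$particles), 0)
  expect_equal(sum(empty$counters), 0)
})

test_that("a scanning ribosome fronting the last site exits and is counted", {
  p <- tiny_params()
  st <- place_particle(new_lattice(p), p, kind = 0, front = p$exit_site)
  out <- register_exits(st, p)
  expect_equal(nrow(out$particles), 0)
  expect_equal(out$counters[["exited"]], 1)
  expect_equal(attr(out, "exits"), 1)
  expect_equal(attr(register_exits(new_lattice(p), p), "exits"), 0)
})

test_that("movement advances by one site and respects exclusion", {
  p <- tiny_params(m_sigma = 1)
  st <- place_particle(new_lattice(p), p, kind = 0, front = p$D_sigma)
  out <- movement_step(st, p)
  expect_equal(out$particles$front, p$D_sigma + 1)

  # particles are visited in decreasing front order, so the trailing
  # ribosome may enter the site its leader vacated this same tact
  st2 <- place_particle(st, p, kind = 0, front = 2 * p$D_sigma)
  out2 <- movement_step(st2, p)
  expect_equal(sort(out2$particles$front),
               c(p$D_sigma + 1, 2 * p$D_sigma + 1))
})

test_that("an elongating ribosome dissociates the scanner it rear-ends", {
  p <- tiny_params(m_eps = 1, m_sigma = 0)  # pin the scanner in place
  st <- new_lattice(p)
  st <- place_particle(st, p, kind = 1, front = p$start_site + 2)
  st <- place_particle(st, p, kind = 0,
                       front = p$start_site + 2 + p$D_sigma)
  out <- movement_step(st, p)
  expect_equal(nrow(out$particles), 1)
  expect_equal(out$particles$kind, 1)
  expect_equal(out$particles$front, p$start_site + 3)
  expect_equal(out$counters[["collision_dissociated"]], 1)

  # with collision dissociation off, both stay put
  poff <- tiny_params(m_eps = 1, m_sigma = 0, collision_dissociation = FALSE)
  set.seed(3)
  out2 <- movement_step(st, poff)
  expect_equal(sort(out2$particles$front),
               c(p$start_site + 2, p$start_site + 2 + p$D_sigma))
  expect_equal(out2$counters[["collision_dissociated"]], 0)
})

test_that("elongating ribosomes never advance past the stop site", {
  p <- tiny_params(m_eps = 1)
  st <- place_particle(new_lattice(p), p, kind = 1, front = p$stop_site)
  out <- movement_step(st, p)
  expect_equal(out$particles$front, p$stop_site)
})

test_that("a paused elongating ribosome moves at delta_eps * m_eps", {
  # delta_eps = 0 freezes a paused ribosome entirely
  p <- tiny_params(m_eps = 1, delta_eps = 0, t_init = 1)
  st <- place_particle(new_lattice(p), p, kind = 0, front = p$start_site)
  st <- attempt_initiation(st, p)
  expect_true(st$particles$paused)
  out <- movement_step(st, p)
  expect_equal(out$particles$front, p$start_site)

  # delta_eps = 1 leaves no pause at all
  p1 <- tiny_params(m_eps = 1, delta_eps = 1, t_init = 1)
  st1 <- place_particle(new_lattice(p1), p1, kind = 0, front = p1$start_site)
  st1 <- attempt_initiation(st1, p1)
  expect_false(st1$particles$paused)
  expect_equal(movement_step(st1, p1)$particles$front, p1$start_site + 1)

  # intermediate delay: empirical move rate ~ delta_eps * m_eps, and the
  # pause clears on the first successful move
  pd <- tiny_params(m_eps = 1, delta_eps = 0.3, t_init = 1)
  std <- place_particle(new_lattice(pd), pd, kind = 0, front = pd$start_site)
  std <- attempt_initiation(std, pd)
  set.seed(11)
  n <- 2000
  moved <- replicate(n, movement_step(std, pd)$particles$front >
                       pd$start_site)
  expect_lt(abs(mean(moved) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  once <- movement_step(std, pd)
  while (once$particles$front == pd$start_site)
    once <- movement_step(once, pd)
  expect_false(once$particles$paused)
})

test_that("spontaneous dissociation removes ribosomes by kind", {
  p <- tiny_params(P_sigma_spont = 1)
  st <- place_particle(new_lattice(p), p, kind = 0, front = p$D_sigma)
  st <- place_particle(st, p, kind = 1, front = p$start_site + 3)
  out <- spontaneous_dissociation_step(st, p)
  expect_equal(out$particles$kind, 1)  # only the scanner was removed
  expect_equal(out$counters[["sigma_spont_dissociated"]], 1)

  p0 <- tiny_params()
  out0 <- spontaneous_dissociation_step(st, p0)
  expect_equal(nrow(out0$particles), 2)

  # binomial expectation for elongating drop-off
  pe <- tiny_params(P_eps_spont = 0.01)
  ste <- place_particle(new_lattice(pe), pe, kind = 1,
                        front = pe$start_site + 3)
  set.seed(9)
  n <- 1e4
  drops <- sum(replicate(n, nrow(spontaneous_dissociation_step(ste, pe)$particles) == 0))
  expect_lt(abs(drops - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
})

test_that("a tact composes the routines in order and is seed-deterministic", {
  p <- tiny_params(lambda_load = 0)
  out <- tact(new_lattice(p), p)
  expect_equal(sum(out$counters), 0)
  expect_true(all(out$sites == 0))

  # a ribosome converting at the start (routine 2) can move as an
  # elongating ribosome in the movement routine of the same tact
  p2 <- tiny_params(t_init = 1, m_eps = 1, lambda_load = 0)
  st <- place_particle(new_lattice(p2), p2, kind = 0, front = p2$start_site)
  out2 <- tact(st, p2)
  expect_equal(out2$particles$kind, 1)
  expect_equal(out2$particles$front, p2$start_site + 1)

  p3 <- tiny_params(lambda_load = 0.5, t_init = 0.5)
  set.seed(123)
  a <- tact(new_lattice(p3), p3, n = 200)
  set.seed(123)
  b <- tact(new_lattice(p3), p3, n = 200)
  expect_identical(a, b)
})

test_that("structural invariants and the conservation ledger hold along runs", {
  # property-style: random parameter draws, checks after bursts of tacts
  set.seed(2024)
  for (rep in 1:8) {
    p <- sim_params(
      L1 = sample(10:25, 1), L2 = sample(2:30, 1), L3 = sample(10:25, 1),
      D_sigma = sample(c(1, 3, 10), 1), D_eps = sample(c(1, 3, 10), 1),
      m_sigma = runif(1, 0.2, 1), m_eps = runif(1, 0.2, 1),
      t_init = runif(1), t_reinit = runif(1, 0, 0.5),
      lambda_load = runif(1, 0, 0.5),
      delta_eps = sample(c(0.1, 1), 1),
      P_sigma_spont = sample(c(0, 0.01), 1),
      P_eps_spont = sample(c(0, 0.01), 1))
    st <- new_lattice(p)
    for (burst in 1:5) {
      st <- tact(st, p, n = 200, checks = TRUE)  # engine audits every tact
      expect_valid_state(st, p)
      expect_ledger_closes(st)
    }
  }
})
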