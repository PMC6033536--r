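# hand-built curve for the pure summary operations
fake_curve <- function(r_in, relative, relative_se = rep(0.01, length(r_in)),
                       scale = 1e-3) {
  stopifnot(length(r_in) == length(relative))
  cv <- data.frame(r_in = r_in, r_out = relative * scale,
                   r_out_se = relative_se * scale,
                   relative = relative, relative_se = relative_se,
                   realized_load_rate = r_in)
  class(cv) <- c("response_curve", "data.frame")
  cv
}

test_that("sweep normalization identities hold exactly", {
  p <- tiny_params(n_tacts = 2e3, seed = 5)
  cv <- sweep_rin(p, r_in = c(0.1, 0.05, 0.02, 0))
  expect_identical(cv$relative[cv$r_in == 0.1], 1)
  expect_identical(cv$relative_se[cv$r_in == 0.1], 0)
  expect_identical(cv$r_out[cv$r_in == 0], 0)
  # bit-identical repetition from the same base seed
  cv2 <- sweep_rin(p, r_in = c(0.1, 0.05, 0.02, 0))
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
})

test_that("sweeps demand the 0.1 anchor and a valid grid", {
  p <- tiny_params(n_tacts = 1e3)
  expect_error(sweep_rin(p, r_in = c(0.05, 0.02)), "anchor")
  expect_error(sweep_rin(p, r_in = c(0.2, 0.1)), "\\[0, 0.1\\]")
})

test_that("find_max locates the maximum, breaking ties toward small r_in", {
  grid <- default_rin_grid()
  mono <- fake_curve(grid, relative = grid * 10)  # increasing in r_in
  expect_equal(find_max(mono)$r_in_at_max, 0.1)
  expect_equal(find_max(mono)$max_relative, 1)

  humped <- fake_curve(c(0.1, 0.06, 0.02, 0), c(1, 1.4, 1.2, 0))
  expect_equal(find_max(humped)$r_in_at_max, 0.06)
  expect_equal(find_max(humped)$max_relative, 1.4)

  tied <- fake_curve(c(0.1, 0.06, 0.02, 0), c(1, 1.4, 1.4, 0))
  expect_equal(find_max(tied)$r_in_at_max, 0.02)

  degenerate <- fake_curve(c(0.1, 0.05, 0), c(0, 0, 0))
  expect_error(find_max(degenerate), "degenerate")
})

test_that("non-monotonicity detection uses interior points and k standard errors", {
  grid <- c(0.1, 0.07, 0.04, 0.02, 0)
  flat <- fake_curve(grid, c(1, 1, 1, 1, 0))
  expect_false(detect_nonmonotonic(flat))

  bump <- fake_curve(grid, c(1, 1, 1.05, 1, 0))
  expect_true(detect_nonmonotonic(bump, k = 2))   # 0.05 > 2 * 0.01
  expect_false(detect_nonmonotonic(bump, k = 6))  # 0.05 < 6 * 0.01

  # an excursion at the anchor itself must not count
  anchored <- fake_curve(grid, c(1.5, 1, 1, 1, 0))
  expect_false(detect_nonmonotonic(anchored))
})

test_that("grid experiments summarize each value and normalize to a reference", {
  p <- tiny_params(n_tacts = 5e3, seed = 8, lambda_load = 0.1)
  ex <- grid_experiment("L2", c(2, 30), p, r_in = c(0.1, 0.05, 0))
  expect_named(ex$curves, c("2", "30"))
  expect_equal(nrow(ex$summary), 2)
  expect_equal(ex$summary$max_vs_reference[1], 1)
  # repression: the longer uORF passes less flux at the unstressed anchor
  expect_lt(ex$summary$r_out_at_anchor[2], ex$summary$r_out_at_anchor[1])
  expect_error(grid_experiment("no_such_knob", c(1, 2), p), "unknown parameter")
})

test_that("threshold scans find the flip and report flanking values", {
  p <- sim_params(L1 = 20, L2 = 10, L3 = 20, n_tacts = 1e3, seed = 12)
  # deterministic predicate on the scanned value exercises the scan
  # bookkeeping (flip location, flanking values) without noise
  crit <- function(curve) attr(curve, "params")$t_init < 0.1
  ts <- threshold_scan("t_init", c(0, 0.2, 0.4), crit, p,
                       r_in = c(0.1, 0.05, 0))
  expect_s3_class(ts, "threshold_scan")
  expect_equal(ts$threshold, 0.2)
  expect_equal(ts$last_before, 0)

  expect_error(
    threshold_scan("t_init", c(0, 0.1), function(curve) TRUE, p,
                   r_in = c(0.1, 0)),
    "no threshold")
})

test_that("a fully absorbing uORF yields a degenerate, non-normalizable sweep", {
  # t_init = 1 without reinitiation lets no scanner through: the anchor
  # flux is zero and the relative curve is undefined by design
  p <- sim_params(L1 = 20, L2 = 10, L3 = 20, t_init = 1, n_tacts = 2e3)
  expect_error(sweep_rin(p, r_in = c(0.1, 0.05, 0)), "normalize")
})
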