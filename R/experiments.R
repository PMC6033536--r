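#' Default loading-rate grid
#'
#' Twenty evenly spaced values of the loading probability `r_in`,
#' descending from 0.1 (the unstressed anchor used for normalization)
#' to 0.
#'
#' @param n Number of grid points.
#' @return Numeric vector of length `n`.
#' @export
default_rin_grid <- function(n = 20) {
  seq(0.1, 0, length.out = n)
}

#' Sweep the loading rate and record the response curve
#'
#' Runs one simulation per `r_in` value and returns the absolute output
#' flux `r_out` together with its value relative to the `r_in = 0.1`
#' anchor, `r_out(r_in) / r_out(0.1)`. A relative value above 1 at an
#' interior point means the model predicts *more* downstream flux under
#' *reduced* loading — the stress-resistance signature.
#'
#' Each grid point runs with seed `params$seed + point_index - 1`, so a
#' sweep is reproducible from a single base seed.
#'
#' @param params Base [sim_params()]; `lambda_load` is overridden by the
#'   grid.
#' @param r_in Grid of loading probabilities within \[0, 0.1\]. Must
#'   contain the normalization anchor 0.1.
#' @return A `response_curve`: data frame with columns `r_in`, `r_out`,
#'   `r_out_se`, `relative`, `relative_se`, `realized_load_rate`, with the
#'   base parameters in `attr(, "params")`.
#' @examples
#' \donttest{
#' p <- sim_params(L2 = 100, n_tacts = 1e4)
#' curve <- sweep_rin(p, r_in = c(0.1, 0.05, 0.02, 0))
#' curve$relative[curve$r_in == 0.1]  # exactly 1
#' }
#' @export
sweep_rin <- function(params, r_in = default_rin_grid()) {
  params <- validate_params(params)
  if (!length(r_in) || any(!is.finite(r_in)) || any(r_in < 0 | r_in > 0.1))
    stop("r_in grid values must lie in [0, 0.1]")
  anchor <- which(abs(r_in - 0.1) < 1e-12)
  if (!length(anchor))
    stop("r_in grid must contain the normalization anchor 0.1")

  runs <- vector("list", length(r_in))
  for (i in seq_along(r_in)) {
    pi <- params
    pi$lambda_load <- r_in[i]
    pi$seed <- params$seed + i - 1L
    runs[[i]] <- run_simulation(pi)
  }
  r_out <- vapply(runs, `[[`, numeric(1), "r_out")
  se <- vapply(runs, `[[`, numeric(1), "r_out_se")
  load <- vapply(runs, `[[`, numeric(1), "realized_load_rate")

  a <- anchor[1]
  r0 <- r_out[a]
  if (r0 <= 0)
    stop("r_out at the anchor r_in = 0.1 is zero; cannot normalize the curve")
  rel <- r_out / r0
  # independent runs: delta-method error of the ratio
  rel_se <- sqrt((se / r0)^2 + (r_out * se[a] / r0^2)^2)
  rel[a] <- 1
  rel_se[a] <- 0

  curve <- data.frame(r_in = r_in, r_out = r_out, r_out_se = se,
                      relative = rel, relative_se = rel_se,
                      realized_load_rate = load)
  attr(curve, "params") <- params
  class(curve) <- c("response_curve", "data.frame")
  curve
}

#' Locate the response-curve maximum
#'
#' The maximum of `r_out` over the grid points with `r_in > 0` (the
#' `r_in = 0` endpoint carries no flux by construction). Because the
#' relative curve is the absolute curve divided by one constant, the
#' absolute and relative maxima sit at the same grid point. Ties are
#' broken toward the smallest `r_in`.
#'
#' @param curve A `response_curve` from [sweep_rin()].
#' @return List with `r_in_at_max`, `max_absolute`, `max_absolute_se`,
#'   `max_relative`, `max_relative_se`.
#' @export
find_max <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  cand <- which(curve$r_in > 0)
  if (!length(cand) || all(curve$r_out[cand] == 0))
    stop("degenerate response curve: no nonzero r_out at positive r_in")
  best <- cand[curve$r_out[cand] == max(curve$r_out[cand])]
  best <- best[which.min(curve$r_in[best])]
  list(r_in_at_max = curve$r_in[best],
       max_absolute = curve$r_out[best],
       max_absolute_se = curve$r_out_se[best],
       max_relative = curve$relative[best],
       max_relative_se = curve$relative_se[best])
}

#' Detect a non-monotonic (stress-resistant) response curve
#'
#' A curve is flagged non-monotonic when some interior point (0 < `r_in`
#' < 0.1) has a relative `r_out` exceeding 1 by more than `k` standard
#' errors — i.e. downstream flux demonstrably *rises* as loading falls
#' below the unstressed level.
#'
#' @param curve A `response_curve`.
#' @param k Standard-error multiplier for the detection threshold.
#' @return `TRUE` or `FALSE`.
#' @export
detect_nonmonotonic <- function(curve, k = 2) {
  stopifnot(inherits(curve, "response_curve"), k >= 0)
  interior <- curve$r_in > 0 & abs(curve$r_in - 0.1) > 1e-12
  any(curve$relative[interior] > 1 + k * curve$relative_se[interior])
}

#' Sweep a model parameter across values, one response curve each
#'
#' For each value of the varied parameter a full [sweep_rin()] is run and
#' summarised: curve maximum, non-monotonicity flag, anchor flux, and the
#' maximum flux normalized to a reference value of the varied parameter
#' (e.g. uORF-length scans are conventionally normalized to the minimal
#' length L2 = 2).
#'
#' @param varying Name of a [sim_params()] field to vary.
#' @param values Values to scan, in scan order.
#' @param base_params Base [sim_params()].
#' @param r_in Loading-rate grid passed to [sweep_rin()].
#' @param reference Value of `varying` used to normalize `max_vs_reference`
#'   (default: the first scanned value).
#' @return A `grid_experiment`: list with `summary` (one row per value)
#'   and `curves` (named list of `response_curve`s).
#' @export
grid_experiment <- function(varying, values, base_params,
                            r_in = default_rin_grid(),
                            reference = values[1]) {
  base_params <- validate_params(base_params)
  if (!varying %in% names(unclass(base_params)))
    stop("unknown parameter name: ", varying)
  if (!reference %in% values)
    stop("reference value must be one of the scanned values")

  curves <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (j in seq_along(values)) {
    pj <- base_params
    pj[[varying]] <- values[j]
    pj$seed <- base_params$seed + (j - 1L) * 1000L
    pj <- validate_params(pj)
    cv <- sweep_rin(pj, r_in = r_in)
    mx <- find_max(cv)
    anchor <- which(abs(cv$r_in - 0.1) < 1e-12)[1]
    rows[[j]] <- data.frame(
      value = values[j],
      r_out_at_anchor = cv$r_out[anchor],
      r_in_at_max = mx$r_in_at_max,
      max_absolute = mx$max_absolute,
      max_absolute_se = mx$max_absolute_se,
      max_relative = mx$max_relative,
      max_relative_se = mx$max_relative_se,
      nonmonotonic = detect_nonmonotonic(cv)
    )
    curves[[j]] <- cv
  }
  summary <- do.call(rbind, rows)
  ref_max <- summary$max_absolute[match(reference, values)]
  summary$max_vs_reference <- summary$max_absolute / ref_max
  names(curves) <- as.character(values)
  structure(list(varying = varying, values = values, reference = reference,
                 summary = summary, curves = curves),
            class = "grid_experiment")
}

#' @export
print.grid_experiment <- function(x, ...) {
  cat(sprintf("Grid experiment over '%s' (%d values, reference %s)\n",
              x$varying, length(x$values), format(x$reference)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Built-in threshold-scan criteria
#'
#' Predicate factories for [threshold_scan()]: detection of a
#' non-monotonic (stress-resistant) curve, its absence, and the curve
#' maximum falling below a cutoff ("resistance essentially abolished";
#' the default cutoff 1.05 operationalizes a near-flat relative curve).
#'
#' @param k Standard-error multiplier, see [detect_nonmonotonic()].
#' @param cutoff Relative-maximum cutoff.
#' @return A function mapping a `response_curve` to `TRUE`/`FALSE`.
#' @name criteria
NULL

#' @rdname criteria
#' @export
criterion_nonmonotonic <- function(k = 2) {
  function(curve) detect_nonmonotonic(curve, k = k)
}

#' @rdname criteria
#' @export
criterion_no_resistance <- function(k = 2) {
  function(curve) !detect_nonmonotonic(curve, k = k)
}

#' @rdname criteria
#' @export
criterion_max_relative_below <- function(cutoff = 1.05) {
  function(curve) find_max(curve)$max_relative < cutoff
}

#' Scan a parameter for the value at which a curve property flips
#'
#' Runs a [grid_experiment()] over `values` (in the given order) and
#' evaluates `criterion` on each response curve. The threshold is the
#' first scanned value whose predicate differs from the first value's;
#' both flanking values are reported.
#'
#' @param varying Name of the [sim_params()] field to scan.
#' @param values Scan values, ordered in the scan direction.
#' @param criterion Predicate on a `response_curve`; see [criteria].
#' @param base_params Base [sim_params()].
#' @param r_in Loading-rate grid.
#' @return A `threshold_scan`: list with `values`, logical `flags`,
#'   `threshold` (first value after the flip), `last_before` (last value
#'   before it), and the underlying `grid_experiment`.
#' @export
threshold_scan <- function(varying, values, criterion, base_params,
                           r_in = default_rin_grid()) {
  stopifnot(is.function(criterion), length(values) >= 2)
  exp <- grid_experiment(varying, values, base_params, r_in = r_in)
  flags <- vapply(exp$curves, criterion, logical(1))
  flip <- which(flags != flags[1])
  if (!length(flip))
    stop(sprintf("no threshold in range: criterion is constantly %s over the scan",
                 flags[1]))
  i <- flip[1]
  structure(list(varying = varying, values = values, flags = unname(flags),
                 threshold = values[i], last_before = values[i - 1],
                 experiment = exp),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Threshold scan over '%s'\n", x$varying))
  cat("  values:", paste(format(x$values), collapse = " "), "\n")
  cat("  flags: ", paste(ifelse(x$flags, "T", "f"), collapse = " "), "\n")
  cat(sprintf("  criterion flips between %s and %s\n",
              format(x$last_before), format(x$threshold)))
  invisible(x)
}

#' Plot a response curve
#'
#' @param x A `response_curve`.
#' @param relative Plot the relative curve (default) or absolute `r_out`.
#' @param se_bars Draw +/- 2 SE bars.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.response_curve <- function(x, relative = TRUE, se_bars = TRUE, ...) {
  y <- if (relative) x$relative else x$r_out
  s <- if (relative) x$relative_se else x$r_out_se
  ylab <- if (relative) "r_out relative to r_in = 0.1" else "r_out"
  graphics::plot(x$r_in, y, type = "b", pch = 16, xlab = "r_in",
                 ylab = ylab, ...)
  if (se_bars)
    graphics::arrows(x$r_in, y - 2 * s, x$r_in, y + 2 * s,
                     angle = 90, code = 3, length = 0.02)
  if (relative) graphics::abline(h = 1, lty = 2)
  invisible(x)
}
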