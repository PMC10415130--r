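# PR-2 metrics: GC/AT skew computation, per-kingdom tolerance boxes,
# compliance calls, NSB rate-ratio diagnostics, and the time-to-PR-2 versus
# time-to-equilibration analysis.

#' GC and AT skews of base compositions
#'
#' Computes the intra-strand skews (G - C) / (G + C) and (A - T) / (A + T).
#' Compositions obeying Chargaff's second parity rule give (0, 0). A zero
#' denominator (a composition with no G+C or no A+T at all) is reported as
#' skew 0 with `skew_degenerate = TRUE`; such states never arise from
#' positive-rate kinetics.
#'
#' @param x A composition: tibble/data frame with columns `A`, `C`, `G`, `T`
#'   (one row per composition), or a named numeric vector.
#' @return A tibble with columns `gc_skew`, `at_skew`, `skew_degenerate`, one
#'   row per composition.
#' @export
#' @examples
#' skews(c(A = 0.3, C = 0.2, G = 0.3, T = 0.2))
skews <- function(x) {
  cm <- composition_matrix_lax(x)
  gden <- cm[, "G"] + cm[, "C"]
  aden <- cm[, "A"] + cm[, "T"]
  tibble::tibble(
    gc_skew = unname(ifelse(gden > 0,
      (cm[, "G"] - cm[, "C"]) / pmax(gden, .Machine$double.xmin), 0)),
    at_skew = unname(ifelse(aden > 0,
      (cm[, "A"] - cm[, "T"]) / pmax(aden, .Machine$double.xmin), 0)),
    skew_degenerate = unname(gden == 0 | aden == 0)
  )
}

# Internal: like composition_matrix() but without the sum-to-1 requirement
# (skews are scale invariant; counts are accepted too).
composition_matrix_lax <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) {
    m <- as.matrix(as.data.frame(x)[base_order()])
  } else {
    if (is.null(names(x))) names(x) <- base_order()
    m <- matrix(x[base_order()], nrow = 1,
                dimnames = list(NULL, base_order()))
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    rlang::abort("base contents/counts must be finite and non-negative")
  }
  m
}

#' Per-kingdom PR-2 tolerance boxes
#'
#' The packaged mean +/- 1 sd regions of the (GC skew, AT skew) plane observed
#' across extant genomes of each kingdom, used as the PR-2 compliance regions.
#' Boxes are closed: a skew exactly on the boundary is compliant.
#'
#' @param kingdom Optional: one of `"eukaryote"`, `"prokaryote"`, `"virus"`
#'   to return a single box.
#' @return A tibble with columns `kingdom`, `gc_mean`, `gc_sd`, `at_mean`,
#'   `at_sd`.
#' @export
#' @examples
#' tolerance_boxes()
#' tolerance_boxes("prokaryote")
tolerance_boxes <- function(kingdom = NULL) {
  boxes <- tibble::tibble(
    kingdom = c("eukaryote", "prokaryote", "virus"),
    gc_mean = c(7.780e-5, 1.425e-4, 2.262e-2),
    gc_sd   = c(1.908e-3, 1.907e-2, 9.666e-2),
    at_mean = c(1.096e-5, -1.386e-5, 3.668e-2),
    at_sd   = c(1.178e-3, 9.401e-3, 1.041e-1)
  )
  if (is.null(kingdom)) return(boxes)
  kingdom <- match.arg(kingdom, boxes$kingdom)
  boxes[boxes$kingdom == kingdom, ]
}

#' PR-2 compliance against a tolerance box
#'
#' A skew pair complies when both |gc_skew - gc_mean| <= gc_sd and
#' |at_skew - at_mean| <= at_sd (closed region).
#'
#' @param s A tibble with columns `gc_skew` and `at_skew` (e.g. from
#'   [skews()]), or a length-2 numeric vector (gc, at).
#' @param box A one-row tolerance box (see [tolerance_boxes()]).
#' @return Logical vector, one entry per skew pair.
#' @export
is_pr2_compliant <- function(s, box = tolerance_boxes("eukaryote")) {
  if (is.numeric(s) && length(s) == 2) {
    s <- tibble::tibble(gc_skew = s[1], at_skew = s[2])
  }
  if (nrow(box) != 1) rlang::abort("`box` must be a single tolerance box")
  abs(s$gc_skew - box$gc_mean) <= box$gc_sd &
    abs(s$at_skew - box$at_mean) <= box$at_sd
}

#' Distribution of the ratio of two independent uniforms
#'
#' Closed-form density and CDF of R = X / Y with X, Y independent U(0, b)
#' (the bound b cancels): f(r) = 1/2 on (0, 1], 1 / (2 r^2) for r > 1;
#' F(r) = r/2 for r <= 1 and 1 - 1/(2r) beyond. This is the reference shape
#' of the NSB pair ratios for unconstrained uniform rate draws.
#'
#' @param r Non-negative ratio value(s).
#' @return Density or CDF values.
#' @export
uniform_ratio_density <- function(r) {
  ifelse(r <= 0, 0, ifelse(r <= 1, 0.5, 0.5 / r^2))
}

#' @rdname uniform_ratio_density
#' @export
uniform_ratio_cdf <- function(r) {
  ifelse(r <= 0, 0, ifelse(r <= 1, r / 2, 1 - 0.5 / r))
}

# Default ratio histogram breaks: equal width 0.5 on the log-ratio scale,
# centred so that one bin, (e^-0.25, e^0.25], contains the NSB equality
# ratio of 1. Log-symmetric bins treat a pair and its reciprocal
# identically, so the histogram mode is an even-handed peak estimator (a
# linear-scale binning of a ratio variable is biased below 1 by the
# reciprocal asymmetry).
ratio_breaks <- function() c(0, exp(seq(-3.25, 3.25, by = 0.5)), Inf)

#' NSB pair-ratio diagnostics for a rate ensemble
#'
#' For each of the six reverse-complement rate pairs, computes the ratio
#' (first member / second member) for every rate set, splits the ensemble by
#' PR-2 compliance, bins each subset into a histogram, and reports the mode
#' bin. Under the no-strand-bias equalities every ratio is exactly 1; for
#' unconstrained uniform draws the ratios follow the classical uniform-ratio
#' distribution.
#'
#' @param rates Tibble of rate sets (12 mutation-label columns).
#' @param compliant Logical vector, one entry per rate set (PR-2 compliance
#'   of the evolved system).
#' @param breaks Histogram breaks; the default is log-symmetric around 1
#'   with a bin (e^-0.25, e^0.25] containing 1.
#' @return A list of class `pr2_ratio_diag` with elements `ratios` (long
#'   tibble: `pair`, `ratio`, `compliant`), `histograms` (binned counts per
#'   pair and subset), `modes` (per pair and subset: the mode bin and whether
#'   it contains 1), and `n_dropped` (zero-denominator ratios excluded).
#' @export
nsb_ratio_diagnostics <- function(rates, compliant, breaks = ratio_breaks()) {
  rates <- validate_rates(rates)
  if (length(compliant) != nrow(rates)) {
    rlang::abort("`compliant` must have one entry per rate set")
  }
  pairs <- nsb_pairs()
  num <- as.matrix(rates[pairs$first])
  den <- as.matrix(rates[pairs$second])
  long <- tibble::tibble(
    pair = rep(pairs$pair, each = nrow(rates)),
    numerator = as.vector(num),
    denominator = as.vector(den),
    compliant = rep(compliant, times = 6)
  )
  n_dropped <- sum(long$denominator == 0)
  long <- long[long$denominator > 0, ]
  long$ratio <- long$numerator / long$denominator
  ratios <- long[, c("pair", "ratio", "compliant")]
  histograms <- ratios |>
    dplyr::mutate(bin = cut(.data$ratio, breaks = breaks,
                            include.lowest = TRUE)) |>
    dplyr::count(.data$pair, .data$compliant, .data$bin, name = "count")
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  modes <- histograms |>
    dplyr::group_by(.data$pair, .data$compliant) |>
    dplyr::slice_max(.data$count, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      bin_lo = lo[as.integer(.data$bin)],
      bin_hi = hi[as.integer(.data$bin)],
      contains_one = .data$bin_lo < 1 & 1 <= .data$bin_hi
    )
  structure(list(ratios = ratios, histograms = histograms, modes = modes,
                 n_dropped = n_dropped, breaks = breaks),
            class = "pr2_ratio_diag")
}

# Internal: bisection refinement of the first time a predicate on the
# composition becomes true, given a bracketing interval [lo, hi] with
# predicate FALSE at lo and TRUE at hi. Returns a time within `resolution`.
bisect_crossing <- function(kvec, c0, lo, hi, predicate, resolution = 1e-3) {
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    comp <- as.numeric(cpp_composition_at(kvec, c0, mid))
    names(comp) <- base_order()
    if (predicate(comp)) hi <- mid else lo <- mid
  }
  hi
}

#' First time a trajectory enters the PR-2 tolerance box
#'
#' Scans the recorded trajectory for the first time both skews fall inside
#' the tolerance box (first crossing; compliance of linear-ODE skew
#' trajectories need not be monotone, so an optional persistence window can
#' require the following `persistence` byr of records to remain compliant).
#' When the generating rate set is supplied, the crossing is refined by
#' bisection between the bracketing records using the exact linear-ODE
#' propagator, to `resolution` byr.
#'
#' @param traj A `pr2_trajectory` tibble from [evolve()].
#' @param box One-row tolerance box.
#' @param rates Optional one-row rate tibble / named 12-vector used to refine
#'   the crossing time by bisection.
#' @param resolution Bisection resolution, byr.
#' @param persistence Require compliance to persist for this many byr of
#'   subsequent records (0 = plain first crossing).
#' @return Crossing time in byr, `0` if already compliant at t = 0, or `NA`
#'   if never compliant within the recorded horizon.
#' @export
time_to_pr2 <- function(traj, box, rates = NULL, resolution = 1e-3,
                        persistence = 0) {
  sk <- skews(traj[base_order()])
  ok <- is_pr2_compliant(sk, box)
  if (persistence > 0) {
    tt <- traj$time_byr
    ok <- vapply(seq_along(ok), function(i) {
      win <- which(tt >= tt[i] & tt <= tt[i] + persistence)
      all(ok[win])
    }, logical(1))
  }
  idx <- which(ok)[1]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1) return(traj$time_byr[1])
  if (is.null(rates)) return(traj$time_byr[idx])
  rates <- validate_rates(rates)
  kvec <- as.numeric(rates[1, mutation_labels()])
  c0 <- unlist(traj[1, base_order()])
  predicate <- function(comp) is_pr2_compliant(skews(comp), box)
  bisect_crossing(kvec, c0, traj$time_byr[idx - 1], traj$time_byr[idx],
                  predicate, resolution)
}

#' Time to compositional equilibration for an ensemble of trajectories
#'
#' Two documented interpretations of the equilibration call:
#' \describe{
#'   \item{oracle_threshold}{A replicate is equilibrated at the first time
#'     max_b |C_b(t) - C_b(inf)| <= `eq_tolerance`, with the stationary
#'     composition C(inf) obtained from the null-space oracle.}
#'   \item{fluctuation_calibrated}{The calibration procedure: the
#'     per-replicate fluctuation between consecutive records is
#'     sum_b |dC_b| / 4; the ensemble-mean fluctuation over `checkpoints`
#'     evenly spaced reference records defines EQtolerance as 1% of its mean;
#'     a replicate is equilibrated at the first record where the range
#'     (max - min) across bases of |dC_b| is at or below EQtolerance.}
#' }
#'
#' @param trajs A list of `pr2_trajectory` tibbles sharing one recording
#'   grid.
#' @param mode `"oracle_threshold"` or `"fluctuation_calibrated"`.
#' @param rates Optional tibble of generating rate sets (one row per
#'   trajectory); required for the oracle mode (stationary compositions and
#'   bisection refinement).
#' @param eq_tolerance Content tolerance for the oracle mode.
#' @param checkpoints Number of reference records for the calibration.
#' @param resolution Bisection resolution (oracle mode), byr.
#' @return A tibble with columns `replicate`, `t_eq` (byr; `NA` when not
#'   reached) and, for the calibrated mode, the attribute `eq_tolerance`.
#' @export
time_to_equilibrium <- function(trajs,
                                mode = c("fluctuation_calibrated",
                                         "oracle_threshold"),
                                rates = NULL, eq_tolerance = 1e-4,
                                checkpoints = 25, resolution = 1e-3) {
  mode <- match.arg(mode)
  times <- trajs[[1]]$time_byr
  arr <- vapply(trajs, function(tr) t(as.matrix(tr[base_order()])),
                matrix(0, 4, length(times)))  # 4 x m x n
  if (mode == "oracle_threshold") {
    if (is.null(rates)) {
      rlang::abort("oracle mode needs the generating `rates`")
    }
    rates <- validate_rates(rates)
    km <- as.matrix(rates[mutation_labels()])
    out <- t_eq_oracle(arr, times, km, eq_tolerance, resolution)
    tibble::tibble(replicate = seq_along(trajs), t_eq = out)
  } else {
    res <- t_eq_fluctuation(arr, times, checkpoints)
    structure(tibble::tibble(replicate = seq_along(trajs), t_eq = res$t_eq),
              eq_tolerance = res$eq_tolerance)
  }
}

# Internal oracle-mode equilibration times for a 4 x m x n array.
t_eq_oracle <- function(arr, times, km, eq_tolerance, resolution = 1e-3) {
  n <- dim(arr)[3]
  out <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    kvec <- km[s, ]
    cinf <- stationary_from_k(kvec)
    if (is.null(cinf)) next
    err <- apply(abs(arr[, , s] - cinf), 2, max)
    idx <- which(err <= eq_tolerance)[1]
    if (is.na(idx)) next
    if (idx == 1) {
      out[s] <- times[1]
    } else {
      predicate <- function(comp) max(abs(comp - cinf)) <= eq_tolerance
      out[s] <- bisect_crossing(kvec, arr[, 1, s], times[idx - 1],
                                times[idx], predicate, resolution)
    }
  }
  out
}

# Internal fluctuation-calibrated equilibration times.
t_eq_fluctuation <- function(arr, times, checkpoints = 25) {
  m <- length(times)
  n <- dim(arr)[3]
  dC <- abs(arr[, -1, , drop = FALSE] - arr[, -m, , drop = FALSE])  # 4 x (m-1) x n
  fluct <- colSums(dC) / 4                                          # (m-1) x n
  if (n == 1) fluct <- matrix(fluct, ncol = 1)
  ref_idx <- unique(round(seq(1, m - 1, length.out = checkpoints)))
  eq_tol <- 0.01 * mean(fluct[ref_idx, ])
  sub <- function(b) matrix(dC[b, , ], ncol = n)
  rng <- pmax(sub(1), sub(2), sub(3), sub(4)) -
    pmin(sub(1), sub(2), sub(3), sub(4))                            # (m-1) x n
  first <- apply(rng <= eq_tol, 2, function(v) which(v)[1])
  t_eq <- ifelse(is.na(first), NA_real_, times[first + 1])
  list(t_eq = t_eq, eq_tolerance = eq_tol)
}

# Internal: stationary composition from a 12-vector of rates; NULL when the
# network is reducible.
stationary_from_k <- function(kvec) {
  M <- cpp_rate_matrix(kvec)
  sv <- svd(M)
  if (sum(sv$d < 1e-10 * max(1, sv$d[1])) > 1) return(NULL)
  v <- sv$v[, 4]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  stats::setNames(v / sum(v), base_order())
}

#' Paired time-to-PR-2 / time-to-equilibration study
#'
#' Samples an ensemble of rate sets and initial compositions, evolves every
#' system with the exact linear-ODE propagator on a shared recording grid,
#' and measures for each replicate the first time its skews enter the PR-2
#' tolerance box and the time it reaches compositional equilibration (both
#' equilibration interpretations available).
#'
#' @param n Number of replicates (>= 100 recommended for distributions).
#' @param rate_mode,multiplier Passed to [sample_rates()].
#' @param init_mode Passed to [sample_initial()].
#' @param box One-row PR-2 tolerance box.
#' @param horizon Simulation horizon, byr. The default study horizon is a
#'   4.28-byr window; extend it to distinguish "slow" from "not reached".
#' @param n_points Number of (uniform) recording intervals on the grid.
#' @param seed Master seed; rate and initial-composition draws use derived
#'   sub-seeds.
#' @param eq_mode Equilibration interpretation: `"fluctuation_calibrated"`,
#'   `"oracle_threshold"`, or `"both"`.
#' @param eq_tolerance Oracle-mode content tolerance.
#' @param resolution Bisection resolution for crossing times, byr.
#' @param chunk_size Systems propagated per memory chunk.
#' @return A `pr2_timing` object: list with `replicates` (tibble: `.draw`,
#'   `t_pr2`, `t_eq` and/or `t_eq_oracle`, final skews, compliance flag) and
#'   `params`. Use [generics::tidy()] / [generics::glance()] to extract.
#' @export
timing_study <- function(n = 1000, rate_mode = "truncnorm_symmetric",
                         multiplier = 1, init_mode = "random_constrained",
                         box = tolerance_boxes("prokaryote"),
                         horizon = 4.28, n_points = 250, seed = 1,
                         eq_mode = c("fluctuation_calibrated",
                                     "oracle_threshold", "both"),
                         eq_tolerance = 1e-4, resolution = 1e-3,
                         chunk_size = 2000) {
  eq_mode <- match.arg(eq_mode)
  if (n < 1) rlang::abort("`n` must be positive")
  rates <- sample_rates(n, mode = rate_mode, multiplier = multiplier,
                        seed = seed)
  inits <- sample_initial(n, mode = init_mode, seed = seed + 1)
  km <- as.matrix(rates[mutation_labels()])
  cm <- as.matrix(inits[base_order()])
  times <- seq(0, horizon, length.out = n_points + 1)
  m <- length(times)

  t_pr2 <- rep(NA_real_, n)
  final_gc <- final_at <- rep(NA_real_, n)
  arr_all <- array(0, dim = c(4, m, n))
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, n)
    arr <- cpp_batch_trajectories(km[idx, , drop = FALSE],
                                  cm[idx, , drop = FALSE], times)
    arr_all[, , idx] <- arr
  }
  for (s in seq_len(n)) {
    comp <- arr_all[, , s]  # 4 x m, rows A C G T
    gc <- (comp[3, ] - comp[2, ]) / (comp[3, ] + comp[2, ])
    at <- (comp[1, ] - comp[4, ]) / (comp[1, ] + comp[4, ])
    ok <- abs(gc - box$gc_mean) <= box$gc_sd &
      abs(at - box$at_mean) <= box$at_sd
    final_gc[s] <- gc[m]
    final_at[s] <- at[m]
    idx <- which(ok)[1]
    if (!is.na(idx)) {
      if (idx == 1) {
        t_pr2[s] <- 0
      } else {
        predicate <- function(cc) is_pr2_compliant(skews(cc), box)
        t_pr2[s] <- bisect_crossing(km[s, ], arr_all[, 1, s],
                                    times[idx - 1], times[idx],
                                    predicate, resolution)
      }
    }
  }

  reps <- tibble::tibble(
    .draw = seq_len(n), t_pr2 = t_pr2,
    final_gc_skew = final_gc, final_at_skew = final_at,
    compliant_at_horizon = is_pr2_compliant(
      tibble::tibble(gc_skew = final_gc, at_skew = final_at), box)
  )
  eq_tol_used <- NA_real_
  if (eq_mode %in% c("fluctuation_calibrated", "both")) {
    res <- t_eq_fluctuation(arr_all, times)
    reps$t_eq <- res$t_eq
    eq_tol_used <- res$eq_tolerance
  }
  if (eq_mode %in% c("oracle_threshold", "both")) {
    te <- t_eq_oracle(arr_all, times, km, eq_tolerance, resolution)
    if (eq_mode == "oracle_threshold") reps$t_eq <- te else reps$t_eq_oracle <- te
  }
  structure(list(
    replicates = reps,
    params = list(n = n, rate_mode = rate_mode, multiplier = multiplier,
                  init_mode = init_mode, box = box, horizon = horizon,
                  n_points = n_points, seed = seed, eq_mode = eq_mode,
                  eq_tolerance = eq_tolerance,
                  eq_tolerance_calibrated = eq_tol_used)
  ), class = "pr2_timing")
}

#' @export
print.pr2_timing <- function(x, ...) {
  g <- generics::glance(x)
  cat("<pr2_timing> ", x$params$n, " replicates, multiplier ",
      x$params$multiplier, ", horizon ", x$params$horizon, " byr\n", sep = "")
  cat(sprintf("  mean t_PR2 %.3f byr | mean t_eq %.3f byr | mean gap %.3f byr\n",
              g$mean_t_pr2, g$mean_t_eq, g$mean_gap))
  cat(sprintf("  PR-2 reached: %.1f%% | equilibrated: %.1f%%\n",
              100 * g$frac_pr2_reached, 100 * g$frac_eq_reached))
  invisible(x)
}

#' Tidy and summarise timing studies
#'
#' `tidy()` returns the per-replicate records; `glance()` a one-row summary
#' with the mean/median crossing times (over replicates where both times were
#' reached), the mean gap t_eq - t_pr2, and the reached fractions.
#'
#' @param x A `pr2_timing` object.
#' @param ... Unused.
#' @export
tidy.pr2_timing <- function(x, ...) x$replicates

#' @rdname tidy.pr2_timing
#' @export
glance.pr2_timing <- function(x, ...) {
  r <- x$replicates
  both <- !is.na(r$t_pr2) & !is.na(r$t_eq)
  tibble::tibble(
    n = nrow(r),
    mean_t_pr2 = mean(r$t_pr2[both]),
    median_t_pr2 = stats::median(r$t_pr2[both]),
    mean_t_eq = mean(r$t_eq[both]),
    median_t_eq = stats::median(r$t_eq[both]),
    mean_gap = mean(r$t_eq[both] - r$t_pr2[both]),
    frac_pr2_reached = mean(!is.na(r$t_pr2)),
    frac_eq_reached = mean(!is.na(r$t_eq)),
    frac_compliant_at_horizon = mean(r$compliant_at_horizon)
  )
}

#' Write timing results to TSV / summary JSON
#'
#' @param x A `pr2_timing` object.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @export
write_timing <- function(x, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) readr::write_tsv(generics::tidy(x), tsv)
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      rlang::abort("writing JSON summaries requires the jsonlite package")
    }
    jsonlite::write_json(as.list(generics::glance(x)), json,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
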