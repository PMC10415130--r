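# Singleton (4-state) mutation kinetics: the general 12-rate ODE network, its
# NSB-reduced form, numerical evolution, and closed-form equilibria.

base_order <- function() c("A", "C", "G", "T")

# Internal: coerce a composition to a named numeric vector in A,C,G,T order.
validate_composition <- function(comp, tol = 1e-9) {
  if (is.data.frame(comp)) comp <- unlist(comp[1, base_order()])
  if (is.null(names(comp))) {
    if (length(comp) != 4) rlang::abort("composition must have 4 entries")
    names(comp) <- base_order()
  }
  comp <- comp[base_order()]
  if (any(!is.finite(comp)) || any(comp < -tol) || any(comp > 1 + tol)) {
    rlang::abort("base contents must lie in [0, 1]")
  }
  if (abs(sum(comp) - 1) > tol) {
    rlang::abort("base contents must sum to 1")
  }
  comp
}

#' Build the 4x4 generator matrix of the mutation network
#'
#' Columns index the source base and rows the target base (A, C, G, T), so the
#' off-diagonal entry in row u, column s is the rate constant of the s -> u
#' mutation and each column sums to zero. With this convention the base-content
#' vector C = (C_A, C_C, C_G, C_T) evolves as dC/dt = M C, which written out
#' per target base is exactly the four kinetic equations of the general model.
#'
#' @param rates A one-row rate tibble or named vector with the 12 mutation
#'   labels (see [mutation_labels()]).
#' @return A 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
#' @examples
#' build_rate_matrix(nsb_expand(reference_symmetric_rates()))
build_rate_matrix <- function(rates) {
  rates <- validate_rates(rates)
  if (nrow(rates) != 1) rlang::abort("expected a single rate set")
  k <- as.numeric(rates[1, mutation_labels()])
  M <- cpp_rate_matrix(k)
  dimnames(M) <- list(base_order(), base_order())
  M
}

# Internal: log-spaced recording grid starting at 0.
record_grid <- function(horizon, n_points = 1000, t_min = NULL) {
  if (is.null(t_min)) t_min <- horizon * 1e-6
  c(0, exp(seq(log(t_min), log(horizon), length.out = n_points)))
}

#' Evolve a genome composition under the mutation ODE network
#'
#' Integrates dC/dt = M C with a stiff-capable solver (deSolve lsoda,
#' rtol 1e-9 / atol 1e-12 by default) and returns the trajectory as a tidy
#' tibble. The system is linear, so the result can be cross-checked against
#' the matrix-exponential solution.
#'
#' @param rates One-row rate tibble or named 12-vector.
#' @param c0 Initial base composition (named A/C/G/T, sums to 1).
#' @param horizon Final time, byr; must be positive.
#' @param record_times Optional increasing vector of output times starting at
#'   0; default is a 1000-point log-spaced grid plus t = 0.
#' @param rtol,atol Solver tolerances.
#' @return A `pr2_trajectory` tibble with columns `time_byr`, `A`, `C`, `G`,
#'   `T`.
#' @export
#' @examples
#' evolve(nsb_expand(reference_symmetric_rates()),
#'        c(A = 0.25, C = 0.25, G = 0.25, T = 0.25), horizon = 4.28)
evolve <- function(rates, c0, horizon = 4.28, record_times = NULL,
                   rtol = 1e-9, atol = 1e-12) {
  if (!is.numeric(horizon) || horizon <= 0) {
    rlang::abort("`horizon` must be positive")
  }
  M <- build_rate_matrix(rates)
  c0 <- validate_composition(c0)
  if (is.null(record_times)) record_times <- record_grid(horizon)
  if (record_times[1] != 0 || is.unsorted(record_times, strictly = TRUE)) {
    rlang::abort("`record_times` must be strictly increasing and start at 0")
  }
  if (max(record_times) > horizon + 1e-12) {
    rlang::abort("`record_times` must not exceed the horizon")
  }
  sol <- deSolve::ode(
    y = unname(c0), times = record_times,
    func = function(t, y, parms) list(as.numeric(parms %*% y)),
    parms = M, rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort("ODE integration failed; see deSolve diagnostics")
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("time_byr", base_order())
  class(out) <- c("pr2_trajectory", class(out))
  out
}

#' Evolve under the NSB-reduced kinetic equations
#'
#' A dedicated integrator for the six-rate no-strand-bias formulation, written
#' directly from the reduced kinetic equations (not by expanding to 12 rates).
#' Used to cross-check that the general and reduced formulations are
#' trajectory-identical when the rates are symmetric.
#'
#' @param sym One-row tibble or named vector with symbols `i`..`n`.
#' @inheritParams evolve
#' @return A `pr2_trajectory` tibble.
#' @export
evolve_nsb <- function(sym, c0, horizon = 4.28, record_times = NULL,
                       rtol = 1e-9, atol = 1e-12) {
  sym <- validate_symmetric(sym)
  if (nrow(sym) != 1) rlang::abort("expected a single symmetric rate set")
  p <- as.list(sym[1, ])
  c0 <- validate_composition(c0)
  if (is.null(record_times)) record_times <- record_grid(horizon)
  # state order A, C, G, T
  deriv <- function(t, y, parms) {
    with(parms, {
      A <- y[1]; C <- y[2]; G <- y[3]; T <- y[4]
      dA <- i * C + l * T + m * G - (j + l + n) * A
      dG <- n * A + k * C + j * T - (m + i + k) * G
      dT <- l * A + i * G + m * C - (l + n + j) * T
      dC <- j * A + n * T + k * G - (i + m + k) * C
      list(c(dA, dC, dG, dT))
    })
  }
  sol <- deSolve::ode(y = unname(c0), times = record_times, func = deriv,
                      parms = p, rtol = rtol, atol = atol)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("time_byr", base_order())
  class(out) <- c("pr2_trajectory", class(out))
  out
}

#' Closed-form equilibrium of the NSB system
#'
#' At stationarity the six-rate system has the unique normalised solution
#' C_A = C_T = (i + m) / (2 (i + j + m + n)) and
#' C_G = C_C = (j + n) / (2 (i + j + m + n)), which satisfies both intra-strand
#' parity identities exactly (PR-2 at equilibrium). Independent of k and l.
#'
#' @param sym One-row tibble or named vector with `i`..`n`; requires
#'   i + j + m + n > 0.
#' @return Named composition vector (A, C, G, T) summing to 1.
#' @export
#' @examples
#' nsb_equilibrium(reference_symmetric_rates())
nsb_equilibrium <- function(sym) {
  sym <- validate_symmetric(sym)
  if (nrow(sym) != 1) rlang::abort("expected a single symmetric rate set")
  i <- sym$i; j <- sym$j; m <- sym$m; n <- sym$n
  tot <- i + j + m + n
  if (tot <= 0) {
    rlang::abort("degenerate NSB system: i + j + m + n must be positive")
  }
  at <- (i + m) / (2 * tot)
  gc <- (j + n) / (2 * tot)
  c(A = at, C = gc, G = gc, T = at)
}

#' Equilibrium G+C content under NSB
#'
#' Solves (n + j) / (i + m) = C_GC / (1 - C_GC) for the equilibrium G+C
#' content, giving (n + j) / (n + j + i + m); independent of the k and l
#' rates. When i + m = 0 with n + j > 0 the limiting value 1 is returned.
#'
#' @inheritParams nsb_equilibrium
#' @return Equilibrium G+C content in \[0, 1\].
#' @export
gc_equilibrium <- function(sym) {
  sym <- validate_symmetric(sym)
  i <- sym$i; j <- sym$j; m <- sym$m; n <- sym$n
  tot <- i + m + j + n
  if (any(tot <= 0)) {
    rlang::abort("degenerate NSB system: i + j + m + n must be positive")
  }
  (n + j) / tot
}

#' Stationary composition of a general 12-rate network
#'
#' Computes the normalised null-space vector of the generator matrix: the
#' long-time limit of the kinetics for an irreducible network. Serves as the
#' linear-algebra oracle against which long-time integration is checked.
#'
#' For reducible networks whose generator has a multi-dimensional null space
#' (more than one closed communicating class) the stationary composition is
#' not unique and an error is raised; the long-time limit then depends on the
#' initial composition and must be obtained with [evolve()].
#'
#' @param rates One-row rate tibble or named 12-vector.
#' @param tol Singular-value threshold for detecting the null space.
#' @return Named composition vector (A, C, G, T) summing to 1.
#' @export
stationary_composition <- function(rates, tol = 1e-10) {
  M <- build_rate_matrix(rates)
  sv <- svd(M)
  null_dim <- sum(sv$d < tol * max(1, sv$d[1]))
  if (null_dim == 0) {
    # generator always has a zero eigenvalue; fall back to smallest
    null_dim <- 1
  }
  if (null_dim > 1) {
    rlang::abort(paste0(
      "reducible mutation network: stationary composition is not unique (",
      null_dim, "-dimensional null space); evolve() from an initial state"
    ))
  }
  v <- sv$v[, 4]
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8)) {
    rlang::abort("null-space vector has negative entries; network malformed")
  }
  v <- pmax(v, 0)
  stats::setNames(v / sum(v), base_order())
}

#' Batch final compositions for an ensemble of rate sets
#'
#' Propagates many systems to a single time with the exact matrix-exponential
#' solution of the linear kinetics (compiled backend). This is the workhorse
#' for Monte Carlo ensembles where per-system adaptive integration would be
#' wasteful.
#'
#' @param rates Tibble with the 12 mutation-label columns, one row per system.
#' @param c0 Either a single composition (recycled) or a tibble/matrix with
#'   columns A, C, G, T and one row per system.
#' @param t Time, byr.
#' @return A tibble with columns `A`, `C`, `G`, `T`, one row per system.
#' @export
final_compositions <- function(rates, c0, t = 4.28) {
  rates <- validate_rates(rates)
  km <- as.matrix(rates[mutation_labels()])
  cm <- composition_matrix(c0)
  if (nrow(cm) != 1 && nrow(cm) != nrow(km)) {
    rlang::abort("`c0` must have 1 row or one row per rate set")
  }
  out <- cpp_final_compositions(km, cm, t)
  colnames(out) <- base_order()
  tibble::as_tibble(out)
}

# Internal: compositions as an n x 4 matrix in A,C,G,T order.
composition_matrix <- function(c0) {
  if (is.data.frame(c0)) {
    as.matrix(c0[base_order()])
  } else if (is.matrix(c0)) {
    c0[, base_order(), drop = FALSE]
  } else {
    matrix(validate_composition(c0), nrow = 1,
           dimnames = list(NULL, base_order()))
  }
}

#' Convergence horizon heuristic
#'
#' Default "large t" used when checking convergence to stationarity:
#' 100 / min(positive rates), capped at 1000 byr.
#'
#' @param rates One-row rate tibble or named 12-vector.
#' @return Time in byr.
#' @export
convergence_horizon <- function(rates) {
  rates <- validate_rates(rates)
  k <- as.numeric(rates[1, mutation_labels()])
  pos <- k[k > 0]
  if (length(pos) == 0) return(1000)
  min(100 / min(pos), 1000)
}

#' Write a trajectory to TSV
#'
#' Columns: `time_byr`, `C_A`, `C_C`, `C_G`, `C_T`.
#'
#' @param traj A `pr2_trajectory` tibble.
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  out <- traj
  names(out) <- c("time_byr", paste0("C_", base_order()))
  readr::write_tsv(out, path)
  invisible(traj)
}
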