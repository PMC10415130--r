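# Seeded Monte Carlo generation of rate sets and initial base compositions,
# following the three simulation protocols: unconstrained uniform draws,
# per-mutation truncated normals, and symmetry-constrained truncated normals.

# Internal: draws from a normal truncated below at 0, via the exact
# inverse-CDF transform (distribution-identical to a zero-truncated normal
# sampler; reproducible from the current RNG stream).
rtrunc0norm <- function(n, mean, sd) {
  if (any(sd < 0)) rlang::abort("sd must be non-negative")
  if (all(sd == 0)) return(rep(mean, length.out = n))
  p0 <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n)
  x <- stats::qnorm(p0 + u * (1 - p0), mean, sd)
  ifelse(sd == 0, mean, pmax(x, 0))
}

#' Upper bound of the uniform rate-sampling range
#'
#' The unconstrained uniform protocol draws every rate in \[0, U_m\] where
#' U_m = mean + m * sd of the largest symmetry-averaged reference rate
#' (the CT/GA pair). With the packaged reference table, m = 1 gives 1.799.
#'
#' @param multiplier Positive standard-deviation multiplier m.
#' @param reference Reference symmetric rate table (columns `mutation`,
#'   `mean`, `sd`); defaults to the packaged table.
#' @return Upper bound, per byr.
#' @export
#' @examples
#' uniform_upper_bound(1)  # 1.799
uniform_upper_bound <- function(multiplier = 1,
                                reference = reference_rates("symmetric")) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    rlang::abort("`multiplier` must be a single positive number")
  }
  row <- reference[which.max(reference$mean), ]
  row$mean + multiplier * row$sd
}

#' Sample mutation-rate sets
#'
#' Three sampling protocols:
#' \describe{
#'   \item{uniform_unconstrained}{12 independent draws from
#'     U(0, [uniform_upper_bound()]) -- the assumption-free protocol.}
#'   \item{truncnorm_individual}{12 independent draws from normals truncated
#'     at 0, centred at the per-mutation reference means with sd scaled by the
#'     multiplier.}
#'   \item{truncnorm_symmetric}{6 draws centred at the symmetry-averaged
#'     reference values (sd scaled by the multiplier), expanded to 12 rates
#'     with exact NSB pairing.}
#' }
#' Draws are taken sequentially from a single seeded RNG stream, so a given
#' (seed, mode, multiplier, n) always reproduces the same ensemble.
#'
#' @param n Number of rate sets.
#' @param mode Sampling protocol (see above).
#' @param multiplier Positive sd multiplier m (the protocols use 1, 2, 5, 10).
#' @param seed Integer seed.
#' @param reference Reference rate table for the chosen mode; defaults to the
#'   packaged individual or symmetric block as appropriate.
#' @return A tibble with columns `.draw` and the 12 mutation labels.
#' @export
#' @examples
#' sample_rates(3, mode = "uniform_unconstrained", seed = 1)
sample_rates <- function(n,
                         mode = c("uniform_unconstrained",
                                  "truncnorm_individual",
                                  "truncnorm_symmetric"),
                         multiplier = 1, seed = 1, reference = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    rlang::abort("`n` must be a positive integer")
  }
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    rlang::abort("`multiplier` must be a single positive number")
  }
  labs <- mutation_labels()
  out <- withr::with_seed(seed, {
    if (mode == "uniform_unconstrained") {
      upper <- uniform_upper_bound(
        multiplier,
        reference %||% reference_rates("symmetric")
      )
      m <- matrix(stats::runif(n * 12, 0, upper), nrow = n,
                  dimnames = list(NULL, labs))
      tibble::as_tibble(m)
    } else if (mode == "truncnorm_individual") {
      ref <- reference %||% reference_rates("individual")
      means <- stats::setNames(ref$mean, ref$mutation)[labs]
      sds <- stats::setNames(ref$sd, ref$mutation)[labs]
      m <- matrix(0, n, 12, dimnames = list(NULL, labs))
      for (d in seq_len(n)) {
        m[d, ] <- rtrunc0norm(12, means, multiplier * sds)
      }
      tibble::as_tibble(m)
    } else {
      ref <- reference %||% reference_rates("symmetric")
      pairs <- nsb_pairs()
      means <- stats::setNames(ref$mean, ref$mutation)[pairs$pair]
      sds <- stats::setNames(ref$sd, ref$mutation)[pairs$pair]
      m <- matrix(0, n, 6, dimnames = list(NULL, pairs$symbol))
      for (d in seq_len(n)) {
        m[d, ] <- rtrunc0norm(6, means, multiplier * sds)
      }
      nsb_expand(tibble::as_tibble(m))
    }
  })
  dplyr::bind_cols(tibble::tibble(.draw = seq_len(n)), out)
}

#' Sample initial base compositions
#'
#' Initial-composition protocols:
#' \describe{
#'   \item{uniform_quarter}{Every composition is (0.25, 0.25, 0.25, 0.25).}
#'   \item{random_constrained}{Two randomly chosen bases are drawn uniformly
#'     within `range` (default the plausible genomic per-base window
#'     0.1--0.4); one of the remaining bases is drawn uniformly in
#'     \[0, 1 - remainder\] and the last takes what is left, so the four always
#'     sum to exactly 1. Infeasible first draws (sum > 1) are resampled.}
#'   \item{corner_skews}{Cycles through the four compositions whose
#'     (GC skew, AT skew) pairs are (1,1), (-1,1), (1,-1), (-1,-1), using the
#'     symmetric split between the two nonzero bases (the extreme-skew
#'     compositions are otherwise underdetermined).}
#' }
#'
#' @param n Number of compositions.
#' @param mode Protocol (see above).
#' @param seed Integer seed.
#' @param range Length-2 allowed window for the two range-constrained bases in
#'   `random_constrained` mode.
#' @return A tibble with columns `.draw`, `A`, `C`, `G`, `T`.
#' @export
sample_initial <- function(n,
                           mode = c("uniform_quarter", "random_constrained",
                                    "corner_skews"),
                           seed = 1, range = c(0.1, 0.4)) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    rlang::abort("`n` must be a positive integer")
  }
  comp <- withr::with_seed(seed, {
    if (mode == "uniform_quarter") {
      matrix(0.25, n, 4, dimnames = list(NULL, base_order()))
    } else if (mode == "random_constrained") {
      if (length(range) != 2 || range[1] < 0 || range[2] > 1 ||
          range[1] > range[2]) {
        rlang::abort("`range` must be an increasing pair within [0, 1]")
      }
      m <- matrix(0, n, 4, dimnames = list(NULL, base_order()))
      for (d in seq_len(n)) {
        repeat {
          ord <- sample.int(4)
          two <- stats::runif(2, range[1], range[2])
          rem <- 1 - sum(two)
          if (rem >= 0) {
            third <- stats::runif(1, 0, rem)
            m[d, ord] <- c(two, third, rem - third)
            break
          }
        }
      }
      m
    } else {
      corners <- rbind(
        c(A = 0.5, C = 0, G = 0.5, T = 0),   # skews ( 1,  1)
        c(A = 0.5, C = 0.5, G = 0, T = 0),   # skews (-1,  1)
        c(A = 0, C = 0, G = 0.5, T = 0.5),   # skews ( 1, -1)
        c(A = 0, C = 0.5, G = 0, T = 0.5)    # skews (-1, -1)
      )
      corners[rep_len(1:4, n), , drop = FALSE]
    }
  })
  dplyr::bind_cols(tibble::tibble(.draw = seq_len(n)),
                   tibble::as_tibble(comp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
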