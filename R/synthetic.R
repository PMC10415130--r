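# Synthetic fixtures: genomes with controlled composition and skews, and
# rate-set ensembles with controlled NSB deviation or constraint conformity.
# Everything here is a pure function of (parameters, seed), so every pipeline
# stage is testable fully offline.

#' Generate a synthetic genome with target composition and skews
#'
#' Draws an i.i.d. sequence whose expected base fractions solve the
#' (gc_content, gc_skew, at_skew) system:
#' C_G = gc (1 + gc_skew) / 2, C_C = gc (1 - gc_skew) / 2,
#' C_A = (1 - gc)(1 + at_skew) / 2, C_T = (1 - gc)(1 - at_skew) / 2.
#' An optional first-order Markov mode introduces controllable neighbour
#' dependence (for dyad-count tests) while keeping the same stationary base
#' composition; real-genome features such as repeats and isochores are not
#' emulated.
#'
#' @param length Sequence length (positive integer).
#' @param gc_content Target G+C fraction.
#' @param gc_skew,at_skew Target skews in \[-1, 1\].
#' @param seed Integer seed.
#' @param markov_correlation Scalar in [0, 1): probability mass added to
#'   self-transitions (0 = i.i.d.). The stationary composition is unchanged.
#' @param id Record id.
#' @return A `Biostrings::DNAStringSet` of length 1.
#' @export
#' @examples
#' make_genome(1000, gc_content = 0.4, gc_skew = 0.1, at_skew = 0, seed = 1)
make_genome <- function(length, gc_content = 0.5, gc_skew = 0, at_skew = 0,
                        seed = 1, markov_correlation = 0,
                        id = "synthetic") {
  if (length < 1 || length != round(length)) {
    rlang::abort("`length` must be a positive integer")
  }
  p <- genome_base_probs(gc_content, gc_skew, at_skew)
  if (markov_correlation < 0 || markov_correlation >= 1) {
    rlang::abort("`markov_correlation` must be in [0, 1)")
  }
  bases <- base_order()
  seq_chars <- withr::with_seed(seed, {
    if (markov_correlation == 0) {
      sample(bases, length, replace = TRUE, prob = p)
    } else {
      # mixture kernel: with prob rho stay, else draw from p; stationary
      # distribution remains p
      rho <- markov_correlation
      out <- character(length)
      out[1] <- sample(bases, 1, prob = p)
      draws <- sample(bases, length, replace = TRUE, prob = p)
      stay <- stats::runif(length) < rho
      for (pos in 2:length) {
        out[pos] <- if (stay[pos]) out[pos - 1] else draws[pos]
      }
      out
    }
  })
  ss <- Biostrings::DNAStringSet(paste0(seq_chars, collapse = ""))
  names(ss) <- id
  ss
}

#' Expected base probabilities for target composition and skews
#'
#' @inheritParams make_genome
#' @return Named probability vector (A, C, G, T).
#' @export
genome_base_probs <- function(gc_content, gc_skew = 0, at_skew = 0) {
  if (gc_content < 0 || gc_content > 1 ||
      abs(gc_skew) > 1 || abs(at_skew) > 1) {
    rlang::abort("infeasible targets: need gc in [0,1] and skews in [-1,1]")
  }
  p <- c(
    A = (1 - gc_content) * (1 + at_skew) / 2,
    C = gc_content * (1 - gc_skew) / 2,
    G = gc_content * (1 + gc_skew) / 2,
    T = (1 - gc_content) * (1 - at_skew) / 2
  )
  if (any(p < 0) || any(p > 1)) {
    rlang::abort("infeasible targets: implied base probabilities outside [0,1]")
  }
  p
}

#' Write a synthetic genome (or any DNAStringSet) to FASTA
#'
#' @param x A `Biostrings::DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(x)
}

#' Generate labelled rate-set ensembles with controlled properties
#'
#' Ensemble kinds:
#' \describe{
#'   \item{nsb_exact}{Six symmetric rates drawn U(0, 1] and expanded, so
#'     every reverse-complement pair is exactly equal.}
#'   \item{nsb_perturbed}{As `nsb_exact`, then the two members of each pair
#'     are multiplied by (1 + eps/2) and (1 - eps/2), giving pair ratios
#'     within \[(1 - eps/2)/(1 + eps/2), (1 + eps/2)/(1 - eps/2)\].}
#'   \item{constraint_conforming}{Uniform draws, then the rates named in
#'     `conform` are re-solved (linear system) so those constraint relations
#'     hold exactly; draws whose solution leaves the non-negative orthant are
#'     rejected and redrawn, and an infeasible/singular solve or exhausted
#'     rejection is reported as an error (never silently dropped).}
#'   \item{adversarial}{Strand-asymmetric sets: pair members drawn with
#'     ratios far from 1 (alternating ~10x and ~0.1x), giving large NSB
#'     residuals.}
#' }
#'
#' @param kind Ensemble kind.
#' @param n Number of rate sets.
#' @param seed Integer seed.
#' @param epsilon Relative pair perturbation for `nsb_perturbed`.
#' @param conform Character vector of target mutations whose constraint
#'   relations are enforced for `constraint_conforming` (default the A->G
#'   relation; enforcing all 12 at once collapses the ensemble to the single
#'   joint solution of the linear system).
#' @return A tibble with columns `.draw`, `kind`, and the 12 mutation labels.
#' @export
make_rate_ensemble <- function(kind = c("nsb_exact", "nsb_perturbed",
                                        "constraint_conforming",
                                        "adversarial"),
                               n = 10, seed = 1, epsilon = 0.1,
                               conform = "AG") {
  kind <- match.arg(kind)
  if (epsilon < 0) rlang::abort("`epsilon` must be non-negative")
  labs <- mutation_labels()
  pairs <- nsb_pairs()
  rates <- withr::with_seed(seed, {
    if (kind %in% c("nsb_exact", "nsb_perturbed")) {
      symm <- matrix(stats::runif(n * 6), nrow = n,
                     dimnames = list(NULL, pairs$symbol))
      full <- nsb_expand(tibble::as_tibble(symm))
      if (kind == "nsb_perturbed") {
        for (p in seq_len(6)) {
          full[[pairs$first[p]]] <- full[[pairs$first[p]]] * (1 + epsilon / 2)
          full[[pairs$second[p]]] <- full[[pairs$second[p]]] * (1 - epsilon / 2)
        }
      }
      full
    } else if (kind == "adversarial") {
      symm <- matrix(stats::runif(n * 6, 0.2, 1), nrow = n,
                     dimnames = list(NULL, pairs$symbol))
      full <- nsb_expand(tibble::as_tibble(symm))
      for (p in seq_len(6)) {
        fac <- if (p %% 2 == 0) 10 else 0.1
        full[[pairs$first[p]]] <- full[[pairs$first[p]]] * fac
      }
      full
    } else {
      upper <- uniform_upper_bound(1)
      m <- matrix(0, n, 12, dimnames = list(NULL, labs))
      for (d in seq_len(n)) {
        done <- FALSE
        for (attempt in 1:100) {
          kvec <- stats::setNames(stats::runif(12, 0, upper), labs)
          sol <- solve_conforming(kvec, conform)
          if (all(sol >= 0)) {
            m[d, ] <- sol
            done <- TRUE
            break
          }
        }
        if (!done) {
          rlang::abort(paste0(
            "constraint solve for subset {", paste(conform, collapse = ","),
            "} produced no non-negative rate set in 100 attempts"))
        }
      }
      tibble::as_tibble(m)
    }
  })
  dplyr::bind_cols(tibble::tibble(.draw = seq_len(n), kind = kind),
                   tibble::as_tibble(rates))
}

# Internal: re-solve the rates in `conform` so that their constraint
# relations hold exactly, holding the remaining rates at their drawn values.
solve_conforming <- function(kvec, conform) {
  labs <- mutation_labels()
  names(kvec) <- labs
  forms <- constraint_forms()[conform]
  free <- conform
  fixed <- setdiff(labs, free)
  # relation for target t: k_t - outer*sum(coef*k) = outer*intercept
  A <- matrix(0, length(free), length(free),
              dimnames = list(free, free))
  b <- numeric(length(free))
  for (ti in seq_along(free)) {
    t <- free[ti]
    f <- forms[[t]]
    A[ti, t] <- 1
    rhs <- f$outer * f$intercept
    for (nm in names(f$terms)) {
      co <- f$outer * f$terms[[nm]]
      if (nm %in% free) {
        A[ti, nm] <- A[ti, nm] - co
      } else {
        rhs <- rhs + co * kvec[[nm]]
      }
    }
    b[ti] <- rhs
  }
  sol <- tryCatch(solve(A, b), error = function(e) {
    rlang::abort(paste0("constraint solve infeasible/singular for subset {",
                        paste(conform, collapse = ","), "}: ",
                        conditionMessage(e)))
  })
  kvec[free] <- sol
  kvec
}
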