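# The twelve generalized linear constraint relations among the mutation rate
# constants (the symbolic-regression-derived interrelations that characterise
# PR-2-compliant rate combinations), NSB-equality residuals, and the
# species-versus-equilibrium-GC-curve comparison.

# Each relation predicts one rate from the other eleven as
# outer * (sum(coef * rate) + intercept). Coefficients are packaged verbatim;
# lowercase symbols kag, kcg, ... map to the source->target labels AG, CG, ...
constraint_forms <- function() {
  list(
    AG = list(outer = -0.6,
              terms = c(CG = 1, GC = -1, AT = 1, TA = -1, CT = 1, TC = -1.3,
                        GA = -1),
              intercept = -0.6),
    GA = list(outer = 0.7,
              terms = c(CG = 1, GC = -1, AT = 1, TA = -1, CT = 1, TC = -1,
                        AG = 1),
              intercept = 0.1),
    TC = list(outer = 0.8,
              terms = c(CG = 0.7, GC = -1, AT = 0.8, TA = -1, AG = 1,
                        GA = -0.8, CT = 1),
              intercept = 0.4),
    CT = list(outer = -0.8,
              terms = c(CG = 1, GC = -1, AT = 0.8, TA = -1, AG = 1, GA = -1,
                        CA = 0.1, TC = -1),
              intercept = -0.3),
    AC = list(outer = -0.8,
              terms = c(GC = 1, CG = -1, AT = 1, TA = -1, GT = 1, TG = -1,
                        CA = -1),
              intercept = -0.3),
    CA = list(outer = 0.8,
              terms = c(GC = 1, CG = -1, AT = 1, TA = -1, GT = 1, TG = -1,
                        AC = 1),
              intercept = 0.2),
    GT = list(outer = -0.8,
              terms = c(GC = 1, CG = -1, AT = 1, TA = -1, TG = -1, AC = 1,
                        CA = -1),
              intercept = -0.2),
    TG = list(outer = 0.8,
              terms = c(GC = 1, CG = -1, AT = 1, TA = -1, GT = 1, AC = 1,
                        CA = -1),
              intercept = 0.1),
    AT = list(outer = -0.5,
              terms = c(TA = -2, CT = 1, TC = -1, AG = 1, GA = -1, GT = 1,
                        TG = -1, AC = 1, CA = -1),
              intercept = -0.5),
    TA = list(outer = 0.5,
              terms = c(AT = 2, CT = 1, TC = -1, AG = 1, GA = -1, GT = 1,
                        TG = -1, AC = 1, CA = -1),
              intercept = -0.1),
    GC = list(outer = -0.4,
              terms = c(CG = -2, TC = 1, CT = -1, GA = 1, AG = -1, GT = 1,
                        TG = -1, AC = 1, CA = -1),
              intercept = -0.06),
    CG = list(outer = 0.4,
              terms = c(GC = 2, TC = 1, CT = -1, GA = 1, AG = -1, GT = 1,
                        TG = -1, AC = 1, CA = -1),
              intercept = 0.9)
  )
}

#' Predict each rate constant from the other eleven
#'
#' Applies the packaged set of twelve generalized linear constraint relations:
#' each target rate is predicted as a fixed linear combination of the
#' remaining rates plus an intercept. Rate combinations that satisfy all
#' twelve relations give PR-2-compliant genomes within the 4.28-byr window;
#' the relations are strictly linear, so predictions interpolate linearly
#' between rate sets.
#'
#' @param rates Tibble of rate sets (12 mutation-label columns), any number of
#'   rows.
#' @return A long tibble with columns `.row`, `mutation`, `actual`,
#'   `predicted`.
#' @export
#' @examples
#' predict_rates(nsb_expand(reference_symmetric_rates()))
predict_rates <- function(rates) {
  rates <- validate_rates(rates)
  km <- as.matrix(rates[mutation_labels()])
  forms <- constraint_forms()
  out <- purrr::imap(forms, function(f, target) {
    pred <- f$outer * (km[, names(f$terms), drop = FALSE] %*% f$terms +
                         f$intercept)
    tibble::tibble(.row = seq_len(nrow(km)), mutation = target,
                   actual = km[, target], predicted = as.numeric(pred))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$.row, .data$mutation)
}

#' Signed residuals of the twelve constraint relations
#'
#' Residual = actual - predicted for each relation, plus the per-rate-set
#' aggregate root-mean-square norm, usable for ranking rate sets by
#' constraint conformity.
#'
#' @inheritParams predict_rates
#' @return A list with `residuals` (wide tibble: `.row` plus one column per
#'   mutation) and `norm` (numeric vector, RMS of the 12 residuals per rate
#'   set).
#' @export
constraint_residuals <- function(rates) {
  pr <- predict_rates(rates)
  pr$residual <- pr$actual - pr$predicted
  wide <- tidyr::pivot_wider(pr[, c(".row", "mutation", "residual")],
                             names_from = "mutation",
                             values_from = "residual")
  norm <- sqrt(rowMeans(as.matrix(wide[mutation_labels()])^2))
  list(residuals = wide, norm = norm)
}

#' Correlation between actual and predicted rates, per relation
#'
#' Pearson correlation of (actual, predicted) across an ensemble for each of
#' the twelve relations. Returns an object with broom-style accessors:
#' `tidy()` gives the per-relation correlations, `glance()` the minimum and
#' mean correlation and the ensemble size.
#'
#' @inheritParams predict_rates
#' @return A `pr2_constraint_fit` object.
#' @export
constraint_correlations <- function(rates) {
  pr <- predict_rates(rates)
  per <- pr |>
    dplyr::group_by(.data$mutation) |>
    dplyr::summarise(
      r = stats::cor(.data$actual, .data$predicted),
      n = dplyr::n(), .groups = "drop"
    )
  structure(list(by_form = per, pairs = pr), class = "pr2_constraint_fit")
}

#' @export
print.pr2_constraint_fit <- function(x, ...) {
  cat("<pr2_constraint_fit> Pearson r per constraint relation:\n")
  print(x$by_form, n = 12)
  invisible(x)
}

#' @rdname constraint_correlations
#' @param x A `pr2_constraint_fit` object.
#' @param ... Unused.
#' @export
tidy.pr2_constraint_fit <- function(x, ...) x$by_form

#' @rdname constraint_correlations
#' @export
glance.pr2_constraint_fit <- function(x, ...) {
  tibble::tibble(
    n = x$by_form$n[1],
    min_r = min(x$by_form$r),
    mean_r = mean(x$by_form$r),
    all_positive = all(x$by_form$r > 0)
  )
}

#' NSB equality residuals of a rate set
#'
#' Per reverse-complement pair: the ratio (first / second) and the absolute
#' difference. Exactly symmetric sets give all ratios 1 and all differences
#' 0. Zero denominators are flagged (`ratio = NA`).
#'
#' @inheritParams predict_rates
#' @return A long tibble with columns `.row`, `pair`, `ratio`, `difference`,
#'   `degenerate`.
#' @export
nsb_residuals <- function(rates) {
  rates <- validate_rates(rates)
  pairs <- nsb_pairs()
  a <- as.matrix(rates[pairs$first])
  b <- as.matrix(rates[pairs$second])
  tibble::tibble(
    .row = rep(seq_len(nrow(rates)), times = 6),
    pair = rep(pairs$pair, each = nrow(rates)),
    ratio = as.vector(ifelse(b > 0, a / b, NA_real_)),
    difference = as.vector(abs(a - b)),
    degenerate = as.vector(b == 0)
  ) |> dplyr::arrange(.data$.row, .data$pair)
}

#' Deviation of observed G+C content from the NSB equilibrium curve
#'
#' For each species, compares the observed genomic G+C fraction with the
#' equilibrium value implied by its symmetric mutation rates through the
#' (n + j) / (i + m) = GC / (1 - GC) relation, reporting signed and
#' absolute-percent deviations.
#'
#' @param sym Tibble of symmetric rate sets (columns `i`..`n`), one row per
#'   species; extra columns (e.g. `species`) are carried through.
#' @param observed_gc Numeric vector of observed G+C fractions, aligned with
#'   the rows of `sym`.
#' @return A tibble with `observed_gc`, `equilibrium_gc`, `deviation`
#'   (observed - equilibrium) and `abs_percent_deviation` (100 |dev| /
#'   equilibrium).
#' @export
species_vs_gc_curve <- function(sym, observed_gc) {
  sym <- validate_symmetric(sym)
  if (length(observed_gc) != nrow(sym)) {
    rlang::abort("`observed_gc` must align with the rows of `sym`")
  }
  if (any(observed_gc < 0 | observed_gc > 1)) {
    rlang::abort("`observed_gc` must be fractions in [0, 1]")
  }
  eq <- gc_equilibrium(sym)
  extra <- setdiff(names(sym), nsb_pairs()$symbol)
  out <- tibble::tibble(
    observed_gc = observed_gc,
    equilibrium_gc = eq,
    deviation = observed_gc - eq,
    abs_percent_deviation = 100 * abs(observed_gc - eq) / eq
  )
  if (length(extra) > 0) out <- dplyr::bind_cols(sym[extra], out)
  out
}

#' Read a species rate/frequency table
#'
#' TSV with columns `species`, `mutation` (two-character code), `value` and
#' `units` (`"rate_per_byr"` or `"frequency"`; frequencies are converted with
#' [frequency_to_rate()]). Returns one rate-set row per species.
#'
#' @param path File path.
#' @param scale Frequency-to-rate conversion constant.
#' @return A tibble with a `species` column plus the 12 mutation-label
#'   columns.
#' @export
read_species_rates <- function(path, scale = 2.831) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("species", "mutation", "value", "units")
  if (!all(need %in% names(tbl))) {
    rlang::abort("species table needs columns species, mutation, value, units")
  }
  bad <- setdiff(unique(tbl$units), c("rate_per_byr", "frequency"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown units: ", paste(bad, collapse = ", ")))
  }
  tbl$rate <- ifelse(tbl$units == "frequency",
                     frequency_to_rate(tbl$value, scale), tbl$value)
  wide <- tidyr::pivot_wider(tbl[, c("species", "mutation", "rate")],
                             names_from = "mutation", values_from = "rate")
  validate_rates(wide)
}
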