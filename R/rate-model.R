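# Mutation-rate domain: the 12 directed rate constants, their no-strand-bias
# (NSB) pairing, packaged human (Trek-derived) reference values, and the
# frequency -> rate conversion.

#' Canonical order of the 12 directed mutation labels
#'
#' Two-character source->target codes ("CT" means the C to T mutation),
#' alphabetically ordered. All tabular rate-set representations in pr2sim use
#' these as column names.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' mutation_labels()
mutation_labels <- function() {
  c("AC", "AG", "AT", "CA", "CG", "CT",
    "GA", "GC", "GT", "TA", "TC", "TG")
}

#' The six NSB rate symbols and their paired mutations
#'
#' Under the no-strand-bias assumption, a mutation and the mutation between its
#' reverse-complementary bases proceed at the same rate, pairing the 12 directed
#' rates into 6 independent constants conventionally written i..n:
#' i = CA/GT, j = AC/TG, k = CG/GC, l = AT/TA, m = CT/GA, n = AG/TC.
#'
#' @return A tibble with columns `symbol`, `pair` (the "CT/GA"-style label),
#'   `first`, `second` (the two member mutation labels).
#' @export
#' @examples
#' nsb_pairs()
nsb_pairs <- function() {
  tibble::tibble(
    symbol = c("i", "j", "k", "l", "m", "n"),
    first  = c("CA", "AC", "CG", "AT", "CT", "AG"),
    second = c("GT", "TG", "GC", "TA", "GA", "TC"),
    pair   = paste(c("CA", "AC", "CG", "AT", "CT", "AG"),
                   c("GT", "TG", "GC", "TA", "GA", "TC"), sep = "/")
  )
}

#' Reference human mutation rate constants
#'
#' The packaged reference table of per-site per-billion-year (byr) rate
#' constants for the human genome, as used to centre and bound the Monte Carlo
#' sampling schemes. `block = "individual"` returns the 12 per-mutation means
#' and standard deviations; `block = "symmetric"` returns the 6
#' strand-symmetry-averaged values keyed by pair label. Both blocks are
#' packaged verbatim and are never cross-derived from one another (they were
#' independently estimated, so lower-block means are not exactly the averages
#' of the upper block).
#'
#' @param block `"individual"` (12 rows) or `"symmetric"` (6 rows).
#' @return A tibble with columns `mutation`, `mean`, `sd` (rates per byr).
#' @export
#' @examples
#' reference_rates("symmetric")
reference_rates <- function(block = c("individual", "symmetric")) {
  block <- match.arg(block)
  if (block == "individual") {
    tibble::tibble(
      mutation = c("AC", "TG", "AG", "TC", "AT", "TA",
                   "CA", "GT", "CG", "GC", "CT", "GA"),
      mean = c(0.198, 0.199, 0.679, 0.875, 0.210, 0.216,
               0.371, 0.269, 0.304, 0.238, 1.173, 1.044),
      sd   = c(0.100, 0.098, 0.553, 0.824, 0.111, 0.132,
               0.505, 0.139, 0.158, 0.117, 0.894, 0.387)
    )
  } else {
    tibble::tibble(
      mutation = c("AC/TG", "AG/TC", "AT/TA", "CA/GT", "CG/GC", "CT/GA"),
      mean = c(0.198, 0.753, 0.212, 0.322, 0.273, 1.109),
      sd   = c(0.099, 0.673, 0.119, 0.378, 0.144, 0.690)
    )
  }
}

#' Reference symmetric rates as a one-row i..n tibble
#'
#' Convenience accessor returning the packaged strand-symmetry-averaged human
#' rates mapped onto the six NSB symbols.
#'
#' @return A one-row tibble with columns `i`, `j`, `k`, `l`, `m`, `n`.
#' @export
reference_symmetric_rates <- function() {
  tbl <- reference_rates("symmetric")
  pairs <- nsb_pairs()
  means <- stats::setNames(tbl$mean, tbl$mutation)
  out <- as.list(means[pairs$pair])
  names(out) <- pairs$symbol
  tibble::as_tibble(out)
}

#' Convert a mutation frequency to a per-byr rate constant
#'
#' Applies the linear Trek-scaling k = scale * f (regression through the
#' origin between genome-wide mutation rate constants and literature mutation
#' frequencies). The default scale 2.831 is the packaged constant; it is a
#' configurable argument, not hard-coded, since it derives from an external
#' regression.
#'
#' @param f Non-negative mutation frequency (dimensionless). Vectorised.
#' @param scale Conversion constant, per byr.
#' @return Rate constant(s), per site per byr.
#' @export
#' @examples
#' frequency_to_rate(0.5)
frequency_to_rate <- function(f, scale = 2.831) {
  if (any(!is.finite(f)) || any(f < 0)) {
    rlang::abort("mutation frequencies must be finite and non-negative")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale < 0) {
    rlang::abort("`scale` must be a single non-negative number")
  }
  scale * f
}

# Internal: validate a rate-set tibble/data frame (rows = rate sets,
# columns = the 12 mutation labels); returns it with columns in canonical
# order as a tibble.
validate_rates <- function(rates) {
  labs <- mutation_labels()
  if (is.numeric(rates) && !is.null(names(rates))) {
    rates <- tibble::as_tibble(as.list(rates))
  }
  missing <- setdiff(labs, names(rates))
  if (length(missing) > 0) {
    rlang::abort(paste0("rate set is missing mutations: ",
                        paste(missing, collapse = ", ")))
  }
  rates <- tibble::as_tibble(rates)
  vals <- as.matrix(rates[labs])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rlang::abort("all 12 rate constants must be finite and non-negative")
  }
  rates
}

# Internal: validate a symmetric (i..n) tibble.
validate_symmetric <- function(sym) {
  syms <- nsb_pairs()$symbol
  if (is.numeric(sym) && !is.null(names(sym))) {
    sym <- tibble::as_tibble(as.list(sym))
  }
  missing <- setdiff(syms, names(sym))
  if (length(missing) > 0) {
    rlang::abort(paste0("symmetric rate set is missing symbols: ",
                        paste(missing, collapse = ", ")))
  }
  sym <- tibble::as_tibble(sym)
  vals <- as.matrix(sym[syms])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rlang::abort("all six symmetric rates must be finite and non-negative")
  }
  sym
}

#' Reduce a 12-rate set to the six NSB rates
#'
#' Checks that each reverse-complement rate pair (CA/GT, AC/TG, CG/GC, AT/TA,
#' CT/GA, AG/TC) agrees within a relative tolerance and returns the pairwise
#' means mapped onto the symbols i..n. Works row-wise on a tibble of rate sets.
#'
#' @param rates A tibble (or named vector) with the 12 mutation-label columns.
#' @param tolerance Maximum allowed relative deviation |a - b| / mean(a, b)
#'   within a pair. Use `Inf` to average without checking.
#' @return A tibble with columns `i`, `j`, `k`, `l`, `m`, `n`, one row per
#'   input rate set; any extra non-rate columns are carried through.
#' @export
#' @examples
#' nsb_reduce(nsb_expand(tibble::tibble(i = 1, j = 1, k = 1, l = 1, m = 1, n = 1)))
nsb_reduce <- function(rates, tolerance = 1e-8) {
  rates <- validate_rates(rates)
  pairs <- nsb_pairs()
  a <- as.matrix(rates[pairs$first])
  b <- as.matrix(rates[pairs$second])
  mid <- (a + b) / 2
  rel <- abs(a - b) / ifelse(mid > 0, mid, 1)
  if (any(rel > tolerance)) {
    bad <- which(colSums(rel > tolerance) > 0)
    rlang::abort(paste0(
      "NSB symmetry violated beyond tolerance for pair(s): ",
      paste(pairs$pair[bad], collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(mid)
  names(out) <- pairs$symbol
  extra <- setdiff(names(rates), mutation_labels())
  if (length(extra) > 0) out <- dplyr::bind_cols(rates[extra], out)
  out
}

#' Expand six NSB rates to the full 12-rate set
#'
#' Inverse of [nsb_reduce()]: both members of each reverse-complement pair are
#' set to the shared value, so `nsb_reduce(nsb_expand(s))` recovers `s`
#' exactly.
#'
#' @param sym A tibble (or named vector) with columns `i`..`n`.
#' @return A tibble with the 12 mutation-label columns, one row per input row.
#' @export
nsb_expand <- function(sym) {
  sym <- validate_symmetric(sym)
  pairs <- nsb_pairs()
  vals <- as.matrix(sym[pairs$symbol])
  out <- matrix(0, nrow(vals), 12,
                dimnames = list(NULL, mutation_labels()))
  for (p in seq_len(nrow(pairs))) {
    out[, pairs$first[p]]  <- vals[, p]
    out[, pairs$second[p]] <- vals[, p]
  }
  out <- tibble::as_tibble(out)
  extra <- setdiff(names(sym), nsb_pairs()$symbol)
  if (length(extra) > 0) out <- dplyr::bind_cols(sym[extra], out)
  out
}

#' Read or write a rate table as TSV
#'
#' Rate tables are stored as tab-separated files with the header
#' `mutation`, `mean`, `sd` (two-character source->target codes, per-byr
#' units), the same layout as [reference_rates()].
#'
#' @param path File path.
#' @param x For writing, a tibble with columns `mutation`, `mean`, `sd`.
#' @return `read_rate_table()` returns a tibble; `write_rate_table()` returns
#'   `x` invisibly.
#' @export
read_rate_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("mutation", "mean", "sd")
  if (!all(need %in% names(tbl))) {
    rlang::abort("rate table must have columns: mutation, mean, sd")
  }
  if (any(tbl$mean < 0) || any(tbl$sd < 0)) {
    rlang::abort("rate table means and sds must be non-negative")
  }
  tbl
}

#' @rdname read_rate_table
#' @export
write_rate_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}
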