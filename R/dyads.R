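# Dinucleotide (dyad) mutation kinetics on the tesseract network: 16 nodes,
# 96 directed single-position substitution edges, NSB pairing into 48 classes,
# numerical evolution, and the equilibrium class structure.

#' The 16 dyads in canonical order
#'
#' Dyads are two-character strings in 5'->3' order ("AC" denotes ApC).
#'
#' @return Character vector of length 16.
#' @export
dyad_labels <- function() {
  b <- base_order()
  as.vector(t(outer(b, b, paste0)))
}

#' Reverse complement of a dyad
#'
#' Complement then reverse: "AC" -> "GT".
#'
#' @param dyad Character vector of two-letter dyads.
#' @return Character vector of reverse complements.
#' @export
dyad_revcomp <- function(dyad) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(dyad, ""), function(x) {
    paste0(comp[x[2]], comp[x[1]])
  }, character(1))
}

#' Enumerate the 96 single-substitution dyad edges
#'
#' Each dyad can mutate at either of its two positions to any of the three
#' alternative bases, giving 96 directed edges on the tesseract graph. Under
#' the no-strand-bias pairing, the partner of an edge is the mutation between
#' the reverse-complement dyads (e.g. ApC -> ApT pairs with GpT -> ApT), an
#' involution with no fixed points that groups the 96 edges into 48 classes.
#'
#' @return A tibble with columns `from`, `to`, `position` (1 or 2),
#'   `mutation` (the substituted base pair, e.g. "CT"), `partner_from`,
#'   `partner_to`, and `class` (a canonical label shared by the two paired
#'   edges).
#' @export
#' @examples
#' nrow(dyad_edges())  # 96
dyad_edges <- function() {
  b <- base_order()
  rows <- list()
  for (d in dyad_labels()) {
    s <- strsplit(d, "")[[1]]
    for (pos in 1:2) {
      for (alt in setdiff(b, s[pos])) {
        to <- s
        to[pos] <- alt
        rows[[length(rows) + 1]] <- tibble::tibble(
          from = d, to = paste0(to, collapse = ""), position = pos,
          mutation = paste0(s[pos], alt)
        )
      }
    }
  }
  edges <- dplyr::bind_rows(rows)
  edges$partner_from <- dyad_revcomp(edges$from)
  edges$partner_to <- dyad_revcomp(edges$to)
  key <- paste(edges$from, edges$to, sep = ">")
  pkey <- paste(edges$partner_from, edges$partner_to, sep = ">")
  edges$class <- ifelse(key < pkey, paste(key, pkey, sep = "|"),
                        paste(pkey, key, sep = "|"))
  edges
}

#' Build a dyad mutation network with attached rate constants
#'
#' @param rates Either a named numeric vector of rates keyed `"FROM>TO"`
#'   covering all 96 edges (`nsb = FALSE`) or all 48 classes (`nsb = TRUE`,
#'   keyed by either member edge), or a single number recycled to every edge,
#'   or `NULL` for unit rates.
#' @param nsb If `TRUE`, rates are interpreted per NSB class and both edges of
#'   each class carry the shared value.
#' @return A `pr2_dyad_network` tibble: the [dyad_edges()] table plus a
#'   `rate` column.
#' @export
build_dyad_network <- function(rates = NULL, nsb = FALSE) {
  edges <- dyad_edges()
  key <- paste(edges$from, edges$to, sep = ">")
  if (is.null(rates)) rates <- 1
  if (length(rates) == 1 && is.null(names(rates))) {
    edges$rate <- as.numeric(rates)
  } else if (nsb) {
    # accept one rate per class, keyed by either member edge
    supplied <- names(rates)
    cls <- edges$class[match(supplied, key)]
    if (any(is.na(cls))) {
      rlang::abort(paste0("unknown edge key(s): ",
                          paste(supplied[is.na(cls)], collapse = ", ")))
    }
    per_class <- tapply(as.numeric(rates), cls, function(v) {
      if (length(unique(v)) > 1) {
        rlang::abort("conflicting rates supplied for one NSB class")
      }
      v[1]
    })
    miss <- setdiff(unique(edges$class), names(per_class))
    if (length(miss) > 0) {
      rlang::abort(paste0("missing rates for ", length(miss), " NSB class(es), e.g. ",
                          miss[1]))
    }
    edges$rate <- as.numeric(per_class[edges$class])
  } else {
    miss <- setdiff(key, names(rates))
    if (length(miss) > 0) {
      rlang::abort(paste0("missing rates for ", length(miss), " edge(s), e.g. ",
                          miss[1]))
    }
    extra <- setdiff(names(rates), key)
    if (length(extra) > 0) {
      rlang::abort(paste0("unknown edge key(s): ", paste(extra, collapse = ", ")))
    }
    edges$rate <- as.numeric(rates[key])
  }
  if (any(edges$rate < 0) || any(!is.finite(edges$rate))) {
    rlang::abort("dyad rates must be finite and non-negative")
  }
  class(edges) <- c("pr2_dyad_network", class(edges))
  edges
}

#' Context-independent dyad rates from a singleton rate set
#'
#' Assigns each dyad edge the singleton rate of its mutating position,
#' ignoring the neighbouring base. This is the construction under which the
#' dyad equilibrium factorises into the outer product of the singleton
#' equilibrium with itself.
#'
#' @param rates One-row rate tibble or named 12-vector.
#' @return A `pr2_dyad_network` tibble.
#' @export
context_independent_network <- function(rates) {
  rates <- validate_rates(rates)
  edges <- dyad_edges()
  k <- stats::setNames(as.numeric(rates[1, mutation_labels()]),
                       mutation_labels())
  edges$rate <- as.numeric(k[edges$mutation])
  class(edges) <- c("pr2_dyad_network", class(edges))
  edges
}

# Internal: 16x16 generator matrix of a dyad network (columns = source dyad).
dyad_rate_matrix <- function(net) {
  labs <- dyad_labels()
  M <- matrix(0, 16, 16, dimnames = list(labs, labs))
  for (e in seq_len(nrow(net))) {
    M[net$to[e], net$from[e]] <- M[net$to[e], net$from[e]] + net$rate[e]
    M[net$from[e], net$from[e]] <- M[net$from[e], net$from[e]] - net$rate[e]
  }
  M
}

# Internal: validate a 16-entry dyad composition.
validate_dyad_composition <- function(d0, tol = 1e-9) {
  labs <- dyad_labels()
  if (is.data.frame(d0)) d0 <- unlist(d0[1, labs])
  if (is.null(names(d0))) {
    if (length(d0) != 16) rlang::abort("dyad composition must have 16 entries")
    names(d0) <- labs
  }
  d0 <- d0[labs]
  if (any(!is.finite(d0)) || any(d0 < -tol)) {
    rlang::abort("dyad contents must be non-negative")
  }
  if (abs(sum(d0) - 1) > tol) rlang::abort("dyad contents must sum to 1")
  d0
}

#' Evolve dyad contents on the tesseract network
#'
#' Integrates the 16-state linear kinetics dD/dt = M D with deSolve (lsoda).
#'
#' @param net A `pr2_dyad_network` from [build_dyad_network()].
#' @param d0 Initial dyad composition: named 16-vector summing to 1, or
#'   `"uniform"`.
#' @inheritParams evolve
#' @return A tibble with `time_byr` plus the 16 dyad columns.
#' @export
evolve_dyads <- function(net, d0 = "uniform", horizon = 4.28,
                         record_times = NULL, rtol = 1e-9, atol = 1e-12) {
  M <- dyad_rate_matrix(net)
  if (identical(d0, "uniform")) {
    d0 <- stats::setNames(rep(1 / 16, 16), dyad_labels())
  }
  d0 <- validate_dyad_composition(d0)
  if (is.null(record_times)) record_times <- record_grid(horizon)
  sol <- deSolve::ode(
    y = unname(d0), times = record_times,
    func = function(t, y, parms) list(as.numeric(parms %*% y)),
    parms = M, rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort("dyad ODE integration failed; see deSolve diagnostics")
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("time_byr", dyad_labels())
  out
}

#' Stationary dyad composition (null-space oracle)
#'
#' @param net A `pr2_dyad_network`.
#' @param tol Singular-value threshold for null-space detection.
#' @return Named 16-vector of stationary dyad contents summing to 1.
#' @export
stationary_dyads <- function(net, tol = 1e-10) {
  M <- dyad_rate_matrix(net)
  sv <- svd(M)
  null_dim <- sum(sv$d < tol * max(1, sv$d[1]))
  if (null_dim == 0) null_dim <- 1
  if (null_dim > 1) {
    rlang::abort("reducible dyad network: stationary composition not unique")
  }
  v <- sv$v[, 16]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  stats::setNames(v / sum(v), dyad_labels())
}

#' Group dyads by their equilibrium content
#'
#' Computes the stationary dyad composition and partitions the 16 dyads into
#' groups whose stationary contents agree within an absolute tolerance. For
#' any network with NSB-paired rates this yields the ten reverse-complement
#' classes {ApA,TpT}, {ApC,GpT}, {ApG,CpT}, {CpA,TpG}, {GpA,TpC}, {CpC,GpG},
#' {CpG}, {GpC}, {ApT}, {TpA}; for generic unconstrained rates all 16 contents
#' differ; with context-independent rates only three distinct values remain.
#'
#' @param net A `pr2_dyad_network`.
#' @param tol Absolute tolerance on stationary contents for merging.
#' @return A tibble with columns `dyad`, `content`, `class_id` (integer id of
#'   the equilibrium class, ordered by decreasing content).
#' @export
equilibrium_classes <- function(net, tol = 1e-6) {
  st <- stationary_dyads(net)
  ord <- order(st, decreasing = TRUE)
  vals <- st[ord]
  cls <- integer(16)
  cur <- 1
  cls[1] <- 1
  for (idx in 2:16) {
    if (abs(vals[idx] - vals[idx - 1]) > tol) cur <- cur + 1
    cls[idx] <- cur
  }
  out <- tibble::tibble(dyad = names(vals), content = as.numeric(vals),
                        class_id = cls)
  dplyr::arrange(out, class_id, dyad)
}

#' Closed-form context-independent dyad equilibrium
#'
#' Under NSB with context-independent rates the 16 stationary dyad contents
#' collapse to three distinct values: the A/T-only dyads take
#' (i+m)^2 / (2(i+j+m+n))^2, the mixed dyads (i+m)(j+n) / (2(i+j+m+n))^2 and
#' the G/C-only dyads (j+n)^2 / (2(i+j+m+n))^2 -- the outer product of the
#' singleton equilibrium with itself, as independence of the two positions
#' dictates.
#'
#' @inheritParams nsb_equilibrium
#' @return Named 16-vector of dyad contents summing to 1.
#' @export
context_independent_equilibrium <- function(sym) {
  eq <- nsb_equilibrium(sym)
  out <- outer(eq, eq)
  v <- as.vector(t(out))
  stats::setNames(v, dyad_labels())
}

#' Read and write dyad rate tables and trajectories
#'
#' Dyad rate files are TSV with columns `source_dyad`, `target_dyad`, `rate`;
#' trajectories are written as 17-column TSV (`time_byr` + 16 dyads).
#'
#' @param path File path.
#' @param nsb Passed to [build_dyad_network()].
#' @return `read_dyad_rates()` returns a `pr2_dyad_network`.
#' @export
read_dyad_rates <- function(path, nsb = FALSE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("source_dyad", "target_dyad", "rate")
  if (!all(need %in% names(tbl))) {
    rlang::abort("dyad rate table needs columns source_dyad, target_dyad, rate")
  }
  rates <- stats::setNames(tbl$rate,
                           paste(tbl$source_dyad, tbl$target_dyad, sep = ">"))
  build_dyad_network(rates, nsb = nsb)
}

#' @rdname read_dyad_rates
#' @param traj A dyad trajectory tibble from [evolve_dyads()].
#' @export
write_dyad_trajectory <- function(traj, path) {
  readr::write_tsv(traj, path)
  invisible(traj)
}
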