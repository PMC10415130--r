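# Shared helpers: independent oracles and fixture constructors.

# Matrix-exponential solution of the linear kinetics (independent of the
# deSolve / compiled propagation paths under test).
expm_solution <- function(rates, c0, t) {
  M <- build_rate_matrix(rates)
  as.numeric(Matrix::expm(M * t) %*% c0)
}

# Random symmetric (i..n) rate set away from degeneracy.
random_symmetric <- function(seed, lower = 0.1, upper = 1) {
  withr::with_seed(seed, {
    v <- stats::runif(6, lower, upper)
    tibble::tibble(i = v[1], j = v[2], k = v[3], l = v[4], m = v[5], n = v[6])
  })
}

# Random NSB dyad network: one U(0, 1] rate per reverse-complement edge
# class, shared by both member edges.
random_nsb_network <- function(seed) {
  edges <- dyad_edges()
  reps <- edges[!duplicated(edges$class), ]
  withr::with_seed(seed, {
    r <- stats::runif(nrow(reps))
  })
  build_dyad_network(
    stats::setNames(r, paste(reps$from, reps$to, sep = ">")),
    nsb = TRUE
  )
}

# Random unconstrained dyad network (96 independent rates).
random_dyad_network <- function(seed) {
  edges <- dyad_edges()
  withr::with_seed(seed, r <- stats::runif(96, 0.1, 1))
  build_dyad_network(stats::setNames(r, paste(edges$from, edges$to, sep = ">")))
}

# The ten reverse-complement dyad equilibrium classes expected under NSB.
expected_nsb_dyad_classes <- function() {
  list(c("AA", "TT"), c("AC", "GT"), c("AG", "CT"), c("CA", "TG"),
       c("GA", "TC"), c("CC", "GG"), "CG", "GC", "AT", "TA")
}

# Canonicalised partition of dyads by class id, for set comparison.
partition_sets <- function(classes) {
  split(classes$dyad, classes$class_id) |>
    lapply(sort) |>
    unname()
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, paste, character(1), collapse = ","))
  identical(key(a), key(b))
}
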