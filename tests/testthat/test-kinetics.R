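uniform_c0 <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("generator matrix follows the column-as-source convention", {
  zero <- nsb_expand(tibble::tibble(i = 0, j = 0, k = 0, l = 0, m = 0, n = 0))
  expect_equal(build_rate_matrix(zero), matrix(0, 4, 4,
    dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))))

  only_ct <- zero
  only_ct$CT <- 1
  M <- build_rate_matrix(only_ct)
  expect_equal(M["T", "C"], 1)
  expect_equal(M["C", "C"], -1)
  expect_equal(sum(M != 0), 2)

  for (seed in 1:5) {
    r <- sample_rates(1, "uniform_unconstrained", seed = seed)
    M <- build_rate_matrix(r)
    expect_equal(unname(colSums(M)), rep(0, 4), tolerance = 1e-12)
  }
})

test_that("evolution matches the matrix-exponential oracle", {
  r <- nsb_expand(reference_symmetric_rates())
  tr <- evolve(r, uniform_c0, horizon = 4.28, record_times = c(0, 1, 4.28))
  for (row in 2:3) {
    oracle <- expm_solution(r, uniform_c0, tr$time_byr[row])
    expect_equal(unname(unlist(tr[row, c("A", "C", "G", "T")])), oracle,
                 tolerance = 1e-8)
  }
})

test_that("degenerate and stationary starts stay constant", {
  zero <- nsb_expand(tibble::tibble(i = 0, j = 0, k = 0, l = 0, m = 0, n = 0))
  c0 <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  tr <- evolve(zero, c0, horizon = 2, record_times = c(0, 1, 2))
  expect_true(all(abs(as.matrix(tr[c("A", "C", "G", "T")]) -
                        rep(c0, each = 3)) < 1e-12))

  sym1 <- tibble::tibble(i = 1, j = 1, k = 1, l = 1, m = 1, n = 1)
  tr <- evolve(nsb_expand(sym1), uniform_c0, horizon = 2,
               record_times = c(0, 1, 2))
  expect_true(all(abs(as.matrix(tr[c("A", "C", "G", "T")]) - 0.25) < 1e-9))
})

test_that("composition sum is conserved along trajectories", {
  for (seed in 1:5) {
    r <- sample_rates(1, "uniform_unconstrained", seed = seed)
    tr <- evolve(r, c(A = 0.1, C = 0.2, G = 0.3, T = 0.4), horizon = 10,
                 record_times = c(0, 0.5, 2, 10))
    sums <- rowSums(tr[c("A", "C", "G", "T")])
    expect_true(all(abs(sums - 1) < 1e-7))
  }
})

test_that("general and NSB-reduced formulations are trajectory-identical", {
  grid <- c(0, 10^seq(-2, log10(4.28), length.out = 40))
  for (seed in 1:5) {
    sym <- random_symmetric(seed)
    tr_gen <- evolve(nsb_expand(sym), uniform_c0, horizon = 4.28,
                     record_times = grid)
    tr_nsb <- evolve_nsb(sym, uniform_c0, horizon = 4.28, record_times = grid)
    expect_true(max(abs(as.matrix(tr_gen[-1]) - as.matrix(tr_nsb[-1]))) < 1e-9)
  }
})

test_that("closed-form NSB equilibrium has the expected values and parity", {
  sym <- reference_symmetric_rates()
  eq <- nsb_equilibrium(sym)
  # direct substitution: (0.322 + 1.109) / (2 * 2.382), (0.198 + 0.753) / (2 * 2.382)
  expect_equal(unname(eq["A"]), 1.431 / 4.764, tolerance = 1e-12)
  expect_equal(unname(eq["C"]), 0.951 / 4.764, tolerance = 1e-12)
  expect_equal(eq[["A"]], eq[["T"]])
  expect_equal(eq[["G"]], eq[["C"]])
  expect_equal(sum(eq), 1)

  expect_equal(unname(nsb_equilibrium(tibble::tibble(i = 1, j = 1, k = 5,
    l = 2, m = 1, n = 1))), rep(0.25, 4))
  absorbing <- nsb_equilibrium(tibble::tibble(i = 1, j = 0, k = 0, l = 1,
                                              m = 1, n = 0))
  expect_equal(absorbing[["G"]], 0)
  expect_equal(absorbing[["C"]], 0)
  expect_error(nsb_equilibrium(tibble::tibble(i = 0, j = 0, k = 1, l = 1,
                                              m = 0, n = 0)), "degenerate")
})

test_that("equilibrium G+C content solves the rate-ratio relation", {
  sym <- reference_symmetric_rates()
  gc <- gc_equilibrium(sym)
  expect_equal(gc, 0.951 / 2.382, tolerance = 1e-12)
  eq <- nsb_equilibrium(sym)
  expect_equal(gc, eq[["G"]] + eq[["C"]], tolerance = 1e-12)
  # the defining relation (n + j) / (i + m) = gc / (1 - gc)
  expect_equal((sym$n + sym$j) / (sym$i + sym$m), gc / (1 - gc),
               tolerance = 1e-12)
  expect_equal(gc_equilibrium(tibble::tibble(i = 1, j = 1, k = 0, l = 0,
                                             m = 1, n = 1)), 0.5)
  expect_equal(gc_equilibrium(tibble::tibble(i = 1, j = 0, k = 1, l = 1,
                                             m = 1, n = 0)), 0)
})

test_that("null-space stationary composition agrees with theory and dynamics", {
  # NSB-expanded rates: equals the closed form
  for (seed in 1:5) {
    sym <- random_symmetric(seed)
    st <- stationary_composition(nsb_expand(sym))
    expect_equal(st, nsb_equilibrium(sym), tolerance = 1e-10)
  }
  # all rates equal: uniform
  allone <- nsb_expand(tibble::tibble(i = 1, j = 1, k = 1, l = 1, m = 1, n = 1))
  expect_equal(unname(stationary_composition(allone)), rep(0.25, 4))
  # long-time evolution converges to the null-space vector
  r <- sample_rates(1, "uniform_unconstrained", seed = 11)
  horizon <- convergence_horizon(r)
  tr <- evolve(r, c(A = 0.7, C = 0.1, G = 0.1, T = 0.1), horizon = horizon,
               record_times = c(0, horizon))
  expect_equal(unname(unlist(tr[2, c("A", "C", "G", "T")])),
               unname(stationary_composition(r)), tolerance = 1e-6)
})

test_that("reducible networks are reported as ambiguous", {
  only_at <- nsb_expand(tibble::tibble(i = 0, j = 0, k = 0, l = 0, m = 0,
                                       n = 0))
  only_at$AT <- 1
  expect_error(stationary_composition(only_at), "reducible")
  # dynamics resolve the ambiguity: mass moves from A to T, C and G frozen
  tr <- evolve(only_at, c(A = 0.5, C = 0.2, G = 0.2, T = 0.1), horizon = 50,
               record_times = c(0, 50))
  final <- unlist(tr[2, c("A", "C", "G", "T")])
  expect_equal(unname(final), c(0, 0.2, 0.2, 0.6), tolerance = 1e-6)
})

test_that("batch propagation matches single-system integration", {
  rates <- sample_rates(8, "uniform_unconstrained", seed = 21)
  fin <- final_compositions(rates, uniform_c0, t = 4.28)
  for (s in c(1, 4, 8)) {
    oracle <- expm_solution(rates[s, ], uniform_c0, 4.28)
    expect_equal(unname(unlist(fin[s, ])), oracle, tolerance = 1e-10)
  }
  expect_equal(rowSums(fin), rep(1, 8), tolerance = 1e-9)
})

test_that("trajectories are written with content column names", {
  r <- nsb_expand(reference_symmetric_rates())
  tr <- evolve(r, uniform_c0, horizon = 1, record_times = c(0, 0.5, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(back, c("time_byr", "C_A", "C_C", "C_G", "C_T"))
  expect_equal(back$C_A, tr$A)
})
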