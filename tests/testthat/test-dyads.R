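test_that("the tesseract network has 96 edges in 48 reverse-complement classes", {
  edges <- dyad_edges()
  expect_equal(nrow(edges), 96)
  expect_equal(length(unique(edges$class)), 48)
  # every node has 2 positions x 3 alternatives outgoing
  expect_true(all(table(edges$from) == 6))
  # the NSB pairing is an involution with no fixed points
  key <- paste(edges$from, edges$to, sep = ">")
  pkey <- paste(edges$partner_from, edges$partner_to, sep = ">")
  expect_true(all(pkey %in% key))
  expect_true(all(pkey != key))
  expect_equal(pkey[match(pkey, key)], key)  # partner-of-partner is self
  expect_true(all(table(edges$class) == 2))
})

test_that("the NSB partner of ApC->ApT is GpT->ApT", {
  edges <- dyad_edges()
  row <- edges[edges$from == "AC" & edges$to == "AT", ]
  expect_equal(row$partner_from, "GT")
  expect_equal(row$partner_to, "AT")
  expect_equal(dyad_revcomp(c("AC", "AA", "CG")), c("GT", "TT", "CG"))
})

test_that("network construction validates rate coverage", {
  expect_error(build_dyad_network(c("AA>AC" = 1)), "missing")
  expect_error(build_dyad_network(c("AA>GG" = 1), nsb = TRUE), "unknown")
  net <- build_dyad_network(2)
  expect_equal(nrow(net), 96)
  expect_true(all(net$rate == 2))
  # NSB: both edges of a class carry the shared value
  nsb <- random_nsb_network(1)
  shared <- tapply(nsb$rate, nsb$class, function(v) diff(range(v)))
  expect_true(all(shared == 0))
})

test_that("dyad evolution matches the matrix-exponential oracle and conserves mass", {
  net <- random_dyad_network(3)
  d0 <- stats::setNames(rep(1 / 16, 16), dyad_labels())
  tr <- evolve_dyads(net, d0, horizon = 4.28, record_times = c(0, 1, 4.28))
  M <- pr2sim:::dyad_rate_matrix(net)
  oracle <- as.numeric(Matrix::expm(M * 4.28) %*% d0)
  expect_equal(unname(unlist(tr[3, -1])), oracle, tolerance = 1e-8)
  expect_true(all(abs(rowSums(tr[-1]) - 1) < 1e-7))
  # all rates zero and uniform-with-equal-rates stay constant
  still <- evolve_dyads(build_dyad_network(0), d0, horizon = 1,
                        record_times = c(0, 1))
  expect_equal(unname(unlist(still[2, -1])), rep(1 / 16, 16))
  flat <- evolve_dyads(build_dyad_network(0.7), d0, horizon = 1,
                       record_times = c(0, 1))
  expect_equal(unname(unlist(flat[2, -1])), rep(1 / 16, 16), tolerance = 1e-9)
})

test_that("NSB dyad networks equilibrate into the ten reverse-complement classes", {
  for (seed in 1:5) {
    net <- random_nsb_network(seed)
    cls <- equilibrium_classes(net)
    expect_equal(max(cls$class_id), 10)
    expect_true(same_partition(partition_sets(cls),
                               expected_nsb_dyad_classes()))
  }
  # long-time integration agrees with the null-space oracle within classes
  net <- random_nsb_network(99)
  st <- stationary_dyads(net)
  tr <- evolve_dyads(net, "uniform", horizon = 500,
                     record_times = c(0, 500))
  expect_equal(unname(unlist(tr[2, -1])), unname(st[dyad_labels()]),
               tolerance = 1e-6)
})

test_that("degenerate and generic networks give 1 and 16 equilibrium classes", {
  flat <- equilibrium_classes(build_dyad_network(1))
  expect_equal(max(flat$class_id), 1)
  for (seed in 1:5) {
    cls <- equilibrium_classes(random_dyad_network(seed))
    expect_equal(max(cls$class_id), 16)
  }
})

test_that("context-independent equilibrium is the outer square of the singleton equilibrium", {
  sym <- reference_symmetric_rates()
  eq16 <- context_independent_equilibrium(sym)
  eq4 <- nsb_equilibrium(sym)
  # ApA content is the square of the A content
  expect_equal(eq16[["AA"]], eq4[["A"]]^2, tolerance = 1e-12)
  expect_equal(unname(eq16["AA"]), (1.431 / 4.764)^2, tolerance = 1e-12)
  # three distinct values for generic rates
  expect_equal(length(unique(signif(eq16, 10))), 3)
  expect_equal(sum(eq16), 1, tolerance = 1e-12)
  # uniform case: all 1/16
  flat <- context_independent_equilibrium(
    tibble::tibble(i = 1, j = 1, k = 1, l = 1, m = 1, n = 1))
  expect_equal(unname(flat), rep(1 / 16, 16))
  # the network built from context-independent rates reaches the closed form
  st <- stationary_dyads(context_independent_network(nsb_expand(sym)))
  expect_equal(unname(st[names(eq16)]), unname(eq16), tolerance = 1e-10)
})

test_that("dyad marginals recover the singleton equilibrium under context independence", {
  for (seed in 1:5) {
    sym <- random_symmetric(seed)
    eq16 <- context_independent_equilibrium(sym)
    eq4 <- nsb_equilibrium(sym)
    first_pos <- vapply(c("A", "C", "G", "T"), function(b) {
      sum(eq16[substr(names(eq16), 1, 1) == b])
    }, numeric(1))
    expect_equal(first_pos, eq4, tolerance = 1e-12)
  }
})

test_that("dyad rate tables round-trip through TSV", {
  net <- random_dyad_network(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(source_dyad = net$from,
                                  target_dyad = net$to, rate = net$rate), path)
  back <- read_dyad_rates(path)
  expect_equal(back$rate, net$rate)
})
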