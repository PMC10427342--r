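test_that("initialization satisfies the structural invariants", {
  cfg <- sorn_config(n_excitatory = 100, p_c = 0.1, n_input_subset = 5,
                     seed = 7)
  net <- init_network(cfg)
  expect_true(all(diag(net$c_ee) == 0))
  expect_true(all((net$w_ee > 0) == (net$c_ee == 1)))
  rows_with_conn <- rowSums(net$c_ee) > 0
  expect_equal(rowSums(net$w_ee)[rows_with_conn],
               rep(1, sum(rows_with_conn)), tolerance = 1e-9)
  expect_equal(rowSums(net$w_ei), rep(1, 100), tolerance = 1e-9)
  expect_equal(rowSums(net$w_ie), rep(1, 20), tolerance = 1e-9)
  expect_equal(rowSums(net$w_oe), rep(1, 3), tolerance = 1e-9)
  expect_true(all(net$e_ee == 0) && all(net$e_oe == 0))
  expect_identical(net$baseline, 0)
  # disjoint input subsets
  pool <- unlist(net$input_map)
  expect_identical(anyDuplicated(pool), 0L)
  expect_length(pool, 3 * 5)
})

test_that("achieved connection fraction matches p_c over seeds (binomial CI)", {
  p <- 0.05; ne <- 200; nseeds <- 100
  fr <- vapply(seq_len(nseeds), function(s) {
    connection_fraction(init_network(sorn_config(ne, p_c = p, seed = s)))
  }, numeric(1))
  n_pairs <- ne * (ne - 1) * nseeds
  se <- sqrt(p * (1 - p) / n_pairs)
  expect_lt(abs(mean(fr) - p), 2.58 * se)
})

test_that("input encoding drives exactly the symbol's subset", {
  net <- random_tiny_network(3, ne = 20, n_input_subset = 4)
  ua <- encode_input("a", net$input_map, 20)
  ub <- encode_input("b", net$input_map, 20)
  expect_identical(sum(ua), 4)
  expect_identical(sum(ua * ub), 0)          # disjoint symbols
  expect_identical(encode_input(NULL, net$input_map, 20), numeric(20))
  expect_error(encode_input("z", net$input_map, 20), "unknown symbol")
})

test_that("a neuron at exactly its threshold fires (step function at 0)", {
  net <- random_tiny_network(1, ne = 5, n_input_subset = 1)
  net$w_ee[] <- 0; net$w_ei[] <- 0; net$w_ie[] <- 0
  net$theta_e[] <- 1; net$s_e[] <- 0; net$s_in[] <- 0
  u <- rep(1, 5)
  net2 <- step_recurrent(net, u = u)
  expect_equal(net2$s_e, rep(1, 5))           # psi == theta fires
  net$theta_e[] <- 1 + 1e-12
  net3 <- step_recurrent(net, u = u)
  expect_equal(net3$s_e, rep(0, 5))
})

test_that("subthreshold network stays silent", {
  net <- random_tiny_network(2, ne = 8, n_input_subset = 2)
  net$w_ee[] <- 0; net$c_ee[] <- 0
  net$theta_e[] <- 0.3
  net2 <- step_recurrent(net, u = numeric(8))
  expect_true(all(net2$s_e == 0))
})

test_that("recurrent and output updates match the scalar double-loop oracle", {
  for (seed in 1:5) {
    net <- random_tiny_network(seed, ne = 10, n_input_subset = 2, p_c = 0.4)
    set.seed(seed + 100)
    net$s_e <- as.numeric(stats::runif(10) < 0.4)
    net$s_in <- as.numeric(stats::runif(2) < 0.4)
    for (step in 1:100) {
      sym <- sample(c("a", "b", "c"), 1)
      u <- encode_input(sym, net$input_map, 10)
      ref <- naive_step_recurrent(net$s_e, net$s_in, net$w_ee, net$w_ei,
                                  net$w_ie, net$theta_e, net$theta_in, u)
      out_ref <- naive_step_output(net$s_e, net$w_oe, net$theta_o)
      out <- step_output(net)
      net <- step_recurrent(net, u = u)
      expect_identical(net$s_e, ref$s_e)
      expect_identical(net$s_in, ref$s_in)
      expect_equal(out$potentials, out_ref$potentials, tolerance = 1e-12)
      expect_identical(out$states, out_ref$states)
    }
  }
})

test_that("permuting neuron indices permutes the trajectory consistently", {
  net <- random_tiny_network(9, ne = 12, n_input_subset = 3, p_c = 0.3)
  set.seed(42)
  perm <- sample(12)
  netp <- net
  netp$w_ee <- net$w_ee[perm, perm]
  netp$c_ee <- net$c_ee[perm, perm]
  netp$w_ei <- net$w_ei[perm, ]
  netp$w_ie <- net$w_ie[, perm]
  netp$w_oe <- net$w_oe[, perm]
  netp$theta_e <- net$theta_e[perm]
  netp$s_e <- net$s_e[perm]
  netp$input_map <- lapply(net$input_map, function(ix) match(ix, perm))
  for (step in 1:30) {
    sym <- c("a", "b", "c")[(step %% 3) + 1]
    u <- encode_input(sym, net$input_map, 12)
    up <- encode_input(sym, netp$input_map, 12)
    expect_identical(up, u[perm])
    net <- step_recurrent(net, u = u)
    netp <- step_recurrent(netp, u = up)
    expect_identical(netp$s_e, net$s_e[perm])
    expect_identical(netp$s_in, net$s_in)
  }
})

test_that("readout takes the argmax with deterministic tie-breaking", {
  expect_identical(readout_symbol(c(0.2, 0.9, 0.1), c("a", "b", "c")), "b")
  expect_identical(readout_symbol(c(0.5, 0.5), c("a", "b")), "a")
  expect_error(readout_symbol(numeric(0)), "empty")
  # argmax follows any permutation of the potentials
  pot <- c(0.1, 0.7, -0.2, 0.4)
  syms <- c("w", "x", "y", "z")
  perms <- list(1:4, 4:1, c(2, 1, 4, 3), c(3, 4, 1, 2), c(2, 3, 4, 1))
  for (p in perms)
    expect_identical(readout_symbol(pot[p], syms[p]),
                     syms[p][which.max(pot[p])])
})

test_that("checkpointing restores the network and RNG state bit-exactly", {
  net <- random_tiny_network(11, ne = 15, n_input_subset = 3)
  path <- tempfile(fileext = ".rds")
  set.seed(5); invisible(stats::runif(3))
  save_network(net, path)
  draws_a <- stats::runif(5)
  net2 <- load_network(path)
  draws_b <- stats::runif(5)
  expect_identical(net2, net)
  expect_identical(draws_a, draws_b)
  unlink(path)
})
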