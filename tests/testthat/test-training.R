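small_counting_setup <- function(seed = 1, ne = 60, n = 3) {
  task <- make_counting_sequence(n, 5)
  cfg <- sorn_config(ne, task$alphabet, p_c = 0.1, n_input_subset = 5,
                     seed = seed)
  list(net = init_network(cfg), task = task)
}

test_that("zero-step stages are the identity", {
  s <- small_counting_setup()
  r1 <- run_stage_one(s$net, s$task, 0)
  r2 <- run_stage_two(s$net, s$task, 0)
  expect_identical(r1$network, s$net)
  expect_identical(r2$network, s$net)
  tr <- train(s$net, s$task, sorn_protocol(100, 100, alternations = 0))
  expect_identical(tr$network$w_ee, s$net$w_ee)
  expect_identical(tr$steps_total, 0L)
})

test_that("stage two freezes the recurrent layer bit-exactly", {
  s <- small_counting_setup(2)
  set.seed(5)
  warm <- run_stage_one(s$net, s$task, 200)
  net <- warm$network
  r <- run_stage_two(net, s$task, 1000)
  expect_identical(r$network$w_ee, net$w_ee)
  expect_identical(r$network$c_ee, net$c_ee)
  expect_identical(r$network$theta_e, net$theta_e)
  expect_identical(r$network$w_ei, net$w_ei)
  expect_identical(r$network$w_ie, net$w_ie)
  expect_identical(nrow(r$events), 0L)        # no structural plasticity
  expect_false(identical(r$network$w_oe, net$w_oe))  # readout does adapt
})

test_that("all plasticity toggles off leaves weights unchanged while states evolve", {
  s <- small_counting_setup(3)
  prot <- sorn_protocol(50, 50, 2,
                        plasticity = list(rstdp_ee = FALSE, rstdp_oe = FALSE,
                                          sn = FALSE, ip_e = FALSE,
                                          ip_o = FALSE, sp = FALSE))
  set.seed(9)
  tr <- train(s$net, s$task, prot)
  expect_identical(tr$network$w_ee, s$net$w_ee)
  expect_identical(tr$network$w_oe, s$net$w_oe)
  expect_identical(tr$network$c_ee, s$net$c_ee)
  expect_identical(tr$network$theta_e, s$net$theta_e)
  expect_identical(tr$network$t, 200L)
})

test_that("training is bit-reproducible and history bookkeeping is consistent", {
  run_once <- function() {
    s <- small_counting_setup(7)
    set.seed(7)
    train(s$net, s$task, sorn_protocol(50, 200, 3), record = "step")
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$network, b$network)
  expect_identical(a$history, b$history)
  expect_identical(a$step_rewards, b$step_rewards)
  expect_identical(a$steps_total, 3L * 250L)
  expect_length(a$step_rewards, a$steps_total)
  expect_identical(nrow(a$history), 3L)
})

test_that("training runs alternate the documented step counts", {
  s <- small_counting_setup(4)
  set.seed(4)
  tr <- train(s$net, s$task, sorn_protocol(100, 2000, 1))
  expect_identical(tr$steps_total, 2100L)
  expect_identical(tr$network$t, 2100L)
})

test_that("an untrained network predicts the counting task at chance level", {
  accs <- vapply(1:20, function(s) {
    task <- make_counting_sequence(4, 5)
    cfg <- sorn_config(100, task$alphabet, p_c = 0.05, seed = s)
    net <- init_network(cfg)
    set.seed(s + 500)
    rep <- evaluate_network(net, task, steps = 300)
    rep$overall
  }, numeric(1))
  # 3 symbols: argmax of random row-normalized readouts is near-uniform
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("a hand-built lookup network solves the motion task perfectly", {
  # input subsets drive the reservoir one-to-one; the readout for symbol
  # k+1 reads exactly the neurons of subset k
  n <- 3
  task <- make_motion_sequence(n, 5)
  cfg <- sorn_config(30, task$alphabet, p_c = 0.05, n_input_subset = 5,
                     seed = 2)
  net <- init_network(cfg)
  net$w_ee[] <- 0; net$c_ee[] <- 0        # pure feedforward relay
  net$theta_e[] <- 0.5                    # fires only under external drive
  net$w_ie[] <- 0; net$theta_in[] <- 2    # inhibition silent
  w_oe <- matrix(0, n, 30)
  for (k in seq_len(n)) {
    succ <- (k %% n) + 1
    w_oe[succ, net$input_map[[as.character(k)]]] <- 1 / 5
  }
  net$w_oe <- w_oe
  net$theta_o[] <- 0.5
  set.seed(11)
  rep <- evaluate_network(net, task, steps = 200)
  expect_equal(rep$overall, 1.0)
})

test_that("inference leaves the network weights untouched", {
  s <- small_counting_setup(5)
  set.seed(3)
  res <- infer(s$net, s$task, 200)
  expect_identical(res$network$w_ee, s$net$w_ee)
  expect_identical(res$network$w_oe, s$net$w_oe)
  expect_length(res$predicted, 200)
  expect_true(all(res$predicted %in% s$task$alphabet))
})

test_that("generation-mode inference feeds read-outs back autonomously", {
  task <- make_motion_sequence(3, 5)
  cfg <- sorn_config(60, task$alphabet, p_c = 0.1, n_input_subset = 5,
                     seed = 6)
  net <- init_network(cfg)
  set.seed(2)
  res <- infer(net, task, steps = 50, mode = "generation")
  expect_length(res$predicted, 50)
  expect_identical(res$seed_symbol, "1")
  expect_true(all(is.na(res$presented[-1])))
})

test_that("mean training reward trends upward across alternations", {
  task <- make_counting_sequence(4, 10)
  cfg <- sorn_config(200, task$alphabet, p_c = 0.05, seed = 8)
  net <- init_network(cfg)
  set.seed(8)
  tr <- train(net, task, sorn_protocol(100, 2000, 20))
  r <- tr$history$reward_stage2
  early <- mean(r[1:5]); late <- mean(r[16:20])
  expect_gte(late, early - 0.05)   # non-decreasing up to plateau noise
  expect_gt(late, 0.5)             # and well above chance by the end
})
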