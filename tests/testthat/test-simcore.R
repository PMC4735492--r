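# Simulation core: initialization, nucleation, expansion, payoffs,
# imitation, full rounds and full runs.

test_that("init_population draws strategies in the stated ranges", {
  net <- generate_ws_network(60, 6, 0.75, seed = 4)
  cfg <- sim_config(alpha = 1)
  withr::with_seed(1, {
    pop <- init_population(net, cfg, leaders = 0:2,
                           control_assignment(saints = 3L, devils = 4L))
    expect_s3_class(pop, "agent_population")
    lead <- pop$strategy[1:3]
    expect_true(all(lead >= 0.5 & lead <= 1))
    expect_identical(pop$strategy[4], 0)
    expect_identical(pop$strategy[5], 1)
    reg <- pop$strategy[pop$role == "regular"]
    expect_true(all(reg >= 0 & reg <= 1))
    expect_true(all(pop$payoff == 0))
  })
  # alpha bounds the regular draws
  cfg2 <- sim_config(alpha = 0.3)
  withr::with_seed(2, {
    pop2 <- init_population(net, cfg2, leaders = 0:2)
    expect_true(all(pop2$strategy[pop2$role == "regular"] <= 0.3))
    expect_true(all(pop2$strategy[1:3] >= 0.5))
  })
  expect_error(sim_config(alpha = 0), class = "raidnet_config_error")
  expect_error(init_population(net, cfg, leaders = 0:2,
                               control_assignment(saints = 2L)),
               class = "raidnet_config_error")  # overlapping roles
})

test_that("nucleation honours the pool, the cap, and control roles", {
  net <- ring_net(10, 4)
  cfg <- sim_config(n = 5L, m = 2L)
  withr::with_seed(3, {
    pop_devils <- pop_with_roles(net, cfg, leaders = 0L, devils = 1:9)
    out <- nucleate(net, pop_devils, 0L, n = 3L, r = 1L)
    expect_length(out$invited, 3)
    expect_setequal(out$nucleus, out$invited)   # devils always join

    pop_saints <- pop_with_roles(net, cfg, leaders = 0L, saints = 1:9)
    out2 <- nucleate(net, pop_saints, 0L, n = 3L, r = 1L)
    expect_length(out2$nucleus, 0)              # saints never join

    # n larger than the pool: everyone within r is invited
    out3 <- nucleate(net, pop_devils, 0L, n = 5L, r = 1L)
    expect_setequal(out3$invited, c(1, 2, 8, 9))

    expect_error(nucleate(net, pop_devils, 1L, 2L, 1L),
                 class = "raidnet_config_error")  # not a leader
  })
})

test_that("expansion invites each friend-of-nucleus exactly once", {
  # star: center 0 is the only friend of every leaf
  net <- star_net(6)
  cfg <- sim_config()
  withr::with_seed(4, {
    pop <- pop_with_roles(net, cfg, leaders = 1L, devils = 0L)
    out <- expand(net, pop, nucleus = c(2L, 3L), already_asked = c(1L, 2L, 3L))
    expect_identical(out$invited, 0L)           # only the center remains
    expect_identical(out$joiners, 0L)           # devil center always joins

    pop2 <- pop_with_roles(net, cfg, leaders = 1L, saints = 0L)
    out2 <- expand(net, pop2, nucleus = c(2L, 3L), already_asked = c(1L, 2L, 3L))
    expect_length(out2$joiners, 0)
    expect_error(expand(net, pop2, integer()), class = "raidnet_parameter_error")
  })
})

test_that("expansion makes one join draw per node regardless of adjacency", {
  # node 0 is adjacent to all three nucleus members 1, 2, 3
  net <- net_from_edges(rbind(c(0, 1), c(0, 2), c(0, 3),
                              c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  cfg <- sim_config()
  withr::with_seed(5, {
    pop <- pop_with_roles(net, cfg, leaders = 4L)
    pop$strategy[1] <- 0.5                      # node 0
    trials <- 10000
    joins <- vapply(seq_len(trials), function(i) {
      0L %in% expand(net, pop, nucleus = 1:3, already_asked = c(4L, 1L, 2L, 3L))$joiners
    }, logical(1))
    p_hat <- mean(joins)
    # one Bernoulli(0.5) draw, not 1 - 0.5^3: 3 sigma binomial band
    expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / trials))
  })
})

test_that("payoffs follow the coordination rule exactly", {
  net <- path_net(6)
  pop <- structure(list(strategy = rep(0.5, 6), role = rep("regular", 6),
                        payoff = numeric(6)), class = "agent_population")
  asked <- c(1L, 2L, 3L); joined <- c(1L, 2L)

  p <- assign_payoffs(pop, asked, joined, occurred = TRUE)
  expect_equal(p, c(0, 1, 1, -1, 0, 0))

  p2 <- assign_payoffs(pop, asked, joined, occurred = FALSE)
  expect_equal(p2, c(0, -1, -1, 1, 0, 0))

  # unequal costs: reward twice the cost; refusal before a failed raid wins +2
  p3 <- assign_payoffs(pop, asked, joined, occurred = FALSE, reward = 2, cost = 1)
  expect_equal(p3, c(0, -1, -1, 2, 0, 0))
  p4 <- assign_payoffs(pop, asked, joined, occurred = TRUE, reward = 2, cost = 1)
  expect_equal(p4, c(0, 2, 2, -1, 0, 0))

  # bookkeeping: exactly the asked nodes have nonzero payoff, and the total
  # decomposes into winners and losers
  expect_setequal(which(p != 0) - 1L, asked)
  expect_equal(sum(p), 1 * 2 - 1 * 1)
  expect_error(assign_payoffs(pop, asked, joined = 5L, TRUE),
               class = "raidnet_parameter_error")
})

test_that("imitation copies strictly better peers, synchronously", {
  net <- path_net(4)
  mk <- function(strategy, role, payoff) {
    structure(list(strategy = strategy, role = role, payoff = payoff),
              class = "agent_population")
  }
  # two regular agents: the -1 agent adopts the +1 agent's strategy
  pop <- mk(c(0.2, 0.9, 0, 0), c("regular", "regular", "saint", "leader"),
            c(1, -1, 5, 5))
  withr::with_seed(6, {
    out <- update_strategies(pop)
    expect_equal(out$strategy[2], 0.2)      # loser adopted winner
    expect_equal(out$strategy[1], 0.2)      # winner kept its own
    expect_equal(out$strategy[3], 0)        # saint never learns, despite payoff 5
    expect_equal(out$strategy[4], 0)        # leader untouched
  })
  # equal payoffs: strict inequality means nothing changes
  pop_eq <- mk(runif(4), rep("regular", 4), rep(1, 4))
  withr::with_seed(7, expect_identical(update_strategies(pop_eq)$strategy,
                                       pop_eq$strategy))
  # fewer than two regular agents: no-op
  pop_one <- mk(c(0.5, 1), c("regular", "devil"), c(-1, 5))
  expect_identical(update_strategies(pop_one)$strategy, pop_one$strategy)
})

test_that("controls are never used as imitation models", {
  # one regular agent with the worst payoff surrounded by a high-payoff
  # saint: over many draws it must never adopt the saint's strategy
  mk <- function() structure(
    list(strategy = c(0.7, 0.3, 0), role = c("regular", "regular", "saint"),
         payoff = c(-1, -1, 5)), class = "agent_population")
  withr::with_seed(8, {
    for (i in 1:50) {
      out <- update_strategies(mk())
      expect_false(any(out$strategy[1:2] == 0))
    }
  })
})

test_that("run_generation assembles consistent raid records", {
  net <- ring_net(10, 4)
  cfg <- sim_config(n = 3L, m = 1L)
  withr::with_seed(9, {
    pop <- pop_with_roles(net, cfg, leaders = 0L, devils = 1:9)
    out <- run_generation(net, pop, cfg)
    rec <- out$record
    expect_true(rec$occurred)                   # m = 1, devils always join
    expect_true(all(rec$joined %in% rec$asked))
    expect_true(all(rec$nucleus_joined %in% rec$nucleus_invited))
    expect_true(all(rec$expansion_joined %in% rec$expansion_invited))
    expect_false(rec$leader %in% rec$asked)
    expect_equal(rec$occurred, length(rec$joined) >= cfg$m)
    expect_true(all(out$population$payoff == 0))  # reset after learning

    # all non-leaders saints: no raid can ever occur
    pop_s <- pop_with_roles(net, cfg, leaders = 0L, saints = 1:9)
    for (i in 1:5) expect_false(run_generation(net, pop_s, cfg)$record$occurred)
  })
})

test_that("simulator raid frequency matches the exact brute-force probability", {
  inst <- oracle_instance()
  p_exact <- oracle_exact_raid_probability()
  expect_equal(p_exact, 1 / 3)        # frozen: enumeration over C(3,2) nuclei

  trials <- 20000
  withr::with_seed(10, {
    hits <- vapply(seq_len(trials), function(i) {
      run_generation(inst$net, inst$pop, inst$cfg)$record$occurred
    }, logical(1))
  })
  p_hat <- mean(hits)
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / trials))
})

test_that("runs are seed-deterministic and keep strategies in [0, 1]", {
  net <- generate_ws_network(50, 6, 0.75, seed = 12)
  cfg <- sim_config(n = 4L, m = 8L, max_generations = 400L)
  a <- run_simulation(net, cfg, leaders = c(0L, 10L, 20L), seed = 99,
                      record_trajectory = TRUE)
  b <- run_simulation(net, cfg, leaders = c(0L, 10L, 20L), seed = 99,
                      record_trajectory = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$mrr, b$mrr)
  expect_identical(a$final_strategies, b$final_strategies)
  expect_equal(a$mrr, a$final_mean_strategy / a$initial_mean_strategy)
  expect_lte(a$generations, cfg$max_generations)

  # property: strategies stay in [0,1]; the regular value set only shrinks
  for (seed in c(1L, 2L, 3L)) {
    r <- run_simulation(net, cfg, leaders = c(0L, 10L, 20L), seed = seed)
    expect_true(all(r$final_strategies >= 0 & r$final_strategies <= 1))
    init <- withr::with_seed(seed, {
      init_population(net, cfg, c(0L, 10L, 20L))$strategy
    })
    regular <- setdiff(seq_len(50), c(0L, 10L, 20L) + 1L)
    expect_true(all(r$final_strategies[regular] %in% init[regular]))
  }
})

test_that("degenerate populations converge immediately with MRR 1", {
  net <- ring_net(12, 4)
  cfg <- sim_config(n = 2L, m = 2L)
  # saints + leaders only: no learners, frozen strategies
  r <- run_simulation(net, cfg, leaders = 0:1,
                      control_assignment(saints = 2:11), seed = 5)
  expect_true(r$converged)
  expect_equal(r$mrr, 1)
  expect_equal(r$generations, 0)

  # no leaders at all: nothing ever changes either
  r2 <- run_simulation(net, cfg, leaders = integer(), seed = 5)
  expect_true(r2$converged)
  expect_equal(r2$mrr, 1)
})

test_that("trajectory and snapshot exports are well-formed", {
  net <- ring_net(12, 4)
  cfg <- sim_config(n = 2L, m = 3L, max_generations = 50L, stall_window = 10L)
  r <- run_simulation(net, cfg, leaders = 0L, seed = 3,
                      record_trajectory = TRUE, snapshot_generations = c(1L, 2L))
  expect_length(r$trajectory, r$generations)

  tf <- withr::local_tempfile(fileext = ".csv")
  trajectory_csv(r, tf)
  traj <- read.csv(tf)
  expect_identical(names(traj), c("generation", "mean_strategy"))
  expect_equal(nrow(traj), r$generations)

  sf <- withr::local_tempfile(fileext = ".csv")
  snapshots_csv(r, sf)
  snap <- read.csv(sf)
  expect_identical(names(snap), c("generation", "node_id", "strategy"))
  expect_equal(nrow(snap), 12 * length(r$snapshots))

  jf <- withr::local_tempfile(fileext = ".json")
  run_to_json(r, jf)
  js <- jsonlite::read_json(jf)
  expect_equal(js$mrr, r$mrr)
  expect_equal(js$generations, r$generations)

  rec <- withr::with_seed(4, {
    pop <- pop_with_roles(net, cfg, leaders = 0L, devils = 1:11)
    run_generation(net, pop, cfg)$record
  })
  rf <- withr::local_tempfile(fileext = ".json")
  record_to_json(rec, rf)
  rj <- jsonlite::read_json(rf, simplifyVector = TRUE)
  expect_equal(rj$occurred, rec$occurred)
  expect_equal(rj$joined, rec$joined)
})
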