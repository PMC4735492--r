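# Simulation core: one full game of nucleation, expansion, coordination
# payoffs, and population-wide pairwise imitation, run to convergence.
#
# All user-facing node ids are 0-based (matching social_network); internal
# state vectors are 1-based and converted only at the API boundary.

ROLE_LEVELS <- c("regular", "leader", "saint", "devil")

#' Simulation configuration
#'
#' Collects every model and experiment parameter. Defaults for the nucleus
#' size `n` and raid threshold `m` are the values picked by
#' [calibrate_baseline()] on the `ws91` fixture so that the baseline Mean
#' Risk-taking Ratio is close to one; everything else follows the model's
#' stated baseline (payoff magnitude normalised to 1, recruitment radius 1,
#' leader strategies in `[0.5, 1]`).
#'
#' @param n nucleus invitation count (how many candidates the leader asks).
#' @param m raid threshold: minimum joiners for the raid to occur.
#' @param r recruitment radius in hops for nucleus sampling.
#' @param reward payoff magnitude for successful coordination (> 0).
#' @param cost payoff magnitude for failed coordination (> 0).
#' @param alpha upper bound in `(0, 1]` on initial non-leader strategies
#'   ("attitude bias"); `alpha = 1` is the unbiased baseline.
#' @param leader_strategy_bounds interval for initial leader strategies.
#' @param saints,devils number of control nodes of each kind.
#' @param placement `"random"` or `"top_degree"` control placement.
#' @param max_generations hard cap on generations per run.
#' @param stall_window generations of unchanged regular-agent strategies
#'   that define convergence.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 5L, m = 11L, r = 1L,
                       reward = 1, cost = 1, alpha = 1,
                       leader_strategy_bounds = c(0.5, 1),
                       saints = 0L, devils = 0L,
                       placement = c("random", "top_degree"),
                       max_generations = 5000L, stall_window = 100L) {
  placement <- match.arg(placement)
  if (!is_count(n, 1L)) rn_config_error("n (nucleus size) must be an integer >= 1")
  if (!is_count(m, 1L)) rn_config_error("m (raid threshold) must be an integer >= 1")
  if (!is_count(r, 1L) && !identical(r, Inf)) rn_config_error("r (radius) must be an integer >= 1 or Inf")
  if (!is.numeric(reward) || reward <= 0) rn_config_error("reward must be > 0")
  if (!is.numeric(cost) || cost <= 0) rn_config_error("cost must be > 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    rn_config_error("alpha must lie in (0, 1]")
  }
  if (length(leader_strategy_bounds) != 2L ||
      leader_strategy_bounds[1L] > leader_strategy_bounds[2L] ||
      leader_strategy_bounds[1L] < 0 || leader_strategy_bounds[2L] > 1) {
    rn_config_error("leader_strategy_bounds must be an interval within [0, 1]")
  }
  if (!is_count(saints) || !is_count(devils)) rn_config_error("saints/devils must be counts")
  if (!is_count(max_generations, 1L)) rn_config_error("max_generations must be >= 1")
  if (!is_count(stall_window, 1L)) rn_config_error("stall_window must be >= 1")
  structure(list(
    n = as.integer(n), m = as.integer(m), r = r,
    reward = reward, cost = cost, alpha = alpha,
    leader_strategy_bounds = as.numeric(leader_strategy_bounds),
    saints = as.integer(saints), devils = as.integer(devils),
    placement = placement,
    max_generations = as.integer(max_generations),
    stall_window = as.integer(stall_window)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n=%d m=%d r=%s reward=%g cost=%g alpha=%g saints=%d devils=%d (%s)\n",
    x$n, x$m, format(x$r), x$reward, x$cost, x$alpha, x$saints, x$devils, x$placement))
  invisible(x)
}

#' Initialize an agent population
#'
#' Leader strategies are drawn uniformly from the leader bounds (default
#' `[0.5, 1]`), regular strategies uniformly from `[0, alpha]`. Saints get
#' strategy 0 and devils strategy 1; control and leader strategies are fixed
#' for the lifetime of a run. All payoffs start at 0. Draws use the current
#' R RNG state ([run_simulation()] seeds it).
#'
#' @param net a `social_network`.
#' @param cfg a [sim_config()].
#' @param leaders node ids (0-based) of leaders.
#' @param controls optional [control_assignment()] with saint/devil ids.
#' @return an `agent_population`: list of `strategy`, `role`, `payoff`
#'   vectors indexed by node id + 1.
#' @export
init_population <- function(net, cfg, leaders, controls = NULL) {
  N <- net$N
  leaders <- as.integer(leaders)
  saints <- as.integer(controls$saints %||% integer())
  devils <- as.integer(controls$devils %||% integer())
  ids <- c(leaders, saints, devils)
  if (length(ids) > 0L && (min(ids) < 0L || max(ids) >= N)) {
    rn_config_error("role node ids must be in 0..N-1")
  }
  if (anyDuplicated(ids)) {
    rn_config_error("leader, saint and devil sets must be disjoint")
  }
  role <- rep("regular", N)
  role[leaders + 1L] <- "leader"
  role[saints + 1L] <- "saint"
  role[devils + 1L] <- "devil"
  strategy <- stats::runif(N, 0, cfg$alpha)
  nl <- length(leaders)
  if (nl > 0L) {
    strategy[leaders + 1L] <- stats::runif(
      nl, cfg$leader_strategy_bounds[1L], cfg$leader_strategy_bounds[2L])
  }
  strategy[saints + 1L] <- 0
  strategy[devils + 1L] <- 1
  structure(list(strategy = strategy, role = role, payoff = numeric(N)),
            class = "agent_population")
}

#' Effective join probabilities of a population
#'
#' Saints never join (probability 0) and devils always join (probability 1)
#' regardless of their stored strategy; everyone else joins with their
#' strategy when asked.
#'
#' @param pop an `agent_population`.
#' @return numeric vector of probabilities indexed by node id + 1.
#' @export
effective_join <- function(pop) {
  p <- pop$strategy
  p[pop$role == "saint"] <- 0
  p[pop$role == "devil"] <- 1
  p
}

#' Nucleation: a leader recruits the raid nucleus
#'
#' Samples `min(n, |neighborhood|)` invitees uniformly without replacement
#' from the nodes within social distance `r` of the leader; each invitee
#' independently joins with its effective join probability. The joiners form
#' the raid nucleus.
#'
#' @param net a `social_network`.
#' @param pop an `agent_population`.
#' @param leader node id of the initiating leader (must hold the leader role).
#' @param n invitation count.
#' @param r recruitment radius.
#' @return list with `invited` and `nucleus` (0-based node id vectors).
#' @export
nucleate <- function(net, pop, leader, n, r) {
  leader <- check_node(net, leader)
  if (pop$role[leader + 1L] != "leader") {
    rn_config_error(sprintf("node %d is not a leader", leader))
  }
  pool <- neighborhood(net, leader, r)
  if (length(pool) == 0L) {
    return(list(invited = integer(), nucleus = integer()))
  }
  k <- min(as.integer(n), length(pool))
  invited <- pool[sample.int(length(pool), k)]
  pj <- effective_join(pop)
  joins <- stats::runif(k) < pj[invited + 1L]
  list(invited = invited, nucleus = invited[joins])
}

#' Expansion: the nucleus asks its direct friends
#'
#' Every direct friend of a nucleus member -- excluding the nucleus itself,
#' the leader, and anyone already asked -- is invited exactly once and makes
#' a single independent join draw at its effective probability, no matter
#' how many nucleus members it is adjacent to.
#'
#' @param net a `social_network`.
#' @param pop an `agent_population`.
#' @param nucleus nonempty vector of nucleus node ids.
#' @param already_asked node ids already invited this round (the nucleus
#'   invitees and the leader).
#' @return list with `invited` and `joiners` (0-based node id vectors).
#' @export
expand <- function(net, pop, nucleus, already_asked = integer()) {
  if (length(nucleus) == 0L) rn_param_error("expand() requires a nonempty nucleus")
  nucleus <- as.integer(nucleus)
  cand <- unique(unlist(net$adj[nucleus + 1L], use.names = FALSE)) - 1L
  invited <- setdiff(cand, c(nucleus, as.integer(already_asked)))
  if (length(invited) == 0L) {
    return(list(invited = integer(), joiners = integer()))
  }
  pj <- effective_join(pop)
  joins <- stats::runif(length(invited)) < pj[invited + 1L]
  list(invited = invited, joiners = invited[joins])
}

#' Coordination payoffs for one raid round
#'
#' If the raid occurs, joiners earn `+reward` and asked non-joiners pay
#' `-cost`; if it fails, joiners pay `-cost` and asked non-joiners earn
#' `+reward`. Everyone not asked (including the leader) has payoff 0.
#'
#' @param pop an `agent_population` (only its size is used).
#' @param asked node ids invited this round.
#' @param joined subset of `asked` that agreed.
#' @param occurred did the raid occur (`|joined| >= m`)?
#' @param reward,cost payoff magnitudes.
#' @return numeric payoff vector indexed by node id + 1.
#' @export
assign_payoffs <- function(pop, asked, joined, occurred, reward = 1, cost = 1) {
  asked <- as.integer(asked); joined <- as.integer(joined)
  if (!all(joined %in% asked)) rn_param_error("joined must be a subset of asked")
  payoff <- numeric(length(pop$strategy))
  refused <- setdiff(asked, joined)
  if (occurred) {
    payoff[joined + 1L] <- reward
    payoff[refused + 1L] <- -cost
  } else {
    payoff[joined + 1L] <- -cost
    payoff[refused + 1L] <- reward
  }
  payoff
}

#' Population-wide pairwise imitation update
#'
#' Synchronously, every regular agent picks one peer uniformly at random
#' from the other regular agents and adopts that peer's pre-update strategy
#' iff the peer's payoff is strictly higher. Leaders, saints and devils
#' neither learn nor serve as models. With fewer than two regular agents the
#' update is a no-op.
#'
#' @param pop an `agent_population` with `payoff` set for this generation.
#' @return the updated `agent_population`.
#' @export
update_strategies <- function(pop) {
  learners <- which(pop$role == "regular")
  nR <- length(learners)
  if (nR < 2L) return(pop)
  pos <- sample.int(nR - 1L, nR, replace = TRUE)
  pos <- pos + (pos >= seq_len(nR))          # skip self
  peers <- learners[pos]
  better <- pop$payoff[peers] > pop$payoff[learners]
  if (any(better)) {
    pop$strategy[learners[better]] <- pop$strategy[peers[better]]
  }
  pop
}

# Precomputed per-run context: 1-based index vectors and leader
# neighborhoods, so the generation step allocates almost nothing.
sim_context <- function(net, cfg, leaders, controls = NULL) {
  leaders <- as.integer(leaders)
  # no leaders is a degenerate but legal world: no raid can ever nucleate
  nbhds <- lapply(leaders, function(v) neighborhood(net, v, cfg$r) + 1L)
  list(
    N = net$N,
    adj = net$adj,
    leaders1 = leaders + 1L,
    nL = length(leaders),
    nbhds = nbhds,
    n = cfg$n, m = cfg$m,
    reward = cfg$reward, cost = cfg$cost
  )
}

# One generation on raw state. strat is the length-N strategy vector
# (1-based); learners1 the regular-agent indices. Returns the new strategy
# vector, a change flag, and the raid record fields (still 1-based).
gen_step <- function(ctx, strat, learners1) {
  if (ctx$nL > 0L) {
    li <- sample.int(ctx$nL, 1L)
    leader1 <- ctx$leaders1[li]
    pool <- ctx$nbhds[[li]]
  } else {
    leader1 <- 0L                       # sentinel: matches no node
    pool <- integer()
  }
  npool <- length(pool)
  if (npool > 0L) {
    k <- if (ctx$n < npool) ctx$n else npool
    nuc_invited <- pool[sample.int(npool, k)]
    njoin <- stats::runif(k) < strat[nuc_invited]
    nucleus <- nuc_invited[njoin]
  } else {
    nuc_invited <- integer(); njoin <- logical(); nucleus <- integer()
  }
  if (length(nucleus) > 0L) {
    cand <- unique(unlist(ctx$adj[nucleus], use.names = FALSE))
    exp_invited <- cand[!(cand %in% nucleus) & cand != leader1 &
                          !(cand %in% nuc_invited)]
    ejoin <- stats::runif(length(exp_invited)) < strat[exp_invited]
    exp_joined <- exp_invited[ejoin]
  } else {
    exp_invited <- integer(); ejoin <- logical(); exp_joined <- integer()
  }
  joined <- c(nucleus, exp_joined)
  occurred <- length(joined) >= ctx$m
  refused <- c(nuc_invited[!njoin], exp_invited[!ejoin])

  payoff <- numeric(ctx$N)
  if (occurred) {
    payoff[joined] <- ctx$reward
    payoff[refused] <- -ctx$cost
  } else {
    payoff[joined] <- -ctx$cost
    payoff[refused] <- ctx$reward
  }

  changed <- FALSE
  nR <- length(learners1)
  if (nR >= 2L) {
    pos <- sample.int(nR - 1L, nR, replace = TRUE)
    pos <- pos + (pos >= seq_len(nR))
    peers <- learners1[pos]
    better <- payoff[peers] > payoff[learners1]
    if (any(better)) {
      src <- peers[better]; dst <- learners1[better]
      changed <- any(strat[src] != strat[dst])
      strat[dst] <- strat[src]
    }
  }
  list(
    strat = strat, changed = changed,
    leader1 = leader1, nuc_invited1 = nuc_invited, nucleus1 = nucleus,
    exp_invited1 = exp_invited, exp_joined1 = exp_joined,
    occurred = occurred, payoff = payoff
  )
}

#' Run one generation: nucleation, expansion, payoffs, imitation
#'
#' Selects a leader uniformly at random, recruits a nucleus within radius
#' `r`, expands through the nucleus's direct friendships, declares the raid
#' if at least `m` agents joined, assigns coordination payoffs, performs the
#' synchronous imitation update, and resets payoffs to zero. An empty
#' neighbourhood or empty nucleus is a degenerate round: nobody beyond the
#' nucleus invitees is asked and the raid fails unless `m` is met.
#'
#' @param net a `social_network`.
#' @param pop an `agent_population` (leaders are the nodes with role
#'   `"leader"`).
#' @param cfg a [sim_config()].
#' @return list with `record` (a `raid_record`) and `population` (updated).
#' @export
run_generation <- function(net, pop, cfg) {
  leaders <- which(pop$role == "leader") - 1L
  ctx <- sim_context(net, cfg, leaders)
  strat <- effective_join(pop)          # controls pinned at 0/1
  st <- gen_step(ctx, strat, which(pop$role == "regular"))
  pop$strategy <- st$strat
  pop$strategy[pop$role == "saint"] <- 0
  pop$strategy[pop$role == "devil"] <- 1
  pop$payoff <- numeric(net$N)          # reset after learning
  record <- structure(list(
    leader = if (st$leader1 > 0L) st$leader1 - 1L else NA_integer_,
    nucleus_invited = sort(st$nuc_invited1 - 1L),
    nucleus_joined = sort(st$nucleus1 - 1L),
    expansion_invited = sort(st$exp_invited1 - 1L),
    expansion_joined = sort(st$exp_joined1 - 1L),
    asked = sort(c(st$nuc_invited1, st$exp_invited1) - 1L),
    joined = sort(c(st$nucleus1, st$exp_joined1) - 1L),
    occurred = st$occurred
  ), class = "raid_record")
  list(record = record, population = pop)
}

#' Run a full simulation to convergence
#'
#' Repeats [run_generation()] until the strategies of all regular agents
#' have been unchanged for `stall_window` consecutive generations, or all
#' regular agents share a single strategy value, or `max_generations` is
#' reached. The Mean Risk-taking Ratio (MRR) is the mean of all `N`
#' strategies after the run divided by the initial mean. Identical seeds
#' give identical results.
#'
#' @param net a `social_network`.
#' @param cfg a [sim_config()].
#' @param leaders leader node ids (0-based).
#' @param controls optional [control_assignment()].
#' @param seed integer seed for the whole run (initialization + dynamics).
#' @param record_trajectory keep the per-generation population mean strategy?
#' @param snapshot_generations generations at which to snapshot all node
#'   strategies (for visualisation export).
#' @return a `raid_run`: `initial_mean_strategy`, `final_mean_strategy`,
#'   `mrr`, `generations`, `converged`, `raids_occurred`, optional
#'   `trajectory` and `snapshots`.
#' @export
run_simulation <- function(net, cfg, leaders, controls = NULL, seed = 1L,
                           record_trajectory = FALSE,
                           snapshot_generations = NULL) {
  if (!is_count(seed)) rn_param_error("seed must be a single integer")
  withr::with_seed(as.integer(seed), {
    pop <- init_population(net, cfg, leaders, controls)
    ctx <- sim_context(net, cfg, leaders, controls)
    learners1 <- which(pop$role == "regular")
    strat <- pop$strategy
    initial_mean <- mean(strat)
    traj <- if (record_trajectory) numeric(cfg$max_generations) else NULL
    snaps <- if (!is.null(snapshot_generations)) list() else NULL
    stall <- 0L; gen <- 0L; converged <- FALSE; n_raids <- 0L

    if (length(learners1) <= 1L) converged <- TRUE    # nothing can evolve

    while (!converged && gen < cfg$max_generations) {
      gen <- gen + 1L
      st <- gen_step(ctx, strat, learners1)
      strat <- st$strat
      if (st$occurred) n_raids <- n_raids + 1L
      if (record_trajectory) traj[gen] <- mean(strat)
      if (!is.null(snaps) && gen %in% snapshot_generations) {
        snaps[[as.character(gen)]] <- strat
      }
      stall <- if (st$changed) 0L else stall + 1L
      ls <- strat[learners1]
      if (stall >= cfg$stall_window || all(ls == ls[1L])) converged <- TRUE
    }

    final_mean <- mean(strat)
    structure(list(
      initial_mean_strategy = initial_mean,
      final_mean_strategy = final_mean,
      mrr = final_mean / initial_mean,
      generations = gen,
      converged = converged,
      raids_occurred = n_raids,
      seed = as.integer(seed),
      trajectory = if (record_trajectory) traj[seq_len(gen)] else NULL,
      snapshots = snaps,
      final_strategies = strat
    ), class = "raid_run")
  })
}

#' @export
print.raid_run <- function(x, ...) {
  cat(sprintf(
    "<raid_run> MRR %.3f (mean strategy %.3f -> %.3f) in %d generations%s\n",
    x$mrr, x$initial_mean_strategy, x$final_mean_strategy, x$generations,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Export a run for downstream tooling
#'
#' `run_to_json()` serialises the scalar results of a run; `trajectory_csv()`
#' writes `generation, mean_strategy` rows; `snapshots_csv()` writes long-form
#' `generation, node_id, strategy` rows for node-colour visualisations.
#'
#' @param run a `raid_run`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
run_to_json <- function(run, path) {
  jsonlite::write_json(run[c("initial_mean_strategy", "final_mean_strategy",
                             "mrr", "generations", "converged",
                             "raids_occurred", "seed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_to_json
#' @param record a `raid_record` from [run_generation()].
#' @export
record_to_json <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_to_json
#' @export
trajectory_csv <- function(run, path) {
  if (is.null(run$trajectory)) rn_param_error("run was made without record_trajectory = TRUE")
  utils::write.csv(
    data.frame(generation = seq_along(run$trajectory),
               mean_strategy = run$trajectory),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname run_to_json
#' @export
snapshots_csv <- function(run, path) {
  if (is.null(run$snapshots) || length(run$snapshots) == 0L) {
    rn_param_error("run has no snapshots; pass snapshot_generations to run_simulation()")
  }
  gens <- as.integer(names(run$snapshots))
  N <- length(run$snapshots[[1L]])
  df <- data.frame(
    generation = rep(gens, each = N),
    node_id = rep(seq_len(N) - 1L, times = length(gens)),
    strategy = unlist(run$snapshots, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
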