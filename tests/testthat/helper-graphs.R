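# Small graphs and populations built in code for the tests.

# Undirected social_network from an explicit 0-based edge list.
net_from_edges <- function(edges) {
  g <- igraph::graph_from_edgelist(edges + 1L, directed = FALSE)
  as_social_network(g)
}

# Path 0 - 1 - 2 - ... - (n-1).
path_net <- function(n) {
  net_from_edges(cbind(0:(n - 2L), 1:(n - 1L)))
}

# Star with center 0 and n - 1 leaves.
star_net <- function(n) {
  net_from_edges(cbind(0L, 1:(n - 1L)))
}

# Ring lattice: generate_ws_network with zero rewiring.
ring_net <- function(n, k) generate_ws_network(n, k, 0, seed = 1L)

# Population with explicit roles on a network; strategies from the current
# RNG unless pinned afterwards.
pop_with_roles <- function(net, cfg = sim_config(), leaders = integer(),
                           saints = integer(), devils = integer()) {
  init_population(net, cfg, leaders,
                  control_assignment(saints = saints, devils = devils))
}

# The fixed 6-node instance used for the brute-force raid-probability
# oracle: leader 0, everyone else pinned to strategy 0 (saint) or 1 (devil).
#   edges: 0-1, 0-2, 0-3, 1-2, 2-4, 3-5
#   devils: 1, 3, 4; saints: 2, 5
oracle_instance <- function() {
  net <- net_from_edges(rbind(c(0, 1), c(0, 2), c(0, 3),
                              c(1, 2), c(2, 4), c(3, 5)))
  cfg <- sim_config(n = 2L, m = 2L, r = 1L)
  pop <- pop_with_roles(net, cfg, leaders = 0L,
                        saints = c(2L, 5L), devils = c(1L, 3L, 4L))
  list(net = net, cfg = cfg, pop = pop)
}

# Independent oracle: exact probability that a raid occurs in the instance
# above, by enumerating every equally likely nucleus invitation subset and
# following the (deterministic, strategies in {0,1}) expansion by hand.
# Uses only the raw edge list, not the package's graph primitives.
oracle_exact_raid_probability <- function() {
  edges <- rbind(c(0, 1), c(0, 2), c(0, 3), c(1, 2), c(2, 4), c(3, 5))
  devils <- c(1L, 3L, 4L)
  n <- 2L; m <- 2L
  friends_of <- function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  }
  pool <- friends_of(0L)                      # r = 1 recruitment pool
  subsets <- utils::combn(pool, min(n, length(pool)), simplify = FALSE)
  hits <- vapply(subsets, function(invited) {
    nucleus <- intersect(invited, devils)
    joined <- nucleus
    if (length(nucleus) > 0L) {
      friends <- unique(unlist(lapply(nucleus, friends_of)))
      expansion <- setdiff(friends, c(nucleus, 0L, invited))
      joined <- c(joined, intersect(expansion, devils))
    }
    length(joined) >= m
  }, logical(1))
  mean(hits)
}
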