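# Intervention regimes: attitude bias (alpha) on initial strategies, and
# saint/devil control nodes placed randomly or on top-degree nodes.

#' Saint/devil control assignment
#'
#' @param saints,devils node id vectors (0-based); must be disjoint.
#' @param placement_mode how the controls were chosen.
#' @return a `control_assignment`.
#' @export
control_assignment <- function(saints = integer(), devils = integer(),
                               placement_mode = c("random", "top_degree")) {
  placement_mode <- match.arg(placement_mode)
  saints <- sort(as.integer(saints)); devils <- sort(as.integer(devils))
  if (length(intersect(saints, devils)) > 0L) {
    rn_config_error("a node cannot be both saint and devil")
  }
  structure(list(saints = saints, devils = devils,
                 placement_mode = placement_mode),
            class = "control_assignment")
}

#' Place control nodes in a network
#'
#' Saints never join a raid when asked; devils always do. Controls are drawn
#' from non-leader nodes, either uniformly at random or as the highest-degree
#' nodes (ties broken by ascending node id). Deterministic given `seed`.
#'
#' @param net a `social_network`.
#' @param role `"saint"` or `"devil"`.
#' @param count how many control nodes.
#' @param mode `"random"` or `"top_degree"`.
#' @param leaders leader node ids, never eligible as controls.
#' @param seed integer seed (used by random placement).
#' @return a [control_assignment()].
#' @export
place_controls <- function(net, role = c("saint", "devil"), count,
                           mode = c("random", "top_degree"),
                           leaders = integer(), seed = 1L) {
  role <- match.arg(role)
  mode <- match.arg(mode)
  if (!is_count(count)) rn_config_error("count must be a nonnegative integer")
  leaders <- as.integer(leaders)
  eligible <- setdiff(seq_len(net$N) - 1L, leaders)
  if (count > length(eligible)) {
    rn_config_error(sprintf("cannot place %d controls among %d non-leader nodes",
                            count, length(eligible)))
  }
  chosen <- if (count == 0L) {
    integer()
  } else if (mode == "top_degree") {
    top_degree_nodes(net, count, exclude = leaders)
  } else {
    withr::with_seed(as.integer(seed),
                     eligible[sample.int(length(eligible), count)])
  }
  if (role == "saint") {
    control_assignment(saints = chosen, placement_mode = mode)
  } else {
    control_assignment(devils = chosen, placement_mode = mode)
  }
}

#' Re-draw regular strategies under an attitude bias
#'
#' Replaces every regular agent's strategy with a fresh draw from
#' `Uniform[0, alpha]`, modelling a population-level shift in tolerance of
#' the risky behaviour. Leader and control strategies are untouched. The
#' bias applies at initialization only; learning may later carry strategies
#' above `alpha` (by copying, so never above the largest initial leader
#' strategy).
#'
#' @param pop an `agent_population`.
#' @param alpha bias bound in `(0, 1]`.
#' @return the modified `agent_population`.
#' @export
alpha_bound_strategies <- function(pop, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    rn_config_error("alpha must lie in (0, 1]")
  }
  reg <- which(pop$role == "regular")
  pop$strategy[reg] <- stats::runif(length(reg), 0, alpha)
  pop
}
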