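# Friendship networks: generation, IO, and degree characterization.
#
# A social_network is an undirected, simple, connected graph whose nodes are
# labelled 0..N-1. It wraps an igraph object (internal vertex i corresponds
# to node id i-1) plus a precomputed adjacency list used by the simulator.

new_social_network <- function(graph, labels = NULL) {
  N <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  structure(
    list(
      graph = graph,
      N = N,
      adj = adj,                                   # internal 1-based
      labels = labels %||% as.character(seq_len(N) - 1L)
    ),
    class = "social_network"
  )
}

validate_network_graph <- function(g, where = "network") {
  if (igraph::is_directed(g)) {
    rn_format_error(sprintf("%s is directed; only undirected networks are supported", where))
  }
  if (any(igraph::which_loop(g))) {
    rn_format_error(sprintf("%s contains self-loops", where))
  }
  if (any(igraph::which_multiple(g))) {
    rn_format_error(sprintf("%s contains parallel edges", where))
  }
  if (igraph::vcount(g) < 3L) {
    rn_format_error(sprintf("%s has fewer than 3 nodes", where))
  }
  if (!igraph::is_connected(g)) {
    rn_format_error(sprintf("%s is not connected (recruitment distances would be undefined)", where))
  }
  invisible(g)
}

#' Build a social network from an igraph object
#'
#' Nodes are relabelled to the contiguous ids `0..N-1` (in the order of the
#' igraph vertices); original vertex names, if any, are preserved as labels.
#'
#' @param g an undirected, simple, connected igraph object with at least 3
#'   vertices.
#' @return a `social_network`.
#' @export
as_social_network <- function(g) {
  validate_network_graph(g)
  labels <- igraph::vertex_attr(g, "name")
  if (!is.null(labels)) labels <- as.character(labels)
  new_social_network(delete_attr_safe(g, "name"), labels)
}

# delete_vertex_attr errors when the attribute is absent; wrap it.
#' @noRd
delete_attr_safe <- function(g, attr) {
  if (attr %in% igraph::vertex_attr_names(g)) igraph::delete_vertex_attr(g, attr) else g
}

#' Generate a connected Watts-Strogatz friendship network
#'
#' Starts from a ring lattice in which every node is tied to its
#' `neighbors` nearest neighbours and rewires each edge with probability
#' `rewire_rate`. Rewiring preserves the edge count (`N * neighbors / 2`).
#' Because recruitment relies on finite social distances, the graph is
#' required to be connected: if a rewiring draw disconnects it, the
#' generator retries with a deterministically advanced seed, up to
#' `max_retries` times. The same `(N, neighbors, rewire_rate, seed)` always
#' produces the identical graph.
#'
#' @param N number of nodes (`N > neighbors`).
#' @param neighbors even number of lattice neighbours per node.
#' @param rewire_rate per-edge rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @param max_retries connectivity retry budget.
#' @return a `social_network`.
#' @export
#' @examples
#' net <- generate_ws_network(91, 6, 0.75, seed = 1)
#' net$N
generate_ws_network <- function(N, neighbors, rewire_rate, seed, max_retries = 100L) {
  if (!is_count(N, 3L) || !is_count(neighbors, 2L) || N <= neighbors) {
    rn_param_error("need integer N > neighbors >= 2")
  }
  if (neighbors %% 2L != 0L) {
    rn_param_error("neighbors must be even (ring lattice symmetry)")
  }
  if (!is.numeric(rewire_rate) || length(rewire_rate) != 1L ||
      is.na(rewire_rate) || rewire_rate < 0 || rewire_rate > 1) {
    rn_param_error("rewire_rate must be a probability in [0, 1]")
  }
  if (!is_count(seed)) rn_param_error("seed must be a single integer")

  for (attempt in seq_len(max_retries)) {
    s <- if (attempt == 1L) as.integer(seed) else derive_seed(seed, attempt)
    g <- withr::with_seed(s, igraph::sample_smallworld(
      dim = 1, size = N, nei = neighbors / 2L, p = rewire_rate,
      loops = FALSE, multiple = FALSE
    ))
    if (igraph::is_connected(g)) {
      net <- new_social_network(igraph::as_undirected(g))
      attr(net, "ws_params") <- list(N = N, neighbors = neighbors,
                                     rewire_rate = rewire_rate, seed = seed)
      return(net)
    }
  }
  rn_gen_error(sprintf(
    "could not generate a connected Watts-Strogatz graph in %d attempts (N=%d, neighbors=%d, p=%g)",
    max_retries, N, neighbors, rewire_rate
  ))
}

check_node <- function(net, node) {
  if (length(node) != 1L || is.na(node) || node != floor(node) ||
      node < 0L || node >= net$N) {
    rn_lookup_error(sprintf("node %s is not in the network (ids are 0..%d)",
                            toString(node), net$N - 1L))
  }
  as.integer(node)
}

#' Nodes within a social distance of a focal node
#'
#' Returns all nodes at shortest-path distance between 1 and `r` hops of
#' `node`, excluding `node` itself. This is the recruitment pool from which
#' a leader draws raid-nucleus invitees.
#'
#' @param net a `social_network`.
#' @param node node id (0-based).
#' @param r hop radius, `r >= 1`; `Inf` means the whole component.
#' @return sorted integer vector of node ids.
#' @export
neighborhood <- function(net, node, r) {
  node <- check_node(net, node)
  if (length(r) != 1L || is.na(r) || r < 1) rn_param_error("radius r must be >= 1")
  order <- if (is.infinite(r)) net$N else as.integer(r)
  out <- igraph::ego(net$graph, order = order, nodes = node + 1L, mindist = 1L)[[1L]]
  sort(as.integer(out) - 1L)
}

#' Highest-degree nodes, deterministically ordered
#'
#' The `k` highest-degree nodes not in `exclude`, with ties broken by
#' ascending node id so that top-degree placement is reproducible.
#'
#' @param net a `social_network`.
#' @param k how many nodes.
#' @param exclude node ids never selected (e.g. leaders).
#' @return integer vector of `k` node ids, highest degree first.
#' @export
top_degree_nodes <- function(net, k, exclude = integer()) {
  if (!is_count(k, 0L)) rn_param_error("k must be a nonnegative integer")
  candidates <- setdiff(seq_len(net$N) - 1L, as.integer(exclude))
  if (k > length(candidates)) {
    rn_param_error(sprintf("k = %d exceeds the %d available nodes", k, length(candidates)))
  }
  deg <- igraph::degree(net$graph)[candidates + 1L]
  candidates[order(-deg, candidates)][seq_len(k)]
}

#' Per-node degrees and their empirical CDF
#'
#' @param net a `social_network`.
#' @return list with `degrees` (per node, in id order) and
#'   `cumulative_frequency`, a data frame of distinct degree values and the
#'   empirical cumulative frequency at each.
#' @export
degree_summary <- function(net) {
  deg <- as.integer(igraph::degree(net$graph))
  vals <- sort(unique(deg))
  list(
    degrees = deg,
    cumulative_frequency = data.frame(
      degree = vals,
      cum_freq = stats::ecdf(deg)(vals)
    )
  )
}

#' Two-sample Kolmogorov-Smirnov comparison of degree distributions
#'
#' Compares the degree multisets of two networks with the asymptotic
#' two-sample KS test (degree ties are expected; the asymptotic p-value is
#' used deliberately).
#'
#' @param net_a,net_b `social_network` objects.
#' @return list with `statistic` (max ECDF gap) and `p_value`.
#' @export
ks_degree_comparison <- function(net_a, net_b) {
  da <- as.numeric(igraph::degree(net_a$graph))
  db <- as.numeric(igraph::degree(net_b$graph))
  kt <- suppressWarnings(stats::ks.test(da, db, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network> %d nodes, %d edges\n",
              x$N, igraph::gsize(x$graph)))
  invisible(x)
}

#' Edge set of a network as a two-column matrix of 0-based node ids
#'
#' Each row is an unordered pair written `(min, max)`; rows are sorted, so
#' two networks have equal edge sets iff their matrices are identical.
#'
#' @param net a `social_network`.
#' @return integer matrix with columns `from`, `to`.
#' @export
network_edges <- function(net) {
  e <- igraph::as_edgelist(net$graph, names = FALSE) - 1L
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  storage.mode(e) <- "integer"
  colnames(e) <- c("from", "to")
  e
}

parse_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(stripped)))
  if (length(keep) == 0L) rn_format_error(sprintf("'%s': no edges found", path))
  from <- integer(length(keep)); to <- integer(length(keep))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(keep)) {
    ln <- keep[i]
    toks <- strsplit(trimws(stripped[ln]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.integer(toks))
    if (length(toks) != 2L || anyNA(vals)) {
      rn_format_error(sprintf(
        "'%s' line %d: expected two whitespace-separated integers, got '%s'",
        path, ln, trimws(lines[ln])))
    }
    if (vals[1L] == vals[2L]) {
      rn_format_error(sprintf("'%s' line %d: self-loop '%d %d'", path, ln, vals[1L], vals[2L]))
    }
    key <- paste(min(vals), max(vals))
    if (!is.null(seen[[key]])) {
      rn_format_error(sprintf("'%s' line %d: duplicate edge '%s' (first seen on line %d)",
                              path, ln, key, seen[[key]]))
    }
    seen[[key]] <- ln
    from[i] <- vals[1L]; to[i] <- vals[2L]
  }
  list(from = from, to = to)
}

#' Load a network from disk
#'
#' Supported formats: two-column whitespace-separated integer edge lists
#' (`#` comments allowed), GraphML, and GML. Input must describe an
#' undirected, simple, connected graph; arbitrary node labels are remapped
#' to contiguous 0-based ids (ascending label order for edge lists) and the
#' original labels are kept in `$labels`.
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"graphml"`, `"gml"`.
#' @return a `social_network`.
#' @export
load_network <- function(path, format = c("edgelist", "graphml", "gml")) {
  format <- match.arg(format)
  if (!file.exists(path)) rn_format_error(sprintf("file '%s' does not exist", path))
  if (format == "edgelist") {
    el <- parse_edgelist(path)
    labels <- sort(unique(c(el$from, el$to)))
    from <- match(el$from, labels); to <- match(el$to, labels)
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    net <- tryCatch(
      { validate_network_graph(g, sprintf("'%s'", path)); new_social_network(g, as.character(labels)) },
      error = function(e) rn_format_error(conditionMessage(e))
    )
    return(net)
  }
  g <- tryCatch(
    igraph::read_graph(path, format = format),
    error = function(e) rn_format_error(sprintf("'%s': %s parse failure: %s",
                                                path, format, conditionMessage(e)))
  )
  if (igraph::is_directed(g)) {
    rn_format_error(sprintf("'%s' declares a directed graph; only undirected networks are accepted", path))
  }
  validate_network_graph(g, sprintf("'%s'", path))
  labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) labels <- igraph::vertex_attr(g, "id")
  g <- delete_attr_safe(delete_attr_safe(g, "name"), "id")
  new_social_network(g, if (is.null(labels)) NULL else as.character(labels))
}

#' Save a network to disk
#'
#' Writes the canonical 0-based node ids so that `load_network(save_network(net))`
#' reproduces the identical edge set.
#'
#' @param net a `social_network`.
#' @param path destination file.
#' @param format one of `"edgelist"`, `"graphml"`, `"gml"`.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, format = c("edgelist", "graphml", "gml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    e <- network_edges(net)
    writeLines(c("# raidnet edge list: node_id node_id",
                 sprintf("%d %d", e[, 1L], e[, 2L])), path)
  } else {
    g <- igraph::set_vertex_attr(net$graph, "name", value = as.character(seq_len(net$N) - 1L))
    for (a in igraph::graph_attr_names(g)) g <- igraph::delete_graph_attr(g, a)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Read / write node-role annotations
#'
#' Roles (leader, saint, devil) are persisted separately from the network as
#' a two-column CSV `node_id,role`, keeping network files standard-format
#' clean. Nodes absent from the file are regular.
#'
#' @param path CSV path.
#' @return `read_roles`: data frame with integer `node_id` and character
#'   `role`.
#' @export
read_roles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "role") %in% names(df))) {
    rn_format_error(sprintf("'%s': role CSV needs columns node_id, role", path))
  }
  bad <- setdiff(unique(df$role), c("leader", "saint", "devil"))
  if (length(bad) > 0L) {
    rn_format_error(sprintf("'%s': unknown role(s): %s", path, toString(bad)))
  }
  df$node_id <- as.integer(df$node_id)
  df[order(df$node_id), c("node_id", "role")]
}

#' @rdname read_roles
#' @param leaders,saints,devils node id vectors.
#' @export
write_roles <- function(path, leaders = integer(), saints = integer(), devils = integer()) {
  df <- data.frame(
    node_id = as.integer(c(leaders, saints, devils)),
    role = rep(c("leader", "saint", "devil"),
               times = c(length(leaders), length(saints), length(devils))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$node_id)) rn_config_error("a node cannot hold two roles")
  utils::write.csv(df[order(df$node_id), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
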