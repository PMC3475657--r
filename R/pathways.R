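#' Classify states as flux producers, collectors or pass-through
#'
#' Over a relaxation, a producer loses occupancy (it sources net flux), a
#' collector gains occupancy (it absorbs net flux), and pass-through
#' states change by less than `threshold`. Because total probability is
#' conserved, the amount produced equals the amount collected up to the
#' occupancy parked in pass-through states. After a saturating jump from
#' the ligand-free equilibrium the only producers are `C0` and `O0`, since
#' no other state holds probability to lose.
#'
#' @param totals Single-segment `flux_totals` from [total_net_flux()], or
#'   an `occupancy_trajectory` (only the endpoint occupancies are used).
#' @param traj The `occupancy_trajectory` of the segment.
#' @param threshold Minimum absolute occupancy change `|delta_P|` for a
#'   state to count as producer/collector (default `1e-4`).
#' @return A `state_classification` tibble with columns `state`,
#'   `delta_P`, `role` (`"producer"`, `"collector"`, `"passthrough"`);
#'   totals produced/collected are attached as attributes.
#' @export
classify_states <- function(totals, traj, threshold = 1e-4) {
  stopifnot(inherits(traj, "occupancy_trajectory"))
  labels <- attr(traj, "state_labels")
  t_end <- if (inherits(totals, "flux_totals")) attr(totals, "t_end") else traj$t[nrow(traj)]
  P <- as.matrix(traj[, labels])
  i_end <- which.min(abs(traj$t - t_end))
  delta <- P[i_end, ] - P[1, ]
  role <- ifelse(delta < -threshold, "producer",
                 ifelse(delta > threshold, "collector", "passthrough"))
  out <- tibble(state = labels, delta_P = unname(delta), role = unname(role))
  produced <- -sum(delta[role == "producer"])
  collected <- sum(delta[role == "collector"])
  structure(out,
            produced = produced, collected = collected,
            imbalance = produced - collected,
            class = c("state_classification", class(tibble())))
}

#' Build the directed graph of integrated net fluxes
#'
#' Each transition with non-zero total net flux becomes one directed edge,
#' oriented along the sign of `F_total` and weighted by its magnitude.
#' For a detailed-balance model the resulting graph is acyclic; directed
#' cycles can only arise from numerical noise and are cancelled by
#' subtracting the cycle's bottleneck weight around it. A cycle whose
#' bottleneck exceeds `cycle_tol` times the largest edge weight signals a
#' genuine violation of the reversibility premise and raises an error.
#'
#' @param totals Single-segment `flux_totals` from [total_net_flux()].
#' @param producers,collectors Character vectors of source and sink state
#'   labels, e.g. from [classify_states()]; used as declared roles.
#'   Independently, every node's exact divergence (inflow minus outflow
#'   of integrated flux, i.e. its occupancy change) is stored so that the
#'   decomposition can respect how much each producer can supply and each
#'   collector absorb.
#' @param cycle_tol Relative bottleneck above which a cycle is an error.
#' @return A `flux_graph`: list with `nodes` (tibble `node`,
#'   `divergence`), `edges` (tibble `from`, `to`, `weight`), `sources`,
#'   `sinks`, `cancelled_cycles`.
#' @export
build_flux_graph <- function(totals, producers, collectors, cycle_tol = 1e-3) {
  stopifnot(inherits(totals, "flux_totals"))
  edges_def <- attr(totals, "edges")
  ed <- tibble(
    from = ifelse(totals$F_total >= 0, edges_def$from, edges_def$to),
    to = ifelse(totals$F_total >= 0, edges_def$to, edges_def$from),
    weight = abs(totals$F_total)
  )
  ed <- ed[ed$weight > 0, ]
  node_names <- sort(unique(c(ed$from, ed$to, producers, collectors)))
  cc <- cancel_cycles(ed, cycle_tol)
  ed <- cc$edges
  cancelled <- cc$cancelled
  div <- vapply(node_names, function(s) {
    sum(ed$weight[ed$to == s]) - sum(ed$weight[ed$from == s])
  }, numeric(1))
  structure(
    list(nodes = tibble(node = node_names, divergence = unname(div)),
         edges = ed,
         sources = intersect(node_names, producers),
         sinks = intersect(node_names, collectors),
         cancelled_cycles = cancelled),
    class = "flux_graph"
  )
}

#' @rdname build_flux_graph
#' @param edges Tibble with columns `from`, `to`, `weight` (all
#'   `weight > 0`) describing an already-oriented flux graph, e.g. a
#'   synthetic benchmark network.
#' @export
flux_graph <- function(edges, producers = NULL, collectors = NULL,
                       cycle_tol = 1e-3) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  ed <- as_tibble(edges)[, c("from", "to", "weight")]
  if (any(ed$weight <= 0)) abort("All edge weights must be > 0.")
  cc <- cancel_cycles(ed, cycle_tol)
  ed <- cc$edges
  node_names <- sort(unique(c(ed$from, ed$to)))
  div <- vapply(node_names, function(s) {
    sum(ed$weight[ed$to == s]) - sum(ed$weight[ed$from == s])
  }, numeric(1))
  structure(
    list(nodes = tibble(node = node_names, divergence = unname(div)),
         edges = ed,
         sources = producers %||% node_names[div < 0],
         sinks = collectors %||% node_names[div > 0],
         cancelled_cycles = cc$cancelled),
    class = "flux_graph"
  )
}

# Cancel residual directed cycles by subtracting each cycle's bottleneck
# weight around it; a cycle with substantial flux (relative to the
# largest edge) is an error, since the time-integrated flux graph of a
# reversible detailed-balance relaxation is acyclic.
cancel_cycles <- function(ed, cycle_tol) {
  max_w <- if (nrow(ed) > 0) max(ed$weight) else 0
  cancelled <- 0L
  repeat {
    cyc <- find_directed_cycle(ed)
    if (is.null(cyc)) break
    idx <- match(paste(cyc$from, cyc$to), paste(ed$from, ed$to))
    bottleneck <- min(ed$weight[idx])
    if (bottleneck > cycle_tol * max_w) {
      abort(sprintf(
        "Directed cycle %s carries bottleneck flux %.3g (> %.1g of max edge weight): the flux graph of a detailed-balance relaxation must be acyclic.",
        paste(c(cyc$from, cyc$to[length(cyc$to)]), collapse = " -> "),
        bottleneck, cycle_tol))
    }
    warn(sprintf("Cancelling numerical-noise cycle %s (bottleneck %.3g).",
                 paste(c(cyc$from, cyc$to[length(cyc$to)]), collapse = " -> "),
                 bottleneck))
    ed$weight[idx] <- ed$weight[idx] - bottleneck
    ed <- ed[ed$weight > 0, ]
    cancelled <- cancelled + 1L
  }
  list(edges = ed, cancelled = cancelled)
}

# Depth-first search for any directed cycle; returns the edge list of one
# cycle (tibble from,to) or NULL if the graph is acyclic.
find_directed_cycle <- function(ed) {
  if (nrow(ed) == 0) return(NULL)
  nodes <- unique(c(ed$from, ed$to))
  adj <- split(seq_len(nrow(ed)), factor(ed$from, levels = nodes))
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 on stack, 2 done
  parent_edge <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cycle <- NULL
  visit <- function(u) {
    color[u] <<- 1L
    for (j in adj[[u]]) {
      v <- ed$to[j]
      if (color[v] == 0L) {
        parent_edge[v] <<- j
        visit(v)
        if (!is.null(cycle)) return()
      } else if (color[v] == 1L) {
        # walk back from u to v along parent edges
        path <- j
        w <- u
        while (w != v) {
          path <- c(parent_edge[w], path)
          w <- ed$from[parent_edge[w]]
        }
        cycle <<- ed[path, c("from", "to")]
        return()
      }
    }
    color[u] <<- 2L
  }
  for (s in nodes) {
    if (color[s] == 0L) visit(s)
    if (!is.null(cycle)) return(cycle)
  }
  NULL
}

topological_order <- function(nodes, ed) {
  indeg <- setNames(rep(0L, length(nodes)), nodes)
  tab <- table(ed$to)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- sort(names(indeg)[indeg == 0L])
  ed2 <- ed
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    order <- c(order, u)
    out <- ed2$to[ed2$from == u]
    ed2 <- ed2[ed2$from != u, ]
    for (v in out) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- sort(c(queue, v))
    }
  }
  if (length(order) != length(nodes)) abort("Graph is not acyclic.")
  order
}

#' Decompose a flux graph into ranked pathway fluxes
#'
#' Iteratively extracts the strongest remaining pathway from a producer to
#' a collector: the path maximizing the minimum available flux along it
#' (the widest / maximum-bottleneck path). The pathway is assigned its
#' bottleneck weight, that weight is removed from every edge of the path,
#' exhausted edges are dropped, and the procedure repeats until no
#' producer-to-collector path with bottleneck above `tol` remains.
#' Extracted bottlenecks are non-increasing with rank.
#'
#' So that the decomposition is complete, the bottleneck of a path also
#' accounts for how much flux its endpoints can still supply or absorb:
#' internally the graph is augmented with a virtual super-source feeding
#' every node of negative divergence with capacity equal to that
#' divergence, and a virtual super-sink draining every node of positive
#' divergence. On a conserved flux graph the per-edge sums of pathway
#' weights then reproduce the original edge weights to round-off. Like
#' any flow decomposition the individual pathway weights depend on the
#' extraction order; ties in bottleneck width are broken
#' deterministically (fewer edges first, then lexicographically smallest
#' state sequence).
#'
#' @param graph A `flux_graph` (must be acyclic).
#' @param tol Absolute bottleneck below which extraction stops.
#' @return A `pathway_decomposition`: list with `pathways` (tibble `rank`,
#'   `path` string `"X0>X1>...>Xk"`, `steps` list-column, `weight`),
#'   `residual` (max leftover edge weight), `total_decomposed`, and
#'   `edge_accounting` (tibble `from`, `to`, `original`, `decomposed`,
#'   `leftover`).
#' @export
decompose_pathways <- function(graph, tol = 1e-12) {
  stopifnot(inherits(graph, "flux_graph"))
  if (!is.null(find_directed_cycle(graph$edges))) {
    abort("`graph` contains a directed cycle; decompose_pathways needs an acyclic flux graph.")
  }
  original <- graph$edges
  SRC <- ".SRC."
  SNK <- ".SNK."
  div <- graph$nodes
  virt <- bind_rows(
    tibble(from = SRC, to = div$node[div$divergence < 0],
           weight = -div$divergence[div$divergence < 0]),
    tibble(from = div$node[div$divergence > 0], to = SNK,
           weight = div$divergence[div$divergence > 0])
  )
  ed <- bind_rows(original, virt)
  paths <- list()
  weights <- numeric(0)
  repeat {
    best <- widest_path(ed, SRC, SNK)
    if (is.null(best) || best$bottleneck < tol) break
    idx <- match(paste(best$path[-length(best$path)], best$path[-1]),
                 paste(ed$from, ed$to))
    ed$weight[idx] <- ed$weight[idx] - best$bottleneck
    ed <- ed[ed$weight > 0, ]
    real <- best$path[-c(1L, length(best$path))]
    paths <- c(paths, list(real))
    weights <- c(weights, best$bottleneck)
  }
  ed <- ed[ed$from != SRC & ed$to != SNK, ]
  acc <- original
  decomposed <- rep(0, nrow(acc))
  for (i in seq_along(paths)) {
    if (length(paths[[i]]) < 2) next
    idx <- match(paste(paths[[i]][-length(paths[[i]])], paths[[i]][-1]),
                 paste(acc$from, acc$to))
    decomposed[idx] <- decomposed[idx] + weights[i]
  }
  structure(
    list(
      pathways = tibble(
        rank = seq_along(paths),
        path = map_chr(paths, paste, collapse = ">"),
        steps = paths,
        weight = weights
      ),
      residual = if (nrow(ed) > 0) max(ed$weight) else 0,
      total_decomposed = sum(weights),
      edge_accounting = tibble(from = acc$from, to = acc$to,
                               original = acc$weight, decomposed = decomposed,
                               leftover = acc$weight - decomposed)
    ),
    class = "pathway_decomposition"
  )
}

# Widest (maximum-bottleneck) path from `source` to `sink` on a DAG.
# Ties among equally wide paths are broken globally: fewest edges first,
# then the lexicographically smallest node sequence. The bottleneck value
# is found by max-min dynamic programming in topological order; the
# tie-broken path is then the lexicographically smallest shortest path in
# the subgraph of edges at least that wide.
widest_path <- function(ed, source, sink) {
  if (nrow(ed) == 0) return(NULL)
  nodes <- unique(c(ed$from, ed$to, source, sink))
  topo <- topological_order(nodes, ed)
  b <- setNames(rep(-Inf, length(nodes)), nodes)
  b[source] <- Inf
  for (u in topo) {
    if (b[u] == -Inf) next
    js <- which(ed$from == u)
    for (j in js) {
      v <- ed$to[j]
      w <- min(b[u], ed$weight[j])
      if (w > b[v]) b[v] <- w
    }
  }
  bstar <- b[sink]
  if (!is.finite(bstar) || bstar <= 0) return(NULL)
  sub <- ed[ed$weight >= bstar, ]
  # BFS distances to the sink over the thresholded subgraph
  dist <- setNames(rep(NA_integer_, length(nodes)), nodes)
  dist[sink] <- 0L
  frontier <- sink
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    prev <- unique(sub$from[sub$to %in% frontier])
    frontier <- prev[is.na(dist[prev])]
    dist[frontier] <- d
  }
  if (is.na(dist[source])) return(NULL)
  # greedy reconstruction of the lexicographically smallest shortest path
  path <- source
  u <- source
  while (u != sink) {
    nxt <- sub$to[sub$from == u]
    nxt <- nxt[!is.na(dist[nxt]) & dist[nxt] == dist[u] - 1L]
    u <- sort(nxt)[1]
    path <- c(path, u)
  }
  list(path = path, bottleneck = unname(bstar))
}

#' @export
print.pathway_decomposition <- function(x, ...) {
  cat(sprintf("<pathway_decomposition> %d pathway(s), total flux %.4g, residual %.3g\n",
              nrow(x$pathways), x$total_decomposed, x$residual))
  print(x$pathways[, c("rank", "path", "weight")], n = nrow(x$pathways))
  invisible(x)
}

#' Tidy a pathway decomposition into its ranked pathway table
#' @param x A `pathway_decomposition`.
#' @param ... Unused.
#' @export
tidy.pathway_decomposition <- function(x, ...) {
  x$pathways[, c("rank", "path", "weight")]
}

#' One-row summary of a pathway decomposition
#' @param x A `pathway_decomposition`.
#' @param ... Unused.
#' @export
glance.pathway_decomposition <- function(x, ...) {
  tibble(n_pathways = nrow(x$pathways),
         total_decomposed = x$total_decomposed,
         residual = x$residual,
         max_weight = if (nrow(x$pathways) > 0) max(x$pathways$weight) else 0)
}

#' Compare activation and deactivation pathways crossing the closed-open edges
#'
#' Gating hysteresis shows up as activation and deactivation pathways
#' crossing different closed-open isomerizations. For each isomerization
#' edge the summed pathway weight crossing it (in either direction) is
#' tabulated for both decompositions; the hysteresis index is the total
#' variation distance between the two normalized crossing distributions -
#' 0 for identical usage, 1 for disjoint sets of isomerization edges.
#'
#' @param activation,deactivation `pathway_decomposition` objects for the
#'   two relaxations.
#' @param model The `ladder_model` (identifies the isomerization edges).
#' @return A `hysteresis_report`: list with `table` (tibble `edge`,
#'   `activation_weight`, `deactivation_weight`) and `index` in `[0, 1]`.
#' @export
hysteresis_report <- function(activation, deactivation, model) {
  stopifnot(inherits(activation, "pathway_decomposition"),
            inherits(deactivation, "pathway_decomposition"),
            inherits(model, "ladder_model"))
  iso <- model$transitions[model$transitions$kind == "isomerization", ]
  crossing <- function(dec) {
    w <- setNames(rep(0, nrow(iso)), iso$edge)
    for (i in seq_len(nrow(dec$pathways))) {
      steps <- dec$pathways$steps[[i]]
      if (length(steps) < 2) next
      a <- steps[-length(steps)]
      b <- steps[-1]
      hit <- iso$edge[match(paste0(a, b), paste0(iso$from, iso$to))]
      hit2 <- iso$edge[match(paste0(b, a), paste0(iso$from, iso$to))]
      used <- unique(c(hit[!is.na(hit)], hit2[!is.na(hit2)]))
      w[used] <- w[used] + dec$pathways$weight[i]
    }
    w
  }
  wa <- crossing(activation)
  wd <- crossing(deactivation)
  pa <- if (sum(wa) > 0) wa / sum(wa) else wa
  pd <- if (sum(wd) > 0) wd / sum(wd) else wd
  structure(
    list(table = tibble(edge = iso$edge,
                        activation_weight = unname(wa),
                        deactivation_weight = unname(wd)),
         index = 0.5 * sum(abs(pa - pd))),
    class = "hysteresis_report"
  )
}

#' @export
print.hysteresis_report <- function(x, ...) {
  cat(sprintf("<hysteresis_report> index = %.3f\n", x$index))
  print(x$table, n = nrow(x$table))
  invisible(x)
}
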