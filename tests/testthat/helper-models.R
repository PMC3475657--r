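# Shared fixtures: all built in code, no stored data.

two_state <- function(k_open = 1, k_close = 2) {
  build_ladder_model(0, list(C0O0 = c(k_open, k_close)), name = "two-state")
}

p_vec <- function(traj, i = nrow(traj)) {
  labels <- attr(traj, "state_labels")
  as.numeric(traj[i, labels])
}

# Random conserved-flux DAG: superpose `n_paths` random forward paths on
# an ordered node set, so interior nodes conserve flux exactly and
# sources/sinks are the path endpoints.
random_conserved_dag <- function(seed, n_nodes = 8, n_paths = 6) {
  set.seed(seed)
  labels <- sprintf("N%02d", seq_len(n_nodes))
  acc <- new.env()
  for (i in seq_len(n_paths)) {
    len <- sample(2:n_nodes, 1)
    nodes <- labels[sort(sample(n_nodes, len))]
    w <- runif(1, 0.1, 1)
    for (j in seq_len(len - 1)) {
      key <- paste(nodes[j], nodes[j + 1], sep = "|")
      acc[[key]] <- (acc[[key]] %||% 0) + w
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  tibble::tibble(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    weight = vapply(keys, function(k) acc[[k]], numeric(1), USE.NAMES = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive enumeration of simple paths between two nodes of a DAG.
enumerate_paths <- function(ed, from, to) {
  out <- list()
  recur <- function(node, path) {
    if (node == to) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (v in ed$to[ed$from == node]) recur(v, c(path, v))
  }
  recur(from, from)
  out
}

# Independent oracle for the flow decomposition: augment with virtual
# source/sink capacities, then greedily replay extraction using full path
# enumeration instead of dynamic programming. `order` picks the widest
# path (same tie-breaks as the package) or the lexicographically smallest
# path (a different, equally valid extraction order).
enumerate_decompose <- function(edges, order = c("widest", "lex"), tol = 1e-12) {
  order <- match.arg(order)
  nodes <- sort(unique(c(edges$from, edges$to)))
  div <- vapply(nodes, function(s) {
    sum(edges$weight[edges$to == s]) - sum(edges$weight[edges$from == s])
  }, numeric(1))
  ed <- rbind(
    edges,
    tibble::tibble(from = ".A.", to = nodes[div < 0], weight = -div[div < 0]),
    tibble::tibble(from = nodes[div > 0], to = ".Z.", weight = div[div > 0])
  )
  paths <- list(); weights <- numeric(0)
  repeat {
    all_paths <- enumerate_paths(ed, ".A.", ".Z.")
    if (length(all_paths) == 0) break
    bn <- vapply(all_paths, function(p) {
      idx <- match(paste(p[-length(p)], p[-1]), paste(ed$from, ed$to))
      min(ed$weight[idx])
    }, numeric(1))
    keep <- bn >= tol
    if (!any(keep)) break
    all_paths <- all_paths[keep]; bn <- bn[keep]
    if (order == "widest") {
      len <- lengths(all_paths)
      key <- vapply(all_paths, paste, "", collapse = ">")
      ord <- order(-bn, len, key)
    } else {
      key <- vapply(all_paths, paste, "", collapse = ">")
      ord <- order(key)
    }
    p <- all_paths[[ord[1]]]; w <- bn[ord[1]]
    idx <- match(paste(p[-length(p)], p[-1]), paste(ed$from, ed$to))
    ed$weight[idx] <- ed$weight[idx] - w
    ed <- ed[ed$weight > 0, ]
    paths <- c(paths, list(p[-c(1, length(p))]))
    weights <- c(weights, w)
  }
  list(paths = paths, weights = weights)
}

# Per-edge sums of pathway weights, for completeness checks.
edge_sums <- function(paths, weights, edges) {
  s <- setNames(rep(0, nrow(edges)), paste(edges$from, edges$to))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (length(p) < 2) next
    k <- paste(p[-length(p)], p[-1])
    s[k] <- s[k] + weights[i]
  }
  unname(s)
}

# High-accuracy ODE oracle for the master equation.
ode_occupancies <- function(model, p0, L, times) {
  Q <- rate_matrix(model, L)
  sol <- deSolve::lsoda(
    y = p0, times = times,
    func = function(t, y, parms) list(as.numeric(Q %*% y)),
    rtol = 1e-10, atol = 1e-12
  )
  unname(sol[, -1, drop = FALSE])
}
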