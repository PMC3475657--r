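#' Ladder models of ligand-gated channel gating
#'
#' A ladder model has `n_steps + 1` closed states `C0..Cn` and the same
#' number of open states `O0..On`, where the index counts bound ligands.
#' Ligand binding proceeds along each row (closed and open), and every
#' liganding level has its own closed-open isomerization, giving
#' `3 * n_steps + 1` reversible transitions. The ten-state, thirteen-edge
#' instance with `n_steps = 4` is the C4L-O4L scheme used to describe
#' cAMP-dependent gating of homotetrameric HCN2 channels.
#'
#' Rate constants are stored at unit ligand concentration: association rate
#' constants of binding edges are in 1/(uM s) and are multiplied by the
#' actual concentration only when a rate matrix is assembled; all other
#' rates are in 1/s. The forward direction of every edge is binding or
#' opening, so positive fluxes later mean "towards more ligands / open".
#'
#' Every square cycle `C(x-1) - Cx - Ox - O(x-1)` of a physically sensible
#' model satisfies detailed balance: the product of rate constants
#' clockwise equals the product counter-clockwise. The constructor rejects
#' models whose relative cycle residual exceeds `balance_tol` (default
#' `1e-6`, generous enough for rate tables rounded to two significant
#' figures).
#'
#' @param n_steps Number of binding steps (`>= 0`); 4 for C4L-O4L.
#' @param rates Rate table: either a data frame with columns
#'   `edge`, `k_forward`, `k_backward`, or a named list mapping edge labels
#'   (e.g. `"C0C1"`, `"C1O1"`) to numeric `c(k_forward, k_backward)`.
#'   All `3 * n_steps + 1` edges must be present.
#' @param name Model name (free text).
#' @param balance_tol Maximum accepted relative detailed-balance residual.
#' @return A `ladder_model`: a list with elements `name`, `n_steps`,
#'   `states` (tibble: `label`, `conformation`, `n_ligands`) and
#'   `transitions` (tibble: `edge`, `from`, `to`, `k_forward`,
#'   `k_backward`, `ligand_dependent`, `kind`).
#' @examples
#' two_state <- build_ladder_model(0, list(C0O0 = c(1, 2)))
#' rate_matrix(two_state, L = 0)
#' @export
build_ladder_model <- function(n_steps, rates, name = sprintf("C%dL-O%dL", n_steps, n_steps),
                               balance_tol = 1e-6) {
  if (length(n_steps) != 1L || n_steps < 0 || n_steps != round(n_steps)) {
    abort("`n_steps` must be a single non-negative integer.")
  }
  n_steps <- as.integer(n_steps)
  skel <- ladder_skeleton(n_steps)
  rates <- normalize_rate_table(rates)

  missing <- setdiff(skel$transitions$edge, rates$edge)
  if (length(missing) > 0) {
    abort(sprintf("Rate table is missing transition(s): %s",
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(rates$edge, skel$transitions$edge)
  if (length(unknown) > 0) {
    abort(sprintf("Rate table contains edges not in a %d-step ladder: %s",
                  n_steps, paste(unknown, collapse = ", ")))
  }
  if (any(!is.finite(rates$k_forward)) || any(!is.finite(rates$k_backward)) ||
      any(rates$k_forward < 0) || any(rates$k_backward < 0)) {
    bad <- rates$edge[!is.finite(rates$k_forward) | !is.finite(rates$k_backward) |
                        rates$k_forward < 0 | rates$k_backward < 0]
    abort(sprintf("Negative or non-finite rate constant on edge(s): %s",
                  paste(bad, collapse = ", ")))
  }

  transitions <- skel$transitions |>
    left_join(rates, by = "edge") |>
    select("edge", "from", "to", "k_forward", "k_backward",
           "ligand_dependent", "kind")

  model <- structure(
    list(name = name, n_steps = n_steps, states = skel$states,
         transitions = transitions),
    class = "ladder_model"
  )

  res <- detailed_balance_residuals(model)
  if (nrow(res) > 0 && any(!(res$residual <= balance_tol))) {
    worst <- res[which.max(res$residual), ]
    abort(sprintf(
      "Detailed balance violated in cycle %s: relative residual %.3g exceeds tolerance %.1g.",
      worst$cycle, worst$residual, balance_tol))
  }
  model
}

# State and transition layout of an n-step ladder, without rates.
ladder_skeleton <- function(n_steps) {
  x <- 0:n_steps
  states <- tibble(
    label = c(paste0("C", x), paste0("O", x)),
    conformation = rep(c("closed", "open"), each = n_steps + 1L),
    n_ligands = c(x, x)
  )
  trans <- list()
  if (n_steps > 0) {
    xs <- seq_len(n_steps)
    trans$closed <- tibble(
      edge = paste0("C", xs - 1L, "C", xs),
      from = paste0("C", xs - 1L), to = paste0("C", xs),
      ligand_dependent = TRUE, kind = "binding_closed"
    )
    trans$open <- tibble(
      edge = paste0("O", xs - 1L, "O", xs),
      from = paste0("O", xs - 1L), to = paste0("O", xs),
      ligand_dependent = TRUE, kind = "binding_open"
    )
  }
  trans$iso <- tibble(
    edge = paste0("C", x, "O", x),
    from = paste0("C", x), to = paste0("O", x),
    ligand_dependent = FALSE, kind = "isomerization"
  )
  list(states = states, transitions = bind_rows(trans))
}

normalize_rate_table <- function(rates) {
  if (is.data.frame(rates)) {
    need <- c("edge", "k_forward", "k_backward")
    if (!all(need %in% names(rates))) {
      abort("A rate data frame needs columns `edge`, `k_forward`, `k_backward`.")
    }
    return(as_tibble(rates)[, need])
  }
  if (is.list(rates) && !is.null(names(rates))) {
    return(tibble(
      edge = names(rates),
      k_forward = unname(map_dbl(rates, ~ as.numeric(.x[[1]]))),
      k_backward = unname(map_dbl(rates, ~ as.numeric(.x[[2]])))
    ))
  }
  abort("`rates` must be a data frame or a named list of c(k_forward, k_backward).")
}

#' Detailed-balance residuals of a ladder model
#'
#' For each square cycle `C(x-1) - Cx - Ox - O(x-1)` the relative residual
#' `|product(clockwise) / product(counter-clockwise) - 1|` is reported.
#' Ligand-concentration factors cancel around a square (one binding step in
#' each direction), so residuals are concentration independent. A zero rate
#' in the denominator product yields an infinite residual rather than an
#' error. Models with `n_steps < 1` have no cycles and give an empty table.
#'
#' @param model A `ladder_model`.
#' @return A tibble with columns `cycle` (e.g. `"C0-C1-O1-O0"`) and
#'   `residual`.
#' @export
detailed_balance_residuals <- function(model) {
  stopifnot(inherits(model, "ladder_model"))
  n <- model$n_steps
  if (n < 1) {
    return(tibble(cycle = character(), residual = numeric()))
  }
  tr <- model$transitions
  kf <- setNames(tr$k_forward, tr$edge)
  kb <- setNames(tr$k_backward, tr$edge)
  xs <- seq_len(n)
  cycle <- sprintf("C%d-C%d-O%d-O%d", xs - 1L, xs, xs, xs - 1L)
  cw <- kf[sprintf("C%dC%d", xs - 1L, xs)] * kf[sprintf("C%dO%d", xs, xs)] *
    kb[sprintf("O%dO%d", xs - 1L, xs)] * kb[sprintf("C%dO%d", xs - 1L, xs - 1L)]
  ccw <- kf[sprintf("C%dO%d", xs - 1L, xs - 1L)] * kf[sprintf("O%dO%d", xs - 1L, xs)] *
    kb[sprintf("C%dO%d", xs, xs)] * kb[sprintf("C%dC%d", xs - 1L, xs)]
  residual <- ifelse(cw == 0 & ccw == 0, 0,
                     ifelse(ccw == 0, Inf, abs(cw / ccw - 1)))
  tibble(cycle = cycle, residual = unname(residual))
}

#' Generator (rate) matrix of a ladder model at a given ligand concentration
#'
#' Assembles the column generator `Q` of the master equation
#' `dP/dt = Q %*% P`: the off-diagonal entry `Q[Y, X]` is the rate constant
#' of the transition `X -> Y` (association rates multiplied by `L`), and
#' each column sums to zero.
#'
#' @param model A `ladder_model`.
#' @param L Ligand concentration in uM (`>= 0`).
#' @return A square numeric matrix with state labels as dimnames, units 1/s.
#' @export
rate_matrix <- function(model, L) {
  stopifnot(inherits(model, "ladder_model"))
  if (length(L) != 1L || !is.finite(L) || L < 0) {
    abort("`L` must be a single finite concentration >= 0 (uM).")
  }
  labels <- model$states$label
  ns <- length(labels)
  Q <- matrix(0, ns, ns, dimnames = list(labels, labels))
  tr <- model$transitions
  i_from <- match(tr$from, labels)
  i_to <- match(tr$to, labels)
  kf <- tr$k_forward * ifelse(tr$ligand_dependent, L, 1)
  kb <- tr$k_backward
  for (j in seq_len(nrow(tr))) {
    Q[i_to[j], i_from[j]] <- Q[i_to[j], i_from[j]] + kf[j]
    Q[i_from[j], i_to[j]] <- Q[i_from[j], i_to[j]] + kb[j]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' @export
print.ladder_model <- function(x, ...) {
  cat(sprintf("<ladder_model> %s: %d binding steps, %d states, %d transitions\n",
              x$name, x$n_steps, nrow(x$states), nrow(x$transitions)))
  res <- detailed_balance_residuals(x)
  if (nrow(res) > 0) {
    cat(sprintf("  max detailed-balance residual: %.3g\n", max(res$residual)))
  }
  print(x$transitions, n = nrow(x$transitions))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ladder model into its transition table
#' @param x A `ladder_model`.
#' @param ... Unused.
#' @export
tidy.ladder_model <- function(x, ...) x$transitions

#' One-row summary of a ladder model
#' @param x A `ladder_model`.
#' @param ... Unused.
#' @export
glance.ladder_model <- function(x, ...) {
  res <- detailed_balance_residuals(x)
  tibble(
    name = x$name,
    n_steps = x$n_steps,
    n_states = nrow(x$states),
    n_transitions = nrow(x$transitions),
    max_balance_residual = if (nrow(res) > 0) max(res$residual) else 0
  )
}
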