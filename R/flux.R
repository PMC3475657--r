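#' Probability-flux densities along a trajectory
#'
#' For every transition `X -> Y` of the model, the unidirectional flux
#' densities are `f_fwd(t) = k_fwd(L) * P_X(t) >= 0` (binding/opening
#' direction) and `f_bwd(t) = -k_bwd * P_Y(t) <= 0`, with association rate
#' constants multiplied by the segment's ligand concentration. Their sum
#' is the net flux density `f_net(t) = k_fwd(L) * P_X(t) - k_bwd * P_Y(t)`,
#' positive for net binding or opening. At a stationary distribution of a
#' detailed-balance model every `f_net` vanishes while the opposed
#' unidirectional components can stay large - the signature of
#' conformational flexibility across that transition.
#'
#' @param traj An `occupancy_trajectory` (one segment) or a
#'   `protocol_trajectory` from [run_protocol()].
#' @param model The `ladder_model` the trajectory was computed for.
#' @return A `flux_record` tibble in long format with columns
#'   (`segment`,) `edge`, `t`, `f_net`, `f_uni_forward`, `f_uni_backward`
#'   (all 1/s). Spectral data of the trajectory are carried along for
#'   exact time integration.
#' @seealso [total_net_flux()], [flux_divergence_check()]
#' @export
flux_density <- function(traj, model) {
  stopifnot(inherits(model, "ladder_model"))
  if (inherits(traj, "protocol_trajectory")) {
    segs <- attr(traj, "segments")
    recs <- lapply(segs, flux_density, model = model)
    out <- bind_rows(lapply(seq_along(recs), function(i) {
      mutate(as_tibble(recs[[i]]), segment = i, .before = 1)
    }))
    return(structure(out,
                     segment_records = recs,
                     class = c("flux_record", class(tibble()))))
  }
  stopifnot(inherits(traj, "occupancy_trajectory"))
  L <- attr(traj, "L")
  labels <- attr(traj, "state_labels")
  if (!identical(labels, model$states$label)) {
    abort("Trajectory states do not match the model; was it produced for this model?")
  }
  tr <- model$transitions
  P <- as.matrix(traj[, labels])
  kf_eff <- tr$k_forward * ifelse(tr$ligand_dependent, L, 1)
  times <- traj$t
  out <- bind_rows(lapply(seq_len(nrow(tr)), function(j) {
    fwd <- kf_eff[j] * P[, tr$from[j]]
    bwd <- -tr$k_backward[j] * P[, tr$to[j]]
    tibble(edge = tr$edge[j], t = times,
           f_net = fwd + bwd, f_uni_forward = fwd, f_uni_backward = bwd)
  }))
  structure(out,
            L = L, times = times,
            edges = tibble(edge = tr$edge, from = tr$from, to = tr$to,
                           kf_eff = kf_eff, k_backward = tr$k_backward),
            state_labels = labels,
            eigen_data = attr(traj, "eigen_data"),
            p0 = as.numeric(P[1, ]), P_last = P,
            class = c("flux_record", class(tibble())))
}

#' @rdname flux_density
#' @export
net_flux_density <- function(traj, model) {
  rec <- flux_density(traj, model)
  keep <- intersect(c("segment", "edge", "t", "f_net"), names(rec))
  as_tibble(rec)[, keep]
}

#' @rdname flux_density
#' @export
unidirectional_flux_density <- function(traj, model) {
  rec <- flux_density(traj, model)
  keep <- intersect(c("segment", "edge", "t", "f_uni_forward", "f_uni_backward"),
                    names(rec))
  as_tibble(rec)[, keep]
}

#' Total net probability flux per transition
#'
#' Integrates each net flux density from the concentration jump (`t = 0`)
#' to `t_end`, giving the dimensionless probability transferred across the
#' edge during the relaxation (a fraction of unity, signed: negative
#' totals mean net unbinding/closing). Two quadratures are available:
#' `"spectral"` (default) integrates the eigen-expansion of the trajectory
#' exactly - each mode contributes `(exp(lambda * t_end) - 1) / lambda`,
#' the conserved `lambda = 0` mode contributes `t_end` - while
#' `"simpson"` applies composite Simpson coefficients to the stored grid
#' and is available for trajectories without spectral data.
#'
#' @param fluxes A `flux_record` from [flux_density()].
#' @param t_end Integration end time (s); defaults to the last grid point.
#'   For protocol-level records, one value per segment (or `NULL`).
#' @param method `"spectral"` or `"simpson"`.
#' @return A tibble with columns (`segment`,) `edge`, `F_total`, `method`,
#'   carrying `t_end` and edge endpoints as attributes.
#' @export
total_net_flux <- function(fluxes, t_end = NULL, method = c("spectral", "simpson")) {
  method <- match.arg(method)
  stopifnot(inherits(fluxes, "flux_record"))
  recs <- attr(fluxes, "segment_records")
  if (!is.null(recs)) {
    if (!is.null(t_end) && length(t_end) == 1L) t_end <- rep(t_end, length(recs))
    tots <- lapply(seq_along(recs), function(i) {
      total_net_flux(recs[[i]], t_end = t_end[i], method = method)
    })
    out <- bind_rows(lapply(seq_along(tots), function(i) {
      mutate(as_tibble(tots[[i]]), segment = i, .before = 1)
    }))
    return(structure(out,
                     t_end = map_dbl(tots, ~ attr(.x, "t_end")),
                     segment_totals = tots,
                     class = c("flux_totals", class(tibble()))))
  }
  times <- attr(fluxes, "times")
  if (is.null(t_end)) t_end <- times[length(times)]
  if (t_end > times[length(times)] + 1e-12 || t_end <= 0) {
    abort("`t_end` must lie in (0, last grid time].")
  }
  edges <- attr(fluxes, "edges")
  eigen_data <- attr(fluxes, "eigen_data")
  if (method == "spectral") {
    if (is.null(eigen_data)) {
      abort("This trajectory has no spectral data (matrix-exponential fallback); use method = \"simpson\".")
    }
    lambda <- eigen_data$lambda
    w <- ifelse(lambda == 0, t_end, expm1(lambda * t_end) / ifelse(lambda == 0, 1, lambda))
    I_state <- drop(eigen_data$A %*% w)  # integral of P_s over [0, t_end]
    names(I_state) <- attr(fluxes, "state_labels")
    F_total <- edges$kf_eff * I_state[edges$from] - edges$k_backward * I_state[edges$to]
  } else {
    idx <- which(times <= t_end + 1e-12)
    F_total <- vapply(edges$edge, function(e) {
      f <- fluxes$f_net[fluxes$edge == e][idx]
      simpson_nonuniform(times[idx], f)
    }, numeric(1))
  }
  structure(
    tibble(edge = edges$edge, F_total = unname(F_total), method = method),
    t_end = t_end, edges = edges,
    p0 = attr(fluxes, "p0"), state_labels = attr(fluxes, "state_labels"),
    class = c("flux_totals", class(tibble()))
  )
}

# Composite Simpson quadrature on a (possibly non-uniform) grid: a
# quadratic is integrated through each consecutive triple of points. With
# an even number of points the final interval is handled by the trapezoid
# rule.
simpson_nonuniform <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  total <- 0
  i <- 1L
  while (i + 2L <= n) {
    h0 <- x[i + 1L] - x[i]
    h1 <- x[i + 2L] - x[i + 1L]
    total <- total + (h0 + h1) / 6 *
      ((2 - h1 / h0) * y[i] +
         (h0 + h1)^2 / (h0 * h1) * y[i + 1L] +
         (2 - h0 / h1) * y[i + 2L])
    i <- i + 2L
  }
  if (i + 1L == n) {
    total <- total + (x[n] - x[n - 1L]) * (y[n] + y[n - 1L]) / 2
  }
  total
}

#' Conservation audit of integrated fluxes
#'
#' For every state `X`, the integrated net flux into `X` minus the flux
#' out of `X` must equal its occupancy change `P_X(t_end) - P_X(0)`
#' (Kirchhoff's rule with storage). The residuals of this balance expose
#' integration error: with spectral integration they sit at numerical
#' round-off.
#'
#' @param totals A `flux_totals` table from [total_net_flux()] (single
#'   segment).
#' @param traj The `occupancy_trajectory` the totals were computed from.
#' @return A tibble with columns `state`, `inflow`, `outflow`, `delta_P`,
#'   `residual`; the maximum absolute residual is attached as attribute
#'   `max_residual`.
#' @export
flux_divergence_check <- function(totals, traj) {
  stopifnot(inherits(totals, "flux_totals"), inherits(traj, "occupancy_trajectory"))
  edges <- attr(totals, "edges")
  labels <- attr(traj, "state_labels")
  t_end <- attr(totals, "t_end")
  P <- as.matrix(traj[, labels])
  i_end <- which.min(abs(traj$t - t_end))
  if (abs(traj$t[i_end] - t_end) > 1e-9 * max(t_end, 1)) {
    abort("`t_end` of the totals is not a grid point of the trajectory.")
  }
  delta <- P[i_end, ] - P[1, ]
  inflow <- vapply(labels, function(s) sum(totals$F_total[edges$to == s]), numeric(1))
  outflow <- vapply(labels, function(s) sum(totals$F_total[edges$from == s]), numeric(1))
  res <- tibble(state = labels,
                inflow = unname(inflow), outflow = unname(outflow),
                delta_P = unname(delta),
                residual = unname(inflow - outflow - delta))
  structure(res, max_residual = max(abs(res$residual)),
            class = c("flux_divergence", class(tibble())))
}
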