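#' Time grid for a relaxation segment
#'
#' Flux densities peak within the first tens of milliseconds after a
#' concentration jump, so the default grid is hybrid: half of the points
#' are geometrically spaced from one hundredth of the uniform step
#' `t_end / (n - 1)` up to `t_end / 10`, the rest uniformly from there to
#' `t_end`, plus the point `t = 0`. Every interval thus shrinks when `n`
#' grows, so quadrature on the grid converges under refinement. The point
#' count must be odd so that composite Simpson quadrature applies to
#' consecutive interval pairs.
#'
#' @param t_end Segment duration in s (> 0).
#' @param n Odd number of grid points (default 2001).
#' @return Strictly increasing numeric vector starting at 0, length `n`.
#' @export
make_time_grid <- function(t_end, n = 2001) {
  stopifnot(t_end > 0, n >= 3)
  if (n %% 2 == 0) abort("`n` must be odd so Simpson pairs cover the grid.")
  n_geo <- (n - 1L) %/% 2L
  n_uni <- n - 1L - n_geo
  t_dense <- t_end / 10
  t_min <- 0.01 * t_end / (n - 1)
  geo <- exp(seq(log(t_min), log(t_dense), length.out = n_geo))
  uni <- seq(t_dense, t_end, length.out = n_uni + 1L)[-1L]
  c(0, geo, uni)
}

#' Concentration-jump protocols
#'
#' A protocol is an ordered list of segments, each holding the ligand
#' concentration at constant `L` (uM) for `duration` seconds; the jump
#' between segments is instantaneous. The default protocol reproduces the
#' standard activation/deactivation experiment: a 5 s pulse of 7.5 uM
#' ligand followed by 20 s of wash-out, starting from equilibrium at
#' `L = 0`.
#'
#' @param L Numeric vector of segment concentrations (uM, `>= 0`).
#' @param duration Numeric vector of segment durations (s, `> 0`).
#' @param label Free-text protocol label.
#' @return A `jump_protocol` tibble with columns `segment`, `L`, `duration`.
#' @examples
#' jump_protocol(L = c(7.5, 0), duration = c(5, 20))
#' @export
jump_protocol <- function(L, duration, label = "") {
  if (length(L) != length(duration) || length(L) == 0) {
    abort("`L` and `duration` must be non-empty vectors of equal length.")
  }
  if (any(!is.finite(L)) || any(L < 0)) abort("All concentrations must be finite and >= 0.")
  if (any(!is.finite(duration)) || any(duration <= 0)) abort("All durations must be > 0.")
  structure(
    tibble(segment = seq_along(L), L = as.numeric(L), duration = as.numeric(duration)),
    label = label,
    class = c("jump_protocol", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname jump_protocol
#' @param pulse_conc Pulse concentration in uM.
#' @param pulse_dur,wash_dur Pulse and wash durations in s.
#' @export
default_protocol <- function(pulse_conc = 7.5, pulse_dur = 5, wash_dur = 20) {
  jump_protocol(L = c(pulse_conc, 0), duration = c(pulse_dur, wash_dur),
                label = sprintf("%g uM pulse", pulse_conc))
}

#' Stationary distribution of a ladder model
#'
#' Solves for the probability vector in the null space of the generator at
#' concentration `L`. At `L = 0` the generator is reducible - liganded
#' states drain into the unliganded pair but cannot refill - so the
#' stationary distribution is defined as the `C0 <-> O0` equilibrium with
#' zero weight elsewhere, which is the natural initial condition before a
#' ligand pulse.
#'
#' @param model A `ladder_model`.
#' @param L Ligand concentration in uM.
#' @return A tibble with columns `state`, `probability` (non-negative,
#'   summing to 1), in the model's state order.
#' @export
stationary_distribution <- function(model, L) {
  p <- stationary_vec(model, L)
  tibble(state = model$states$label, probability = p)
}

stationary_vec <- function(model, L) {
  labels <- model$states$label
  if (L == 0) {
    iso0 <- model$transitions[model$transitions$edge == paste0("C", 0, "O", 0), ]
    kf <- iso0$k_forward
    kb <- iso0$k_backward
    if (kf + kb == 0) {
      abort("Non-unique stationary distribution at L = 0: C0 and O0 are disconnected (both C0O0 rates are zero).")
    }
    p <- setNames(numeric(length(labels)), labels)
    p["C0"] <- kb / (kf + kb)
    p["O0"] <- kf / (kf + kb)
    return(unname(p[labels]))
  }
  Q <- rate_matrix(model, L)
  ns <- nrow(Q)
  # uniqueness: the zero eigenvalue of the generator must be simple
  ev <- eigen(Q, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (sum(abs(Re(ev)) < 1e-10 * scale & abs(Im(ev)) < 1e-10 * scale) != 1L) {
    abort(sprintf(
      "Non-unique stationary distribution at L = %g: the transition graph splits into disconnected components (check for zero rates).", L))
  }
  M <- rbind(Q, rep(1, ns))
  p <- qr.solve(M, c(rep(0, ns), 1))
  if (any(p < -1e-9)) {
    abort("Stationary solve produced negative probabilities; model may be ill-conditioned.")
  }
  p <- pmax(p, 0)
  p / sum(p)
}

#' Propagate state probabilities by eigen-decomposition of the generator
#'
#' Computes `P(t) = exp(Q t) %*% p0` on a time grid by spectral
#' reconstruction. Generators of detailed-balance models are similar to
#' symmetric matrices via the stationary-distribution similarity
#' transform; when every stationary weight is positive the symmetrized
#' eigenproblem is solved for numerical robustness (real spectrum,
#' orthogonal modes). Otherwise (e.g. `L = 0`, where liganded states carry
#' zero stationary weight) a general eigen-decomposition is used, and if
#' its eigenvector matrix is too ill-conditioned the routine falls back to
#' a scaled-and-squared matrix exponential with a warning (the trajectory
#' then carries no spectral data, so downstream integrals use Simpson
#' quadrature).
#'
#' @param model A `ladder_model`.
#' @param p0 Initial probability vector (numeric in state order, or the
#'   tibble returned by [stationary_distribution()]); must sum to 1 within
#'   `1e-9`.
#' @param L Ligand concentration in uM held during the segment.
#' @param times Time grid starting at 0 (s); see [make_time_grid()].
#' @return An `occupancy_trajectory`: a tibble with column `t` and one
#'   probability column per state, carrying the segment concentration and
#'   the eigen-data (`lambda`, amplitude matrix `A` with
#'   `P(t) = A %*% exp(lambda * t)`) as attributes.
#' @export
propagate <- function(model, p0, L, times) {
  stopifnot(inherits(model, "ladder_model"))
  labels <- model$states$label
  if (is.data.frame(p0)) {
    p0 <- p0$probability[match(labels, p0$state)]
  }
  p0 <- as.numeric(p0)
  if (length(p0) != length(labels) || abs(sum(p0) - 1) > 1e-9 || any(p0 < -1e-12)) {
    abort("`p0` must be a probability vector over the model's states summing to 1.")
  }
  if (length(times) < 1 || times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing and start at 0.")
  }
  Q <- rate_matrix(model, L)
  sp <- spectral_decomposition(Q, model, L)
  if (is.null(sp)) {
    warn("Eigenvector matrix is ill-conditioned; falling back to a scaled-and-squared matrix exponential (no spectral data retained).")
    P <- propagate_expm(Q, p0, times)
    eigen_data <- NULL
  } else {
    coef <- drop(sp$Vinv %*% p0)
    A <- sp$V * rep(coef, each = nrow(sp$V))
    P <- A %*% exp(outer(sp$lambda, times))
    eigen_data <- list(lambda = sp$lambda, A = A)
  }
  Pt <- t(P)
  colnames(Pt) <- labels
  out <- bind_cols(tibble(t = times), as_tibble(Pt))
  structure(out,
            L = L, eigen_data = eigen_data, state_labels = labels,
            model_name = model$name,
            class = c("occupancy_trajectory", class(tibble())))
}

# Spectral decomposition of the generator: Q = V diag(lambda) Vinv with a
# real spectrum. Returns NULL if only an ill-conditioned general
# decomposition is available.
spectral_decomposition <- function(Q, model, L) {
  ns <- nrow(Q)
  pi_st <- tryCatch(stationary_vec(model, L), error = function(e) NULL)
  if (!is.null(pi_st) && all(pi_st > 1e-12)) {
    s <- sqrt(pi_st)
    S <- Q * outer(1 / s, s)
    if (max(abs(S - t(S))) <= 1e-6 * max(abs(S), 1)) {
      e <- eigen((S + t(S)) / 2, symmetric = TRUE)
      lambda <- clamp_spectrum(e$values)
      V <- e$vectors * s
      Vinv <- t(e$vectors) * rep(1 / s, each = ns)
      return(list(lambda = lambda, V = V, Vinv = Vinv))
    }
  }
  e <- eigen(Q)
  if (max(abs(Im(e$values))) > 1e-9 * max(abs(e$values), 1)) return(NULL)
  V <- Re(e$vectors)
  rc <- rcond(V)
  if (!is.finite(rc) || rc < 1e-10) return(NULL)
  list(lambda = clamp_spectrum(Re(e$values)), V = V, Vinv = solve(V))
}

# Snap near-zero eigenvalues of a generator to exactly 0 (the conserved
# mode); tiny positive parts are numerical noise.
clamp_spectrum <- function(lambda) {
  scale <- max(abs(lambda), 1)
  lambda[abs(lambda) < 1e-12 * scale] <- 0
  pmin(lambda, 0)
}

propagate_expm <- function(Q, p0, times) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    abort("The matrix-exponential fallback needs the Matrix package.")
  }
  P <- vapply(times, function(t1) {
    as.numeric(Matrix::expm(Matrix::Matrix(Q * t1)) %*% p0)
  }, numeric(length(p0)))
  matrix(P, nrow = length(p0))
}

#' Run a concentration-jump protocol
#'
#' Chains one deterministic relaxation per protocol segment: the first
#' segment starts from the stationary distribution at the pre-protocol
#' concentration (default `L = 0`, the `C0 <-> O0` equilibrium), and each
#' later segment starts from the final occupancy of the previous one.
#' Occupancies are continuous across the jumps; only the rates change.
#'
#' @param model A `ladder_model`.
#' @param protocol A [jump_protocol()].
#' @param n_points Odd number of grid points per segment.
#' @param L_init Pre-protocol concentration defining the initial
#'   equilibrium (uM, default 0).
#' @return A `protocol_trajectory` tibble with columns `segment`, `t`
#'   (time within the segment, s) and one column per state; the individual
#'   `occupancy_trajectory` objects are kept in the `segments` attribute.
#' @export
run_protocol <- function(model, protocol, n_points = 2001, L_init = 0) {
  stopifnot(inherits(model, "ladder_model"), inherits(protocol, "jump_protocol"))
  p0 <- stationary_vec(model, L_init)
  segs <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    times <- make_time_grid(protocol$duration[i], n_points)
    segs[[i]] <- propagate(model, p0, protocol$L[i], times)
    p0 <- as.numeric(segs[[i]][nrow(segs[[i]]), model$states$label])
    p0 <- p0 / sum(p0)
  }
  out <- bind_rows(lapply(seq_along(segs), function(i) {
    mutate(as_tibble(segs[[i]]), segment = i, .before = 1)
  }))
  structure(out,
            segments = segs, protocol = protocol, model_name = model$name,
            state_labels = model$states$label,
            class = c("protocol_trajectory", class(tibble())))
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf("<occupancy_trajectory> %d time points at L = %g uM\n",
              nrow(x), attr(x, "L")))
  NextMethod()
}

#' @export
print.protocol_trajectory <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat(sprintf("<protocol_trajectory> %d segment(s): %s\n", nrow(pr),
              paste(sprintf("%g uM / %g s", pr$L, pr$duration), collapse = " -> ")))
  NextMethod()
}
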