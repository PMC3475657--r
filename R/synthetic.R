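#' Specification for the synthetic ladder-model generator
#'
#' Rate constants are drawn log-uniformly from plausible ranges:
#' association rates of a small cyclic-nucleotide ligand on the order of
#' 0.1-10 / (uM s) (approaching the diffusion limit at the top),
#' dissociation rates of 0.1-20 / s, and isomerization rates of
#' 0.1-200 / s spanning slow gating to the fast flicker of strongly
#' liganded channels. `fixed` pins individual rate constants (by rate
#' name, e.g. `k_O3C3 = 3` for the backward rate of edge `C3O3`) before
#' the detailed-balance closure.
#'
#' @param seed Integer RNG seed; the same spec always generates the same
#'   model.
#' @param n_steps Number of binding steps.
#' @param assoc_range,dissoc_range,iso_range Two-element `c(low, high)`
#'   log-uniform sampling ranges (1/(uM s) for association, 1/s
#'   otherwise).
#' @param fixed Named list of pinned rate constants.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed, n_steps = 4,
                           assoc_range = c(0.1, 10),
                           dissoc_range = c(0.1, 20),
                           iso_range = c(0.1, 200),
                           fixed = list()) {
  check_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      abort(sprintf("`%s` must be positive and ordered c(low, high).", what))
    }
  }
  check_range(assoc_range, "assoc_range")
  check_range(dissoc_range, "dissoc_range")
  check_range(iso_range, "iso_range")
  structure(
    list(seed = as.integer(seed), n_steps = as.integer(n_steps),
         assoc_range = assoc_range, dissoc_range = dissoc_range,
         iso_range = iso_range, fixed = fixed),
    class = "generator_spec"
  )
}

# Resolve a rate name "k_<X><Y>" against the ladder's edge set: <X><Y>
# matching an edge pins its forward rate, the reversed order pins the
# backward rate.
resolve_rate_name <- function(name, edges) {
  stem <- sub("^k_", "", name)
  if (stem %in% edges) return(list(edge = stem, side = "k_forward"))
  rev2 <- paste0(substr(stem, 3, 4), substr(stem, 1, 2))
  if (rev2 %in% edges) return(list(edge = rev2, side = "k_backward"))
  abort(sprintf("Pinned rate `%s` does not name a transition of this ladder.", name))
}

#' Generate a random reversible ladder model satisfying detailed balance
#'
#' Closed-row binding rates and all isomerization rates are sampled freely
#' (log-uniform, or pinned via `spec$fixed`); each open-row association
#' rate is sampled and its dissociation rate is then solved from the
#' square-cycle balance condition, so every cycle residual is zero by
#' construction. A pinned open-row dissociation rate that contradicts the
#' closure of its cycle raises an error naming the cycle.
#'
#' @param spec A [generator_spec()].
#' @return A validated `ladder_model`.
#' @export
generate_ladder_rates <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_steps
  skel <- ladder_skeleton(n)
  edges <- skel$transitions$edge
  xs <- seq_len(n)

  rates <- with_seed(spec$seed, {
    r <- tibble(edge = edges, k_forward = NA_real_, k_backward = NA_real_)
    set_rate <- function(r, edge, side, value) {
      r[[side]][r$edge == edge] <- value
      r
    }
    if (n > 0) {
      for (x in xs) {
        e <- sprintf("C%dC%d", x - 1L, x)
        r <- set_rate(r, e, "k_forward", log_uniform(1, spec$assoc_range))
        r <- set_rate(r, e, "k_backward", log_uniform(1, spec$dissoc_range))
      }
    }
    for (x in 0:n) {
      e <- sprintf("C%dO%d", x, x)
      r <- set_rate(r, e, "k_forward", log_uniform(1, spec$iso_range))
      r <- set_rate(r, e, "k_backward", log_uniform(1, spec$iso_range))
    }
    if (n > 0) {
      for (x in xs) {
        e <- sprintf("O%dO%d", x - 1L, x)
        r <- set_rate(r, e, "k_forward", log_uniform(1, spec$assoc_range))
      }
    }
    r
  })

  # pins override sampled values before balance closure
  pinned_open_dissoc <- list()
  for (nm in names(spec$fixed)) {
    loc <- resolve_rate_name(nm, edges)
    if (loc$side == "k_backward" && grepl("^O", loc$edge)) {
      pinned_open_dissoc[[loc$edge]] <- spec$fixed[[nm]]
    } else {
      rates[[loc$side]][rates$edge == loc$edge] <- spec$fixed[[nm]]
    }
  }

  # balance closure: K_open_bind(x) = K_closed_bind(x) * K_iso(x) / K_iso(x-1)
  if (n > 0) {
    for (x in xs) {
      eC <- sprintf("C%dC%d", x - 1L, x)
      eO <- sprintf("O%dO%d", x - 1L, x)
      iso_lo <- sprintf("C%dO%d", x - 1L, x - 1L)
      iso_hi <- sprintf("C%dO%d", x, x)
      g <- function(e, side) rates[[side]][rates$edge == e]
      denom <- g(eC, "k_forward") * g(iso_hi, "k_forward") * g(iso_lo, "k_backward")
      numer <- g(eO, "k_forward") * g(eC, "k_backward") *
        g(iso_lo, "k_forward") * g(iso_hi, "k_backward")
      cycle <- sprintf("C%d-C%d-O%d-O%d", x - 1L, x, x, x - 1L)
      if (denom == 0) {
        abort(sprintf("Cannot close detailed balance in cycle %s: a required rate is zero.", cycle))
      }
      solved <- numer / denom
      pin <- pinned_open_dissoc[[eO]]
      if (!is.null(pin)) {
        if (abs(pin / solved - 1) > 1e-9) {
          abort(sprintf(
            "Pinned rate k_%s%s = %g over-constrains cycle %s: detailed balance requires %g.",
            substr(eO, 3, 4), substr(eO, 1, 2), pin, cycle, solved))
        }
        solved <- pin
      }
      rates$k_backward[rates$edge == eO] <- solved
    }
  }

  build_ladder_model(n, rates,
                     name = sprintf("synthetic-%dstep-seed%d", n, spec$seed))
}

#' Synthetic demonstration model of the C4L-O4L type
#'
#' A hand-tuned synthetic four-step ladder used throughout the examples
#' and tests. It pins the two published rate constraints
#' `k_O3C3 = k_O4C4 = 3 / s` and `k_C3O3 = k_C4O4 = 200 / s` and chooses
#' the remaining eleven transitions so that the model reproduces the
#' qualitative gating phenotype of cAMP-activated HCN2 channels -
#' negligible opening flux through the empty and doubly liganded channel,
#' activation entering the open row mainly at one, three and four
#' ligands, a metastable doubly liganded open state, and deactivation
#' returning through the low-liganded isomerizations. It is synthetic: no
#' claim is made that the free rates equal the experimentally fitted
#' ones.
#'
#' @return A `ladder_model` with 10 states and 13 transitions.
#' @export
demo_ladder_model <- function() {
  rates <- list(
    # closed-row binding: k_forward in 1/(uM s), k_backward in 1/s
    C0C1 = c(2, 10),
    C1C2 = c(4, 2),
    C2C3 = c(2, 2),
    C3C4 = c(20, 100),
    # open-row binding: dissociation fixed by detailed balance
    O0O1 = c(2, 1 / 3),
    O1O2 = c(4, 1 / 6),
    O2O3 = c(10, 9),
    O3O4 = c(4, 20),
    # closed-open isomerizations (1/s); x = 3, 4 pinned to the published
    # constraints
    C0O0 = c(0.5, 3),
    C1O1 = c(10, 2),
    C2O2 = c(1.2, 0.02),
    C3O3 = c(200, 3),
    C4O4 = c(200, 3)
  )
  build_ladder_model(4, rates, name = "c4l_o4l_demo")
}

#' Stochastic ensemble oracle: Gillespie simulation of a jump protocol
#'
#' Simulates `n_channels` independent channels by the exact stochastic
#' simulation algorithm, with per-edge rates switching instantaneously at
#' the protocol's concentration jumps. Channels are initialized by
#' sampling the stationary distribution at `L_init`. Each channel draws
#' from its own RNG stream derived from the root seed, so results are
#' reproducible and independent of simulation order. Occupancy is sampled
#' at the bin edges of a hybrid time grid per segment; directed
#' transition events are counted per bin.
#'
#' @param model A `ladder_model`.
#' @param protocol A [jump_protocol()].
#' @param n_channels Number of channels (`>= 1`).
#' @param seed Root seed (integer).
#' @param n_bins Number of bins per segment (bin edges follow
#'   [make_time_grid()] with `n_bins + 1` points; use an even `n_bins`).
#' @param L_init Pre-protocol concentration (uM).
#' @param p0 Optional explicit initial probability vector (state order);
#'   overrides the stationary initialization.
#' @return An `ensemble_counts` object: list with `n_channels`, `seed`,
#'   `edges` (transition table), `state_labels` and per-segment elements
#'   `bin_edges`, `occupancy` (states x bin edges), `counts_forward` /
#'   `counts_backward` (transitions x bins).
#' @export
gillespie_ensemble <- function(model, protocol, n_channels, seed,
                               n_bins = 500, L_init = 0, p0 = NULL) {
  stopifnot(inherits(model, "ladder_model"), inherits(protocol, "jump_protocol"),
            n_channels >= 1)
  labels <- model$states$label
  tr <- model$transitions
  kf_eff <- vapply(seq_len(nrow(protocol)), function(s) {
    tr$k_forward * ifelse(tr$ligand_dependent, protocol$L[s], 1)
  }, numeric(nrow(tr)))
  kb <- matrix(tr$k_backward, nrow(tr), nrow(protocol))
  bin_edges <- lapply(protocol$duration, function(d) make_time_grid(d, n_bins + 1L))
  if (is.null(p0)) p0 <- stationary_vec(model, L_init)
  stopifnot(length(p0) == length(labels), abs(sum(p0) - 1) < 1e-9)
  raw <- .gillespie_ensemble_cpp(
    n_states = length(labels),
    trans_from = match(tr$from, labels) - 1L,
    trans_to = match(tr$to, labels) - 1L,
    kf_eff = matrix(kf_eff, nrow(tr)), kb = kb,
    p0 = p0, bin_edges_list = bin_edges,
    n_channels = as.integer(n_channels), root_seed = as.numeric(seed)
  )
  segments <- lapply(raw, function(s) {
    dimnames(s$occupancy) <- list(labels, NULL)
    dimnames(s$counts_forward) <- list(tr$edge, NULL)
    dimnames(s$counts_backward) <- list(tr$edge, NULL)
    s
  })
  structure(
    list(n_channels = as.integer(n_channels), seed = seed,
         state_labels = labels, edges = tr[, c("edge", "from", "to")],
         protocol = protocol, segments = segments),
    class = "ensemble_counts"
  )
}

#' @export
print.ensemble_counts <- function(x, ...) {
  cat(sprintf("<ensemble_counts> %d channels, %d segment(s), seed %s\n",
              x$n_channels, length(x$segments), format(x$seed)))
  invisible(x)
}

#' Ensemble occupancy fractions at the sampled bin edges
#'
#' @param counts An `ensemble_counts` object.
#' @return A tibble with columns `segment`, `t`, `state`, `count`,
#'   `fraction`.
#' @export
ensemble_occupancy <- function(counts) {
  stopifnot(inherits(counts, "ensemble_counts"))
  bind_rows(lapply(seq_along(counts$segments), function(s) {
    seg <- counts$segments[[s]]
    occ <- seg$occupancy
    tibble(
      segment = s,
      t = rep(seg$bin_edges, each = nrow(occ)),
      state = rep(rownames(occ), ncol(occ)),
      count = as.integer(occ),
      fraction = as.numeric(occ) / counts$n_channels
    )
  }))
}

#' Empirical flux densities from ensemble transition counts
#'
#' Estimates the unidirectional flux densities of every transition as
#' directed event counts divided by `n_channels * bin width`, with
#' Poisson standard errors, and the net density as their (signed) sum.
#' Comparison against the deterministic densities of [flux_density()] is
#' the package's primary cross-validation.
#'
#' @param counts An `ensemble_counts` object.
#' @return A tibble with columns `segment`, `edge`, `bin_start`,
#'   `bin_end`, `t_mid`, `f_uni_forward`, `se_forward`, `f_uni_backward`
#'   (`<= 0`), `se_backward`, `f_net`, `se_net` (all 1/s).
#' @export
empirical_flux <- function(counts) {
  stopifnot(inherits(counts, "ensemble_counts"))
  N <- counts$n_channels
  bind_rows(lapply(seq_along(counts$segments), function(s) {
    seg <- counts$segments[[s]]
    be <- seg$bin_edges
    dt <- diff(be)
    nb <- length(dt)
    edges <- rownames(seg$counts_forward)
    cf <- as.numeric(seg$counts_forward)
    cb <- as.numeric(seg$counts_backward)
    denom <- rep(N * dt, each = length(edges))
    tibble(
      segment = s,
      edge = rep(edges, nb),
      bin_start = rep(be[-length(be)], each = length(edges)),
      bin_end = rep(be[-1], each = length(edges)),
      t_mid = rep((be[-length(be)] + be[-1]) / 2, each = length(edges)),
      f_uni_forward = cf / denom,
      se_forward = sqrt(cf) / denom,
      f_uni_backward = -cb / denom,
      se_backward = sqrt(cb) / denom,
      f_net = (cf - cb) / denom,
      se_net = sqrt(cf + cb) / denom
    )
  }))
}
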