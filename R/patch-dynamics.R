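# Grove patch-dynamics: a state-transition (Markov) model of the grove
# mosaic under a fire-frequency forcing. States describe the condition of one
# landscape patch; fire frequency f (annual burn probability) tilts the
# transition probabilities toward degradation and loss.

GROVE_STATES <- c("healthy", "degraded", "recovering", "singleton", "new", "absent")

#' Transition model over grove states
#'
#' Validates and wraps a row-stochastic transition matrix over the six grove
#' states (`healthy`, `degraded`, `recovering`, `singleton`, `new`,
#' `absent`).
#'
#' @param matrix 6 x 6 numeric matrix, rows = from-state, columns = to-state,
#'   each row summing to 1; dimnames default to the grove states.
#' @param f the fire-frequency parameter the matrix was built at (annual burn
#'   probability, in \[0, 1\]); informational.
#' @return object of class `transition_model`.
#' @export
transition_model <- function(matrix, f = NA_real_) {
  matrix <- as.matrix(matrix)
  if (!identical(dim(matrix), c(6L, 6L))) {
    stop("transition matrix must be 6 x 6 over the grove states", call. = FALSE)
  }
  if (is.null(dimnames(matrix))) dimnames(matrix) <- list(GROVE_STATES, GROVE_STATES)
  if (any(matrix < 0 | matrix > 1)) stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    stop("every row of the transition matrix must sum to 1", call. = FALSE)
  }
  structure(list(P = matrix, f = f, states = GROVE_STATES),
            class = "transition_model")
}

#' Default fire-driven grove transition model
#'
#' A demonstration parameterization in which every degradation pathway scales
#' with the fire frequency f and every recovery pathway with (1 - f):
#' transitions toward `degraded`/`absent` are nondecreasing in f and
#' transitions toward `healthy`/`recovering`/`new` nonincreasing, so
#' equilibrium grove occupancy falls monotonically as fire frequency rises.
#' At f = 1 the `absent` state is absorbing and reachable from everywhere
#' (grove loss); at f = 0 groves persist and bare patches are recolonized.
#' The numbers are illustrative defaults for exploring the model's qualitative
#' behaviour, not field-calibrated probabilities.
#'
#' @param f annual patch burn probability in \[0, 1\].
#' @return a [transition_model()].
#' @export
fire_transition_model <- function(f) {
  stopifnot_scalar(f)
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]", call. = FALSE)
  P <- matrix(0, 6, 6, dimnames = list(GROVE_STATES, GROVE_STATES))
  # degradation pathways scale with f, recovery pathways with (1 - f);
  # self-transitions of the intermediate states are constant so that every
  # column is monotone in f (toward degraded/absent: nondecreasing; toward
  # healthy/recovering/new: nonincreasing).
  P["healthy", "degraded"] <- 0.5 * f
  P["healthy", "healthy"] <- 1 - 0.5 * f
  P["degraded", "absent"] <- 0.3 * f
  P["degraded", "recovering"] <- 0.25 * (1 - f)
  P["degraded", "degraded"] <- 0.5
  P["degraded", "singleton"] <- 1 - sum(P["degraded", ]) # 0.25 - 0.05 f
  P["recovering", "healthy"] <- 0.6 * (1 - f)
  P["recovering", "degraded"] <- 0.6 * f
  P["recovering", "recovering"] <- 0.4
  P["singleton", "absent"] <- 0.3 * f
  P["singleton", "new"] <- 0.3 * (1 - f)
  P["singleton", "singleton"] <- 0.7
  P["new", "healthy"] <- 0.5 * (1 - f)
  P["new", "absent"] <- 0.5 * f
  P["new", "new"] <- 0.5
  P["absent", "new"] <- 0.2 * (1 - f)
  P["absent", "absent"] <- 0.8 + 0.2 * f
  transition_model(P, f = f)
}

#' Advance patch states one year
#'
#' Each patch transitions independently according to its current state's row
#' of the transition matrix.
#'
#' @param states character (or factor) vector of current patch states.
#' @param model a [transition_model()].
#' @return character vector of next-year states.
#' @export
step_states <- function(states, model) {
  stopifnot(inherits(model, "transition_model"))
  states <- as.character(states)
  if (!all(states %in% model$states)) stop("unknown state in `states`", call. = FALSE)
  out <- character(length(states))
  for (s in unique(states)) {
    sel <- states == s
    out[sel] <- sample(model$states, sum(sel), replace = TRUE, prob = model$P[s, ])
  }
  out
}

#' Stationary distribution of a transition model
#'
#' Power iteration to tolerance 1e-12. For irreducible aperiodic chains this
#' is the unique stationary distribution; for reducible chains (e.g. an
#' absorbing `absent` state) it returns the limit from a uniform start and
#' flags the result.
#'
#' @param model a [transition_model()].
#' @param tol convergence tolerance (default 1e-12).
#' @param max_iter iteration cap.
#' @return named probability vector with attribute `irreducible` (logical).
#' @export
stationary_distribution <- function(model, tol = 1e-12, max_iter = 1e6) {
  stopifnot(inherits(model, "transition_model"))
  P <- model$P
  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  irreducible <- igraph::is_connected(g, mode = "strong")
  # iterate the lazy chain (P + I)/2: same stationary law, but aperiodic, so
  # power iteration converges even for periodic inputs
  L <- (P + diag(nrow(P))) / 2
  pi <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(max_iter)) {
    nxt <- as.vector(pi %*% L)
    if (max(abs(nxt - pi)) < tol) { pi <- nxt; break }
    pi <- nxt
  }
  pi <- pi / sum(pi)
  names(pi) <- model$states
  attr(pi, "irreducible") <- irreducible
  pi
}

#' Simulate a grove mosaic trajectory
#'
#' Seeded simulation of a lattice of independent patches under a transition
#' model, recording each patch's state and the landscape state proportions
#' every year.
#'
#' @param model a [transition_model()].
#' @param n_patches number of lattice patches.
#' @param years number of simulated years (>= 1).
#' @param seed RNG seed.
#' @param init initial states: a single state name, a vector of length
#'   `n_patches`, or `NULL` for all-`healthy`.
#' @return object of class `mosaic_trajectory`: list with `states`
#'   (years+1 x n_patches character matrix, row 1 = initial condition) and
#'   `proportions` (years+1 x 6 matrix of state proportions).
#' @export
simulate_mosaic <- function(model, n_patches = 500, years = 500, seed = 1,
                            init = NULL) {
  stopifnot(inherits(model, "transition_model"))
  if (years < 1) stop("`years` must be at least 1", call. = FALSE)
  init <- if (is.null(init)) rep("healthy", n_patches) else rep_len(as.character(init), n_patches)
  if (!all(init %in% model$states)) stop("unknown state in `init`", call. = FALSE)
  states <- matrix(NA_character_, nrow = years + 1L, ncol = n_patches)
  states[1L, ] <- init
  with_seed(seed, {
    for (t in seq_len(years)) {
      states[t + 1L, ] <- step_states(states[t, ], model)
    }
  })
  props <- t(apply(states, 1L, function(r) {
    tabulate(factor(r, levels = model$states), nbins = 6L) / n_patches
  }))
  colnames(props) <- model$states
  structure(list(states = states, proportions = props, model = model),
            class = "mosaic_trajectory")
}

#' Equilibrium grove occupancy
#'
#' The long-run proportion of patches in grove-bearing states (`healthy`,
#' `recovering`, `new`), averaged over the final stretch of a simulated
#' trajectory.
#'
#' @param trajectory a `mosaic_trajectory`.
#' @param tail_years number of final years to average over (default 100).
#' @return proportion in \[0, 1\].
#' @export
grove_occupancy <- function(trajectory, tail_years = 100) {
  stopifnot(inherits(trajectory, "mosaic_trajectory"))
  pr <- trajectory$proportions
  rows <- max(1L, nrow(pr) - tail_years + 1L):nrow(pr)
  mean(rowSums(pr[rows, c("healthy", "recovering", "new"), drop = FALSE]))
}
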