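#' Instantaneous activation drive
#'
#' The sigmoidal drive toward which each activation decays,
#' `g_i = 1/2 * (1 + tanh(sum_j w_ij u_j + I_i))`.  This is the fixed
#' target of the rate dynamics `tau du/dt = -u + g(w, u, I)`.
#'
#' @param w `n x n` weight matrix; entry `(j, i)` is the connection from
#'   neuron `i` to neuron `j`.
#' @param u Activation vector, entries in `[0, 1]`.
#' @param I Cue current vector.
#' @return Numeric vector with entries strictly in `(0, 1)`.
#' @examples
#' activation_drive(matrix(0, 3, 3), rep(0.5, 3), rep(0, 3))  # all 0.5
#' @export
activation_drive <- function(w, u, I) {
  w <- check_weights(w)
  n <- nrow(w)
  if (length(u) != n)
    stop("'u' has length ", length(u), " but 'w' is ", n, " x ", n)
  if (length(I) != n)
    stop("'I' has length ", length(I), " but 'w' is ", n, " x ", n)
  0.5 * (1 + tanh(drop(w %*% u) + I))
}

#' Relax the network to a steady state
#'
#' Integrates `tau du_i/dt = -u_i + 1/2 (1 + tanh(sum_j w_ij u_j + I_i))`
#' by forward Euler until the maximum activation rate of change per unit
#' time drops below `params$tol`, or the time cap `params$t_relax` is
#' reached.  With `dt < tau` the Euler update is a convex combination of
#' the current state and a value in `(0, 1)`, so activations remain in
#' `[0, 1]` throughout.
#'
#' @param w Weight matrix (`n x n`).
#' @param I Cue current vector of length `n`.
#' @param u0 Initial activations, entries in `[0, 1]`.
#' @param params A [model_params()] object (only the dynamics fields
#'   `tau`, `dt`, `tol`, `t_relax` are used).
#' @param record_energy If `TRUE`, also return the Lyapunov energy
#'   `-1/2 u' w u` after every Euler step (used to monitor descent).
#' @return A list with elements `u` (final state), `converged` (logical),
#'   `steps` (Euler steps taken) and, optionally, `energy`.
#' @examples
#' p <- model_params()
#' r <- relax(matrix(0, 4, 4), rep(0, 4), runif(4), p)
#' r$u  # all 0.5: unique fixed point of -u + 1/2
#' @export
relax <- function(w, I, u0, params = model_params(),
                  record_energy = FALSE) {
  w <- check_weights(w)
  n <- nrow(w)
  if (length(I) != n)
    stop("'I' has length ", length(I), " but 'w' is ", n, " x ", n)
  if (length(u0) != n)
    stop("'u0' has length ", length(u0), " but 'w' is ", n, " x ", n)
  if (any(u0 < 0 | u0 > 1)) stop("'u0' entries must lie in [0, 1]")
  .relax_euler(w, as.numeric(I), as.numeric(u0),
               params$tau, params$dt, params$tol, params$t_relax,
               record_energy)
}

#' Classify a relaxed state against the stored patterns
#'
#' Computes the Pearson correlation between an activity vector and each
#' stored binary pattern, and returns the id of the best-matching pattern
#' if its correlation exceeds `r_threshold` (ties broken by the lowest
#' pattern id).  Returns `NA` ("no attractor") if no pattern exceeds the
#' threshold or if the activity vector is constant (correlation
#' undefined).
#'
#' @param u Activity vector of length `n_neurons`.
#' @param patterns A [build_patterns()] pattern set.
#' @param r_threshold Correlation threshold in `(0, 1]`; the default 0.7
#'   is the retrieval-success criterion also used for capacity curves.
#' @return Integer pattern id (row of `patterns$x`) or `NA_integer_`.
#' @examples
#' ps <- build_patterns()
#' classify_attractor(ps$x[2, ], ps)  # 2: self-correlation is 1
#' classify_attractor(rep(0.5, ps$n_neurons), ps)  # NA: zero variance
#' @export
classify_attractor <- function(u, patterns, r_threshold = 0.7) {
  stopifnot(inherits(patterns, "pattern_set"),
            r_threshold > 0, r_threshold <= 1)
  if (length(u) != patterns$n_neurons)
    stop("'u' has length ", length(u), " but patterns have ",
         patterns$n_neurons, " neurons")
  if (sd(u) == 0) return(NA_integer_)
  r <- apply(patterns$x, 1L, function(p) cor(u, p))
  best <- which.max(r)  # which.max already breaks ties by lowest index
  if (r[best] > r_threshold) as.integer(best) else NA_integer_
}

# Validate a weight matrix: square numeric matrix.
check_weights <- function(w) {
  if (!is.matrix(w)) w <- as.matrix(w)
  if (!is.numeric(w) || nrow(w) != ncol(w))
    stop("'w' must be a square numeric matrix")
  w
}

#' Empty weight matrix
#'
#' @param n_neurons Network size.
#' @return An `n x n` zero matrix (the naive, untrained network).
#' @export
zero_weights <- function(n_neurons) {
  matrix(0, n_neurons, n_neurons)
}
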