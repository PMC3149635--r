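#' Normalize cue currents to the unit interval
#'
#' Affine map `I_hat = (I + I_max) / (2 * I_max)` taking cue currents in
#' `[-I_max, I_max]` onto `[0, 1]`, so that they are comparable with the
#' steady-state activations when forming the mismatch vector.
#'
#' @param I Cue current vector.
#' @param I_max Cue bound (> 0).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' normalize_cue(c(-5, 0, 5), 5)  # 0, 0.5, 1
#' @export
normalize_cue <- function(I, I_max = 5) {
  if (I_max <= 0) stop("'I_max' must be positive")
  (I + I_max) / (2 * I_max)
}

#' Hebbian learning plasticity matrix
#'
#' `HLP_ji = S * u_i * (2 * u_j - 1)`: connections from an active
#' presynaptic neuron `i` are reinforced by `+S` onto active postsynaptic
#' neurons, changed by `-S` onto silent ones, and nothing happens when
#' the presynaptic neuron is silent.  Intermediate activations
#' interpolate continuously between these cases.
#'
#' @param u Steady-state activation vector in `[0, 1]`.
#' @param S Synthesis factor (>= 0); `S = 0` blocks Hebbian plasticity.
#' @return `n x n` weight-change matrix (entry `(j, i)` for connection
#'   `i -> j`).
#' @examples
#' hlp_matrix(c(1, 0), 0.8)  # (2,1) entry -0.8, (1,1) entry +0.8
#' @export
hlp_matrix <- function(u, S) {
  stopifnot(S >= 0)
  if (any(u < 0 | u > 1)) stop("'u' entries must lie in [0, 1]")
  S * outer(2 * u - 1, u)
}

#' Mismatch vector
#'
#' `m = I_hat - u`: the elementwise disagreement between the normalized
#' cue and the steady state reached by the network.  Units with `m = +1`
#' were cue-activated but suppressed in the attractor (AS); units with
#' `m = -1` were cue-suppressed but active (SA).  When the retrieved
#' attractor equals the cue (as in initial learning) `m` is the zero
#' vector.
#'
#' @param i_hat Normalized cue in `[0, 1]` (see [normalize_cue()]).
#' @param u Steady-state activations in `[0, 1]`.
#' @return Numeric vector with entries in `[-1, 1]`.
#' @export
mismatch_vector <- function(i_hat, u) {
  if (length(i_hat) != length(u))
    stop("'i_hat' and 'u' must have the same length")
  i_hat - u
}

#' Mismatch-induced degradation matrix
#'
#' `MID_ji = D * u_i * m_j`: connections from active neurons onto AS
#' units (`m_j = +1`) gain `+D` (degrading the inhibition that kept them
#' silent), and connections onto SA units (`m_j = -1`) lose `D`
#' (degrading the excitation that kept them active).  The matrix is zero
#' whenever the cue matches the attractor.
#'
#' @param u Steady-state activation vector in `[0, 1]`.
#' @param m Mismatch vector (see [mismatch_vector()]).
#' @param D Degradation factor (>= 0); `D = 0` blocks degradation.
#' @return `n x n` weight-change matrix.
#' @export
mid_matrix <- function(u, m, D) {
  stopifnot(D >= 0)
  if (length(u) != length(m)) stop("'u' and 'm' must have the same length")
  D * outer(m, u)
}

#' Apply a session's weight update with saturation
#'
#' `w' = clip(w + hlp + mid, -s0, +s0)` with the diagonal re-zeroed
#' (no self-connections).  Truncation at `+/- s0` prevents any memory
#' from dominating indefinitely.
#'
#' @param w Current weight matrix.
#' @param hlp,mid Weight-change matrices from [hlp_matrix()] and
#'   [mid_matrix()] (either may be a scalar 0).
#' @param s0 Saturation bound (> 0).
#' @return Updated weight matrix with `|w'| <= s0` and zero diagonal.
#' @export
update_weights <- function(w, hlp, mid, s0 = 1) {
  stopifnot(s0 > 0)
  w <- check_weights(w)
  w2 <- w + hlp + mid
  w2[w2 > s0] <- s0
  w2[w2 < -s0] <- -s0
  diag(w2) <- 0
  w2
}

#' Inter-session synaptic decay
#'
#' Discrete decay event `w' = (1 - gamma) * w`, applied once per declared
#' inter-session interval (in the standard protocols: once after
#' training, before the first reexposure session).
#'
#' @param w Weight matrix.
#' @param gamma Decay fraction in `[0, 1)`.
#' @return Decayed weight matrix.
#' @export
apply_decay <- function(w, gamma) {
  if (gamma < 0 || gamma >= 1) stop("'gamma' must lie in [0, 1)")
  (1 - gamma) * check_weights(w)
}
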