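#' Model parameters
#'
#' Bundles every tunable scalar of the simulator, with the defaults used
#' throughout the behavioral protocols.  All quantities are unitless
#' except the time-like ones, which are expressed in units of the neural
#' time constant `tau`.
#'
#' @param tau Neural time constant of the rate dynamics (> 0).
#' @param dt Euler integration step; must satisfy `0 < dt < tau` (the
#'   update is then a convex combination, which keeps activations in
#'   `[0, 1]`).
#' @param tol Steady-state tolerance: integration stops when
#'   `max_i |du_i/dt| < tol`.
#' @param t_relax Time cap for a single relaxation, in units of `tau`.
#' @param S Hebbian synthesis factor (>= 0).  `S = 0` models protein
#'   synthesis inhibition (anisomycin); values above the default model
#'   plasticity enhancers.
#' @param D Mismatch degradation factor (>= 0).  `D = 0` models
#'   degradation blockade.
#' @param gamma Inter-session synaptic decay fraction in `[0, 1)`;
#'   applied as a discrete event `w <- (1 - gamma) * w` where a protocol
#'   declares it.
#' @param s0 Saturation bound on synaptic weights; every update is
#'   truncated to `[-s0, s0]`.
#' @param I_max Cue current bound; training cues use `+I_max` on active
#'   and `-I_max` on inactive neurons.
#' @param test_strength Weak cue current used on context neurons in
#'   retrieval tests.
#' @param sigmoid_midpoint,sigmoid_slope Parameters of the logistic
#'   `f(t) = 1 / (1 + exp(-slope * (t - midpoint)))` that mixes the shock
#'   and non-shock cues as a function of reexposure duration `t` in
#'   `[0, 10]`.
#' @param r_threshold Pearson correlation threshold above which a relaxed
#'   state is classified as a stored pattern.
#'
#' @return A named list of class `"model_params"`.
#' @examples
#' p <- model_params()
#' p$S
#' model_params(S = 0)$S  # anisomycin condition
#' @export
model_params <- function(tau = 1, dt = 0.1 * tau, tol = 1e-6,
                         t_relax = 100 * tau,
                         S = 0.8, D = 1.25, gamma = 0.15, s0 = 1,
                         I_max = 5, test_strength = 0.1,
                         sigmoid_midpoint = 5, sigmoid_slope = 1,
                         r_threshold = 0.7) {
  stopifnot(tau > 0, dt > 0, dt < tau, tol > 0, t_relax > 0,
            S >= 0, D >= 0, gamma >= 0, gamma < 1, s0 > 0, I_max > 0,
            test_strength > 0, sigmoid_slope > 0,
            r_threshold > 0, r_threshold <= 1)
  structure(list(tau = tau, dt = dt, tol = tol, t_relax = t_relax,
                 S = S, D = D, gamma = gamma, s0 = s0,
                 I_max = I_max, test_strength = test_strength,
                 sigmoid_midpoint = sigmoid_midpoint,
                 sigmoid_slope = sigmoid_slope,
                 r_threshold = r_threshold),
            class = "model_params")
}

# Apply a named list of overrides to a model_params object, re-validating.
override_params <- function(params, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(params)
  stopifnot(is.list(overrides))
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown) > 0L)
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "))
  do.call(model_params, modifyList(unclass(params), overrides))
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}
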