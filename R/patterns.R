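#' Build the memory pattern set
#'
#' Lays out three binary memory patterns over `n_neurons` units in fixed,
#' deterministic index blocks:
#'
#' 1. **unrelated** - a memory with no neuron in common with the others;
#' 2. **shock** - the fear memory: `n_shared` context neurons plus a
#'    block of shock neurons;
#' 3. **nonshock** - the extinction memory: the same `n_shared` context
#'    neurons plus a distinct block of non-shock neurons.
#'
#' Each pattern has exactly `active_size` active neurons.  Patterns 2 and
#' 3 share exactly the `n_shared` context neurons; pattern 1 is disjoint
#' from both.  Retrieval tests cue `cue_size` neurons of the shock
#' pattern, preferring shared (context) neurons first, so with the
#' defaults the test cue is exactly the 4 context neurons.
#'
#' @param n_neurons Network size (default 100).
#' @param active_size Active neurons per pattern (default 14).
#' @param n_shared Neurons shared between the shock and non-shock
#'   patterns (default 4; varied in overlap sweeps).
#' @param cue_size Number of neurons carrying the weak retrieval cue
#'   (default 4).
#' @return An object of class `"pattern_set"`: a list with the binary
#'   pattern matrix `x` (3 rows: unrelated, shock, nonshock), the index
#'   sets `unrelated_idx`, `shared_idx`, `shock_idx`, `nonshock_idx`,
#'   `context_idx` (test-cue neurons), and the size fields.
#' @examples
#' ps <- build_patterns()
#' sum(ps$x[2, ] * ps$x[3, ])  # 4 shared context neurons
#' @export
build_patterns <- function(n_neurons = 100, active_size = 14,
                           n_shared = 4, cue_size = 4) {
  stopifnot(n_neurons >= 1, active_size >= 1,
            n_shared >= 0, n_shared <= active_size,
            cue_size >= 1, cue_size <= active_size)
  needed <- active_size +                  # unrelated block
    n_shared +                             # shared context block
    2 * (active_size - n_shared)           # shock- and nonshock-unique
  if (needed > n_neurons)
    stop("pattern layout does not fit: needs ", needed, " neurons but ",
         "the network has ", n_neurons)

  unrelated_idx <- seq_len(active_size)
  off <- active_size
  shared_idx <- if (n_shared > 0) off + seq_len(n_shared) else integer(0)
  off <- off + n_shared
  n_unique <- active_size - n_shared
  shock_idx <- if (n_unique > 0) off + seq_len(n_unique) else integer(0)
  off <- off + n_unique
  nonshock_idx <- if (n_unique > 0) off + seq_len(n_unique) else integer(0)

  x <- matrix(0, nrow = 3, ncol = n_neurons,
              dimnames = list(c("unrelated", "shock", "nonshock"), NULL))
  x[1, unrelated_idx] <- 1
  x[2, c(shared_idx, shock_idx)] <- 1
  x[3, c(shared_idx, nonshock_idx)] <- 1

  # test-cue neurons: shared context first, then shock-unique neurons
  context_idx <- c(shared_idx, shock_idx)[seq_len(cue_size)]

  structure(list(n_neurons = n_neurons, active_size = active_size,
                 n_shared = n_shared, cue_size = cue_size,
                 x = x,
                 unrelated_idx = unrelated_idx, shared_idx = shared_idx,
                 shock_idx = shock_idx, nonshock_idx = nonshock_idx,
                 context_idx = context_idx),
            class = "pattern_set")
}

#' @rdname build_patterns
#' @param n_context Alias of `n_shared` kept for the default layout.
#' @export
build_default_patterns <- function(n_neurons = 100, active_size = 14,
                                   n_context = 4) {
  build_patterns(n_neurons, active_size, n_shared = n_context,
                 cue_size = n_context)
}

#' @rdname build_patterns
#' @export
build_overlap_patterns <- function(n_shared, n_neurons = 100,
                                   active_size = 14, cue_size = 4) {
  build_patterns(n_neurons, active_size, n_shared = n_shared,
                 cue_size = cue_size)
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf(
    "Pattern set: %d neurons, %d active/pattern, %d shared, %d cue neurons\n",
    x$n_neurons, x$active_size, x$n_shared, x$cue_size))
  invisible(x)
}

#' Novel (never-stored) pattern
#'
#' A deterministic binary pattern of `active_size` neurons occupying the
#' highest-index block of the network, disjoint from every stored
#' pattern.  Used to model exposure to an unrelated context: learning it
#' engages plasticity without touching the synapses of the stored
#' memories.
#'
#' @param patterns A [build_patterns()] pattern set.
#' @return Binary activity vector of length `n_neurons`.
#' @export
novel_pattern <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  n <- patterns$n_neurons
  idx <- (n - patterns$active_size + 1L):n
  used <- which(colSums(patterns$x) > 0)
  if (any(idx %in% used))
    stop("no room for a novel pattern disjoint from the stored ones")
  p <- numeric(n)
  p[idx] <- 1
  p
}

#' Full-strength training cue for a binary pattern
#'
#' `I_i = +I_max` on the pattern's active neurons and `-I_max` elsewhere,
#' so that the cue fully clamps the network to the pattern during
#' learning.  Note that [normalize_cue()] of a training cue recovers the
#' binary pattern exactly.
#'
#' @param pattern Binary (0/1) activity vector.
#' @param I_max Cue bound.
#' @return Cue current vector.
#' @export
training_cue <- function(pattern, I_max = 5) {
  if (!all(pattern %in% c(0, 1))) stop("'pattern' must be binary (0/1)")
  I_max * (2 * pattern - 1)
}

#' Weak retrieval-test cue
#'
#' A weak current (`strength`, default 0.1) on the `cue_size` context
#' neurons and 0 elsewhere.  With `strength = 0` this is the free-recall
#' (random retrieval) condition.
#'
#' @param patterns A [build_patterns()] pattern set.
#' @param strength Cue current on the context neurons (>= 0).
#' @return Cue current vector.
#' @export
test_cue <- function(patterns, strength = 0.1) {
  stopifnot(inherits(patterns, "pattern_set"), strength >= 0)
  I <- numeric(patterns$n_neurons)
  I[patterns$context_idx] <- strength
  I
}

#' Reexposure-duration mixing sigmoid
#'
#' `f(t) = 1 / (1 + exp(-slope * (t - midpoint)))`, the monotone map from
#' reexposure duration `t` in `[0, 10]` to the fraction of the non-shock
#' cue present in the reexposure input.  `f(midpoint) = 0.5`.
#'
#' @param t Reexposure duration(s).
#' @param midpoint Duration at which the mix is 50/50 (default 5).
#' @param slope Steepness of the transition (default 1).
#' @return Value(s) in `(0, 1)`.
#' @export
sigmoid_f <- function(t, midpoint = 5, slope = 1) {
  1 / (1 + exp(-slope * (t - midpoint)))
}

#' Mixed reexposure cue
#'
#' `I(t) = (1 - f(t)) * training_cue(shock) + f(t) * training_cue(nonshock)`:
#' for short durations the cue resembles the shock memory, for long
#' durations the non-shock memory, with intermediate durations yielding
#' mixed patterns.  Context neurons receive `+I_max` at every `t`.
#'
#' @param t Reexposure duration in `[0, 10]`.
#' @param patterns A [build_patterns()] pattern set.
#' @param I_max Cue bound.
#' @param midpoint,slope Sigmoid parameters (see [sigmoid_f()]).
#' @return Cue current vector.
#' @export
mixed_cue <- function(t, patterns, I_max = 5, midpoint = 5, slope = 1) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (t < 0 || t > 10) stop("'t' must lie in [0, 10]")
  f <- sigmoid_f(t, midpoint, slope)
  (1 - f) * training_cue(patterns$x["shock", ], I_max) +
    f * training_cue(patterns$x["nonshock", ], I_max)
}
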