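# Shared fixtures: deterministic trained weight matrices built through the
# package's own session machinery (training cues clamp the steady state, so
# the resulting matrices are reproducible given the seed).

default_ps <- build_patterns()
default_pars <- model_params()

# Train the given pattern ids sequentially (full session updates: HLP+MID).
train_weights <- function(pattern_ids, patterns = default_ps,
                          params = default_pars, S = params$S, seed = 1) {
  set.seed(seed)
  w <- zero_weights(patterns$n_neurons)
  for (id in pattern_ids) {
    out <- run_session(w, sess_train(id, S = S), patterns, params)
    w <- out$w
  }
  w
}

# Matrix after the standard protocol's learning phase (memories 1 and 2).
trained_w12 <- function(...) train_weights(1:2, ...)

# Matrix holding only the shock memory, strongly cue-retrievable.
trained_shock_only <- function() train_weights(2)

# Brute-force oracle for the discrete plasticity rules, written directly
# from the case table: an active presynaptic neuron strengthens its
# connection onto an active postsynaptic neuron by +S and changes it by -S
# onto a silent one; nothing happens from a silent presynaptic neuron.
# Mismatch degradation adds +D onto cue-active-but-suppressed (AS) units
# and -D onto cue-suppressed-but-active (SA) units, again only from active
# presynaptic neurons.
hlp_oracle <- function(u_pre, u_post, S) {
  if (u_pre == 0) return(0)
  if (u_post == 1) S else -S
}
mid_oracle <- function(u_pre, u_post, i_hat_post, D) {
  if (u_pre == 0) return(0)
  if (i_hat_post == 1 && u_post == 0) return(D)   # AS unit
  if (i_hat_post == 0 && u_post == 1) return(-D)  # SA unit
  0                                               # AA or SS: no mismatch
}
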