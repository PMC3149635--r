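FREEZING_HIGH <- 90
FREEZING_LOW <- 10

#' Freezing readout for a classified attractor
#'
#' Retrieval of the shock pattern yields 90% freezing over the test
#' duration; any other outcome (another pattern or no attractor) yields
#' the 10% baseline.
#'
#' @param label Integer pattern id from [classify_attractor()] (possibly
#'   `NA`).
#' @param shock_id Row index of the shock pattern (default 2).
#' @return 90 or 10 (percent of test duration spent freezing).
#' @export
freezing_from_label <- function(label, shock_id = 2L) {
  ifelse(!is.na(label) & label == shock_id, FREEZING_HIGH, FREEZING_LOW)
}

#' Session constructors
#'
#' A protocol is an ordered list of sessions:
#' * `sess_train(pattern)` - learning of a full pattern (1 = unrelated,
#'   2 = shock, 3 = nonshock) under its full-strength training cue;
#' * `sess_reexpose(t)` - nonreinforced reexposure of duration `t`,
#'   cueing the sigmoid mixture of the shock and non-shock cues;
#' * `sess_test()` - a retrieval test with the weak context cue; weights
#'   are never updated by tests;
#' * `sess_decay()` - a discrete inter-session decay event
#'   `w <- (1 - gamma) w`.
#'
#' Training and reexposure sessions accept per-session `S` and `D`
#' overrides that model drug administration in that session only
#' (anisomycin: `S = 0`; enhancer: `S = 0.95`; degradation blockade:
#' `D = 0`).
#'
#' @param pattern Pattern id to train (1, 2 or 3).
#' @param t Reexposure duration in `[0, 10]`.
#' @param S,D Optional per-session plasticity overrides (>= 0).
#' @param label Optional free-text label (reported for test sessions).
#' @return A list of class `"session"`.
#' @name sessions
NULL

new_session <- function(kind, pattern = NA_integer_, t = NA_real_,
                        S = NULL, D = NULL, label = NULL) {
  if (!is.null(S) && S < 0) stop("session 'S' override must be >= 0")
  if (!is.null(D) && D < 0) stop("session 'D' override must be >= 0")
  structure(list(kind = kind, pattern = pattern, t = t,
                 S = S, D = D, label = label),
            class = "session")
}

#' @rdname sessions
#' @export
sess_train <- function(pattern, S = NULL, D = NULL, label = NULL) {
  stopifnot(pattern %in% 1:3)
  new_session("TRAIN", pattern = as.integer(pattern), S = S, D = D,
              label = label)
}

#' @rdname sessions
#' @export
sess_train_unrelated <- function(S = NULL, D = NULL, label = NULL) {
  new_session("TRAIN_UNRELATED", S = S, D = D, label = label)
}

#' @rdname sessions
#' @export
sess_reexpose <- function(t, S = NULL, D = NULL, label = NULL) {
  if (t < 0 || t > 10) stop("reexposure duration 't' must lie in [0, 10]")
  new_session("REEXPOSE", t = t, S = S, D = D, label = label)
}

#' @rdname sessions
#' @export
sess_test <- function(label = NULL) {
  new_session("TEST", label = label)
}

#' @rdname sessions
#' @export
sess_decay <- function() {
  new_session("DECAY")
}

#' Execute one session on a weight matrix
#'
#' Training and reexposure sessions draw a random initial state
#' `u0 ~ Uniform[0, 0.1]^N` from the current RNG stream, relax the
#' network under the session cue, and apply one plasticity update
#' computed from the final steady state: `w' = clip(w + HLP + MID, +/-s0)`
#' with the session's effective `S` and `D`.  Test sessions relax under
#' the weak context cue, classify the attractor and return the freezing
#' value, leaving the weights untouched.  Decay sessions multiply the
#' weights by `1 - gamma`.
#'
#' @param w Weight matrix.
#' @param session A [sessions] object.
#' @param patterns A [build_patterns()] pattern set.
#' @param params A [model_params()] bundle.
#' @return A list with `w` (possibly updated weights), `converged`, and,
#'   for test sessions, `label` and `freezing`.
#' @export
run_session <- function(w, session, patterns, params = model_params()) {
  stopifnot(inherits(session, "session"),
            inherits(patterns, "pattern_set"))
  kind <- session$kind
  if (kind == "DECAY")
    return(list(w = apply_decay(w, params$gamma), converged = TRUE))

  n <- patterns$n_neurons
  u0 <- runif(n, 0, 0.1)

  if (kind == "TEST") {
    I <- test_cue(patterns, params$test_strength)
    res <- relax(w, I, u0, params)
    label <- classify_attractor(res$u, patterns, params$r_threshold)
    return(list(w = w, converged = res$converged, label = label,
                freezing = freezing_from_label(label), u = res$u))
  }

  I <- switch(kind,
    TRAIN = training_cue(patterns$x[session$pattern, ], params$I_max),
    TRAIN_UNRELATED = training_cue(novel_pattern(patterns), params$I_max),
    REEXPOSE = mixed_cue(session$t, patterns, params$I_max,
                         params$sigmoid_midpoint, params$sigmoid_slope),
    stop("unknown session kind: ", kind))
  res <- relax(w, I, u0, params)
  S_eff <- if (is.null(session$S)) params$S else session$S
  D_eff <- if (is.null(session$D)) params$D else session$D
  hlp <- hlp_matrix(res$u, S_eff)
  m <- mismatch_vector(normalize_cue(I, params$I_max), res$u)
  mid <- mid_matrix(res$u, m, D_eff)
  list(w = update_weights(w, hlp, mid, params$s0),
       converged = res$converged, u = res$u)
}

#' Retrieval test over replicates of a fixed network
#'
#' Draws `n_reps` random initial states, relaxes each under the weak
#' context cue, classifies the reached attractor, and maps retrieval to
#' freezing (90% for the shock pattern, 10% otherwise).
#'
#' @param w Weight matrix (held fixed; tests never update weights).
#' @param patterns A [build_patterns()] pattern set.
#' @param n_reps Number of replicate initializations (>= 1).
#' @param params A [model_params()] bundle.
#' @return A list of class `"freezing_stats"`: `mean`, `sem`, `n`,
#'   `counts` (retrievals per label, `NONE` for no attractor) and the
#'   per-replicate `freezing` vector.
#' @export
run_test <- function(w, patterns, n_reps = 100, params = model_params()) {
  stopifnot(n_reps >= 1)
  labels <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    res <- run_session(w, sess_test(), patterns, params)
    labels[r] <- res$label
  }
  freezing <- freezing_from_label(labels)
  freezing_stats(freezing, labels, rownames(patterns$x))
}

freezing_stats <- function(freezing, labels, pattern_names) {
  n <- length(freezing)
  lab <- factor(ifelse(is.na(labels), "NONE", pattern_names[labels]),
                levels = c(pattern_names, "NONE"))
  structure(list(mean = mean(freezing),
                 sem = if (n > 1) sd(freezing) / sqrt(n) else 0,
                 n = n,
                 counts = table(lab),
                 freezing = freezing),
            class = "freezing_stats")
}

#' @export
print.freezing_stats <- function(x, ...) {
  cat(sprintf("Freezing: %.1f +/- %.2f %% (n = %d)\n", x$mean, x$sem, x$n))
  print(x$counts)
  invisible(x)
}

#' Define a protocol
#'
#' @param sessions Ordered list of [sessions].
#' @param n_replicates Independent replicate simulations; each replicate
#'   runs the whole session sequence on its own evolving weight matrix,
#'   starting from zero weights, so reported SEMs cover whole-protocol
#'   variability (default 100).
#' @param seed Optional RNG seed; each replicate gets its own derived
#'   seed, making results invariant to replicate execution order.
#' @param patterns Pattern set (default [build_patterns()]).
#' @param params Parameter bundle (default [model_params()]).
#' @param label Free-text protocol label carried into result tables.
#' @return A list of class `"protocol_spec"`.
#' @export
protocol_spec <- function(sessions, n_replicates = 100, seed = NULL,
                          patterns = build_patterns(),
                          params = model_params(), label = "") {
  stopifnot(is.list(sessions), length(sessions) >= 1,
            all(vapply(sessions, inherits, logical(1), "session")),
            n_replicates >= 1)
  kinds <- vapply(sessions, `[[`, character(1), "kind")
  first_test <- match("TEST", kinds)
  first_train <- match("TRAIN", kinds)
  if (!is.na(first_test) && (is.na(first_train) || first_test < first_train))
    warning("protocol has a TEST session before any TRAIN session")
  structure(list(sessions = sessions, n_replicates = n_replicates,
                 seed = seed, patterns = patterns, params = params,
                 label = label),
            class = "protocol_spec")
}

#' Run a protocol over replicates
#'
#' Executes the full session sequence once per replicate (weights evolve
#' within each replicate, starting from the untrained zero matrix) and
#' aggregates freezing over replicates for every test session.
#'
#' @param spec A [protocol_spec()].
#' @return A data frame with one row per test session: `protocol`,
#'   `test_index`, `session_index`, `session_label`, `mean_freezing`,
#'   `sem_freezing`, `n_replicates`, retrieval counts
#'   (`n_unrelated`, `n_shock`, `n_nonshock`, `n_none`) and
#'   `n_nonconverged` (replicates in which any relaxation hit the time
#'   cap).  The per-replicate freezing matrix is attached as attribute
#'   `"freezing"`.
#' @examples
#' \donttest{
#' spec <- protocol_spec(list(sess_train(1), sess_train(2), sess_test()),
#'                       n_replicates = 20, seed = 1)
#' run_protocol(spec)
#' }
#' @export
run_protocol <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  sessions <- spec$sessions
  kinds <- vapply(sessions, `[[`, character(1), "kind")
  test_pos <- which(kinds == "TEST")
  n_tests <- length(test_pos)
  n_reps <- spec$n_replicates
  n <- spec$patterns$n_neurons

  rep_seeds <- NULL
  if (!is.null(spec$seed)) {
    set.seed(spec$seed)
    rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  }

  freezing <- matrix(NA_real_, n_reps, max(n_tests, 1L))
  labels <- matrix(NA_integer_, n_reps, max(n_tests, 1L))
  nonconv <- logical(n_reps)

  for (r in seq_len(n_reps)) {
    if (!is.null(rep_seeds)) set.seed(rep_seeds[r])
    w <- zero_weights(n)
    ti <- 0L
    for (s in sessions) {
      out <- run_session(w, s, spec$patterns, spec$params)
      w <- out$w
      if (!isTRUE(out$converged)) nonconv[r] <- TRUE
      if (s$kind == "TEST") {
        ti <- ti + 1L
        freezing[r, ti] <- out$freezing
        labels[r, ti] <- out$label
      }
    }
  }
  if (any(nonconv))
    warning(sum(nonconv), " of ", n_reps,
            " replicates had a relaxation that hit the time cap")

  if (n_tests == 0L) {
    res <- data.frame(protocol = character(0))
    attr(res, "freezing") <- freezing[, 0, drop = FALSE]
    return(res)
  }

  pat_names <- rownames(spec$patterns$x)
  rows <- lapply(seq_len(n_tests), function(k) {
    st <- freezing_stats(freezing[, k], labels[, k], pat_names)
    lbl <- sessions[[test_pos[k]]]$label
    data.frame(protocol = spec$label, test_index = k,
               session_index = test_pos[k],
               session_label = if (is.null(lbl)) "" else lbl,
               mean_freezing = st$mean, sem_freezing = st$sem,
               n_replicates = st$n,
               n_unrelated = as.integer(st$counts[["unrelated"]]),
               n_shock = as.integer(st$counts[["shock"]]),
               n_nonshock = as.integer(st$counts[["nonshock"]]),
               n_none = as.integer(st$counts[["NONE"]]),
               n_nonconverged = sum(nonconv))
  })
  res <- do.call(rbind, rows)
  attr(res, "freezing") <- freezing
  res
}
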