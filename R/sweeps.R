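# The standard nonreinforced-reexposure protocol: learn the unrelated
# and shock memories, one inter-session decay event, one reexposure of
# duration t (with optional per-session drug overrides), then a test.
standard_protocol <- function(t, S_reexp = NULL, D_reexp = NULL,
                              S_train = NULL, pre_test = FALSE) {
  sessions <- list(sess_train(1, S = S_train),
                   sess_train(2, S = S_train))
  if (pre_test) sessions <- c(sessions, list(sess_test("post-training")))
  c(sessions,
    list(sess_decay(),
         sess_reexpose(t, S = S_reexp, D = D_reexp),
         sess_test("post-reexposure")))
}

cell_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Sweep reexposure duration
#'
#' Runs the standard protocol (train unrelated + shock memories, decay,
#' one reexposure, test) at each duration `t`, for each drug condition,
#' with a fresh replicate set per cell.  This is the simulation behind
#' the duration-response summaries (vehicle extinction onset around
#' `t = 8`; the V-shaped anisomycin curve).
#'
#' @param t_values Reexposure durations (default `0:10`).
#' @param conditions Named list of conditions; each entry is a list of
#'   per-reexposure-session overrides among `S`, `D` (empty = vehicle).
#' @param n_replicates Replicates per cell (default 100).
#' @param seed Base seed; every (t, condition) cell derives its own.
#' @param patterns,params Pattern set and parameter bundle.
#' @return Tidy data frame with `t`, `condition`, `mean_freezing`,
#'   `sem_freezing`, retrieval counts and `n_replicates`.
#' @export
sweep_duration <- function(t_values = 0:10,
                           conditions = list(vehicle = list(),
                                             anisomycin = list(S = 0)),
                           n_replicates = 100, seed = 1,
                           patterns = build_patterns(),
                           params = model_params()) {
  stopifnot(length(t_values) >= 1, length(conditions) >= 1)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("'conditions' must be a named list")
  grid <- expand.grid(t = t_values, condition = names(conditions),
                      stringsAsFactors = FALSE)
  seeds <- cell_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cond <- conditions[[grid$condition[i]]]
    spec <- protocol_spec(
      standard_protocol(grid$t[i], S_reexp = cond$S, D_reexp = cond$D),
      n_replicates = n_replicates, seed = seeds[i],
      patterns = patterns, params = params,
      label = "duration_sweep")
    res <- run_protocol(spec)
    data.frame(t = grid$t[i], condition = grid$condition[i],
               mean_freezing = res$mean_freezing,
               sem_freezing = res$sem_freezing,
               n_unrelated = res$n_unrelated, n_shock = res$n_shock,
               n_nonshock = res$n_nonshock, n_none = res$n_none,
               n_replicates = n_replicates)
  })
  do.call(rbind, rows)
}

#' Smallest duration at which extinction occurs in controls
#'
#' The extinction onset: the smallest `t` on the swept grid whose mean
#' freezing falls below the 50% midpoint of the 10/90 freezing map.
#'
#' @param sweep Result of [sweep_duration()].
#' @param condition Condition to inspect (default `"vehicle"`).
#' @param threshold Freezing midpoint (default 50).
#' @return The smallest such `t`, or `NA` if freezing never drops below
#'   the threshold.
#' @export
extinction_onset <- function(sweep, condition = "vehicle",
                             threshold = 50) {
  s <- sweep[sweep$condition == condition, ]
  hit <- s$t[s$mean_freezing < threshold]
  if (length(hit) == 0) NA_real_ else min(hit)
}

#' Sweep the overlap between the shock and extinction patterns
#'
#' Rebuilds the pattern set with `n_shared` coactive neurons between the
#' shock and non-shock patterns (overlap = `n_shared / active_size`) and
#' sweeps reexposure duration under the vehicle condition.  Above a
#' critical overlap, pattern completion reinstates the shock attractor at
#' every duration and extinction never occurs.
#'
#' @param n_shared_values Shared-neuron counts (default `0:14`).
#' @param t_values Reexposure durations per overlap (default `0:10`).
#' @param n_replicates Replicates per cell (default 100).
#' @param seed Base seed.
#' @param params Parameter bundle.
#' @param n_neurons,active_size,cue_size Pattern layout (defaults
#'   100/14/4).
#' @return Tidy data frame with `n_shared`, `overlap_pct`, `t`,
#'   `mean_freezing`, `sem_freezing` and `n_replicates`.
#' @export
sweep_overlap <- function(n_shared_values = 0:14, t_values = 0:10,
                          n_replicates = 100, seed = 1,
                          params = model_params(),
                          n_neurons = 100, active_size = 14,
                          cue_size = 4) {
  grid <- expand.grid(n_shared = n_shared_values, t = t_values)
  seeds <- cell_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ps <- build_patterns(n_neurons, active_size,
                         n_shared = grid$n_shared[i], cue_size = cue_size)
    spec <- protocol_spec(standard_protocol(grid$t[i]),
                          n_replicates = n_replicates, seed = seeds[i],
                          patterns = ps, params = params,
                          label = "overlap_sweep")
    res <- run_protocol(spec)
    data.frame(n_shared = grid$n_shared[i],
               overlap_pct = 100 * grid$n_shared[i] / active_size,
               t = grid$t[i],
               mean_freezing = res$mean_freezing,
               sem_freezing = res$sem_freezing,
               n_replicates = n_replicates)
  })
  do.call(rbind, rows)
}

#' Largest overlap at which extinction still occurs
#'
#' @param sweep Result of [sweep_overlap()].
#' @param threshold Freezing midpoint (default 50).
#' @return The largest `overlap_pct` for which some swept duration
#'   yields mean freezing below the threshold, or `NA` if none does.
#' @export
overlap_boundary <- function(sweep, threshold = 50) {
  ext <- tapply(sweep$mean_freezing < threshold, sweep$overlap_pct, any)
  pct <- as.numeric(names(ext))[ext]
  if (length(pct) == 0) NA_real_ else max(pct)
}

#' Sweep training strength against reexposure duration
#'
#' For each training synthesis factor `S_train` and duration `t`, trains
#' both memories with `S = S_train`, then runs one reexposure with the
#' given reexposure condition (`S_reexp = NULL` keeps the vehicle value;
#' `S_reexp = 0` models anisomycin).  Stronger training shrinks the
#' extinction region and protects the shock memory from reconsolidation
#' blockade.
#'
#' @param S_train_values Training `S` values.
#' @param t_values Reexposure durations.
#' @param S_reexp Reexposure `S` override (`NULL` = vehicle).
#' @param n_replicates,seed,patterns,params As in [sweep_duration()].
#' @return Tidy data frame with `S_train`, `t`, `mean_freezing`,
#'   `sem_freezing` and `n_replicates`.
#' @export
sweep_strength <- function(S_train_values = seq(0.6, 1, by = 0.1),
                           t_values = 0:10, S_reexp = NULL,
                           n_replicates = 100, seed = 1,
                           patterns = build_patterns(),
                           params = model_params()) {
  grid <- expand.grid(S_train = S_train_values, t = t_values)
  seeds <- cell_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- protocol_spec(
      standard_protocol(grid$t[i], S_reexp = S_reexp,
                        S_train = grid$S_train[i]),
      n_replicates = n_replicates, seed = seeds[i],
      patterns = patterns, params = params, label = "strength_sweep")
    res <- run_protocol(spec)
    data.frame(S_train = grid$S_train[i], t = grid$t[i],
               mean_freezing = res$mean_freezing,
               sem_freezing = res$sem_freezing,
               n_replicates = n_replicates)
  })
  do.call(rbind, rows)
}

#' Sweep the reexposure synthesis or degradation factor
#'
#' Holds training at the default parameters and varies `S` (or `D`)
#' during the reexposure session across durations, reproducing the
#' regime summaries: lowering `S` blocks reconsolidation for short and
#' intermediate durations but preserves the memory by blocking
#' extinction at long ones.
#'
#' @param values Values of the swept factor during reexposure.
#' @param which Either `"S"` or `"D"`.
#' @param t_values Reexposure durations.
#' @param n_replicates,seed,patterns,params As in [sweep_duration()].
#' @return Tidy data frame with the swept factor, `t`, `mean_freezing`,
#'   `sem_freezing` and `n_replicates`.
#' @export
sweep_reexposure_factor <- function(values, which = c("S", "D"),
                                    t_values = 0:10,
                                    n_replicates = 100, seed = 1,
                                    patterns = build_patterns(),
                                    params = model_params()) {
  which <- match.arg(which)
  grid <- expand.grid(value = values, t = t_values)
  seeds <- cell_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- protocol_spec(
      standard_protocol(grid$t[i],
                        S_reexp = if (which == "S") grid$value[i] else NULL,
                        D_reexp = if (which == "D") grid$value[i] else NULL),
      n_replicates = n_replicates, seed = seeds[i],
      patterns = patterns, params = params, label = "factor_sweep")
    res <- run_protocol(spec)
    out <- data.frame(value = grid$value[i], t = grid$t[i],
                      mean_freezing = res$mean_freezing,
                      sem_freezing = res$sem_freezing,
                      n_replicates = n_replicates)
    names(out)[1] <- paste0(which, "_reexposure")
    out
  })
  do.call(rbind, rows)
}
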