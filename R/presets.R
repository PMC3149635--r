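#' List the bundled protocol presets
#'
#' Presets are YAML files shipped under `extdata/protocols/`, one per
#' modeled behavioral experiment (training/reexposure sequences with the
#' drug condition of every arm).
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "protocols", package = "memrecon")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

preset_path <- function(name) {
  path <- system.file("extdata", "protocols", paste0(name, ".yaml"),
                      package = "memrecon")
  if (path == "")
    stop("unknown preset '", name, "'; available presets: ",
         paste(list_presets(), collapse = ", "))
  path
}

parse_session <- function(s) {
  kind <- toupper(s$kind)
  switch(kind,
    TRAIN = sess_train(s$pattern, S = s$S, D = s$D, label = s$label),
    TRAIN_UNRELATED = sess_train_unrelated(S = s$S, D = s$D,
                                           label = s$label),
    REEXPOSE = sess_reexpose(s$t, S = s$S, D = s$D, label = s$label),
    TEST = sess_test(label = s$label),
    DECAY = sess_decay(),
    stop("unknown session kind in preset: ", s$kind))
}

#' Load a protocol preset
#'
#' Reads a preset by name (bundled) or from a YAML file path.  A preset
#' declares a label, optional parameter overrides, and one or more
#' *arms* (experimental conditions such as vehicle vs. anisomycin), each
#' an ordered session list.
#'
#' @param name Preset name (see [list_presets()]) or path to a YAML file.
#' @return A list with `label`, `params` overrides and `arms` (a named
#'   list of session lists).
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name else preset_path(name)
  y <- yaml::read_yaml(path)
  if (is.null(y$arms) || length(y$arms) == 0)
    stop("preset '", name, "' declares no arms")
  arms <- lapply(y$arms, function(a) lapply(a$sessions, parse_session))
  list(label = if (is.null(y$label)) name else y$label,
       params = y$params, arms = arms)
}

apply_experiment_overrides <- function(arms, params, set) {
  if (length(set) == 0) return(list(arms = arms, params = params))
  par_keys <- intersect(names(set), names(params))
  params <- override_params(params, set[par_keys])
  rest <- set[setdiff(names(set), par_keys)]
  session_keys <- c("S_train", "D_train", "S_reexposure", "D_reexposure",
                    "t_reexposure")
  unknown <- setdiff(names(rest), session_keys)
  if (length(unknown) > 0)
    stop("unknown override key(s): ", paste(unknown, collapse = ", "))
  arms <- lapply(arms, function(sessions) {
    lapply(sessions, function(s) {
      if (s$kind == "TRAIN") {
        if (!is.null(rest$S_train)) s$S <- rest$S_train
        if (!is.null(rest$D_train)) s$D <- rest$D_train
      } else if (s$kind == "REEXPOSE") {
        if (!is.null(rest$S_reexposure)) s$S <- rest$S_reexposure
        if (!is.null(rest$D_reexposure)) s$D <- rest$D_reexposure
        if (!is.null(rest$t_reexposure)) s$t <- rest$t_reexposure
      }
      s
    })
  })
  list(arms = arms, params = params)
}

#' Run a preset experiment
#'
#' Runs every arm of a preset with the same seed (so arms differ only
#' through their declared drug conditions, which makes vehicle/drug
#' comparisons paired) and binds the per-test freezing statistics into
#' one tidy table.
#'
#' @param preset Preset name or YAML file path (see [load_preset()]).
#' @param n_replicates Replicates per arm (default 100).
#' @param seed RNG seed shared by all arms.
#' @param params Base [model_params()]; preset-level overrides and
#'   `set` entries are applied on top.
#' @param patterns Pattern set (default [build_patterns()]).
#' @param set Named list of overrides: any [model_params()] field, or
#'   `S_train`, `D_train`, `S_reexposure`, `D_reexposure`,
#'   `t_reexposure` to rewrite the corresponding sessions of every arm.
#' @param out_dir If non-`NULL`, write `results.csv`, `summary.json` and
#'   `manifest.json` there (see [write_run()]).
#' @return Tidy data frame: one row per arm x test session, with a
#'   `condition` column naming the arm.
#' @examples
#' \donttest{
#' run_experiment("fig3c", n_replicates = 20, seed = 1)
#' }
#' @export
run_experiment <- function(preset, n_replicates = 100, seed = 1,
                           params = model_params(),
                           patterns = build_patterns(),
                           set = list(), out_dir = NULL) {
  p <- load_preset(preset)
  params <- override_params(params, p$params)
  ov <- apply_experiment_overrides(p$arms, params, set)
  res <- lapply(names(ov$arms), function(arm) {
    spec <- protocol_spec(ov$arms[[arm]], n_replicates = n_replicates,
                          seed = seed, patterns = patterns,
                          params = ov$params, label = p$label)
    out <- run_protocol(spec)
    out$condition <- arm
    out
  })
  res <- do.call(rbind, res)
  res <- res[, c("protocol", "condition",
                 setdiff(names(res), c("protocol", "condition")))]
  if (!is.null(out_dir))
    write_run(res, out_dir,
              config = list(preset = p$label, n_replicates = n_replicates,
                            seed = seed, set = set,
                            params = unclass(ov$params)))
  res
}

#' Write a result table with its manifest
#'
#' Writes `results.csv` (tidy long table), `summary.json` (the same rows
#' as JSON) and `manifest.json` (config snapshot, seed, package version,
#' output paths and wall time) into `out_dir`.
#'
#' @param res Result data frame.
#' @param out_dir Output directory (created if missing).
#' @param config Named list snapshotting the run configuration.
#' @return Invisibly, the manifest list.
#' @export
write_run <- function(res, out_dir, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out_dir, "results.csv")
  js <- file.path(out_dir, "summary.json")
  mf <- file.path(out_dir, "manifest.json")
  write.csv(res, csv, row.names = FALSE)
  jsonlite::write_json(res, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "memrecon",
    version = as.character(utils::packageVersion("memrecon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = c(basename(csv), basename(js)))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
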