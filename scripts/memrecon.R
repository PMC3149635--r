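#!/usr/bin/env Rscript
# Command-line driver for the memrecon attractor-network simulator.
#
# Usage:
#   Rscript scripts/memrecon.R run <preset> [--n-replicates N] [--seed S]
#       [--out DIR] [--set key=value ...]
#   Rscript scripts/memrecon.R sweep <duration|overlap|strength|factor>
#       [--seed S] [--n-replicates N] [--out DIR] [--set key=value ...]
#   Rscript scripts/memrecon.R landscape <preset> [--seed S] [--out DIR]
#   Rscript scripts/memrecon.R capacity [--sizes 100,200,300]
#       [--patterns 1,3,5,10] [--active-size 14] [--cue-size 4]
#       [--trials 200] [--seed S] [--out DIR]
#
# All tabular output is tidy CSV; every run writes a manifest.json next
# to its results.

suppressPackageStartupMessages(library(memrecon))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: memrecon.R <run|sweep|landscape|capacity> [...]\n",
      "       run <preset>: one of ",
      paste(list_presets(), collapse = ", "), "\n", sep = "")
  quit(status = 1L)
}
if (length(args) < 1) usage()
cmd <- args[[1]]
rest <- args[-1]

# minimal flag parser: --key value pairs plus repeated --set key=value
parse_flags <- function(x) {
  flags <- list(set = list())
  pos <- character(0)
  i <- 1
  while (i <= length(x)) {
    a <- x[[i]]
    if (a == "--set") {
      kv <- strsplit(x[[i + 1]], "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("--set expects key=value, got: ", x[[i + 1]])
      val <- suppressWarnings(as.numeric(kv[2]))
      flags$set[[kv[1]]] <- if (is.na(val)) kv[2] else val
      i <- i + 2
    } else if (startsWith(a, "--")) {
      flags[[gsub("-", "_", sub("^--", "", a))]] <- x[[i + 1]]
      i <- i + 2
    } else {
      pos <- c(pos, a)
      i <- i + 1
    }
  }
  flags$positional <- pos
  flags
}

fl <- tryCatch(parse_flags(rest), error = function(e) {
  message(conditionMessage(e)); usage()
})
num <- function(x, default) if (is.null(x)) default else as.numeric(x)
ints <- function(x, default) {
  if (is.null(x)) default else as.integer(strsplit(x, ",")[[1]])
}
seed <- num(fl$seed, 1)
n_reps <- num(fl$n_replicates, 100)
out_dir <- if (is.null(fl$out)) "." else fl$out

status <- 0L
if (cmd == "run") {
  if (length(fl$positional) != 1) usage()
  preset <- fl$positional[[1]]
  if (!(preset %in% list_presets()) && !file.exists(preset)) {
    message("unknown preset '", preset, "'; valid presets: ",
            paste(list_presets(), collapse = ", "))
    quit(status = 1L)
  }
  res <- run_experiment(preset, n_replicates = n_reps, seed = seed,
                        set = fl$set, out_dir = out_dir)
  print(res[, c("condition", "session_label", "mean_freezing",
                "sem_freezing")], row.names = FALSE)
} else if (cmd == "sweep") {
  if (length(fl$positional) != 1) usage()
  kind <- fl$positional[[1]]
  res <- switch(kind,
    duration = sweep_duration(n_replicates = n_reps, seed = seed),
    overlap = sweep_overlap(n_replicates = n_reps, seed = seed),
    strength = sweep_strength(n_replicates = n_reps, seed = seed,
                              S_reexp = fl$set$S_reexposure),
    factor = sweep_reexposure_factor(
      values = if (is.null(fl$values)) seq(0, 1, 0.2) else
        as.numeric(strsplit(fl$values, ",")[[1]]),
      which = if (is.null(fl$which)) "S" else fl$which,
      n_replicates = n_reps, seed = seed),
    { message("unknown sweep '", kind,
              "'; use duration, overlap, strength or factor")
      quit(status = 1L) })
  write_run(res, out_dir, config = list(command = "sweep", kind = kind,
                                        seed = seed,
                                        n_replicates = n_reps))
  cat("wrote", nrow(res), "rows to", file.path(out_dir, "results.csv"),
      "\n")
} else if (cmd == "landscape") {
  if (length(fl$positional) != 1) usage()
  preset <- fl$positional[[1]]
  set.seed(seed)
  ps <- build_patterns()
  pars <- model_params()
  p <- load_preset(preset)
  arm <- p$arms[[1]]
  w <- zero_weights(ps$n_neurons)
  for (s in arm) if (s$kind != "TEST") w <- run_session(w, s, ps, pars)$w
  L <- energy_landscape(w, ps)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(L),
                   file.path(out_dir, "landscape.csv"), row.names = FALSE)
  grDevices::png(file.path(out_dir, "landscape.png"), 800, 700)
  plot(L, main = paste("Energy landscape after", p$label,
                       "(first arm, weights only)"))
  grDevices::dev.off()
  cat("wrote landscape.csv and landscape.png to", out_dir, "\n")
} else if (cmd == "capacity") {
  res <- capacity_curve(n_sizes = ints(fl$sizes, c(100, 200, 300)),
                        p_counts = ints(fl$patterns, c(1, 3, 5, 10, 15)),
                        active_size = num(fl$active_size, 14),
                        cue_size = num(fl$cue_size, 4),
                        n_trials = num(fl$trials, 200), seed = seed)
  write_run(res, out_dir, config = list(command = "capacity",
                                        seed = seed))
  print(res, row.names = FALSE)
} else {
  usage()
}
quit(status = status)
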