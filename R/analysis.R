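#' Lyapunov energy of a network state
#'
#' The quadratic Hopfield energy `E(u) = -1/2 * sum_ij w_ij u_i u_j`,
#' optionally including the cue term `- sum_i I_i u_i`.  Landscapes are
#' drawn for the no-cue network by default, matching free recall.
#'
#' @param w Weight matrix.
#' @param u Activity vector.
#' @param I Optional cue current vector; if supplied, its linear term is
#'   included.
#' @return Scalar energy.
#' @examples
#' network_energy(matrix(0, 3, 3), rep(1, 3))  # 0
#' @export
network_energy <- function(w, u, I = NULL) {
  w <- check_weights(w)
  if (length(u) != nrow(w))
    stop("'u' has length ", length(u), " but 'w' is ", nrow(w), " x ",
         ncol(w))
  e <- -0.5 * drop(crossprod(u, w %*% u))
  if (!is.null(I)) e <- e - sum(I * u)
  e
}

#' Multiple discriminant analysis projection of the pattern set
#'
#' Eigen-decomposes the between-pattern scatter matrix
#' `S_b = sum_c (mu_c - mu)(mu_c - mu)'` (with `mu_c` the stored
#' patterns and `mu` their global mean) and keeps the top `P - 1`
#' eigenvectors, giving the low-dimensional encoding subspace in which
#' the attractor basins are visualized (a plane for the default 3
#' patterns).  Eigenvector signs follow a deterministic convention
#' (first nonzero component positive).
#'
#' @param patterns A [build_patterns()] pattern set, or a numeric matrix
#'   with one pattern per row.
#' @return A list of class `"mda_projection"`: `basis` (`(P-1) x N`,
#'   orthonormal rows), `values` (eigenvalues), `mu` (global mean),
#'   `pattern_coords` (projected stored patterns, one row each).
#' @export
mda_projection <- function(patterns) {
  x <- if (inherits(patterns, "pattern_set")) patterns$x else
    as.matrix(patterns)
  P <- nrow(x)
  if (P < 2) stop("need at least 2 patterns to build a projection")
  mu <- colMeans(x)
  centered <- sweep(x, 2, mu)
  Sb <- crossprod(centered)  # sum of (mu_c - mu)(mu_c - mu)'
  eig <- eigen(Sb, symmetric = TRUE)
  keep <- min(P - 1, sum(eig$values > max(eig$values) * 1e-10))
  if (keep < P - 1)
    warning("between-pattern scatter is rank-deficient (identical ",
            "patterns?): returning ", keep, " basis vector(s)")
  basis <- t(eig$vectors[, seq_len(keep), drop = FALSE])
  # deterministic sign: first nonzero component of each row positive
  for (i in seq_len(nrow(basis))) {
    nz <- which(abs(basis[i, ]) > 1e-12)[1]
    if (!is.na(nz) && basis[i, nz] < 0) basis[i, ] <- -basis[i, ]
  }
  structure(list(basis = basis, values = eig$values[seq_len(keep)],
                 mu = mu,
                 pattern_coords = centered %*% t(basis)),
            class = "mda_projection")
}

#' Project activity states into the MDA subspace
#'
#' @param proj An [mda_projection()].
#' @param u A state vector, or a matrix with one state per row.
#' @return Matrix of projected coordinates (one row per state).
#' @export
project_states <- function(proj, u) {
  stopifnot(inherits(proj, "mda_projection"))
  u <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  sweep(u, 2, proj$mu) %*% t(proj$basis)
}

#' Energy landscape over the MDA plane
#'
#' Samples network states (half uniform-random binary states with
#' `active_size` active neurons, covering basin ridges; half states
#' relaxed from random `Uniform[0, 0.1]` initializations with no cue,
#' covering basin interiors), computes each state's energy in the
#' original `N`-dimensional space, projects the states onto the MDA
#' plane, and assigns every grid cell the mean energy of its
#' `k_neighbors` nearest sampled points.
#'
#' @param w Weight matrix.
#' @param patterns A [build_patterns()] pattern set (supplies sizes and
#'   the projection targets).
#' @param proj Optional [mda_projection()]; computed from `patterns` if
#'   missing.
#' @param n_samples Total sampled states (default 2000).
#' @param k_neighbors Neighbors averaged per grid cell (default 20).
#' @param grid_res Grid resolution per axis (default 50).
#' @param params A [model_params()] bundle (for the relaxed samples).
#' @return A data frame of class `"energy_landscape"` with columns `x`,
#'   `y`, `energy` and `n_in_cell` (sampled states falling inside the
#'   cell; 0 marks cells whose energy is interpolated from neighbors,
#'   not directly sampled).  The projected stored patterns are attached
#'   as attribute `"pattern_coords"`.
#' @export
energy_landscape <- function(w, patterns, proj = NULL,
                             n_samples = 2000, k_neighbors = 20,
                             grid_res = 50, params = model_params()) {
  stopifnot(inherits(patterns, "pattern_set"), n_samples >= k_neighbors,
            k_neighbors >= 1, grid_res >= 2)
  w <- check_weights(w)
  n <- patterns$n_neurons
  if (is.null(proj)) proj <- mda_projection(patterns)
  if (nrow(proj$basis) < 2)
    stop("energy landscape needs a 2-D projection (3 distinct patterns)")

  n_binary <- floor(n_samples / 2)
  n_relaxed <- n_samples - n_binary
  states <- matrix(0, n_samples, n)
  for (i in seq_len(n_binary)) {
    states[i, sample.int(n, patterns$active_size)] <- 1
  }
  no_cue <- numeric(n)
  for (i in seq_len(n_relaxed)) {
    u0 <- runif(n, 0, 0.1)
    states[n_binary + i, ] <- relax(w, no_cue, u0, params)$u
  }

  energies <- apply(states, 1, function(u) network_energy(w, u))
  coords <- project_states(proj, states)
  pat_coords <- proj$pattern_coords[, 1:2, drop = FALSE]

  rx <- range(c(coords[, 1], pat_coords[, 1]))
  ry <- range(c(coords[, 2], pat_coords[, 2]))
  pad <- 0.02
  rx <- rx + c(-1, 1) * pad * diff(rx)
  ry <- ry + c(-1, 1) * pad * diff(ry)
  gx <- seq(rx[1], rx[2], length.out = grid_res)
  gy <- seq(ry[1], ry[2], length.out = grid_res)
  grid <- expand.grid(x = gx, y = gy)

  d2 <- outer(grid$x, coords[, 1], "-")^2 +
    outer(grid$y, coords[, 2], "-")^2
  k <- k_neighbors
  cell_energy <- apply(d2, 1, function(d) {
    mean(energies[order(d)[seq_len(k)]])
  })
  sx <- diff(gx[1:2]) / 2
  sy <- diff(gy[1:2]) / 2
  n_in_cell <- vapply(seq_len(nrow(grid)), function(i) {
    sum(abs(coords[, 1] - grid$x[i]) <= sx &
          abs(coords[, 2] - grid$y[i]) <= sy)
  }, integer(1))

  out <- data.frame(x = grid$x, y = grid$y, energy = cell_energy,
                    n_in_cell = n_in_cell)
  class(out) <- c("energy_landscape", "data.frame")
  attr(out, "pattern_coords") <- pat_coords
  out
}

#' @export
plot.energy_landscape <- function(x, ...) {
  gx <- sort(unique(x$x))
  gy <- sort(unique(x$y))
  z <- matrix(x$energy, nrow = length(gx))
  graphics::image(gx, gy, z, xlab = "MDA 1", ylab = "MDA 2",
                  col = grDevices::hcl.colors(64, "Blue-Red 3",
                                              rev = TRUE), ...)
  pc <- attr(x, "pattern_coords")
  if (!is.null(pc)) {
    graphics::points(pc[, 1], pc[, 2], pch = 21, bg = "white", cex = 1.4)
    graphics::text(pc[, 1], pc[, 2], labels = rownames(pc), pos = 3)
  }
  invisible(x)
}

# Energy of the grid cell nearest to a projected point.
landscape_energy_at <- function(landscape, point) {
  d2 <- (landscape$x - point[1])^2 + (landscape$y - point[2])^2
  landscape$energy[which.min(d2)]
}

#' Storage-capacity curves
#'
#' For each network size and pattern count, stores random sparse binary
#' patterns sequentially with the Hebbian rule only (full-strength cues,
#' saturation at `s0`), then runs retrieval trials: a randomly chosen
#' stored pattern is cued through `cue_size` of its active neurons at
#' the weak test strength from a random initial state, and retrieval
#' succeeds when the Pearson correlation between the relaxed state and
#' the target pattern exceeds `r_threshold`.
#'
#' @param n_sizes Network sizes.
#' @param p_counts Numbers of stored patterns.
#' @param active_size Active neurons per pattern (default 14; halving
#'   pattern and cue size raises capacity).
#' @param cue_size Cued neurons per retrieval trial (default 4).
#' @param n_trials Retrieval trials per (size, count) cell (default 200).
#' @param params A [model_params()] bundle.
#' @param cue_strength Current on the cued neurons; defaults to the full
#'   training strength `params$I_max` (a partial but unambiguous cue, so
#'   that failures measure storage interference rather than cue
#'   weakness).
#' @param seed Optional seed for reproducible curves.
#' @return Data frame with `n_neurons`, `n_patterns`, `success_frac`,
#'   `n_trials` and `r_threshold`.
#' @export
capacity_curve <- function(n_sizes = c(100, 200, 300),
                           p_counts = c(1, 3, 5, 10, 15, 20),
                           active_size = 14, cue_size = 4,
                           n_trials = 200, params = model_params(),
                           cue_strength = NULL, seed = NULL) {
  if (is.null(cue_strength)) cue_strength <- params$I_max
  stopifnot(active_size <= min(n_sizes), cue_size <= active_size,
            n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (n in n_sizes) {
    for (p in p_counts) {
      pats <- matrix(0, p, n)
      for (c in seq_len(p)) pats[c, sample.int(n, active_size)] <- 1
      w <- zero_weights(n)
      for (c in seq_len(p)) {
        u0 <- runif(n, 0, 0.1)
        cue <- training_cue(pats[c, ], params$I_max)
        st <- relax(w, cue, u0, params)$u
        w <- update_weights(w, hlp_matrix(st, params$S), 0, params$s0)
      }
      ok <- 0L
      for (trial in seq_len(n_trials)) {
        target <- sample.int(p, 1)
        cue_idx <- sample(which(pats[target, ] == 1), cue_size)
        I <- numeric(n)
        I[cue_idx] <- cue_strength
        u0 <- runif(n, 0, 0.1)
        u <- relax(w, I, u0, params)$u
        if (sd(u) > 0 &&
            cor(u, pats[target, ]) > params$r_threshold) ok <- ok + 1L
      }
      rows[[length(rows) + 1L]] <-
        data.frame(n_neurons = n, n_patterns = p,
                   success_frac = ok / n_trials, n_trials = n_trials,
                   r_threshold = params$r_threshold)
    }
  }
  do.call(rbind, rows)
}
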