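# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Polynomial least squares via explicit normal equations.
oracle_polyfit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

oracle_polyeval <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)
}

# OLS via normal equations for an arbitrary design matrix.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Brute-force Ward agglomeration: at each step compute the within-SS
# increase for every cluster pair and merge the minimum (ties: lowest index
# pair). Returns the list of partitions after each merge and the increases.
oracle_ward <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  partitions <- list()
  increases <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        A <- X[clusters[[i]], , drop = FALSE]
        B <- X[clusters[[j]], , drop = FALSE]
        ca <- colMeans(A); cb <- colMeans(B)
        dss <- nrow(A) * nrow(B) / (nrow(A) + nrow(B)) * sum((ca - cb)^2)
        if (dss < best[1] - 1e-12) best <- c(dss, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    clusters[[j]] <- NULL
    increases <- c(increases, best[1])
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, identity)
  }
  list(partitions = partitions, increases = increases)
}

# Canonical form of a partition (list of index vectors) for comparison.
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, min, numeric(1)))]
}

# Partition of 1..n after the first m merges of an hclust-style merge matrix.
partition_after <- function(merge, n, m) {
  members <- lapply(seq_len(n), identity)  # singletons by negative index
  merged_sets <- list()
  alive <- rep(TRUE, n)
  for (s in seq_len(m)) {
    get <- function(idx) {
      if (idx < 0) { alive[-idx] <<- FALSE; -idx }
      else { out <- merged_sets[[idx]]; merged_sets[idx] <<- list(NULL); out }
    }
    merged_sets[[s]] <- sort(c(get(merge[s, 1]), get(merge[s, 2])))
  }
  live <- Filter(Negate(is.null), merged_sets)
  c(lapply(which(alive), identity), live)
}

# Brute-force integer cross-correlation peak between two frames.
oracle_xcorr_shift <- function(ref, frame, max_shift = 6) {
  d <- dim(ref)
  best <- c(-Inf, NA, NA)
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
      xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
      s <- sum(ref[ys - dy, xs - dx] * frame[ys, xs])
      if (s > best[1]) best <- c(s, dx, dy)
    }
  }
  best[2:3]  # (dx, dy) such that frame ~= ref shifted by (dx, dy)
}

# Total within-cluster sum of squares of a partition.
within_ss <- function(X, labels) {
  sum(vapply(unique(labels), function(g) {
    sub <- X[labels == g, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

# Small rendered test scene: a handful of bright cells in a reduced volume.
make_small_scene <- function(n_cells = 12, seed = 7, n_volumes = 20,
                             noise = "none") {
  geom <- acquisition_geometry(fov_x = 96, fov_y = 64, z_range = 36,
                               n_x = 48, n_y = 32, n_planes = 6,
                               frame_rate = 6)
  gt <- generate_brain(geom, n_cells, seed = seed, min_distance = 10,
                       responsive_fraction = 0.5)
  prot <- stimulus_protocol(onsets = c(4, 10), stim_duration = 2,
                            dot_diameter = 5, screen_distance = 30)
  model <- activity_model(noise = noise, baseline_rate = 0.05,
                          stim_response_prob = 1)
  traces <- generate_activity(gt, prot, model, duration = n_volumes,
                              rate = 1, seed = seed + 1)
  list(geom = geom, gt = gt, prot = prot, model = model, traces = traces)
}
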