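# Independent oracles, deliberately naive: straight loops over definitions.

# interface count by enumerating every voxel and its 6 faces
bf_interface_count <- function(labels) {
  labels <- unclass(labels)
  d <- dim(labels)
  cnt <- 0L
  steps <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (labels[z, y, x] != 1L) next
    for (k in 1:6) {
      p <- c(z, y, x) + steps[k, ]
      if (any(p < 1L) || any(p > d)) next
      if (labels[p[1], p[2], p[3]] == 3L) { cnt <- cnt + 1L; break }
    }
  }
  cnt
}

# best Youden J over every threshold including the infinities, rule >=
bf_youden <- function(values, outcomes) {
  cand <- c(-Inf, sort(unique(values)), Inf)
  j <- vapply(cand, function(ct) {
    mean(values[outcomes == 1] >= ct) + mean(values[outcomes == 0] < ct) - 1
  }, 0)
  best <- max(j)
  obs <- sort(unique(values))
  jobs <- vapply(obs, function(ct) {
    mean(values[outcomes == 1] >= ct) + mean(values[outcomes == 0] < ct) - 1
  }, 0)
  list(j = best, cutoff = obs[which(jobs == best)[1]])
}

# AUC as the Mann-Whitney statistic with midranks
bf_auc <- function(scores, outcomes) {
  r <- rank(scores)
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small, quick phantom for unit tests (default grid is used in the
# recovery tests, this one elsewhere)
small_phantom_config <- function(..., grid_shape = c(24L, 64L, 64L),
                                 voxel_spacing_mm = c(3, 1.25, 1.25),
                                 tumor_radius_mm = 8) {
  phantom_config(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
                 tumor_radius_mm = tumor_radius_mm, ...)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
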