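# Independent oracles and small fixture builders used across the suite.

# Build a minimal planar surface_grid from a logical covered matrix
# (periodic in both axes, unit cell weights), constructing the neighbor
# table with plain double loops so it does not share code with the
# package's vectorized grid construction.
make_planar_grid <- function(covered, cell_area = 1, leaflet = "upper") {
  nx <- nrow(covered); ny <- ncol(covered)
  n <- nx * ny
  nbr4 <- matrix(NA_integer_, n, 4)
  idx <- function(i, j) ((j - 1) %% ny) * nx + ((i - 1) %% nx) + 1
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      c0 <- idx(i, j)
      nbr4[c0, ] <- c(idx(i - 1, j), idx(i + 1, j),
                      idx(i, j - 1), idx(i, j + 1))
    }
  }
  nbr4[nbr4 == seq_len(n)] <- NA_integer_
  coords <- cbind(rep(seq_len(nx), ny) - 0.5,
                  rep(seq_len(ny), each = nx) - 0.5)
  structure(list(projection = "planar", covered = as.vector(covered),
                 weight = rep(cell_area, n), nbr4 = nbr4,
                 coords = coords, dims = c(nx, ny),
                 Lx = nx, Ly = ny, total_area = n * cell_area,
                 leaflet = leaflet, cell_size = sqrt(cell_area)),
            class = "surface_grid")
}

# Exhaustive queue-based flood fill on a logical covered matrix with
# periodic wrap; returns an integer component label per uncovered cell
# (0 for covered cells). Deliberately naive: scans every cell, grows
# each component cell by cell.
flood_fill_oracle <- function(covered, connectivity = 4) {
  nx <- nrow(covered); ny <- ncol(covered)
  lab <- matrix(0L, nx, ny)
  steps <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    steps <- c(steps, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  comp <- 0L
  for (j0 in seq_len(ny)) for (i0 in seq_len(nx)) {
    if (covered[i0, j0] || lab[i0, j0] != 0L) next
    comp <- comp + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- comp
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (s in steps) {
        i <- (cur[1] - 1 + s[1]) %% nx + 1
        j <- (cur[2] - 1 + s[2]) %% ny + 1
        if (!covered[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- comp
          queue <- c(queue, list(c(i, j)))
        }
      }
    }
  }
  lab
}

# Canonical partition signature: cells grouped by component, each group
# sorted, groups sorted by first member — comparable across labelings.
partition_signature <- function(cells, labels) {
  groups <- lapply(split(cells, labels), sort)
  unname(groups[order(vapply(groups, min, numeric(1)))])
}

# Brute-force nearest-neighbor distances between rows of a point matrix.
nn_distances <- function(p) {
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  apply(d, 1, min)
}

# Compare package components (with keep_cells = TRUE) against the
# oracle labeling: identical partitions of the uncovered cells.
expect_same_partition <- function(defects_df, oracle_lab) {
  un <- which(as.vector(oracle_lab) != 0L)
  sig_oracle <- partition_signature(un, as.vector(oracle_lab)[un])
  cells <- attr(defects_df, "cells")
  sig_pkg <- partition_signature(unlist(cells),
                                 rep(seq_along(cells),
                                     lengths(cells)))
  expect_identical(sig_pkg, sig_oracle)
}
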