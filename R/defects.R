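#' @title Interfacial surface grids
#' @description
#' A `surface_grid` discretizes one leaflet's interfacial surface into
#' cells with per-cell area weights and an occupancy state. Flat patches
#' map to a periodic Cartesian grid; tubules to an unrolled
#' (theta * R, z) grid periodic in both axes; vesicles to a cube-sphere
#' atlas of six gnomonic faces with exact per-cell spherical area weights
#' and recorded cross-face adjacency. A cell is covered iff at least one
#' polar-bead occlusion disc reaches the cell center's position on the
#' surface (geodesic distance on curved surfaces), so the projection
#' only rasterizes and never distorts the coverage rule.
#' @name surface_grid
NULL

# cube-sphere face bases: p(u, v) = normalize(u*e1 + v*e2 + n)
cube_faces <- function() {
  list(
    list(n = c(0, 0, 1),  e1 = c(1, 0, 0),  e2 = c(0, 1, 0)),
    list(n = c(0, 0, -1), e1 = c(1, 0, 0),  e2 = c(0, -1, 0)),
    list(n = c(1, 0, 0),  e1 = c(0, 1, 0),  e2 = c(0, 0, 1)),
    list(n = c(-1, 0, 0), e1 = c(0, -1, 0), e2 = c(0, 0, 1)),
    list(n = c(0, 1, 0),  e1 = c(0, 0, 1),  e2 = c(1, 0, 0)),
    list(n = c(0, -1, 0), e1 = c(0, 0, -1), e2 = c(1, 0, 0)))
}

# locate points (n x 3, on the unit sphere) : face id and (u, v)
cube_locate <- function(p) {
  faces <- cube_faces()
  dots <- vapply(faces, function(f) p %*% f$n, numeric(nrow(p)))
  if (nrow(p) == 1) dots <- matrix(dots, nrow = 1)
  face <- max.col(dots, ties.method = "first")
  u <- v <- numeric(nrow(p))
  for (k in seq_along(faces)) {
    i <- face == k
    if (!any(i)) next
    s <- dots[i, k]
    u[i] <- (p[i, , drop = FALSE] %*% faces[[k]]$e1) / s
    v[i] <- (p[i, , drop = FALSE] %*% faces[[k]]$e2) / s
  }
  list(face = face, u = u, v = v)
}

#' Project a leaflet surface onto an occupancy grid
#'
#' @param config A `membrane_config`.
#' @param leaflet Leaflet to scan (`"upper"`/`"lower"` or
#'   `"outer"`/`"inner"`).
#' @param cell_size Nominal cell edge (Angstrom, > 0; default 1).
#' @return A `surface_grid`: list with `projection`, `covered` (logical
#'   per cell), `weight` (Angstrom^2 per cell), `nbr4` (integer matrix
#'   of 4-neighbors honoring periodic wrap / cross-face adjacency),
#'   `coords` (projection coordinates per cell), `total_area`, and
#'   bookkeeping fields. If the leaflet carries no bead the grid is
#'   all-uncovered and flagged with attribute `empty_leaflet`.
#' @export
project_surface <- function(config, leaflet, cell_size = 1) {
  stopifnot(inherits(config, "membrane_config"))
  if (cell_size <= 0) stop("cell_size must be > 0")
  b <- config$beads
  pb <- b[b$bead_class == "polar" & b$leaflet == leaflet, , drop = FALSE]
  surf <- leaflet_surface(config, leaflet)
  grid <- switch(config$geometry,
    flat = grid_planar(pb, surf, cell_size, "planar"),
    cylinder = grid_cylinder(pb, surf, cell_size),
    sphere = grid_sphere(pb, surf, cell_size))
  grid$leaflet <- leaflet
  grid$cell_size <- cell_size
  if (nrow(pb) == 0) attr(grid, "empty_leaflet") <- TRUE
  class(grid) <- "surface_grid"
  grid
}

#' @export
print.surface_grid <- function(x, ...) {
  cat("Surface grid (", x$projection, "), ", length(x$covered),
      " cells, leaflet ", x$leaflet, "\n", sep = "")
  cat("  scanned area:", signif(x$total_area, 6), "A^2;",
      "uncovered fraction:",
      signif(mean(!x$covered), 4), "\n")
  invisible(x)
}

# periodic Cartesian grid over Lx x Ly; beads as (x, y) with per-bead radius
grid_planar <- function(pb, surf, cell_size, projection,
                        Lx = surf$Lx, Ly = surf$Ly,
                        bx = pb$x, by = pb$y) {
  if (Lx <= 0 || Ly <= 0) {
    return(list(projection = projection, covered = logical(0),
                weight = numeric(0), nbr4 = matrix(integer(0), 0, 4),
                coords = matrix(numeric(0), 0, 2), dims = c(0L, 0L),
                total_area = 0))
  }
  nx <- max(1L, as.integer(round(Lx / cell_size)))
  ny <- max(1L, as.integer(round(Ly / cell_size)))
  csx <- Lx / nx; csy <- Ly / ny
  covered <- matrix(FALSE, nx, ny)
  if (length(bx) > 0) {
    r <- pb$cover_radius
    bx <- bx %% Lx; by <- by %% Ly
    for (i in seq_along(bx)) {
      wx <- ceiling(r[i] / csx); wy <- ceiling(r[i] / csy)
      ix <- (floor(bx[i] / csx) + (-wx):wx) %% nx
      iy <- (floor(by[i] / csy) + (-wy):wy) %% ny
      cx <- (ix + 0.5) * csx; cy <- (iy + 0.5) * csy
      dx <- abs(cx - bx[i]); dx <- pmin(dx, Lx - dx)
      dy <- abs(cy - by[i]); dy <- pmin(dy, Ly - dy)
      hit <- outer(dx^2, dy^2, "+") <= r[i]^2
      covered[ix + 1L, iy + 1L] <- covered[ix + 1L, iy + 1L] | hit
    }
  }
  n <- nx * ny
  idx <- matrix(seq_len(n), nx, ny)
  shift <- function(m, dx, dy) {
    m[(seq_len(nx) - 1 + dx) %% nx + 1, (seq_len(ny) - 1 + dy) %% ny + 1,
      drop = FALSE]
  }
  nbr4 <- cbind(as.vector(shift(idx, -1, 0)), as.vector(shift(idx, 1, 0)),
                as.vector(shift(idx, 0, -1)), as.vector(shift(idx, 0, 1)))
  # degenerate axes (single row/col): drop self-neighbors
  nbr4[nbr4 == seq_len(n)] <- NA_integer_
  coords <- cbind((as.vector(row(idx)) - 0.5) * csx,
                  (as.vector(col(idx)) - 0.5) * csy)
  list(projection = projection, covered = as.vector(covered),
       weight = rep(csx * csy, n), nbr4 = nbr4, coords = coords,
       dims = c(nx, ny), Lx = Lx, Ly = Ly, total_area = Lx * Ly)
}

# cylinder: unroll to (R*theta, z); geodesic distance is the unrolled
# Euclidean distance, so the planar kernel applies verbatim
grid_cylinder <- function(pb, surf, cell_size) {
  th <- atan2(pb$y, pb$x) %% (2 * pi)
  grid_planar(pb, surf, cell_size, "cylindrical-unroll",
              Lx = 2 * pi * surf$R, Ly = surf$L,
              bx = th * surf$R, by = pb$z %% surf$L)
}

# cube-sphere atlas
grid_sphere <- function(pb, surf, cell_size) {
  R <- surf$R
  n_side <- max(2L, as.integer(round(2 * R / cell_size)))
  du <- 2 / n_side
  faces <- cube_faces()
  ctr <- (seq_len(n_side) - 0.5) * du - 1
  uu <- matrix(ctr, n_side, n_side)
  vv <- matrix(ctr, n_side, n_side, byrow = TRUE)
  per_face <- n_side * n_side
  n <- 6L * per_face
  cell_of <- function(w) pmin(pmax(floor((w + 1) / du), 0), n_side - 1)
  # cell centers in 3D and exact-ish area weights (midpoint Jacobian)
  coords3 <- matrix(NA_real_, n, 3)
  weight <- numeric(n)
  for (k in 1:6) {
    f <- faces[[k]]
    denom <- sqrt(1 + uu^2 + vv^2)
    px <- (uu * f$e1[1] + vv * f$e2[1] + f$n[1]) / denom
    py <- (uu * f$e1[2] + vv * f$e2[2] + f$n[2]) / denom
    pz <- (uu * f$e1[3] + vv * f$e2[3] + f$n[3]) / denom
    rows <- (k - 1L) * per_face + seq_len(per_face)
    coords3[rows, ] <- cbind(as.vector(px), as.vector(py), as.vector(pz)) * R
    weight[rows] <- R^2 * du^2 / as.vector(denom)^3
  }
  # coverage: per bead, mark cells within geodesic reach on each face it
  # projects onto (faces it faces, with margin for edge overlap)
  covered <- logical(n)
  if (nrow(pb) > 0) {
    bp <- as.matrix(pb[, c("x", "y", "z")])
    bp <- bp / sqrt(rowSums(bp^2))      # unit vectors
    r <- pb$cover_radius
    for (k in 1:6) {
      f <- faces[[k]]
      s <- as.numeric(bp %*% f$n)
      cand <- which(s > 0.3)
      if (length(cand) == 0) next
      ub <- as.numeric(bp[cand, , drop = FALSE] %*% f$e1) / s[cand]
      vb <- as.numeric(bp[cand, , drop = FALSE] %*% f$e2) / s[cand]
      # generous window: gnomonic stretch factor <= (1+u^2+v^2)
      mrg <- (r[cand] / R) * (1 + ub^2 + vb^2) * 1.5 + du
      sel <- abs(ub) <= 1 + mrg & abs(vb) <= 1 + mrg
      cand <- cand[sel]; ub <- ub[sel]; vb <- vb[sel]; mrg <- mrg[sel]
      for (j in seq_along(cand)) {
        iu <- cell_of(ub[j] - mrg[j]):cell_of(ub[j] + mrg[j])
        iv <- cell_of(vb[j] - mrg[j]):cell_of(vb[j] + mrg[j])
        cells <- (k - 1L) * per_face + outer(iu + 1L, iv * n_side, "+")
        ca <- coords3[cells, , drop = FALSE] %*% bp[cand[j], ] / R
        geo <- R * acos(pmin(1, pmax(-1, as.numeric(ca))))
        covered[cells[geo <= r[cand[j]]]] <- TRUE
      }
    }
  }
  # 4-neighbors: in-face by index; across edges geometrically
  nbr4 <- matrix(NA_integer_, n, 4)
  within <- function(iu, iv, k) (k - 1L) * per_face + iv * n_side + iu + 1L
  iu_all <- rep(rep(0:(n_side - 1L), n_side), 6)
  iv_all <- rep(rep(0:(n_side - 1L), each = n_side), 6)
  face_all <- rep(1:6, each = per_face)
  steps <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in seq_along(steps)) {
    iu2 <- iu_all + steps[[s]][1]
    iv2 <- iv_all + steps[[s]][2]
    inside <- iu2 >= 0 & iu2 < n_side & iv2 >= 0 & iv2 < n_side
    nbr4[inside, s] <- within(iu2[inside], iv2[inside], face_all[inside])
    out <- which(!inside)
    if (length(out) > 0) {
      # step beyond the face edge in gnomonic coords, then relocate
      u2 <- (iu2[out] + 0.5) * du - 1
      v2 <- (iv2[out] + 0.5) * du - 1
      p2 <- matrix(NA_real_, length(out), 3)
      for (k in 1:6) {
        i <- face_all[out] == k
        if (!any(i)) next
        f <- faces[[k]]
        raw <- cbind(u2[i]) %*% rbind(f$e1) + cbind(v2[i]) %*% rbind(f$e2) +
          matrix(f$n, sum(i), 3, byrow = TRUE)
        p2[i, ] <- raw / sqrt(rowSums(raw^2))
      }
      loc <- cube_locate(p2)
      nbr4[out, s] <- within(cell_of(loc$u), cell_of(loc$v), loc$face)
    }
  }
  list(projection = "spherical-cube-atlas", covered = covered,
       weight = weight, nbr4 = nbr4,
       coords = cbind(iu_all, iv_all), coords3 = coords3,
       dims = c(n_side, n_side), n_faces = 6L, R = R,
       total_area = sum(weight))
}
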