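#' @title Bead-model membrane configurations
#' @description Internal constructor for `membrane_config` objects.
#' @noRd
new_membrane_config <- function(geometry, dimensions, beads,
                                area_per_lipid, half_thickness,
                                leaflet_mode = "midplane",
                                ground_truth_voids = NULL) {
  structure(list(geometry = geometry, dimensions = dimensions,
                 beads = beads, area_per_lipid = area_per_lipid,
                 half_thickness = half_thickness,
                 leaflet_mode = leaflet_mode,
                 ground_truth_voids = ground_truth_voids),
            class = "membrane_config")
}

empty_beads <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             bead_class = character(0), species = character(0),
             leaflet = character(0), lipid_id = integer(0),
             cover_radius = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.membrane_config <- function(x, ...) {
  cat("Bead-model membrane (", x$geometry, ")\n", sep = "")
  cat("  dimensions:",
      paste(names(x$dimensions), unlist(x$dimensions), sep = "=",
            collapse = ", "), "Angstrom\n")
  cat("  beads:", nrow(x$beads), " (",
      sum(x$beads$bead_class == "polar"), "polar )\n")
  cat("  area per lipid:", x$area_per_lipid, "A^2;",
      "half thickness:", x$half_thickness, "A\n")
  if (!is.null(x$ground_truth_voids)) {
    cat("  ground-truth voids:", nrow(x$ground_truth_voids), "\n")
  }
  invisible(x)
}

# Draw n species assignments from the composition (seeded upstream).
draw_species <- function(comp, n) {
  if (n == 0) return(character(0))
  sample(comp$name, n, replace = TRUE, prob = comp$fraction)
}

# One lipid -> one polar bead at the interfacial surface plus aliphatic
# beads stacked towards the mid-plane. `inward` is a unit vector (or
# matrix of unit vectors) pointing from the interface to the mid-plane.
lipid_beads <- function(pos, inward, species, leaflet, comp, id0) {
  n <- nrow(pos)
  if (n == 0) return(empty_beads())
  cr <- comp$cover_radius[match(species, comp$name)]
  sterol <- comp$headgroup[match(species, comp$name)] == "sterol"
  depths <- c(0, 5, 11)           # polar at surface, tails beneath
  cls <- c("polar", "aliphatic", "aliphatic")
  rows <- vector("list", length(depths))
  for (k in seq_along(depths)) {
    keep <- if (k == 3) !sterol else rep(TRUE, n)  # sterols: one tail bead
    if (!any(keep)) next
    p <- pos[keep, , drop = FALSE] + depths[k] * inward[keep, , drop = FALSE]
    rows[[k]] <- data.frame(
      x = p[, 1], y = p[, 2], z = p[, 3], bead_class = cls[k],
      species = species[keep], leaflet = leaflet,
      lipid_id = (id0 + seq_len(n))[keep],
      cover_radius = ifelse(cls[k] == "polar", cr[keep], NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Build a flat bilayer patch
#'
#' Places `n_lipids_per_leaflet` lipids per leaflet on a jittered square
#' lattice whose cell area equals `area_per_lipid`. Polar beads sit at
#' the interfacial planes `z = +/- half_thickness`; aliphatic beads are
#' stacked beneath them towards the mid-plane. The patch is periodic in
#' x and y. Species are assigned by a seeded multinomial draw from
#' `comp`.
#'
#' @param comp A [lipid_composition()].
#' @param n_lipids_per_leaflet Lipid count per leaflet (>= 0).
#' @param area_per_lipid Interfacial area per lipid (Angstrom^2).
#' @param jitter In-plane Gaussian jitter s.d. (Angstrom, >= 0).
#' @param seed Integer seed; every stochastic step is scoped to it.
#' @param half_thickness Distance from mid-plane to the interfacial
#'   plane (Angstrom).
#' @return A `membrane_config` with geometry `"flat"` and dimensions
#'   `Lx`, `Ly` such that `Lx * Ly ~= n * area_per_lipid`.
#' @export
build_flat_patch <- function(comp, n_lipids_per_leaflet,
                             area_per_lipid = 70, jitter = 1.5,
                             seed = 1, half_thickness = 20) {
  stopifnot(inherits(comp, "lipid_composition"))
  n <- n_lipids_per_leaflet
  if (n < 0) stop("n_lipids_per_leaflet must be >= 0")
  if (area_per_lipid <= 0) stop("area_per_lipid must be > 0")
  if (jitter < 0) stop("jitter must be >= 0")
  d <- sqrt(area_per_lipid)
  if (n == 0) {
    return(new_membrane_config("flat", list(Lx = 0, Ly = 0),
                               empty_beads(), area_per_lipid,
                               half_thickness))
  }
  # pick lattice dims nx x ny >= n with minimal excess (exact when n factors)
  nx_cand <- max(1, floor(sqrt(n)) - 4):(ceiling(sqrt(n)) + 4)
  ny_cand <- ceiling(n / nx_cand)
  excess <- nx_cand * ny_cand - n
  i <- which.min(excess)
  nx <- nx_cand[i]; ny <- ny_cand[i]
  Lx <- nx * d; Ly <- ny * d
  withr::with_seed(seed, {
    beads <- lapply(c(upper = 1, lower = -1), function(sgn) {
      sites <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
      if (nrow(sites) > n) sites <- sites[sample(nrow(sites), n), ]
      px <- (sites$ix + 0.5) * d + stats::rnorm(n, 0, jitter)
      py <- (sites$iy + 0.5) * d + stats::rnorm(n, 0, jitter)
      pos <- cbind(px %% Lx, py %% Ly, rep(sgn * half_thickness, n))
      inward <- cbind(0, 0, rep(-sgn, n))
      lipid_beads(pos, inward, draw_species(comp, n),
                  if (sgn > 0) "upper" else "lower", comp,
                  id0 = if (sgn > 0) 0L else n)
    })
  })
  new_membrane_config("flat", list(Lx = Lx, Ly = Ly),
                      do.call(rbind, beads), area_per_lipid,
                      half_thickness)
}

# Fibonacci (golden-angle) lattice: n near-equal-area points on the
# unit sphere.
fibonacci_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# Tangent-plane Gaussian jitter of points on a sphere of radius R,
# reprojected to the sphere.
jitter_on_sphere <- function(p, R, jitter) {
  n <- nrow(p)
  if (n == 0 || jitter == 0) return(p * R)
  u <- p
  # arbitrary tangent basis per point
  a <- cbind(-u[, 2], u[, 1], 0)
  deg <- sqrt(rowSums(a^2)) < 1e-8
  if (any(deg)) a[deg, ] <- matrix(c(1, 0, 0), sum(deg), 3, byrow = TRUE)
  a <- a / sqrt(rowSums(a^2))
  b <- cbind(u[, 2] * a[, 3] - u[, 3] * a[, 2],
             u[, 3] * a[, 1] - u[, 1] * a[, 3],
             u[, 1] * a[, 2] - u[, 2] * a[, 1])
  q <- u * R + a * stats::rnorm(n, 0, jitter) + b * stats::rnorm(n, 0, jitter)
  q * (R / sqrt(rowSums(q^2)))
}

#' Build a spherical vesicle
#'
#' Lipids are placed on seeded golden-angle (near equal-area) lattices on
#' the two interfacial spheres at radii `radius +/- half_thickness`, with
#' tangent-plane jitter. Leaflet lipid counts are set either by the
#' mid-plane approximation `4*pi*radius^2 / area_per_lipid` for both
#' leaflets (`leaflet_mode = "midplane"`, the convention of the
#' worked liposome arithmetic: a vesicle of R = 30 nm at s = 0.7 nm^2
#' holds about 2 x 4*pi*R^2/s ~ 3.2e4 lipids) or by the true interfacial
#' areas `4*pi*(radius +/- half_thickness)^2 / area_per_lipid`
#' (`leaflet_mode = "interfacial"`). Under the mid-plane mode the outer
#' leaflet is geometrically dilated, which is exactly the packing stress
#' that makes highly curved membranes defect-rich.
#'
#' @inheritParams build_flat_patch
#' @param radius Mid-bilayer radius (Angstrom); must exceed
#'   `half_thickness`.
#' @param leaflet_mode `"midplane"` (default) or `"interfacial"`; see
#'   Details.
#' @return A `membrane_config` with geometry `"sphere"`.
#' @export
build_vesicle <- function(comp, radius, area_per_lipid = 70,
                          jitter = 1.5, seed = 1, half_thickness = 20,
                          leaflet_mode = c("midplane", "interfacial")) {
  stopifnot(inherits(comp, "lipid_composition"))
  leaflet_mode <- match.arg(leaflet_mode)
  if (area_per_lipid <= 0) stop("area_per_lipid must be > 0")
  if (jitter < 0) stop("jitter must be >= 0")
  if (radius <= half_thickness) {
    stop("vesicle radius (", radius, " A) must exceed the bilayer ",
         "half-thickness (", half_thickness, " A); the inner leaflet ",
         "would have non-positive radius")
  }
  R_out <- radius + half_thickness
  R_in <- radius - half_thickness
  n_out <- if (leaflet_mode == "midplane") {
    round(4 * pi * radius^2 / area_per_lipid)
  } else round(4 * pi * R_out^2 / area_per_lipid)
  n_in <- if (leaflet_mode == "midplane") {
    round(4 * pi * radius^2 / area_per_lipid)
  } else round(4 * pi * R_in^2 / area_per_lipid)
  withr::with_seed(seed, {
    place <- function(n, R_leaf, leaflet, sgn, id0) {
      u <- fibonacci_sphere(n)
      # seeded random orientation so lattices of the two leaflets differ
      ang <- stats::runif(3, 0, 2 * pi)
      u <- u %*% rotation_matrix(ang)
      pos <- jitter_on_sphere(u, R_leaf, jitter)
      inward <- (pos / sqrt(rowSums(pos^2))) * sgn
      lipid_beads(pos, inward, draw_species(comp, n), leaflet, comp, id0)
    }
    beads <- rbind(place(n_out, R_out, "outer", -1, 0L),
                   place(n_in, R_in, "inner", +1, n_out))
  })
  new_membrane_config("sphere", list(radius = radius),
                      beads, area_per_lipid, half_thickness,
                      leaflet_mode)
}

rotation_matrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

#' Build a cylindrical tubule
#'
#' Lipids are placed on jittered lattices wrapped on the two interfacial
#' cylinders at radii `radius +/- half_thickness`; the tubule is periodic
#' along its axis (z). Leaflet counts follow `leaflet_mode` as in
#' [build_vesicle()]: `"midplane"` uses `2*pi*radius*length /
#' area_per_lipid` for both leaflets, `"interfacial"` the true leaflet
#' areas.
#'
#' @inheritParams build_vesicle
#' @param length Tubule length along z (Angstrom).
#' @return A `membrane_config` with geometry `"cylinder"`.
#' @export
build_tubule <- function(comp, radius, length, area_per_lipid = 70,
                         jitter = 1.5, seed = 1, half_thickness = 20,
                         leaflet_mode = c("midplane", "interfacial")) {
  stopifnot(inherits(comp, "lipid_composition"))
  leaflet_mode <- match.arg(leaflet_mode)
  if (area_per_lipid <= 0) stop("area_per_lipid must be > 0")
  if (jitter < 0) stop("jitter must be >= 0")
  if (length < 0) stop("length must be >= 0")
  if (radius <= half_thickness) {
    stop("tubule radius (", radius, " A) must exceed the bilayer ",
         "half-thickness (", half_thickness, " A)")
  }
  if (length == 0) {
    return(new_membrane_config("cylinder",
                               list(radius = radius, length = 0),
                               empty_beads(), area_per_lipid,
                               half_thickness, leaflet_mode))
  }
  R_out <- radius + half_thickness
  R_in <- radius - half_thickness
  withr::with_seed(seed, {
    place <- function(R_leaf, leaflet, sgn, id0) {
      R_count <- if (leaflet_mode == "midplane") radius else R_leaf
      n_target <- round(2 * pi * R_count * length / area_per_lipid)
      if (n_target == 0) return(empty_beads())
      # lattice n_th x n_z on the unrolled leaflet surface
      d <- sqrt(2 * pi * R_leaf * length / n_target)
      n_th <- max(1, round(2 * pi * R_leaf / d))
      n_z <- max(1, round(n_target / n_th))
      n <- n_th * n_z
      g <- expand.grid(it = seq_len(n_th) - 1, iz = seq_len(n_z) - 1)
      th <- (g$it + 0.5) * 2 * pi / n_th +
        stats::rnorm(n, 0, jitter) / R_leaf
      zz <- ((g$iz + 0.5) * length / n_z + stats::rnorm(n, 0, jitter)) %%
        length
      pos <- cbind(R_leaf * cos(th), R_leaf * sin(th), zz)
      inward <- cbind(sgn * cos(th), sgn * sin(th), 0)
      lipid_beads(pos, inward, draw_species(comp, n), leaflet, comp, id0)
    }
    outer <- place(R_out, "outer", -1, 0L)
    inner <- place(R_in, "inner", +1,
                   max(0L, suppressWarnings(max(outer$lipid_id, 0L))))
    beads <- rbind(outer, inner)
  })
  new_membrane_config("cylinder", list(radius = radius, length = length),
                      beads, area_per_lipid, half_thickness, leaflet_mode)
}

#' Draw defect areas from the exponential law
#'
#' Samples `n` i.i.d. areas `A_min + Exponential(mean = Ac)`, the law
#' that interfacial packing-defect areas follow (abundance proportional
#' to `exp(-A/Ac)` above a minimal resolvable area).
#'
#' @param Ac Decay constant (Angstrom^2, > 0).
#' @param A_min Left offset (Angstrom^2, >= 0).
#' @param n Number of draws (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of `n` areas.
#' @export
sample_exponential_areas <- function(Ac, A_min = 0, n, seed = 1) {
  if (Ac <= 0) stop("Ac must be > 0")
  if (A_min < 0) stop("A_min must be >= 0")
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(numeric(0))
  withr::with_seed(seed, A_min + stats::rexp(n, rate = 1 / Ac))
}

# ---- void implantation -----------------------------------------------

#' Specify ground-truth voids
#'
#' @param shape `"disc"` or `"square"` (squares are supported on flat
#'   patches only).
#' @param target_area Footprint area per void (Angstrom^2, > 0).
#' @param leaflet Leaflet name (`"upper"`/`"lower"` for flat,
#'   `"outer"`/`"inner"` for curved geometries).
#' @param count Number of voids when placed randomly.
#' @param centers Optional explicit centers: for flat patches a matrix of
#'   (x, y); for curved geometries a matrix of 3D points which are
#'   projected radially onto the leaflet surface. Overrides `count`.
#' @param seed Integer seed for random placement.
#' @param min_separation Minimum center-to-center distance for random
#'   placement (Angstrom). Defaults to twice the footprint
#'   circumradius (disjoint footprints); larger values keep the carved
#'   voids from coalescing through the bead-removal margin.
#' @return A `void_spec` list.
#' @export
void_spec <- function(shape = c("disc", "square"), target_area, leaflet,
                      count = 1, centers = NULL, seed = 1,
                      min_separation = NULL) {
  shape <- match.arg(shape)
  if (target_area <= 0) stop("target_area must be > 0")
  if (is.null(centers) && count < 0) stop("count must be >= 0")
  structure(list(shape = shape, target_area = target_area,
                 leaflet = leaflet, count = count, centers = centers,
                 seed = seed, min_separation = min_separation),
            class = "void_spec")
}

# footprint circumradius used for overlap checks
void_circumradius <- function(spec) {
  if (spec$shape == "disc") sqrt(spec$target_area / pi)
  else sqrt(spec$target_area) * sqrt(2) / 2
}

# surface coordinates and metric helpers per geometry/leaflet
leaflet_surface <- function(config, leaflet) {
  h <- config$half_thickness
  switch(config$geometry,
    flat = {
      sgn <- if (leaflet == "upper") 1 else -1
      list(type = "flat", Lx = config$dimensions$Lx,
           Ly = config$dimensions$Ly, z = sgn * h,
           area = config$dimensions$Lx * config$dimensions$Ly)
    },
    sphere = {
      R <- config$dimensions$radius +
        if (leaflet == "outer") h else -h
      list(type = "sphere", R = R, area = 4 * pi * R^2)
    },
    cylinder = {
      R <- config$dimensions$radius +
        if (leaflet == "outer") h else -h
      list(type = "cylinder", R = R, L = config$dimensions$length,
           area = 2 * pi * R * config$dimensions$length)
    })
}

# geodesic / in-surface distance between points given a surface
surface_distance <- function(surf, a, b) {
  if (surf$type == "flat") {
    dx <- abs(a[, 1] - b[1]); dx <- pmin(dx, surf$Lx - dx)
    dy <- abs(a[, 2] - b[2]); dy <- pmin(dy, surf$Ly - dy)
    sqrt(dx^2 + dy^2)
  } else if (surf$type == "sphere") {
    ca <- pmin(1, pmax(-1, (a %*% b) / surf$R^2))
    surf$R * acos(as.numeric(ca))
  } else {
    tha <- atan2(a[, 2], a[, 1]); thb <- atan2(b[2], b[1])
    dth <- abs(tha - thb); dth <- pmin(dth, 2 * pi - dth)
    dz <- abs(a[, 3] - b[3]); dz <- pmin(dz, surf$L - dz)
    sqrt((surf$R * dth)^2 + dz^2)
  }
}

random_surface_point <- function(surf) {
  if (surf$type == "flat") {
    c(stats::runif(1, 0, surf$Lx), stats::runif(1, 0, surf$Ly), surf$z)
  } else if (surf$type == "sphere") {
    v <- stats::rnorm(3); surf$R * v / sqrt(sum(v^2))
  } else {
    th <- stats::runif(1, 0, 2 * pi)
    c(surf$R * cos(th), surf$R * sin(th), stats::runif(1, 0, surf$L))
  }
}

#' Implant ground-truth voids into a configuration
#'
#' Removes every polar bead whose occlusion disc intersects a void
#' footprint on the named leaflet, and records the realized voids in
#' `ground_truth_voids`. Random placement rejects candidate centers whose
#' footprints would overlap an accepted one (bounded retries), so the
#' implanted voids are pairwise disjoint.
#'
#' @param config A `membrane_config`.
#' @param voids A [void_spec()].
#' @param max_tries Retry budget per void for random placement.
#' @return The modified `membrane_config`.
#' @export
implant_voids <- function(config, voids, max_tries = 1000) {
  stopifnot(inherits(config, "membrane_config"),
            inherits(voids, "void_spec"))
  surf <- leaflet_surface(config, voids$leaflet)
  if (voids$shape == "square" && surf$type != "flat") {
    stop("square voids are only supported on flat patches")
  }
  rv <- void_circumradius(voids)
  sep <- voids$min_separation
  if (is.null(sep)) sep <- 2 * rv
  if (voids$target_area > surf$area) {
    stop("void target_area (", voids$target_area,
         " A^2) exceeds the leaflet surface area (",
         signif(surf$area, 4), " A^2)")
  }
  # resolve centers
  if (!is.null(voids$centers)) {
    centers <- as.matrix(voids$centers)
    if (surf$type == "flat") {
      if (ncol(centers) == 2) centers <- cbind(centers, surf$z)
      centers[, 3] <- surf$z
    } else {
      if (ncol(centers) != 3) stop("curved-surface centers must be 3D")
      if (surf$type == "sphere") {
        centers <- centers * (surf$R / sqrt(rowSums(centers^2)))
      } else {
        rho <- sqrt(centers[, 1]^2 + centers[, 2]^2)
        centers[, 1:2] <- centers[, 1:2] * (surf$R / rho)
        centers[, 3] <- centers[, 3] %% surf$L
      }
    }
    if (nrow(centers) > 1) {
      for (i in 2:nrow(centers)) {
        d <- surface_distance(surf, centers[seq_len(i - 1), , drop = FALSE],
                              centers[i, ])
        if (any(d < 2 * rv)) stop("explicit void centers overlap")
      }
    }
  } else {
    n <- voids$count
    if (n == 0) return(config)
    centers <- matrix(NA_real_, n, 3)
    withr::with_seed(voids$seed, {
      placed <- 0
      for (i in seq_len(n)) {
        ok <- FALSE
        for (t in seq_len(max_tries)) {
          cand <- random_surface_point(surf)
          if (placed == 0 ||
              all(surface_distance(surf,
                                   centers[seq_len(placed), , drop = FALSE],
                                   cand) >= sep)) {
            placed <- placed + 1
            centers[placed, ] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("could not place ", n, " non-overlapping voids after ",
               max_tries, " tries each (placed ", placed, ")")
        }
      }
    })
  }
  # remove polar beads whose disc intersects any footprint
  b <- config$beads
  polar <- which(b$bead_class == "polar" & b$leaflet == voids$leaflet)
  if (length(polar) > 0) {
    pp <- as.matrix(b[polar, c("x", "y", "z")])
    drop_lipids <- integer(0)
    for (i in seq_len(nrow(centers))) {
      d <- surface_distance(surf, pp, centers[i, ])
      if (voids$shape == "disc") {
        hit <- d < rv + b$cover_radius[polar]
      } else {
        # axis-aligned square on a flat patch: disc-rectangle intersection
        half <- sqrt(voids$target_area) / 2
        dx <- abs(pp[, 1] - centers[i, 1]); dx <- pmin(dx, surf$Lx - dx)
        dy <- abs(pp[, 2] - centers[i, 2]); dy <- pmin(dy, surf$Ly - dy)
        cx <- pmax(dx - half, 0); cy <- pmax(dy - half, 0)
        hit <- sqrt(cx^2 + cy^2) < b$cover_radius[polar]
      }
      drop_lipids <- union(drop_lipids, b$lipid_id[polar[hit]])
    }
    if (length(drop_lipids) > 0) {
      keep <- !(b$lipid_id %in% drop_lipids & b$leaflet == voids$leaflet)
      config$beads <- b[keep, , drop = FALSE]
    }
  }
  gt <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                   area = voids$target_area, leaflet = voids$leaflet,
                   shape = voids$shape, stringsAsFactors = FALSE)
  config$ground_truth_voids <- rbind(config$ground_truth_voids, gt)
  config
}
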