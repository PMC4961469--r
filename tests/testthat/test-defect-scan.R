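comp <- copi_composition()

test_that("a dense defect-free lattice is fully covered", {
  p <- build_flat_patch(comp, 256, area_per_lipid = 64, jitter = 0,
                        seed = 1)
  g <- project_surface(p, "upper", cell_size = 1)
  expect_true(all(g$covered))
  expect_equal(nrow(detect_defects(g)), 0)
  expect_error(project_surface(p, "upper", cell_size = 0), "cell_size")
})

test_that("an implanted square void is recovered within the raster band", {
  # dense lattice (2 A spacing) so bead removal carves little beyond
  # the footprint; the residual scales with the lattice granularity
  p <- build_flat_patch(comp, 1600, area_per_lipid = 4, jitter = 0,
                        seed = 1)
  ctr <- c(p$dimensions$Lx / 2, p$dimensions$Ly / 2)
  p <- implant_voids(p, void_spec("square", 25, "upper",
                                  centers = matrix(ctr, 1)))
  for (cs in c(1, 0.5)) {
    g <- project_surface(p, "upper", cell_size = cs)
    uncov <- sum(g$weight[!g$covered])
    band <- 2 * 4 * sqrt(25) * max(cs, 1)  # 2 * perimeter * cell band
    expect_lt(abs(uncov - 25), band)
  }
  # resolution convergence: halving the cell changes the estimate by
  # less than one perimeter band
  g1 <- project_surface(p, "upper", 1)
  g2 <- project_surface(p, "upper", 0.5)
  a1 <- sum(g1$weight[!g1$covered]); a2 <- sum(g2$weight[!g2$covered])
  expect_lt(abs(a1 - a2), 4 * sqrt(25) * 1)
})

test_that("spherical grids conserve area and expose empty leaflets", {
  v <- build_vesicle(comp, 80, seed = 2)
  g <- project_surface(v, "outer", cell_size = 1)
  expect_lt(abs(g$total_area - 4 * pi * 100^2) / (4 * pi * 100^2), 0.02)
  expect_true(all(g$weight > 0))

  none <- build_flat_patch(comp, 0)
  g0 <- project_surface(build_flat_patch(comp, 4, jitter = 0), "upper")
  # remove the leaflet's beads to hit the all-uncovered flag
  stripped <- build_flat_patch(comp, 4, jitter = 0)
  stripped$beads <- stripped$beads[stripped$beads$leaflet == "lower", ]
  gs <- project_surface(stripped, "upper")
  expect_true(isTRUE(attr(gs, "empty_leaflet")))
  expect_true(all(!gs$covered))
})

test_that("connectivity semantics distinguish diagonal contacts", {
  m <- matrix(TRUE, 7, 7)
  m[3, 3] <- FALSE; m[4, 4] <- FALSE     # touch only at a corner
  g <- make_planar_grid(m)
  expect_equal(nrow(detect_defects(g, connectivity = 4)), 2)
  expect_equal(nrow(detect_defects(g, connectivity = 8)), 1)
  expect_equal(nrow(detect_defects(make_planar_grid(matrix(TRUE, 5, 5)))),
               0)
})

test_that("component labeling matches the exhaustive flood-fill oracle", {
  set.seed(123)  # test-local RNG for fixture patterns
  for (p_uncov in c(0.2, 0.4, 0.6)) {
    for (conn in c(4, 8)) {
      m <- matrix(stats::runif(50 * 37) > p_uncov, 50, 37)
      g <- make_planar_grid(m)
      d <- detect_defects(g, connectivity = conn, keep_cells = TRUE)
      lab <- flood_fill_oracle(m, conn)
      expect_same_partition(d, lab)
      expect_equal(sum(d$area), sum(!m))  # area conservation, unit cells
    }
  }
  # explicit periodic wrap: a component crossing both edges is one
  m <- matrix(TRUE, 10, 10)
  m[1, 4] <- FALSE; m[10, 4] <- FALSE
  m[5, 1] <- FALSE; m[5, 10] <- FALSE
  d <- detect_defects(make_planar_grid(m), keep_cells = TRUE)
  expect_same_partition(d, flood_fill_oracle(m, 4))
  expect_equal(nrow(d), 2)
})

test_that("implanted discs are recovered one-to-one with true areas", {
  # dense lattice with tight cover discs: the removal margin
  # (void radius + cover radius) stays well below the void separation
  comp_tight <- copi_composition(cover_radius_phospholipid = 3,
                                 cover_radius_sterol = 3)
  patch <- build_flat_patch(comp_tight, 10000, area_per_lipid = 2.25,
                            jitter = 0, seed = 2)   # 150 x 150 A, dense
  patch <- implant_voids(patch, void_spec("disc", 30, "upper",
                                          count = 50, seed = 31,
                                          min_separation = 14))
  g <- project_surface(patch, "upper", cell_size = 1)
  d <- detect_defects(g)
  expect_equal(nrow(d), 50)
  band <- 2 * pi * sqrt(30 / pi) * 1     # perimeter * cell_size
  expect_true(all(abs(d$area - 30) <= band))
  expect_lt(stats::sd(d$area), band)
})

test_that("defect areas plus covered area account for the whole leaflet", {
  p <- build_flat_patch(comp, 500, seed = 8)   # jittered, real defects
  g <- project_surface(p, "upper")
  d <- detect_defects(g)
  total <- sum(d$area) + sum(g$weight[g$covered])
  expect_lt(abs(total - g$total_area) / g$total_area, 0.02)
  v <- build_vesicle(comp, 90, seed = 8)
  gv <- project_surface(v, "outer")
  dv <- detect_defects(gv)
  expect_lt(abs(sum(dv$area) + sum(gv$weight[gv$covered]) -
                  gv$total_area) / gv$total_area, 0.02)
})

test_that("cylindrical scans honor both periodic directions", {
  tb <- build_tubule(comp, 80, 200, seed = 3)
  g <- project_surface(tb, "outer")
  surf_area <- 2 * pi * 100 * 200
  expect_lt(abs(g$total_area - surf_area) / surf_area, 0.02)
  tube_dense <- build_tubule(comp, 40, 100, area_per_lipid = 2.25,
                             jitter = 0, seed = 3, half_thickness = 10,
                             leaflet_mode = "interfacial")
  tb2 <- implant_voids(tube_dense,
                       void_spec("disc", 40, "outer", count = 5,
                                 seed = 12, min_separation = 20))
  d <- detect_defects(project_surface(tb2, "outer", 1))
  expect_equal(nrow(d), 5)
  band <- 2 * pi * sqrt(40 / pi) * 1
  expect_true(all(abs(d$area - 40) <= band))
})
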