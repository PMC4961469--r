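comp <- copi_composition()

test_that("flat patch area and composition track the request", {
  empty <- build_flat_patch(comp, 0)
  expect_equal(nrow(empty$beads), 0)
  expect_equal(empty$dimensions$Lx * empty$dimensions$Ly, 0)

  p <- build_flat_patch(comp, 256, area_per_lipid = 70, seed = 3)
  area <- p$dimensions$Lx * p$dimensions$Ly
  expect_lt(abs(area - 256 * 70) / (256 * 70), 0.05)
  # brute-force area oracle: lattice cells are congruent squares
  expect_equal(area, sum(rep(70, 256)))

  p2 <- build_flat_patch(comp, 1000, seed = 42)
  polar <- p2$beads[p2$beads$bead_class == "polar", ]
  realized <- table(factor(polar$species, levels = comp$name)) /
    nrow(polar)
  expect_true(all(abs(as.numeric(realized) - comp$fraction) <= 0.03))
})

test_that("realized species fractions converge to the composition", {
  p <- build_flat_patch(comp, 10000, seed = 7)
  polar <- p$beads[p$beads$bead_class == "polar", ]
  realized <- table(factor(polar$species, levels = comp$name)) /
    nrow(polar)
  expect_true(all(abs(as.numeric(realized) - comp$fraction) <= 0.015))
})

test_that("builders are deterministic under a fixed seed", {
  expect_identical(build_flat_patch(comp, 200, seed = 9),
                   build_flat_patch(comp, 200, seed = 9))
  expect_identical(build_vesicle(comp, 100, seed = 9),
                   build_vesicle(comp, 100, seed = 9))
  expect_identical(build_tubule(comp, 100, 400, seed = 9),
                   build_tubule(comp, 100, 400, seed = 9))
  # different seed moves at least some coordinates
  expect_false(identical(build_flat_patch(comp, 200, seed = 9),
                         build_flat_patch(comp, 200, seed = 10)))
})

test_that("vesicle lipid counts follow the surface-area bookkeeping", {
  # mid-plane approximation: R = 30 nm, s = 0.7 nm^2 -> ~3.2e4 lipids
  v <- build_vesicle(comp, 300, area_per_lipid = 70, seed = 1)
  n_lip <- length(unique(v$beads$lipid_id))
  expect_lt(abs(n_lip - 2 * 4 * pi * 300^2 / 70) /
              (2 * 4 * pi * 300^2 / 70), 0.02)

  # interfacial mode: R_out/R_in = 2 forces a 4:1 leaflet count ratio
  v2 <- build_vesicle(comp, 60, half_thickness = 20,
                      leaflet_mode = "interfacial", seed = 1)
  b <- v2$beads[v2$beads$bead_class == "polar", ]
  ratio <- sum(b$leaflet == "outer") / sum(b$leaflet == "inner")
  expect_equal(ratio, 4, tolerance = 0.02)

  expect_error(build_vesicle(comp, 15, half_thickness = 20),
               "must exceed")
})

test_that("vesicle bead spacing matches the equal-area lattice scale", {
  v <- build_vesicle(comp, 100, area_per_lipid = 70, jitter = 0,
                     seed = 5, leaflet_mode = "interfacial")
  b <- v$beads[v$beads$bead_class == "polar" & v$beads$leaflet == "outer", ]
  nn <- nn_distances(as.matrix(b[, c("x", "y", "z")]))
  expect_lt(abs(mean(nn) - sqrt(70)) / sqrt(70), 0.15)
})

test_that("tubule counts, periodicity and the empty case behave", {
  t0 <- build_tubule(comp, 100, 0, seed = 1)
  expect_equal(nrow(t0$beads), 0)

  tb <- build_tubule(comp, 100, 500, seed = 1,
                     leaflet_mode = "interfacial")
  b <- tb$beads[tb$beads$bead_class == "polar" & tb$beads$leaflet == "outer", ]
  target <- 2 * pi * 120 * 500 / 70
  expect_lt(abs(nrow(b) - target) / target, 0.05)
  expect_true(all(b$z >= 0 & b$z <= 500))
})

test_that("exponential area sampler obeys its law", {
  expect_length(sample_exponential_areas(10, 15, 0), 0)
  x <- sample_exponential_areas(10, 15, 1e5, seed = 2)
  expect_equal(mean(x), 25, tolerance = 0.2 / 25)
  expect_true(all(x >= 15))
  a <- sample_exponential_areas(10, 0, 2e4, seed = 3)
  b <- sample_exponential_areas(20, 0, 2e4, seed = 3)
  expect_lt(stats::quantile(a, 0.95), stats::quantile(b, 0.95))
  expect_error(sample_exponential_areas(-1, 0, 10), "Ac")
  expect_error(sample_exponential_areas(10, 0, -1), "n must")
})

test_that("void implantation removes exactly the beads its rule names", {
  dense <- build_flat_patch(comp, 400, area_per_lipid = 25, jitter = 0,
                            seed = 1)
  ctr <- c(dense$dimensions$Lx / 2, dense$dimensions$Ly / 2)
  vs <- void_spec("square", target_area = 25, leaflet = "upper",
                  centers = matrix(ctr, 1))
  out <- implant_voids(dense, vs)
  expect_equal(out$ground_truth_voids$area, 25)
  # oracle: recompute the removal set by brute-force disc/square check
  b <- dense$beads
  pol <- b[b$bead_class == "polar" & b$leaflet == "upper", ]
  half <- sqrt(25) / 2
  cx <- pmax(abs(pol$x - ctr[1]) - half, 0)
  cy <- pmax(abs(pol$y - ctr[2]) - half, 0)
  should_go <- pol$lipid_id[sqrt(cx^2 + cy^2) < pol$cover_radius]
  gone <- setdiff(pol$lipid_id, out$beads$lipid_id[
    out$beads$leaflet == "upper"])
  expect_setequal(gone, should_go)
  expect_gt(length(gone), 0)
})

test_that("random void placement yields disjoint footprints", {
  patch <- build_flat_patch(comp, 2500, area_per_lipid = 36, jitter = 0,
                            seed = 2)
  vs <- void_spec("disc", target_area = 30, leaflet = "upper",
                  count = 50, seed = 11)
  out <- implant_voids(patch, vs)
  gt <- out$ground_truth_voids
  expect_equal(nrow(gt), 50)
  rv <- sqrt(30 / pi)
  d <- as.matrix(stats::dist(gt[, c("x", "y")]))
  diag(d) <- Inf
  expect_true(all(d >= 2 * rv))        # pairwise footprint disjointness

  expect_identical(implant_voids(patch, void_spec("disc", 30, "upper",
                                                  count = 0)),
                   patch)
  expect_error(implant_voids(patch, void_spec("disc", 1e9, "upper", 1)),
               "exceeds")
})

test_that("leaflet areas match lipid counts across geometries", {
  p <- build_flat_patch(comp, 900, seed = 4)
  expect_lt(abs(p$dimensions$Lx * p$dimensions$Ly - 900 * 70) /
              (900 * 70), 0.05)
  v <- build_vesicle(comp, 120, seed = 4, leaflet_mode = "interfacial")
  for (leaf in c("outer", "inner")) {
    R <- 120 + if (leaf == "outer") 20 else -20
    n <- sum(v$beads$bead_class == "polar" & v$beads$leaflet == leaf)
    expect_lt(abs(n * 70 - 4 * pi * R^2) / (4 * pi * R^2), 0.05)
  }
  tb <- build_tubule(comp, 120, 400, seed = 4,
                     leaflet_mode = "interfacial")
  for (leaf in c("outer", "inner")) {
    R <- 120 + if (leaf == "outer") 20 else -20
    n <- sum(tb$beads$bead_class == "polar" & tb$beads$leaflet == leaf)
    expect_lt(abs(n * 70 - 2 * pi * R * 400) / (2 * pi * R * 400), 0.05)
  }
})
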