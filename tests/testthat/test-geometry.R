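test_that("dihedral matches its defining examples and the projection oracle", {
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], c(1, 1, 0)), 0)
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], c(-1, 1, 0)), 180)
  d90 <- dihedral(p[[1]], p[[2]], p[[3]], c(0, 1, 1))
  expect_equal(abs(d90), 90)
  expect_equal(d90, oracle_dihedral(p[[1]], p[[2]], p[[3]], c(0, 1, 1)))

  set.seed(42)
  for (i in 1:1000) {
    q <- lapply(1:4, function(k) stats::runif(3, -5, 5))
    ref <- oracle_dihedral(q[[1]], q[[2]], q[[3]], q[[4]])
    expect_lt(abs(wrap_angle(dihedral(q[[1]], q[[2]], q[[3]], q[[4]]) - ref)),
              1e-9)
  }
})

test_that("dihedral rejects degenerate geometry", {
  o <- c(0, 0, 0)
  expect_error(dihedral(c(1, 0, 0), o, o, c(0, 1, 0)), "degenerate")
  expect_error(dihedral(c(2, 0, 0), c(1, 0, 0), o, c(-1, 0, 0)),
               "collinear")
})

test_that("ring centroid is the arithmetic mean and translation-equivariant", {
  hexagon <- t(sapply(0:5, function(k) {
    c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }))
  rownames(hexagon) <- paste0("X", 1:6)
  conf <- fake_conformer(hexagon)
  expect_equal(ring_centroid(conf, rownames(hexagon)), c(x = 0, y = 0, z = 0),
               tolerance = 1e-12)
  conf2 <- fake_conformer(sweep(hexagon, 2, c(0, 0, -10)))
  expect_equal(unname(ring_centroid(conf2, rownames(hexagon))), c(0, 0, 10))
  # independent mean oracle on the purine template
  tpl <- build_template("NAD_plus")
  ring <- tpl$topology$rings$adenine
  expect_equal(unname(ring_centroid(tpl, ring)),
               unname(apply(tpl$xyz[ring, ], 2, mean)))
  expect_error(ring_centroid(conf, c("X1", "MISSING")), "missing")
})

test_that("inter-base distance is the centroid separation and rigid-motion invariant", {
  tpl <- build_template("NADH")
  cn <- ring_centroid(tpl, tpl$topology$rings$nicotinamide)
  ca <- ring_centroid(tpl, tpl$topology$rings$adenine)
  expect_equal(interbase_distance(tpl), sqrt(sum((cn - ca)^2)))
  set.seed(7)
  for (i in 1:5) {
    expect_equal(interbase_distance(rigid_move_conformer(tpl)),
                 interbase_distance(tpl), tolerance = 1e-9)
  }
})

test_that("plane angle handles parallel, antiparallel and perpendicular rings", {
  base <- rbind(
    N1N = c(0, 0, 0), C2N = c(1, 0, 0), C6N = c(0, 1, 0),
    C5A = c(5, 5, 0), C4A = c(6, 5, 0), C6A = c(5, 6, 0)
  )
  expect_equal(interbase_plane_angle(fake_conformer(base)), 0)
  opp <- base
  opp[c("C4A", "C6A"), ] <- base[c("C6A", "C4A"), ]
  expect_equal(interbase_plane_angle(fake_conformer(opp)), 180)
  perp <- base
  perp["C4A", ] <- base["C5A", ] + c(0, 1, 0)
  perp["C6A", ] <- base["C5A", ] + c(0, 0, 1)
  expect_equal(interbase_plane_angle(fake_conformer(perp)), 90)
})

test_that("mirror-flipping one ring normal complements the plane angle to 180", {
  tpl <- build_template("ox4_NAD")
  a0 <- interbase_plane_angle(tpl)
  flipped <- tpl
  flipped$xyz[c("C4A", "C6A"), ] <- tpl$xyz[c("C6A", "C4A"), ]
  expect_equal(a0 + interbase_plane_angle(flipped), 180, tolerance = 1e-9)
})

test_that("radius of gyration matches symmetry cases and a direct-sum oracle", {
  one <- fake_conformer(matrix(c(3, -2, 8), 1), masses = 14.007)
  expect_equal(radius_of_gyration(one), 0)
  two <- fake_conformer(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two), 1)
  tpl <- build_template("NAD_plus")
  m <- tpl$topology$atoms$mass
  com <- colSums(tpl$xyz * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(tpl$xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(tpl), oracle)
  set.seed(3)
  expect_equal(radius_of_gyration(rigid_move_conformer(tpl)),
               radius_of_gyration(tpl), tolerance = 1e-9)
})

test_that("superposed RMSD removes rigid motion and matches the rotation-grid oracle", {
  tpl <- build_template("NADH")
  expect_equal(rmsd_superposed(tpl, tpl), 0)
  set.seed(11)
  moved <- rigid_move_conformer(tpl)
  expect_lt(rmsd_superposed(tpl, moved), 1e-9)
  # raw (no-superposition) variant does register the motion
  expect_gt(rmsd_superposed(tpl, moved, superpose = FALSE), 1)

  set.seed(99)
  for (i in 1:20) {
    A <- matrix(stats::rnorm(12, sd = 2), 4)
    B <- A + matrix(stats::rnorm(12, sd = 0.3), 4)
    expect_equal(nadfold:::kabsch_rmsd(A, B), oracle_rmsd(A, B),
                 tolerance = 1e-3)
    expect_equal(nadfold:::kabsch_rmsd(A, B), nadfold:::kabsch_rmsd(B, A),
                 tolerance = 1e-9)
  }
})

test_that("RMSD enforces matching topologies and selections", {
  a <- build_template("NAD_plus")
  b <- build_template("NADH")
  expect_error(rmsd_superposed(a, b), "mismatch")
  expect_error(rmsd_superposed(a, a, selection = character(0)), "empty")
  expect_error(rmsd_superposed(a, a, selection = "QQ1"), "unknown")
})

test_that("compute_metrics populates every field and is rigid-motion invariant", {
  tpl <- build_template("ox2_NAD")
  m <- compute_metrics(tpl)
  expect_false(anyNA(m))
  expect_gte(m$d, 12)
  expect_lte(m$d, 15)
  expect_true(m$plane_angle >= 0 && m$plane_angle <= 180)
  set.seed(5)
  m2 <- compute_metrics(rigid_move_conformer(tpl))
  for (col in names(m)) {
    expect_equal(m2[[col]], m[[col]], tolerance = 1e-8, info = col)
  }
  # round trip through the torsion driver
  m3 <- compute_metrics(set_dihedral(tpl, "chi_N", -160))
  expect_equal(m3$chi_N, -160, tolerance = 1e-6)
})
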