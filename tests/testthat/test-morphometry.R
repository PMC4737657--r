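# Mesh volumetry, areas, hulls, docked counting and measurement error.

test_that("unit cube: volume, areas and hull agree with closed forms", {
  cube <- make_unit_cube()
  expect_true(mesh_is_watertight(cube))
  expect_equal(mesh_volume(cube), 1)
  expect_equal(region_area(cube, "all"), 6)
  expect_equal(region_area(cube, "all_faces"), 6)
  expect_equal(region_area(cube, "top"), 1)
  expect_equal(region_area(cube, "empty"), 0)
  expect_equal(region_hull_volume(cube, "all_faces"), 1)
  expect_error(region_area(cube, "nope"), "no region")
})

test_that("orientation-inconsistent or open meshes are rejected", {
  cube <- make_unit_cube()
  open_mesh <- tagged_mesh(cube$vertices, cube$triangles[-1, ],
                           regions = list(all_faces = 1:11))
  expect_false(mesh_is_watertight(open_mesh))
  expect_error(mesh_volume(open_mesh), "watertight")
  expect_error(region_hull_volume(open_mesh, "all_faces"), "watertight")
  flipped <- cube
  flipped$triangles[1, ] <- flipped$triangles[1, c(1, 3, 2)]
  expect_false(mesh_is_watertight(flipped))
})

test_that("convex hull matches an independent reference on frozen point sets", {
  # reference volumes/areas computed once with an independent qhull-based
  # implementation on these exact deterministic point sets
  set.seed(42)
  p <- matrix(runif(60), 20, 3)
  h <- convex_hull_3d(p)
  expect_equal(h$volume, 0.38537994725844765, tolerance = 1e-12)
  expect_equal(h$area, 3.0474942563363956, tolerance = 1e-12)
  set.seed(99)
  q <- matrix(rnorm(45), 15, 3)
  h2 <- convex_hull_3d(q)
  expect_equal(h2$volume, 11.75845817346532, tolerance = 1e-12)
  expect_equal(h2$area, 31.323929213190016, tolerance = 1e-12)
})

test_that("degenerate point sets raise geometry errors", {
  expect_error(convex_hull_3d(matrix(runif(9), 3, 3)), ">= 4 points")
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(convex_hull_3d(flat), "coplanar")
  line <- cbind(seq_len(10), 2 * seq_len(10), 3 * seq_len(10))
  expect_error(convex_hull_3d(line), "coplanar|collinear")
})

test_that("spine-mesh hull volumetry is within 2% of analytic values", {
  # r = 0.5 um sphere head: nominal volume 0.5236 um^3
  for (n_phi in c(16, 32, 48)) {
    mesh <- generate_spine_mesh(0.5236, neck_length = 0.5,
                                neck_diameter = 0.2,
                                n_theta = max(24, n_phi), n_phi = n_phi)
    truth <- attr(mesh, "truth")
    expect_true(mesh_is_watertight(mesh))
    hull_head <- region_hull_volume(mesh, "head")
    expect_equal(hull_head, truth$head_volume, tolerance = 0.02)
    expect_equal(hull_head, 0.5236, tolerance = 0.02)
    expect_equal(region_area(mesh, "head"), truth$head_area,
                 tolerance = 0.02)
    expect_equal(region_area(mesh, "head"), 4 * pi * 0.5^2,
                 tolerance = 0.025)
  }
})

test_that("neck volume is the whole-minus-head difference", {
  expect_equal(neck_volume(1.0, 0.6), 0.4)
  expect_equal(neck_volume(0.7, 0.7), 0)
  expect_error(neck_volume(0.5, 0.6), "inconsistent")
  # generated fixture: whole - head equals the analytic cylinder volume
  mesh <- generate_spine_mesh(0.3, neck_length = 0.8, neck_diameter = 0.15)
  truth <- attr(mesh, "truth")
  whole <- mesh_volume(mesh)
  head <- region_hull_volume(mesh, "head")
  expect_equal(neck_volume(whole, head), pi * 0.075^2 * 0.8,
               tolerance = 0.02)
  expect_equal(truth$neck_volume, pi * 0.075^2 * 0.8)
})

test_that("hull volume is invariant under rigid motion", {
  mesh <- generate_spine_mesh(0.2, 0.4, 0.12, n_theta = 24, n_phi = 16)
  v0 <- region_hull_volume(mesh, "head")
  rot <- rotation_matrix(c(1, 2, 3), 0.83)
  moved <- mesh
  moved$vertices <- sweep(mesh$vertices %*% t(rot), 2, c(5, -2, 11), "+")
  expect_equal(region_hull_volume(moved, "head"), v0,
               tolerance = 1e-9)
})

test_that("hull of a convex region equals the enclosed mesh volume", {
  cube <- make_unit_cube()
  expect_equal(region_hull_volume(cube, "all_faces"), mesh_volume(cube),
               tolerance = 1e-12)
  # grid clipping is a no-op for a convex fixture
  expect_equal(region_hull_volume(cube, "all_faces", clip = "grid",
                                  grid_n = 12),
               1, tolerance = 0.02)
})

test_that("degenerate regions cannot form hulls", {
  cube <- make_unit_cube()
  cube$regions$one_tri <- 1L
  expect_error(region_hull_volume(cube, "one_tri"), "coplanar|>= 4")
})

test_that("docked counts match construction and brute-force oracles", {
  mesh <- generate_spine_mesh(0.524, 0.7, 0.2)
  # constructed cloud: 30 centers at 50 nm, 70 at 500 nm above the AZ
  az_verts <- unique(as.vector(mesh$triangles[mesh$regions$active_zone, ]))
  anchor <- mesh$vertices[az_verts[1], ]
  dir <- anchor / sqrt(sum(anchor^2))
  mk <- function(d_nm, n) {
    ctr <- matrix(rep((anchor + dir * d_nm / 1000) * 1000, n),
                  ncol = 3, byrow = TRUE)
    data.frame(x_nm = ctr[, 1], y_nm = ctr[, 2], z_nm = ctr[, 3])
  }
  cloud <- rbind(mk(50, 30), mk(500, 70))
  expect_equal(count_docked(cloud, mesh), 30)
  # empty cloud
  expect_equal(count_docked(cloud[0, ], mesh), 0L)
  # jittered cloud near the boundary: exact agreement with the
  # independently coded all-pairs oracle
  set.seed(12)
  jit <- generate_vesicle_cloud(80, mesh, docked_fraction_target = 0.4,
                                seed = 12, margin_nm = 2, far_max_nm = 250)
  expect_equal(count_docked(jit, mesh), ref_count_docked(jit, mesh))
  expect_equal(count_docked(jit, mesh), sum(jit$docked))
})

test_that("docked count is monotone in the threshold", {
  mesh <- generate_spine_mesh(0.3, 0.5, 0.15)
  cloud <- generate_vesicle_cloud(120, mesh, 0.35, seed = 9)
  counts <- sapply(c(25, 50, 100, 200, 400, 700),
                   function(th) count_docked(cloud, mesh, th))
  expect_true(all(diff(counts) >= 0))
})

test_that("docked counting requires an active zone and finite coordinates", {
  mesh <- generate_spine_mesh(0.3, 0.5, 0.15)
  naked <- tagged_mesh(mesh$vertices, mesh$triangles,
                       regions = mesh$regions[c("head", "whole_spine")])
  cloud <- generate_vesicle_cloud(5, mesh, seed = 1)
  expect_error(count_docked(cloud, naked), "active_zone")
  bad <- cloud
  bad$x_nm[1] <- Inf
  expect_error(count_docked(bad, mesh), "finite")
})

test_that("PSD centroid distances follow translation geometry", {
  mesh <- generate_spine_mesh(0.3, 0.5, 0.15)
  expect_equal(psd_centroid_distance(mesh, mesh), 0)
  shifted <- mesh
  shifted$vertices <- sweep(mesh$vertices, 2, c(3, 4, 0), "+")
  expect_equal(psd_centroid_distance(mesh, shifted), 5)
  # area-weighted centroid agrees with a direct computation
  idx <- mesh$regions$psd
  tr <- mesh$triangles[idx, , drop = FALSE]
  v <- mesh$vertices
  w <- numeric(nrow(tr))
  cent <- matrix(0, nrow(tr), 3)
  for (i in seq_len(nrow(tr))) {
    a <- v[tr[i, 1], ]; b <- v[tr[i, 2], ]; c_ <- v[tr[i, 3], ]
    w[i] <- 0.5 * sqrt(sum(cross3(b - a, c_ - a)^2))
    cent[i, ] <- (a + b + c_) / 3
  }
  direct <- colSums(cent * w) / sum(w)
  expect_equal(region_centroid(mesh, "psd"), direct)
  naked <- tagged_mesh(mesh$vertices, mesh$triangles,
                       regions = list(head = mesh$regions$head))
  expect_error(psd_centroid_distance(naked, mesh), "no region")
})

test_that("point-to-triangle distances agree with the reference
           decomposition", {
  set.seed(77)
  a <- c(0, 0, 0); b <- c(1, 0, 0); c_ <- c(0.3, 1.2, 0)
  pts <- matrix(rnorm(300, sd = 1.5), 100, 3)
  fast <- synaptometry:::point_triangle_distance(pts, a, b, c_)
  slow <- apply(pts, 1, ref_point_tri_dist, a = a, b = b, c = c_)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("measurement error summarizes repeated tracings", {
  expect_equal(measurement_error(c(0.2, 0.2, 0.2))$sem, 0)
  me <- measurement_error(c(0.10, 0.10, 0.11, 0.11))
  expect_equal(me$mean, 0.105)
  expect_equal(me$sem, 0.00289, tolerance = 2e-3)
  expect_equal(me$relative_sem, 0.0275, tolerance = 2e-3)
  expect_error(measurement_error(0.3), "at least 2")
  expect_error(measurement_error(c(-0.1, 0.2)), "positive")
})

test_that("synthetic tracer noise reproduces ~1% median relative error", {
  # 4 replicate tracings per spine at 2% multiplicative noise
  set.seed(55)
  pop <- generate_population(population_config(seed = 55))
  rel <- sapply(pop$head_volume, function(v) {
    reps <- v * exp(rnorm(4, 0, 0.02))
    measurement_error(reps)$relative_sem
  })
  expect_equal(median(rel), 0.01, tolerance = 0.25)
  expect_lt(mean(rel > 0.05), 0.1)  # <5% error for the vast majority
})
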