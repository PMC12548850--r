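# Point-cloud preprocessing: accumulation, voxel downsampling, statistical
# outlier removal (vs the brute-force oracle), world transform, PLY I/O.

test_that("frame accumulation collapses exact duplicates only", {
  set.seed(2)
  a <- matrix(runif(300), 100, 3)
  shared <- a[1:40, ]
  b <- rbind(shared, matrix(runif(180), 60, 3))
  acc <- accumulate_frames(list(point_cloud(a), point_cloud(b)))
  expect_equal(n_points(acc), 160L)

  one <- accumulate_frames(list(point_cloud(a)))
  expect_equal(one$points, a, ignore_attr = TRUE)

  thirty <- accumulate_frames(rep(list(point_cloud(a)), 30))
  expect_equal(n_points(thirty), 100L)

  expect_error(accumulate_frames(list()), "non-empty")
})

test_that("accumulation is order-insensitive as a point set", {
  set.seed(3)
  a <- matrix(runif(60), 20, 3); b <- matrix(runif(90), 30, 3)
  ab <- accumulate_frames(list(point_cloud(a), point_cloud(b)))
  ba <- accumulate_frames(list(point_cloud(b), point_cloud(a)))
  key <- function(m) sort(apply(m, 1, paste, collapse = "/"))
  expect_equal(key(ab$points), key(ba$points))
})

test_that("voxel downsampling keeps the first point per occupied voxel", {
  one <- voxel_downsample(point_cloud(matrix(c(1, 2, 3), 1)), 0.01)
  expect_equal(n_points(one), 1L)

  two <- point_cloud(rbind(c(0.001, 0, 0), c(0.002, 0, 0)))
  kept <- voxel_downsample(two, 0.010)
  expect_equal(kept$points, matrix(c(0.001, 0, 0), 1))

  # 10x10x10 grid at 5 mm spacing, 10 mm voxels: 2 points per voxel per axis
  g <- grid_cloud(10, 0.005)
  ds <- voxel_downsample(g, 0.010)
  expect_equal(n_points(ds), 125L)
  expect_equal(n_points(ds), voxel_count_oracle(g$points, 0.010))

  expect_error(voxel_downsample(g, 0), "positive")
})

test_that("voxel downsampling is idempotent and never grows the cloud", {
  set.seed(4)
  cloud <- point_cloud(matrix(runif(900, 0, 0.3), 300, 3))
  for (vs in c(0.01, 0.05)) {
    once <- voxel_downsample(cloud, vs)
    expect_lte(n_points(once), n_points(cloud))
    twice <- voxel_downsample(once, vs)
    expect_equal(twice$points, once$points)
    expect_equal(n_points(once), voxel_count_oracle(cloud$points, vs))
  }
})

test_that("outlier removal matches the brute-force oracle", {
  # uniform grid with k = 3: every point (even a corner) has at least 3
  # neighbours at exactly one spacing, so all d_i are equal, the spread is
  # zero and nothing strictly exceeds the threshold
  g <- grid_cloud(6, 0.01)
  res <- remove_outliers(g, k = 3, sigma_mult = 2)
  expect_equal(res$removed, integer(0))
  expect_equal(res$mean_dist, knn_mean_dist_oracle(g$points, 3))
  expect_equal(knn_mean_dist_oracle(g$points, 6),
               remove_outliers(g, k = 6)$mean_dist)

  # Gaussian blob plus one far point: exactly the far point removed
  set.seed(7)
  blob <- matrix(rnorm(1500, 0, 0.02), 500, 3)
  far <- c(1, 0, 0)
  cloud <- point_cloud(rbind(blob, far))
  res <- remove_outliers(cloud, k = 30, sigma_mult = 2)
  expect_equal(res$removed, 501L)
  expect_equal(res$removed, remove_outliers_oracle(cloud$points, 30, 2))

  # random clouds, implementation vs oracle removal sets
  for (s in 1:3) {
    set.seed(100 + s)
    n <- sample(50:400, 1)
    pts <- matrix(rnorm(3 * n, 0, 0.05), n, 3)
    pts[sample(n, 5), ] <- pts[sample(n, 5), ] + 0.8
    res <- remove_outliers(point_cloud(pts), k = 10, sigma_mult = 1.5)
    expect_equal(res$removed, remove_outliers_oracle(pts, 10, 1.5))
  }
})

test_that("grid-accelerated kNN equals the oracle on large surface clouds", {
  # surface-like cloud (as produced by back-projecting a depth map)
  K <- small_K()
  set.seed(9)
  pts <- backproject_pixels(runif(3000, 0, K$width - 1),
                            runif(3000, 0, K$height - 1),
                            runif(3000, 0.5, 3), K)
  d_fast <- fruitfusion:::cpp_knn_mean_dist(pts, 30L)
  d_oracle <- knn_mean_dist_oracle(pts, 30)
  expect_equal(d_fast, d_oracle, tolerance = 1e-12)
})

test_that("outlier removal guards degenerate inputs and is monotone in sigma", {
  g <- grid_cloud(3, 0.01)  # 27 points
  expect_warning(res <- remove_outliers(g, k = 27), "unchanged")
  expect_equal(n_points(res$cloud), 27L)

  set.seed(8)
  pts <- rbind(matrix(rnorm(600, 0, 0.02), 200, 3),
               matrix(runif(30, 0.3, 0.6), 10, 3))
  removed_by_sigma <- vapply(c(0.5, 1, 2, 3), function(s) {
    length(remove_outliers(point_cloud(pts), k = 10, sigma_mult = s)$removed)
  }, numeric(1))
  expect_true(all(diff(removed_by_sigma) <= 0))
})

test_that("world transform applies scale and rigid motion, invertibly", {
  cloud <- point_cloud(rbind(c(1000, 0, 0), c(0, 500, 2000)))
  mm <- world_transform(cloud, diag(4), scale = 0.001)
  expect_equal(mm$points, rbind(c(1, 0, 0), c(0, 0.5, 2)))

  T <- diag(4); T[1:3, 4] <- c(0.1, -0.2, 0.3)
  ang <- 0.3
  T[1:2, 1:2] <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  fwd <- world_transform(mm, T, 1)
  back <- world_transform(fwd, solve(T), 1)
  expect_lt(max(abs(back$points - mm$points)), 1e-9)

  expect_equal(world_transform(mm)$points, mm$points)
})

test_that("PLY round trip preserves points and colors", {
  set.seed(10)
  pts <- matrix(runif(90, -2, 2), 30, 3)
  cols <- matrix(sample(0:255, 90, replace = TRUE), 30, 3)
  cloud <- point_cloud(pts, cols)
  dir <- withr::local_tempdir()
  for (fmt in c("ascii", "binary")) {
    path <- file.path(dir, paste0("cloud_", fmt, ".ply"))
    write_ply(cloud, path, format = fmt)
    back <- read_ply(path)
    # coordinates are stored as float32
    expect_equal(back$points, pts, tolerance = 1e-6)
    expect_equal(back$colors, cols, ignore_attr = TRUE)
  }
  # colorless cloud
  path <- file.path(dir, "plain.ply")
  write_ply(point_cloud(pts), path)
  expect_null(read_ply(path)$colors)
})
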