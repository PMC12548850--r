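# Shared fixtures: a small test camera, brute-force oracles, and tiny scene
# parameters sized for fast unit runs.

test_K <- function() camera_intrinsics(fx = 600, fy = 600, cx = 424, cy = 240,
                                       width = 848, height = 480)

small_K <- function() camera_intrinsics(fx = 100, fy = 100, cx = 52, cy = 30,
                                        width = 106, height = 60)

# Brute-force O(N^2) kNN mean-distance oracle (independent of the C++ path).
knn_mean_dist_oracle <- function(pts, k) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  vapply(seq_len(n), function(i) mean(sort(d[i, ])[seq_len(k)]), numeric(1))
}

# Brute-force statistical outlier removal oracle.
remove_outliers_oracle <- function(pts, k, sigma_mult) {
  d <- knn_mean_dist_oracle(pts, k)
  which(d > mean(d) + sigma_mult * sd(d))
}

# Brute-force voxel grouping oracle: count of occupied voxels.
voxel_count_oracle <- function(pts, voxel) {
  key <- apply(floor(pts / voxel), 1, paste, collapse = "/")
  length(unique(key))
}

# A regular 3-D grid cloud.
grid_cloud <- function(n_side, spacing, origin = c(0, 0, 0)) {
  g <- expand.grid(x = seq_len(n_side) - 1, y = seq_len(n_side) - 1,
                   z = seq_len(n_side) - 1)
  point_cloud(as.matrix(g) * spacing + rep(origin, each = nrow(g)))
}

tiny_scene_params <- function(seed = 1, ...) {
  scene_params(n_fruits = 4, clutter_density = 12, seed = seed, ...)
}
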