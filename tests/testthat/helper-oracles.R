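# Independent reference implementations and fixtures used across tests.

# Closed unit cube [0,1]^3 as a tagged mesh, outward oriented.
make_unit_cube <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tr <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom
              c(5, 6, 7), c(5, 7, 8),   # top
              c(1, 2, 6), c(1, 6, 5),   # front
              c(3, 4, 8), c(3, 8, 7),   # back
              c(1, 5, 8), c(1, 8, 4),   # left
              c(2, 3, 7), c(2, 7, 6))   # right
  tagged_mesh(v, tr, regions = list(all_faces = 1:12, top = 3:4,
                                    empty = integer(0)))
}

# Reference point-to-triangle distance via a different decomposition:
# distance to the plane if the foot lies inside the triangle, else the
# minimum of the three point-to-segment distances.
ref_point_tri_dist <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * w))^2))
  }
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n <- n / sqrt(sum(n^2))
  foot <- p - sum((p - a) * n) * n
  # barycentric test of the foot
  m <- cbind(b - a, c - a)
  coef <- tryCatch(qr.solve(m, foot - a), error = function(e) c(-1, -1))
  inside <- coef[1] >= 0 && coef[2] >= 0 && sum(coef) <= 1
  d_edges <- min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
  if (inside) min(abs(sum((p - a) * n)), d_edges) else d_edges
}

# Brute-force docked counter built on the reference distance.
ref_count_docked <- function(cloud, mesh, threshold_nm = 100) {
  pts <- as.matrix(cloud[, c("x_nm", "y_nm", "z_nm")]) / 1000
  idx <- mesh$regions$active_zone
  tr <- mesh$triangles[idx, , drop = FALSE]
  v <- mesh$vertices
  n_docked <- 0L
  for (i in seq_len(nrow(pts))) {
    d <- Inf
    for (j in seq_len(nrow(tr))) {
      d <- min(d, ref_point_tri_dist(pts[i, ], v[tr[j, 1], ],
                                     v[tr[j, 2], ], v[tr[j, 3], ]))
    }
    if (d * 1000 <= threshold_nm) n_docked <- n_docked + 1L
  }
  n_docked
}

# Small population with hand-laid connectivity for pair-finding tests.
make_toy_records <- function() {
  data.frame(
    spine_id = paste0("s", 1:8),
    dendrite_id = c("d1", "d1", "d1", "d2", "d2", "d3", "d3", "d3"),
    axon_id = c("a1", "a1", "a1", "a2", "a2", "a3", "a4", "a5"),
    head_volume = c(0.10, 0.11, 0.30, 0.20, 0.25, 0.15, 0.18, 0.22),
    stringsAsFactors = FALSE
  )
}

# Plain cross product, kept independent of the package internals.
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Rigid rotation matrix from an axis-angle (unit axis).
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}
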