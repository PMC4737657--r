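# Tagged triangulated surface meshes and the geometric measurements taken
# from them: convex-hull volumetry, region areas, neck volume by
# subtraction, docked-vesicle counts and PSD centroid distances.

#' Construct a tagged triangulated surface mesh
#'
#' A closed triangulated surface with named triangle-region tags, the
#' container for spine morphometry. Region tags identify at least the spine
#' `head` and `whole_spine` triangle sets (the head/neck boundary is a
#' human segmentation judgment and therefore an input, not a computation),
#' and optionally a `psd` and `active_zone` patch.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates in um.
#' @param triangles Integer m x 3 matrix of 1-based vertex indices; outward
#'   orientation is expected for volume computations.
#' @param regions Named list mapping region name to an integer vector of
#'   triangle indices. If both `head` and `whole_spine` are present, `head`
#'   must be a subset of `whole_spine`.
#' @param validate Check index bounds and region containment, default `TRUE`.
#' @return Object of class `"tagged_mesh"`.
#' @export
tagged_mesh <- function(vertices, triangles, regions = list(),
                        validate = TRUE) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  triangles <- matrix(as.integer(as.matrix(triangles)),
                      ncol = 3, dimnames = NULL)
  if (ncol(vertices) != 3) stop("`vertices` must be n x 3", call. = FALSE)
  if (validate) {
    if (any(triangles < 1) || any(triangles > nrow(vertices))) {
      stop("triangle indices out of range", call. = FALSE)
    }
    for (nm in names(regions)) {
      idx <- regions[[nm]]
      if (any(idx < 1) || any(idx > nrow(triangles))) {
        stop("region `", nm, "` has triangle indices out of range",
             call. = FALSE)
      }
    }
    if (all(c("head", "whole_spine") %in% names(regions)) &&
        !all(regions$head %in% regions$whole_spine)) {
      stop("region `head` must be a subset of `whole_spine`", call. = FALSE)
    }
  }
  structure(list(vertices = vertices, triangles = triangles,
                 regions = lapply(regions, as.integer)),
            class = "tagged_mesh")
}

#' @export
print.tagged_mesh <- function(x, ...) {
  cat(sprintf("Tagged mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  if (length(x$regions)) {
    cat("  regions:",
        paste(sprintf("%s (%d)", names(x$regions),
                      lengths(x$regions)), collapse = ", "), "\n")
  }
  invisible(x)
}

region_triangles <- function(mesh, region) {
  if (identical(region, "all")) return(seq_len(nrow(mesh$triangles)))
  if (!region %in% names(mesh$regions)) {
    stop("mesh has no region tagged `", region, "`", call. = FALSE)
  }
  mesh$regions[[region]]
}

#' Check that a mesh is watertight and manifold
#'
#' Every edge must be shared by exactly two triangles, with opposite
#' orientation (so the surface is closed, manifold and consistently
#' oriented) -- the precondition for volume computations.
#'
#' @param mesh A `"tagged_mesh"`.
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  # directed edges of each triangle
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  und <- table(key_und)
  if (any(und != 2)) return(FALSE)
  # consistent orientation: each directed edge appears exactly once
  !anyDuplicated(key_dir)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin); requires a watertight, consistently outward-oriented mesh.
#'
#' @param mesh A `"tagged_mesh"`.
#' @return Volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  if (!mesh_is_watertight(mesh)) {
    stop("mesh is not watertight; volume undefined", call. = FALSE)
  }
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
             a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
             a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  abs(vol)
}

#' Surface area of a tagged region
#'
#' Sum of the areas of the region's triangles.
#'
#' @param mesh A `"tagged_mesh"`.
#' @param region Region name, or `"all"` for the whole surface. An empty
#'   region set yields 0.
#' @return Area in um^2.
#' @export
region_area <- function(mesh, region) {
  idx <- region_triangles(mesh, region)
  if (length(idx) == 0) return(0)
  tr <- mesh$triangles[idx, , drop = FALSE]
  v <- mesh$vertices
  ab <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  ac <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Convex hull of a 3D point set
#'
#' Incremental convex hull: seeded with an extremal tetrahedron, each
#' remaining point outside the current hull removes its visible faces and is
#' reconnected along the horizon. Points interior to (or on) the running
#' hull are skipped, which leaves the hull and its volume unchanged.
#'
#' @param points Numeric n x 3 matrix (n >= 4, not all coplanar).
#' @return List with `faces` (k x 3 matrix of 1-based indices into `points`,
#'   outward oriented), `volume` and `area`.
#' @export
convex_hull_3d <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("`points` must be n x 3", call. = FALSE)
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(z) diff(range(z))), 1e-300)
  tol <- 1e-10 * scale
  if (n < 4) stop("degenerate region: need >= 4 points for a 3D hull",
                  call. = FALSE)

  seed <- hull_seed_tetrahedron(pts, tol)
  if (is.null(seed)) {
    stop("degenerate region: points are collinear or coplanar",
         call. = FALSE)
  }
  interior <- colMeans(pts[seed, , drop = FALSE])

  faces <- list(seed[c(1, 2, 3)], seed[c(1, 3, 4)],
                seed[c(1, 4, 2)], seed[c(2, 4, 3)])
  faces <- lapply(faces, orient_outward, pts = pts, interior = interior)

  for (p in setdiff(seq_len(n), seed)) {
    vis <- vapply(faces, function(f) {
      nrm <- tri_normal(pts[f[1], ], pts[f[2], ], pts[f[3], ])
      sum(nrm * (pts[p, ] - pts[f[1], ])) > tol
    }, logical(1))
    if (!any(vis)) next
    visible <- faces[vis]
    hidden <- faces[!vis]
    # horizon: undirected edges of visible faces not shared by two visible
    edges <- do.call(rbind, lapply(visible, function(f) {
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    newf <- lapply(seq_len(nrow(horizon)), function(i) {
      orient_outward(c(horizon[i, 1], horizon[i, 2], p), pts, interior)
    })
    faces <- c(hidden, newf)
  }

  fm <- do.call(rbind, faces)
  a <- pts[fm[, 1], , drop = FALSE]
  b <- pts[fm[, 2], , drop = FALSE]
  c_ <- pts[fm[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
             a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
             a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  ab <- b - a
  ac <- c_ - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  list(faces = fm, volume = abs(vol), area = sum(sqrt(rowSums(cr^2))) / 2)
}

# Pick four points spanning a non-degenerate tetrahedron, or NULL.
hull_seed_tetrahedron <- function(pts, tol) {
  i1 <- which.min(pts[, 1])
  i2 <- which.max(pts[, 1])
  if (sqrt(sum((pts[i1, ] - pts[i2, ])^2)) < tol) {
    # x-extent degenerate; try other axes
    for (ax in 2:3) {
      i1 <- which.min(pts[, ax]); i2 <- which.max(pts[, ax])
      if (sqrt(sum((pts[i1, ] - pts[i2, ])^2)) >= tol) break
    }
    if (sqrt(sum((pts[i1, ] - pts[i2, ])^2)) < tol) return(NULL)
  }
  d <- pts[i2, ] - pts[i1, ]
  # farthest from the line i1-i2
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * d[3] - rel[, 3] * d[2],
              rel[, 3] * d[1] - rel[, 1] * d[3],
              rel[, 1] * d[2] - rel[, 2] * d[1])
  dist_line <- sqrt(rowSums(cr^2)) / sqrt(sum(d^2))
  i3 <- which.max(dist_line)
  if (dist_line[i3] < tol) return(NULL)
  # farthest from the plane i1-i2-i3
  nrm <- tri_normal(pts[i1, ], pts[i2, ], pts[i3, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dist_plane <- abs(rel %*% nrm)
  i4 <- which.max(dist_plane)
  if (dist_plane[i4] < tol) return(NULL)
  c(i1, i2, i3, i4)
}

tri_normal <- function(a, b, c_) {
  u <- b - a
  v <- c_ - a
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

orient_outward <- function(f, pts, interior) {
  nrm <- tri_normal(pts[f[1], ], pts[f[2], ], pts[f[3], ])
  if (sum(nrm * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

#' Convex-hull volume of a tagged mesh region
#'
#' The measured volume of a spine head or whole spine: the volume of the
#' convex hull of the vertices belonging to the region's triangles. For the
#' convex regions the segmentation produces in practice, the hull coincides
#' with the enclosed surface; for non-convex regions `clip = "grid"`
#' subtracts (by regular-grid point sampling and ray-parity inside tests)
#' the part of the hull that lies outside the closed mesh.
#'
#' @param mesh A watertight `"tagged_mesh"`.
#' @param region Region name (must contain >= 4 non-coplanar vertices).
#' @param clip `"none"` (default) or `"grid"`.
#' @param grid_n Sampling resolution per axis for `clip = "grid"`.
#' @return Volume in um^3.
#' @export
region_hull_volume <- function(mesh, region, clip = c("none", "grid"),
                               grid_n = 24) {
  clip <- match.arg(clip)
  if (!mesh_is_watertight(mesh)) {
    stop("mesh is not watertight; hull volume not meaningful", call. = FALSE)
  }
  idx <- region_triangles(mesh, region)
  if (length(idx) == 0) stop("region `", region, "` is empty", call. = FALSE)
  vids <- unique(as.vector(mesh$triangles[idx, , drop = FALSE]))
  hull <- convex_hull_3d(mesh$vertices[vids, , drop = FALSE])
  if (clip == "none") return(hull$volume)

  # fraction of hull-interior sample points also inside the closed mesh
  pts <- mesh$vertices[vids, , drop = FALSE]
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  # cell midpoints: strictly interior samples avoid on-surface ambiguity
  mid <- function(a, b) {
    h <- (b - a) / grid_n
    seq(a + h / 2, b - h / 2, length.out = grid_n)
  }
  gx <- mid(lo[1], hi[1])
  gy <- mid(lo[2], hi[2])
  gz <- mid(lo[3], hi[3])
  grid <- as.matrix(expand.grid(gx, gy, gz))
  in_hull <- points_in_hull(grid, pts, hull$faces)
  if (!any(in_hull)) return(hull$volume)
  inside_mesh <- vapply(which(in_hull), function(i) {
    point_in_mesh(grid[i, ], mesh)
  }, logical(1))
  hull$volume * mean(inside_mesh)
}

points_in_hull <- function(query, pts, faces) {
  ok <- rep(TRUE, nrow(query))
  for (i in seq_len(nrow(faces))) {
    f <- faces[i, ]
    nrm <- tri_normal(pts[f[1], ], pts[f[2], ], pts[f[3], ])
    d <- sweep(query, 2, pts[f[1], ]) %*% nrm
    ok <- ok & (d <= 1e-12)
  }
  ok
}

# Ray-parity inside test along +x with a slightly irrational direction to
# dodge edge-on hits.
point_in_mesh <- function(p, mesh) {
  dir <- c(0.577350269189626, 0.211324865405187, 0.788675134594813)
  v <- mesh$vertices
  tr <- mesh$triangles
  hits <- 0L
  for (i in seq_len(nrow(tr))) {
    a <- v[tr[i, 1], ]; b <- v[tr[i, 2], ]; c_ <- v[tr[i, 3], ]
    # Moller-Trumbore
    e1 <- b - a; e2 <- c_ - a
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * h)
    if (abs(det) < 1e-14) next
    s <- p - a
    u <- sum(s * h) / det
    if (u < 0 || u > 1) next
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    vv <- sum(dir * q) / det
    if (vv < 0 || u + vv > 1) next
    t <- sum(e2 * q) / det
    if (t > 1e-12) hits <- hits + 1L
  }
  (hits %% 2L) == 1L
}

#' Neck volume by subtraction
#'
#' The spine neck volume is the difference between the whole-spine and the
#' head volume measurements.
#'
#' @param whole Whole-spine volume (um^3).
#' @param head Head volume (um^3); must not exceed `whole` (a head larger
#'   than its whole spine flags a segmentation inconsistency).
#' @return `whole - head` in um^3.
#' @export
neck_volume <- function(whole, head) {
  if (any(head > whole)) {
    stop("head volume exceeds whole-spine volume: inconsistent segmentation",
         call. = FALSE)
  }
  whole - head
}

#' Minimum distance from points to a mesh region
#'
#' Exact minimum point-to-triangle distance from each query point to the
#' triangles of a tagged region.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh A `"tagged_mesh"`.
#' @param region Region name.
#' @return Numeric vector of distances in the mesh's units.
#' @export
min_distance_to_region <- function(points, mesh, region) {
  idx <- region_triangles(mesh, region)
  if (length(idx) == 0) stop("region `", region, "` is empty", call. = FALSE)
  points <- matrix(as.numeric(points), ncol = 3)
  tr <- mesh$triangles[idx, , drop = FALSE]
  v <- mesh$vertices
  d <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(tr))) {
    a <- v[tr[i, 1], ]; b <- v[tr[i, 2], ]; c_ <- v[tr[i, 3], ]
    d <- pmin(d, point_triangle_distance(points, a, b, c_))
  }
  d
}

# Distance from each row of `p` to triangle (a, b, c): project onto the
# triangle plane, clamp to the triangle via barycentric regions (Ericson's
# region decomposition, vectorized over points).
point_triangle_distance <- function(p, a, b, c_) {
  ab <- b - a
  ac <- c_ - a
  ap <- sweep(p, 2, a)
  d1 <- ap %*% ab
  d2 <- ap %*% ac
  bp <- sweep(p, 2, b)
  d3 <- bp %*% ab
  d4 <- bp %*% ac
  cp <- sweep(p, 2, c_)
  d5 <- cp %*% ab
  d6 <- cp %*% ac

  n <- nrow(p)
  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)

  set_pt <- function(which, pt) {
    sel <- which & !done
    if (any(sel)) {
      res[sel, ] <<- matrix(pt, sum(sel), 3, byrow = TRUE)
      done[which] <<- TRUE
    }
  }
  # vertex regions
  set_pt(d1 <= 0 & d2 <= 0, a)
  set_pt(d3 >= 0 & d4 <= d3, b)
  set_pt(d6 >= 0 & d5 <= d6, c_)
  # edge ab
  vc <- d1 * d4 - d3 * d2
  sel <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(sel)) {
    t <- d1[sel] / (d1[sel] - d3[sel])
    res[sel, ] <- matrix(a, sum(sel), 3, byrow = TRUE) + outer(t, ab)
    done[sel] <- TRUE
  }
  # edge ac
  vb <- d5 * d2 - d1 * d6
  sel <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(sel)) {
    t <- d2[sel] / (d2[sel] - d6[sel])
    res[sel, ] <- matrix(a, sum(sel), 3, byrow = TRUE) + outer(t, ac)
    done[sel] <- TRUE
  }
  # edge bc
  va <- d3 * d6 - d5 * d4
  sel <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(sel)) {
    t <- (d4[sel] - d3[sel]) / ((d4[sel] - d3[sel]) + (d5[sel] - d6[sel]))
    res[sel, ] <- matrix(b, sum(sel), 3, byrow = TRUE) + outer(t, c_ - b)
    done[sel] <- TRUE
  }
  # interior
  sel <- !done
  if (any(sel)) {
    denom <- va + vb + vc
    v_ <- vb[sel] / denom[sel]
    w <- vc[sel] / denom[sel]
    res[sel, ] <- matrix(a, sum(sel), 3, byrow = TRUE) +
      outer(as.vector(v_), ab) + outer(as.vector(w), ac)
  }
  sqrt(rowSums((p - res)^2))
}

#' Count docked vesicles by the 100-nm membrane-distance rule
#'
#' A vesicle is counted as docked when its center lies within `threshold_nm`
#' of the presynaptic active-zone membrane (the region across from the PSD):
#' the minimum point-to-triangle distance from the center to the
#' `active_zone` triangles is at most the threshold (closed inequality).
#' Mesh coordinates are in um and vesicle centers in nm; the conversion is
#' internal.
#'
#' @param cloud A vesicle cloud: data frame with `x_nm`, `y_nm`, `z_nm`
#'   columns (see [generate_vesicle_cloud()]), or an n x 3 matrix in nm.
#' @param mesh A `"tagged_mesh"` (um) with an `active_zone` region.
#' @param threshold_nm Distance threshold in nm, default 100.
#' @return Integer count of docked vesicles.
#' @export
count_docked <- function(cloud, mesh, threshold_nm = 100) {
  pts <- vesicle_centers_nm(cloud)
  if (!"active_zone" %in% names(mesh$regions)) {
    stop("mesh has no region tagged `active_zone`", call. = FALSE)
  }
  if (nrow(pts) == 0) return(0L)
  d <- min_distance_to_region(pts / 1000, mesh, "active_zone") * 1000
  sum(d <= threshold_nm)
}

vesicle_centers_nm <- function(cloud) {
  if (is.data.frame(cloud)) {
    need <- c("x_nm", "y_nm", "z_nm")
    if (!all(need %in% names(cloud))) {
      stop("vesicle cloud must have columns x_nm, y_nm, z_nm", call. = FALSE)
    }
    pts <- as.matrix(cloud[, need])
  } else {
    pts <- as.matrix(cloud)
    if (nrow(pts) > 0 && ncol(pts) != 3) {
      stop("vesicle matrix must be n x 3 (nm)", call. = FALSE)
    }
  }
  if (nrow(pts) > 0 && any(!is.finite(pts))) {
    stop("vesicle coordinates must be finite", call. = FALSE)
  }
  pts
}

#' Area-weighted centroid of a tagged region
#'
#' @param mesh A `"tagged_mesh"`.
#' @param region Region name (non-empty).
#' @return Length-3 numeric vector (um).
#' @export
region_centroid <- function(mesh, region) {
  idx <- region_triangles(mesh, region)
  if (length(idx) == 0) stop("region `", region, "` is empty", call. = FALSE)
  tr <- mesh$triangles[idx, , drop = FALSE]
  v <- mesh$vertices
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  w <- sqrt(rowSums(cr^2)) / 2
  cent <- (a + b + c_) / 3
  unname(colSums(cent * w) / sum(w))
}

#' Distance between the PSD centroids of two spines
#'
#' Euclidean distance between the area-weighted centroids of the two `psd`
#' regions -- the between-synapse distance measure used along axons.
#'
#' @param mesh_a,mesh_b `"tagged_mesh"` objects, each with a `psd` region.
#' @return Distance in um.
#' @export
psd_centroid_distance <- function(mesh_a, mesh_b) {
  sqrt(sum((region_centroid(mesh_a, "psd") -
            region_centroid(mesh_b, "psd"))^2))
}

#' Repeated-measurement error of spine head volume
#'
#' Segmenting a spine head involves human judgment, so volumes are measured
#' several times (e.g. four times, twice each by two tracers) and the
#' standard error of the mean summarizes the measurement error.
#'
#' @param measurements Numeric vector of repeated head-volume measurements
#'   (um^3), length >= 2, all positive.
#' @return List with `mean` (um^3), `sem` (sd / sqrt(k), um^3) and
#'   `relative_sem` (sem / mean, dimensionless).
#' @examples
#' measurement_error(c(0.10, 0.10, 0.11, 0.11))
#' @export
measurement_error <- function(measurements) {
  if (length(measurements) < 2) {
    stop("need at least 2 repeated measurements", call. = FALSE)
  }
  if (any(measurements <= 0)) {
    stop("measurements must be positive", call. = FALSE)
  }
  m <- mean(measurements)
  sem <- stats::sd(measurements) / sqrt(length(measurements))
  list(mean = m, sem = sem, relative_sem = sem / m)
}
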