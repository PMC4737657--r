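# Synthetic neuropil: spine-metric populations with realistic cross-metric
# correlation structure, axon-coupled pair structure with a calibrated
# within-pair jitter, toy spine meshes and presynaptic vesicle clouds with
# ground-truth docked labels.

# Fixed per-component substream offsets added to the top-level seed, so each
# stage is reproducible in isolation.
SEED_OFFSETS <- c(population = 0L, pairs = 1000L, vesicles = 2000L,
                  replicates = 3000L, null = 4000L)

#' Configuration of a synthetic spine population
#'
#' The head-volume population is modeled as log-normal: the observed
#' distributions are highly skewed with a long tail, and a log-normal with
#' log-scale `log_sigma = 0.6` reproduces the two anchors used throughout --
#' a random-pair median CV near 0.39 and (at n = 287) a max/min dynamic
#' range of the order of tens-fold. The remaining metrics are generated as
#' power laws of head volume with log-normal noise: strong coupling for head
#' area (r^2 ~ 0.99), intermediate for PSD area and docked vesicles, weak
#' for neck diameter, and none for neck length.
#'
#' @param n_spines Number of spines (>= 2), default 287.
#' @param median_head_volume Median head volume in um^3, default 0.05.
#' @param log_sigma Standard deviation of natural-log head volume (> 0),
#'   default 0.6.
#' @param range_factor_target Nominal dynamic range (max/min) the population
#'   is expected to span (~60); recorded for reporting, not enforced on the
#'   sample.
#' @param metric_coupling Named list of per-metric coupling parameters, each
#'   a list with `exponent`, `prefactor` and `log_noise_sd` (>= 0); see
#'   [default_metric_coupling()].
#' @param n_dendrites Number of dendrites spines are distributed over,
#'   default 15.
#' @param seed Integer seed.
#' @return A validated list of class `"population_config"`.
#' @export
population_config <- function(n_spines = 287, median_head_volume = 0.05,
                              log_sigma = 0.6, range_factor_target = 60,
                              metric_coupling = default_metric_coupling(),
                              n_dendrites = 15, seed = 1) {
  cfg <- list(n_spines = n_spines, median_head_volume = median_head_volume,
              log_sigma = log_sigma,
              range_factor_target = range_factor_target,
              metric_coupling = metric_coupling,
              n_dendrites = n_dendrites, seed = seed)
  issues <- validate_population_config(cfg)
  if (length(issues)) {
    stop("invalid population config: ", paste(issues, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "population_config")
}

validate_population_config <- function(cfg) {
  issues <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  chk(is.numeric(cfg$n_spines) && cfg$n_spines >= 2,
      "n_spines: must be >= 2")
  chk(is.numeric(cfg$median_head_volume) && cfg$median_head_volume > 0,
      "median_head_volume: must be > 0")
  chk(is.numeric(cfg$log_sigma) && cfg$log_sigma > 0,
      "log_sigma: must be > 0")
  chk(is.numeric(cfg$range_factor_target) && cfg$range_factor_target > 1,
      "range_factor_target: must be > 1")
  chk(is.numeric(cfg$n_dendrites) && cfg$n_dendrites >= 1,
      "n_dendrites: must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed: must be a single integer")
  for (m in names(cfg$metric_coupling)) {
    cp <- cfg$metric_coupling[[m]]
    chk(all(c("exponent", "prefactor", "log_noise_sd") %in% names(cp)),
        paste0("metric_coupling.", m,
               ": needs exponent, prefactor, log_noise_sd"))
    if (!is.null(cp$log_noise_sd)) {
      chk(cp$log_noise_sd >= 0,
          paste0("metric_coupling.", m, ".log_noise_sd: must be >= 0"))
    }
    if (!is.null(cp$prefactor)) {
      chk(cp$prefactor > 0,
          paste0("metric_coupling.", m, ".prefactor: must be > 0"))
    }
  }
  issues
}

#' Default cross-metric coupling parameters
#'
#' Power-law couplings `metric = prefactor * head_volume^exponent *
#' exp(noise)` with `noise ~ N(0, log_noise_sd^2)`. Head area tracks volume
#' almost deterministically (a quasi-spherical head has area proportional to
#' V^(2/3); the small log-noise leaves r^2 ~ 0.99). PSD area and docked
#' vesicles scale close to linearly with volume with moderate scatter, neck
#' diameter couples only weakly, and neck length is independent of head
#' volume (`exponent = 0`). Neck volume is derived from neck length and
#' diameter as a cylinder, not sampled.
#'
#' @return Named list of coupling parameter lists.
#' @export
default_metric_coupling <- function() {
  list(
    head_area = list(exponent = 2 / 3, prefactor = 4.84, log_noise_sd = 0.04),
    psd_area = list(exponent = 0.9, prefactor = 0.46, log_noise_sd = 0.25),
    docked_vesicles = list(exponent = 0.8, prefactor = 120,
                           log_noise_sd = 0.30),
    neck_diameter = list(exponent = 0.1, prefactor = 0.19,
                         log_noise_sd = 0.25),
    neck_length = list(exponent = 0, prefactor = 0.60, log_noise_sd = 0.50)
  )
}

#' Generate a synthetic spine-record population
#'
#' Draws `n_spines` head volumes from the configured log-normal and derives
#' the coupled metrics from the power laws in `config$metric_coupling`.
#' Docked-vesicle counts are Poisson draws around the power-law mean. Every
#' spine initially receives a unique axon; dendrites are assigned uniformly.
#' The whole-spine volume is head volume plus the cylindrical neck volume,
#' so the additive volume invariant holds by construction. Deterministic
#' given `config$seed`.
#'
#' @param config A `"population_config"` (or plain list with the same
#'   fields).
#' @return A data frame with one row per spine and columns `spine_id`,
#'   `dendrite_id`, `axon_id`, `head_volume` (um^3), `head_area` (um^2),
#'   `psd_area` (um^2), `neck_length` (um), `neck_diameter` (um),
#'   `neck_volume` (um^3), `docked_vesicles` (count) and
#'   `whole_spine_volume` (um^3). The config is attached as attribute
#'   `"config"`.
#' @examples
#' pop <- generate_population(population_config(n_spines = 50, seed = 7))
#' cor(log(pop$head_area), log(pop$head_volume))^2 # ~0.99
#' @export
generate_population <- function(config = population_config()) {
  if (!inherits(config, "population_config")) {
    config <- do.call(population_config, config)
  }
  set.seed(as.integer(config$seed) + SEED_OFFSETS[["population"]])
  n <- as.integer(config$n_spines)
  v <- stats::rlnorm(n, meanlog = log(config$median_head_volume),
                     sdlog = config$log_sigma)

  powerlaw <- function(metric) {
    cp <- config$metric_coupling[[metric]]
    cp$prefactor * v^cp$exponent *
      exp(stats::rnorm(n, 0, cp$log_noise_sd))
  }
  head_area <- powerlaw("head_area")
  psd_area <- powerlaw("psd_area")
  neck_diameter <- powerlaw("neck_diameter")
  neck_length <- powerlaw("neck_length")
  docked <- stats::rpois(n, lambda = powerlaw("docked_vesicles"))
  neck_vol <- pi * (neck_diameter / 2)^2 * neck_length

  out <- data.frame(
    spine_id = sprintf("spine_%03d", seq_len(n)),
    dendrite_id = sprintf("dend_%02d",
                          sample(config$n_dendrites, n, replace = TRUE)),
    axon_id = sprintf("axon_%03d", seq_len(n)),
    head_volume = v,
    head_area = head_area,
    psd_area = psd_area,
    neck_length = neck_length,
    neck_diameter = neck_diameter,
    neck_volume = neck_vol,
    docked_vesicles = docked,
    whole_spine_volume = v + neck_vol,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  out
}

#' Calibrate the within-pair log-jitter to a target median pair CV
#'
#' Pair members are generated as `v * exp(+delta/2)` and `v * exp(-delta/2)`
#' with `delta ~ N(0, sigma_delta^2)`, so each pair's CV is exactly
#' `sqrt(2) * tanh(|delta| / 2)` -- independent of the base size `v`. The
#' median over pairs is therefore `sqrt(2) * tanh(median|delta| / 2)` with
#' `median|delta| = qnorm(0.75) * sigma_delta` (the half-normal median,
#' 0.6745 sigma). Inverting gives the closed form
#' \deqn{\sigma_\delta = \frac{2\,\mathrm{atanh}(\mathrm{CV}^*/\sqrt{2})}
#'   {\Phi^{-1}(0.75)}.}
#'
#' @param target_median_cv Target median pair CV in `[0, 1)`; the empirical
#'   anchor is 0.083.
#' @return The calibrated `sigma_delta` (dimensionless); 0 maps to 0, and
#'   0.083 maps to ~0.1742.
#' @export
calibrate_within_pair_sd <- function(target_median_cv) {
  if (!is.numeric(target_median_cv) || length(target_median_cv) != 1 ||
      is.na(target_median_cv) || target_median_cv < 0 ||
      target_median_cv >= 1) {
    stop("`target_median_cv` must be in [0, 1)", call. = FALSE)
  }
  if (target_median_cv == 0) return(0)
  2 * atanh(target_median_cv / sqrt(2)) / stats::qnorm(0.75)
}

#' Configuration of axon-coupled pair generation
#'
#' Exactly one of `within_pair_log_sd` and `target_median_pair_cv` may be
#' left `NULL`; the other is derived via [calibrate_within_pair_sd()] (or
#' its forward map).
#'
#' @param n_pairs Number of axon-coupled same-dendrite pairs, default 17.
#' @param within_pair_log_sd Standard deviation `sigma_delta` of the
#'   log-ratio of pair members (>= 0), or `NULL` to derive from the target.
#' @param target_median_pair_cv Target median pair CV, or `NULL` to derive
#'   from `within_pair_log_sd`. Default 0.083.
#' @param seed Integer seed.
#' @return A list of class `"pair_config"` with both parameters filled in.
#' @export
pair_config <- function(n_pairs = 17, within_pair_log_sd = NULL,
                        target_median_pair_cv = 0.083, seed = 1) {
  if (is.null(within_pair_log_sd) && is.null(target_median_pair_cv)) {
    stop("one of `within_pair_log_sd` / `target_median_pair_cv` must be set",
         call. = FALSE)
  }
  if (is.null(within_pair_log_sd)) {
    within_pair_log_sd <- calibrate_within_pair_sd(target_median_pair_cv)
  } else {
    if (within_pair_log_sd < 0) {
      stop("within_pair_log_sd: must be >= 0", call. = FALSE)
    }
    if (is.null(target_median_pair_cv)) {
      target_median_pair_cv <-
        sqrt(2) * tanh(stats::qnorm(0.75) * within_pair_log_sd / 2)
    }
  }
  if (n_pairs < 0) stop("n_pairs: must be >= 0", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs),
                 within_pair_log_sd = within_pair_log_sd,
                 target_median_pair_cv = target_median_pair_cv,
                 seed = seed),
            class = "pair_config")
}

#' Plant axon-coupled same-dendrite pairs in a population
#'
#' Selects `2 * n_pairs` spines, draws each pair's base size from the
#' population's head-volume distribution, and sets the two members to
#' `v * exp(+delta/2)` and `v * exp(-delta/2)` with
#' `delta ~ N(0, sigma_delta^2)`. The multiplicative, symmetric jitter
#' preserves the pair geometric mean (and hence the shape of the population
#' distribution on the log scale). Both members receive the same axon and
#' dendrite id; all other spines keep their unique axons. Metrics coupled to
#' head volume are re-derived for the modified members from the population's
#' coupling config.
#'
#' @param population A spine-record data frame from [generate_population()].
#' @param config A `"pair_config"`.
#' @return List with `population` (the modified records) and `truth` (data
#'   frame of planted pairs: `pair_id`, member ids, `base_volume`, `delta`,
#'   and the realized `pair_cv`).
#' @export
generate_coupled_pairs <- function(population, config = pair_config()) {
  if (!inherits(config, "pair_config")) config <- do.call(pair_config, config)
  n <- nrow(population)
  if (n < 1) stop("population is empty", call. = FALSE)
  if (2L * config$n_pairs > n) {
    stop("n_pairs * 2 (", 2L * config$n_pairs,
         ") exceeds population size (", n, ")", call. = FALSE)
  }
  set.seed(as.integer(config$seed) + SEED_OFFSETS[["pairs"]])
  pop <- population
  if (config$n_pairs == 0) {
    return(list(population = pop,
                truth = data.frame(pair_id = character(0),
                                   spine_a = character(0),
                                   spine_b = character(0),
                                   base_volume = numeric(0),
                                   delta = numeric(0),
                                   pair_cv = numeric(0))))
  }
  members <- matrix(sample(n, 2L * config$n_pairs, replace = FALSE),
                    ncol = 2)
  base_v <- sample(population$head_volume, config$n_pairs, replace = TRUE)
  delta <- stats::rnorm(config$n_pairs, 0, config$within_pair_log_sd)

  pcfg <- attr(population, "config")
  truth <- vector("list", config$n_pairs)
  for (k in seq_len(config$n_pairs)) {
    ia <- members[k, 1]
    ib <- members[k, 2]
    va <- base_v[k] * exp(delta[k] / 2)
    vb <- base_v[k] * exp(-delta[k] / 2)
    pop$head_volume[ia] <- va
    pop$head_volume[ib] <- vb
    pop$axon_id[c(ia, ib)] <- sprintf("axon_pair_%02d", k)
    pop$dendrite_id[ib] <- pop$dendrite_id[ia]
    if (!is.null(pcfg)) {
      for (i in c(ia, ib)) {
        pop <- rederive_metrics(pop, i, pcfg)
      }
    }
    truth[[k]] <- data.frame(
      pair_id = sprintf("pair_%02d", k),
      spine_a = pop$spine_id[ia], spine_b = pop$spine_id[ib],
      base_volume = base_v[k], delta = delta[k],
      pair_cv = pair_cv(va, vb), stringsAsFactors = FALSE
    )
  }
  attr(pop, "config") <- pcfg
  list(population = pop, truth = do.call(rbind, truth))
}

# Re-sample the volume-coupled metrics of record `i` after its head volume
# changed, keeping the additive volume identity.
rederive_metrics <- function(pop, i, pcfg) {
  v <- pop$head_volume[i]
  pl <- function(metric) {
    cp <- pcfg$metric_coupling[[metric]]
    cp$prefactor * v^cp$exponent * exp(stats::rnorm(1, 0, cp$log_noise_sd))
  }
  pop$head_area[i] <- pl("head_area")
  pop$psd_area[i] <- pl("psd_area")
  pop$docked_vesicles[i] <- stats::rpois(1, pl("docked_vesicles"))
  pop$neck_diameter[i] <- pl("neck_diameter")
  pop$neck_volume[i] <- pi * (pop$neck_diameter[i] / 2)^2 * pop$neck_length[i]
  pop$whole_spine_volume[i] <- v + pop$neck_volume[i]
  pop
}

#' Toy spine mesh: spherical head on a cylindrical neck
#'
#' Builds a closed, watertight surface of revolution: a sphere of the radius
#' implied by `head_volume` joined to a cylindrical neck of the given length
#' and diameter, with triangle tags for `head` (the spherical part above the
#' head/neck junction), `whole_spine` (everything), and a `psd` patch at the
#' top pole, mirrored as `active_zone` (in this toy fixture the apposed
#' presynaptic membrane coincides with the PSD patch). Analytic ground-truth
#' measurements are attached as attribute `"truth"`: the head volume is the
#' spherical-cap volume above the junction plane, the neck volume is the
#' exact cylinder volume, and the head area is the spherical-zone area.
#'
#' @param head_volume Nominal head volume in um^3 (the sphere's volume);
#'   must be positive.
#' @param neck_length Neck length in um; zero is allowed only with
#'   `allow_zero_neck = TRUE`.
#' @param neck_diameter Neck diameter in um; must be positive and smaller
#'   than the head diameter.
#' @param n_theta Azimuthal segments, default 48.
#' @param n_phi Polar rows on the spherical part, default 32.
#' @param psd_fraction Approximate fraction of polar rows tagged as PSD,
#'   default 0.15.
#' @param allow_zero_neck Permit a degenerate zero-length neck, default
#'   `FALSE`.
#' @return A `"tagged_mesh"` with attribute `"truth"`: list with
#'   `head_volume` (cap), `neck_volume`, `whole_volume`, `head_area`,
#'   `sphere_radius` and `junction_z`.
#' @export
generate_spine_mesh <- function(head_volume, neck_length, neck_diameter,
                                n_theta = 48, n_phi = 32,
                                psd_fraction = 0.15,
                                allow_zero_neck = FALSE) {
  if (head_volume <= 0) stop("head_volume must be positive", call. = FALSE)
  if (neck_diameter <= 0) stop("neck_diameter must be positive", call. = FALSE)
  if (neck_length < 0 || (neck_length == 0 && !allow_zero_neck)) {
    stop("neck_length must be positive (zero only with allow_zero_neck)",
         call. = FALSE)
  }
  r <- (3 * head_volume / (4 * pi))^(1 / 3)
  rn <- neck_diameter / 2
  if (rn >= r) {
    stop("neck_diameter must be smaller than the head diameter",
         call. = FALSE)
  }
  zj <- -sqrt(r^2 - rn^2)        # junction plane (head meets neck)
  theta_j <- acos(zj / r)        # polar angle of the junction ring
  phis <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]

  verts <- matrix(c(0, 0, r), ncol = 3,
                  dimnames = NULL)             # top pole, vertex 1
  ring_start <- integer(n_phi)                 # first vertex id of each ring
  thetas <- seq(0, theta_j, length.out = n_phi + 1)[-1]
  for (i in seq_len(n_phi)) {
    th <- thetas[i]
    ring_start[i] <- nrow(verts) + 1L
    verts <- rbind(verts, cbind(r * sin(th) * cos(phis),
                                r * sin(th) * sin(phis),
                                r * cos(th)))
  }
  # bottom neck ring (same radius as junction ring) and bottom center
  zb <- zj - neck_length
  bottom_start <- nrow(verts) + 1L
  verts <- rbind(verts, cbind(rn * cos(phis), rn * sin(phis), zb))
  bottom_center <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, zb))

  tris <- list()
  tags <- list()
  add <- function(tri, tag) {
    tris[[length(tris) + 1L]] <<- tri
    tags[[length(tags) + 1L]] <<- tag
  }
  nxt <- function(j) if (j == n_theta) 1L else j + 1L
  # top fan (row 0)
  for (j in seq_len(n_theta)) {
    add(c(1L, ring_start[1] + j - 1L, ring_start[1] + nxt(j) - 1L),
        "sphere_row_1")
  }
  # sphere quad rows
  for (i in seq_len(n_phi - 1)) {
    a <- ring_start[i]
    b <- ring_start[i + 1]
    for (j in seq_len(n_theta)) {
      j2 <- nxt(j)
      add(c(a + j - 1L, b + j - 1L, b + j2 - 1L), paste0("sphere_row_", i + 1))
      add(c(a + j - 1L, b + j2 - 1L, a + j2 - 1L), paste0("sphere_row_", i + 1))
    }
  }
  # neck wall: junction ring (last sphere ring) down to bottom ring
  a <- ring_start[n_phi]
  for (j in seq_len(n_theta)) {
    j2 <- nxt(j)
    add(c(a + j - 1L, bottom_start + j - 1L, bottom_start + j2 - 1L), "neck")
    add(c(a + j - 1L, bottom_start + j2 - 1L, a + j2 - 1L), "neck")
  }
  # bottom cap fan (faces down)
  for (j in seq_len(n_theta)) {
    j2 <- nxt(j)
    add(c(bottom_center, bottom_start + j2 - 1L, bottom_start + j - 1L),
        "neck")
  }

  trimat <- do.call(rbind, tris)
  tagvec <- unlist(tags)
  sphere_idx <- which(startsWith(tagvec, "sphere_row_"))
  psd_rows <- max(2L, round(psd_fraction * n_phi))
  psd_idx <- which(tagvec %in% paste0("sphere_row_", seq_len(psd_rows)))

  mesh <- tagged_mesh(
    verts, trimat,
    regions = list(head = sphere_idx,
                   whole_spine = seq_len(nrow(trimat)),
                   psd = psd_idx,
                   active_zone = psd_idx)
  )
  h <- r - zj  # cap height above the junction plane
  attr(mesh, "truth") <- list(
    head_volume = pi * h^2 * (3 * r - h) / 3,
    neck_volume = pi * rn^2 * neck_length,
    whole_volume = pi * h^2 * (3 * r - h) / 3 + pi * rn^2 * neck_length,
    head_area = 2 * pi * r * h,
    sphere_radius = r,
    junction_z = zj
  )
  mesh
}

#' Synthetic presynaptic vesicle cloud with ground-truth docked labels
#'
#' Places vesicle centers radially above the mesh's `active_zone` patch: a
#' known docked subset at distances strictly below the docking threshold and
#' the rest well beyond it, with a guard margin on both sides of the
#' boundary so the ground-truth labels are unambiguous. Labels are assigned
#' at generation time, giving the 100-nm counter ([count_docked()]) an
#' exact oracle.
#'
#' @param n_vesicles Total number of vesicle centers (>= 0).
#' @param mesh A `"tagged_mesh"` (um) with an `active_zone` region.
#' @param docked_fraction_target Fraction placed on the docked side, default
#'   0.3.
#' @param seed Integer seed.
#' @param threshold_nm Docking threshold in nm, default 100.
#' @param margin_nm Guard margin kept clear on each side of the threshold,
#'   default 5 nm.
#' @param far_max_nm Farthest placement distance in nm, default 600.
#' @param terminal_id,associated_spine_id Identifier labels carried in the
#'   output.
#' @return A data frame of class `"vesicle_cloud"` with columns `x_nm`,
#'   `y_nm`, `z_nm`, `terminal_id` and the logical ground truth `docked`.
#' @export
generate_vesicle_cloud <- function(n_vesicles, mesh,
                                   docked_fraction_target = 0.3, seed = 1,
                                   threshold_nm = 100, margin_nm = 5,
                                   far_max_nm = 600,
                                   terminal_id = "terminal_01",
                                   associated_spine_id = "spine_001") {
  if (!"active_zone" %in% names(mesh$regions)) {
    stop("mesh has no region tagged `active_zone`", call. = FALSE)
  }
  if (n_vesicles < 0) stop("n_vesicles must be >= 0", call. = FALSE)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      z_nm = numeric(0), terminal_id = character(0),
                      docked = logical(0), stringsAsFactors = FALSE)
  if (n_vesicles == 0) {
    out <- structure(empty, class = c("vesicle_cloud", "data.frame"))
    attr(out, "associated_spine_id") <- associated_spine_id
    return(out)
  }
  set.seed(as.integer(seed) + SEED_OFFSETS[["vesicles"]])
  n_docked <- round(docked_fraction_target * n_vesicles)
  docked <- c(rep(TRUE, n_docked), rep(FALSE, n_vesicles - n_docked))

  # anchor points: vertices of the active-zone patch (um), offset radially
  az_tris <- mesh$triangles[mesh$regions$active_zone, , drop = FALSE]
  az_verts <- unique(as.vector(az_tris))
  anchors <- mesh$vertices[az_verts[sample.int(length(az_verts), n_vesicles,
                                               replace = TRUE)], ,
                           drop = FALSE]
  dirs <- anchors / sqrt(rowSums(anchors^2))  # outward radial (sphere at 0)
  d_nm <- ifelse(docked,
                 stats::runif(n_vesicles, margin_nm,
                              threshold_nm - margin_nm),
                 stats::runif(n_vesicles,
                              1.05 * (threshold_nm + margin_nm), far_max_nm))
  centers_nm <- (anchors + dirs * d_nm / 1000) * 1000
  out <- data.frame(x_nm = centers_nm[, 1], y_nm = centers_nm[, 2],
                    z_nm = centers_nm[, 3], terminal_id = terminal_id,
                    docked = docked, stringsAsFactors = FALSE)
  out <- structure(out, class = c("vesicle_cloud", "data.frame"))
  attr(out, "associated_spine_id") <- associated_spine_id
  out
}
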