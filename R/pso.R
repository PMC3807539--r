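# Multiswarm PSO over constrained polar sections. Each section holds one
# swarm whose particles are 1-D radial positions along the section bisector;
# the fitness is the interpolated Euclidean distance-map value at the
# particle's image point (0 = on an edge, lower is better).

#' PSO configuration
#'
#' Defaults follow the CT preset: 9 scaled contours (= particles per swarm),
#' 45 snaxels (control points = polar sections), 10 iterations, inertia
#' weight 0.5 and learning factor 0.9. The `mr` preset uses 7 scaled
#' contours, 35 snaxels, 10 iterations, inertia 0.4, learning 0.7.
#'
#' @param n_scaled_contours number of radially scaled template copies; also
#'   the number of particles per swarm.
#' @param n_control_points number of snaxels = polar sections.
#' @param iterations PSO iterations per swarm.
#' @param inertia inertia weight (weight of the previous velocity).
#' @param learning learning factor (attraction to personal/global bests).
#' @param seed master RNG seed; per-swarm child streams are derived from it.
#' @param scale_range (low, high) radial multipliers bracketing the target
#'   boundary; also the per-section search bounds.
#' @param stability_stop if `TRUE`, a swarm stops early once its best fitness
#'   changes by < 1e-6 for 3 consecutive iterations.
#' @return a `pso_config` list.
#' @export
pso_config <- function(n_scaled_contours = 9L, n_control_points = 45L,
                       iterations = 10L, inertia = 0.5, learning = 0.9,
                       seed = 1L, scale_range = c(0.7, 1.3),
                       stability_stop = FALSE) {
  if (n_scaled_contours < 1) stop("n_scaled_contours must be >= 1")
  if (n_control_points < 3) stop("n_control_points must be >= 3")
  if (iterations < 0) stop("iterations must be >= 0")
  if (inertia < 0 || learning < 0) stop("inertia and learning must be >= 0")
  if (scale_range[1] <= 0 || scale_range[1] > scale_range[2])
    stop("scale_range must satisfy 0 < low <= high")
  structure(list(n_scaled_contours = as.integer(n_scaled_contours),
                 n_control_points = as.integer(n_control_points),
                 iterations = as.integer(iterations),
                 inertia = inertia, learning = learning,
                 seed = as.integer(seed), scale_range = scale_range,
                 stability_stop = isTRUE(stability_stop)),
            class = "pso_config")
}

#' Preset PSO configurations
#'
#' `"ct"`: 9 scaled contours, 45 snaxels, 10 iterations, inertia 0.5,
#' learning 0.9. `"mr"`: 7 scaled contours, 35 snaxels, 10 iterations,
#' inertia 0.4, learning 0.7.
#'
#' @param preset `"ct"` or `"mr"`.
#' @param ... overrides passed to [pso_config()].
#' @return a `pso_config`.
#' @export
preset_config <- function(preset = c("ct", "mr"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ct = list(n_scaled_contours = 9L, n_control_points = 45L,
              iterations = 10L, inertia = 0.5, learning = 0.9),
    mr = list(n_scaled_contours = 7L, n_control_points = 35L,
              iterations = 10L, inertia = 0.4, learning = 0.7))
  do.call(pso_config, utils::modifyList(base, list(...)))
}

#' Initial particle radii from scaled template contours
#'
#' Scales each section's template boundary radius by `n_scaled_contours`
#' factors evenly spaced over `scale_range`; the resulting radii seed the
#' section's particles, and the section search bounds are
#' `(low * r_i, high * r_i)`, confining the target boundary.
#'
#' @param template a `template_shape`.
#' @param grid a [polar_grid()] (K = number of control points).
#' @param config a [pso_config()].
#' @return list with `radii` (K x n matrix of initial radii) and `bounds`
#'   (K x 2 matrix of per-section (r_min, r_max)).
#' @export
generate_scaled_contours <- function(template, grid, config) {
  if (sum(template$boundary) == 0) stop("template boundary is empty")
  base_r <- template_radii(template, grid$n_sections)
  n <- config$n_scaled_contours
  factors <- if (n == 1) mean(config$scale_range)
             else seq(config$scale_range[1], config$scale_range[2],
                      length.out = n)
  list(radii = outer(base_r, factors),
       bounds = cbind(r_min = config$scale_range[1] * base_r,
                      r_max = config$scale_range[2] * base_r))
}

#' Distance-map fitness of a radial control point
#'
#' Bilinearly interpolated distance-map value at the point
#' `origin + radius * (cos(theta_i), sin(theta_i))` on the section bisector;
#' lower is better, 0 means the point lies on an edge. Points outside the
#' frame return `Inf` (improper particle).
#'
#' @param radius radial position(s), px.
#' @param section section index (1-based).
#' @param grid a [polar_grid()].
#' @param dmap distance map from [distance_map()].
#' @return fitness value(s); `Inf` outside the frame.
#' @export
radial_fitness <- function(radius, section, grid, dmap) {
  th <- grid$angles[section]
  v <- bilinear_at(dmap, grid$origin[1] + radius * sin(th),
                   grid$origin[2] + radius * cos(th))
  ifelse(is.na(v), Inf, v)
}

#' Constrain a particle to its section search space
#'
#' Radii outside `(r_min, r_max)` are clamped to the violated bound with the
#' velocity zeroed; non-finite radii are resampled uniformly inside the
#' bounds (velocity zeroed).
#'
#' @param radius,velocity particle state.
#' @param bounds c(r_min, r_max), r_min < r_max.
#' @param rand uniform(0,1) sampler used for resampling.
#' @return list(radius, velocity).
#' @export
constrain_particle <- function(radius, velocity, bounds, rand = stats::runif) {
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy r_min < r_max")
  if (!is.finite(radius)) {
    radius <- bounds[1] + rand(1) * (bounds[2] - bounds[1])
    velocity <- 0
  } else if (radius < bounds[1]) {
    radius <- bounds[1]; velocity <- 0
  } else if (radius > bounds[2]) {
    radius <- bounds[2]; velocity <- 0
  }
  list(radius = radius, velocity = velocity)
}

#' Initialize a swarm for one polar section
#'
#' Particles start at the given radii with zero velocity; personal bests are
#' the initial positions and the global best is the fittest initial particle.
#'
#' @param section section index.
#' @param radii initial particle radii.
#' @param bounds c(r_min, r_max) search bounds.
#' @param fitness_fn function(radius) -> fitness (lower is better).
#' @return a `swarm` object.
#' @export
make_swarm <- function(section, radii, bounds, fitness_fn) {
  fit <- vapply(radii, fitness_fn, numeric(1))
  best <- which.min(fit)
  structure(list(
    section = section,
    radius = radii, velocity = rep(0, length(radii)),
    pbest_radius = radii, pbest_fitness = fit,
    gbest_radius = radii[best], gbest_fitness = fit[best],
    bounds = bounds, fitness_fn = fitness_fn
  ), class = "swarm")
}

#' One PSO iteration of a swarm
#'
#' For each particle in order: draw r1 then r2 from `rand`, update
#' `v <- inertia * v + learning * r1 * (pbest - x) + learning * r2 * (gbest - x)`
#' and `x <- x + v`, enforce the section constraint
#' ([constrain_particle()]), evaluate the fitness, and update the personal
#' best and (immediately) the swarm's global best when improved.
#'
#' @param swarm a `swarm` from [make_swarm()].
#' @param config a [pso_config()] (uses `inertia` and `learning`).
#' @param rand uniform(0,1) sampler; replaceable for deterministic tests.
#' @return the updated `swarm`.
#' @export
pso_step <- function(swarm, config, rand = stats::runif) {
  for (i in seq_along(swarm$radius)) {
    r1 <- rand(1); r2 <- rand(1)
    v <- config$inertia * swarm$velocity[i] +
      config$learning * r1 * (swarm$pbest_radius[i] - swarm$radius[i]) +
      config$learning * r2 * (swarm$gbest_radius - swarm$radius[i])
    x <- swarm$radius[i] + v
    st <- constrain_particle(x, v, swarm$bounds, rand)
    swarm$radius[i] <- st$radius
    swarm$velocity[i] <- st$velocity
    f <- swarm$fitness_fn(st$radius)
    if (f < swarm$pbest_fitness[i]) {
      swarm$pbest_fitness[i] <- f
      swarm$pbest_radius[i] <- st$radius
      if (f < swarm$gbest_fitness) {
        swarm$gbest_fitness <- f
        swarm$gbest_radius <- st$radius
      }
    }
  }
  swarm
}

#' Connect per-section best particles into a segmentation
#'
#' Builds the closed polygon through the K global-best control points in
#' section-angle order and rasterizes its interior to a binary mask.
#'
#' @param swarms list of K `swarm` objects (finite global bests).
#' @param grid the [polar_grid()] the swarms were built on.
#' @param frame c(height, width) of the output mask.
#' @return a `segmentation_result`: `contour` (data.frame section, angle,
#'   radius, row, col), `mask`, `origin`.
#' @export
assemble_contour <- function(swarms, grid, frame) {
  radii <- vapply(swarms, function(s) s$gbest_radius, numeric(1))
  if (any(!is.finite(radii)) ||
      any(!is.finite(vapply(swarms, function(s) s$gbest_fitness, numeric(1)))))
    stop("section unsolved: non-finite global best")
  th <- grid$angles
  vr <- grid$origin[1] + radii * sin(th)
  vc <- grid$origin[2] + radii * cos(th)
  h <- frame[1]; w <- frame[2]
  pts <- cbind(rep(0:(w - 1), each = h), rep.int(0:(h - 1), w)) # (x, y)
  inside <- mgcv::in.out(cbind(c(vc, vc[1]), c(vr, vr[1])), pts)
  structure(list(
    contour = data.frame(section = seq_along(th), angle = th, radius = radii,
                         row = vr, col = vc),
    mask = matrix(as.numeric(inside), h, w),
    origin = grid$origin
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation: %d control points, origin (%.1f, %.1f), area %d px\n",
              nrow(x$contour), x$origin[1], x$origin[2],
              as.integer(sum(x$mask))))
  invisible(x)
}

#' Segment an image with the polar multiswarm method
#'
#' Full pipeline on one image: edge extraction and Euclidean distance map,
#' mutual-information placement of the shape template, polar-grid
#' construction, scaled-contour seeding, independent per-section PSO, and
#' contour assembly. Deterministic for a fixed `config$seed` (per-swarm
#' child RNG streams keep sections independent).
#'
#' @param image numeric matrix in \[0, 1\].
#' @param template a `template_shape` (same frame size as `image`).
#' @param config a [pso_config()].
#' @param edge_threshold relative gradient threshold for the edge mask.
#' @param smooth_sigma Gaussian pre-smoothing sigma (px) before the gradient.
#' @param fitness `"dmap"` (distance map only, the default) or
#'   `"dmap+shape"`, which adds a shape-prior penalty
#'   `w2 * 0.5 * |r^2 - r_template^2| * (2 pi / K)` — the polar-area
#'   contribution of the control point to the shape energy.
#' @param w2 weight of the shape penalty when `fitness = "dmap+shape"`.
#' @return a `segmentation_result` with additional fields `traces`
#'   ((iterations+1) x K matrix of per-swarm best fitness), `grid`, `dmap`,
#'   `config`.
#' @export
run_segmentation <- function(image, template, config = pso_config(),
                             edge_threshold = 0.3, smooth_sigma = 1,
                             fitness = c("dmap", "dmap+shape"), w2 = 0.01) {
  check_image(image, min_dim = 8L)
  fitness <- match.arg(fitness)
  edges <- gradient_edge_mask(image, edge_threshold, smooth_sigma)
  if (sum(edges) == 0) stop("empty edge map: nothing to segment")
  dmap <- distance_map(edges)

  origin <- locate_origin(image, template)
  K <- config$n_control_points
  grid <- polar_grid(origin, K)
  seeds <- generate_scaled_contours(template, grid, config)

  set.seed(config$seed)
  child_seeds <- sample.int(2^30, K)

  n_iter <- config$iterations
  traces <- matrix(NA_real_, n_iter + 1L, K)
  swarms <- vector("list", K)
  for (k in seq_len(K)) {
    base_fit <- function(r) radial_fitness(r, k, grid, dmap)
    fit_fn <- if (fitness == "dmap") base_fit else {
      r_t <- mean(seeds$bounds[k, ]) / mean(config$scale_range) # template radius
      function(r) base_fit(r) + w2 * 0.5 * abs(r^2 - r_t^2) * (2 * pi / K)
    }
    sw <- make_swarm(k, seeds$radii[k, ], seeds$bounds[k, ], fit_fn)
    traces[1L, k] <- sw$gbest_fitness
    set.seed(child_seeds[k])
    stable <- 0L
    if (n_iter > 0) for (it in seq_len(n_iter)) {
      prev <- sw$gbest_fitness
      sw <- pso_step(sw, config)
      traces[it + 1L, k] <- sw$gbest_fitness
      if (config$stability_stop) {
        stable <- if (prev - sw$gbest_fitness < 1e-6) stable + 1L else 0L
        if (stable >= 3L) {
          traces[(it + 1L):(n_iter + 1L), k] <- sw$gbest_fitness
          break
        }
      }
    }
    swarms[[k]] <- sw
  }

  res <- assemble_contour(swarms, grid, dim(image))
  res$traces <- traces
  res$grid <- grid
  res$dmap <- dmap
  res$config <- config
  res
}
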