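# Scenario fixture generators: idealized cyst layouts (one lumen agent, an
# inner luminal-epithelial shell, an outer myoepithelial shell, enclosed by
# inert media generators) and random general-position point clouds. Both
# consume the current R random stream, so seed with set.seed() (or run them
# through the engine's stream) for reproducibility.

.ring_points <- function(n, radius, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(radius * cos(ang), radius * sin(ang))
}

# deterministic near-uniform sphere layout (golden-angle spiral)
.fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.jitter_ball <- function(n, d, jitter) {
  if (jitter <= 0) return(matrix(0, n, d))
  u <- matrix(rnorm(n * d), n, d)
  u <- u / sqrt(rowSums(u^2))
  r <- jitter * runif(n)^(1 / d)
  u * r
}

#' Generate an idealized cyst scenario
#'
#' One `lmn` (lumen) agent at the origin, `n_lec` luminal epithelial agents
#' on a circle (2D) or Fibonacci sphere (3D) of radius `r_lec`, `n_mec`
#' myoepithelial agents at `r_mec`, and `n_media` inert media generators at
#' `r_media` enclosing everything. Shells are phase-offset (2D) so that no
#' three generators are exactly collinear through the origin; `jitter` adds
#' an independent uniform displacement of norm at most `jitter` to each
#' biological shell point (media are left exact to guarantee enclosure).
#'
#' @param dimension 2 or 3.
#' @param n_lec,n_mec,n_media shell counts (at least 3 in 2D / 4 in 3D).
#' @param r_lumen lumen scale; the default shell radii are multiples of it.
#' @param r_lec,r_mec,r_media shell radii, `0 < r_lec < r_mec < r_media`.
#' @param jitter maximum displacement applied to lec/mec points.
#' @return a scenario data.frame (`id`, `type`, `x`, `y`, `z`, `info`); the
#'   generated layout is validated to keep every non-media V-cell bounded.
#' @export
generate_cyst <- function(dimension = 2L, n_lec = 8L, n_mec = 12L,
                          n_media = if (dimension == 2L) 24L else 48L,
                          r_lumen = 1, r_lec = 2 * r_lumen,
                          r_mec = 3.2 * r_lumen, r_media = 5.5 * r_lumen,
                          jitter = 0) {
  d <- as.integer(dimension)
  if (!(d %in% c(2L, 3L)))
    .vc_stop("vcellsim_invalid_input", "dimension must be 2 or 3")
  min_n <- if (d == 2L) 3L else 4L
  if (n_lec < min_n || n_mec < min_n || n_media < min_n)
    .vc_stop("vcellsim_invalid_input", "each shell needs at least %d points", min_n)
  if (!(0 < r_lec && r_lec < r_mec && r_mec < r_media))
    .vc_stop("vcellsim_invalid_input", "need 0 < r_lec < r_mec < r_media")
  if (d == 2L) {
    lec <- .ring_points(n_lec, r_lec)
    mec <- .ring_points(n_mec, r_mec, phase = pi / n_mec)
    med <- .ring_points(n_media, r_media, phase = pi / (2 * n_media))
  } else {
    lec <- .fibonacci_sphere(n_lec, r_lec)
    mec <- .fibonacci_sphere(n_mec, r_mec)
    med <- .fibonacci_sphere(n_media, r_media)
  }
  lec <- lec + .jitter_ball(n_lec, d, jitter)
  mec <- mec + .jitter_ball(n_mec, d, jitter)
  coords <- rbind(rep(0, d), lec, mec, med)
  types <- c("lmn", rep("lec", n_lec), rep("mec", n_mec), rep("media", n_media))
  scen <- data.frame(id = seq_len(nrow(coords)), type = types,
                     x = coords[, 1L], y = coords[, 2L],
                     z = if (d == 3L) coords[, 3L] else NA_real_,
                     info = NA_character_, stringsAsFactors = FALSE)
  mesh <- triangulate(scen[, c("id", "x", "y", if (d == 3L) "z")])
  bio <- scen$id[scen$type != "media"]
  if (length(intersect(bio, mesh$hull_ids)))
    .vc_stop("vcellsim_generation_error",
             "generated cyst is not media-enclosed; increase n_media or r_media")
  scen
}

#' Generate a random general-position point cloud scenario
#'
#' `n` points uniform in `bounds` with pairwise distance at least
#' `min_separation` (rejection sampling).
#'
#' @param dimension 2 or 3.
#' @param n number of points (at least `dimension + 1`).
#' @param bounds either `c(lo, hi)` applied to every axis or a 2 x d matrix
#'   (rows lo, hi).
#' @param min_separation minimum pairwise distance.
#' @param type cell type token assigned to every point (default `"lec"`).
#' @param max_tries rejection-sampling cap before an infeasible-density
#'   error.
#' @return a scenario data.frame.
#' @export
generate_random_cloud <- function(dimension = 2L, n = 30L, bounds = c(0, 1),
                                  min_separation = 0, type = "lec",
                                  max_tries = 1000L * n) {
  d <- as.integer(dimension)
  if (!(d %in% c(2L, 3L)) || n < d + 1L)
    .vc_stop("vcellsim_invalid_input", "need dimension 2 or 3 and n >= dim+1")
  if (is.matrix(bounds)) {
    lo <- bounds[1L, ]; hi <- bounds[2L, ]
  } else {
    lo <- rep(bounds[1L], d); hi <- rep(bounds[2L], d)
  }
  pts <- matrix(NA_real_, n, d)
  got <- 0L; tries <- 0L
  while (got < n) {
    if (tries >= max_tries)
      .vc_stop("vcellsim_infeasible_density",
               "could not place %d points with separation %g in %d tries",
               n, min_separation, max_tries)
    cand <- lo + runif(d) * (hi - lo)
    tries <- tries + 1L
    if (got > 0L && min_separation > 0) {
      dd <- sqrt(rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2L, cand)^2))
      if (any(dd < min_separation)) next
    }
    got <- got + 1L
    pts[got, ] <- cand
  }
  # resample degenerate minimal clouds (probability ~0, but cheap to guard)
  if (n == d + 1L && abs(.cpp_orient(pts)) <= .TOL_PREDICATE)
    return(generate_random_cloud(d, n, bounds, min_separation, type, max_tries))
  data.frame(id = seq_len(n), type = type,
             x = pts[, 1L], y = pts[, 2L],
             z = if (d == 3L) pts[, 3L] else NA_real_,
             info = NA_character_, stringsAsFactors = FALSE)
}

#' Hexagon growth fixture
#'
#' One lec "grower" at the origin surrounded by 6 lec agents at distance
#' `ring_radius` (a regular hexagon fan) inside a media ring: the canonical
#' fixture for the growth rule, whose initial center V-cell is a regular
#' hexagon of area `2*sqrt(3)*(ring_radius/2)^2`.
#'
#' @param ring_radius distance of the 6 ring agents from the grower.
#' @param r_media,n_media enclosing media ring.
#' @return a scenario data.frame; agent 1 is the central grower.
#' @export
hexagon_fixture <- function(ring_radius = 2, r_media = 4 * ring_radius,
                            n_media = 16L) {
  ring <- .ring_points(6L, ring_radius)
  med <- .ring_points(n_media, r_media, phase = pi / (2 * n_media))
  coords <- rbind(c(0, 0), ring, med)
  data.frame(id = seq_len(nrow(coords)),
             type = c(rep("lec", 7L), rep("media", n_media)),
             x = coords[, 1L], y = coords[, 2L], z = NA_real_,
             info = NA_character_, stringsAsFactors = FALSE)
}

#' Packaged demonstration scenarios
#'
#' Scripted counterparts of the framework's qualitative demonstrations:
#' `cyst2d` (movement + growth + division + death in a 2D cyst), `cyst3d`
#' (movement in a 3D cyst), `rotation2d` (lec shell rotating rigidly about
#' the lumen), `growth2d` (hexagon fixture growing to 1.5x its area) and
#' `absorb3d` (an outlying mec captured by the cyst).
#'
#' @param name one of `"cyst2d"`, `"cyst3d"`, `"rotation2d"`, `"growth2d"`,
#'   `"absorb3d"`.
#' @param steps number of engine steps (scripted demos interpret this as the
#'   number of scripted actions).
#' @param seed integer seed.
#' @return a `"dv_trajectory"`.
#' @export
run_demo <- function(name = c("cyst2d", "cyst3d", "rotation2d", "growth2d",
                              "absorb3d"),
                     steps = 100L, seed = 42L) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "cyst2d") {
    scen <- generate_cyst(2L, jitter = 0.08)
    cfg <- behavior_config(
      steps = steps, seed = seed,
      types = list(
        lec = list(program = c("move", "grow", "divide", "die"),
                   step_length = 0.02, target_factor = 1.15,
                   division_factor = 1.35, death_prob = 0.002),
        mec = list(program = c("move"), step_length = 0.02)))
    return(sim_run(cfg, scen))
  }
  if (name == "cyst3d") {
    scen <- generate_cyst(3L, n_lec = 12L, n_mec = 20L, n_media = 48L,
                          jitter = 0.08)
    cfg <- behavior_config(
      steps = steps, seed = seed,
      types = list(lec = list(program = "move", step_length = 0.02),
                   mec = list(program = "move", step_length = 0.02)))
    return(sim_run(cfg, scen))
  }
  if (name == "rotation2d") {
    scen <- generate_cyst(2L)
    cfg <- behavior_config(steps = 0L, seed = seed, theta = 2 * pi / steps)
    state <- simulation_state(scen, cfg)
    lec_ids <- state$agents$id[state$agents$type == "lec"]
    lmn_id <- state$agents$id[state$agents$type == "lmn"]
    summaries <- .summary_row(state)
    for (k in seq_len(steps)) {
      state <- act_rotate(state, lec_ids, lmn_id)
      state$step_index <- state$step_index + 1L
      summaries <- rbind(summaries, .summary_row(state))
    }
    return(structure(list(summaries = summaries, events = state$events,
                          final_state = state), class = "dv_trajectory"))
  }
  if (name == "growth2d") {
    scen <- hexagon_fixture()
    cfg <- behavior_config(steps = 0L, seed = seed)
    state <- simulation_state(scen, cfg)
    target <- 1.5 * vcell_measure(state$mesh, 1L)
    state <- act_grow(state, 1L, target = target)
    state$step_index <- state$step_index + 1L
    return(structure(list(summaries = .summary_row(state),
                          events = state$events, final_state = state),
                     class = "dv_trajectory"))
  }
  # absorb3d: cyst plus one outlying mec drawn into the lec shell
  scen <- generate_cyst(3L, n_lec = 12L, n_mec = 20L, n_media = 48L)
  outlier <- data.frame(id = max(scen$id) + 1L, type = "mec",
                        x = 0.55 * max(scen$x[scen$type == "media"]),
                        y = 0.31, z = 0.17, info = NA_character_,
                        stringsAsFactors = FALSE)
  scen <- rbind(scen, outlier)
  cfg <- behavior_config(steps = 0L, seed = seed,
                         types = list(mec = list(step_length = 0.1)))
  state <- simulation_state(scen, cfg)
  absorbers <- state$agents$id[state$agents$type %in% c("lmn", "lec")]
  state <- act_absorb(state, absorbers, outlier$id)
  state$step_index <- state$step_index + 1L
  structure(list(summaries = .summary_row(state), events = state$events,
                 final_state = state), class = "dv_trajectory")
}
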