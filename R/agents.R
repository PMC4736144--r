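# Biomimetic V-cell agent behaviors. Every behavior acts only on the agent's
# own fields and its 1-hop Delaunay neighborhood; media agents are inert and
# are never moved, grown, divided, removed or absorbed.

.alive_agents <- function(state) state$agents[state$agents$alive, , drop = FALSE]

.agent_idx <- function(state, agent_id, need_alive = TRUE) {
  i <- match(agent_id, state$agents$id)
  if (is.na(i) || (need_alive && !state$agents$alive[i]))
    .vc_stop("vcellsim_unknown_agent", "no alive agent with id %s",
             format(agent_id))
  i
}

.check_not_media <- function(state, i, what) {
  if (state$agents$type[i] == "media")
    .vc_stop("vcellsim_inert_agent", "%s: agent %d is media (inert)",
             what, state$agents$id[i])
}

.agent_coords <- function(state) {
  a <- .alive_agents(state)
  m <- cbind(a$x, a$y, if (state$dim == 3L) a$z)
  rownames(m) <- as.character(a$id)
  m
}

.rebuild <- function(state) {
  a <- .alive_agents(state)
  pts <- data.frame(id = a$id, x = a$x, y = a$y)
  if (state$dim == 3L) pts$z <- a$z
  state$mesh <- triangulate(pts)
  state
}

.state_diameter <- function(state) {
  m <- .agent_coords(state)
  sqrt(sum((apply(m, 2L, max) - apply(m, 2L, min))^2))
}

# TRUE if placing agent `agent_id` at `newpt` keeps it clear of all other
# alive centers (duplicate-point threshold)
.placement_ok <- function(state, agent_id, newpt) {
  m <- .agent_coords(state)
  m <- m[rownames(m) != as.character(agent_id), , drop = FALSE]
  dmin <- .DUP_FACTOR * .state_diameter(state)
  all(sqrt(rowSums(sweep(m, 2L, newpt)^2)) >= dmin)
}

.log_event <- function(state, event, agent, other = NA_integer_, detail = "") {
  state$events <- rbind(state$events, data.frame(
    step = state$step_index, event = event, agent = as.integer(agent),
    other = as.integer(other), detail = detail, stringsAsFactors = FALSE))
  state
}

# single seeded random stream, serialised in the state (and in checkpoints)
.with_rng <- function(state, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  if (is.null(state$rng_state)) set.seed(state$config$seed)
  else assign(".Random.seed", state$rng_state, envir = genv)
  value <- fn()
  state$rng_state <- get(".Random.seed", envir = genv)
  list(state = state, value = value)
}

.random_unit <- function(d) {
  if (d == 2L) {
    a <- runif(1L, 0, 2 * pi)
    c(cos(a), sin(a))
  } else {
    v <- rnorm(3L)
    v / sqrt(sum(v^2))
  }
}

.type_param <- function(state, type, name) state$config$types[[type]][[name]]

#' Move an agent
#'
#' Displaces the agent's center by `step_length * u`, where `u` is a uniform
#' random unit vector, or, when the agent has a bias direction, the
#' normalised sum of the bias and a random unit vector scaled by the type's
#' `noise_weight` (noise weight 0 gives a deterministic biased step). The
#' mesh is rebuilt. A displacement that would land within the
#' duplicate-point threshold of another center is rejected: the state is
#' returned unchanged apart from a logged `move_rejected` event.
#'
#' @param state a `"dv_state"`.
#' @param agent_id id of an alive, non-media agent.
#' @return the updated state.
#' @export
act_move <- function(state, agent_id) {
  i <- .agent_idx(state, agent_id)
  .check_not_media(state, i, "act_move")
  d <- state$dim
  step_len <- state$agents$step_length[i]
  r <- .with_rng(state, function() .random_unit(d))
  state <- r$state
  u <- r$value
  bias <- c(state$agents$bias_x[i], state$agents$bias_y[i],
            if (d == 3L) state$agents$bias_z[i])
  if (!any(is.na(bias))) {
    nw <- .type_param(state, state$agents$type[i], "noise_weight")
    v <- bias / sqrt(sum(bias^2)) + nw * u
    u <- v / sqrt(sum(v^2))
  }
  if (step_len == 0)
    return(.log_event(state, "move", agent_id, detail = "step_length 0"))
  old <- c(state$agents$x[i], state$agents$y[i], if (d == 3L) state$agents$z[i])
  newpt <- old + step_len * u
  if (!.placement_ok(state, agent_id, newpt))
    return(.log_event(state, "move_rejected", agent_id))
  state$agents$x[i] <- newpt[1L]
  state$agents$y[i] <- newpt[2L]
  if (d == 3L) state$agents$z[i] <- newpt[3L]
  state <- .rebuild(state)
  .log_event(state, "move", agent_id)
}

#' Grow an agent toward its target size
#'
#' While the agent's V-cell measure is below `target` and fewer than `k_grow`
#' iterations have run, every 1-hop non-media neighbor is displaced outward
#' along the (agent center -> neighbor center) direction by a fixed increment
#' `delta_push_frac` x (mean neighbor distance); the mesh is rebuilt after
#' each iteration. The grower's own center never moves, and since each
#' bisector constraint of its V-cell can only relax, the measure is
#' non-decreasing across iterations.
#'
#' @inheritParams act_move
#' @param target optional absolute target measure; defaults to the agent's
#'   `target_size`.
#' @return the updated state.
#' @export
act_grow <- function(state, agent_id, target = NULL) {
  i <- .agent_idx(state, agent_id)
  .check_not_media(state, i, "act_grow")
  target <- target %||% state$agents$target_size[i]
  if (is.na(target))
    .vc_stop("vcellsim_invalid_input", "agent %d has no target size", agent_id)
  g <- c(state$agents$x[i], state$agents$y[i], if (state$dim == 3L) state$agents$z[i])
  iters <- 0L
  k_grow <- state$config$k_grow
  repeat {
    m <- vcell_measure(state$mesh, agent_id)   # unbounded-cell error on hull
    if (m >= target || iters >= k_grow) break
    nb <- neighbors(state$mesh, agent_id)
    rows <- match(nb, state$agents$id)
    keep <- state$agents$type[rows] != "media"
    nb <- nb[keep]; rows <- rows[keep]
    if (length(nb) == 0L) break
    nbm <- cbind(state$agents$x[rows], state$agents$y[rows],
                 if (state$dim == 3L) state$agents$z[rows])
    dists <- sqrt(rowSums(sweep(nbm, 2L, g)^2))
    delta <- state$config$delta_push_frac * mean(dists)
    for (k in seq_along(nb)) {
      dir <- (nbm[k, ] - g) / dists[k]
      newpt <- nbm[k, ] + delta * dir
      if (!.placement_ok(state, nb[k], newpt)) next
      j <- rows[k]
      state$agents$x[j] <- newpt[1L]
      state$agents$y[j] <- newpt[2L]
      if (state$dim == 3L) state$agents$z[j] <- newpt[3L]
    }
    state <- .rebuild(state)
    iters <- iters + 1L
  }
  .log_event(state, "grow", agent_id,
             detail = sprintf("iters=%d measure=%.8g", iters,
                              vcell_measure(state$mesh, agent_id)))
}

#' Divide an agent
#'
#' Creates a daughter agent with a fresh id that inherits the parent's type,
#' step length, division threshold and bias. The daughter center is placed at
#' `eps_div_frac * step_length` from the parent in a random direction
#' (resampled up to 10 times if the placement would collide). Parent and
#' daughter target sizes are each set to half the parent's pre-division
#' target size; the daughter records the parent id as its lineage.
#'
#' @inheritParams act_move
#' @return the updated state.
#' @export
act_divide <- function(state, agent_id) {
  i <- .agent_idx(state, agent_id)
  .check_not_media(state, i, "act_divide")
  d <- state$dim
  eps_div <- state$config$eps_div_frac * state$agents$step_length[i]
  if (eps_div <= 0) {
    # non-motile divider: fall back to a fraction of local neighbor spacing
    nb <- neighbors(state$mesh, agent_id)
    rows <- match(nb, state$agents$id)
    g <- c(state$agents$x[i], state$agents$y[i], if (d == 3L) state$agents$z[i])
    nbm <- cbind(state$agents$x[rows], state$agents$y[rows],
                 if (d == 3L) state$agents$z[rows])
    eps_div <- 1e-3 * mean(sqrt(rowSums(sweep(nbm, 2L, g)^2)))
  }
  old <- c(state$agents$x[i], state$agents$y[i], if (d == 3L) state$agents$z[i])
  placed <- NULL
  for (try in 1:10) {
    r <- .with_rng(state, function() .random_unit(d))
    state <- r$state
    cand <- old + eps_div * r$value
    if (.placement_ok(state, agent_id, cand) &&
        sqrt(sum((cand - old)^2)) >= .DUP_FACTOR * .state_diameter(state)) {
      placed <- cand
      break
    }
  }
  if (is.null(placed))
    .vc_stop("vcellsim_duplicate_point",
             "act_divide: no collision-free daughter placement for agent %d",
             agent_id)
  new_id <- max(state$agents$id) + 1L
  parent <- state$agents[i, , drop = FALSE]
  half_target <- parent$target_size / 2
  state$agents$target_size[i] <- half_target
  daughter <- parent
  daughter$id <- new_id
  daughter$x <- placed[1L]; daughter$y <- placed[2L]
  if (d == 3L) daughter$z <- placed[3L]
  daughter$target_size <- half_target
  daughter$lineage <- agent_id
  daughter$group <- NA_character_
  state$agents <- rbind(state$agents, daughter)
  rownames(state$agents) <- NULL
  state <- .rebuild(state)
  .log_event(state, "divide", agent_id, other = new_id)
}

#' Remove an agent (death / disintegration)
#'
#' Deletes the agent's generator and rebuilds the mesh; neighboring V-cells
#' expand passively to fill the void. With `lambda_fill > 0` the former
#' 1-hop non-media neighbors additionally drift toward the removed center by
#' that fraction of their distance, mimicking active void filling.
#'
#' @inheritParams act_move
#' @param lambda_fill drift fraction in `[0, 1]`; defaults to the config
#'   value (0 reproduces pure passive re-tessellation).
#' @return the updated state.
#' @export
act_remove <- function(state, agent_id, lambda_fill = NULL) {
  i <- .agent_idx(state, agent_id)
  .check_not_media(state, i, "act_remove")
  lambda_fill <- lambda_fill %||% state$config$lambda_fill
  d <- state$dim
  void <- c(state$agents$x[i], state$agents$y[i], if (d == 3L) state$agents$z[i])
  former <- neighbors(state$mesh, agent_id)
  state$agents$alive[i] <- FALSE
  state <- .rebuild(state)
  if (lambda_fill > 0) {
    rows <- match(former, state$agents$id)
    keep <- state$agents$type[rows] != "media" & state$agents$alive[rows]
    for (j in rows[keep]) {
      p <- c(state$agents$x[j], state$agents$y[j], if (d == 3L) state$agents$z[j])
      newpt <- p + lambda_fill * (void - p)
      if (!.placement_ok(state, state$agents$id[j], newpt)) next
      state$agents$x[j] <- newpt[1L]
      state$agents$y[j] <- newpt[2L]
      if (d == 3L) state$agents$z[j] <- newpt[3L]
    }
    state <- .rebuild(state)
  }
  .log_event(state, "remove", agent_id)
}

#' Absorb an agent into a group
#'
#' Iterative capture: at each iteration the target center moves by at most
#' its `step_length` toward the centroid of the absorber centers and the mesh
#' is rebuilt; capture completes when every non-media 1-hop neighbor of the
#' target belongs to `absorber_ids`. On completion the target is flagged with
#' a group label (its type is unchanged).
#'
#' @inheritParams act_move
#' @param absorber_ids non-empty set of alive agent ids doing the absorbing.
#' @param target_id id of the alive, non-media agent being absorbed.
#' @return the updated state.
#' @export
act_absorb <- function(state, absorber_ids, target_id) {
  if (length(absorber_ids) == 0L)
    .vc_stop("vcellsim_invalid_input", "act_absorb: empty absorber set")
  for (a in absorber_ids) .agent_idx(state, a)
  ti <- .agent_idx(state, target_id)
  .check_not_media(state, ti, "act_absorb")
  if (target_id %in% absorber_ids)
    .vc_stop("vcellsim_invalid_input", "target cannot be an absorber")
  d <- state$dim
  step_len <- state$agents$step_length[ti]
  if (step_len <= 0)
    .vc_stop("vcellsim_invalid_input", "target has step_length 0; cannot be drawn in")
  arow <- match(absorber_ids, state$agents$id)
  centroid <- c(mean(state$agents$x[arow]), mean(state$agents$y[arow]),
                if (d == 3L) mean(state$agents$z[arow]))
  iters <- 0L
  repeat {
    nb <- neighbors(state$mesh, target_id)
    nb_type <- state$agents$type[match(nb, state$agents$id)]
    if (all(nb[nb_type != "media"] %in% absorber_ids)) break
    if (iters >= state$config$k_absorb)
      .vc_stop("vcellsim_absorb_stalled",
               "act_absorb: capture of agent %d did not complete in %d iterations",
               target_id, state$config$k_absorb)
    ti <- .agent_idx(state, target_id)
    p <- c(state$agents$x[ti], state$agents$y[ti], if (d == 3L) state$agents$z[ti])
    gap <- centroid - p
    dist <- sqrt(sum(gap^2))
    if (dist > 0) {
      newpt <- p + min(step_len, dist) * gap / dist
      if (.placement_ok(state, target_id, newpt)) {
        state$agents$x[ti] <- newpt[1L]
        state$agents$y[ti] <- newpt[2L]
        if (d == 3L) state$agents$z[ti] <- newpt[3L]
        state <- .rebuild(state)
      }
    }
    iters <- iters + 1L
  }
  state$agents$group[ti] <- sprintf("absorbed:%d", min(as.integer(absorber_ids)))
  .log_event(state, "absorb", target_id, other = min(as.integer(absorber_ids)),
             detail = sprintf("iters=%d", iters))
}

#' Rigidly rotate a group of agents about a pivot (2D only)
#'
#' All group centers are rotated by `theta` radians about the pivot agent's
#' center in one rigid map; the mesh is rebuilt once.
#'
#' @inheritParams act_move
#' @param group_ids alive non-media agents to rotate (must not contain the
#'   pivot).
#' @param pivot_id alive agent acting as the rotation center.
#' @param theta rotation angle in radians; defaults to the config value.
#' @return the updated state.
#' @export
act_rotate <- function(state, group_ids, pivot_id, theta = NULL) {
  if (state$dim != 2L)
    .vc_stop("vcellsim_unsupported_dimension", "act_rotate is 2D only")
  theta <- theta %||% state$config$theta
  if (pivot_id %in% group_ids)
    .vc_stop("vcellsim_invalid_input", "pivot cannot be in the rotating group")
  rows <- vapply(group_ids, function(g) .agent_idx(state, g), 1L)
  for (j in rows) .check_not_media(state, j, "act_rotate")
  pi_ <- .agent_idx(state, pivot_id)
  pv <- c(state$agents$x[pi_], state$agents$y[pi_])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  rel <- cbind(state$agents$x[rows], state$agents$y[rows]) - matrix(pv, length(rows), 2L, byrow = TRUE)
  newm <- rel %*% t(R) + matrix(pv, length(rows), 2L, byrow = TRUE)
  state$agents$x[rows] <- newm[, 1L]
  state$agents$y[rows] <- newm[, 2L]
  state <- .rebuild(state)
  .log_event(state, "rotate", pivot_id,
             detail = sprintf("n=%d theta=%.8g", length(rows), theta))
}
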