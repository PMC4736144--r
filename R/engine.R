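# Discrete-step scheduler: one activation per alive non-media agent per step,
# in an order shuffled by the single seeded stream; the mesh is rebuilt after
# every topology-mutating action, so agents acting later within a step see
# updated neighborhoods.

.CHECKPOINT_FORMAT <- "vcellsim-checkpoint"
.CHECKPOINT_VERSION <- 1L

.empty_events <- function() data.frame(
  step = integer(), event = character(), agent = integer(),
  other = integer(), detail = character(), stringsAsFactors = FALSE)

#' Construct a simulation state from a scenario
#'
#' Merges a scenario table (see [read_scenario()], [generate_cyst()],
#' [generate_random_cloud()]) with a behavior configuration into a runnable
#' state: per-agent behavior parameters are filled in from the per-type
#' config, target sizes defaulting to `target_factor` x the agent's initial
#' V-cell measure, division thresholds to `division_factor` x the initial
#' measure (an absolute `division_threshold` overrides). The initial mesh is
#' built and the media-enclosure invariant is validated.
#'
#' @param scenario a data.frame with columns `id`, `type`, `x`, `y`
#'   (optionally `z`, `info`), or the list returned by [read_scenario()].
#' @param config a `"dv_config"` from [behavior_config()].
#' @return an object of class `"dv_state"`.
#' @export
simulation_state <- function(scenario, config = behavior_config()) {
  if (is.list(scenario) && !is.data.frame(scenario) && !is.null(scenario$agents))
    scenario <- scenario$agents
  stopifnot(inherits(config, "dv_config"))
  need <- c("id", "type", "x", "y")
  if (!all(need %in% names(scenario)))
    .vc_stop("vcellsim_invalid_input", "scenario needs columns %s",
             paste(need, collapse = ", "))
  if (!all(scenario$type %in% .CELL_TYPES))
    .vc_stop("vcellsim_invalid_input", "unknown cell type(s): %s",
             paste(setdiff(unique(scenario$type), .CELL_TYPES), collapse = ", "))
  d <- if ("z" %in% names(scenario) && !all(is.na(scenario$z))) 3L else 2L
  ag <- data.frame(
    id = as.integer(scenario$id),
    type = as.character(scenario$type),
    x = as.numeric(scenario$x), y = as.numeric(scenario$y),
    z = if (d == 3L) as.numeric(scenario$z) else NA_real_,
    stringsAsFactors = FALSE)
  tp <- function(name) vapply(ag$type, function(t) {
    v <- config$types[[t]][[name]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 1.0, USE.NAMES = FALSE)
  ag$step_length <- ifelse(ag$type == "media", 0, tp("step_length"))
  ag$target_size <- NA_real_
  ag$division_threshold <- NA_real_
  bias_of <- function(t, k) {
    b <- config$types[[t]]$bias
    if (is.null(b)) NA_real_ else as.numeric(b[k])
  }
  ag$bias_x <- vapply(ag$type, bias_of, 1.0, k = 1L, USE.NAMES = FALSE)
  ag$bias_y <- vapply(ag$type, bias_of, 1.0, k = 2L, USE.NAMES = FALSE)
  ag$bias_z <- if (d == 3L) vapply(ag$type, bias_of, 1.0, k = 3L, USE.NAMES = FALSE) else NA_real_
  ag$alive <- TRUE
  ag$lineage <- NA_integer_
  ag$group <- NA_character_
  ag$info <- if ("info" %in% names(scenario)) as.character(scenario$info) else NA_character_

  state <- structure(list(
    agents = ag, dim = d, config = config, mesh = NULL,
    step_index = 0L, rng_state = NULL, events = .empty_events()
  ), class = "dv_state")
  state <- .rebuild(state)
  validate_state(state)
  # size-dependent defaults need the initial tessellation
  bio <- which(ag$type != "media")
  for (i in bio) {
    m0 <- vcell_measure(state$mesh, ag$id[i])
    tf <- config$types[[ag$type[i]]]$target_factor
    state$agents$target_size[i] <- tf * m0
    abs_thr <- config$types[[ag$type[i]]]$division_threshold
    state$agents$division_threshold[i] <-
      if (!is.na(abs_thr)) abs_thr
      else config$types[[ag$type[i]]]$division_factor * m0
  }
  state
}

#' @export
print.dv_state <- function(x, ...) {
  a <- .alive_agents(x)
  tab <- table(factor(a$type, levels = .CELL_TYPES))
  cat(sprintf("dv_state (%dD) at step %d: %s\n", x$dim, x$step_index,
              paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", ")))
  invisible(x)
}

#' Validate the core state invariants
#'
#' Checks that the mesh generators are exactly the centers of alive agents
#' and that the media enclosure holds (no alive non-media agent on the
#' convex hull, i.e. every biological V-cell is bounded). An
#' enclosure-violation error names the offending agent.
#'
#' @param state a `"dv_state"`.
#' @return `state`, invisibly.
#' @export
validate_state <- function(state) {
  a <- .alive_agents(state)
  stopifnot(setequal(a$id, state$mesh$ids))
  bio <- a$id[a$type != "media"]
  offenders <- intersect(bio, state$mesh$hull_ids)
  if (length(offenders))
    .vc_stop("vcellsim_enclosure_violation",
             "media enclosure violated: agent %d on the convex hull",
             offenders[1L])
  invisible(state)
}

# one agent's behavior program; returns updated state
.run_program <- function(state, agent_id) {
  i <- match(agent_id, state$agents$id)
  if (is.na(i) || !state$agents$alive[i]) return(state)
  type <- state$agents$type[i]
  prog <- state$config$types[[type]]$program
  for (beh in prog) {
    i <- match(agent_id, state$agents$id)
    if (!state$agents$alive[i]) break
    if (beh == "move") {
      state <- act_move(state, agent_id)
    } else if (beh == "grow") {
      state <- act_grow(state, agent_id)
    } else if (beh == "divide") {
      if (vcell_measure(state$mesh, agent_id) >=
          state$agents$division_threshold[i])
        state <- act_divide(state, agent_id)
    } else if (beh == "die") {
      p <- .type_param(state, type, "death_prob")
      r <- .with_rng(state, function() runif(1L))
      state <- r$state
      if (r$value < p) {
        state <- act_remove(state, agent_id)
        break
      }
    }
    validate_state(state)
  }
  state
}

#' Advance the simulation by one step
#'
#' Activates every alive non-media agent exactly once, in an order uniformly
#' shuffled by the seeded stream; each agent executes its type's behavior
#' program. Agents created by division during the step are not activated
#' until the next step; agents removed earlier in the step are skipped.
#'
#' @param state a `"dv_state"`.
#' @return the state after the step, with `step_index` incremented.
#' @export
sim_step <- function(state) {
  a <- .alive_agents(state)
  actors <- a$id[a$type != "media"]
  r <- .with_rng(state, function() sample(actors))
  state <- r$state
  for (id in r$value) state <- .run_program(state, id)
  state$step_index <- state$step_index + 1L
  state
}

.summary_row <- function(state) {
  a <- .alive_agents(state)
  tab <- table(factor(a$type, levels = .CELL_TYPES))
  bio <- a$id[a$type != "media"]
  total <- sum(vapply(bio, function(id) vcell_measure(state$mesh, id), 1.0))
  data.frame(step = state$step_index,
             n_lmn = as.integer(tab[["lmn"]]), n_lec = as.integer(tab[["lec"]]),
             n_mec = as.integer(tab[["mec"]]), n_media = as.integer(tab[["media"]]),
             n_total = nrow(a), bio_measure = total)
}

#' Run a simulation
#'
#' Executes `config$steps` steps from a stream seeded by `config$seed`,
#' recording a per-step summary (agent counts per type and total biological
#' V-cell measure) and the full event log.
#'
#' @param config a `"dv_config"`.
#' @param scenario as in [simulation_state()]; alternatively pass an
#'   existing `"dv_state"` to continue it.
#' @return an object of class `"dv_trajectory"`: list with `summaries`
#'   (data.frame, one row per recorded step including step 0), `events`
#'   (data.frame) and `final_state`.
#' @export
sim_run <- function(config, scenario) {
  state <- if (inherits(scenario, "dv_state")) scenario
           else simulation_state(scenario, config)
  summaries <- .summary_row(state)
  for (s in seq_len(config$steps - state$step_index)) {
    state <- sim_step(state)
    summaries <- rbind(summaries, .summary_row(state))
  }
  structure(list(summaries = summaries, events = state$events,
                 final_state = state), class = "dv_trajectory")
}

#' @export
print.dv_trajectory <- function(x, ...) {
  n <- nrow(x$summaries)
  cat(sprintf("dv_trajectory: %d recorded steps, %d events\n", n, nrow(x$events)))
  print(utils::tail(x$summaries, 3L))
  invisible(x)
}

#' Save / load a simulation checkpoint
#'
#' Checkpoints are versioned JSON holding the agents, configuration, step
#' index, event log and the serialized random-stream state, so that resuming
#' from a checkpoint reproduces the exact event log of an uninterrupted run.
#'
#' @param state a `"dv_state"`.
#' @param path file path for the checkpoint.
#' @return `checkpoint_save()` returns `path` invisibly; `checkpoint_load()`
#'   returns the restored `"dv_state"`.
#' @export
checkpoint_save <- function(state, path) {
  stopifnot(inherits(state, "dv_state"))
  # doubles are serialised as %.17g strings: exact round trip, Inf/NA safe
  ag <- state$agents
  for (col in .AGENT_NUM_COLS) ag[[col]] <- sprintf("%.17g", ag[[col]])
  payload <- list(
    format = .CHECKPOINT_FORMAT,
    version = .CHECKPOINT_VERSION,
    dim = state$dim,
    step_index = state$step_index,
    rng_state = state$rng_state,
    config = .encode_numbers(unclass(state$config)),
    agents = ag,
    events = state$events
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

.AGENT_NUM_COLS <- c("x", "y", "z", "step_length", "target_size",
                     "division_threshold", "bias_x", "bias_y", "bias_z")

.encode_numbers <- function(x) {
  if (is.list(x)) return(lapply(x, .encode_numbers))
  if (is.double(x)) return(sprintf("%.17g", x))
  x
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) {
  if (!file.exists(path))
    .vc_stop("vcellsim_checkpoint_format", "checkpoint file not found: %s", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    .vc_stop("vcellsim_checkpoint_format",
                             "corrupt checkpoint: %s", conditionMessage(e)))
  if (!identical(raw$format, .CHECKPOINT_FORMAT) ||
      !identical(as.integer(raw$version), .CHECKPOINT_VERSION))
    .vc_stop("vcellsim_checkpoint_format",
             "not a vcellsim checkpoint (or version mismatch)")
  cfg <- raw$config
  types <- lapply(cfg$types, function(tp) {
    tp$program <- as.character(unlist(tp$program))
    if (!is.null(tp$bias)) tp$bias <- as.numeric(tp$bias)
    tp[vapply(tp, is.null, TRUE)] <- NULL
    tp
  })
  config <- behavior_config(
    steps = cfg$steps, seed = cfg$seed, types = types,
    delta_push_frac = cfg$delta_push_frac, k_grow = cfg$k_grow,
    eps_div_frac = cfg$eps_div_frac, lambda_fill = cfg$lambda_fill,
    theta = cfg$theta, k_absorb = cfg$k_absorb)
  ag <- as.data.frame(raw$agents, stringsAsFactors = FALSE)
  ag$id <- as.integer(ag$id)
  ag$lineage <- suppressWarnings(as.integer(ag$lineage))
  ag$alive <- as.logical(ag$alive)
  for (col in .AGENT_NUM_COLS)   # "NA" strings coerce to NA by design
    ag[[col]] <- suppressWarnings(as.numeric(ag[[col]]))
  for (col in c("group", "info", "type")) ag[[col]] <- as.character(ag[[col]])
  ev <- if (is.null(raw$events) || length(raw$events) == 0L) .empty_events()
        else {
          e <- as.data.frame(raw$events, stringsAsFactors = FALSE)
          e$step <- as.integer(e$step); e$agent <- as.integer(e$agent)
          e$other <- as.integer(e$other)
          e$event <- as.character(e$event); e$detail <- as.character(e$detail)
          e
        }
  state <- structure(list(
    agents = ag, dim = as.integer(raw$dim), config = config, mesh = NULL,
    step_index = as.integer(raw$step_index),
    rng_state = if (is.null(raw$rng_state)) NULL else as.integer(raw$rng_state),
    events = ev
  ), class = "dv_state")
  state <- .rebuild(state)
  validate_state(state)
  state
}
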