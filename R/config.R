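# Behavior configuration: per-type behavior programs plus the numeric knobs
# shared by all behaviors. Serialisable to/from YAML.

.DEFAULT_TYPE_PARAMS <- list(
  step_length        = 0.05,   # displacement per move activation (length units)
  noise_weight       = 0.5,    # weight of the random unit vector under bias
  target_factor      = 1.0,    # target_size = factor x initial V-cell measure
  division_factor    = Inf,    # divide when measure >= factor x initial measure
  division_threshold = NA_real_, # absolute threshold; overrides division_factor
  death_prob         = 0.0,    # per-activation removal probability ("die")
  bias               = NULL    # optional preferred direction (unit vector)
)

.KNOWN_BEHAVIORS <- c("move", "grow", "divide", "die")

#' Behavior configuration for a simulation
#'
#' Assembles the per-type behavior programs and global behavior parameters.
#' Media agents are always inert; any program given for them is rejected.
#'
#' @param steps total number of engine steps for [sim_run()].
#' @param seed integer seed for the single simulation random stream.
#' @param types named list (names from `lmn`, `lec`, `mec`, `media`), each a
#'   list with an optional `program` (ordered character vector of behaviors
#'   among `"move"`, `"grow"`, `"divide"`, `"die"`) plus overrides for the
#'   per-type parameters `step_length`, `noise_weight`, `target_factor`,
#'   `division_factor`, `division_threshold`, `death_prob`, `bias`.
#' @param delta_push_frac growth push increment, as a fraction of the
#'   grower's mean 1-hop neighbor distance (default 0.02).
#' @param k_grow maximum growth iterations per activation (default 50).
#' @param eps_div_frac daughter placement offset as a fraction of the
#'   parent's `step_length` (default 0.1).
#' @param lambda_fill drift fraction of former neighbors toward a removed
#'   agent's center (0 = pure passive re-tessellation).
#' @param theta rotation angle per [act_rotate()] activation, radians.
#' @param k_absorb maximum capture iterations for [act_absorb()].
#' @return an object of class `"dv_config"`.
#' @export
behavior_config <- function(steps = 100L, seed = 42L, types = list(),
                            delta_push_frac = 0.02, k_grow = 50L,
                            eps_div_frac = 0.1, lambda_fill = 0,
                            theta = pi / 6, k_absorb = 1000L) {
  # tolerate string-encoded numbers (YAML/JSON round trips)
  steps <- as.integer(steps); seed <- as.integer(seed)
  k_grow <- as.integer(k_grow); k_absorb <- as.integer(k_absorb)
  delta_push_frac <- as.numeric(delta_push_frac)
  eps_div_frac <- as.numeric(eps_div_frac)
  lambda_fill <- as.numeric(lambda_fill)
  theta <- as.numeric(theta)
  stopifnot(steps >= 0, k_grow >= 1, k_absorb >= 1,
            delta_push_frac >= 0, eps_div_frac >= 0,
            lambda_fill >= 0, lambda_fill <= 1)
  full <- list()
  for (tp in .CELL_TYPES) {
    spec <- types[[tp]] %||% list()
    prog <- as.character(spec$program %||% character())
    bad <- setdiff(prog, .KNOWN_BEHAVIORS)
    if (length(bad))
      .vc_stop("vcellsim_invalid_input", "unknown behavior(s): %s",
               paste(bad, collapse = ", "))
    if (tp == "media" && length(prog))
      .vc_stop("vcellsim_invalid_input", "media agents are inert; no program allowed")
    pars <- .DEFAULT_TYPE_PARAMS
    for (nm in names(spec)) {
      if (nm == "program") next
      if (!nm %in% names(.DEFAULT_TYPE_PARAMS))
        .vc_stop("vcellsim_invalid_input", "unknown type parameter '%s'", nm)
      # numeric coercion also repairs "Inf"/"NA" strings from JSON/YAML
      pars[[nm]] <- suppressWarnings(
        if (nm == "bias") as.numeric(spec[[nm]]) else as.numeric(spec[[nm]])[1L])
    }
    if (pars$step_length < 0 || pars$death_prob < 0 || pars$death_prob > 1)
      .vc_stop("vcellsim_invalid_input", "invalid parameters for type %s", tp)
    full[[tp]] <- c(list(program = prog), pars)
  }
  structure(list(
    steps = as.integer(steps), seed = as.integer(seed), types = full,
    delta_push_frac = delta_push_frac, k_grow = as.integer(k_grow),
    eps_div_frac = eps_div_frac, lambda_fill = lambda_fill,
    theta = theta, k_absorb = as.integer(k_absorb)
  ), class = "dv_config")
}

#' @export
print.dv_config <- function(x, ...) {
  cat(sprintf("dv_config: %d steps, seed %d\n", x$steps, x$seed))
  for (tp in names(x$types)) {
    prog <- x$types[[tp]]$program
    if (length(prog))
      cat(sprintf("  %-5s: %s\n", tp, paste(prog, collapse = " -> ")))
  }
  invisible(x)
}

#' Read / write a behavior configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a `"dv_config"`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- tryCatch(suppressWarnings(yaml::read_yaml(path)), error = function(e)
    .vc_stop("vcellsim_parse_error", "cannot parse YAML config: %s",
             conditionMessage(e)))
  args <- raw[intersect(names(raw), names(formals(behavior_config)))]
  if (!is.null(args$types)) {
    args$types <- lapply(args$types, function(tp) {
      if (!is.null(tp$bias)) tp$bias <- as.numeric(tp$bias)
      if (!is.null(tp$program)) tp$program <- as.character(unlist(tp$program))
      tp
    })
  }
  do.call(behavior_config, args)
}

#' @rdname read_config
#' @param config a `"dv_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dv_config"))
  out <- unclass(config)
  # drop defaults-only media block noise: keep everything, YAML is cheap
  out$types <- lapply(out$types, function(tp) {
    tp <- tp[!vapply(tp, is.null, TRUE)]
    tp[!vapply(tp, function(v) length(v) == 1L && is.na(v), TRUE)]
  })
  yaml::write_yaml(out, path, precision = 17L)  # exact double round trip
  invisible(path)
}
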