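# Configuration file I/O. One human-readable YAML file mirroring the schema of
# inst/extdata/defaults.yaml; unspecified fields fall back to the defaults.

#' Load a model/control configuration file
#'
#' Reads a YAML configuration with the documented top-level sections `seed`,
#' `params`, `treatment`, `ranges`, `control`, and `goal`. Every field is
#' optional: missing values are filled from the package defaults, then the
#' whole configuration is validated (each violation names the offending
#' field). Unknown fields are an error, so typos do not silently fall back
#' to defaults.
#'
#' @param path Path to a YAML file. A minimal file may name only, e.g.,
#'   `seed: 1`.
#' @return List with elements `params` ([moth_params()]), `treatment`
#'   ([treatment()]), `ranges` ([effort_ranges()]), `control`
#'   ([control_config()]), `goal` ([goal_spec()]), and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

build_config <- function(raw) {
  known <- c("seed", "params", "treatment", "ranges", "control", "goal")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  d <- default_config()
  sect <- function(name, allowed) {
    s <- raw[[name]]
    if (is.null(s)) s <- list()
    bad <- setdiff(names(s), allowed)
    if (length(bad))
      stop(sprintf("unknown field(s) in '%s': %s", name,
                   paste(bad, collapse = ", ")))
    s
  }
  p <- sect("params", names(d$params))
  params <- do.call(moth_params, p)
  tr <- sect("treatment", names(d$treatment))
  treat <- treatment(actuation = tr$actuation %||% d$treatment$actuation,
                     abdomen = tr$abdomen %||% d$treatment$abdomen,
                     reduced_scale = tr$reduced_scale)
  rg <- sect("ranges", names(d$ranges))
  ranges <- do.call(effort_ranges, rg)
  cc <- sect("control", c(names(d$control)))
  control <- do.call(control_config,
                     c(cc, list(seed = raw$seed %||% d$seed)))
  gl <- sect("goal", names(d$goal))
  goal <- goal_spec(amplitudes = gl$amplitudes %||% NULL,
                    frequencies = gl$frequencies %||% NULL,
                    x_goal = gl$x_goal %||% NULL,
                    theta_goal = gl$theta_goal %||% NULL)
  list(params = params, treatment = treat, ranges = ranges,
       control = control, goal = goal, seed = control$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to a YAML file
#'
#' Serializes a configuration (as returned by [load_config()]) so that
#' reloading it reproduces identical objects.
#'
#' @param config List as returned by [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.numeric(v) && length(v) > 1) as.list(v) else v)
  }
  out <- list(
    seed = as.integer(config$seed),
    params = strip(config$params),
    treatment = strip(config$treatment),
    ranges = strip(config$ranges),
    control = strip(config$control[setdiff(names(config$control), "seed")]),
    goal = strip(config$goal)
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
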