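#' Default run configuration
#'
#' The full parameter set of the package with its standard values: the
#' Naka-Rushton constants (`M = 100`, `x_theta = 30`, `x_0 = 30`), the
#' population and synaptic time constants (`tau_E = 20`, `tau_I = 10`,
#' `tau_EE = 100`, `tau_EI = 25`, `tau_IE = tau_II = 10` ms), the
#' intra- and inter-unit coupling strengths, the external gain `J_EO`,
#' the single-unit feedback strengths, and the run-control keys
#' (`model`, `dt`, `duration`, `seed`, `n_units`, `amplitude`).
#'
#' @return a named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    model = "mean_field", dt = 0.1, duration = 2000, seed = 1L,
    n_units = 8L, amplitude = 1,
    # single-unit feedback models
    tau = 20, W_pos = 1, W_der = 0,
    # mean-field time constants (ms)
    tau_E = 20, tau_I = 10, tau_EE = 100, tau_EI = 25, tau_IE = 10,
    tau_II = 10,
    # coupling strengths, within and between NSSUs
    J_EE_intra = 300, J_EI_intra = 450, J_IE_intra = 900, J_II_intra = 900,
    J_EE_inter = 150, J_EI_inter = 300, J_IE_inter = 600, J_II_inter = 600,
    J_EO = 3000,
    # Naka-Rushton transfer
    M = 100, x_theta = 30, x_0 = 30),
    class = "run_config")
}

validate_config <- function(cfg) {
  for (key in c("tau", "tau_E", "tau_I", "tau_EE", "tau_EI", "tau_IE",
                "tau_II"))
    if (cfg[[key]] <= 0) stop("`", key, "` must be > 0")
  if (cfg$J_EO < 0 || cfg$J_EO > 6000)
    stop("`J_EO` = ", cfg$J_EO, " outside the admissible range 0-6000")
  for (key in grep("^J_", names(cfg), value = TRUE))
    if (cfg[[key]] < 0) stop("`", key, "` must be >= 0")
  if (cfg$M <= 0) stop("`M` must be > 0")
  if (cfg$x_0 <= 0) stop("`x_0` must be > 0")
  if (cfg$W_pos < 0 || cfg$W_der < 0)
    stop("`W_pos` and `W_der` must be >= 0")
  if (cfg$dt <= 0) stop("`dt` must be > 0")
  if (cfg$duration <= 0) stop("`duration` must be > 0")
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of parameter overrides and fills every omitted key
#' from [default_config()]. Unknown keys are rejected rather than silently
#' ignored (a typo in a parameter name must not produce a default-valued
#' run), and out-of-range values are rejected naming the admissible range.
#' An empty file yields the full default set.
#'
#' @param path path to a YAML file.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Save a run configuration to YAML
#'
#' Writes all keys so that [load_config()] round-trips exactly.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_params
#' @name config_params
#' @title Construct model parameter objects from a run configuration
#' @description Translate the flat key set of a `run_config` into the
#'   structured parameter objects the simulators take.
#' @param cfg a `run_config` list.
#' @return [config_feedback_params()] a [feedback_params()];
#'   [config_mean_field_params()] a [mean_field_params()];
#'   [config_naka_rushton_params()] a [naka_rushton_params()].
NULL

#' @rdname config_params
#' @export
config_feedback_params <- function(cfg)
  feedback_params(tau = cfg$tau, w_pos = cfg$W_pos, w_der = cfg$W_der)

#' @rdname config_params
#' @export
config_mean_field_params <- function(cfg)
  mean_field_params(
    tau_e = cfg$tau_E, tau_i = cfg$tau_I,
    tau_syn = c(EE = cfg$tau_EE, EI = cfg$tau_EI, IE = cfg$tau_IE,
                II = cfg$tau_II),
    j_intra = c(EE = cfg$J_EE_intra, EI = cfg$J_EI_intra,
                IE = cfg$J_IE_intra, II = cfg$J_II_intra),
    j_inter = c(EE = cfg$J_EE_inter, EI = cfg$J_EI_inter,
                IE = cfg$J_IE_inter, II = cfg$J_II_inter),
    j_eo = cfg$J_EO)

#' @rdname config_params
#' @export
config_naka_rushton_params <- function(cfg)
  naka_rushton_params(m_max = cfg$M, x_theta = cfg$x_theta,
                      x_half = cfg$x_0)

provenance_header <- function(config = NULL, seed = NULL) {
  hash <- if (!is.null(config)) rlang::hash(unclass(config)) else NA
  c(sprintf("# wmcircuit %s",
            as.character(utils::packageVersion("wmcircuit"))),
    sprintf("# config_hash: %s", hash),
    sprintf("# seed: %s", if (is.null(seed)) NA else seed))
}

#' Write and read rate traces as commented CSV
#'
#' Traces are written as plain CSV preceded by `#`-prefixed provenance
#' lines (package version, configuration hash, seed). Reruns with the same
#' configuration and seed produce bit-identical files. `read_trace` skips
#' the provenance lines.
#'
#' @param trace a data frame (e.g. a `rate_trace` or `population_trace`).
#' @param path output file.
#' @param config optional `run_config` recorded in the header hash.
#' @param seed optional seed recorded in the header.
#' @return `write_trace`: `path`, invisibly. `read_trace`: the data frame.
#' @export
write_trace <- function(trace, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, seed), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  utils::read.csv(path, comment.char = "#")
}

#' Write and read SDN event logs as JSON lines
#'
#' The first line is a header object carrying provenance (package version,
#' configuration hash, seed); each following line is one event object. A
#' run with no events writes a valid log containing only the header.
#'
#' @param events an event data frame from [sdn_events()].
#' @param path output file.
#' @param config optional `run_config` recorded in the header.
#' @param seed optional seed recorded in the header.
#' @return `write_events`: `path`, invisibly. `read_events`: the event
#'   data frame (zero rows for an event-free log).
#' @export
write_events <- function(events, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(wmcircuit =
                   as.character(utils::packageVersion("wmcircuit")),
                 config_hash = if (!is.null(config))
                   rlang::hash(unclass(config)) else NA,
                 seed = if (is.null(seed)) NA else seed)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, na = "null"), con)
  if (nrow(events))
    for (k in seq_len(nrow(events)))
      writeLines(jsonlite::toJSON(as.list(events[k, ]),
                                  auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L)
    return(data.frame(t = numeric(), event = character(),
                      feature_id = character(), set_id = character(),
                      rate = numeric()))
  do.call(rbind, lapply(lines[-1L], function(l)
    as.data.frame(jsonlite::fromJSON(l))))
}
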