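# Structured (YAML) configuration files tying the pieces together. A config
# may carry any of the sections `neuron:`, `network:`, `training:`,
# `synthetic:` and `schedule:`; absent fields fall back to constructor
# defaults.

#' Read / write a structured configuration file
#'
#' The file is YAML with up to five sections. `neuron` maps to
#' [neuron_params()] (`u_rest, u_reset, u_th, tau_m, dt, gain`), `network`
#' carries `n_input, n_hidden, n_class, seed`, `training` maps to
#' [train_config()], `synthetic` to [synth_config()] and `schedule` to
#' [streaming_schedule()].
#'
#' @param path YAML file path.
#' @return `read_config` returns a list of class `lsm_config` with
#'   constructed component objects (`$neuron`, `$network`, `$training`,
#'   `$synthetic`, `$schedule`); missing sections are built from defaults.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(fun, args) {
    args <- args %||% list()
    do.call(fun, args[intersect(names(args), names(formals(fun)))])
  }
  cfg <- list(
    neuron = build(neuron_params, raw$neuron),
    training = build(train_config, raw$training),
    synthetic = build(synth_config, raw$synthetic),
    schedule = build(streaming_schedule, raw$schedule),
    network = raw$network %||% list()
  )
  class(cfg) <- "lsm_config"
  cfg
}

#' @rdname read_config
#' @param config a list whose components are written as the corresponding
#'   sections (component objects are flattened to plain fields).
#' @export
write_config <- function(config, path) {
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  out <- list(neuron = strip(config$neuron),
              network = strip(config$network),
              training = strip(config$training),
              synthetic = strip(config$synthetic),
              schedule = strip(config$schedule))
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}
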