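#' Run a compartment-model simulation from a declarative config file
#'
#' Reads a YAML file describing a parameter set, feedback schedule, cue and
#' initial state, and runs [simulate_ode()]. Recognized keys:
#'
#' * `regime`: `"high_feedback"` or `"low_feedback"` (or a `params` mapping
#'   passed to [ode_params()]).
#' * `schedule`: either `constant: <multiplier>`, `oscillating: true`
#'   (package default), or `times:` / `multipliers:` lists.
#' * `cue`: mapping with `rate`, `t_on`, `t_off` (optional).
#' * `initial`: mapping `Aa/Ap/Pa/Pp`, or `quadrant: <label>` to start from
#'   the corresponding stable attractor of the parameter set.
#' * `t_end`, `by`: output time grid (defaults 300, 1).
#'
#' @param path path to the YAML config.
#' @return The trajectory data.frame from [simulate_ode()].
#' @export
run_ode_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config files require the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  params <- if (!is.null(cfg$params)) do.call(ode_params, cfg$params)
            else par_regime(cfg$regime %||% "high_feedback")
  schedule <- if (is.null(cfg$schedule)) constant_schedule()
    else if (!is.null(cfg$schedule$constant))
      constant_schedule(cfg$schedule$constant)
    else if (isTRUE(cfg$schedule$oscillating)) oscillating_schedule()
    else feedback_schedule(unlist(cfg$schedule$times),
                           unlist(cfg$schedule$multipliers),
                           isTRUE(cfg$schedule$apply_to_kPA))
  cue <- if (is.null(cfg$cue)) NULL
         else polarity_cue(cfg$cue$rate, cfg$cue$t_on, cfg$cue$t_off)
  initial <- if (!is.null(cfg$initial$quadrant)) {
    fps <- find_steady_states(params)
    stable <- fps[fps$stability == "stable", ]
    labs <- apply(stable[, c("Aa", "Ap", "Pa", "Pp")], 1,
                  classify_quadrant, params = params)
    row <- stable[match(cfg$initial$quadrant, labs), ]
    if (any(is.na(row))) stop("no stable attractor in quadrant ",
                              cfg$initial$quadrant)
    unlist(row[1, c("Aa", "Ap", "Pa", "Pp")])
  } else unlist(cfg$initial[c("Aa", "Ap", "Pa", "Pp")])
  t_end <- cfg$t_end %||% 300
  by <- cfg$by %||% 1
  simulate_ode(initial, params, seq(0, t_end, by = by),
               schedule = schedule, cue = cue)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
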