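# Time evolution of tracer populations under the hopping rules.

#' Map a uniform variate to a hop direction
#'
#' The quartile rule used by the lattice engine: `u < 0.25` left,
#' `0.25 <= u < 0.5` right, `0.5 <= u < 0.75` up, otherwise down.
#'
#' @param u numeric vector of variates in `[0, 1)`.
#' @return character vector of direction tokens.
#' @export
#' @examples
#' sample_direction(c(0.1, 0.25, 0.6, 0.9999))
sample_direction <- function(u) {
  if (any(u < 0 | u >= 1)) stopf("u must lie in [0, 1)")
  c("left", "right", "up", "down")[findInterval(u, c(0, 0.25, 0.5, 0.75))]
}

#' Per-step escape probability of a bound tracer
#'
#' A tracer bound to a scaffold (PRO) site escapes at each time step with the
#' Boltzmann probability \eqn{P_{escape} = e^{-E/k_BT}}.
#'
#' @param binding_energy binding energy in \eqn{k_BT} units (>= 0).
#' @return escape probability.
#' @export
#' @examples
#' escape_probability(c(0, 2, 6, 10))
escape_probability <- function(binding_energy) {
  if (any(binding_energy < 0)) stopf("binding_energy must be >= 0")
  exp(-binding_energy)
}

#' Simulation schedule
#'
#' Bundles annealing and measurement durations, the recording grid and the
#' ensemble count. Binding conditions are annealed (run unrecorded) before the
#' measurement clock starts so the bound fraction is thermally equilibrated;
#' the study's annealing duration is 2000 ms whenever PRO sites are present.
#'
#' @param measure_ms duration of the recorded measurement, ms.
#' @param anneal_ms annealing duration, ms; `NULL` means "2000 ms if the
#'   obstacle field contains PRO sites, else 0" (resolved at simulation time).
#' @param n_record number of recording instants.
#' @param spacing `"log"` (default; suits log-log analysis) or `"linear"`.
#' @param record_steps explicit 1-based measurement step indices overriding
#'   `n_record`/`spacing`.
#' @param n_ensembles number of independent replicate simulations intended
#'   for this schedule (used by sweep helpers).
#' @return an object of class `sim_schedule`.
#' @export
#' @examples
#' sim_schedule(200)                   # 200 ms measurement, log-spaced frames
#' sim_schedule(2000, anneal_ms = 2000)
sim_schedule <- function(measure_ms, anneal_ms = NULL, n_record = 60,
                         spacing = c("log", "linear"), record_steps = NULL,
                         n_ensembles = 1) {
  spacing <- match.arg(spacing)
  if (measure_ms <= 0) stopf("measure_ms must be positive")
  if (!is.null(anneal_ms) && anneal_ms < 0) stopf("anneal_ms must be >= 0")
  structure(
    list(measure_ms = measure_ms, anneal_ms = anneal_ms,
         n_record = n_record, spacing = spacing,
         record_steps = record_steps, n_ensembles = n_ensembles),
    class = "sim_schedule")
}

# Resolve a schedule against a lattice/continuous time step: integer step
# counts and the recording grid (1-based measurement step indices).
resolve_schedule <- function(schedule, dt, has_pro) {
  n_measure <- as.integer(round(schedule$measure_ms / dt))
  anneal_ms <- schedule$anneal_ms
  if (is.null(anneal_ms)) anneal_ms <- if (has_pro) 2000 else 0
  n_anneal <- as.integer(round(anneal_ms / dt))
  rec <- schedule$record_steps
  if (is.null(rec)) {
    rec <- if (schedule$spacing == "log")
      unique(round(exp(seq(0, log(n_measure), length.out = schedule$n_record))))
    else unique(round(seq(1, n_measure, length.out = schedule$n_record)))
  }
  rec <- sort(unique(as.integer(rec)))
  if (length(rec) == 0 || rec[1] < 1 || rec[length(rec)] > n_measure)
    stopf("record steps must lie in [1, %d]", n_measure)
  list(n_measure = n_measure, n_anneal = n_anneal, record_steps = rec)
}

#' Advance a tracer population through one simulation
#'
#' Runs the lattice Monte Carlo: at every time step each tracer draws a hop
#' direction by the quartile rule; a CRO destination always reflects; a PRO
#' destination reflects with probability `p_reflect` and binds the arriving
#' tracer (bound tracers escape per step with probability
#' \eqn{e^{-E/k_BT}}); under self-crowding a destination holding another
#' tracer blocks the hop, and a PRO holding a bound tracer acts as a CRO.
#' With `recursive = TRUE` (the default) tracers blocked by another tracer
#' are re-examined in a second pass against their originally chosen
#' destinations, so a hop into a site vacated later in the same sweep is not
#' falsely rejected.
#'
#' Binding conditions are annealed before measurement (see [sim_schedule()]);
#' displacements are then recorded from the measurement origin as unwrapped
#' coordinates, so the mean squared displacement is meaningful across the
#' periodic boundary.
#'
#' @param cfg a [lattice_config()].
#' @param field an [build_obstacle_field()] result.
#' @param tracers a [place_tracers()] result.
#' @param schedule a [sim_schedule()].
#' @param recursive logical: apply the second (false-self-blocking) pass?
#'   Only meaningful under exclusion.
#' @param escape_rule `"boltzmann"` (escape when the variate is below
#'   \eqn{P_{escape}}; default) or `"literal"` (the inverted text reading,
#'   kept for comparison).
#' @param seed optional RNG seed for the whole run.
#' @param check_invariants logical: verify exclusion and obstacle-occupancy
#'   invariants after every measured step (slow; for tests on small lattices).
#' @param anneal_monitor_every record the bound fraction every this many
#'   annealing steps (0 = off); returned as `anneal_bound_fraction`.
#' @return an object of class `cd_trajectory`: recording times `times_ms`,
#'   displacement matrices `x`/`y` in \eqn{\mu m} (rows = recording times,
#'   columns = tracers), final `bound` flags and the run parameters.
#' @export
#' @examples
#' cfg <- lattice_config(n_side = 50)
#' f <- build_obstacle_field(cfg)
#' p <- place_tracers(cfg, f, n_tracers = 10, exclusion = FALSE, seed = 1)
#' tr <- simulate_lattice(cfg, f, p, sim_schedule(10), seed = 1)
#' tr$times_ms[1:3]
simulate_lattice <- function(cfg, field, tracers, schedule,
                             recursive = TRUE,
                             escape_rule = c("boltzmann", "literal"),
                             seed = NULL, check_invariants = FALSE,
                             anneal_monitor_every = 0L) {
  stopifnot(inherits(cfg, "lattice_config"),
            inherits(field, "obstacle_field"),
            inherits(tracers, "tracer_population"),
            inherits(schedule, "sim_schedule"))
  escape_rule <- match.arg(escape_rule)
  sch <- resolve_schedule(schedule, cfg$time_step, field$a_pro > 0)
  res <- with_seed(seed, lattice_sim_cpp(
    cfg$n_side, as.integer(field$site_kind),
    as.integer(tracers$row - 1L), as.integer(tracers$col - 1L),
    tracers$exclusion, recursive,
    field$reflect_probability, escape_probability(field$binding_energy),
    sch$n_anneal, sch$n_measure, sch$record_steps,
    as.integer(anneal_monitor_every), escape_rule == "literal",
    check_invariants))
  structure(
    list(times_ms = sch$record_steps * cfg$time_step,
         x = res$x * cfg$step_length,
         y = res$y * cfg$step_length,
         bound = res$bound,
         anneal_bound_fraction = res$anneal_bound_fraction,
         engine = "lattice",
         params = list(
           n_side = cfg$n_side, dt = cfg$time_step,
           step_length = cfg$step_length,
           D = cfg$free_diffusion_coefficient,
           a_dt = tracers$a_dt, a_cro = field$a_cro, a_pro = field$a_pro,
           binding_energy = field$binding_energy,
           p_reflect = field$reflect_probability,
           exclusion = tracers$exclusion, recursive = recursive,
           escape_rule = escape_rule,
           n_anneal = sch$n_anneal, n_measure = sch$n_measure,
           seed = seed)),
    class = "cd_trajectory")
}

#' @export
print.cd_trajectory <- function(x, ...) {
  p <- x$params
  cat(sprintf("%s trajectory: %d tracers, %d frames over %g ms\n",
              x$engine, ncol(x$x), nrow(x$x), max(x$times_ms)))
  cat(sprintf("  a_DT %.3g, a_CRO %.3g, a_PRO %.3g, E %g kT%s\n",
              p$a_dt, if (is.null(p$a_cro)) 0 else p$a_cro,
              if (is.null(p$a_pro)) 0 else p$a_pro,
              if (is.null(p$binding_energy)) 0 else p$binding_energy,
              if (isTRUE(p$exclusion)) ", self-crowding" else ""))
  invisible(x)
}

#' Advance a self-crowded population by one step with chosen directions
#'
#' Applies one time step of the exclusion-mode sweep with externally supplied
#' hop directions, exposing the sequential pass and the optional second
#' (false-self-blocking) pass directly. Useful for studying how specific
#' blocking configurations resolve; the stochastic engines draw directions
#' internally.
#'
#' @param cfg,field the world objects.
#' @param row,col 1-based tracer coordinates (distinct sites).
#' @param directions character vector per tracer: `"left"`, `"right"`,
#'   `"up"`, `"down"`, or `"stay"`.
#' @param recursive apply the second pass over blocked tracers?
#' @return list with updated `row`/`col`, `moved` and `blocked_by_dt` flags
#'   (the latter reports pass-one labelling even when pass two resolves it).
#' @export
#' @examples
#' cfg <- lattice_config(n_side = 10)
#' f <- build_obstacle_field(cfg)
#' # two adjacent tracers; the first is aimed at the second's site
#' step_population(cfg, f, row = c(5, 5), col = c(5, 6),
#'                 directions = c("right", "right"))
step_population <- function(cfg, field, row, col, directions,
                            recursive = TRUE) {
  stopifnot(inherits(cfg, "lattice_config"), inherits(field, "obstacle_field"))
  tokens <- c("left", "right", "up", "down", "stay")
  dir <- match(match.arg(directions, tokens, several.ok = TRUE), tokens) - 1L
  dir[dir == 4L] <- -1L
  res <- lattice_step_cpp(cfg$n_side, as.integer(field$site_kind),
                          as.integer(row - 1L), as.integer(col - 1L),
                          dir, recursive, field$reflect_probability)
  res$row <- res$row + 1L
  res$col <- res$col + 1L
  res
}

#' Outcome of a single attempted hop (testing aid)
#'
#' Applies exactly one destination check of the sequential sweep to tracer
#' `i` for a pre-chosen direction and reflection variate, and reports whether
#' it moved, was blocked by another tracer, or arrived on a scaffold site
#' (newly bound).
#'
#' @param cfg,field,tracers the world objects.
#' @param i tracer index (1-based).
#' @param direction one of `"left"`, `"right"`, `"up"`, `"down"`.
#' @param u_reflect uniform variate used for a partial-reflection check.
#' @return a list with `moved`, `blocked_by_dt`, `newly_bound` and the
#'   resulting 1-based `row`/`col` of the tracer.
#' @export
attempt_hop <- function(cfg, field, tracers, i, direction,
                        u_reflect = 1) {
  dir <- match(match.arg(direction, c("left", "right", "up", "down")),
               c("left", "right", "up", "down")) - 1L
  res <- attempt_hop_cpp(cfg$n_side, as.integer(field$site_kind),
                         as.integer(tracers$row - 1L),
                         as.integer(tracers$col - 1L),
                         as.integer(i), dir, tracers$exclusion,
                         field$reflect_probability, u_reflect)
  res$row <- res$row + 1L
  res$col <- res$col + 1L
  res
}
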