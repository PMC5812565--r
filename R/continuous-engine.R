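# Continuous-space Brownian dynamics of hard disks: the reference model
# against which the lattice algorithm's self-crowding behaviour is checked.

#' Number of hard disks realizing an area fraction
#'
#' @param a_dt target area fraction.
#' @param box_side box side, \eqn{\mu m}.
#' @param radius disk exclusion radius, \eqn{\mu m}.
#' @return integer disk count, `round(a_dt * box^2 / (pi r^2))`.
#' @export
#' @examples
#' disk_count(0.0001)  # one receptor disk in a 1 um^2 box
disk_count <- function(a_dt, box_side = 1, radius = 6e-3) {
  as.integer(round(a_dt * box_side^2 / (pi * radius^2)))
}

#' Gaussian step proposals for Brownian disks
#'
#' Each displacement component is drawn independently as
#' \eqn{\sqrt{2 D \Delta t}\,\xi} with \eqn{\xi} standard normal.
#'
#' @param n number of disks.
#' @param D free diffusion coefficient, \eqn{\mu m^2 ms^{-1}}.
#' @param dt time step, ms.
#' @return an `n x 2` matrix of proposed displacements in \eqn{\mu m}.
#' @export
propose_step <- function(n, D = 0.2e-3, dt = 1e-3) {
  if (D < 0 || dt <= 0) stopf("D must be >= 0 and dt > 0")
  matrix(sqrt(2 * D * dt) * rnorm(2 * n), ncol = 2,
         dimnames = list(NULL, c("dx", "dy")))
}

#' Initial non-overlapping disk placement
#'
#' Uniform rejection sampling of centres with minimum-image pair distance at
#' least twice the radius. Dense packings beyond the reach of rejection
#' sampling (roughly area fraction 0.5 and above) fall back to a square-grid
#' seed, which [simulate_disks()] then randomizes with an equilibration run.
#'
#' @param n disk count.
#' @param box_side box side, \eqn{\mu m}.
#' @param radius disk radius, \eqn{\mu m}.
#' @param max_attempts rejection-sampling budget before falling back (or
#'   failing when even the grid seed is infeasible).
#' @param seed optional RNG seed.
#' @return a list with centre coordinates `x`, `y` (\eqn{\mu m}) and a
#'   `method` tag (`"rejection"` or `"grid"`).
#' @export
place_disks <- function(n, box_side = 1, radius = 6e-3,
                        max_attempts = 200L * n + 1000L, seed = NULL) {
  a <- n * pi * radius^2 / box_side^2
  if (n == 0) return(list(x = numeric(0), y = numeric(0), method = "rejection"))
  if (a <= 0.45) {
    pos <- with_seed(seed, place_disks_cpp(n, box_side, radius,
                                           as.integer(max_attempts)))
    return(list(x = pos$x, y = pos$y, method = "rejection"))
  }
  # grid seed for dense packings
  m <- ceiling(sqrt(n))
  spacing <- box_side / m
  if (spacing < 2 * radius)
    stopf("capacity error: %d disks of radius %g do not fit a %g box",
          n, radius, box_side)
  idx <- with_seed(seed, sample.int(m * m, n))
  gx <- ((idx - 1) %% m + 0.5) * spacing
  gy <- ((idx - 1) %/% m + 0.5) * spacing
  list(x = gx, y = gy, method = "grid")
}

#' Brownian dynamics of hard disks in a periodic box
#'
#' Monte Carlo integration of the overdamped Langevin motion of receptor-sized
#' hard disks: every step each disk sequentially proposes a Gaussian
#' displacement (per-axis sd \eqn{\sqrt{2D\Delta t}}) which is rejected if it
#' would bring any pair of centres closer than twice the radius under the
#' minimum-image convention. Obstacle-free: this engine models pure
#' self-crowding.
#'
#' @param a_dt target area fraction of disks; ignored if `n_disks` given.
#' @param schedule a [sim_schedule()]; its `anneal_ms` (plus
#'   `equil_steps` when the initial placement fell back to a grid seed) is run
#'   unrecorded before measurement.
#' @param box_side box side, \eqn{\mu m} (default 1).
#' @param radius disk exclusion radius, \eqn{\mu m} (default 6 nm).
#' @param D free diffusion coefficient, \eqn{\mu m^2 ms^{-1}}.
#' @param dt time step, ms.
#' @param n_disks explicit disk count.
#' @param exclusion logical; `FALSE` simulates non-interacting disks (free
#'   Brownian motion, useful as a closed-form check).
#' @param equil_steps extra unrecorded randomization steps applied when the
#'   dense grid-seed placement is used (default 2000).
#' @param seed optional RNG seed.
#' @param check_invariants verify the non-overlap invariant after every
#'   measured step (O(n^2); tests only).
#' @return a `cd_trajectory` (same schema as [simulate_lattice()], engine tag
#'   `"continuous"`).
#' @export
#' @examples
#' tr <- simulate_disks(0.0001, sim_schedule(5), seed = 1)
#' ncol(tr$x)  # one disk
simulate_disks <- function(a_dt, schedule, box_side = 1, radius = 6e-3,
                           D = 0.2e-3, dt = 1e-3, n_disks = NULL,
                           exclusion = TRUE, equil_steps = 2000L,
                           seed = NULL, check_invariants = FALSE) {
  stopifnot(inherits(schedule, "sim_schedule"))
  if (is.null(n_disks)) n_disks <- disk_count(a_dt, box_side, radius)
  sch <- resolve_schedule(schedule, dt, has_pro = FALSE)
  res <- with_seed(seed, {
    pos <- place_disks(n_disks, box_side, radius)
    n_equil <- sch$n_anneal +
      if (pos$method == "grid") as.integer(equil_steps) else 0L
    out <- disk_sim_cpp(pos$x, pos$y, box_side, radius, D, dt,
                        n_equil, sch$n_measure, sch$record_steps,
                        exclusion, check_invariants)
    out$placement <- pos$method
    out
  })
  structure(
    list(times_ms = sch$record_steps * dt,
         x = res$x, y = res$y,
         bound = rep(FALSE, n_disks),
         engine = "continuous",
         params = list(
           box_side = box_side, radius = radius, D = D, dt = dt,
           a_dt = n_disks * pi * radius^2 / box_side^2,
           n_disks = n_disks, exclusion = exclusion,
           placement = res$placement,
           n_measure = sch$n_measure, seed = seed)),
    class = "cd_trajectory")
}
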