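# Construction of the discrete simulation world: lattice geometry from the
# physical constants, obstacle placement, tracer placement.

#' Lattice hop length from the free diffusion coefficient
#'
#' For two-dimensional normal diffusion the mean squared displacement grows as
#' \eqn{\langle r^2\rangle = 4Dt}, so a random walk taking one hop per time
#' step \eqn{\Delta t} reproduces a free diffusion coefficient \eqn{D} when
#' the hop length is \eqn{\Delta l = \sqrt{4 D \Delta t}}.
#'
#' @param D free diffusion coefficient, \eqn{\mu m^2\,ms^{-1}}.
#' @param dt time step, ms.
#' @return hop length in \eqn{\mu m}.
#' @export
#' @examples
#' derive_step_length(0.2e-3, 1e-3)  # ~8.94e-4 um, the receptor default
derive_step_length <- function(D, dt) {
  if (!is.numeric(D) || !is.numeric(dt) || any(D <= 0) || any(dt <= 0))
    stopf("D and dt must be positive")
  sqrt(4 * D * dt)
}

#' Number of lattice sites per side for a target physical extent
#'
#' Sites sit at the ends of edges of length `step_length`; a side of physical
#' length `target_area_side` therefore carries
#' `round(target_area_side / step_length)` edges and one more site than that.
#' With the receptor defaults this recovers a 1119 x 1119 lattice spanning
#' close to 1 \eqn{\mu m^2}.
#'
#' @param target_area_side desired physical side length, \eqn{\mu m}.
#' @param step_length lattice edge length, \eqn{\mu m}.
#' @return integer number of sites per side.
#' @export
#' @examples
#' derive_n_side(1, derive_step_length(0.2e-3, 1e-3))  # 1119
derive_n_side <- function(target_area_side, step_length) {
  if (target_area_side <= 0 || step_length <= 0)
    stopf("arguments must be positive")
  as.integer(round(target_area_side / step_length) + 1)
}

#' Physical and discrete geometry of the simulation lattice
#'
#' Bundles the free diffusion coefficient, time step, derived hop length and
#' lattice size. The defaults are the receptor values: free diffusion
#' coefficient \eqn{0.2\times10^{-3}\,\mu m^2 ms^{-1}} measured in the
#' extrasynaptic membrane, \eqn{\Delta t = 10^{-3}} ms, and a lattice spanning
#' 1 \eqn{\mu m^2} (1119 sites per side).
#'
#' @param D free diffusion coefficient, \eqn{\mu m^2\,ms^{-1}}.
#' @param dt time step, ms.
#' @param target_side physical lattice side, \eqn{\mu m}; ignored when
#'   `n_side` is given.
#' @param n_side number of sites per side; derived from `target_side` when
#'   `NULL`.
#' @return an object of class `lattice_config`.
#' @export
#' @examples
#' lattice_config()              # paper-scale geometry
#' lattice_config(n_side = 200)  # desk-scale lattice
lattice_config <- function(D = 0.2e-3, dt = 1e-3, target_side = 1,
                           n_side = NULL) {
  step_length <- derive_step_length(D, dt)
  if (is.null(n_side)) n_side <- derive_n_side(target_side, step_length)
  n_side <- as.integer(n_side)
  if (n_side < 3L) stopf("n_side must be at least 3")
  structure(
    list(n_side = n_side, step_length = step_length, time_step = dt,
         free_diffusion_coefficient = D, boundary = "periodic"),
    class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf("Lattice: %d x %d sites, periodic\n", x$n_side, x$n_side))
  cat(sprintf("  hop length  %.4g um  (side %.4g um)\n",
              x$step_length, (x$n_side - 1) * x$step_length))
  cat(sprintf("  time step   %.4g ms, free D %.4g um^2/ms\n",
              x$time_step, x$free_diffusion_coefficient))
  invisible(x)
}

# Count of sites implied by an area fraction: round-half-up of a * n^2.
sites_for_fraction <- function(a, n_side)
  as.integer(round_half_up(a * as.double(n_side)^2))

#' Place reflecting and binding obstacles on the lattice
#'
#' Distributes completely-reflecting obstacles (CROs: immobile sites that
#' always block a hop) and partially-reflecting binding obstacles (PROs:
#' immobile scaffold sites that block a hop with probability `p_reflect` and
#' bind an arriving tracer, released per step with probability
#' \eqn{e^{-E/k_BT}}) uniformly at random without overlap. Site counts are the
#' requested fractions times the number of sites, rounded half up; the
#' realized fractions are recorded on the result.
#'
#' @param cfg a [lattice_config()].
#' @param a_cro,a_pro requested area fractions of CRO and PRO sites.
#' @param binding_energy tracer-scaffold binding energy in units of
#'   \eqn{k_BT} (>= 0); the study values are 2 (weak), 6 (intermediate) and
#'   10 (strong).
#' @param p_reflect probability that a PRO reflects an incoming tracer
#'   (default 0.5; CROs always reflect).
#' @param seed optional RNG seed for reproducible placement.
#' @return an object of class `obstacle_field` with the site-kind matrix
#'   (`0` empty, `1` CRO, `2` PRO) and realized fractions.
#' @export
#' @examples
#' cfg <- lattice_config(n_side = 50)
#' f <- build_obstacle_field(cfg, a_cro = 0.2, seed = 1)
#' f$a_cro
build_obstacle_field <- function(cfg, a_cro = 0, a_pro = 0,
                                 binding_energy = 0, p_reflect = 0.5,
                                 seed = NULL) {
  stopifnot(inherits(cfg, "lattice_config"))
  if (a_cro < 0 || a_pro < 0 || a_cro > 1 || a_pro > 1 || a_cro + a_pro > 1)
    stopf("obstacle fractions must lie in [0,1] and sum to at most 1")
  if (binding_energy < 0) stopf("binding_energy must be >= 0")
  if (p_reflect < 0 || p_reflect > 1) stopf("p_reflect must lie in [0,1]")
  n <- cfg$n_side
  n2 <- as.double(n)^2
  k_cro <- sites_for_fraction(a_cro, n)
  k_pro <- sites_for_fraction(a_pro, n)
  if (k_cro + k_pro > n2) stopf("requested obstacles exceed the lattice")
  kind <- matrix(0L, n, n)
  if (k_cro + k_pro > 0) {
    picks <- with_seed(seed, sample.int(n * n, k_cro + k_pro))
    if (k_cro > 0) kind[picks[seq_len(k_cro)]] <- 1L
    if (k_pro > 0) kind[picks[k_cro + seq_len(k_pro)]] <- 2L
  }
  structure(
    list(site_kind = kind,
         binding_energy = binding_energy,
         reflect_probability = p_reflect,
         a_cro = k_cro / n2, a_pro = k_pro / n2,
         requested = c(a_cro = a_cro, a_pro = a_pro),
         n_side = n),
    class = "obstacle_field")
}

#' @export
print.obstacle_field <- function(x, ...) {
  cat(sprintf("Obstacle field on %d x %d sites\n", x$n_side, x$n_side))
  cat(sprintf("  reflecting (CRO): a = %.5g\n", x$a_cro))
  cat(sprintf("  binding   (PRO): a = %.5g, E = %g kT, P_reflect = %g\n",
              x$a_pro, x$binding_energy, x$reflect_probability))
  invisible(x)
}

#' Place diffusing tracers on the lattice
#'
#' Tracers (the lattice representation of individual receptors) are placed
#' uniformly at random on non-CRO sites. In exclusion mode (self-crowding) no
#' two tracers may share a site; without exclusion, tracers are independent
#' and may co-occupy sites. A tracer initially landing on a PRO site starts
#' bound.
#'
#' @param cfg a [lattice_config()].
#' @param field an [build_obstacle_field()] result on the same lattice.
#' @param a_dt requested tracer area fraction; ignored when `n_tracers`
#'   is given.
#' @param exclusion logical: steric exclusion among tracers (self-crowding)?
#' @param seed optional RNG seed.
#' @param n_tracers explicit tracer count overriding `a_dt`.
#' @return an object of class `tracer_population` with 1-based `row`/`col`
#'   coordinates, `bound` flags and the realized `a_dt`.
#' @export
#' @examples
#' cfg <- lattice_config(n_side = 50)
#' f <- build_obstacle_field(cfg)
#' p <- place_tracers(cfg, f, a_dt = 0.01, exclusion = TRUE, seed = 1)
#' p$n_tracers
place_tracers <- function(cfg, field, a_dt = 0, exclusion = TRUE,
                          seed = NULL, n_tracers = NULL) {
  stopifnot(inherits(cfg, "lattice_config"), inherits(field, "obstacle_field"))
  if (field$n_side != cfg$n_side) stopf("field and config lattice sizes differ")
  if (is.null(n_tracers)) {
    if (a_dt < 0 || a_dt > 1) stopf("a_dt must lie in [0,1]")
    n_tracers <- sites_for_fraction(a_dt, cfg$n_side)
  }
  n_tracers <- as.integer(n_tracers)
  n <- cfg$n_side
  open_sites <- which(field$site_kind != 1L)   # anything but a CRO
  if (exclusion && n_tracers > length(open_sites))
    stopf("capacity error: %d tracers requested but only %d non-CRO sites",
          n_tracers, length(open_sites))
  picks <- if (n_tracers == 0) integer(0)
  else with_seed(seed, {
    if (exclusion) sample(open_sites, n_tracers)
    else open_sites[sample.int(length(open_sites), n_tracers, replace = TRUE)]
  })
  row <- ((picks - 1L) %% n) + 1L
  col <- ((picks - 1L) %/% n) + 1L
  structure(
    list(row = row, col = col,
         bound = field$site_kind[picks] == 2L,
         exclusion = isTRUE(exclusion),
         n_tracers = n_tracers,
         a_dt = n_tracers / as.double(n)^2,
         n_side = n),
    class = "tracer_population")
}

#' @export
print.tracer_population <- function(x, ...) {
  cat(sprintf("%d tracers on %d x %d sites (a_DT = %.3g), %s\n",
              x$n_tracers, x$n_side, x$n_side, x$a_dt,
              if (x$exclusion) "self-crowding (steric exclusion)"
              else "independent (no self-crowding)"))
  if (any(x$bound)) cat(sprintf("  %d initially bound to scaffold sites\n",
                                sum(x$bound)))
  invisible(x)
}
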