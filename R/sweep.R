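# Reproducible experiment orchestration: parameter sweeps over crowding
# grids, per-cell ensemble management and seeding, convergence diagnostics.

#' Specify a parameter sweep
#'
#' Describes a grid of crowding conditions to simulate and characterize. The
#' `"paper"` scale runs the full-size study conditions (1119^2 lattice, 2 s
#' measurements); the `"desk"` scale (default) shrinks the lattice side,
#' measurement duration and ensemble count so a grid completes on one CPU in
#' minutes, while keeping the hop length, time step and all probabilities at
#' their physical values -- area fractions, not absolute counts, are the
#' controlled variables.
#'
#' @param engine `"lattice"` or `"continuous"`.
#' @param a_dt,a_cro,a_pro,binding_energy vectors of area fractions and
#'   binding energies forming the grid (full crossing).
#' @param exclusion logical (or `"both"`): self-crowding mode(s) to run.
#' @param recursive logical: use the two-pass blocked-tracer resolution.
#' @param scale `"desk"` or `"paper"`.
#' @param n_side lattice sites per side (default 200 desk / 1119 paper).
#' @param measure_ms measurement duration (default 200 desk / 2000 paper).
#' @param anneal_ms annealing duration; `NULL` = 2000 ms when PROs present.
#' @param n_ensembles replicate simulations per cell (default 20 desk /
#'   250 paper).
#' @param n_record recording instants per run.
#' @param base_seed integer base seed; per-(cell, ensemble) seeds are derived
#'   with [derive_seed()].
#' @return an object of class `sweep_spec`.
#' @export
#' @examples
#' sweep_spec(a_dt = c(1e-4, 1e-2), n_ensembles = 4)
sweep_spec <- function(engine = c("lattice", "continuous"),
                       a_dt = 0, a_cro = 0, a_pro = 0, binding_energy = 0,
                       exclusion = TRUE, recursive = TRUE,
                       scale = c("desk", "paper"),
                       n_side = NULL, measure_ms = NULL, anneal_ms = NULL,
                       n_ensembles = NULL, n_record = 50, base_seed = 1L) {
  engine <- match.arg(engine)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  if (is.null(n_side)) n_side <- if (desk) 200L else 1119L
  if (is.null(measure_ms)) measure_ms <- if (desk) 200 else 2000
  if (is.null(n_ensembles)) n_ensembles <- if (desk) 20L else 250L
  excl <- if (identical(exclusion, "both")) c(FALSE, TRUE) else exclusion
  grid <- expand.grid(a_dt = a_dt, a_cro = a_cro, a_pro = a_pro,
                      binding_energy = binding_energy, exclusion = excl,
                      KEEP.OUT.ATTRS = FALSE)
  structure(
    list(engine = engine, grid = grid, recursive = recursive, scale = scale,
         n_side = n_side, measure_ms = measure_ms, anneal_ms = anneal_ms,
         n_ensembles = as.integer(n_ensembles), n_record = n_record,
         base_seed = as.integer(base_seed)),
    class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("%s sweep (%s scale): %d cells x %d ensembles\n",
              x$engine, x$scale, nrow(x$grid), x$n_ensembles))
  print(x$grid)
  invisible(x)
}

#' Run a parameter sweep
#'
#' Simulates every grid cell of a [sweep_spec()] with `n_ensembles`
#' independent replicates, characterizes the ensemble-averaged MSD of each
#' cell with [fit_alpha()], and returns one row per cell. Per-ensemble
#' characterizations (fitted on each replicate's own MSD) are attached for
#' convergence diagnostics. Infeasible cells (for example tracer counts
#' exceeding the open sites) are recorded as failed rows, not errors.
#'
#' @param spec a [sweep_spec()].
#' @param t_obs observation horizon for the effective diffusion coefficient,
#'   ms.
#' @param progress print one line per cell.
#' @return a data frame of class `sweep_result`: grid columns plus realized
#'   fractions, `alpha`, `D_fit`, `D_eff_nm2_us`, `regime`, `n_tracers`,
#'   `n_ensembles`, `seed`, `scale`, `ok` and `message`; per-ensemble fits in
#'   `attr(, "ensemble_fits")`.
#' @export
#' @examples
#' \donttest{
#' spec <- sweep_spec(a_dt = 1e-3, n_side = 100, measure_ms = 20,
#'                    n_ensembles = 2)
#' run_sweep(spec)
#' }
run_sweep <- function(spec, t_obs = 2000, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- spec$grid
  if (nrow(grid) == 0) {
    out <- data.frame(cell = integer(0), grid,
                      realized_a_dt = numeric(0), alpha = numeric(0),
                      D_fit = numeric(0), D_eff_nm2_us = numeric(0),
                      regime = character(0), n_tracers = integer(0),
                      n_ensembles = integer(0), seed = integer(0),
                      scale = character(0), ok = logical(0),
                      message = character(0))
    attr(out, "ensemble_fits") <- list()
    attr(out, "spec") <- spec
    class(out) <- c("sweep_result", "data.frame")
    return(out)
  }
  rows <- vector("list", nrow(grid))
  ens_fits <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    if (progress)
      message(sprintf("cell %d/%d: a_DT=%g a_CRO=%g a_PRO=%g E=%g",
                      cell, nrow(grid), g$a_dt, g$a_cro, g$a_pro,
                      g$binding_energy))
    res <- tryCatch({
      trajs <- lapply(seq_len(spec$n_ensembles), function(e) {
        seed <- derive_seed(spec$base_seed, cell, e)
        simulate_cell(spec, g, seed)
      })
      prof <- ensemble_msd(trajs)
      fit <- fit_alpha(prof, t_obs = t_obs)
      per_ens <- lapply(trajs, function(tr)
        tryCatch(fit_alpha(ensemble_msd(tr), t_obs = t_obs),
                 error = function(e) NULL))
      list(fit = fit, per_ens = per_ens,
           n_tracers = ncol(trajs[[1]]$x),
           realized_a_dt = trajs[[1]]$params$a_dt,
           ok = TRUE, message = "")
    }, error = function(e) list(fit = NULL, per_ens = NULL,
                                n_tracers = NA_integer_,
                                realized_a_dt = NA_real_,
                                ok = FALSE, message = conditionMessage(e)))
    fit <- res$fit
    rows[[cell]] <- data.frame(
      cell = cell, g,
      realized_a_dt = res$realized_a_dt,
      alpha = if (res$ok) fit$alpha else NA_real_,
      D_fit = if (res$ok) fit$D_fit else NA_real_,
      D_eff_nm2_us = if (res$ok) fit$D_eff_nm2_us else NA_real_,
      regime = if (res$ok) fit$regime else NA_character_,
      n_tracers = res$n_tracers,
      n_ensembles = spec$n_ensembles,
      seed = derive_seed(spec$base_seed, cell, 1L),
      scale = spec$scale, ok = res$ok, message = res$message,
      stringsAsFactors = FALSE)
    ens_fits[[cell]] <- res$per_ens
  }
  out <- do.call(rbind, rows)
  attr(out, "ensemble_fits") <- ens_fits
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", "data.frame")
  out
}

# One ensemble member of one grid cell.
simulate_cell <- function(spec, g, seed) {
  sch <- sim_schedule(spec$measure_ms, anneal_ms = spec$anneal_ms,
                      n_record = spec$n_record)
  if (spec$engine == "continuous") {
    if (g$a_cro > 0 || g$a_pro > 0)
      stopf("the continuous engine is obstacle-free")
    return(simulate_disks(g$a_dt, sch, exclusion = g$exclusion, seed = seed))
  }
  cfg <- lattice_config(n_side = spec$n_side)
  field <- build_obstacle_field(cfg, a_cro = g$a_cro, a_pro = g$a_pro,
                                binding_energy = g$binding_energy,
                                seed = derive_seed(seed, 1L))
  pop <- place_tracers(cfg, field, a_dt = g$a_dt, exclusion = g$exclusion,
                       seed = derive_seed(seed, 2L))
  simulate_lattice(cfg, field, pop, sch, recursive = spec$recursive,
                   seed = derive_seed(seed, 3L))
}

#' Convergence diagnostics for a sweep
#'
#' Standard errors of the anomalous exponent and effective diffusion
#' coefficient across the per-ensemble fits of each grid cell, with a flag
#' for cells whose `SE(alpha)` exceeds `se_tol`. Single-ensemble cells are
#' flagged as unassessable rather than erroring.
#'
#' @param result a [run_sweep()] result.
#' @param se_tol flag threshold on `SE(alpha)` (default 0.05).
#' @return data frame with one row per cell: `alpha_se`, `d_eff_se`,
#'   `n_fits` and `flag`.
#' @export
convergence_report <- function(result, se_tol = 0.05) {
  stopifnot(inherits(result, "sweep_result"))
  ens <- attr(result, "ensemble_fits")
  rows <- lapply(seq_along(ens), function(cell) {
    fits <- Filter(Negate(is.null), ens[[cell]])
    n <- length(fits)
    if (n < 2) {
      return(data.frame(cell = cell, n_fits = n, alpha_se = NA_real_,
                        d_eff_se = NA_real_, flag = "too-few-ensembles"))
    }
    a <- vapply(fits, `[[`, numeric(1), "alpha")
    d <- vapply(fits, `[[`, numeric(1), "D_eff_nm2_us")
    a_se <- sd(a) / sqrt(n)
    data.frame(cell = cell, n_fits = n, alpha_se = a_se,
               d_eff_se = sd(d) / sqrt(n),
               flag = if (a_se > se_tol) "wide-se" else "ok")
  })
  do.call(rbind, rows)
}
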