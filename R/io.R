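# Plain-text serialization: MSD tables with unit-carrying headers,
# trajectory tables, characterization records and run manifests.

#' Write / read an MSD table
#'
#' Two-column delimited text with a `#` header block carrying the units and
#' provenance fields, so externally digitized MSD curves can be exchanged
#' with the fitting tools.
#'
#' @param profile an [ensemble_msd()] result or data frame with `time_ms`,
#'   `msd_um2`.
#' @param path file path.
#' @param extra named character vector of extra header fields.
#' @return `write_msd_table` returns `path` invisibly; `read_msd_table`
#'   returns an `msd_profile`.
#' @export
write_msd_table <- function(profile, path, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# MSD table",
               "# columns: time_ms msd_um2",
               "# units: time ms, MSD um^2",
               if (!is.null(attr(profile, "n_tracers")))
                 sprintf("# n_tracers: %d", attr(profile, "n_tracers")),
               if (!is.null(attr(profile, "n_ensembles")))
                 sprintf("# n_ensembles: %d", attr(profile, "n_ensembles")),
               if (length(extra)) sprintf("# %s: %s", names(extra), extra)),
             con)
  write.table(data.frame(time_ms = profile$time_ms,
                         msd_um2 = profile$msd_um2),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_msd_table
#' @export
read_msd_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("time_ms", "msd_um2") %in% names(out)))
    stopf("not an MSD table: %s", path)
  hdr <- grep("^#", readLines(path, n = 20), value = TRUE)
  nt <- sub(".*n_tracers: *", "", grep("n_tracers:", hdr, value = TRUE))
  ne <- sub(".*n_ensembles: *", "", grep("n_ensembles:", hdr, value = TRUE))
  if (length(nt)) attr(out, "n_tracers") <- as.integer(nt)
  if (length(ne)) attr(out, "n_ensembles") <- as.integer(ne)
  class(out) <- c("msd_profile", "data.frame")
  out
}

#' Write a trajectory record as a delimited table plus JSON manifest
#'
#' One row per (frame, tracer) with columns `time_ms`, `tracer_id`,
#' `x_unwrapped`, `y_unwrapped` (\eqn{\mu m}, displacement from the
#' measurement origin) and `bound`; the full parameterization, engine tag and
#' seed go to `<path>.manifest.json` so any run can be regenerated from its
#' manifest alone.
#'
#' @param traj a `cd_trajectory`.
#' @param path output table path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cd_trajectory"))
  n_rec <- nrow(traj$x)
  n_tr <- ncol(traj$x)
  tab <- data.frame(
    time_ms = rep(traj$times_ms, times = n_tr),
    tracer_id = rep(seq_len(n_tr), each = n_rec),
    x_unwrapped = as.vector(traj$x),
    y_unwrapped = as.vector(traj$y),
    bound = rep(traj$bound, each = n_rec))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(list(engine = traj$engine), traj$params)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a diffusion characterization as JSON
#'
#' @param fit a [fit_alpha()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_characterization <- function(fit, path) {
  stopifnot(inherits(fit, "diffusion_fit"))
  rec <- list(alpha = fit$alpha, D_fit = fit$D_fit, D_eff = fit$D_eff,
              D_eff_nm2_us = fit$D_eff_nm2_us, regime = fit$regime,
              crossover_time_ms = fit$crossover_time_ms,
              crossover_length_um2 = fit$crossover_length_um2,
              t_obs_ms = fit$t_obs, settings = fit$settings)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
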