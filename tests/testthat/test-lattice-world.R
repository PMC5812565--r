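# Lattice geometry, obstacle placement and tracer placement.

test_that("hop length and lattice size follow from the physical constants", {
  dl <- derive_step_length(0.2e-3, 1e-3)
  expect_equal(dl, sqrt(4 * 0.2e-3 * 1e-3), tolerance = 1e-12)
  expect_equal(signif(dl, 2), 8.9e-4)          # the printed receptor value
  expect_equal(derive_step_length(0.25, 1), 1.0)
  expect_equal(derive_step_length(1e-2, 4e-2), 0.04)
  expect_error(derive_step_length(-1, 1), "positive")
  expect_error(derive_step_length(1, 0), "positive")

  expect_identical(derive_n_side(1, dl), 1119L)
  expect_identical(derive_n_side(1, 0.5), 3L)
  expect_identical(derive_n_side(1, 0.1), 11L)
  expect_error(derive_n_side(0, 1))
})

test_that("lattice_config derives a consistent geometry", {
  cfg <- lattice_config()
  expect_identical(cfg$n_side, 1119L)
  expect_equal(cfg$step_length,
               sqrt(4 * cfg$free_diffusion_coefficient * cfg$time_step),
               tolerance = 1e-12)
  expect_identical(cfg$boundary, "periodic")
  expect_error(lattice_config(n_side = 2), "at least 3")
})

test_that("obstacle counts are round-half-up of fraction times sites", {
  cfg <- lattice_config()    # 1119^2 = 1,252,161 sites
  f <- build_obstacle_field(cfg, a_cro = 0.25, seed = 1)
  # integer oracle: 0.25 * 1252161 = 313040.25 -> 313040
  expect_identical(sum(f$site_kind == 1L), 313040L)
  expect_identical(sum(f$site_kind == 2L), 0L)
  expect_equal(f$a_cro, 313040 / 1252161)

  w <- empty_world(10)
  expect_true(all(w$field$site_kind == 0L))
  expect_error(build_obstacle_field(desk_config(10), a_cro = 0.5, a_pro = 0.6),
               "sum")
  expect_error(build_obstacle_field(desk_config(10), a_cro = -0.1))
  expect_error(build_obstacle_field(desk_config(10), binding_energy = -1))
  expect_error(build_obstacle_field(desk_config(10), p_reflect = 1.5))
})

test_that("CRO and PRO sites never overlap and fractions are realized", {
  cfg <- desk_config(60)
  f <- build_obstacle_field(cfg, a_cro = 0.3, a_pro = 0.2,
                            binding_energy = 6, seed = 5)
  expect_identical(sum(f$site_kind == 1L), 1080L)  # round(0.3 * 3600)
  expect_identical(sum(f$site_kind == 2L), 720L)   # round(0.2 * 3600)
  expect_lte(abs(f$a_cro - 0.3), 0.5 / 3600)
  expect_lte(abs(f$a_pro - 0.2), 0.5 / 3600)
})

test_that("tracer placement respects obstacles, exclusion and counts", {
  cfg <- lattice_config()
  f <- build_obstacle_field(cfg)
  p <- place_tracers(cfg, f, a_dt = 0.001, exclusion = TRUE, seed = 3)
  expect_identical(p$n_tracers, 1252L)          # round(0.001 * 1252161)
  sites <- (p$col - 1L) * cfg$n_side + p$row
  expect_identical(anyDuplicated(sites), 0L)

  w <- empty_world(10)
  p0 <- place_tracers(w$cfg, w$field, a_dt = 0)
  expect_identical(p0$n_tracers, 0L)

  cfg10 <- desk_config(10)
  full <- build_obstacle_field(cfg10, a_cro = 1, seed = 1)
  expect_error(place_tracers(cfg10, full, a_dt = 0.1, exclusion = TRUE),
               "capacity")

  # tracers avoid CROs, may sit on PROs, and start bound there
  fm <- build_obstacle_field(cfg10, a_cro = 0.3, a_pro = 0.3,
                             binding_energy = 2, seed = 2)
  pm <- place_tracers(cfg10, fm, a_dt = 0.2, exclusion = TRUE, seed = 4)
  kinds <- fm$site_kind[cbind(pm$row, pm$col)]
  expect_true(all(kinds != 1L))
  expect_identical(pm$bound, kinds == 2L)
})

test_that("placement is reproducible under a fixed seed", {
  cfg <- desk_config(80)
  f1 <- build_obstacle_field(cfg, a_cro = 0.2, seed = 42)
  f2 <- build_obstacle_field(cfg, a_cro = 0.2, seed = 42)
  expect_identical(f1$site_kind, f2$site_kind)
  p1 <- place_tracers(cfg, f1, a_dt = 0.05, seed = 43)
  p2 <- place_tracers(cfg, f2, a_dt = 0.05, seed = 43)
  expect_identical(p1[c("row", "col", "bound")], p2[c("row", "col", "bound")])
})

test_that("placements are spatially uniform over coarse bins", {
  cfg <- desk_config(100)
  f <- build_obstacle_field(cfg)
  p <- place_tracers(cfg, f, n_tracers = 10000, exclusion = FALSE, seed = 9)
  bin <- (ceiling(p$row / 10) - 1L) * 10L + ceiling(p$col / 10)
  counts <- tabulate(bin, nbins = 100)
  pval <- stats::chisq.test(counts)$p.value
  expect_gt(pval, 0.001)
})
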