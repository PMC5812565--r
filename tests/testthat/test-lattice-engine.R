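# Hopping rules, binding kinetics and the false-self-blocking recursion.

test_that("direction sampling follows the quartile rule", {
  expect_identical(sample_direction(c(0, 0.1, 0.2499)),
                   c("left", "left", "left"))
  expect_identical(sample_direction(c(0.25, 0.49)), c("right", "right"))
  expect_identical(sample_direction(c(0.5, 0.74)), c("up", "up"))
  expect_identical(sample_direction(c(0.75, 0.9999)), c("down", "down"))
  expect_error(sample_direction(1), "\\[0, 1\\)")
})

test_that("escape probability is the Boltzmann factor of the binding energy", {
  expect_identical(escape_probability(0), 1)
  expect_equal(escape_probability(2), 0.13534, tolerance = 1e-4)
  expect_equal(escape_probability(10), 4.5400e-5, tolerance = 1e-4)
  expect_error(escape_probability(-0.1), ">= 0")
})

test_that("single hops respect obstacle and occupancy rules", {
  cfg <- desk_config(10)
  f <- build_obstacle_field(cfg)
  f$site_kind[5, 6] <- 1L   # CRO to the right of (5,5)
  f$site_kind[5, 4] <- 2L   # PRO to the left
  pop <- place_tracers(cfg, f, n_tracers = 0)
  pop$row <- c(5L, 4L); pop$col <- c(5L, 5L); pop$bound <- c(FALSE, FALSE)
  pop$exclusion <- TRUE; pop$n_tracers <- 2L

  # CRO destination: complete reflection
  out <- attempt_hop(cfg, f, pop, 1, "right", u_reflect = 0.99)
  expect_false(out$moved)
  expect_identical(c(out$row, out$col), c(5L, 5L))

  # PRO destination with u >= P_reflect: hop and bind
  out <- attempt_hop(cfg, f, pop, 1, "left", u_reflect = 0.7)
  expect_true(out$moved)
  expect_true(out$newly_bound)
  expect_identical(c(out$row, out$col), c(5L, 4L))

  # PRO destination with u < P_reflect: partial reflection
  out <- attempt_hop(cfg, f, pop, 1, "left", u_reflect = 0.3)
  expect_false(out$moved)

  # occupied empty destination blocks and is labelled
  out <- attempt_hop(cfg, f, pop, 2, "down", u_reflect = 0.9)
  expect_false(out$moved)
  expect_true(out$blocked_by_dt)

  # free empty destination: plain hop
  out <- attempt_hop(cfg, f, pop, 1, "down", u_reflect = 0.9)
  expect_true(out$moved)
})

test_that("the recursion pass resolves false self-blocking of two tracers", {
  cfg <- desk_config(10)
  f <- build_obstacle_field(cfg)
  # tracer 1 aims at tracer 2's site; tracer 2 aims at a free site.
  # processing order (1, 2): pass one blocks tracer 1, pass two frees it.
  res <- step_population(cfg, f, row = c(5, 5), col = c(5, 6),
                         directions = c("right", "right"), recursive = TRUE)
  expect_identical(res$moved, c(TRUE, TRUE))
  expect_identical(res$col, c(6L, 7L))
  expect_identical(res$blocked_by_dt, c(TRUE, FALSE))

  # without the second pass only the unobstructed tracer moves
  res1 <- step_population(cfg, f, row = c(5, 5), col = c(5, 6),
                          directions = c("right", "right"), recursive = FALSE)
  expect_identical(res1$moved, c(FALSE, TRUE))
  expect_identical(res1$col, c(5L, 7L))

  # opposite processing order: same final occupancy, no pass-two needed
  res2 <- step_population(cfg, f, row = c(5, 5), col = c(5, 6)[2:1],
                          directions = c("right", "right"), recursive = TRUE)
  expect_setequal(paste(res2$row, res2$col), paste(res$row, res$col))
})

test_that("a fully packed lattice is frozen", {
  cfg <- desk_config(4)
  f <- build_obstacle_field(cfg)
  g <- expand.grid(row = 1:4, col = 1:4)
  dirs <- rep(c("left", "right", "up", "down"), 4)
  res <- step_population(cfg, f, g$row, g$col, dirs, recursive = TRUE)
  expect_false(any(res$moved))
  expect_identical(res$row, as.integer(g$row))
  expect_identical(res$col, as.integer(g$col))
})

test_that("free ensemble MSD matches 4 D t within three standard errors", {
  n_tracers <- 1000
  msd <- free_lattice_msd(n_tracers, measure_ms = 1, n_side = 100,
                          seed = 11, n_record = 20)
  cfg <- desk_config()
  expected <- 4 * cfg$free_diffusion_coefficient * msd$time_ms
  # relative SE of a mean of n_tracers squared displacements is sqrt(2/n)
  se <- expected * sqrt(2 / n_tracers)
  expect_true(all(abs(msd$msd_um2 - expected) <= 3 * se))
})

test_that("tracer count, exclusion and obstacle avoidance hold during runs", {
  cfg <- desk_config(30)
  f <- build_obstacle_field(cfg, a_cro = 0.2, a_pro = 0.2,
                            binding_energy = 2, seed = 7)
  p <- place_tracers(cfg, f, a_dt = 0.2, exclusion = TRUE, seed = 8)
  # check_invariants makes the C++ engine stop on any violation
  tr <- simulate_lattice(cfg, f, p, sim_schedule(5, anneal_ms = 1),
                         seed = 9, check_invariants = TRUE)
  expect_identical(ncol(tr$x), p$n_tracers)
  expect_identical(length(tr$bound), p$n_tracers)
})

test_that("runs are bit-reproducible under a fixed seed", {
  w <- empty_world(20)
  p <- place_tracers(w$cfg, w$field, n_tracers = 5, exclusion = TRUE, seed = 1)
  t1 <- simulate_lattice(w$cfg, w$field, p, sim_schedule(5), seed = 77)
  t2 <- simulate_lattice(w$cfg, w$field, p, sim_schedule(5), seed = 77)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
})

test_that("independent mode allows co-occupancy; zero tracers are a no-op", {
  cfg <- desk_config(5)
  f <- build_obstacle_field(cfg)
  p <- place_tracers(cfg, f, n_tracers = 20, exclusion = FALSE, seed = 2)
  tr <- simulate_lattice(cfg, f, p, sim_schedule(2), seed = 3)
  # 20 tracers on 25 sites for 2000 steps: co-occupancy is unavoidable and
  # must not have been blocked -- displacement variance matches free hopping
  expect_gt(mean(tr$x[nrow(tr$x), ]^2 + tr$y[nrow(tr$y), ]^2), 0)

  p0 <- place_tracers(cfg, f, n_tracers = 0)
  tr0 <- simulate_lattice(cfg, f, p0, sim_schedule(2), seed = 3)
  expect_identical(ncol(tr0$x), 0L)
})

test_that("annealing equilibrates the bound fraction under binding", {
  cfg <- desk_config(60)
  f <- build_obstacle_field(cfg, a_pro = 0.4, binding_energy = 2, seed = 21)
  p <- place_tracers(cfg, f, n_tracers = 1500, exclusion = FALSE, seed = 22)
  tr <- simulate_lattice(cfg, f, p, sim_schedule(1, anneal_ms = 50),
                         seed = 23, anneal_monitor_every = 500L)
  bf <- tr$anneal_bound_fraction
  n <- length(bf)
  early <- bf[1:ceiling(n / 10)]
  late <- bf[(n - ceiling(n / 10) + 1):n]
  # mean-field kinetic balance: a tracer leaves the bound pool only by
  # escaping AND hopping to a non-PRO site; it enters by passing the partial
  # reflection of a PRO destination.  f_b / f_f = a (1-P_r) / (p_esc (1-a)).
  a <- f$a_pro; pr <- f$reflect_probability
  pe <- escape_probability(f$binding_energy)
  stat <- a * (1 - pr) / (a * (1 - pr) + pe * (1 - a))
  expect_lt(abs(mean(late) - stat), 0.05)
  # binding accumulates from the uniform initial placement toward equilibrium
  expect_lt(mean(early), mean(late))
  # the bound fraction drifts during early annealing, then is stationary
  expect_lt(abs(mean(late) - mean(bf[(n %/% 2):n])), 0.03)
})

test_that("bound tracers dwell according to the escape probability", {
  cfg <- desk_config(15)
  # all-PRO lattice, strong binding: almost no displacement over a short run
  f_strong <- build_obstacle_field(cfg, a_pro = 1, binding_energy = 10, seed = 1)
  f_weak <- build_obstacle_field(cfg, a_pro = 1, binding_energy = 0, seed = 1)
  p <- place_tracers(cfg, f_strong, n_tracers = 100, exclusion = FALSE, seed = 2)
  sch <- sim_schedule(1, anneal_ms = 0)
  strong <- simulate_lattice(cfg, f_strong, p, sch, seed = 3)
  weak <- simulate_lattice(cfg, f_weak, p, sch, seed = 3)
  msd_s <- mean(strong$x[nrow(strong$x), ]^2 + strong$y[nrow(strong$y), ]^2)
  msd_w <- mean(weak$x[nrow(weak$x), ]^2 + weak$y[nrow(weak$y), ]^2)
  # dwell ~ e^E steps: mobility ratio should be drastic, not marginal
  expect_lt(msd_s, msd_w / 100)
})
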