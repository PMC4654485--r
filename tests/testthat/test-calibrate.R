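test_that("default priors carry the class medians and 2-log bounds", {
  pr <- default_priors(canonical)
  expect_equal(nrow(pr), 91)
  med <- attr(pr, "class_medians")
  expect_equal(unname(med["mrna_decay"]), 1.2e-3)
  expect_equal(unname(med["mir_decay"]), 1e-4)
  expect_equal(unname(med["protein_decay"]), 2.5e-4)
  expect_equal(unname(med["translation"]), 3)
  expect_equal(unname(med["mrna_level"]), 2.8e-5)
  expect_equal(unname(med["protein_level"]), 0.08)
  row <- pr[pr$id == "kd_ago1_mrna", ]
  expect_equal(row$class, "mrna_decay")
  expect_equal(row$median, 1.2e-3)
  expect_equal(row$lower, 1.2e-5)
  expect_equal(row$upper, 1.2e-1)
  expect_equal(pr[pr$id == "kt_vegf", "median"], 3)
  ## every parameter has a class and positive bounds
  expect_true(all(pr$lower > 0 & pr$upper > pr$lower))
})

test_that("the SSE objective does plain residual arithmetic", {
  m <- toy_birth_death(ks = 0.01, kd = 0.001)
  ro <- readout_definition("a", "A")
  ## the model sits at steady state: its relative trace is exactly 1
  ds <- calibration_dataset(c(0, 60, 120), c(1, 2, 1), c(0.1, 0.1, 0.1),
                            ro, protocol(21, 120))
  o1 <- sse_objective(numeric(0), m, list(ds))
  expect_equal(as.numeric(o1), 1)  # residuals (0, -1, 0)
  ## doubling every residual quadruples the objective
  ds2 <- calibration_dataset(c(0, 60, 120), c(1, 3, 1),
                             c(0.1, 0.1, 0.1), ro, protocol(21, 120))
  o2 <- sse_objective(numeric(0), m, list(ds2))
  expect_equal(as.numeric(o2), 4)
  ## weighting by sd
  ow <- sse_objective(numeric(0), m, list(ds), weight_by_sd = TRUE)
  expect_equal(as.numeric(ow), (1 / 0.1)^2)
})

test_that("self-generated noise-free data give a zero objective", {
  pr <- protocol(2, 720, output_every_min = 10)
  ds <- generate_western_fixture(canonical, pr, "total_ago1",
                                 n_points = 5, noise_cv = 0, seed = 3)
  o <- sse_objective(numeric(0), canonical, list(ds))
  expect_lt(as.numeric(o), 1e-10)
})

test_that("fixture generation is deterministic and carries its noise", {
  m <- toy_birth_death(ks = 1e-3, kd = 1e-3)
  ## drive the trace away from flat so noise acts on structure
  pr <- protocol(21, 120, perturbations = list(), output_every_min = 5)
  ro <- readout_definition("a", "A")
  d1 <- generate_western_fixture(m, pr, ro, n_points = 5,
                                 noise_cv = 0.1, seed = 11)
  d2 <- generate_western_fixture(m, pr, ro, n_points = 5,
                                 noise_cv = 0.1, seed = 11)
  expect_identical(d1$value, d2$value)
  d3 <- generate_western_fixture(m, pr, ro, n_points = 5,
                                 noise_cv = 0.1, seed = 12)
  expect_false(identical(d3$value, d1$value))
  expect_equal(d1$value[1], 1)
  expect_equal(d1$sd, pmax(0.1 * d1$value, 1e-12))
})

test_that("the multiplicative noise has the requested CV", {
  ## Monte-Carlo on a cheap model: 400 fixtures, point-wise CV ~ 0.1
  m <- toy_birth_death(ks = 0.01, kd = 0.001)
  pr <- protocol(21, 60, output_every_min = 30)
  ro <- readout_definition("a", "A")
  vals <- vapply(seq_len(400), function(s)
    generate_western_fixture(m, pr, ro, n_points = 3, noise_cv = 0.1,
                             seed = s)$value[3], 0)
  cv <- stats::sd(vals) / mean(vals)
  expect_gt(cv, 0.08)
  expect_lt(cv, 0.12)
})

test_that("zero free parameters returns the model unchanged", {
  pr <- protocol(2, 360, output_every_min = 30)
  ds <- generate_western_fixture(canonical, pr, "total_hif1a",
                                 n_points = 4, noise_cv = 0, seed = 1)
  fit <- fit_parameters(canonical, list(ds), free = character(0))
  expect_length(coef(fit), 0)
  expect_equal(fit$objective, fit$initial_objective)
  expect_identical(param_values(fit$model), param_values(canonical))
})

test_that("datasets round-trip through delimited text", {
  pr <- protocol(2, 720)
  ds <- calibration_dataset(c(0, 360, 720), c(1, 0.8, 0.6),
                            c(0.05, 0.05, 0.05),
                            "total_ago1", pr)
  path <- tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$time_min, ds$time_min)
  expect_equal(back$value, ds$value)
  expect_equal(back$sd, ds$sd)
  expect_equal(back$readout$members, ds$readout$members)
  expect_equal(back$condition$o2_percent, 2)
})

test_that("calibration recovers perturbed parameters from clean data", {
  ## round-trip: perturb two kinetic constants x3, fit them back on a
  ## noise-free fixture of the AGO1 decline
  pr <- protocol(2, 1440, output_every_min = 30)
  ds_ago <- generate_western_fixture(canonical, pr, "total_ago1",
                                     n_points = 8, noise_cv = 0,
                                     seed = 5)
  ds_let7 <- generate_western_fixture(canonical, pr, "total_let7",
                                      n_points = 8, noise_cv = 0,
                                      seed = 6)
  free <- c("kf_ago1_pb", "Vm_let7")
  wrong <- param_values(canonical)[free] * 3
  m0 <- set_params(canonical, wrong)
  fit <- fit_parameters(m0, list(ds_ago, ds_let7), free = free,
                        n_starts = 1, maxiter = 20)
  expect_lt(fit$objective, fit$initial_objective)
  rel_err <- abs(coef(fit) - param_values(canonical)[free]) /
    param_values(canonical)[free]
  expect_lt(max(rel_err), 0.10)
})
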