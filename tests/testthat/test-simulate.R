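test_that("steady-state finder solves the synthesis/decay balance", {
  m <- toy_birth_death(ks = 0.01, kd = 0.001)
  ss <- find_normoxic_steady_state(m)
  expect_equal(unname(ss[["A"]]), 10, tolerance = 1e-6)
  expect_lt(attr(ss, "residual"), 1e-8)
})

test_that("normoxia is a fixed point: 48 h of 21% O2 moves nothing", {
  tc <- run_protocol(canonical, protocol(21, 2880,
                                         output_every_min = 60))
  ss <- tc$conc[1, ]
  keep <- ss > 1e-12  # dormant perturbants sit at zero
  reldev <- abs(sweep(tc$conc[, keep], 2, ss[keep], "/") - 1)
  expect_lt(max(reldev), 0.01)
})

test_that("hypoxia produces the HIF-1a overshoot and its TTP control", {
  tc <- run_protocol(canonical, protocol(2, 2880, output_every_min = 10))
  hif <- relative_expression(tc, "total_hif1a")
  t <- tc$time
  ipk <- which.max(hif)
  ## rises, peaks within the first ~10 h, declines to a plateau above 1
  expect_gt(hif[ipk], 3)
  expect_gt(t[ipk], 240)
  expect_lt(t[ipk], 840)
  expect_lt(hif[length(hif)], 0.8 * hif[ipk])
  expect_gt(hif[length(hif)], 1.5)
  ## normoxic level is low relative to the hypoxic peak
  expect_lt(1 / hif[ipk], 0.25)
  ## TTP silencing lengthens the overshoot
  tsi <- run_protocol(canonical, protocol(
    2, 2880, perturbation("sirna_silencing", "TTP_mRNA", 1e-3),
    output_every_min = 10))
  hsi <- relative_expression(tsi, "total_hif1a")
  expect_gt(tsi$time[which.max(hsi)], t[ipk])
})

test_that("AGO1 falls below baseline only after a let-7 loading delay", {
  tc <- run_protocol(canonical, protocol(2, 2880, output_every_min = 10))
  ago <- relative_expression(tc, "total_ago1")
  t <- tc$time
  expect_gt(min(ago[t <= 60]), 0.97)   # near 1 during the first hour
  expect_lt(ago[t == 1440], 0.8)       # clearly depressed by 24 h
  expect_lt(ago[t == 2880], ago[t == 1440] + 0.02)
})

test_that("relative expression normalises to the t = 0 level", {
  tc <- run_protocol(canonical, protocol(2, 360, output_every_min = 60))
  for (ro in c("total_hif1a", "total_ago1", "vegf_protein")) {
    expect_identical(relative_expression(tc, ro)[1], 1)
  }
  ## hand-built two-point time course
  fk <- fake_timecourse(c(0, 60),
                        matrix(c(1, 2), 2, 1,
                               dimnames = list(NULL, "VEGF")))
  tr <- relative_expression(fk, readout_definition("v", "VEGF"))
  expect_equal(as.numeric(tr), c(1, 2))
  ## zero baseline is an error
  fk0 <- fake_timecourse(c(0, 60),
                         matrix(c(0, 2), 2, 1,
                                dimnames = list(NULL, "VEGF")))
  expect_error(relative_expression(fk0, readout_definition("v", "VEGF")),
               "zero at t = 0")
})

test_that("total VEGF produced integrates the translation flux", {
  kt <- param_values(canonical)[["kt_vegf"]]
  ## zero mRNA -> zero production
  z <- matrix(0, 25, 2,
              dimnames = list(NULL, c("VEGF_mRNA", "VEGF")))
  fkz <- fake_timecourse(seq(0, 1440, length.out = 25), z)
  expect_equal(as.numeric(total_vegf_produced(fkz)), 0)
  ## constant mRNA m over T minutes -> kt * m * T
  m <- 2e-6
  cm <- matrix(c(rep(m, 25), rep(0, 25)), 25, 2,
               dimnames = list(NULL, c("VEGF_mRNA", "VEGF")))
  fkc <- fake_timecourse(seq(0, 1440, length.out = 25), cm)
  expect_equal(as.numeric(total_vegf_produced(fkc)), kt * m * 1440,
               tolerance = 1e-12)
  ## span beyond the simulated range errors
  expect_error(total_vegf_produced(fkc, span_min = 2000), "span")
})

test_that("hypoxia raises 24-h VEGF production above normoxia", {
  t1 <- run_protocol(canonical, protocol(1, 1440, output_every_min = 10))
  t21 <- run_protocol(canonical, protocol(21, 1440,
                                          output_every_min = 10))
  expect_gt(as.numeric(total_vegf_produced(t1)),
            as.numeric(total_vegf_produced(t21)))
})

test_that("free VEGF mRNA fraction is a proper fraction and O2-graded", {
  tc2 <- run_protocol(canonical, protocol(2, 2880,
                                          output_every_min = 60))
  fr2 <- free_vegf_mrna_fraction(tc2)
  expect_true(all(fr2 >= 0 & fr2 <= 1))
  ## all-free edge case
  af <- matrix(c(1, 1, 0, 0, 0, 0), 2, 3,
               dimnames = list(NULL, c("VEGF_mRNA", "VEGF_mRNA_RISC",
                                       "VEGF_mRNA_PB")))
  expect_equal(as.numeric(free_vegf_mrna_fraction(
    fake_timecourse(c(0, 10), af))), c(1, 1))
  ## lower O2 leaves a larger free fraction at matched late times
  tc1 <- run_protocol(canonical, protocol(1, 2880,
                                          output_every_min = 60))
  tc21 <- run_protocol(canonical, protocol(21, 2880,
                                           output_every_min = 60))
  fr1 <- free_vegf_mrna_fraction(tc1)
  fr21 <- free_vegf_mrna_fraction(tc21)
  n <- length(fr1)
  expect_gt(fr1[n], fr2[n])
  expect_gt(fr2[n], fr21[n])
  ## AGO1 overexpression pushes the fraction back down
  toe <- run_protocol(canonical, protocol(
    2, 2880, perturbation("mrna_overexpression", "AGO1_mRNA", 0.08),
    output_every_min = 60))
  froe <- free_vegf_mrna_fraction(toe)
  expect_true(all(froe[-1] < fr2[-1]))
})

test_that("onset delay matches the closed-form inversion", {
  ## c(t) = c0 + (1 - exp(-t/tau)): threshold time has a closed form
  tau <- 100; c0 <- 0.5
  t <- seq(0, 300, by = 1)
  conc <- matrix(c0 + (1 - exp(-t / tau)), ncol = 1,
                 dimnames = list(NULL, "X"))
  fk <- fake_timecourse(t, conc)
  inc120 <- (1 - exp(-120 / tau))
  expected <- -tau * log(1 - 0.05 * inc120)
  expect_equal(onset_delay(fk, "X"), expected, tolerance = 1e-3)
  ## constant species: undefined
  flat <- fake_timecourse(t, matrix(1, length(t), 1,
                                    dimnames = list(NULL, "X")))
  expect_true(is.na(onset_delay(flat, "X")))
  ## instantaneous step at t = 0
  step <- fake_timecourse(t, matrix(c(0, rep(1, length(t) - 1)),
                                    ncol = 1,
                                    dimnames = list(NULL, "X")))
  expect_lt(onset_delay(step, "X"), 1)
})

test_that("48-h total HIF-1a decreases as oxygen rises", {
  ends <- vapply(c(0.5, 1, 2, 5, 21), function(pc) {
    tc <- run_protocol(canonical, protocol(pc, 2880,
                                           output_every_min = 120))
    unname(tail(relative_expression(tc, "total_hif1a"), 1))
  }, 0)
  expect_true(all(diff(ends) < 0))
})

test_that("halving solver tolerances leaves readouts unchanged to 0.1%", {
  pr1 <- protocol(2, 1440, output_every_min = 60)
  pr2 <- protocol(2, 1440, output_every_min = 60,
                  rtol = 5e-9, atol = 5e-13)
  a <- run_protocol(canonical, pr1)
  b <- run_protocol(canonical, pr2)
  for (ro in c("total_hif1a", "total_ago1", "vegf_protein")) {
    ra <- relative_expression(a, ro)
    rb <- relative_expression(b, ro)
    expect_lt(max(abs(ra - rb) / pmax(abs(ra), 1e-12)), 1e-3)
  }
  va <- as.numeric(total_vegf_produced(a))
  vb <- as.numeric(total_vegf_produced(b))
  expect_lt(abs(va - vb) / va, 1e-3)
})
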