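test_that("decay-model sensitivity matches the closed form", {
  ## d[A]/dt = -k[A], A(0) = a0  =>  dA/dk (t) = -a0 * t * exp(-k t)
  k <- 0.05; a0 <- 2
  m <- toy_decay(k, a0)
  pr <- protocol(21, 60, output_every_min = 5)
  init <- c(A = a0)
  tt <- seq(0, 60, by = 5)
  expected <- -a0 * tt * exp(-k * tt)
  s_cs <- local_sensitivity(m, pr, "A", "k", init = init)
  expect_identical(attr(s_cs, "method"), "complex_step")
  expect_equal(as.numeric(s_cs), expected, tolerance = 1e-6)
  s_cd <- local_sensitivity(m, pr, "A", "k",
                            method = "central_difference", init = init)
  expect_equal(as.numeric(s_cd), expected, tolerance = 1e-4)
})

test_that("a parameter outside the reachable sub-network has zero effect", {
  ## perturbant binding constants cannot influence the untreated run
  pr <- protocol(2, 240, output_every_min = 60)
  s <- local_sensitivity(canonical, pr, "HIF1A", "kf_anti_let7")
  expect_true(all(abs(s) < 1e-12))
})

test_that("sensitivity shares form a probability vector", {
  pars <- c("kf_phd2_o2", "kf_hif_import", "kf_ago1_let7", "kp21")
  sh <- sensitivity_shares(canonical,
                           protocol(2, 360, output_every_min = 60),
                           species = "HIF1A", parameters = pars)
  expect_true(all(sh$share >= 0))
  expect_equal(sum(sh$share), 1, tolerance = 1e-9)
  ## single parameter gets share 1
  sh1 <- sensitivity_shares(canonical,
                            protocol(2, 240, output_every_min = 60),
                            species = "HIF1A",
                            parameters = "kf_phd2_o2")
  expect_equal(sh1$share, 1)
  ## each copy of a duplicated parameter gets half the combined share
  shd <- sensitivity_shares(canonical,
                            protocol(2, 240, output_every_min = 60),
                            species = "HIF1A",
                            parameters = c("kf_phd2_o2", "kf_phd2_o2",
                                           "kf_hif_import"))
  expect_equal(shd$share[1], shd$share[2])
  expect_equal(sum(shd$share), 1, tolerance = 1e-9)
  single <- sensitivity_shares(canonical,
                               protocol(2, 240, output_every_min = 60),
                               species = "HIF1A",
                               parameters = c("kf_phd2_o2",
                                              "kf_hif_import"))
  expect_equal(shd$share[1], single$share[1] / 2, tolerance = 1e-9)
})

test_that("complex step and central differences agree closely", {
  pr <- protocol(2, 360, output_every_min = 30)
  for (pid in c("kf_hif_import", "kf_phd2_o2")) {
    s1 <- local_sensitivity(canonical, pr, "HIF1A", pid,
                            method = "complex_step")
    s2 <- local_sensitivity(canonical, pr, "HIF1A", pid,
                            method = "central_difference")
    scale <- max(abs(s2))
    expect_lt(max(abs(s1 - s2)) / scale, 1e-3)
  }
})

test_that("complex-step shares are insensitive to the step size", {
  pr <- protocol(2, 240, output_every_min = 60)
  i1 <- local_sensitivity(canonical, pr, "HIF1A", "kf_phd2_o2",
                          h = 1e-7)
  i2 <- local_sensitivity(canonical, pr, "HIF1A", "kf_phd2_o2",
                          h = 5e-8)
  expect_lt(max(abs(i1 - i2)) / max(abs(i1)), 1e-6)
})

test_that("O2-hydroxylase affinities dominate HIF-1a sensitivity", {
  pars <- c("kf_phd2_o2", "kf_fih_o2", "kf_hif_import", "kp21",
            "kf_ago1_mir15a", "kf_vegf_risc")
  sh <- sensitivity_shares(canonical,
                           protocol(2, 720, output_every_min = 60),
                           species = "HIF1A", parameters = pars,
                           method = "central_difference")
  o2_rank <- sh$rank[sh$parameter == "kf_phd2_o2"]
  expect_lte(o2_rank, stats::median(sh$rank))
})

test_that("direct production/degradation rates can be excluded", {
  pars <- c("kt_hif", "kd_hif", "kf_hif_import", "kf_phd2_o2")
  sh <- sensitivity_shares(canonical,
                           protocol(2, 240, output_every_min = 60),
                           species = "HIF1A", parameters = pars,
                           method = "central_difference",
                           exclude_direct = TRUE)
  expect_false(any(c("kt_hif", "kd_hif") %in% sh$parameter))
  expect_equal(sum(sh$share), 1, tolerance = 1e-9)
})

test_that("re-equilibration scan: unit multiplier reproduces baseline", {
  pr <- protocol(2, 720, output_every_min = 60)
  sc <- scan_with_reequilibration(canonical, "kf_hif_import",
                                  c(1), pr,
                                  readouts = "total_hif1a")
  base <- run_protocol(canonical, pr)
  expect_equal(as.numeric(sc$traces[["1"]][, "total_hif1a"]),
               as.numeric(relative_expression(base, "total_hif1a")),
               tolerance = 1e-8)
})

test_that("faster nuclear import builds more HIF-1 complex", {
  pr <- protocol(2, 720, output_every_min = 60)
  sc <- scan_with_reequilibration(canonical, "kf_hif_import",
                                  c(0.5, 1, 2), pr,
                                  readouts = "hif1_complex")
  ## absolute HIF-1 complex at the end of the window increases with the
  ## import rate (relative traces share each multiplier's own baseline,
  ## so compare absolute levels from the stored re-equilibrated states)
  lvl <- vapply(c("0.5", "1", "2"), function(k) {
    tr <- sc$traces[[k]][, "hif1_complex"]
    st <- sc$states[[k]][["HIF1"]]
    unname(tr[length(tr)] * st)
  }, 0)
  expect_true(all(diff(lvl) > 0))
})

test_that("stronger let-7/AGO1 association lowers normoxic AGO1", {
  sc <- scan_with_reequilibration(canonical, "kf_ago1_let7", c(1, 5),
                                  protocol(2, 60, output_every_min = 60),
                                  readouts = "total_ago1")
  ago_base <- sum(sc$states[["1"]][c("AGO1", "let7_AGO1", "let7_AGO1_N",
                                     "miR15a_AGO1")])
  ago_x5 <- sum(sc$states[["5"]][c("AGO1", "let7_AGO1", "let7_AGO1_N",
                                   "miR15a_AGO1")])
  expect_lt(ago_x5, ago_base)
})
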