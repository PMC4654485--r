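test_that("oxygen and copy-number unit conversions match their anchors", {
  expect_equal(o2_percent_to_concentration(21), 209)
  expect_equal(o2_percent_to_concentration(2), 19.9)
  expect_equal(o2_percent_to_concentration(0), 0)
  expect_error(o2_percent_to_concentration(-1), "0, 21")
  expect_error(o2_percent_to_concentration(22), "0, 21")
  ## linear and invertible on [0, 21]
  pct <- seq(0, 21, by = 1.5)
  conc <- o2_percent_to_concentration(pct, signif_digits = NULL)
  expect_equal(conc, 209 * pct / 21)
  expect_equal(conc * 21 / 209, pct)

  expect_equal(copies_to_concentration(0), 0)
  expect_equal(copies_to_concentration(602214), 1, tolerance = 1e-6)
  expect_equal(copies_to_concentration(1e4), 1.661e-2, tolerance = 1e-3)
  expect_error(copies_to_concentration(10, volume_pL = 0), "volume")
  expect_error(copies_to_concentration(-1), ">= 0")
})

test_that("the canonical instance has the published dimensions", {
  v <- validate_model(canonical)
  cnt <- attr(v, "counts")
  expect_equal(unname(cnt["species"]), 47)
  expect_equal(unname(cnt["reactions"]), 57)
  expect_equal(unname(cnt["parameters"]), 91)
  expect_equal(nrow(v), 0)
  expect_setequal(canonical$compartments$id, c("cytoplasm", "nucleus"))
  ## every reaction belongs to exactly one functional group
  groups <- vapply(canonical$reactions, function(r) r$group, "")
  expect_true(all(groups %in% c("oxygen_sensing", "hif_transcription",
                                "let7_arm", "mir15a_vegf_arm",
                                "turnover", "perturbation")))
})

test_that("miR decay asymmetry and p-body asymmetry hold structurally", {
  p <- param_values(canonical)
  ## free miRs decay faster than RISC-bound miRs
  expect_gt(p[["kd_let7_free"]], p[["kd_let7_bound"]])
  expect_gt(p[["kd_mir15a_free"]], p[["kd_mir15a_bound"]])
  ## p-body mRNA decays slower than the free cytoplasmic form, and the
  ## exit rate is small
  expect_lt(p[["kd_ago1_pb"]], p[["kd_ago1_mrna"]])
  expect_lt(p[["kd_dicer_pb"]], p[["kd_dicer_mrna"]])
  expect_lt(p[["kd_vegf_pb"]], p[["kd_vegf_mrna"]])
  expect_lt(p[["kr_ago1_pb"]], p[["kd_ago1_mrna"]])
})

test_that("pre-miR-15a production is oxygen independent", {
  f <- attr(assemble_rhs(canonical), "flux")
  p <- param_values(canonical)
  j <- which(vapply(canonical$reactions, function(r) r$id, "") == "v38")
  y21 <- initial_state(canonical)
  y21[["O2"]] <- o2_percent_to_concentration(21)
  y1 <- y21
  y1[["O2"]] <- o2_percent_to_concentration(1)
  expect_identical(f(y21, p)[j], f(y1, p)[j])
})

test_that("severed HIF-driven transcription leaves let-7 and TTP basal", {
  m <- set_params(canonical, c(Vm_ttp = 1e-30, Vm_let7 = 1e-30,
                               Vm_vegf = 1e-30))
  tc <- run_protocol(m, protocol(2, 1440, output_every_min = 30))
  let7 <- relative_expression(tc, "total_let7")
  ttp_tr <- species_trace(tc, "TTP")[, 1]
  expect_lt(max(abs(let7 - 1)), 0.25)
  ## TTP has no basal transcription, so severing HIF drive leaves it at
  ## trace levels (canonical normoxic TTP is ~1e-2 uM)
  expect_lt(max(ttp_tr), 1e-4)
})

test_that("without PHD2 and FIH, normoxic HIF-1a rises monotonically", {
  zero <- c(PHD2 = 0, FIH = 0, PHD2_Fe_DG = 0, FIH_Fe_DG = 0,
            PHD2_Fe_DG_O2 = 0, FIH_Fe_DG_O2 = 0)
  m <- set_initial(canonical, zero)
  init <- initial_state(m)
  tc <- run_protocol(m, protocol(21, 720, output_every_min = 30),
                     init = init)
  tot <- rowSums(species_trace(tc, c("HIF1A", "HIF1A_OH", "HIF1A_N",
                                     "HIF1")))
  ## hydroxylation was the only strong sink: HIF-1a climbs towards its
  ## synthesis/decay balance (TTP feedback only bites much later)
  expect_true(all(diff(tot) > 0))
  expect_gt(tot[length(tot)] / tot[1], 5)
})

test_that("perturbation grammar adjusts doses and respects Kd", {
  ## overexpression bumps the target mRNA initial condition
  pm <- apply_perturbations(canonical, perturbation(
    "mrna_overexpression", "AGO1_mRNA", 0.04))
  expect_equal(initial_state(pm)[["AGO1_mRNA"]],
               initial_state(canonical)[["AGO1_mRNA"]] + 0.04)
  ## mimics feed the precursor pool
  pm2 <- apply_perturbations(canonical, perturbation(
    "mir_mimic", "miR15a", 0.01))
  expect_equal(initial_state(pm2)[["pre_miR15a"]],
               initial_state(canonical)[["pre_miR15a"]] + 0.01)
  ## siRNA Kd is honoured through the off-rate
  pm3 <- apply_perturbations(canonical, perturbation(
    "sirna_silencing", "TTP_mRNA", 0.002, kd_uM = 1e-3))
  p3 <- param_values(pm3)
  expect_equal(p3[["kr_si_ttp"]] / p3[["kf_si_ttp"]], 1e-3)
  ## unknown targets error
  expect_error(apply_perturbations(canonical, perturbation(
    "mrna_overexpression", "NOPE_mRNA", 0.01)), "unknown")
  ## silencing a target without built-in machinery appends a pair
  pm4 <- apply_perturbations(canonical, perturbation(
    "sirna_silencing", "Dicer_mRNA", 0.001))
  expect_true("agent_Dicer_mRNA" %in% pm4$species$id)
  expect_equal(length(pm4$reactions), 58)
})

test_that("zero-dose perturbations reproduce the untreated trajectory", {
  pr0 <- protocol(2, 360, output_every_min = 30)
  base <- run_protocol(canonical, pr0)
  for (pt in list(
    perturbation("sirna_silencing", "TTP_mRNA", 0),
    perturbation("mir_antagonist", "let7_AGO1", 0),
    perturbation("mrna_overexpression", "AGO1_mRNA", 0),
    perturbation("mir_mimic", "miR15a", 0),
    perturbation("cocl2", "CoCl2", 0))) {
    tc <- run_protocol(canonical, protocol(2, 360, list(pt),
                                           output_every_min = 30))
    expect_identical(tc$conc[, colnames(base$conc)], base$conc)
  }
})

test_that("CoCl2 stabilises HIF-1a and induces VEGF in normoxia", {
  tc <- run_protocol(canonical,
                     protocol(21, 1440, perturbation("cocl2", "CoCl2",
                                                     200),
                              output_every_min = 30))
  hif <- relative_expression(tc, "total_hif1a")
  veg <- relative_expression(tc, "vegf_protein")
  expect_gt(hif[length(hif)], 1.5)
  expect_gt(veg[length(veg)], 1.5)
})
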