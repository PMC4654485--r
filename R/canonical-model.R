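## The canonical HIF--let-7--AGO1--VEGF network: 47 species, 57 reactions,
## 91 kinetic parameters across a cytoplasmic and a nuclear compartment.
## Reversible binding/transport steps are single reactions carrying a
## forward and a reverse constant; 47 reactions are pure mass action and 10
## use saturating (Michaelis-Menten / Hill) kinetics.
##
## Parameter values marked "fitted" were obtained by calibrating the
## network against the quantitative anchors used to validate it (relative
## VEGF induction at 24 h in 2% O2 and at 8 h in 1% O2, the timing of the
## HIF-1a overshoot, and the relative AGO1 decline in hypoxia), starting
## from class-median priors (see default_priors()).  No reference parameter
## listing ships with this package: the registry below is the package's own
## calibrated instance, and fit provenance is recorded per parameter.

.canonical_species <- function() {
  cyt <- "cytoplasm"; nuc <- "nucleus"
  rbind(
    ## -- oxygen sensing -------------------------------------------------
    species_def("O2",            cyt, "small_molecule", 209,   "dissolved O2"),
    species_def("HIF1A_mRNA",    cyt, "mRNA",   2.25883e-05, "HIF-1a mRNA"),
    species_def("HIF1A",         cyt, "protein", 3.80246e-06,  "HIF-1a (cytoplasm)"),
    species_def("PHD2",          cyt, "protein", 0.00134959,   "PHD2 (apo)"),
    species_def("FIH",           cyt, "protein", 0.000539837,   "FIH (apo)"),
    species_def("Fe",            cyt, "small_molecule", 48.6019,  "Fe(II)"),
    species_def("DG",            cyt, "small_molecule", 248.602, "2-oxoglutarate"),
    species_def("PHD2_Fe_DG",    cyt, "complex", 0.655928, "PHD2:Fe:2OG"),
    species_def("FIH_Fe_DG",     cyt, "complex", 0.262371, "FIH:Fe:2OG"),
    species_def("PHD2_Fe_DG_O2", cyt, "complex", 0.342722, "PHD2:Fe:2OG:O2"),
    species_def("FIH_Fe_DG_O2",  cyt, "complex", 0.137089, "FIH:Fe:2OG:O2"),
    species_def("HIF1A_OH",      cyt, "protein", 6.77685e-07, "hydroxylated HIF-1a"),
    species_def("VHL",           cyt, "protein", 1, "pVHL"),
    ## -- HIF-dependent transcription ------------------------------------
    species_def("HIF1A_N",  nuc, "protein", 7.60493e-06,  "HIF-1a N"),
    species_def("HIF1B",    nuc, "protein", 0.169948,  "HIF-1b N"),
    species_def("HIF1",     nuc, "complex", 0.000152052,  "HIF-1 complex N"),
    species_def("TTP_mRNA", cyt, "mRNA",    6.03462e-06,  "TTP mRNA"),
    species_def("TTP",      cyt, "protein", 0.0120692,  "TTP"),
    ## -- let-7 biogenesis and targeting ---------------------------------
    species_def("pri_let7",     nuc, "miR_precursor", 9.86207e-07, "pri-let-7 N"),
    species_def("pre_let7",     cyt, "miR_precursor", 1.97732e-06, "pre-let-7"),
    species_def("let7",         cyt, "miR_mature", 5.47653e-05, "let-7 (free)"),
    species_def("AGO1_mRNA",    cyt, "mRNA", 3.79676e-05, "AGO1 mRNA (free)"),
    species_def("AGO1_mRNA_PB", cyt, "mRNA", 0.000464389,  "AGO1 mRNA (p-body)"),
    species_def("AGO1",         cyt, "protein", 0.113903, "AGO1 (free)"),
    species_def("let7_AGO1",    cyt, "complex", 0.00030578, "let-7:AGO1 RISC"),
    species_def("let7_AGO1_N",  nuc, "complex", 0.000611561, "let-7:AGO1 N"),
    species_def("Dicer_mRNA",   cyt, "mRNA", 3.79676e-05, "Dicer mRNA (free)"),
    species_def("Dicer_mRNA_PB", cyt, "mRNA", 0.000464389, "Dicer mRNA (p-body)"),
    species_def("Dicer",        cyt, "protein", 0.113903, "Dicer"),
    ## -- miR-15a / VEGF arm ----------------------------------------------
    species_def("pre_miR15a",     cyt, "miR_precursor", 0.000197684, "pre-miR-15a"),
    species_def("miR15a",         cyt, "miR_mature", 4.98053e-05, "miR-15a (free)"),
    species_def("miR15a_AGO1",    cyt, "complex", 7.78642e-05, "miR-15a:AGO1 RISC"),
    species_def("VEGF_mRNA",      cyt, "mRNA", 4.02669e-07, "VEGF mRNA (free)"),
    species_def("VEGF_mRNA_RISC", cyt, "complex", 8.21164e-07,
                "VEGF mRNA:miR-15a RISC"),
    species_def("VEGF_mRNA_PB",   cyt, "mRNA", 3.28465e-05, "VEGF mRNA (p-body)"),
    species_def("VEGF",           cyt, "protein", 0.00069029, "VEGF"),
    ## -- perturbants (dormant at zero dose) ------------------------------
    species_def("CoCl2",          cyt, "perturbant", 0, "CoCl2"),
    species_def("CoCl2_PHD2_c",   cyt, "complex", 0, "CoCl2:PHD2:Fe:2OG"),
    species_def("CoCl2_FIH_c",    cyt, "complex", 0, "CoCl2:FIH:Fe:2OG"),
    species_def("siRNA_TTP",      cyt, "perturbant", 0, "siRNA vs TTP mRNA"),
    species_def("siRNA_TTP_c",    cyt, "complex", 0, "siRNA:TTP mRNA"),
    species_def("siRNA_AGO1",     cyt, "perturbant", 0, "siRNA vs AGO1 mRNA"),
    species_def("siRNA_AGO1_c",   cyt, "complex", 0, "siRNA:AGO1 mRNA"),
    species_def("anti_let7",      cyt, "perturbant", 0, "let-7 antagonist"),
    species_def("anti_let7_c",    cyt, "complex", 0, "antagonist:let-7 RISC"),
    species_def("anti_miR15a",    cyt, "perturbant", 0, "miR-15a antagonist"),
    species_def("anti_miR15a_c",  cyt, "complex", 0,
                "antagonist:miR-15a RISC")
  )
}

## id, value, units, provenance.  Second-order constants are uM^-1 min^-1,
## first-order min^-1, zero-order and Vm uM min^-1, K constants uM.
.canonical_parameter_table <- function() {
  p <- function(id, value, units, prov = "fitted") {
    data.frame(id = id, value = value, units = units, provenance = prov,
               stringsAsFactors = FALSE)
  }
  rbind(
    ## oxygen sensing
    p("kp_hif_mrna",     3.4e-8, "uM/min", "default_median"),
    p("kd_hif_mrna",     1.2e-3, "1/min",  "default_median"),
    p("kcat_ttp_hif",    3.1e-6,   "1/min"),
    p("Km_ttp_hif",      1e-4,   "uM"),
    p("kt_hif",          3,      "1/min",  "default_median"),
    p("kd_hif",          2.5e-4, "1/min",  "default_median"),
    p("kf_phd2_fedg",    0.1,    "1/(uM*min)"),
    p("kr_phd2_fedg",    0.01,   "1/min"),
    p("kf_fih_fedg",     0.1,    "1/(uM*min)"),
    p("kr_fih_fedg",     0.01,   "1/min"),
    p("kf_phd2_o2",      2e-3,   "1/(uM*min)"),
    p("kr_phd2_o2",      0.8,    "1/min"),
    p("kf_fih_o2",       2e-3,   "1/(uM*min)"),
    p("kr_fih_o2",       0.8,    "1/min"),
    p("kcat_hydrox_phd2", 4,    "1/min"),
    p("Km_hydrox_phd2",  0.1,    "uM"),
    p("kf_hydrox_fih",   30,     "1/(uM*min)"),
    p("kcat_vhl",        1,      "1/min"),
    p("Km_vhl",          0.01,   "uM"),
    ## nuclear transport, dimerisation, TTP
    p("kf_hif_import",   0.4,   "1/min"),
    p("kr_hif_export",   0.2,   "1/min"),
    p("kf_hif_dimer",    10,     "1/(uM*min)"),
    p("kr_hif_dimer",    0.085,   "1/min"),
    p("Vm_ttp",          6e-8,   "uM/min"),
    p("Km_ttp",          6e-4,   "uM"),
    p("n_ttp",           2,      "-"),
    p("kd_ttp_mrna",     6e-4, "1/min", "default_median"),
    p("kt_ttp",          3,      "1/min", "default_median"),
    p("kd_ttp",          1.5e-3, "1/min"),
    ## let-7 arm
    p("k0_let7",         1e-7,   "uM/min"),
    p("Vm_let7",         1.7e-5,   "uM/min"),
    p("kp21",            6e-4,   "uM"),
    p("n_let7",          2,      "-"),
    p("Vm_drosha",       1e-4,   "uM/min"),
    p("Km_drosha",       1e-4,   "uM"),
    p("kf_drosha_fb",    0.025,      "1/min"),
    p("kcat_dicer_let7", 0.05,    "1/min"),
    p("Km_dicer_let7",   0.01,   "uM"),
    p("kd_let7_free",    0.02,   "1/min"),
    p("kd_let7_bound",   1e-4,   "1/min", "default_median"),
    p("kf_ago1_let7",    0.25,     "1/(uM*min)"),
    p("kr_ago1_let7",    5e-3,   "1/min"),
    p("kf_risc_import",  0.01,   "1/min"),
    p("kr_risc_export",  5e-3,   "1/min"),
    p("kp_ago1_mrna",    9.2e-8, "uM/min", "default_median"),
    p("kd_ago1_mrna",    1.2e-3, "1/min",  "default_median"),
    p("kt_ago1",         3,      "1/min",  "default_median"),
    p("kd_ago1",         1e-3,   "1/min"),
    p("kf_ago1_pb",      8,     "1/(uM*min)"),
    p("kr_ago1_pb",      1e-4,   "1/min"),
    p("kd_ago1_pb",      1e-4,   "1/min"),
    p("kp_dicer_mrna",   9.2e-8, "uM/min", "default_median"),
    p("kd_dicer_mrna",   1.2e-3, "1/min",  "default_median"),
    p("kt_dicer",        3,      "1/min",  "default_median"),
    p("kd_dicer",        1e-3,   "1/min"),
    p("kf_dicer_pb",     8,     "1/(uM*min)"),
    p("kr_dicer_pb",     1e-4,   "1/min"),
    p("kd_dicer_pb",     1e-4,   "1/min"),
    ## miR-15a / VEGF arm
    p("kp_mir15a",       2e-6,   "uM/min"),
    p("kcat_dicer_mir15a", 2.2e-5,  "1/min"),
    p("Km_dicer_mir15a", 5e-5,   "uM"),
    p("kd_mir15a_free",  0.04,   "1/min"),
    p("kd_mir15a_bound", 1e-4,   "1/min", "default_median"),
    p("kf_ago1_mir15a",  0.07,     "1/(uM*min)"),
    p("kr_ago1_mir15a",  5e-3,   "1/min"),
    p("k0_vegf",         7.5e-9,   "uM/min"),
    p("Vm_vegf",         3e-8,   "uM/min"),
    p("Km_vegf",         3e-4,   "uM"),
    p("n_vegf",          2,      "-"),
    p("kd_vegf_mrna",    1.2e-3, "1/min", "default_median"),
    p("kcat_ttp_vegf",   2e-7,   "1/min"),
    p("Km_ttp_vegf",     1e-4,   "uM"),
    p("kf_vegf_risc",    550,    "1/(uM*min)"),
    p("kr_vegf_risc",    1e-3,   "1/min"),
    p("kf_vegf_pb",      0.02,   "1/min"),
    p("kr_vegf_pb",      1e-4,   "1/min"),
    p("kd_vegf_pb",      4e-4,   "1/min"),
    p("kt_vegf",         3,      "1/min", "default_median"),
    p("kd_vegf",         1.75e-3,   "1/min"),
    ## perturbant binding
    p("kf_si_ttp",       10,     "1/(uM*min)", "user"),
    p("kr_si_ttp",       0.01,   "1/min",      "user"),
    p("kf_si_ago1",      10,     "1/(uM*min)", "user"),
    p("kr_si_ago1",      0.01,   "1/min",      "user"),
    p("kf_anti_let7",    10,     "1/(uM*min)", "user"),
    p("kr_anti_let7",    1e-4,   "1/min",      "user"),
    p("kf_anti_mir15a",  10,     "1/(uM*min)", "user"),
    p("kr_anti_mir15a",  1e-4,   "1/min",      "user"),
    p("kf_cocl2_phd2",   0.05,   "1/(uM*min)", "user"),
    p("kr_cocl2_phd2",   0.01,   "1/min",      "user"),
    p("kf_cocl2_fih",    0.05,   "1/(uM*min)", "user"),
    p("kr_cocl2_fih",    0.01,   "1/min",      "user")
  )
}

.canonical_reactions <- function() {
  ma1 <- function(k, sp = character()) {
    rate_law("mass_action_1", c(k = k), species = sp)
  }
  ma2 <- function(k, sp) rate_law("mass_action_2", c(k = k), species = sp)
  rev <- function(kf, kr, fwd, back) {
    rate_law("mass_action_rev", c(kf = kf, kr = kr), species = fwd,
             reverse_species = back)
  }
  list(
    ## ---- oxygen sensing / HIF-1a stabilisation (v1-v12) ---------------
    reaction("v1", products = c(HIF1A_mRNA = 1),
             rate = ma1("kp_hif_mrna"),
             description = "basal HIF-1a transcription",
             group = "oxygen_sensing"),
    reaction("v2", reactants = c(HIF1A_mRNA = 1),
             rate = ma1("kd_hif_mrna", "HIF1A_mRNA"),
             description = "HIF-1a mRNA basal decay",
             group = "oxygen_sensing"),
    reaction("v3", reactants = c(HIF1A_mRNA = 1), modifiers = "TTP",
             rate = rate_law("michaelis_menten",
                             c(kcat = "kcat_ttp_hif", Km = "Km_ttp_hif"),
                             species = "HIF1A_mRNA", enzyme = "TTP"),
             description = "TTP-mediated HIF-1a mRNA destabilisation",
             group = "oxygen_sensing"),
    reaction("v4", products = c(HIF1A = 1), modifiers = "HIF1A_mRNA",
             rate = ma1("kt_hif", "HIF1A_mRNA"),
             description = "HIF-1a translation",
             group = "oxygen_sensing"),
    reaction("v5", reactants = c(HIF1A = 1),
             rate = ma1("kd_hif", "HIF1A"),
             description = "HIF-1a basal (hydroxylation-independent) decay",
             group = "oxygen_sensing"),
    reaction("v6", reactants = c(PHD2 = 1, Fe = 1, DG = 1),
             products = c(PHD2_Fe_DG = 1),
             rate = rev("kf_phd2_fedg", "kr_phd2_fedg",
                        c("PHD2", "Fe"), "PHD2_Fe_DG"),
             description = "PHD2 + Fe + 2-OG holoenzyme assembly",
             group = "oxygen_sensing"),
    reaction("v7", reactants = c(FIH = 1, Fe = 1, DG = 1),
             products = c(FIH_Fe_DG = 1),
             rate = rev("kf_fih_fedg", "kr_fih_fedg",
                        c("FIH", "Fe"), "FIH_Fe_DG"),
             description = "FIH + Fe + 2-OG holoenzyme assembly",
             group = "oxygen_sensing"),
    reaction("v8", reactants = c(PHD2_Fe_DG = 1, O2 = 1),
             products = c(PHD2_Fe_DG_O2 = 1),
             rate = rev("kf_phd2_o2", "kr_phd2_o2",
                        c("PHD2_Fe_DG", "O2"), "PHD2_Fe_DG_O2"),
             description = "O2 loading of PHD2 holoenzyme",
             group = "oxygen_sensing"),
    reaction("v9", reactants = c(FIH_Fe_DG = 1, O2 = 1),
             products = c(FIH_Fe_DG_O2 = 1),
             rate = rev("kf_fih_o2", "kr_fih_o2",
                        c("FIH_Fe_DG", "O2"), "FIH_Fe_DG_O2"),
             description = "O2 loading of FIH holoenzyme",
             group = "oxygen_sensing"),
    reaction("v10", reactants = c(HIF1A = 1), products = c(HIF1A_OH = 1),
             modifiers = "PHD2_Fe_DG_O2",
             rate = rate_law("michaelis_menten",
                             c(kcat = "kcat_hydrox_phd2",
                               Km = "Km_hydrox_phd2"),
                             species = "HIF1A", enzyme = "PHD2_Fe_DG_O2"),
             description = "PHD2-mediated HIF-1a hydroxylation",
             group = "oxygen_sensing"),
    reaction("v11", reactants = c(HIF1A = 1), products = c(HIF1A_OH = 1),
             modifiers = "FIH_Fe_DG_O2",
             rate = ma2("kf_hydrox_fih", c("HIF1A", "FIH_Fe_DG_O2")),
             description = "FIH-mediated HIF-1a hydroxylation",
             group = "oxygen_sensing"),
    reaction("v12", reactants = c(HIF1A_OH = 1), modifiers = "VHL",
             rate = rate_law("michaelis_menten",
                             c(kcat = "kcat_vhl", Km = "Km_vhl"),
                             species = "HIF1A_OH", enzyme = "VHL"),
             description = "pVHL-mediated degradation of hydroxylated HIF-1a",
             group = "oxygen_sensing"),
    ## ---- nuclear transport, HIF-1 complex, TTP (v13-v18) ---------------
    reaction("v13", reactants = c(HIF1A = 1), products = c(HIF1A_N = 1),
             rate = rev("kf_hif_import", "kr_hif_export",
                        "HIF1A", "HIF1A_N"),
             description = "HIF-1a nucleocytoplasmic shuttling",
             group = "hif_transcription"),
    reaction("v14", reactants = c(HIF1A_N = 1, HIF1B = 1),
             products = c(HIF1 = 1),
             rate = rev("kf_hif_dimer", "kr_hif_dimer",
                        c("HIF1A_N", "HIF1B"), "HIF1"),
             description = "HIF-1a/HIF-1b dimerisation (CBP/p300 included)",
             group = "hif_transcription"),
    reaction("v15", products = c(TTP_mRNA = 1), modifiers = "HIF1",
             rate = rate_law("hill_activation",
                             c(Vm = "Vm_ttp", K = "Km_ttp", n = "n_ttp"),
                             species = "HIF1"),
             description = "HIF-dependent TTP transcription",
             group = "hif_transcription"),
    reaction("v16", reactants = c(TTP_mRNA = 1),
             rate = ma1("kd_ttp_mrna", "TTP_mRNA"),
             description = "TTP mRNA decay", group = "hif_transcription"),
    reaction("v17", products = c(TTP = 1), modifiers = "TTP_mRNA",
             rate = ma1("kt_ttp", "TTP_mRNA"),
             description = "TTP translation", group = "hif_transcription"),
    reaction("v18", reactants = c(TTP = 1), rate = ma1("kd_ttp", "TTP"),
             description = "TTP decay", group = "hif_transcription"),
    ## ---- let-7 biogenesis and targeting (v19-v37) ----------------------
    reaction("v19", products = c(pri_let7 = 1), modifiers = "HIF1",
             rate = rate_law("hill_activation",
                             c(Vm = "Vm_let7", K = "kp21", n = "n_let7",
                               k0 = "k0_let7"),
                             species = "HIF1"),
             description = "HIF-dependent pri-let-7 transcription",
             group = "let7_arm"),
    reaction("v20", reactants = c(pri_let7 = 1), products = c(pre_let7 = 1),
             modifiers = "let7_AGO1_N",
             rate = rate_law("michaelis_menten",
                             c(Vm = "Vm_drosha", Km = "Km_drosha",
                               kact = "kf_drosha_fb"),
                             species = "pri_let7",
                             activator = "let7_AGO1_N"),
             description = paste("combined Drosha processing + XPO-5 export,",
                                 "stimulated by nuclear let-7:AGO1"),
             group = "let7_arm"),
    reaction("v21", reactants = c(pre_let7 = 1), products = c(let7 = 1),
             modifiers = "Dicer",
             rate = rate_law("michaelis_menten",
                             c(kcat = "kcat_dicer_let7",
                               Km = "Km_dicer_let7"),
                             species = "pre_let7", enzyme = "Dicer"),
             description = "Dicer maturation of pre-let-7",
             group = "let7_arm"),
    reaction("v22", reactants = c(let7 = 1),
             rate = ma1("kd_let7_free", "let7"),
             description = "free let-7 decay (fast)", group = "let7_arm"),
    reaction("v23", reactants = c(let7 = 1, AGO1 = 1),
             products = c(let7_AGO1 = 1),
             rate = rev("kf_ago1_let7", "kr_ago1_let7",
                        c("let7", "AGO1"), "let7_AGO1"),
             description = "reversible let-7:AGO1 RISC formation",
             group = "let7_arm"),
    reaction("v24", reactants = c(let7_AGO1 = 1), products = c(AGO1 = 1),
             rate = ma1("kd_let7_bound", "let7_AGO1"),
             description = "bound let-7 turnover (slow); AGO1 recycled",
             group = "let7_arm"),
    reaction("v25", reactants = c(let7_AGO1 = 1),
             products = c(let7_AGO1_N = 1),
             rate = rev("kf_risc_import", "kr_risc_export",
                        "let7_AGO1", "let7_AGO1_N"),
             description = "let-7:AGO1 nucleocytoplasmic shuttling",
             group = "let7_arm"),
    reaction("v26", products = c(AGO1_mRNA = 1),
             rate = ma1("kp_ago1_mrna"),
             description = "AGO1 transcription", group = "let7_arm"),
    reaction("v27", reactants = c(AGO1_mRNA = 1),
             rate = ma1("kd_ago1_mrna", "AGO1_mRNA"),
             description = "free AGO1 mRNA decay", group = "let7_arm"),
    reaction("v28", products = c(AGO1 = 1), modifiers = "AGO1_mRNA",
             rate = ma1("kt_ago1", "AGO1_mRNA"),
             description = "AGO1 translation", group = "let7_arm"),
    reaction("v29", reactants = c(AGO1 = 1), rate = ma1("kd_ago1", "AGO1"),
             description = "free AGO1 decay", group = "let7_arm"),
    reaction("v30", reactants = c(AGO1_mRNA = 1),
             products = c(AGO1_mRNA_PB = 1), modifiers = "let7_AGO1",
             rate = rev("kf_ago1_pb", "kr_ago1_pb",
                        c("AGO1_mRNA", "let7_AGO1"), "AGO1_mRNA_PB"),
             description = paste("let-7-RISC routing of AGO1 mRNA to",
                                 "p-bodies (small exit flux back)"),
             group = "let7_arm"),
    reaction("v31", reactants = c(AGO1_mRNA_PB = 1),
             rate = ma1("kd_ago1_pb", "AGO1_mRNA_PB"),
             description = "p-body AGO1 mRNA decay (slow)",
             group = "let7_arm"),
    reaction("v32", products = c(Dicer_mRNA = 1),
             rate = ma1("kp_dicer_mrna"),
             description = "Dicer transcription", group = "let7_arm"),
    reaction("v33", reactants = c(Dicer_mRNA = 1),
             rate = ma1("kd_dicer_mrna", "Dicer_mRNA"),
             description = "free Dicer mRNA decay", group = "let7_arm"),
    reaction("v34", products = c(Dicer = 1), modifiers = "Dicer_mRNA",
             rate = ma1("kt_dicer", "Dicer_mRNA"),
             description = "Dicer translation", group = "let7_arm"),
    reaction("v35", reactants = c(Dicer = 1),
             rate = ma1("kd_dicer", "Dicer"),
             description = "Dicer decay", group = "let7_arm"),
    reaction("v36", reactants = c(Dicer_mRNA = 1),
             products = c(Dicer_mRNA_PB = 1), modifiers = "let7_AGO1",
             rate = rev("kf_dicer_pb", "kr_dicer_pb",
                        c("Dicer_mRNA", "let7_AGO1"), "Dicer_mRNA_PB"),
             description = "let-7-RISC routing of Dicer mRNA to p-bodies",
             group = "let7_arm"),
    reaction("v37", reactants = c(Dicer_mRNA_PB = 1),
             rate = ma1("kd_dicer_pb", "Dicer_mRNA_PB"),
             description = "p-body Dicer mRNA decay (slow)",
             group = "let7_arm"),
    ## ---- miR-15a / VEGF arm (v38-v51) ----------------------------------
    reaction("v38", products = c(pre_miR15a = 1),
             rate = ma1("kp_mir15a"),
             description = "constitutive (hypoxia-independent) pre-miR-15a production",
             group = "mir15a_vegf_arm"),
    reaction("v39", reactants = c(pre_miR15a = 1), products = c(miR15a = 1),
             modifiers = "Dicer",
             rate = rate_law("michaelis_menten",
                             c(kcat = "kcat_dicer_mir15a",
                               Km = "Km_dicer_mir15a"),
                             species = "pre_miR15a", enzyme = "Dicer"),
             description = "Dicer maturation of pre-miR-15a",
             group = "mir15a_vegf_arm"),
    reaction("v40", reactants = c(miR15a = 1),
             rate = ma1("kd_mir15a_free", "miR15a"),
             description = "free miR-15a decay (fast)",
             group = "mir15a_vegf_arm"),
    reaction("v41", reactants = c(miR15a = 1, AGO1 = 1),
             products = c(miR15a_AGO1 = 1),
             rate = rev("kf_ago1_mir15a", "kr_ago1_mir15a",
                        c("miR15a", "AGO1"), "miR15a_AGO1"),
             description = "reversible miR-15a:AGO1 RISC formation",
             group = "mir15a_vegf_arm"),
    reaction("v42", reactants = c(miR15a_AGO1 = 1), products = c(AGO1 = 1),
             rate = ma1("kd_mir15a_bound", "miR15a_AGO1"),
             description = "bound miR-15a turnover (slow); AGO1 recycled",
             group = "mir15a_vegf_arm"),
    reaction("v43", products = c(VEGF_mRNA = 1), modifiers = "HIF1",
             rate = rate_law("hill_activation",
                             c(Vm = "Vm_vegf", K = "Km_vegf", n = "n_vegf",
                               k0 = "k0_vegf"),
                             species = "HIF1"),
             description = "HIF-dependent VEGF transcription (with basal)",
             group = "mir15a_vegf_arm"),
    reaction("v44", reactants = c(VEGF_mRNA = 1),
             rate = ma1("kd_vegf_mrna", "VEGF_mRNA"),
             description = "free VEGF mRNA decay",
             group = "mir15a_vegf_arm"),
    reaction("v45", reactants = c(VEGF_mRNA = 1), modifiers = "TTP",
             rate = rate_law("michaelis_menten",
                             c(kcat = "kcat_ttp_vegf", Km = "Km_ttp_vegf"),
                             species = "VEGF_mRNA", enzyme = "TTP"),
             description = "TTP-mediated VEGF mRNA destabilisation",
             group = "mir15a_vegf_arm"),
    reaction("v46", reactants = c(VEGF_mRNA = 1, miR15a_AGO1 = 1),
             products = c(VEGF_mRNA_RISC = 1),
             rate = rev("kf_vegf_risc", "kr_vegf_risc",
                        c("VEGF_mRNA", "miR15a_AGO1"), "VEGF_mRNA_RISC"),
             description = "miR-15a RISC capture of VEGF mRNA",
             group = "mir15a_vegf_arm"),
    reaction("v47", reactants = c(VEGF_mRNA_RISC = 1),
             products = c(VEGF_mRNA_PB = 1, miR15a_AGO1 = 1),
             rate = ma1("kf_vegf_pb", "VEGF_mRNA_RISC"),
             description = "p-body deposition of RISC-bound VEGF mRNA",
             group = "mir15a_vegf_arm"),
    reaction("v48", reactants = c(VEGF_mRNA_PB = 1),
             products = c(VEGF_mRNA = 1),
             rate = ma1("kr_vegf_pb", "VEGF_mRNA_PB"),
             description = "p-body exit of VEGF mRNA (small flux)",
             group = "mir15a_vegf_arm"),
    reaction("v49", reactants = c(VEGF_mRNA_PB = 1),
             rate = ma1("kd_vegf_pb", "VEGF_mRNA_PB"),
             description = "p-body VEGF mRNA decay (slow)",
             group = "mir15a_vegf_arm"),
    reaction("v50", products = c(VEGF = 1), modifiers = "VEGF_mRNA",
             rate = ma1("kt_vegf", "VEGF_mRNA"),
             description = "VEGF translation (free mRNA only)",
             group = "mir15a_vegf_arm"),
    reaction("v51", reactants = c(VEGF = 1), rate = ma1("kd_vegf", "VEGF"),
             description = "VEGF decay", group = "mir15a_vegf_arm"),
    ## ---- perturbant binding (v52-v57; zero flux at zero dose) ----------
    reaction("v52", reactants = c(siRNA_TTP = 1, TTP_mRNA = 1),
             products = c(siRNA_TTP_c = 1),
             rate = rev("kf_si_ttp", "kr_si_ttp",
                        c("siRNA_TTP", "TTP_mRNA"), "siRNA_TTP_c"),
             description = "siRNA sequestration of TTP mRNA (Kd 1e-3 uM)",
             group = "perturbation"),
    reaction("v53", reactants = c(siRNA_AGO1 = 1, AGO1_mRNA = 1),
             products = c(siRNA_AGO1_c = 1),
             rate = rev("kf_si_ago1", "kr_si_ago1",
                        c("siRNA_AGO1", "AGO1_mRNA"), "siRNA_AGO1_c"),
             description = "siRNA sequestration of AGO1 mRNA (Kd 1e-3 uM)",
             group = "perturbation"),
    reaction("v54", reactants = c(anti_let7 = 1, let7_AGO1 = 1),
             products = c(anti_let7_c = 1, AGO1 = 1),
             rate = rev("kf_anti_let7", "kr_anti_let7",
                        c("anti_let7", "let7_AGO1"),
                        c("anti_let7_c", "AGO1")),
             description = paste("antagonist inactivation of let-7 RISC",
                                 "(AGO1 released)"),
             group = "perturbation"),
    reaction("v55", reactants = c(anti_miR15a = 1, miR15a_AGO1 = 1),
             products = c(anti_miR15a_c = 1, AGO1 = 1),
             rate = rev("kf_anti_mir15a", "kr_anti_mir15a",
                        c("anti_miR15a", "miR15a_AGO1"),
                        c("anti_miR15a_c", "AGO1")),
             description = paste("antagonist inactivation of miR-15a RISC",
                                 "(AGO1 released)"),
             group = "perturbation"),
    reaction("v56", reactants = c(CoCl2 = 1, PHD2_Fe_DG = 1),
             products = c(CoCl2_PHD2_c = 1),
             rate = rev("kf_cocl2_phd2", "kr_cocl2_phd2",
                        c("CoCl2", "PHD2_Fe_DG"), "CoCl2_PHD2_c"),
             description = "CoCl2 sequestration of PHD2 holoenzyme",
             group = "perturbation"),
    reaction("v57", reactants = c(CoCl2 = 1, FIH_Fe_DG = 1),
             products = c(CoCl2_FIH_c = 1),
             rate = rev("kf_cocl2_fih", "kr_cocl2_fih",
                        c("CoCl2", "FIH_Fe_DG"), "CoCl2_FIH_c"),
             description = "CoCl2 sequestration of FIH holoenzyme",
             group = "perturbation")
  )
}

#' Build the canonical HIF--let-7--AGO1--VEGF model
#'
#' Constructs the two-compartment endothelial-cell network: oxygen sensing
#' (PHD2/FIH holoenzyme assembly, O2 loading, HIF-1a hydroxylation and
#' pVHL-mediated degradation), reversible HIF-1a nuclear import and HIF-1
#' complex formation, HIF-driven transcription of TTP / pri-let-7 / VEGF,
#' TTP destabilisation of HIF-1a and VEGF mRNAs, let-7 biogenesis with the
#' nuclear let-7:AGO1 positive processing loop, AGO1/Dicer silencing into
#' p-bodies, constitutive miR-15a production, and miR-15a-RISC repression
#' of VEGF mRNA.  Dormant perturbant species (siRNAs, miR antagonists,
#' CoCl2) and their binding reactions are part of the canonical network and
#' carry zero initial concentration.
#'
#' Dissolved O2 is a clamped boundary species: protocols set its level and
#' the integrator holds it constant.
#'
#' @param params Optional named numeric vector of parameter overrides
#'   applied on top of the calibrated registry values.
#' @return A `hifmir_model` with 47 species, 57 reactions and 91
#'   parameters.
#' @export
#' @examples
#' m <- build_canonical_model()
#' attr(validate_model(m), "counts")
build_canonical_model <- function(params = NULL) {
  comps <- rbind(compartment("cytoplasm", "cytoplasm"),
                 compartment("nucleus", "nucleus"))
  m <- hifmir_model(compartments = comps,
                    species = .canonical_species(),
                    reactions = .canonical_reactions(),
                    parameters = .canonical_parameter_table(),
                    clamped = "O2",
                    name = "HIF-let7-AGO1-VEGF")
  if (!is.null(params)) m <- set_params(m, params)
  m
}
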