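## Small networks built in code, used across the suite.

## One species with zero-order synthesis and first-order decay:
## steady state = ks/kd.
toy_birth_death <- function(ks = 0.01, kd = 0.001) {
  hifmir_model(
    compartments = compartment("cytoplasm"),
    species = species_def("A", "cytoplasm", "protein", 0),
    reactions = list(
      reaction("syn", products = c(A = 1),
               rate = rate_law("mass_action_1", c(k = "ks"))),
      reaction("dec", reactants = c(A = 1),
               rate = rate_law("mass_action_1", c(k = "kd"),
                               species = "A"))),
    parameters = data.frame(id = c("ks", "kd"), value = c(ks, kd),
                            units = c("uM/min", "1/min"),
                            provenance = "user"),
    name = "birth-death")
}

## Pure first-order decay of A (no synthesis); A(0) = a0.
toy_decay <- function(k = 0.05, a0 = 2) {
  hifmir_model(
    compartments = compartment("cytoplasm"),
    species = species_def("A", "cytoplasm", "protein", a0),
    reactions = list(
      reaction("dec", reactants = c(A = 1),
               rate = rate_law("mass_action_1", c(k = "k"),
                               species = "A"))),
    parameters = data.frame(id = "k", value = k, units = "1/min",
                            provenance = "user"),
    name = "decay")
}

## Linear chain A -> B -> C with first-order steps (closed; matrix ODE).
toy_chain <- function(k1 = 0.2, k2 = 0.05, a0 = 1) {
  hifmir_model(
    compartments = compartment("cytoplasm"),
    species = rbind(species_def("A", "cytoplasm", "protein", a0),
                    species_def("B", "cytoplasm", "protein", 0),
                    species_def("C", "cytoplasm", "protein", 0)),
    reactions = list(
      reaction("r1", reactants = c(A = 1), products = c(B = 1),
               rate = rate_law("mass_action_1", c(k = "k1"),
                               species = "A")),
      reaction("r2", reactants = c(B = 1), products = c(C = 1),
               rate = rate_law("mass_action_1", c(k = "k2"),
                               species = "B"))),
    parameters = data.frame(id = c("k1", "k2"), value = c(k1, k2),
                            units = "1/min", provenance = "user"),
    name = "chain")
}

## Reversible binding A + B <-> C with no synthesis or decay: the pools
## A + C and B + C are conserved.
toy_binding <- function(kf = 5, kr = 0.1, a0 = 1, b0 = 0.6) {
  hifmir_model(
    compartments = compartment("cytoplasm"),
    species = rbind(species_def("A", "cytoplasm", "protein", a0),
                    species_def("B", "cytoplasm", "protein", b0),
                    species_def("C", "cytoplasm", "complex", 0)),
    reactions = list(
      reaction("bind", reactants = c(A = 1, B = 1), products = c(C = 1),
               rate = rate_law("mass_action_rev", c(kf = "kf", kr = "kr"),
                               species = c("A", "B"),
                               reverse_species = "C"))),
    parameters = data.frame(id = c("kf", "kr"), value = c(kf, kr),
                            units = c("1/(uM*min)", "1/min"),
                            provenance = "user"),
    name = "binding")
}

## The canonical model, shared across test files (building it is cheap;
## its normoxic steady state is memoised inside the package).
canonical <- build_canonical_model()

## Fabricate a minimal time-course object for readout arithmetic tests.
fake_timecourse <- function(time, conc, model = canonical) {
  structure(list(time = time, conc = conc, model = model,
                 protocol = protocol(21, max(time)),
                 baseline = conc[1, ]),
            class = "hifmir_timecourse")
}
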