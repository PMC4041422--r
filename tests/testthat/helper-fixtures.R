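# Shared fixtures: canonical rate constants and system builders used across
# the suite. All concentrations are final (post-mix), in uM.

frt_irp1 <- function(mn = 0) rate_lookup("FRT_IRP1", mn)
aco2_irp1 <- function(mn = 0) rate_lookup("ACO2_IRP1", mn)
frt_eif4f <- function(mn = 0) rate_lookup("FRT_eIF4F", mn)

one_protein_system <- function(rna = 0.05, protein = 1.0, rate = frt_irp1()) {
  binding_system(rna, binding_protein("P", protein, rate))
}

noiseless_trace <- function(rate = frt_irp1(), rna = 0.05, protein = 1.0,
                            kind = "anisotropy", ...) {
  sys <- one_protein_system(rna, protein, rate)
  generate_trace(sys, signal_model(kind, noise_sd = 0), ...)
}

# random one- or two-protein systems for property tests
random_system <- function(n_proteins = 2L) {
  rates <- replicate(n_proteins, rate_parameters(
    k_on = 10^stats::runif(1, 0.5, 2.7),
    k_off = 10^stats::runif(1, 0, 1.2)
  ), simplify = FALSE)
  proteins <- lapply(seq_len(n_proteins), function(i) {
    binding_protein(paste0("P", i), stats::runif(1, 0.01, 1), rates[[i]])
  })
  binding_system(stats::runif(1, 0.01, 1), proteins)
}
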