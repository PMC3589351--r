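# Shared settings for the numbered analysis scripts. Sourced, not run.
#
# Two simulated cancer types, each with two independent cohorts per modality,
# a planted 95% cross-cohort direction-consistency rate, and a candidate-gene
# catalog with mutation-class expression shifts. Sizes are chosen so the whole
# workflow runs in a couple of minutes on one core.

library(concordia)

MASTER_SEED <- 1L
CANCERS <- c("cancerA", "cancerB")

cfg <- default_run_config(seed = MASTER_SEED, cancers = CANCERS,
                          n_genes = 2000, n_markers = 300,
                          consistency = 0.95)
# stricter copy-number control for the second cancer, mirroring the design
# option of dropping to 1% FDR where 5% concordance is poor
cfg$cna_fdr_override <- list(cancerB = 0.01)

DATA_DIR <- "results/data"
CALLS_DIR <- "results/calls"

cohort_specs <- function(cfg, cancer) {
  idx <- match(cancer, cfg$cancers)
  ex <- cfg$expression; me <- cfg$methylation; cn <- cfg$cna
  ds <- function(off) derive_seed(cfg$seed, 10 * idx + off)
  list(
    expression = cohort_spec(n_genes = ex$n_genes, n_cancer = ex$n_cancer,
                             n_normal = ex$n_normal, frac_de = ex$frac_de,
                             effect_size = ex$effect_size, noise_sd = ex$noise_sd,
                             consistency = ex$consistency, seed = ds(1)),
    methylation = cohort_spec(n_genes = me$n_genes, n_cancer = me$n_cancer,
                              n_normal = me$n_normal, frac_de = me$frac_de,
                              effect_size = me$effect_size, noise_sd = me$noise_sd,
                              consistency = me$consistency, seed = ds(4)),
    cna = cohort_spec(n_genes = cn$n_markers, n_cancer = cn$n_samples,
                      n_normal = 2, frac_de = cn$frac_alt,
                      effect_size = cn$amplitude, noise_sd = cn$noise_sd,
                      consistency = cn$consistency, seed = ds(5)),
    seed = ds
  )
}
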