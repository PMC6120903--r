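# Default parameters of the synthetic ALE-compendium generator.
# These mirror the composition of the curated compendium the package is
# designed around: ~178 conditions, replicate counts between 1 and 115
# (mean ~3), a background fixation rate of 0.0068 mutations per genome per
# generation, a hypermutator subpopulation at ~6% with a 40x rate multiplier
# biased toward DNA-maintenance genes, 86% coding genome, and the empirical
# mutation-type mixture.
seed: 1
n_genes: 4000
genome_length: 4641652
coding_fraction: 0.86
gene_sdlog: 0.45
n_conditions: 178
strains: [MG1655, BW25113, W3110, REL606, B, DH10B]
media: [LB, M9 glucose, M9 glycerol, MOPS glucose, M9 acetate, LB low-salt]
stresses: [antibiotic, osmotic, acid, heat, anaerobic, oxidative, butanol, ethanol, alkaline, cold]
stress_count_probs: [0.15, 0.6, 0.25]
generations_choices: [500, 1000, 2000, 5000, 10000, 20000, 30000, 40000]
generations_probs: [0.45, 0.2, 0.12, 0.1, 0.06, 0.04, 0.02, 0.01]
lambda: 0.0068
core_size: 6
core_prob: 0.4
hypermutator_fraction: 0.0627
hypermutator_multiplier: 40
n_dna_genes: 30
mutator_dna_bias: 3
type_mix:
  SNP: 0.57
  deletion: 0.26
  insertion: 0.09
  amplification: 0.08
  inversion: 0.0
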