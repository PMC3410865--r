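# trajmix

Bayesian nonparametric inference of time-dependent signatures of microbial
taxa from 16S sequencing-count time series under known perturbations, such
as repeated courses of a broad-spectrum antibiotic.

Longitudinal microbiome studies are usually summarized with static
per-sample diversity indices or pairwise dissimilarities, which cannot say
how fast a taxon recovers after a perturbation, whether it settles at a new
equilibrium, or which taxa respond as a coordinated sub-community.
`trajmix` models the counts themselves: each reference OTU's trajectory is
assigned, by a Dirichlet-process infinite mixture shared across subjects,
to a latent *prototype signature* — a continuous-time log-amplitude curve,
piecewise defined over the five intervals delimited by two antibiotic
pulses (pre-treatment, pulse 1, post-1, pulse 2, post-2):

- constant at the pre-treatment equilibrium `mu_a` and at the pulse
  transient levels `X_b`, `X_d`;
- exponential relaxation on each post-pulse interval, e.g.
  `f(t) = mu_c + (X_b − mu_c)·exp(−(t − t_c0)/lambda_c)`, with equilibrium
  level `mu_c` and relaxation time `lambda_c` in days.

Reversible-jump binary switches tie equilibrium levels and relaxation
times exactly equal across intervals, so each signature's effective
dimension is learned from the data. Counts are negative binomial with mean
`exp(f + gamma_so + phi_st)` (per-taxon baseline offset, per-sample
read-depth offset) and variance `m + eps·m²`, with separate dispersions on
pulse and quiescent intervals.

From the posterior the package computes:

- **Signature-diversity scores** — SD1: expected fraction of taxa with >1
  equilibrium level / relaxation time; SD2: exponentiated-entropy
  equivalent number of signatures per 100 refOTUs; SD3: combined-vs-
  independent SD2 ratio measuring cross-subject sharing, with a
  permutation test of the independent-ecosystems null.
- **Relaxation-time distributions** — kernel density over per-taxon
  posterior-median relaxation constants.
- **Consensus signature groups** — average-linkage clustering of posterior
  co-assignment probabilities, consensus trajectories on a common
  time-scale, and hypergeometric taxon enrichment with BH-FDR.
- **Bayesian D-optimal experimental design** — greedy selection of future
  sampling days maximizing the expected log-determinant of the NB-GLM
  Fisher information, plus held-out RMSE evaluation of design strategies.
- **A matched synthetic-data generator** for end-to-end recovery
  benchmarking at study-like conditions (two 5-day pulses, irregular
  sampling, count CV ≈ 0.6).

## Worked example

```r
library(trajmix)

sim <- generate_counts_dataset(sim_config(seed = 1))   # 3 subjects, 2 pulses
dat <- filter_refotus(sim$dataset)    # keep taxa with >=5 counts at >=10 days
fit <- run_mcmc(dat, sim$schedules, mcmc_config(seed = 1),
                hyper = sim_config()$hyper)

sd1_scores(fit)
sapply(fit$subjects, function(s) sd2_score(fit, s))
sd3_score(fit)$sd3
relaxation_time_density(fit, "c")
csgs <- build_csgs(coassignment_matrix(fit), fit)
head(csg_enrichment_table(csgs, fit))
```

which prints (desk-scale protocol, 2 chains × 4,000 iterations, ~4 min):

```
Posterior samples: J=400 (2 chain(s)), 59 unit(s), 3 subject(s)
  occupied signatures: mean 7.46 (range 7-9)
  subject    sd1_mu sd1_lambda
1      S1 0.9985000  0.3253750
2      S2 0.9997368  0.3448684
3      S3 0.9993750  0.3467500
   S1    S2    S3
31.61 28.09 29.72
SD3: 0.352   (permutation p = 0.005, 199 permutations)
Relaxation-time distribution, interval (c): 59 constants, median 3.91 days, bw 0.548
CSGs: 7  sizes: 15 3 11 14 7 6 3
```

Read: nearly every taxon changes equilibrium level after at least one
pulse (`sd1_mu ≈ 1`), about a third of the posterior supports distinct
relaxation times after the two pulses, a typical subject uses ≈30
equivalent signatures per 100 taxa (`SD2`), and `SD3 = 0.35` (near the
full-sharing bound of 1/3 for three subjects) says the subjects' responses
are largely shared — as they should be, since the generator drew all
subjects from one signature library. The seven consensus groups recover
the occupied generating signatures; the top enrichment rows flag the
*Bacteroides*-labelled group, though at this toy size nothing clears the
FDR threshold.

The same pipeline runs from a single YAML config via
`run_full_analysis(config, out_dir)` or from a shell through the thin CLI
`inst/cli/trajmix.R` (subcommands `simulate`, `fit`, `summarize`,
`design`, `benchmark`).

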