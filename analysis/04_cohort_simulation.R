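#!/usr/bin/env Rscript
# Synthetic twin-cohort simulation against the analytic curves.
#
# Generates a registry-style cohort (half monozygote, dizygote co-twins
# susceptible with probability 0.188), ascertains pairs with at least
# one diagnosis at a fixed 55-month observation age, and compares the
# empirical pairwise concordances with the analytic curves. Then follows
# the same cohort longitudinally — the proposed critical test: the MZ
# concordance must climb toward 100% while the DZ concordance saturates
# at S_inher. Writes the pair table, summary, trajectory, and manifest
# under results/.

suppressPackageStartupMessages(library(mmtwin))
dir.create("results", showWarnings = FALSE)

pm <- param_library("asd_male")
cfg <- cohort_config(100000, pm, fraction_mz = 0.5, s_inher = 0.188,
                     observation_age = 55, seed = 20140922)

pairs <- generate_twin_cohort(cfg)
asc <- ascertain_pairs(pairs)
summ <- empirical_concordance(asc, by_zygosity = TRUE)
write_twin_cohort(pairs[seq_len(1000), ], "results/twin_pairs_sample.csv")
write.csv(summ, "results/concordance_summary.csv", row.names = FALSE,
          quote = FALSE)
write_manifest("results", cfg, seed = cfg$seed)

cat("Empirical pairwise concordance at a 55-month observation age:\n")
print(summ)
cat(sprintf("  analytic C_M(55) = %.4f, C_D(55) = %.4f\n",
            mz_concordance(55, pm), dz_concordance(55, 0.188, pm)))

ages <- c(24, 42, 55, 90, 124, 160, 240, 360)
traj <- concordance_trajectory(cfg, ages)
write.csv(traj, "results/concordance_trajectory.csv", row.names = FALSE,
          quote = FALSE)
cat("\nLongitudinal trajectory of the same cohort:\n")
print(traj, digits = 3)
cat("MZ concordance approaches 100% as every pair passes the onset\n")
cat("distribution's upper reach; DZ saturates at S_inher = 0.188.\n")

cfg_biased <- cohort_config(100000, pm, fraction_mz = 1,
                            observation_age = 55, reporting_bias = 0.5,
                            seed = 20140922)
biased <- empirical_concordance(
  ascertain_pairs(generate_twin_cohort(cfg_biased)))
cat(sprintf(
  "\nConcordant-pair under-reporting (bias 0.5) drags C_M from %.3f to %.3f —\n",
  mz_concordance(55, pm), biased$rate))
cat("the registry bias works against, not for, the genetic hypothesis.\n")
cat("wrote results/twin_pairs_sample.csv, concordance_summary.csv,\n")
cat("      concordance_trajectory.csv, manifest.json\n")
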