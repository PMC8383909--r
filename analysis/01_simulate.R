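#!/usr/bin/env Rscript
# Stage 1: simulate a complete MA experiment at reduced genomic scale.
#
# Emulates the study design: a GC-rich (66%) multi-contig genome, 26 MA
# lines propagated for 788 generations at a base SNM+INDEL rate of
# 11.56e-10 per site per generation, lognormal between-line rate variation
# (sdlog 1.15), a C>T-dominated folded spectrum with hypermutable CTC/CAC
# contexts, and 24% of events as short INDELs. The genome is 2 Mb so the
# whole analysis runs on a laptop; rates and tests are scale-free.

suppressMessages(library(mamut))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260928L

cfg <- default_config(out_dir = out, seed = seed)
cfg$genome$lengths <- rep(500000L, 4L)
# keep a workable number of accepted mutations at 2 Mb: scale the base rate
# so the expected SNM count matches the study's count per callable Mb
cfg$experiment$base_mu <- 1991 / (26 * 2e6 * 788) * (2e6 / 84e6) * 42
# quality noise emulating the real data's imperfect callability (~72%
# genome-wide in the study): low-MQ repeat-like blocks, low-depth and
# low-GQ sites, and rare multi-line alternate-read artifacts
cfg$noise <- noise_params(low_mq_frac = 0.20, low_dp_frac = 0.03,
                          low_gq_frac = 0.02, shared_alt_rate = 1e-5)
yaml::write_yaml(cfg, file.path(out, "config.yaml"))

genome <- generate_genome(cfg$genome$n_contigs, cfg$genome$lengths,
                          cfg$genome$gc, cfg$genome$repeat_density,
                          seed = seed)
write_genome(genome, file.path(out, "genome.fasta"))

truth <- simulate_ma_experiment(
  genome, cfg$experiment$n_lines, cfg$experiment$t, cfg$experiment$base_mu,
  line_dist = cfg$experiment$line_dist,
  context_boosts = cfg$experiment$context_boosts,
  indel_fraction = cfg$experiment$indel_fraction, seed = seed + 1L)
write_table_tsv(truth$mutations, file.path(out, "truth_mutations.tsv"),
                seed = seed + 1L)

calls <- emit_call_records(genome, truth, noise = cfg$noise,
                           seed = seed + 2L)
write_calls_vcf(calls, file.path(out, "calls.vcf"))

cat(sprintf("genome: %d contigs, %d bp, GC %.3f\n", length(genome$seq),
            sum(nchar(genome$seq)), mamut:::genome_gc(genome)))
cat(sprintf("truth: %d mutations (%d SNM, %d DEL, %d INS)\n",
            nrow(truth$mutations),
            sum(truth$mutations$class == "SNM"),
            sum(truth$mutations$class == "DEL"),
            sum(truth$mutations$class == "INS")))
cat(sprintf("per-line SNM counts span %d-%d (lognormal line effects)\n",
            min(tabulate(truth$mutations$line_id, 26)),
            max(tabulate(truth$mutations$line_id, 26))))
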