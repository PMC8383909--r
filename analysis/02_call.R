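#!/usr/bin/env Rscript
# Stage 2: callable mask, mutation calling, spike-in callability and the
# contamination screen.
#
# The quality tracks of the all-sites genotyping summary are regenerated
# deterministically from the stage-1 config and seed (the VCF holds the
# variant records; the tracks are the per-site summary the mask is built
# from).

suppressMessages(library(mamut))

out <- "results/analysis"
cfg <- yaml::read_yaml(file.path(out, "config.yaml"))
seed <- cfg$seed

genome <- read_genome(file.path(out, "genome.fasta"))
truth <- utils::read.table(file.path(out, "truth_mutations.tsv"),
                           header = TRUE, sep = "\t", comment.char = "#")
truth_obj <- structure(list(mutations = truth,
                            n_lines = cfg$experiment$n_lines),
                       class = "ma_truth")
calls <- emit_call_records(genome, truth_obj, noise = do.call(noise_params, cfg$noise),
                           seed = seed + 2L)

th <- do.call(calling_thresholds,
              cfg$thresholds[setdiff(names(cfg$thresholds), "dp_rule")])
mask <- build_callable_mask(calls, th)
write_mask_bed(mask, file.path(out, "callable.bed"))
cat(sprintf("mask: %.1f%% of %d bp callable\n", 100 * mask$callable_rate,
            sum(mask$contig_len)))

res <- call_candidate_mutations(calls, mask, th)
write_table_tsv(res$mutations, file.path(out, "mutations.tsv"), seed = seed)
cat(sprintf("calling: %d accepted, %d rejected\n", nrow(res$mutations),
            nrow(res$rejections)))
if (nrow(res$rejections))
  print(table(res$rejections$rule))

# line-specific callability from spike-in probes planted per line
probes <- spike_in_probes(genome, cfg$probes$spacing)
rec <- do.call(rbind, lapply(seq_len(cfg$experiment$n_lines), function(ln) {
  pc <- plant_probes(calls, probes, ln, seed = seed + 100L + ln)
  call_candidate_mutations(pc, mask, th)$mutations
}))
callability <- spike_in_callability(probes, rec,
                                    lines = seq_len(cfg$experiment$n_lines))
write_table_tsv(callability, file.path(out, "spike_in_callability.tsv"),
                seed = seed)
cat(sprintf("spike-ins: %d probes, mean line callability %.3f\n",
            nrow(probes), mean(callability$rate)))

scr <- contamination_screen(calls)
write_table_tsv(scr$flagged, file.path(out, "contamination_flags.tsv"),
                seed = seed)
cat(sprintf("contamination screen: %d pair(s) flagged\n", nrow(scr$flagged)))
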