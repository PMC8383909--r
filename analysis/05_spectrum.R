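#!/usr/bin/env Rscript
# Stage 5: the SNM spectrum and coding-sequence selection check.
#
# Folds accepted SNMs into the six strand-collapsed types, computes the
# GC-corrected deviations from the equal-rate expectation, compares the
# synthetic spectrum against a reference spectrum, and estimates Ka/Ks on
# the concatenated mutated coding sequence.

suppressMessages(library(mamut))

out <- "results/analysis"
cfg <- yaml::read_yaml(file.path(out, "config.yaml"))
seed <- cfg$seed

genome <- read_genome(file.path(out, "genome.fasta"))
# the generated annotation is rebuilt from the stage-1 seed (FASTA carries
# no gene models)
genome_ann <- generate_genome(cfg$genome$n_contigs,
                              unlist(cfg$genome$lengths), cfg$genome$gc,
                              cfg$genome$repeat_density, seed = seed)
muts <- utils::read.table(file.path(out, "mutations.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
snms <- muts[muts$class == "SNM", ]

counts <- table(factor(fold_snm(snms$ref, snms$alt),
                       levels = names(default_spectrum())))
gc <- mamut:::genome_gc(genome)
sp <- gc_corrected_spectrum(stats::setNames(as.numeric(counts),
                                            names(default_spectrum())), gc)
write_table_tsv(sp$table, file.path(out, "spectrum.tsv"), seed = seed)
print(sp)

# deviation ratio against the generating marginal spectrum; the CTC/CAC
# context boosts shift mass towards C-source types, so C-type ratios sit
# slightly above 1 and A-type ratios below
ref <- gc_corrected_spectrum(default_spectrum() * 1000, gc)
ratio <- spectrum_ratio(sp, ref)
write_table_tsv(ratio, file.path(out, "spectrum_ratio.tsv"), seed = seed)
cat("deviation ratios vs the generating marginal spectrum:\n")
print(round(stats::setNames(ratio$ratio, ratio$type), 2))

# Ka/Ks on concatenated CDS carrying at least one SNM
ann <- genome_ann$annotation
cds <- ann[ann$feature_class == "CDS", ]
snm_cds <- snms[assign_feature_class(snms$contig, snms$pos, ann) == "CDS", ]
hit <- unique(unlist(lapply(seq_len(nrow(snm_cds)), function(i) {
  which(cds$contig == snm_cds$contig[i] & cds$start <= snm_cds$pos[i] &
          cds$end >= snm_cds$pos[i])
})))
if (length(hit)) {
  cds_hit <- cds[sort(hit), ]
  # trim each block to a full codon frame before concatenation
  lens <- (cds_hit$end - cds_hit$start + 1L) %/% 3L * 3L
  keep <- lens > 0L
  cds_hit <- cds_hit[keep, ]; lens <- lens[keep]
  seqs <- vapply(seq_len(nrow(cds_hit)), function(i)
    substr(genome$seq[[cds_hit$contig[i]]], cds_hit$start[i],
           cds_hit$start[i] + lens[i] - 1L), character(1))
  concat <- paste(seqs, collapse = "")
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  mapped <- do.call(rbind, lapply(seq_len(nrow(snm_cds)), function(i) {
    j <- which(cds_hit$contig == snm_cds$contig[i] &
                 cds_hit$start <= snm_cds$pos[i] &
                 cds_hit$start + lens - 1L >= snm_cds$pos[i])
    if (!length(j)) return(NULL)
    data.frame(pos = offsets[j[1]] + snm_cds$pos[i] - cds_hit$start[j[1]] + 1L,
               ref = snm_cds$ref[i], alt = snm_cds$alt[i])
  }))
  kk <- ka_ks(concat, mapped)
  write_table_tsv(data.frame(ka = kk$ka, ks = kk$ks, ratio = kk$ratio,
                             n_obs_syn = kk$n_obs_syn,
                             n_obs_nonsyn = kk$n_obs_nonsyn,
                             fisher_p = kk$fisher_p),
                  file.path(out, "ka_ks.tsv"), seed = seed)
  cat(sprintf("Ka/Ks over %d coding SNMs in %d bp of CDS: %.2f (Fisher p = %.2f)\n",
              nrow(mapped), nchar(concat), kk$ratio, kk$fisher_p))
} else {
  cat("no coding SNMs in this run; Ka/Ks skipped\n")
}
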