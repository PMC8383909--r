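#!/usr/bin/env Rscript
# Stage 4: genomic context of mutated sites.
#
# Context-feature matrix (GC/entropy/complexity at several scales, their
# local variability, canonical trinucleotide contexts, feature classes and
# distances) for all accepted SNMs and a random callable background, plus
# the alternate-DNA-conformation motif enrichment in 21-bp windows.

suppressMessages(library(mamut))

out <- "results/analysis"
cfg <- yaml::read_yaml(file.path(out, "config.yaml"))
seed <- cfg$seed

genome <- read_genome(file.path(out, "genome.fasta"))
muts <- utils::read.table(file.path(out, "mutations.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
mask <- read_mask_bed(file.path(out, "callable.bed"),
                      stats::setNames(nchar(genome$seq), names(genome$seq)))
snms <- muts[muts$class == "SNM", ]

set.seed(seed + 8L)
n_rand <- 2000L
rand <- do.call(rbind, lapply(names(mask$intervals), function(cn) {
  k <- round(n_rand * mask$callable_bp[[cn]] / sum(mask$callable_bp))
  if (k == 0) return(NULL)
  data.frame(contig = cn, pos = mamut:::sample_callable(mask$intervals[[cn]], k))
}))
rand <- rand[!paste(rand$contig, rand$pos) %in%
               paste(snms$contig, snms$pos), ]

sites <- rbind(cbind(snms[, c("contig", "pos")], mutated = 1L),
               cbind(rand, mutated = 0L))
feats <- context_features(genome, sites[, c("contig", "pos")],
                          w_scales = cfg$model$w_scales,
                          W_scales = cfg$model$W_scales)
feats$mutated <- sites$mutated
write_table_tsv(feats, file.path(out, "context_features.tsv"),
                seed = seed + 8L)
cat(sprintf("features: %d sites (%d mutated), %d columns\n",
            nrow(feats), sum(feats$mutated), ncol(feats)))

num <- names(feats)[vapply(feats, is.numeric, logical(1))]
num <- setdiff(num, c("pos", "mutated"))
delta <- vapply(num, function(cl) {
  mean(feats[[cl]][feats$mutated == 1], na.rm = TRUE) -
    mean(feats[[cl]][feats$mutated == 0], na.rm = TRUE)
}, numeric(1))
cat("largest mutated-vs-background feature shifts:\n")
print(head(sort(abs(delta), decreasing = TRUE), 5))

# motif enrichment in 21-bp windows around mutated vs random sites
window21 <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    s <- genome$seq[[df$contig[i]]]
    p <- df$pos[i]
    if (p < 11 || p > nchar(s) - 10) NA_character_
    else substr(s, p - 10, p + 10)
  }, character(1))
}
wm <- stats::na.omit(window21(snms))
wr <- stats::na.omit(window21(rand))
enr <- motif_enrichment(wm, wr, n_boot = 1000L, seed = seed + 9L)
write_table_tsv(enr, file.path(out, "motif_enrichment.tsv"),
                seed = seed + 9L)
print(enr[, c("motif", "prop_mutated", "prop_random", "fold", "p_kw")])
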