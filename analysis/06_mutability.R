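#!/usr/bin/env Rscript
# Stage 6: modelling mutability.
#
# Elastic-net logistic regression of mutated vs non-mutated sites on the
# stage-4 context features, with a replicate ensemble for coefficient CIs,
# binned calibration of predicted vs observed mutability, cross-prediction
# between two independently simulated datasets, and the binary C>T
# spectrum classifier.

suppressMessages(library(mamut))

out <- "results/analysis"
cfg <- yaml::read_yaml(file.path(out, "config.yaml"))
seed <- cfg$seed

feats <- utils::read.table(file.path(out, "context_features.tsv"),
                           header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
label <- feats$mutated
feats$mutated <- NULL
fm <- build_feature_matrix(feats, label)
cat(sprintf("feature matrix: %d rows x %d predictors (%d dropped as near-zero variance)\n",
            nrow(fm$x), ncol(fm$x), length(fm$dropped)))

model <- train_mutability(fm, n_nonmutated = cfg$model$n_nonmutated,
                          replicates = cfg$model$replicates,
                          alpha = cfg$model$alpha, seed = seed + 10L)
write_table_tsv(model$coef_summary, file.path(out, "model_coefficients.tsv"),
                seed = seed + 10L)
cs <- model$coef_summary[model$coef_summary$term != "(Intercept)", ]
top <- cs[order(-abs(cs$median)), ][1:10, ]
cat("ten strongest predictors of mutability:\n")
print(top, row.names = FALSE, digits = 3)

cal <- calibrate_predictions(model, fm)
write_table_tsv(cal$bins, file.path(out, "calibration.tsv"),
                seed = seed + 10L)
cat(sprintf("calibration: slope %.2f, r^2 %.2f over %d bins\n",
            cal$slope, cal$r_squared, nrow(cal$bins)))

# cross-prediction against an independently simulated second dataset from
# the same generative model
g2 <- generate_genome(2, c(300000L, 200000L), cfg$genome$gc,
                      cfg$genome$repeat_density, seed = seed + 20L)
tr2 <- simulate_ma_experiment(
  g2, cfg$experiment$n_lines, cfg$experiment$t, cfg$experiment$base_mu,
  line_dist = cfg$experiment$line_dist,
  context_boosts = cfg$experiment$context_boosts,
  indel_fraction = cfg$experiment$indel_fraction, seed = seed + 21L)
snms2 <- tr2$mutations[tr2$mutations$class == "SNM", ]
set.seed(seed + 22L)
# background size chosen to match stage-4's mutated:background ratio so
# the two calibrations are on a comparable prevalence
rand2 <- data.frame(
  contig = sample(names(g2$seq), 600, replace = TRUE,
                  prob = nchar(g2$seq)))
rand2$pos <- vapply(rand2$contig, function(cn)
  sample.int(nchar(g2$seq[[cn]]), 1L), integer(1))
sites2 <- rbind(cbind(snms2[, c("contig", "pos")], mutated = 1L),
                cbind(rand2, mutated = 0L))
feats2 <- context_features(g2, sites2[, c("contig", "pos")],
                           w_scales = cfg$model$w_scales,
                           W_scales = cfg$model$W_scales)
fm2 <- build_feature_matrix(feats2, sites2$mutated)
crossed <- cross_predict(model, fm2)
write_table_tsv(crossed$bins, file.path(out, "cross_calibration.tsv"),
                seed = seed + 22L)
cat(sprintf("cross-prediction: slope %.2f, r^2 %.2f (%d shared columns)\n",
            crossed$slope, crossed$r_squared, length(crossed$shared_columns)))

# binary C>T classifier on SNM sites (context of the site, spectrum label)
muts <- utils::read.table(file.path(out, "mutations.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
snms <- muts[muts$class == "SNM", ]
key <- paste(feats$contig, feats$pos)
snm_rows <- match(paste(snms$contig, snms$pos), key)
ok <- !is.na(snm_rows)
ct_label <- as.numeric(fold_snm(snms$ref[ok], snms$alt[ok]) == "C>T")
snm_feats <- feats[snm_rows[ok], ]
snm_feats <- snm_feats[, !grepl("^GC_", names(snm_feats))]  # drop GC of site
fm_ct <- build_feature_matrix(snm_feats, ct_label)
for (b in c("none", "down", "up", "smote")) {
  res <- train_ct_classifier(fm_ct, balancing = b, seed = seed + 30L)
  cat(sprintf("C>T classifier (%5s): accuracy %.3f vs baseline %.3f (exact binomial p = %.3g)\n",
              b, res$accuracy, res$baseline, res$p_value))
}
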