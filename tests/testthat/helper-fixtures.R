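# Fixture builders used across the suite; everything is constructed in code.

# minimal ma_genome from named character sequences
toy_genome <- function(seqs, annotation = NULL, classes = NULL) {
  if (is.null(classes))
    classes <- stats::setNames(rep("nuclear", length(seqs)), names(seqs))
  if (is.null(annotation))
    annotation <- data.frame(contig = character(), start = integer(),
                             end = integer(), feature_class = character(),
                             stringsAsFactors = FALSE)
  structure(list(seq = seqs, contig_class = classes,
                 target_gc = NA_real_, annotation = annotation),
            class = "ma_genome")
}

# one variant-site record block: focal lines carry the alternate allele,
# shared_lines additional lines carry >1/6 alternate reads without a call
variant_site <- function(contig, pos, ref, alt, focal, n_lines,
                         dp = 20L, gq = 99L, qual = 1000, mq = 60,
                         shared_lines = 0L, focal_ref_reads = 0L) {
  gt <- integer(n_lines)
  gt[focal] <- 1L
  n_alt <- integer(n_lines)
  n_ref <- rep(dp, n_lines)
  n_alt[focal] <- dp - focal_ref_reads
  n_ref[focal] <- focal_ref_reads
  if (shared_lines > 0L) {
    carriers <- setdiff(seq_len(n_lines), focal)[seq_len(shared_lines)]
    n_alt[carriers] <- ceiling(dp / 3)
    n_ref[carriers] <- dp - n_alt[carriers]
  }
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             qual = qual, mq = mq, line_id = seq_len(n_lines), gt = gt,
             dp = dp, gq = gq, n_ref = n_ref, n_alt = n_alt,
             stringsAsFactors = FALSE)
}

# ma_calls with perfect quality tracks and the given variant records
toy_calls <- function(genome, n_lines, variants,
                      dp_track = 550, mq_track = 60, qual_track = 1000) {
  lens <- nchar(genome$seq)
  tracks <- lapply(lens, function(n) {
    list(mq = rep(mq_track, n), qual = rep(qual_track, n),
         dp = rep(dp_track, n), n_gq99 = rep(n_lines, n))
  })
  structure(list(tracks = tracks, variants = variants, n_lines = n_lines,
                 lines = paste0("line_", seq_len(n_lines)),
                 contig_class = genome$contig_class,
                 contig_len = lens),
            class = "ma_calls")
}

# brute-force linguistic complexity: enumerate all substrings directly
brute_L <- function(seq) {
  n <- nchar(seq)
  distinct <- 0
  maxv <- 0
  for (k in seq_len(n)) {
    subs <- substring(seq, 1:(n - k + 1), k:n)
    distinct <- distinct + length(unique(subs))
    maxv <- maxv + min(4^k, n - k + 1)
  }
  distinct / maxv
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# shared simulated dataset with a strong planted context effect: sites in
# the canonical CTC upstream context mutate at 10x the base rate
make_ctc_dataset <- function(seed, genome_bp = 300000, n_lines = 12,
                             n_nonmutated = 800) {
  g <- generate_genome(1, genome_bp, 0.66, 0, seed = seed)
  tr <- simulate_ma_experiment(g, n_lines, 788,
                               base_mu = 450 / (n_lines * genome_bp * 788),
                               context_boosts = c(CTC = 10),
                               indel_fraction = 0, seed = seed + 1)
  snms <- tr$mutations
  set.seed(seed + 2)
  rand <- data.frame(contig = "contig_1",
                     pos = sample(2100:(genome_bp - 2100), n_nonmutated))
  rand <- rand[!rand$pos %in% snms$pos, , drop = FALSE]
  sites <- rbind(snms[, c("contig", "pos")], rand)
  label <- c(rep(1, nrow(snms)), rep(0, nrow(rand)))
  feats <- context_features(g, sites, w_scales = c(2L, 10L),
                            W_scales = c(5L, 21L))
  list(fm = build_feature_matrix(feats, label), genome = g, truth = tr)
}
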