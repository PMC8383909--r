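# Synthetic mutation-accumulation experiments: genome, truth mutations,
# call records and metadata with the statistical structure the downstream
# analysis assumes (GC-rich genome, lognormal between-line rate variation,
# context-biased spectrum, INDELs sharing the line multiplier, spike-ins).

#' Default folded SNM spectrum
#'
#' Six folded single-nucleotide-mutation type probabilities emulating a
#' transition-dominated, strongly C-to-T-biased spectrum (C>T carries about
#' half of all SNMs; transversions are rare).
#'
#' @return named numeric 6-vector summing to 1.
#' @export
default_spectrum <- function() {
  c("A>C" = 0.06, "A>G" = 0.13, "A>T" = 0.06,
    "C>A" = 0.12, "C>G" = 0.11, "C>T" = 0.52)
}

SNM_TYPES <- names(default_spectrum())

#' Generate a synthetic multi-contig genome
#'
#' Sequences are drawn i.i.d. with the target GC fraction; a configurable
#' fraction of each contig is overwritten with low-complexity/repeat blocks
#' (tiled short units) that are annotated as repeats. Gene models (5'UTR,
#' CDS exons, introns, 3'UTR) are laid down along each contig with
#' intergenic gaps.
#'
#' @param n_contigs number of contigs.
#' @param lengths integer vector of contig lengths (bp).
#' @param gc target GC fraction in [0, 1].
#' @param repeat_density fraction of sequence drawn from repeat templates.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param classes contig classes (nuclear/plastid/mitochondrial).
#' @return an object of class `ma_genome`: list with `seq` (named character
#'   vector), `contig_class`, `target_gc`, `annotation` (data.frame contig,
#'   start, end, feature_class; 1-based closed coordinates).
#' @export
generate_genome <- function(n_contigs, lengths, gc = 0.66,
                            repeat_density = 0, seed = 1L,
                            classes = rep("nuclear", n_contigs)) {
  if (n_contigs < 1L || length(lengths) != n_contigs)
    bad_arg("lengths must have one entry per contig")
  if (any(lengths <= 0)) bad_arg("contig lengths must be positive")
  if (gc < 0 || gc > 1) bad_arg("gc must be in [0, 1]")
  if (repeat_density < 0 || repeat_density >= 1)
    bad_arg("repeat_density must be in [0, 1)")
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- character(n_contigs)
  names(seqs) <- paste0("contig_", seq_len(n_contigs))
  ann <- list()
  for (i in seq_len(n_contigs)) {
    len <- lengths[i]
    bases <- sample(BASES, len, replace = TRUE, prob = probs)
    # repeat blocks: tiled 1-6 bp units drawn with the same base bias
    if (repeat_density > 0) {
      target_bp <- round(repeat_density * len)
      placed <- 0L
      while (placed < target_bp) {
        blk <- min(sample(200:800, 1L), target_bp - placed, len)
        start <- sample.int(len - blk + 1L, 1L)
        unit <- sample(BASES, sample(1:6, 1L), replace = TRUE, prob = probs)
        bases[start:(start + blk - 1L)] <-
          rep_len(unit, blk)
        ann[[length(ann) + 1L]] <- data.frame(
          contig = names(seqs)[i], start = start, end = start + blk - 1L,
          feature_class = "repeat", stringsAsFactors = FALSE)
        placed <- placed + blk
      }
    }
    seqs[i] <- paste(bases, collapse = "")
    # gene models along the contig (nuclear contigs only)
    if (classes[i] == "nuclear") {
      pos <- 1L
      while (pos < len - 2000L) {
        pos <- pos + sample(500:2000, 1L)  # intergenic gap
        u5 <- sample(100:300, 1L)
        n_ex <- sample(2:5, 1L)
        segs <- list(c(u5, "UTR5"))
        for (e in seq_len(n_ex)) {
          segs[[length(segs) + 1L]] <- c(sample(200:500, 1L), "CDS")
          if (e < n_ex)
            segs[[length(segs) + 1L]] <- c(sample(100:300, 1L), "intron")
        }
        segs[[length(segs) + 1L]] <- c(sample(100:300, 1L), "UTR3")
        for (sg in segs) {
          w <- as.integer(sg[1])
          if (pos + w - 1L > len) break
          ann[[length(ann) + 1L]] <- data.frame(
            contig = names(seqs)[i], start = pos, end = pos + w - 1L,
            feature_class = sg[2], stringsAsFactors = FALSE)
          pos <- pos + w
        }
      }
    }
  }
  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(contig = character(), start = integer(), end = integer(),
               feature_class = character(), stringsAsFactors = FALSE)
  structure(list(seq = seqs,
                 contig_class = stats::setNames(classes, names(seqs)),
                 target_gc = gc, annotation = annotation),
            class = "ma_genome")
}

#' @export
print.ma_genome <- function(x, ...) {
  cat("ma_genome:", length(x$seq), "contig(s),",
      sum(nchar(x$seq)), "bp, target GC", x$target_gc, "\n")
  invisible(x)
}

# genome GC fraction over all contigs
genome_gc <- function(genome) {
  counts <- rowSums(vapply(genome$seq, function(s)
    Biostrings::letterFrequency(Biostrings::DNAString(s), BASES),
    numeric(4)))
  unname((counts[2] + counts[3]) / sum(counts))
}

# Per-site relative mutability weights from canonical *upstream*
# trinucleotide contexts: a boost named CTC elevates sites whose focal base
# is the final C of a CTC run on either strand (forward matches boost the
# third base of the match; reverse-complement matches boost the first).
context_weights <- function(genome, contig, context_boosts) {
  s <- genome$seq[[contig]]
  n <- nchar(s)
  w <- rep(1, n)
  if (!length(context_boosts)) return(w)
  find_all <- function(pat) {
    m <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m)
  }
  for (ctx in names(context_boosts)) {
    fwd <- find_all(ctx) + 2L
    rev <- find_all(revcomp(ctx))
    hits <- c(fwd, rev)
    hits <- hits[hits >= 1L & hits <= n]
    if (length(hits)) w[hits] <- w[hits] * context_boosts[[ctx]]
  }
  w
}

#' Simulate mutation accumulation over a genome
#'
#' A haploid, neutral accumulation model with no recombination: each line
#' receives a Poisson number of events with mean multiplier x base_mu x
#' genome length x t, where the per-line multiplier is lognormal (normalized
#' to mean 1 so `base_mu` is the expected per-site rate). Event positions
#' are uniform, reweighted by trinucleotide context boosts; SNM alternate
#' alleles are drawn from the folded spectrum; a fraction of events are
#' short INDELs, which share the line multiplier with SNMs (inducing the
#' between-line SNM/INDEL count correlation).
#'
#' @param genome an `ma_genome`.
#' @param n_lines number of MA lines.
#' @param t generations.
#' @param base_mu expected rate per site per generation.
#' @param line_dist list(meanlog, sdlog) of the lognormal line multiplier.
#' @param spectrum_probs named folded 6-type probabilities (sum 1).
#' @param context_boosts named vector, canonical surrounding trinucleotide
#'   to rate multiplier (e.g. `c(CTC = 5, CAC = 5)`).
#' @param indel_fraction fraction of events that are INDELs.
#' @param del_fraction fraction of INDELs that are deletions.
#' @param seed RNG seed.
#' @return object of class `ma_truth`: list with `mutations` (data.frame
#'   line_id, contig, pos, ref, alt, class, length), `line_rates`,
#'   `spectrum_probs`, `context_boosts`, `indel_fraction`, `t`.
#' @export
simulate_ma_experiment <- function(genome, n_lines, t, base_mu,
                                   line_dist = list(meanlog = -3.01,
                                                    sdlog = 1.15),
                                   spectrum_probs = default_spectrum(),
                                   context_boosts = c(CTC = 5, CAC = 5),
                                   indel_fraction = 0.24,
                                   del_fraction = 0.566,
                                   seed = 1L) {
  if (base_mu < 0) bad_arg("base_mu must be >= 0")
  if (n_lines < 1L) bad_arg("n_lines must be >= 1")
  if (abs(sum(spectrum_probs) - 1) > 1e-9)
    bad_arg("spectrum_probs must sum to 1")
  if (!all(SNM_TYPES %in% names(spectrum_probs)))
    bad_arg("spectrum_probs must be named with the six folded types")
  set.seed(seed)
  lens <- nchar(genome$seq)
  total_len <- sum(lens)
  # per-line multiplier, normalized to mean 1
  raw <- stats::rlnorm(n_lines, line_dist$meanlog, line_dist$sdlog)
  mult <- raw / exp(line_dist$meanlog + line_dist$sdlog^2 / 2)
  # Site weights: context boosts, times a base-composition factor so the
  # marginal folded-type distribution of generated SNMs matches
  # spectrum_probs (C-source types need a C:G site, A-source an A:T site).
  p_c <- sum(spectrum_probs[startsWith(SNM_TYPES, "C")])
  gc_frac <- genome_gc(genome)
  f_gc <- if (gc_frac > 0) p_c / gc_frac else 0
  f_at <- if (gc_frac < 1) (1 - p_c) / (1 - gc_frac) else 0
  weights <- lapply(names(genome$seq), function(cn) {
    w <- context_weights(genome, cn, context_boosts)
    b <- utf8ToInt(genome$seq[[cn]])
    is_gc <- b == 67L | b == 71L  # C or G
    w * ifelse(is_gc, f_gc, f_at)
  })
  names(weights) <- names(genome$seq)
  contig_w <- vapply(weights, sum, numeric(1))
  n_ev <- stats::rpois(n_lines, mult * base_mu * total_len * t)
  line_id <- rep(seq_len(n_lines), n_ev)
  n_tot <- length(line_id)
  empty <- data.frame(line_id = integer(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      class = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (n_tot == 0L) {
    mutations <- empty
  } else {
    ctg <- sample(names(genome$seq), n_tot, replace = TRUE,
                  prob = contig_w / sum(contig_w))
    pos <- integer(n_tot)
    for (cn in unique(ctg)) {
      idx <- which(ctg == cn)
      pos[idx] <- sample.int(lens[[cn]], length(idx), replace = TRUE,
                             prob = weights[[cn]])
    }
    ref <- substring(genome$seq[ctg], pos, pos)
    is_indel <- stats::runif(n_tot) < indel_fraction
    klass <- ifelse(is_indel,
                    ifelse(stats::runif(n_tot) < del_fraction, "DEL", "INS"),
                    "SNM")
    alt <- character(n_tot)
    len <- rep(1L, n_tot)
    # SNMs: draw the folded type conditional on the source base
    for (src in c("A", "C")) {
      idx <- which(klass == "SNM" &
                     ref %in% c(src, chartr("AC", "TG", src)))
      if (!length(idx)) next
      types <- SNM_TYPES[startsWith(SNM_TYPES, src)]
      p <- spectrum_probs[types]
      drawn <- sample(types, length(idx), replace = TRUE, prob = p / sum(p))
      alt_folded <- sub(".*>", "", drawn)
      flip <- ref[idx] %in% c("G", "T")
      alt[idx] <- ifelse(flip, chartr("ACGT", "TGCA", alt_folded),
                         alt_folded)
    }
    di <- which(klass == "DEL")
    if (length(di)) {
      dlen <- 1L + stats::rgeom(length(di), 1 / 3)  # mean 3 bp
      dlen <- pmax(1L, pmin(dlen, lens[ctg[di]] - pos[di]))
      ref[di] <- substring(genome$seq[ctg[di]], pos[di], pos[di] + dlen)
      alt[di] <- substring(ref[di], 1L, 1L)
      len[di] <- dlen
    }
    ii <- which(klass == "INS")
    if (length(ii)) {
      ilen <- 1L + stats::rgeom(length(ii), 1 / 2)  # mean 2 bp
      ins <- vapply(ilen, function(k)
        paste(sample(BASES, k, replace = TRUE), collapse = ""), character(1))
      alt[ii] <- paste0(ref[ii], ins)
      len[ii] <- ilen
    }
    mutations <- data.frame(line_id = line_id, contig = ctg, pos = pos,
                            ref = ref, alt = alt, class = klass,
                            length = len, stringsAsFactors = FALSE)
  }
  # Positions are effectively drawn without replacement across the whole
  # experiment: recurrent same-site hits are vanishingly rare at genomic
  # scale and would be a discreteness artifact of scaled-down genomes.
  mutations <- mutations[!duplicated(mutations[c("contig", "pos")]), ]
  structure(list(mutations = mutations, line_rates = mult,
                 spectrum_probs = spectrum_probs,
                 context_boosts = context_boosts,
                 indel_fraction = indel_fraction, t = t,
                 n_lines = n_lines),
            class = "ma_truth")
}

#' @export
print.ma_truth <- function(x, ...) {
  cat("ma_truth:", nrow(x$mutations), "mutations across", x$n_lines,
      "lines over", x$t, "generations\n")
  invisible(x)
}

#' Spike-in probe mutations at regular intervals
#'
#' One probe per `spacing` interval per contig at deterministic positions
#' (spacing, 2 x spacing, ...), used to estimate line-specific callability.
#'
#' @param genome an `ma_genome`.
#' @param spacing interval in bp (default 27000).
#' @return data.frame contig, pos, ref, alt.
#' @export
spike_in_probes <- function(genome, spacing = 27000L) {
  if (spacing <= 0) bad_arg("spacing must be positive")
  out <- lapply(names(genome$seq), function(cn) {
    len <- nchar(genome$seq[[cn]])
    n <- len %/% spacing
    if (n == 0L) return(NULL)
    pos <- spacing * seq_len(n)
    ref <- substring(genome$seq[[cn]], pos, pos)
    data.frame(contig = cn, pos = pos, ref = ref,
               alt = chartr("ACGT", "CATG", ref), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Default quality-noise parameters for call-record emission
#'
#' All zero: a noiseless experiment in which every truth mutation in
#' callable territory is recovered.
#'
#' @param low_mq_frac fraction of the genome in low-MQ (MQ 30) blocks.
#' @param low_dp_frac fraction of sites with combined DP below threshold.
#' @param low_gq_frac fraction of sites with fewer than 3 lines at GQ 99.
#' @param shared_alt_rate per-bp rate of spurious sites where many lines
#'   carry alternate reads (triggers the neighborhood filter).
#' @param shared_alt_lines number of lines carrying alt reads at such sites.
#' @return named list of noise parameters.
#' @export
noise_params <- function(low_mq_frac = 0, low_dp_frac = 0, low_gq_frac = 0,
                         shared_alt_rate = 0, shared_alt_lines = 14L) {
  list(low_mq_frac = low_mq_frac, low_dp_frac = low_dp_frac,
       low_gq_frac = low_gq_frac, shared_alt_rate = shared_alt_rate,
       shared_alt_lines = shared_alt_lines)
}

#' Emit per-site call records for a synthetic experiment
#'
#' Produces the object the calling stage consumes: per-contig quality tracks
#' (site MQ, QUAL, combined DP, number of lines at GQ 99) summarizing the
#' all-sites genotyping output, plus per-line variant records at truth and
#' noise sites. Truth mutations appear as single-line alternate alleles;
#' noise injects records that the filter cascade must reject.
#'
#' @param genome an `ma_genome`.
#' @param truth an `ma_truth`.
#' @param noise list from [noise_params()].
#' @param seed RNG seed.
#' @param n_lines number of lines genotyped (default from truth).
#' @param depth_per_line mean per-line read depth.
#' @return object of class `ma_calls`: list with `tracks` (per contig),
#'   `variants` (long data.frame: contig, pos, ref, alt, qual, mq, line_id,
#'   gt, dp, gq, n_ref, n_alt), `n_lines`, `lines`.
#' @export
emit_call_records <- function(genome, truth, noise = noise_params(),
                              seed = 1L, n_lines = truth$n_lines,
                              depth_per_line = 21) {
  set.seed(seed)
  lens <- nchar(genome$seq)
  tracks <- lapply(names(genome$seq), function(cn) {
    n <- lens[[cn]]
    tr <- list(mq = rep(60, n), qual = rep(1000, n),
               dp = rep(round(n_lines * depth_per_line), n),
               n_gq99 = rep(n_lines, n))
    if (noise$low_mq_frac > 0) {
      target <- round(noise$low_mq_frac * n)
      placed <- 0L
      while (placed < target) {
        blk <- min(sample(100:1000, 1L), target - placed)
        st <- sample.int(n - blk + 1L, 1L)
        tr$mq[st:(st + blk - 1L)] <- 30
        placed <- placed + blk
      }
    }
    if (noise$low_dp_frac > 0) {
      idx <- sample.int(n, round(noise$low_dp_frac * n))
      tr$dp[idx] <- round(tr$dp[idx] * 0.2)
    }
    if (noise$low_gq_frac > 0) {
      idx <- sample.int(n, round(noise$low_gq_frac * n))
      tr$n_gq99[idx] <- 2L
    }
    tr
  })
  names(tracks) <- names(genome$seq)

  mut <- truth$mutations
  site_key <- unique(mut[c("contig", "pos", "ref", "alt")])
  recs <- list()
  emit_site <- function(cn, pos, ref, alt, focal_lines, shared_lines = 0L) {
    dp <- pmax(6L, stats::rpois(n_lines, depth_per_line))
    gt <- integer(n_lines)
    n_alt <- integer(n_lines)
    n_ref <- dp
    gt[focal_lines] <- 1L
    n_alt[focal_lines] <- dp[focal_lines]
    n_ref[focal_lines] <- 0L
    if (shared_lines > 0L) {
      others <- setdiff(seq_len(n_lines), focal_lines)
      carriers <- sample(others, min(shared_lines, length(others)))
      n_alt[carriers] <- pmax(2L, round(dp[carriers] * 0.3))
      n_ref[carriers] <- dp[carriers] - n_alt[carriers]
    }
    data.frame(contig = cn, pos = pos, ref = ref, alt = alt,
               qual = tracks[[cn]]$qual[pos], mq = tracks[[cn]]$mq[pos],
               line_id = seq_len(n_lines), gt = gt, dp = dp, gq = 99L,
               n_ref = n_ref, n_alt = n_alt, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(mut))) {
    recs[[length(recs) + 1L]] <- emit_site(
      mut$contig[i], mut$pos[i], mut$ref[i], mut$alt[i],
      focal_lines = mut$line_id[i])
  }
  if (noise$shared_alt_rate > 0) {
    for (cn in names(genome$seq)) {
      n_noise <- stats::rpois(1L, noise$shared_alt_rate * lens[[cn]])
      if (n_noise == 0L) next
      pos <- sample.int(lens[[cn]], n_noise)
      for (p in pos) {
        ref <- substr(genome$seq[[cn]], p, p)
        alt <- chartr("ACGT", "CATG", ref)
        recs[[length(recs) + 1L]] <- emit_site(
          cn, p, ref, alt, focal_lines = integer(),
          shared_lines = noise$shared_alt_lines)
      }
    }
  }
  variants <- if (length(recs)) do.call(rbind, recs) else
    emit_site(names(genome$seq)[1], 1L, "A", "C", integer())[0, ]
  structure(list(tracks = tracks, variants = variants, n_lines = n_lines,
                 lines = paste0("line_", seq_len(n_lines)),
                 contig_class = genome$contig_class,
                 contig_len = lens),
            class = "ma_calls")
}

#' @export
print.ma_calls <- function(x, ...) {
  cat("ma_calls:", length(unique(paste(x$variants$contig, x$variants$pos))),
      "variant site(s) across", x$n_lines, "lines\n")
  invisible(x)
}

#' Plant spike-in probes into a line's call records
#'
#' Returns a copy of `calls` whose variant records additionally contain the
#' probe mutations as single-line alternate alleles of `line`, emulating the
#' per-line alignment sets carrying synthetic mutations at known sites.
#'
#' @param calls an `ma_calls`.
#' @param probes data.frame from [spike_in_probes()].
#' @param line line index the probes are planted in.
#' @param depth_per_line mean per-line read depth.
#' @param seed RNG seed.
#' @return an `ma_calls` with the probe records appended.
#' @export
plant_probes <- function(calls, probes, line, depth_per_line = 21,
                         seed = 1L) {
  set.seed(seed)
  recs <- lapply(seq_len(nrow(probes)), function(i) {
    cn <- probes$contig[i]; p <- probes$pos[i]
    dp <- pmax(6L, stats::rpois(calls$n_lines, depth_per_line))
    gt <- integer(calls$n_lines); gt[line] <- 1L
    n_alt <- integer(calls$n_lines); n_alt[line] <- dp[line]
    n_ref <- dp; n_ref[line] <- 0L
    data.frame(contig = cn, pos = p, ref = probes$ref[i],
               alt = probes$alt[i],
               qual = calls$tracks[[cn]]$qual[p],
               mq = calls$tracks[[cn]]$mq[p],
               line_id = seq_len(calls$n_lines), gt = gt, dp = dp,
               gq = 99L, n_ref = n_ref, n_alt = n_alt,
               stringsAsFactors = FALSE)
  })
  calls$variants <- rbind(calls$variants, do.call(rbind, recs))
  calls
}
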