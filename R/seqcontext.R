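# Per-site genomic-context features: base-composition statistics at several
# scales, their local variability, canonical trinucleotide contexts, feature
# classes, distances to features, and alternate-DNA-conformation motifs.

#' Normalized Shannon entropy of a DNA sequence
#'
#' Base-composition entropy scaled to [0, 1]: 0 for a homopolymer, 1 when all
#' four nucleotides are equally frequent.
#'
#' @param seq a single DNA string (ACGT only).
#' @return entropy in [0, 1].
#' @export
#' @examples
#' shannon_entropy("ACGT")  # 1
#' shannon_entropy("AAAA")  # 0
shannon_entropy <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    bad_arg("seq must be a single non-empty string")
  codes <- base_codes(seq)
  if (anyNA(codes)) bad_arg("seq contains non-ACGT characters")
  p <- tabulate(codes, 4L) / length(codes)
  p <- p[p > 0]
  -sum(p * log2(p)) / 2
}

#' Linguistic complexity of a DNA sequence
#'
#' Ratio of the number of distinct substrings of the sequence (over all
#' lengths k = 1..n) to the maximum attainable number,
#' sum_k min(4^k, n - k + 1). Equals 1 when every possible substring is
#' present, and decreases with sequence repetitiveness.
#'
#' @param seq a single DNA string (ACGT only).
#' @return complexity in (0, 1].
#' @export
#' @examples
#' linguistic_complexity("ACGT")  # 1
#' linguistic_complexity("AAAA")  # 0.4
linguistic_complexity <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    bad_arg("seq must be a single non-empty string")
  cpp_linguistic_complexity(seq)
}

# fetch the subsequence [start, end] (1-based closed) or NA if out of bounds
contig_window <- function(genome, contig, start, end) {
  s <- genome$seq[[contig]]
  if (is.null(s)) bad_arg("unknown contig: ", contig)
  if (start < 1L || end > nchar(s)) return(NA_character_)
  substr(s, start, end)
}

#' Window statistics (GC, entropy, complexity) around a site
#'
#' Statistics are computed over the window of w bp extending upstream and
#' downstream from the site, including the site itself (total length 2w + 1).
#' Sites closer than w to a contig edge, or windows containing ambiguity
#' codes, yield missing values.
#'
#' @param genome an `ma_genome` (see [generate_genome()] / [read_genome()]).
#' @param contig contig name.
#' @param pos 1-based position.
#' @param w half-width in bp (window length 2w + 1).
#' @return named numeric vector `c(GC =, E =, L =)`; all NA if missing.
#' @export
windowed_stats <- function(genome, contig, pos, w) {
  win <- contig_window(genome, contig, pos - w, pos + w)
  na <- c(GC = NA_real_, E = NA_real_, L = NA_real_)
  if (is.na(win)) return(na)
  codes <- base_codes(win)
  if (anyNA(codes)) return(na)
  p <- tabulate(codes, 4L) / length(codes)
  pp <- p[p > 0]
  c(GC = p[2] + p[3],
    E = -sum(pp * log2(pp)) / 2,
    L = cpp_linguistic_complexity(win))
}

# vectorized GC and E over all length-W windows of a string; list(GC=, E=)
sliding_gc_entropy <- function(seq, W) {
  codes <- base_codes(seq)
  n <- length(codes)
  counts <- vapply(1:4, function(b) {
    cs <- c(0L, cumsum(codes == b))
    cs[(W + 1):(n + 1)] - cs[1:(n - W + 1)]
  }, integer(n - W + 1))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  p <- counts / W
  plogp <- ifelse(p > 0, p * log2(p), 0)
  bad <- rowSums(counts) < W  # windows overlapping non-ACGT characters
  gc <- p[, 2] + p[, 3]
  e <- -rowSums(plogp) / 2
  gc[bad] <- NA_real_
  e[bad] <- NA_real_
  list(GC = gc, E = e)
}

#' Local variability of window statistics around a site
#'
#' For each of GC, entropy and complexity, computes the statistic in every
#' window of length W that contains the site (there are W such windows) and
#' returns the standard deviation across them.
#'
#' @inheritParams windowed_stats
#' @param W window length in bp.
#' @return named numeric vector `c(dGC =, dE =, dL =)`; all NA near edges.
#' @export
delta_stats <- function(genome, contig, pos, W) {
  na <- c(dGC = NA_real_, dE = NA_real_, dL = NA_real_)
  region <- contig_window(genome, contig, pos - W + 1L, pos + W - 1L)
  if (is.na(region)) return(na)
  if (anyNA(base_codes(region))) return(na)
  ge <- sliding_gc_entropy(region, W)
  lv <- cpp_lcomplexity_sliding(region, W)
  c(dGC = stats::sd(ge$GC), dE = stats::sd(ge$E), dL = stats::sd(lv))
}

#' Canonical trinucleotide contexts of a site
#'
#' Returns the upstream, surrounding, and downstream trinucleotides of a site
#' (each including the site), canonicalized so the focal base is A or C: when
#' the reference base is G or T all three triplets are reverse-complemented
#' and the upstream/downstream slots are swapped.
#'
#' @inheritParams windowed_stats
#' @return named character vector `c(up =, surr =, down =)`; NA near edges
#'   or when the neighborhood contains ambiguity codes.
#' @export
trinucleotide_contexts <- function(genome, contig, pos) {
  na <- c(up = NA_character_, surr = NA_character_, down = NA_character_)
  win <- contig_window(genome, contig, pos - 2L, pos + 2L)
  if (is.na(win)) return(na)
  win <- toupper(win)
  if (anyNA(base_codes(win))) return(na)
  up <- substr(win, 1L, 3L)
  surr <- substr(win, 2L, 4L)
  down <- substr(win, 3L, 5L)
  center <- substr(win, 3L, 3L)
  if (center %in% c("G", "T")) {
    c(up = revcomp(down), surr = revcomp(surr), down = revcomp(up))
  } else {
    c(up = up, surr = surr, down = down)
  }
}

FEATURE_PRECEDENCE <- c("CDS", "UTR5", "UTR3", "intron", "intergenic")

#' Assign a feature class to sites
#'
#' Overlapping annotations are resolved by precedence: CDS over 5'/3' UTR
#' over intron; unannotated sites are intergenic.
#'
#' @param contig,pos vectors of contig names and 1-based positions.
#' @param annotation data.frame with columns contig, start, end,
#'   feature_class (values among CDS, UTR5, UTR3, intron).
#' @return character vector of feature classes.
#' @export
assign_feature_class <- function(contig, pos, annotation) {
  out <- rep("intergenic", length(pos))
  if (is.null(annotation) || nrow(annotation) == 0L) return(out)
  rank <- match(annotation$feature_class, FEATURE_PRECEDENCE)
  for (ctg in unique(contig)) {
    ai <- which(annotation$contig == ctg)
    si <- which(contig == ctg)
    if (!length(ai) || !length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(pos[si], pos[si]),
      IRanges::IRanges(annotation$start[ai], annotation$end[ai]))
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    best <- tapply(rank[ai][S4Vectors::subjectHits(ov)], qh, min)
    out[si[as.integer(names(best))]] <- FEATURE_PRECEDENCE[best]
  }
  out
}

#' Distance from sites to the nearest feature of a class
#'
#' @inheritParams assign_feature_class
#' @param class feature class to measure distance to.
#' @return integer vector of distances in bp (0 when inside a feature); NA
#'   when the contig carries no feature of that class.
#' @export
distance_to_feature <- function(contig, pos, annotation, class) {
  out <- rep(NA_integer_, length(pos))
  ann <- annotation[annotation$feature_class == class, , drop = FALSE]
  for (ctg in unique(contig)) {
    ai <- which(ann$contig == ctg)
    si <- which(contig == ctg)
    if (!length(ai) || !length(si)) next
    # 0 inside a feature, else offset from the nearest feature boundary
    out[si] <- vapply(pos[si], function(p) {
      as.integer(min(pmax(ann$start[ai] - p, p - ann$end[ai], 0L)))
    }, integer(1))
  }
  out
}

#' Default alternate-conformation motif parameters
#'
#' Arm/loop thresholds for palindrome, mirror, G-quadruplex and triplex motif
#' scanning. Defaults are chosen so motifs are detectable in 21-bp windows.
#'
#' @return named list of scan parameters.
#' @export
motif_params <- function(pal_arm = 5L, pal_loop_max = 5L,
                         mirror_arm = 5L, mirror_loop_max = 5L,
                         g4_run = 3L, g4_loop_min = 1L, g4_loop_max = 7L,
                         triplex_arm = 6L, triplex_loop_max = 8L) {
  list(pal_arm = pal_arm, pal_loop_max = pal_loop_max,
       mirror_arm = mirror_arm, mirror_loop_max = mirror_loop_max,
       g4_run = g4_run, g4_loop_min = g4_loop_min, g4_loop_max = g4_loop_max,
       triplex_arm = triplex_arm, triplex_loop_max = triplex_loop_max)
}

# count (start, arm, loop) triples whose two arms satisfy `match_fun`,
# optionally requiring the whole span to be homopurine or homopyrimidine
count_arm_repeats <- function(seq, arm_min, loop_max, match_fun,
                              homo_tract = FALSE) {
  n <- nchar(seq)
  hits <- 0L
  if (n < 2L * arm_min) return(0L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(n - 2L * arm_min + 1L)) {
    for (a in arm_min:((n - i + 1L) %/% 2L)) {
      for (l in 0:loop_max) {
        j <- i + a + l  # start of the second arm
        if (j + a - 1L > n) break
        arm1 <- substr(seq, i, i + a - 1L)
        arm2 <- substr(seq, j, j + a - 1L)
        if (!match_fun(arm1, arm2)) next
        if (homo_tract) {
          span <- chars[i:(j + a - 1L)]
          if (!(all(span %in% c("A", "G")) || all(span %in% c("C", "T"))))
            next
        }
        hits <- hits + 1L
      }
    }
  }
  hits
}

#' Scan a sequence for alternate-DNA-conformation motifs
#'
#' Detects potential palindromes (arm equal to the reverse complement of the
#' opposite arm), mirrors (arm equal to the reverse of the opposite arm),
#' G-quadruplexes (four runs of >= g4_run G separated by short loops), and
#' triplex motifs (homopurine or homopyrimidine mirror repeats).
#'
#' @param seq a single DNA string.
#' @param params list from [motif_params()].
#' @return named integer vector of motif counts
#'   (`palindrome`, `mirror`, `g4`, `triplex`).
#' @export
detect_motifs <- function(seq, params = motif_params()) {
  seq <- toupper(seq)
  pal <- count_arm_repeats(seq, params$pal_arm, params$pal_loop_max,
                           function(a, b) identical(b, revcomp(a)))
  mir <- count_arm_repeats(seq, params$mirror_arm, params$mirror_loop_max,
                           function(a, b) identical(strsplit(b, "")[[1]],
                                                    rev(strsplit(a, "")[[1]])))
  tpx <- count_arm_repeats(seq, params$triplex_arm, params$triplex_loop_max,
                           function(a, b) identical(strsplit(b, "")[[1]],
                                                    rev(strsplit(a, "")[[1]])),
                           homo_tract = TRUE)
  g4_re <- sprintf("G{%d,}([ACGT]{%d,%d}G{%d,}){3}",
                   params$g4_run, params$g4_loop_min, params$g4_loop_max,
                   params$g4_run)
  m <- gregexpr(g4_re, seq, perl = TRUE)[[1]]
  g4 <- if (m[1] == -1L) 0L else length(m)
  c(palindrome = pal, mirror = mir, g4 = g4, triplex = tpx)
}

#' Motif enrichment around mutated versus random sites
#'
#' Compares the proportion of windows containing at least one motif of each
#' type between windows centered on mutated sites and windows centered on
#' randomly sampled sites, with a Kruskal-Wallis rank test and bootstrap
#' confidence intervals on the proportions.
#'
#' @param mut_windows,rand_windows character vectors of window sequences.
#' @param params list from [motif_params()].
#' @param n_boot bootstrap replicates for the 95% CIs.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per motif type: proportions, fold
#'   (mutated/random), Kruskal-Wallis p, bootstrap CI bounds per group.
#' @export
motif_enrichment <- function(mut_windows, rand_windows,
                             params = motif_params(), n_boot = 1000L,
                             seed = 1L) {
  if (!length(mut_windows) || !length(rand_windows))
    bad_arg("both window groups must be non-empty")
  hits_m <- t(vapply(mut_windows, detect_motifs, integer(4), params = params))
  hits_r <- t(vapply(rand_windows, detect_motifs, integer(4), params = params))
  motifs <- colnames(hits_m)
  set.seed(seed)
  out <- lapply(motifs, function(mt) {
    xm <- as.integer(hits_m[, mt] > 0L)
    xr <- as.integer(hits_r[, mt] > 0L)
    pm <- mean(xm); pr <- mean(xr)
    kw <- if (stats::var(c(xm, xr)) == 0) NA_real_ else
      stats::kruskal.test(list(xm, xr))$p.value
    bm <- replicate(n_boot, mean(sample(xm, replace = TRUE)))
    br <- replicate(n_boot, mean(sample(xr, replace = TRUE)))
    data.frame(motif = mt, prop_mutated = pm, prop_random = pr,
               fold = if (pr > 0) pm / pr else NA_real_, p_kw = kw,
               ci_lo_mutated = stats::quantile(bm, 0.025, names = FALSE),
               ci_hi_mutated = stats::quantile(bm, 0.975, names = FALSE),
               ci_lo_random = stats::quantile(br, 0.025, names = FALSE),
               ci_hi_random = stats::quantile(br, 0.975, names = FALSE))
  })
  do.call(rbind, out)
}

#' Full context-feature table for a set of sites
#'
#' Computes, for each site: GC/E/L in windows of half-width `w_scales`;
#' their local variability (standard deviation across overlapping windows of
#' length `W_scales`); canonical trinucleotide contexts; feature class; and
#' distance to the nearest feature of each annotated class.
#'
#' @param genome an `ma_genome`.
#' @param sites data.frame with columns contig, pos.
#' @param w_scales half-widths for window statistics (default 2, 10, 100,
#'   1000, i.e. window lengths 5, 21, 201, 2001).
#' @param W_scales window lengths for the variability statistics (default
#'   5, 21, 201, 2001).
#' @return data.frame, one row per site, stable column order.
#' @export
context_features <- function(genome, sites,
                             w_scales = c(2L, 10L, 100L, 1000L),
                             W_scales = c(5L, 21L, 201L, 2001L)) {
  n <- nrow(sites)
  res <- data.frame(contig = sites$contig, pos = sites$pos,
                    stringsAsFactors = FALSE)
  for (w in w_scales) {
    m <- t(mapply(function(ctg, p) windowed_stats(genome, ctg, p, w),
                  sites$contig, sites$pos))
    res[[paste0("GC_w", w)]] <- m[, "GC"]
    res[[paste0("E_w", w)]] <- m[, "E"]
    res[[paste0("L_w", w)]] <- m[, "L"]
  }
  for (W in W_scales) {
    m <- t(mapply(function(ctg, p) delta_stats(genome, ctg, p, W),
                  sites$contig, sites$pos))
    res[[paste0("dGC_W", W)]] <- m[, "dGC"]
    res[[paste0("dE_W", W)]] <- m[, "dE"]
    res[[paste0("dL_W", W)]] <- m[, "dL"]
  }
  tri <- t(mapply(function(ctg, p) trinucleotide_contexts(genome, ctg, p),
                  sites$contig, sites$pos))
  res$tri_up <- tri[, "up"]
  res$tri_surr <- tri[, "surr"]
  res$tri_down <- tri[, "down"]
  res$feature_class <- assign_feature_class(sites$contig, sites$pos,
                                            genome$annotation)
  ann_classes <- setdiff(unique(genome$annotation$feature_class), NA)
  for (cl in ann_classes) {
    res[[paste0("dist_", cl)]] <-
      distance_to_feature(sites$contig, sites$pos, genome$annotation, cl)
  }
  res
}
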