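# Callable-site determination and the de novo mutation filter cascade.
#
# A site is callable iff MQ >= 50, QUAL >= 100 (nuclear; 70 organelle),
# combined DP >= threshold (nuclear default 167, defined as mean - 1 SD of
# combined DP), and >= 3 lines haploid-genotyped at the maximum GQ of 99.
# A candidate mutation is accepted iff its site is callable, the alternate
# allele is present in exactly one line, that line has GQ 99, the record is
# biallelic, focal depth >= 6, at most 1/6 of the focal reads carry the
# reference allele, and no site within 10 bp has >= 14 lines with more than
# 1/6 alternate reads.

#' Calling filter thresholds
#'
#' Defaults follow the documented cascade for the original dataset. The
#' combined-DP rule can be recomputed per dataset as mean - 1 SD
#' (`dp_rule = "mean_minus_sd"`) instead of the fixed defaults.
#'
#' @param mq_min minimum site mapping quality.
#' @param qual_min_nuclear,qual_min_organelle minimum site QUAL.
#' @param dp_min_nuclear,dp_min_organelle minimum combined read depth.
#' @param dp_rule "fixed" or "mean_minus_sd".
#' @param gq_max maximum (required) genotype quality.
#' @param gq99_lines_min lines required at GQ 99 for callability.
#' @param focal_dp_min minimum focal-line depth for a candidate.
#' @param max_ref_frac maximum fraction of focal reads carrying the
#'   reference allele.
#' @param neighborhood_bp neighborhood filter distance (inclusive).
#' @param neighborhood_lines lines with >1/6 alt reads that poison a
#'   neighborhood.
#' @return named list of thresholds.
#' @export
calling_thresholds <- function(mq_min = 50, qual_min_nuclear = 100,
                               qual_min_organelle = 70,
                               dp_min_nuclear = 167,
                               dp_min_organelle = 167,
                               dp_rule = c("fixed", "mean_minus_sd"),
                               gq_max = 99L, gq99_lines_min = 3L,
                               focal_dp_min = 6L, max_ref_frac = 1 / 6,
                               neighborhood_bp = 10L,
                               neighborhood_lines = 14L) {
  list(mq_min = mq_min, qual_min_nuclear = qual_min_nuclear,
       qual_min_organelle = qual_min_organelle,
       dp_min_nuclear = dp_min_nuclear,
       dp_min_organelle = dp_min_organelle,
       dp_rule = match.arg(dp_rule), gq_max = gq_max,
       gq99_lines_min = gq99_lines_min, focal_dp_min = focal_dp_min,
       max_ref_frac = max_ref_frac, neighborhood_bp = neighborhood_bp,
       neighborhood_lines = neighborhood_lines)
}

#' Build the callable mask from per-site call records
#'
#' @param calls an `ma_calls` (with quality tracks).
#' @param thresholds list from [calling_thresholds()].
#' @return object of class `ma_mask`: list with `intervals` (named list of
#'   IRanges per contig), `contig_class`, `contig_len`, `totals` (callable
#'   bp per contig class), `callable_rate`.
#' @export
build_callable_mask <- function(calls, thresholds = calling_thresholds()) {
  if (is.null(calls$tracks))
    bad_arg("calls carry no quality tracks; the mask needs all-sites data")
  th <- thresholds
  intervals <- list()
  for (cn in names(calls$tracks)) {
    tr <- calls$tracks[[cn]]
    organelle <- calls$contig_class[[cn]] != "nuclear"
    qual_min <- if (organelle) th$qual_min_organelle else th$qual_min_nuclear
    dp_min <- if (th$dp_rule == "mean_minus_sd") {
      mean(tr$dp) - stats::sd(tr$dp)
    } else if (organelle) th$dp_min_organelle else th$dp_min_nuclear
    ok <- tr$mq >= th$mq_min & tr$qual >= qual_min & tr$dp >= dp_min &
      tr$n_gq99 >= th$gq99_lines_min
    ok[is.na(ok)] <- FALSE
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    intervals[[cn]] <- IRanges::IRanges(starts[r$values], ends[r$values])
  }
  callable_bp <- vapply(intervals, function(ir) sum(IRanges::width(ir)),
                        numeric(1))
  totals <- tapply(callable_bp, calls$contig_class[names(intervals)], sum)
  structure(list(intervals = intervals, contig_class = calls$contig_class,
                 contig_len = calls$contig_len,
                 totals = totals,
                 callable_bp = callable_bp,
                 callable_rate = sum(callable_bp) / sum(calls$contig_len)),
            class = "ma_mask")
}

#' @export
print.ma_mask <- function(x, ...) {
  cat("ma_mask:", sum(x$callable_bp), "of", sum(x$contig_len),
      sprintf("bp callable (%.1f%%)\n", 100 * x$callable_rate))
  invisible(x)
}

#' Are sites inside the callable mask?
#'
#' @param mask an `ma_mask`.
#' @param contig,pos site vectors.
#' @return logical vector.
#' @export
site_callable <- function(mask, contig, pos) {
  out <- logical(length(pos))
  for (cn in unique(contig)) {
    idx <- which(contig == cn)
    ir <- mask$intervals[[cn]]
    if (is.null(ir)) next
    out[idx] <- IRanges::overlapsAny(IRanges::IRanges(pos[idx], pos[idx]), ir)
  }
  out
}

#' Accept or reject candidate de novo mutations
#'
#' Applies the full filter cascade (see module header) to the variant
#' records of a call set. Rejections are returned with the failing rule.
#'
#' @param calls an `ma_calls`.
#' @param mask an `ma_mask` built from the same call set.
#' @param thresholds list from [calling_thresholds()].
#' @return list with `mutations` (accepted, data.frame line_id, contig, pos,
#'   ref, alt, class, length) and `rejections` (contig, pos, rule).
#' @export
call_candidate_mutations <- function(calls, mask,
                                     thresholds = calling_thresholds()) {
  th <- thresholds
  v <- calls$variants
  if (!nrow(v))
    return(list(mutations = v[0, c("line_id", "contig", "pos", "ref", "alt")],
                rejections = data.frame()))
  key <- paste(v$contig, v$pos, sep = ":")
  # per-site summaries
  agg <- function(x, f) tapply(x, key, f)
  first <- !duplicated(key)
  site_info <- v[first, c("contig", "pos", "ref", "alt", "qual", "mq")]
  site_info$key <- key[first]
  n_alt_lines <- agg(v$gt, function(g) sum(g == 1L))
  n_altread_lines <- agg(v$n_alt / pmax(v$dp, 1L),
                         function(f) sum(f > 1 / 6))
  site_info$n_alt_lines <- as.integer(n_alt_lines[site_info$key])
  site_info$n_altread_lines <- as.integer(n_altread_lines[site_info$key])
  site_info$callable <- site_callable(mask, site_info$contig, site_info$pos)
  site_info$biallelic <- !grepl(",", site_info$alt, fixed = TRUE)

  # neighborhood poisoning: any site within neighborhood_bp (inclusive)
  # where >= neighborhood_lines lines carry >1/6 alt reads
  site_info$poisoned <- FALSE
  bad <- site_info[site_info$n_altread_lines >= th$neighborhood_lines, ]
  if (nrow(bad)) {
    for (cn in unique(site_info$contig)) {
      si <- which(site_info$contig == cn)
      bi <- which(bad$contig == cn)
      if (!length(bi)) next
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(site_info$pos[si], site_info$pos[si]),
        IRanges::IRanges(bad$pos[bi] - th$neighborhood_bp,
                         bad$pos[bi] + th$neighborhood_bp))
      site_info$poisoned[si] <- hit
    }
  }

  focal <- v[v$gt == 1L, ]
  fkey <- paste(focal$contig, focal$pos, sep = ":")
  m <- match(fkey, site_info$key)
  info <- site_info[m, ]
  ref_frac <- focal$n_ref / pmax(focal$dp, 1L)

  rule <- rep(NA_character_, nrow(focal))
  fail <- function(cond, name) ifelse(is.na(rule) & cond, name, rule)
  rule <- fail(!info$callable, "not_callable")
  rule <- fail(info$n_alt_lines != 1L, "alt_in_multiple_lines")
  rule <- fail(focal$gq != th$gq_max, "focal_gq")
  rule <- fail(!info$biallelic, "multiallelic")
  rule <- fail(focal$dp < th$focal_dp_min, "focal_depth")
  rule <- fail(ref_frac > th$max_ref_frac, "ref_read_fraction")
  rule <- fail(info$poisoned, "neighborhood")

  acc <- focal[is.na(rule), c("line_id", "contig", "pos", "ref", "alt")]
  acc$class <- ifelse(nchar(acc$ref) == 1L & nchar(acc$alt) == 1L, "SNM",
                      ifelse(nchar(acc$alt) > nchar(acc$ref), "INS", "DEL"))
  acc$length <- ifelse(acc$class == "SNM", 1L,
                       abs(nchar(acc$alt) - nchar(acc$ref)))
  rej <- data.frame(contig = focal$contig[!is.na(rule)],
                    pos = focal$pos[!is.na(rule)],
                    line_id = focal$line_id[!is.na(rule)],
                    rule = rule[!is.na(rule)], stringsAsFactors = FALSE)
  rownames(acc) <- NULL
  list(mutations = acc, rejections = rej)
}

#' Line-specific callability from spike-in probes
#'
#' @param probes data.frame from [spike_in_probes()].
#' @param recovered data.frame of accepted mutations (with line_id) from
#'   probe-planted call sets.
#' @param lines line indices to report.
#' @return data.frame line_id, n_probes, n_recovered, rate.
#' @export
spike_in_callability <- function(probes, recovered, lines) {
  if (!nrow(probes)) bad_arg("no probes supplied")
  pk <- paste(probes$contig, probes$pos, sep = ":")
  out <- lapply(lines, function(ln) {
    rec <- recovered[recovered$line_id == ln, , drop = FALSE]
    rk <- paste(rec$contig, rec$pos, sep = ":")
    n_rec <- sum(pk %in% rk)
    data.frame(line_id = ln, n_probes = length(pk), n_recovered = n_rec,
               rate = n_rec / length(pk))
  })
  do.call(rbind, out)
}

#' Pairwise alternate-allele sharing between lines
#'
#' share(i, j) is the fraction of line i's alternate alleles also carried by
#' line j. Pairs whose share exceeds mean + k x SD of the off-diagonal
#' entries are flagged as possible contamination.
#'
#' @param calls an `ma_calls`.
#' @param k flagging threshold in off-diagonal standard deviations.
#' @return list with `share` (matrix, NA rows for lines without alternate
#'   alleles) and `flagged` (data.frame line_i, line_j, share).
#' @export
contamination_screen <- function(calls, k = 5) {
  if (calls$n_lines < 2L) bad_arg("need at least 2 lines")
  v <- calls$variants[calls$variants$gt == 1L, ]
  alleles <- split(paste(v$contig, v$pos, v$alt, sep = ":"), v$line_id)
  n <- calls$n_lines
  share <- matrix(NA_real_, n, n,
                  dimnames = list(seq_len(n), seq_len(n)))
  for (i in seq_len(n)) {
    ai <- alleles[[as.character(i)]]
    if (is.null(ai) || !length(ai)) next  # undefined row
    for (j in seq_len(n)) {
      if (i == j) { share[i, j] <- 1; next }
      aj <- alleles[[as.character(j)]]
      share[i, j] <- if (is.null(aj)) 0 else
        length(intersect(ai, aj)) / length(ai)
    }
  }
  off <- share[row(share) != col(share)]
  thr <- mean(off, na.rm = TRUE) + k * stats::sd(off, na.rm = TRUE)
  idx <- which(share > thr & row(share) != col(share), arr.ind = TRUE)
  flagged <- data.frame(line_i = idx[, 1], line_j = idx[, 2],
                        share = share[idx])
  flagged <- flagged[order(-flagged$share), , drop = FALSE]
  rownames(flagged) <- NULL
  list(share = share, threshold = thr, flagged = flagged)
}
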