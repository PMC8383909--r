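# Format readers and writers: FASTA genomes, multi-sample VCF call records,
# BED masks, annotation and generic TSV tables with provenance headers.

#' Read a genome from FASTA
#'
#' Lowercase (soft-masked) stretches are recorded as repeat annotation and
#' the sequence is uppercased.
#'
#' @param path FASTA file.
#' @param classes named contig classes (default all nuclear).
#' @return an `ma_genome`.
#' @export
read_genome <- function(path, classes = NULL) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, ">"))
    stop("malformed FASTA header at line 1 of ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*", "", names(seqs))
  # Biostrings normalizes case, so soft-masked (lowercase) runs are
  # recovered from the raw text and recorded as repeat intervals
  raw <- readLines(path)
  hdr <- grep("^>", raw)
  ann <- list()
  for (i in seq_along(hdr)) {
    cn <- sub("\\s.*", "", sub("^>", "", raw[hdr[i]]))
    last <- if (i < length(hdr)) hdr[i + 1] - 1L else length(raw)
    body <- paste(raw[seq(hdr[i] + 1L, last)], collapse = "")
    low <- gregexpr("[acgt]+", body)[[1]]
    if (low[1] != -1L) {
      ann[[length(ann) + 1L]] <- data.frame(
        contig = cn, start = as.integer(low),
        end = as.integer(low) + attr(low, "match.length") - 1L,
        feature_class = "repeat", stringsAsFactors = FALSE)
    }
  }
  if (is.null(classes))
    classes <- stats::setNames(rep("nuclear", length(seqs)), names(seqs))
  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(contig = character(), start = integer(), end = integer(),
               feature_class = character(), stringsAsFactors = FALSE)
  structure(list(seq = seqs, contig_class = classes[names(seqs)],
                 target_gc = genome_gc_from_seqs(seqs),
                 annotation = annotation),
            class = "ma_genome")
}

genome_gc_from_seqs <- function(seqs) {
  counts <- rowSums(vapply(seqs, function(s)
    Biostrings::letterFrequency(Biostrings::DNAString(s), BASES),
    numeric(4)))
  unname((counts[2] + counts[3]) / sum(counts))
}

#' Write a genome to FASTA
#'
#' @param genome an `ma_genome`.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write call records as a multi-sample VCF (v4.2)
#'
#' Haploid genotypes; site QUAL and INFO MQ; FORMAT GT:DP:GQ:AD.
#'
#' @param calls an `ma_calls`.
#' @param path output file.
#' @export
write_calls_vcf <- function(calls, path) {
  v <- calls$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mamut",
    sprintf("##contig=<ID=%s,length=%d>", names(calls$contig_len),
            calls$contig_len),
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$lines), collapse = "\t")), con)
  key <- paste(v$contig, v$pos, sep = ":")
  for (k in unique(key)) {
    rows <- v[key == k, ]
    rows <- rows[order(rows$line_id), ]
    gtf <- sprintf("%d:%d:%d:%d,%d", rows$gt, rows$dp, rows$gq,
                   rows$n_ref, rows$n_alt)
    writeLines(paste(c(rows$contig[1], rows$pos[1], ".", rows$ref[1],
                       rows$alt[1], format(rows$qual[1]), "PASS",
                       sprintf("MQ=%g", rows$mq[1]), "GT:DP:GQ:AD", gtf),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read variant call records from a multi-sample VCF
#'
#' Returns an `ma_calls` with variant records only (no all-sites quality
#' tracks; a mask must be supplied separately to the calling stage).
#' Records with missing GQ are assigned GQ 0 so the cascade treats them as
#' non-callable.
#'
#' @param path VCF file.
#' @return an `ma_calls` (tracks = NULL).
#' @export
read_calls <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  gt <- vcfR::extract.gt(vcf, "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, "AD")
  mq <- suppressWarnings(as.numeric(sub(".*MQ=([0-9.e+-]+).*", "\\1",
                                        fix$INFO)))
  n_sites <- nrow(fix)
  ad_parts <- strsplit(as.character(ad), ",", fixed = TRUE)
  ad_ref <- matrix(vapply(ad_parts, function(x)
    suppressWarnings(as.integer(x[1])), integer(1)), n_sites)
  ad_alt <- matrix(vapply(ad_parts, function(x)
    suppressWarnings(as.integer(x[2])), integer(1)), n_sites)
  recs <- lapply(seq_along(samples), function(si) {
    data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT,
               qual = as.numeric(fix$QUAL), mq = mq,
               line_id = si,
               gt = as.integer(gt[, si] %in% c("1", "1/1", "1|1")),
               dp = as.integer(dp[, si]),
               gq = ifelse(is.na(gq[, si]), 0L, as.integer(gq[, si])),
               n_ref = ad_ref[, si], n_alt = ad_alt[, si],
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, recs)
  variants <- variants[order(variants$contig, variants$pos,
                             variants$line_id), ]
  rownames(variants) <- NULL
  contig_len <- local({
    m <- regmatches(vcf@meta,
                    regexec("##contig=<ID=([^,>]+),length=(\\d+)",
                            vcf@meta))
    m <- m[vapply(m, length, integer(1)) == 3L]
    stats::setNames(vapply(m, function(x) as.integer(x[3]), integer(1)),
                    vapply(m, function(x) x[2], character(1)))
  })
  structure(list(tracks = NULL, variants = variants,
                 n_lines = length(samples), lines = samples,
                 contig_class = stats::setNames(
                   rep("nuclear", length(contig_len)), names(contig_len)),
                 contig_len = contig_len),
            class = "ma_calls")
}

#' Write a callable mask as BED
#'
#' BED uses 0-based half-open intervals; internal intervals are 1-based
#' closed and converted on output.
#'
#' @param mask an `ma_mask`.
#' @param path output file.
#' @export
write_mask_bed <- function(mask, path) {
  rows <- unlist(lapply(names(mask$intervals), function(cn) {
    ir <- mask$intervals[[cn]]
    if (!length(ir)) return(character())
    sprintf("%s\t%d\t%d", cn, IRanges::start(ir) - 1L, IRanges::end(ir))
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Read a callable mask from BED
#'
#' @param path BED file.
#' @param contig_len named contig lengths.
#' @param contig_class named contig classes (default nuclear).
#' @return an `ma_mask`.
#' @export
read_mask_bed <- function(path, contig_len, contig_class = NULL) {
  bed <- utils::read.table(path, sep = "\t", col.names = c("contig",
                                                           "start", "end"),
                           stringsAsFactors = FALSE)
  if (is.null(contig_class))
    contig_class <- stats::setNames(rep("nuclear", length(contig_len)),
                                    names(contig_len))
  intervals <- lapply(names(contig_len), function(cn) {
    b <- bed[bed$contig == cn, , drop = FALSE]
    IRanges::IRanges(b$start + 1L, b$end)
  })
  names(intervals) <- names(contig_len)
  callable_bp <- vapply(intervals, function(ir) sum(IRanges::width(ir)),
                        numeric(1))
  structure(list(intervals = intervals, contig_class = contig_class,
                 contig_len = contig_len,
                 totals = tapply(callable_bp, contig_class[names(intervals)],
                                 sum),
                 callable_bp = callable_bp,
                 callable_rate = sum(callable_bp) / sum(contig_len)),
            class = "ma_mask")
}

# short stable hash of a config list (for provenance headers)
config_hash <- function(config) {
  s <- yaml::as.yaml(config)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Write a TSV table with a provenance header
#'
#' The first line is a comment carrying the config hash and seed.
#'
#' @param df data.frame.
#' @param path output file.
#' @param hash config hash string.
#' @param seed seed used for the stage.
#' @export
write_table_tsv <- function(df, path, hash = "na", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config=%s seed=%s", hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
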