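# Folded SNM spectrum, GC-corrected deviations, cross-dataset spectrum
# ratios, and an NG86-style counting estimator of Ka/Ks on concatenated
# mutated coding sequence.

#' Fold an SNM into its strand-collapsed type
#'
#' Complementary changes are collapsed so the reference base is A or C,
#' giving six types: A>C, A>G, A>T, C>A, C>G, C>T.
#'
#' @param ref,alt single-base reference and alternate alleles (vectorized).
#' @return character vector of folded types.
#' @export
#' @examples
#' fold_snm("G", "A")  # "C>T"
fold_snm <- function(ref, alt) {
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L) || any(ref == alt))
    bad_arg("ref and alt must be distinct single bases")
  flip <- ref %in% c("G", "T")
  r <- ifelse(flip, chartr("ACGT", "TGCA", ref), ref)
  a <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  paste0(r, ">", a)
}

#' GC-corrected mutation spectrum
#'
#' Under equal per-type rates, the expected share of a C-source type is
#' gc/3 and of an A-source type (1 - gc)/3 (a site must carry the source
#' base for the type to occur there). The deviation is the observed share
#' divided by this expectation; a chi-square goodness-of-fit test is run
#' against the expected shares.
#'
#' @param counts named counts (or weights) for the six folded types.
#' @param gc genome GC fraction in (0, 1).
#' @return object of class `ma_spectrum`: data.frame `table` (type, count,
#'   observed, expected, deviation) plus `gc`, `chisq`, `p`.
#' @export
#' @examples
#' sp <- gc_corrected_spectrum(c("A>C" = 1, "A>G" = 1, "A>T" = 1,
#'                               "C>A" = 1, "C>G" = 1, "C>T" = 1), gc = 0.5)
#' sp$table$deviation  # all 1
gc_corrected_spectrum <- function(counts, gc) {
  if (gc <= 0 || gc >= 1) bad_arg("gc must be in (0, 1)")
  full <- stats::setNames(numeric(6), SNM_TYPES)
  if (is.null(names(counts)))
    bad_arg("counts must be named with the folded types")
  unknown <- setdiff(names(counts), SNM_TYPES)
  if (length(unknown)) bad_arg("unknown SNM types: ",
                               paste(unknown, collapse = ", "))
  full[names(counts)] <- counts
  if (any(full < 0) || sum(full) <= 0)
    bad_arg("counts must be non-negative with a positive total")
  observed <- full / sum(full)
  expected <- ifelse(startsWith(SNM_TYPES, "C"), gc / 3, (1 - gc) / 3)
  names(expected) <- SNM_TYPES
  deviation <- observed / expected
  chi <- suppressWarnings(stats::chisq.test(full, p = expected))
  structure(list(table = data.frame(type = SNM_TYPES, count = unname(full),
                                    observed = unname(observed),
                                    expected = unname(expected),
                                    deviation = unname(deviation),
                                    stringsAsFactors = FALSE),
                 gc = gc, chisq = unname(chi$statistic), p = chi$p.value),
            class = "ma_spectrum")
}

#' @export
print.ma_spectrum <- function(x, ...) {
  cat("GC-corrected SNM spectrum (GC =", x$gc, ")\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("chi-square = %.2f, p = %.3g\n", x$chisq, x$p))
  invisible(x)
}

#' Per-type ratio of spectrum deviations between two datasets
#'
#' @param table_a,table_b `ma_spectrum` objects.
#' @return data.frame: type, deviation_a, deviation_b, ratio.
#' @export
spectrum_ratio <- function(table_a, table_b) {
  if (any(table_b$table$expected <= 0) || any(table_b$table$deviation <= 0))
    bad_arg("reference spectrum has zero deviations")
  data.frame(type = table_a$table$type,
             deviation_a = table_a$table$deviation,
             deviation_b = table_b$table$deviation,
             ratio = table_a$table$deviation / table_b$table$deviation,
             stringsAsFactors = FALSE)
}

# per-codon synonymous site fraction and change classification (NG86-style
# equal-weight pathway counting, no transition/transversion weighting)
codon_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (identical(code[[alt]], aa)) syn <- syn + 1 / 3
    }
  }
  syn
}

#' NG86-style Ka/Ks from mutations in concatenated coding sequence
#'
#' Synonymous and nonsynonymous site counts are obtained per codon as the
#' fraction of the three possible changes at each position that preserve
#' the encoded amino acid, summed over the sequence; observed substitutions
#' are classified by their codon effect. Ka = nonsynonymous substitutions /
#' nonsynonymous sites, Ks likewise; a Fisher exact test is run on the
#' 2 x 2 substitution/site counts.
#'
#' @param cds_concat in-frame concatenated coding sequence (length divisible
#'   by 3).
#' @param mutations data.frame with pos (1-based within `cds_concat`), ref,
#'   alt (single-base SNMs).
#' @return list: ka, ks, ratio, n_sites_syn, n_sites_nonsyn, n_obs_syn,
#'   n_obs_nonsyn, fisher_p.
#' @export
ka_ks <- function(cds_concat, mutations) {
  n <- nchar(cds_concat)
  if (n %% 3 != 0) bad_arg("coding sequence length must be divisible by 3")
  cds_concat <- toupper(cds_concat)
  code <- as.list(Biostrings::GENETIC_CODE)
  codons <- substring(cds_concat, seq(1, n, 3), seq(3, n, 3))
  syn_sites <- sum(vapply(codons, codon_syn_sites, numeric(1), code = code))
  nonsyn_sites <- n - syn_sites
  obs_syn <- 0L
  obs_nonsyn <- 0L
  for (i in seq_len(nrow(mutations))) {
    p <- mutations$pos[i]
    if (p < 1L || p > n) bad_arg("mutation position outside the sequence")
    if (substr(cds_concat, p, p) != toupper(mutations$ref[i]))
      bad_arg("reference mismatch at position ", p)
    ci <- (p - 1L) %/% 3L + 1L
    off <- (p - 1L) %% 3L + 1L
    alt_codon <- codons[ci]
    substr(alt_codon, off, off) <- toupper(mutations$alt[i])
    if (identical(code[[alt_codon]], code[[codons[ci]]]))
      obs_syn <- obs_syn + 1L
    else obs_nonsyn <- obs_nonsyn + 1L
  }
  ka <- obs_nonsyn / nonsyn_sites
  ks <- obs_syn / syn_sites
  fisher <- stats::fisher.test(round(matrix(
    c(obs_nonsyn, obs_syn, nonsyn_sites, syn_sites), nrow = 2)))
  list(ka = ka, ks = ks, ratio = if (ks > 0) ka / ks else Inf,
       n_sites_syn = syn_sites, n_sites_nonsyn = nonsyn_sites,
       n_obs_syn = obs_syn, n_obs_nonsyn = obs_nonsyn,
       fisher_p = fisher$p.value)
}
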