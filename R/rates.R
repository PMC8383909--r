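# Mutation-rate estimation and its distribution: generations from colony
# counts, the per-site per-generation rate, distribution fitting across
# lines, overdispersion relative to Poisson, a neutral Poisson accumulation
# simulation of the experiment, and spatial clustering tests (inter-mutation
# distances and windowed counts against uniform placement on callable sites).

#' Per-site per-generation mutation rate
#'
#' mu = Nmu / (Nc x Nlines x t). Stratified estimates (per line, contig,
#' feature class or variant class) use the same estimator with numerator and
#' denominator adjusted to the stratum.
#'
#' @param n_mu mutation count.
#' @param n_c callable genome length in bp.
#' @param n_lines number of MA lines.
#' @param t generations.
#' @param stratum optional label for the estimate.
#' @return data.frame with the inputs and `mu`.
#' @export
#' @examples
#' mutation_rate(1991, 84e6, 26, 788)$mu  # ~11.57e-10
mutation_rate <- function(n_mu, n_c, n_lines, t, stratum = "genome") {
  if (any(n_c <= 0) || any(n_lines <= 0) || any(t <= 0))
    bad_arg("Nc, Nlines and t must be positive")
  if (any(n_mu < 0)) bad_arg("Nmu must be >= 0")
  data.frame(stratum = stratum, n_mu = n_mu, n_c = n_c, n_lines = n_lines,
             t = t, mu = n_mu / (n_c * n_lines * t),
             stringsAsFactors = FALSE)
}

#' Generations from colony counts
#'
#' t = (log Nt - log N0) / log 2 per growth assay; assays are summed over
#' the experiment by the caller. Lines lacking assays conventionally receive
#' the mean of the measured lines.
#'
#' @param n0,nt colony counts before and after growth.
#' @return generations (vectorized).
#' @export
generations_from_colonies <- function(n0, nt) {
  if (any(n0 <= 0) || any(nt <= 0)) bad_arg("colony counts must be positive")
  log2(nt / n0)
}

#' Fit candidate distributions to per-line counts or rates
#'
#' Maximum-likelihood fits of normal, lognormal, gamma, Poisson and
#' exponential distributions, ranked by AIC, each with a Kolmogorov-Smirnov
#' statistic against the fitted distribution. Discrete families are fitted
#' to the same numeric vector as the continuous ones.
#'
#' @param values numeric vector (>= 5 values).
#' @return list with `fits` (data.frame distribution, aic, ks_D, and
#'   parameter estimates as a list-column), `best` (lowest-AIC name).
#' @export
fit_count_distributions <- function(values) {
  if (length(values) < 5L) bad_arg("need at least 5 values")
  if (stats::sd(values) == 0)
    bad_arg("degenerate input: all values are equal")
  fams <- c("norm", "lnorm", "gamma", "pois", "exp")
  rows <- lapply(fams, function(d) {
    positive_only <- d %in% c("lnorm", "gamma", "exp")
    if (positive_only && any(values <= 0))
      return(data.frame(distribution = d, aic = NA_real_, ks_D = NA_real_))
    vals <- if (d == "pois") round(values) else values
    fit <- try(suppressWarnings(fitdistrplus::fitdist(vals, d)),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      return(data.frame(distribution = d, aic = NA_real_, ks_D = NA_real_))
    est <- as.list(fit$estimate)
    # KS statistic against the fitted distribution (both ECDF sides, so it
    # is also valid for the discrete Poisson)
    cdf <- function(q) do.call(paste0("p", d), c(list(q), est))
    xs <- sort(unique(vals))
    ec <- stats::ecdf(vals)
    D <- max(abs(ec(xs) - cdf(xs)),
             abs(c(0, ec(xs[-length(xs)])) - cdf(xs - .Machine$double.eps^0.5)))
    out <- data.frame(distribution = d, aic = fit$aic, ks_D = D)
    out$estimate <- list(est)
    out
  })
  fits <- do.call(rbind, rows)
  fits <- fits[order(fits$aic), ]
  rownames(fits) <- NULL
  list(fits = fits, best = fits$distribution[1])
}

#' Between-line overdispersion relative to Poisson
#'
#' lambda is the mean per-line count, sigma2 the sample variance; their
#' ratio quantifies overdispersion (1 under Poisson). A KS statistic of the
#' counts against Poisson(lambda) is computed with a parametric-bootstrap
#' p-value (safe for the discreteness of the Poisson).
#'
#' @param per_line_counts named or unnamed integer vector of counts.
#' @param exclusions indices (or names) of lines to drop, e.g. hypermutants.
#' @param n_boot parametric bootstrap replicates for the KS p-value.
#' @param seed RNG seed.
#' @return list: lambda, sigma2, ratio, ks_D, ks_p, n_lines.
#' @export
overdispersion_test <- function(per_line_counts, exclusions = NULL,
                                n_boot = 1000L, seed = 1L) {
  counts <- per_line_counts
  if (!is.null(exclusions)) {
    counts <- if (is.character(exclusions))
      counts[setdiff(names(counts), exclusions)]
    else counts[-exclusions]
  }
  if (length(counts) < 2L) bad_arg("need at least 2 lines")
  lambda <- mean(counts)
  sigma2 <- stats::var(counts)
  ks_stat <- function(x, lam) {
    xs <- sort(unique(x))
    ec <- stats::ecdf(x)
    max(abs(ec(xs) - stats::ppois(xs, lam)),
        abs(ec(xs - 1L) - stats::ppois(xs - 1L, lam)))
  }
  D <- ks_stat(counts, lambda)
  set.seed(seed)
  D_null <- replicate(n_boot, {
    x <- stats::rpois(length(counts), lambda)
    ks_stat(x, mean(x))
  })
  list(lambda = lambda, sigma2 = sigma2, ratio = sigma2 / lambda,
       ks_D = D, ks_p = mean(D_null >= D), n_lines = length(counts))
}

#' Neutral Poisson accumulation simulation of the MA experiment
#'
#' Each replicate draws `n_lines` per-line mutation counts from Poisson with
#' mean mu x Nc x t (mutations arising independently at a constant rate) and
#' records the between-line sample variance. Summaries over replicates give
#' the null expectation for the observed between-line variance.
#'
#' @param mu per-site per-generation rate.
#' @param n_c callable genome length (bp).
#' @param n_lines lines per replicate.
#' @param t generations.
#' @param reps replicates (default 1000).
#' @param seed RNG seed.
#' @return list: lambda, variances (per replicate), median, ci (2.5%/97.5%).
#' @export
simulate_poisson_ma <- function(mu, n_c, n_lines, t, reps = 1000L,
                                seed = 1L) {
  if (reps < 1L) bad_arg("reps must be >= 1")
  if (n_c <= 0 || n_lines <= 0 || t <= 0)
    bad_arg("Nc, Nlines and t must be positive")
  lambda <- mu * n_c * t
  set.seed(seed)
  variances <- replicate(reps, stats::var(stats::rpois(n_lines, lambda)))
  list(lambda = lambda, variances = variances,
       median = stats::median(variances),
       ci = stats::quantile(variances, c(0.025, 0.975), names = FALSE))
}

# uniform draws of k positions from the callable intervals of one contig
sample_callable <- function(ir, k) {
  w <- IRanges::width(ir)
  pick <- sample.int(length(ir), k, replace = TRUE, prob = w)
  IRanges::start(ir)[pick] +
    floor(stats::runif(k) * w[pick])
}

# within-contig inter-mutation distances, pooled across lines
imd_observed <- function(mutations) {
  unlist(lapply(split(mutations$pos, mutations$contig), function(p) {
    if (length(p) < 2L) return(numeric())
    diff(sort(p))
  }), use.names = FALSE)
}

#' Inter-mutation distance clustering test
#'
#' Distances between SNMs on the same contig (irrespective of line) are
#' compared with distances for the same number of mutations placed uniformly
#' on callable sites, over `iters` iterations, with a two-sample KS test
#' against the pooled null. Short-range structure (< 10 bp) is summarized
#' separately, with the count of adjacent pairs and, when a genome is
#' supplied, the reference dinucleotides at adjacent pairs.
#'
#' @param mutations data.frame with contig, pos (SNMs).
#' @param mask an `ma_mask`.
#' @param iters null iterations (default 1000).
#' @param seed RNG seed.
#' @param genome optional `ma_genome` for the dinucleotide breakdown.
#' @return list: observed, null (pooled), ks_D, ks_p, short_range
#'   (data.frame: n_lt10_obs, expected_lt10, n_adjacent), dinucleotides.
#'   Empty result when no contig carries >= 2 mutations.
#' @export
imd_test <- function(mutations, mask, iters = 1000L, seed = 1L,
                     genome = NULL) {
  obs <- imd_observed(mutations)
  if (!length(obs))
    return(list(observed = numeric(), null = numeric(),
                ks_D = NA_real_, ks_p = NA_real_,
                short_range = data.frame(), dinucleotides = NULL))
  per_contig <- table(mutations$contig)
  set.seed(seed)
  null_pool <- unlist(lapply(seq_len(iters), function(i) {
    sim <- do.call(rbind, lapply(names(per_contig), function(cn) {
      data.frame(contig = cn,
                 pos = sample_callable(mask$intervals[[cn]],
                                       per_contig[[cn]]))
    }))
    imd_observed(sim)
  }), use.names = FALSE)
  ks <- suppressWarnings(stats::ks.test(obs, null_pool))
  n_adj <- sum(obs == 1)
  short <- data.frame(n_lt10_obs = sum(obs < 10),
                      expected_lt10 = sum(null_pool < 10) / iters,
                      n_adjacent = n_adj)
  dinuc <- NULL
  if (!is.null(genome) && n_adj > 0) {
    dn <- character()
    for (cn in unique(mutations$contig)) {
      p <- sort(mutations$pos[mutations$contig == cn])
      adj <- p[which(diff(p) == 1L)]
      if (length(adj))
        dn <- c(dn, substring(genome$seq[[cn]], adj, adj + 1L))
    }
    dinuc <- sort(table(dn), decreasing = TRUE)
  }
  list(observed = obs, null = null_pool, ks_D = unname(ks$statistic),
       ks_p = ks$p.value, short_range = short, dinucleotides = dinuc)
}

#' Windowed mutation-count clustering test
#'
#' Counts SNMs in genomic sections of the given sizes and compares the
#' distribution of per-window counts with that of uniform placements on
#' callable sites (two-sample KS per window size).
#'
#' @param mutations data.frame with contig, pos.
#' @param mask an `ma_mask`.
#' @param sizes window sizes in bp.
#' @param iters null iterations.
#' @param seed RNG seed.
#' @return data.frame: size, ks_D, ks_p.
#' @export
window_clustering <- function(mutations, mask,
                              sizes = c(1e3, 1e4, 1e5, 5e5),
                              iters = 1000L, seed = 1L) {
  if (!nrow(mutations)) bad_arg("no mutations supplied")
  window_counts <- function(df, size) {
    unlist(lapply(names(mask$contig_len), function(cn) {
      n_win <- ceiling(mask$contig_len[[cn]] / size)
      p <- df$pos[df$contig == cn]
      tabulate(pmin(n_win, (p - 1L) %/% size + 1L), n_win)
    }), use.names = FALSE)
  }
  per_contig <- table(mutations$contig)
  set.seed(seed)
  out <- lapply(sizes, function(size) {
    obs <- window_counts(mutations, size)
    null_pool <- unlist(lapply(seq_len(iters), function(i) {
      sim <- do.call(rbind, lapply(names(per_contig), function(cn) {
        data.frame(contig = cn,
                   pos = sample_callable(mask$intervals[[cn]],
                                         per_contig[[cn]]))
      }))
      window_counts(sim, size)
    }), use.names = FALSE)
    ks <- suppressWarnings(stats::ks.test(obs, null_pool))
    data.frame(size = size, ks_D = unname(ks$statistic), ks_p = ks$p.value)
  })
  do.call(rbind, out)
}

#' Two-sample KS comparison of per-line rate (or count) distributions
#'
#' @param counts_a,counts_b numeric vectors.
#' @return list: D, p.
#' @export
compare_rate_distributions <- function(counts_a, counts_b) {
  ks <- suppressWarnings(stats::ks.test(counts_a, counts_b))
  list(D = unname(ks$statistic), p = ks$p.value)
}
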