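# Pipeline driver: a single configuration object ties the synthetic
# experiment, calling, rate, spectrum and mutability stages into one
# reproducible run with per-stage seeds and a provenance log.

#' Default run configuration
#'
#' The default emulates the study design at a reduced genomic scale: a 2 Mb
#' GC-rich (66%) genome across 4 contigs, 26 MA lines over 788 generations
#' at a base rate of 11.56e-10 per site per generation, lognormal
#' between-line rate variation (sdlog 1.15), a C>T-dominated folded
#' spectrum with hypermutable CTC/CAC contexts, 24% of events INDELs, and
#' spike-in probes every 27 kb.
#'
#' @param out_dir output directory for tables.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(out_dir = tempfile("mamut_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    genome = list(n_contigs = 4L, lengths = rep(500000L, 4L), gc = 0.66,
                  repeat_density = 0.1),
    experiment = list(n_lines = 26L, t = 788, base_mu = 11.56e-10,
                      line_dist = list(meanlog = -3.01, sdlog = 1.15),
                      indel_fraction = 0.24,
                      context_boosts = c(CTC = 5, CAC = 5)),
    noise = noise_params(),
    thresholds = calling_thresholds(),
    probes = list(spacing = 27000L),
    clustering = list(iters = 200L,
                      window_sizes = c(1e3, 1e4, 1e5, 5e5)),
    poisson_null = list(reps = 1000L),
    model = list(enabled = TRUE, n_nonmutated = 1000L, replicates = 3L,
                 alpha = 0.5,
                 w_scales = c(2L, 10L, 100L), W_scales = c(5L, 21L, 201L))
  )
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Stages: genome generation, mutation accumulation, call-record emission,
#' callable mask, filter cascade, spike-in callability, contamination
#' screen, rate estimation (genome-wide, per line, per variant class),
#' distribution fitting, overdispersion and Poisson-null simulation,
#' clustering tests, GC-corrected spectrum, and (optionally) the elastic-net
#' mutability model with calibration. All tables are written to
#' `config$out_dir` with provenance headers; a run log records per-stage
#' results and filter rejection counts.
#'
#' @param config list from [default_config()].
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # the hash identifies the analysis settings, not the output location
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  logfile <- file.path(config$out_dir, "provenance.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logfile, append = TRUE)
  cat(sprintf("run config=%s seed=%d\n", hash, config$seed), file = logfile)
  emit <- function(df, name, seed) {
    write_table_tsv(df, file.path(config$out_dir, paste0(name, ".tsv")),
                    hash, seed)
  }

  g <- config$genome
  genome <- generate_genome(g$n_contigs, g$lengths, g$gc, g$repeat_density,
                            seed = derive_seed(config$seed, 1L))
  write_genome(genome, file.path(config$out_dir, "genome.fasta"))
  log_line("genome: %d contigs, %d bp, GC %.3f", length(genome$seq),
           sum(nchar(genome$seq)), genome_gc(genome))

  e <- config$experiment
  truth <- simulate_ma_experiment(
    genome, e$n_lines, e$t, e$base_mu, line_dist = e$line_dist,
    context_boosts = e$context_boosts, indel_fraction = e$indel_fraction,
    seed = derive_seed(config$seed, 2L))
  emit(truth$mutations, "truth_mutations", derive_seed(config$seed, 2L))
  log_line("truth: %d mutations", nrow(truth$mutations))

  calls <- emit_call_records(genome, truth, noise = config$noise,
                             seed = derive_seed(config$seed, 3L))
  write_calls_vcf(calls, file.path(config$out_dir, "calls.vcf"))
  mask <- build_callable_mask(calls, config$thresholds)
  write_mask_bed(mask, file.path(config$out_dir, "callable.bed"))
  log_line("mask: %.1f%% callable", 100 * mask$callable_rate)

  called <- call_candidate_mutations(calls, mask, config$thresholds)
  emit(called$mutations, "mutations", derive_seed(config$seed, 3L))
  rej <- table(called$rejections$rule)
  for (r in names(rej)) log_line("filter %s: %d rejected", r, rej[[r]])
  log_line("calling: %d accepted", nrow(called$mutations))

  probes <- spike_in_probes(genome, config$probes$spacing)
  callability <- if (nrow(probes)) {
    rec <- lapply(seq_len(min(calls$n_lines, 5L)), function(ln) {
      pc <- plant_probes(calls, probes, ln,
                         seed = derive_seed(config$seed, 100L + ln))
      call_candidate_mutations(pc, mask, config$thresholds)$mutations
    })
    spike_in_callability(probes, do.call(rbind, rec),
                         lines = seq_len(min(calls$n_lines, 5L)))
  } else data.frame()
  if (nrow(callability))
    emit(callability, "spike_in_callability", config$seed)

  contam <- contamination_screen(calls)
  emit(data.frame(contam$flagged), "contamination_flags", config$seed)

  snms <- called$mutations[called$mutations$class == "SNM", ]
  nc <- sum(mask$callable_bp)
  rates <- rbind(
    mutation_rate(nrow(snms), nc, e$n_lines, e$t, "SNM"),
    mutation_rate(sum(called$mutations$class == "DEL"), nc, e$n_lines, e$t,
                  "DEL"),
    mutation_rate(sum(called$mutations$class == "INS"), nc, e$n_lines, e$t,
                  "INS"))
  emit(rates, "rates", config$seed)
  log_line("rates: mu_SNM=%.3e", rates$mu[1])

  per_line <- tabulate(snms$line_id, e$n_lines)
  emit(data.frame(line_id = seq_len(e$n_lines), n_snm = per_line),
       "per_line_counts", config$seed)
  fits <- try(fit_count_distributions(per_line), silent = TRUE)
  if (!inherits(fits, "try-error"))
    emit(fits$fits[, c("distribution", "aic", "ks_D")],
         "count_distribution_fits", config$seed)
  over <- overdispersion_test(per_line,
                              seed = derive_seed(config$seed, 4L))
  emit(data.frame(lambda = over$lambda, sigma2 = over$sigma2,
                  ratio = over$ratio, ks_D = over$ks_D, ks_p = over$ks_p),
       "overdispersion", derive_seed(config$seed, 4L))
  pois <- simulate_poisson_ma(rates$mu[1], nc, e$n_lines, e$t,
                              reps = config$poisson_null$reps,
                              seed = derive_seed(config$seed, 5L))
  emit(data.frame(lambda = pois$lambda, median_variance = pois$median,
                  ci_lo = pois$ci[1], ci_hi = pois$ci[2]),
       "poisson_null", derive_seed(config$seed, 5L))

  imd <- imd_test(snms, mask, iters = config$clustering$iters,
                  seed = derive_seed(config$seed, 6L), genome = genome)
  if (!is.na(imd$ks_D))
    emit(cbind(data.frame(ks_D = imd$ks_D, ks_p = imd$ks_p),
               imd$short_range),
         "imd", derive_seed(config$seed, 6L))
  wc <- try(window_clustering(snms, mask,
                              sizes = config$clustering$window_sizes,
                              iters = config$clustering$iters,
                              seed = derive_seed(config$seed, 7L)),
            silent = TRUE)
  if (!inherits(wc, "try-error"))
    emit(wc, "window_clustering", derive_seed(config$seed, 7L))

  spec <- NULL
  if (nrow(snms)) {
    counts <- table(factor(fold_snm(snms$ref, snms$alt),
                           levels = SNM_TYPES))
    spec <- gc_corrected_spectrum(stats::setNames(as.numeric(counts),
                                                  SNM_TYPES),
                                  gc = genome_gc(genome))
    emit(spec$table, "spectrum", config$seed)
    log_line("spectrum: C>T deviation %.2f",
             spec$table$deviation[spec$table$type == "C>T"])
  }

  model <- NULL
  calib <- NULL
  if (isTRUE(config$model$enabled) && nrow(snms) >= 10L) {
    m <- config$model
    set.seed(derive_seed(config$seed, 8L))
    rand <- do.call(rbind, lapply(names(mask$intervals), function(cn) {
      k <- round(m$n_nonmutated *
                   mask$callable_bp[[cn]] / sum(mask$callable_bp))
      if (k == 0L) return(NULL)
      data.frame(contig = cn, pos = sample_callable(mask$intervals[[cn]], k))
    }))
    rand <- rand[!paste(rand$contig, rand$pos) %in%
                   paste(snms$contig, snms$pos), ]
    sites <- rbind(snms[, c("contig", "pos")], rand)
    label <- c(rep(1, nrow(snms)), rep(0, nrow(rand)))
    feats <- context_features(genome, sites, w_scales = m$w_scales,
                              W_scales = m$W_scales)
    fm <- build_feature_matrix(feats, label)
    model <- train_mutability(fm, n_nonmutated = m$n_nonmutated,
                              replicates = m$replicates, alpha = m$alpha,
                              seed = derive_seed(config$seed, 9L))
    emit(model$coef_summary, "model_coefficients",
         derive_seed(config$seed, 9L))
    calib <- calibrate_predictions(model, fm)
    emit(calib$bins, "calibration", derive_seed(config$seed, 9L))
    log_line("model: %d predictors, calibration slope %.3f",
             length(model$columns), calib$slope)
  }

  log_line("done")
  invisible(list(genome = genome, truth = truth, calls = calls,
                 mask = mask, called = called, rates = rates,
                 per_line = per_line, overdispersion = over,
                 poisson_null = pois, imd = imd,
                 window_clustering = if (inherits(wc, "try-error")) NULL
                 else wc,
                 spectrum = spec, contamination = contam,
                 callability = callability, model = model,
                 calibration = calib, config = config, hash = hash))
}
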