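genome50k <- toy_genome(c(ctg = strrep("ACGTG", 10000)))

test_that("callability thresholds behave at their boundaries", {
  n <- nchar(genome50k$seq[[1]])
  calls <- toy_calls(genome50k, 5, variant_site("ctg", 100, "A", "C", 1, 5))
  # exactly at the documented thresholds
  calls$tracks$ctg$mq[] <- 50
  calls$tracks$ctg$qual[] <- 100
  calls$tracks$ctg$dp[] <- 167
  calls$tracks$ctg$n_gq99[] <- 3
  mask <- build_callable_mask(calls)
  expect_true(site_callable(mask, "ctg", 100))
  # MQ one unit below
  calls$tracks$ctg$mq[100] <- 49
  mask <- build_callable_mask(calls)
  expect_false(site_callable(mask, "ctg", 100))
  expect_true(site_callable(mask, "ctg", 101))
})

test_that("organelle contigs use the lower QUAL threshold", {
  g <- toy_genome(c(pt = strrep("ACGT", 1000)),
                  classes = c(pt = "plastid"))
  calls <- toy_calls(g, 5, variant_site("pt", 10, "A", "G", 1, 5),
                     qual_track = 70)
  th <- calling_thresholds(dp_min_organelle = 100)
  mask <- build_callable_mask(calls, th)
  expect_true(site_callable(mask, "pt", 10))
  # a nuclear contig with QUAL 70 would not be callable
  gn <- toy_genome(c(nu = strrep("ACGT", 1000)))
  calls_n <- toy_calls(gn, 5, variant_site("nu", 10, "A", "G", 1, 5),
                       qual_track = 70)
  mask_n <- build_callable_mask(calls_n)
  expect_false(site_callable(mask_n, "nu", 10))
})

test_that("the mean minus one SD depth rule can replace the fixed cutoff", {
  calls <- toy_calls(genome50k, 5, variant_site("ctg", 100, "A", "C", 1, 5),
                     dp_track = 50)  # below the fixed 167
  expect_false(site_callable(build_callable_mask(calls), "ctg", 100))
  th <- calling_thresholds(dp_rule = "mean_minus_sd")
  calls$tracks$ctg$dp <- 50 + stats::rnorm(nchar(genome50k$seq[[1]]), 0, 2)
  mask <- build_callable_mask(calls, th)
  expect_gt(mask$callable_rate, 0.5)
})

test_that("the filter cascade accepts clean singletons and rejects others", {
  n_lines <- 20
  v <- rbind(
    variant_site("ctg", 100, "A", "C", focal = 1, n_lines),   # clean
    variant_site("ctg", 500, "A", "C", focal = c(1, 2), n_lines),  # 2 lines
    variant_site("ctg", 900, "A", "C", focal = 3, n_lines,
                 dp = 6L, focal_ref_reads = 2L),  # 2/6 ref reads
    variant_site("ctg", 1300, "A", "C", focal = 4, n_lines, dp = 5L),
    variant_site("ctg", 1700, "A", "C,G", focal = 5, n_lines),  # multiallelic
    variant_site("ctg", 2100, "A", "C", focal = 6, n_lines, gq = 98L))
  calls <- toy_calls(genome50k, n_lines, v)
  res <- call_candidate_mutations(calls, build_callable_mask(calls))
  expect_equal(res$mutations$pos, 100)
  rules <- res$rejections$rule[order(res$rejections$pos)]
  expect_equal(rules, c("alt_in_multiple_lines", "alt_in_multiple_lines",
                        "ref_read_fraction", "focal_depth", "multiallelic",
                        "focal_gq"))
})

test_that("boundary of the one-in-six reference-read rule", {
  n_lines <- 20
  v <- rbind(
    variant_site("ctg", 100, "A", "C", 1, n_lines, dp = 6L,
                 focal_ref_reads = 1L),   # exactly 1/6: allowed
    variant_site("ctg", 500, "A", "C", 2, n_lines, dp = 12L,
                 focal_ref_reads = 2L),   # 2/12 = 1/6: allowed
    variant_site("ctg", 900, "A", "C", 3, n_lines, dp = 12L,
                 focal_ref_reads = 3L))   # 3/12 > 1/6: rejected
  calls <- toy_calls(genome50k, n_lines, v)
  res <- call_candidate_mutations(calls, build_callable_mask(calls))
  expect_setequal(res$mutations$pos, c(100, 500))
})

test_that("shared-alt neighborhoods poison candidates within 10 bp", {
  n_lines <- 20
  mk <- function(cand_pos, noise_pos) {
    v <- rbind(
      variant_site("ctg", cand_pos, "A", "C", focal = 1, n_lines),
      variant_site("ctg", noise_pos, "G", "T", focal = integer(),
                   n_lines, shared_lines = 14L))
    calls <- toy_calls(genome50k, n_lines, v)
    call_candidate_mutations(calls, build_callable_mask(calls))
  }
  # 9 bp away: rejected; boundary 10 bp: rejected (inclusive); 11 bp: kept
  expect_equal(nrow(mk(1000, 1009)$mutations), 0)
  expect_equal(mk(1000, 1009)$rejections$rule[1], "neighborhood")
  expect_equal(nrow(mk(1000, 1010)$mutations), 0)
  expect_equal(nrow(mk(1000, 1011)$mutations), 1)
  # 13 carrier lines are not enough to poison
  v <- rbind(variant_site("ctg", 1000, "A", "C", 1, n_lines),
             variant_site("ctg", 1005, "G", "T", integer(), n_lines,
                          shared_lines = 13L))
  calls <- toy_calls(genome50k, n_lines, v)
  expect_equal(nrow(call_candidate_mutations(
    calls, build_callable_mask(calls))$mutations), 1)
})

test_that("accepted mutations always lie inside the callable mask", {
  g <- generate_genome(1, 100000, 0.66, 0, seed = 21)
  tr <- simulate_ma_experiment(g, 10, 788, 5e-8, seed = 22)
  calls <- emit_call_records(g, tr,
                             noise = noise_params(low_mq_frac = 0.1,
                                                  low_gq_frac = 0.05),
                             seed = 23, n_lines = 10)
  mask <- build_callable_mask(calls)
  res <- call_candidate_mutations(calls, mask)
  if (nrow(res$mutations))
    expect_true(all(site_callable(mask, res$mutations$contig,
                                  res$mutations$pos)))
})

test_that("tightening any single threshold never grows the accepted set", {
  g <- generate_genome(1, 100000, 0.66, 0, seed = 31)
  tr <- simulate_ma_experiment(g, 15, 788, 5e-8, seed = 32)
  calls <- emit_call_records(g, tr,
                             noise = noise_params(low_mq_frac = 0.05,
                                                  shared_alt_rate = 2e-4),
                             seed = 33, n_lines = 15)
  base_th <- calling_thresholds(dp_min_nuclear = 100)
  base <- call_candidate_mutations(calls, build_callable_mask(calls, base_th),
                                   thresholds = base_th)
  base_keys <- paste(base$mutations$contig, base$mutations$pos,
                     base$mutations$line_id)
  tighter <- list(
    calling_thresholds(dp_min_nuclear = 100, mq_min = 65),
    calling_thresholds(dp_min_nuclear = 200),
    calling_thresholds(dp_min_nuclear = 100, focal_dp_min = 12),
    calling_thresholds(dp_min_nuclear = 100, max_ref_frac = 0),
    calling_thresholds(dp_min_nuclear = 100, neighborhood_bp = 50),
    calling_thresholds(dp_min_nuclear = 100, neighborhood_lines = 5))
  for (th in tighter) {
    res <- call_candidate_mutations(calls, build_callable_mask(calls, th),
                                    thresholds = th)
    keys <- paste(res$mutations$contig, res$mutations$pos,
                  res$mutations$line_id)
    expect_true(all(keys %in% base_keys))
  }
})

test_that("the cascade agrees with an independent re-evaluation", {
  g <- generate_genome(1, 80000, 0.66, 0, seed = 41)
  tr <- simulate_ma_experiment(g, 16, 788, 8e-8, seed = 42)
  calls <- emit_call_records(g, tr,
                             noise = noise_params(shared_alt_rate = 3e-4),
                             seed = 43, n_lines = 16)
  mask <- build_callable_mask(calls)
  res <- call_candidate_mutations(calls, mask)
  # oracle: re-apply every rule directly on the long records, in a
  # different order, with plain data-frame operations
  v <- calls$variants
  v$key <- paste(v$contig, v$pos)
  alt_lines <- tapply(v$gt, v$key, sum)
  many_alt <- tapply(v$n_alt / v$dp > 1 / 6, v$key, sum)
  ok_keys <- character()
  for (k in unique(v$key)) {
    rows <- v[v$key == k, ]
    f <- rows[rows$gt == 1, ]
    if (nrow(f) != 1) next
    pos <- f$pos
    near <- unique(v$key[v$contig == f$contig & abs(v$pos - pos) <= 10])
    if (any(many_alt[near] >= 14)) next
    if (grepl(",", f$alt)) next
    if (f$gq != 99 || f$dp < 6 || f$n_ref / f$dp > 1 / 6) next
    if (!site_callable(mask, f$contig, pos)) next
    if (alt_lines[[k]] != 1) next
    ok_keys <- c(ok_keys, k)
  }
  expect_setequal(paste(res$mutations$contig, res$mutations$pos), ok_keys)
})

test_that("spike-in callability is the recovered fraction per line", {
  probes <- data.frame(contig = "ctg", pos = c(100, 200, 300, 400, 500,
                                               600, 700, 800, 900, 1000),
                       ref = "A", alt = "C")
  recovered <- data.frame(line_id = c(rep(1, 9), rep(2, 10)),
                          contig = "ctg",
                          pos = c(seq(100, 900, 100), seq(100, 1000, 100)))
  out <- spike_in_callability(probes, recovered, lines = 1:2)
  expect_equal(out$rate, c(0.9, 1.0))
  expect_error(spike_in_callability(probes[0, ], recovered, 1), "probes")
})

test_that("probe recovery equals mask membership on noiseless data", {
  g <- generate_genome(1, 60000, 0.66, 0, seed = 51)
  tr <- simulate_ma_experiment(g, 8, 100, 0, seed = 51)
  calls <- emit_call_records(g, tr, noise = noise_params(low_mq_frac = 0.2),
                             seed = 52, n_lines = 8)
  mask <- build_callable_mask(calls)
  probes <- spike_in_probes(g, 5000)
  pc <- plant_probes(calls, probes, line = 3, seed = 53)
  rec <- call_candidate_mutations(pc, mask)$mutations
  rate <- spike_in_callability(probes, rec, lines = 3)$rate
  expect_equal(rate, mean(site_callable(mask, probes$contig, probes$pos)))
})

test_that("contamination screen flags engineered allele sharing", {
  n_lines <- 10
  # line 3 carries 40 alleles; line 2 shares 30 of them (75%) plus 10 own
  v <- list()
  pos <- 1000
  for (i in 1:40) {
    pos <- pos + 50
    v[[length(v) + 1]] <- variant_site("ctg", pos, "A", "C",
                                       focal = if (i <= 30) c(2, 3) else 3,
                                       n_lines)
  }
  for (ln in c(1, 2, 4:10)) {
    for (i in 1:10) {
      pos <- pos + 50
      v[[length(v) + 1]] <- variant_site("ctg", pos, "A", "C", focal = ln,
                                         n_lines)
    }
  }
  calls <- toy_calls(genome50k, n_lines, do.call(rbind, v))
  scr <- contamination_screen(calls)
  expect_equal(scr$share[2, 3], 30 / 40)
  expect_true(any(scr$flagged$line_i == 2 & scr$flagged$line_j == 3) ||
                any(scr$flagged$line_i == 3 & scr$flagged$line_j == 2))
  # all other pairs unflagged
  other <- scr$flagged[!(scr$flagged$line_i %in% c(2, 3) &
                           scr$flagged$line_j %in% c(2, 3)), ]
  expect_equal(nrow(other), 0)
})

test_that("identical and disjoint allele sets give share 1 and 0", {
  n_lines <- 3
  v <- rbind(variant_site("ctg", 100, "A", "C", c(1, 2), n_lines),
             variant_site("ctg", 200, "A", "G", c(1, 2), n_lines),
             variant_site("ctg", 300, "A", "T", 3, n_lines))
  calls <- toy_calls(genome50k, n_lines, v)
  scr <- contamination_screen(calls)
  expect_equal(scr$share[1, 2], 1)
  expect_equal(scr$share[1, 3], 0)
  expect_error(contamination_screen(toy_calls(genome50k, 1,
    variant_site("ctg", 100, "A", "C", 1, 1))), "2 lines")
})
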