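test_that("entropy hits its extremes and hand-computed midpoint", {
  expect_equal(shannon_entropy("AAAA"), 0)
  expect_equal(shannon_entropy("ACGT"), 1)
  expect_equal(shannon_entropy("AACC"), 0.5)
  expect_error(shannon_entropy(""), "non-empty")
  expect_error(shannon_entropy("ACGN"), "ACGT")
})

test_that("linguistic complexity matches brute-force enumeration", {
  expect_equal(linguistic_complexity("ACGT"), 1)
  expect_equal(linguistic_complexity("AAAA"), 0.4)
  set.seed(5)
  for (n in c(3, 7, 15, 30)) {
    for (i in 1:5) {
      s <- random_dna(n, gc = stats::runif(1, 0.2, 0.8))
      expect_equal(linguistic_complexity(s), brute_L(s))
    }
  }
  # low-complexity repeats score below random sequence
  expect_lt(linguistic_complexity(strrep("AT", 20)),
            linguistic_complexity(random_dna(40)))
})

test_that("complexity is invariant under reverse complement", {
  set.seed(6)
  for (i in 1:10) {
    s <- random_dna(sample(10:40, 1))
    expect_equal(linguistic_complexity(s), linguistic_complexity(revcomp(s)))
  }
})

test_that("window statistics match hand counts and edge contracts", {
  g <- toy_genome(c(x = "ACGTACGTACG"))
  ws <- windowed_stats(g, "x", 6, 5)  # the full 11-mer
  expect_equal(unname(ws["GC"]), 6 / 11)
  hp <- toy_genome(c(x = strrep("A", 50)))
  expect_equal(unname(windowed_stats(hp, "x", 25, 10)["E"]), 0)
  # near-edge windows are missing
  expect_true(all(is.na(windowed_stats(g, "x", 2, 5))))
  expect_true(all(is.na(windowed_stats(g, "x", 10, 5))))
})

test_that("delta statistics vanish on periodic and homopolymer sequence", {
  per <- toy_genome(c(x = strrep("AC", 200)))
  d <- delta_stats(per, "x", 200, 10)
  expect_equal(unname(d["dGC"]), 0)
  hp <- toy_genome(c(x = strrep("G", 400)))
  expect_equal(unname(delta_stats(hp, "x", 200, 21)["dE"]), 0)
  # step change in composition produces positive dGC
  step <- toy_genome(c(x = paste0(strrep("A", 50), strrep("G", 50))))
  d2 <- delta_stats(step, "x", 50, 5)
  expect_gt(unname(d2["dGC"]), 0)
  # the 5 windows around the boundary enumerate directly
  wins <- substring(step$seq[["x"]], 46:50, 50:54)
  expect_equal(unname(d2["dGC"]),
               stats::sd(vapply(wins, function(w)
                 mean(strsplit(w, "")[[1]] %in% c("G", "C")), numeric(1))))
  expect_true(all(is.na(delta_stats(step, "x", 2, 10))))
})

test_that("trinucleotide canonicalization follows the worked examples", {
  g <- toy_genome(c(x = "AGATA"))
  expect_equal(trinucleotide_contexts(g, "x", 3),
               c(up = "AGA", surr = "GAT", down = "ATA"))
  g2 <- toy_genome(c(x = "TATCT"))
  expect_equal(trinucleotide_contexts(g2, "x", 3),
               c(up = "AGA", surr = "GAT", down = "ATA"))
  # idempotence: a canonical site maps to itself
  g3 <- toy_genome(c(x = "GCAGG"))
  ctx <- trinucleotide_contexts(g3, "x", 3)
  expect_equal(unname(ctx["surr"]), "CAG")
  expect_true(substr(ctx["surr"], 2, 2) %in% c("A", "C"))
  # exactly 32 canonical triplets exist per slot
  all_tri <- apply(expand.grid(BASES <- c("A", "C", "G", "T"), BASES,
                               BASES), 1, paste, collapse = "")
  canon <- unique(vapply(all_tri, function(tri) {
    g <- toy_genome(c(x = paste0("A", tri, "A")))
    unname(trinucleotide_contexts(g, "x", 3)["surr"])
  }, character(1)))
  expect_length(canon, 32)
  expect_true(all(substr(canon, 2, 2) %in% c("A", "C")))
  # edges are missing
  expect_true(all(is.na(trinucleotide_contexts(g, "x", 1))))
})

test_that("feature classes follow the precedence hierarchy", {
  ann <- data.frame(contig = "x", start = c(10, 10, 50, 70),
                    end = c(30, 40, 60, 80),
                    feature_class = c("CDS", "intron", "UTR3", "intron"))
  expect_equal(assign_feature_class("x", 20, ann), "CDS")   # CDS over intron
  expect_equal(assign_feature_class("x", 35, ann), "intron")
  expect_equal(assign_feature_class("x", 55, ann), "UTR3")
  expect_equal(assign_feature_class("x", 100, ann), "intergenic")
  ann2 <- rbind(ann, data.frame(contig = "x", start = 50, end = 60,
                                feature_class = "intron"))
  expect_equal(assign_feature_class("x", 55, ann2), "UTR3")  # UTR over intron
})

test_that("distances to features include zero inside and NA when absent", {
  ann <- data.frame(contig = "x", start = 100, end = 200,
                    feature_class = "CDS")
  expect_equal(distance_to_feature("x", 150, ann, "CDS"), 0)
  expect_equal(distance_to_feature("x", 300, ann, "CDS"), 100)
  expect_true(is.na(distance_to_feature("x", 300, ann, "UTR5")))
})

test_that("motif scanning matches arm/loop case analysis", {
  hits <- detect_motifs("GGGTGGGTGGGTGGG")
  expect_gt(hits[["g4"]], 0)
  # arm ACGT, loop T: palindromic (RC of ACGT is ACGT), not a mirror
  p4 <- motif_params(pal_arm = 4, mirror_arm = 4)
  hits2 <- detect_motifs("ACGTTACGT", p4)
  expect_gt(hits2[["palindrome"]], 0)
  expect_equal(hits2[["mirror"]], 0)
  # homopolymer: mirror and triplex but no palindrome
  hits3 <- detect_motifs(strrep("A", 21))
  expect_gt(hits3[["mirror"]], 0)
  expect_gt(hits3[["triplex"]], 0)
  expect_equal(hits3[["palindrome"]], 0)
  # mixed-purine/pyrimidine mirror is not a triplex
  hits4 <- detect_motifs("ACACTTCACA", motif_params(mirror_arm = 5,
                                                    triplex_arm = 5))
  expect_gt(hits4[["mirror"]], 0)
  expect_equal(hits4[["triplex"]], 0)
})

test_that("motif enrichment separates planted from matched windows", {
  set.seed(9)
  # background windows carry the motif at a low rate, planted windows always
  rand <- c(replicate(58, random_dna(21)),
            replicate(2, paste0(random_dna(3), "GGGAGGGAGGGAGGG",
                                random_dna(3))))
  planted <- replicate(40, paste0(random_dna(3), "GGGAGGGAGGGAGGG",
                                  random_dna(3)))
  enr <- motif_enrichment(planted, rand, n_boot = 200, seed = 10)
  g4 <- enr[enr$motif == "g4", ]
  expect_equal(g4$prop_mutated, 1)
  expect_lt(g4$p_kw, 0.001)
  expect_gt(g4$fold, 5)
  # identical groups: fold 1, no signal
  enr2 <- motif_enrichment(rand, rand, n_boot = 100, seed = 11)
  expect_true(all(is.na(enr2$fold) | abs(enr2$fold - 1) < 1e-9))
  expect_error(motif_enrichment(character(), rand), "non-empty")
})

test_that("context features are reverse-complement invariant", {
  set.seed(12)
  g <- toy_genome(c(x = random_dna(4000, gc = 0.66)))
  grc <- toy_genome(c(x = revcomp(g$seq[["x"]])))
  n <- nchar(g$seq[["x"]])
  sites <- sample(1200:2800, 8)
  f1 <- context_features(g, data.frame(contig = "x", pos = sites),
                         w_scales = c(2L, 10L), W_scales = c(5L, 21L))
  f2 <- context_features(grc, data.frame(contig = "x", pos = n - sites + 1L),
                         w_scales = c(2L, 10L), W_scales = c(5L, 21L))
  num <- setdiff(names(f1)[vapply(f1, is.numeric, logical(1))], "pos")
  for (cl in num) expect_equal(f1[[cl]], f2[[cl]], tolerance = 1e-12)
  expect_equal(f1$tri_surr, f2$tri_surr)
  expect_equal(f1$tri_up, f2$tri_up)
  expect_equal(f1$tri_down, f2$tri_down)
})
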