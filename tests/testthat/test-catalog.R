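test_that("N50 follows the cumulative-coverage definition", {
  expect_identical(compute_n50(100), 100)
  expect_identical(compute_n50(c(1, 1, 1, 1)), 1)
  # cumulative from largest: 80, 150 >= 125 => 70
  expect_identical(compute_n50(c(80, 70, 50, 30, 20)), 70)
  expect_error(compute_n50(numeric(0)), "non-empty")
  expect_error(compute_n50(c(10, 0)), "positive")
})

test_that("quality filter keeps inclusive boundaries and logs rejections", {
  gs <- list(
    ok = make_genome("ok", "ACGTACGTACGTACGTACGT", 72, 3),
    edge = make_genome("edge", "ACGTACGTACGTACGTACGT", 50.0, 10.0),
    low = make_genome("low", "ACGTACGTACGTACGTACGT", 49.9, 0),
    dirty = make_genome("dirty", "ACGTACGTACGTACGTACGT", 90, 10.1))
  qf <- quality_filter(gs)
  expect_setequal(names(qf$retained), c("ok", "edge"))
  expect_setequal(qf$rejections$mag_id, c("low", "dirty"))
  expect_equal(qf$rejections$reason[qf$rejections$mag_id == "low"],
               "low_completeness")
  strict <- quality_filter(gs, strict = TRUE)
  expect_setequal(names(strict$retained), "ok")
  gs$bad <- make_genome("bad", "ACGT", 50, 1)
  gs$bad$completeness <- NA
  expect_error(quality_filter(gs), "bad")
})

test_that("alignment oracle scores hand-checked pairs", {
  expect_identical(ani_oracle("ACGT", "ACGT"), 1.0)
  expect_identical(ani_oracle("AAAA", "TTTT"), 0.0)
  expect_identical(ani_oracle("ACGTACGT", "ACGAACGT"), 0.875)
  expect_error(ani_oracle(strrep("A", 2e5), "ACGT"), "100 kb")
})

test_that("MinHash ANI handles identity, disjointness and known divergence", {
  a <- make_genome("a", random_dna(5000, 1))
  expect_identical(estimate_ani(a, a)$ani, 1)
  b <- make_genome("b", random_dna(5000, 2))
  r <- estimate_ani(a, b)
  # two unrelated random sequences share essentially no 16-mers
  expect_lt(r$aligned_fraction, 0.01)
  # a pair at ~1% true divergence estimates within 0.005 of the oracle
  seq_a <- random_dna(50000, 3)
  seq_b <- mutate_exact(seq_a, 500, seed = 4)
  est <- estimate_ani(make_genome("x", seq_a), make_genome("y", seq_b))
  oracle <- ani_oracle_windows(seq_a, seq_b, window = 2500, n_windows = 8)
  expect_equal(est$ani, oracle, tolerance = 0.005)
  expect_error(estimate_ani(make_genome("s", "ACGT"), a), "k = 16")
})

test_that("no shared k-mers gives an undefined ANI", {
  a <- make_genome("a", strrep("A", 100))
  b <- make_genome("b", strrep("C", 100))
  r <- estimate_ani(a, b)
  expect_true(is.na(r$ani))
  expect_identical(r$aligned_fraction, 0)
})

test_that("dereplication recovers planted clusters exactly", {
  for (s in 1:3) {
    cfg <- synth_config(seed = s, n_clusters = 3, genomes_per_cluster = 3,
                        genome_length = 20000, within_divergence = 0.0025,
                        between_divergence = 0.10)
    gs <- generate_genome_set(cfg)
    der <- dereplicate(gs$genomes)
    expect_length(der$representatives, 3)
    # recovered partition equals the planted partition (Rand index 1)
    expect_identical(unname(table(der$clusters, gs$clusters) > 0) |> rowSums(),
                     rep(1, 3))
    split_rec <- split(names(der$clusters), der$clusters)
    split_true <- split(names(gs$clusters), gs$clusters)
    expect_setequal(unname(lapply(split_rec, sort)), unname(lapply(split_true, sort)))
  }
})

test_that("dereplication is idempotent and monotone in the threshold", {
  cfg <- synth_config(seed = 8, n_clusters = 3, genomes_per_cluster = 3,
                      genome_length = 15000, within_divergence = 0.0025)
  gs <- generate_genome_set(cfg)
  der <- dereplicate(gs$genomes)
  again <- dereplicate(gs$genomes[der$representatives])
  expect_length(again$representatives, length(der$representatives))
  expect_true(all(lengths(again$members) == 1))
  n_clusters <- vapply(c(0.95, 0.99, 0.999),
                       function(t) length(dereplicate(gs$genomes,
                                                      ani_threshold = t)$representatives),
                       0)
  expect_true(all(diff(n_clusters) >= 0))
})

test_that("representative selection follows score then length then id", {
  seq <- random_dna(3000, 11)
  a <- make_genome("MAGa", seq, completeness = 90, contamination = 1)
  b <- make_genome("MAGb", seq, completeness = 95, contamination = 1)
  der <- dereplicate(list(MAGa = a, MAGb = b))
  expect_length(der$representatives, 1)
  expect_identical(unname(der$representatives), "MAGb")
  single <- dereplicate(list(MAGa = a))
  expect_identical(unname(single$representatives), "MAGa")
  expect_identical(unname(single$clusters), "C001")
  empty <- dereplicate(list())
  expect_length(empty$representatives, 0)
})

test_that("novelty calls implement the ANI < 95% or NA rule", {
  seq <- random_dna(10000, 13)
  mag_same <- make_genome("same", seq)
  mag_far <- make_genome("far", mutate_exact(seq, 1000, seed = 14))
  mag_alien <- make_genome("alien", strrep("AC", 500))
  refs <- list(ref1 = make_genome("ref1", seq))
  nov <- call_novelty(list(same = mag_same, far = mag_far,
                           alien = mag_alien), refs)
  expect_false(nov$novel[nov$mag_id == "same"])
  expect_equal(nov$best_ani[nov$mag_id == "same"], 1)
  expect_true(nov$novel[nov$mag_id == "far"])    # oracle identity ~0.90
  expect_true(nov$novel[nov$mag_id == "alien"])
  expect_true(is.na(nov$best_ani[nov$mag_id == "alien"]))
  none <- call_novelty(list(same = mag_same), list())
  expect_true(all(none$novel))
  expect_true(all(is.na(none$best_ani)))
})

test_that("catalog summary reports the novel percentage of clusters", {
  genomes <- setNames(lapply(1:10, function(i)
    make_genome(sprintf("MAG%02d", i), random_dna(100, i))),
    sprintf("MAG%02d", 1:10))
  der <- dereplicate(genomes, ani_threshold = 0.999)
  reps <- der$representatives
  make_nov <- function(n_novel) data.frame(
    mag_id = reps, best_reference = NA, best_ani = NA,
    novel = seq_along(reps) <= n_novel)
  s <- summarize_catalog(der, make_nov(8), genomes)
  expect_identical(s$n_clusters, 10L)
  expect_identical(s$novel_pct_headline, 80)
  s0 <- summarize_catalog(der, make_nov(0), genomes)
  expect_identical(s0$novel_pct, 0)
  expect_identical(s$length_mean, 100)
})
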