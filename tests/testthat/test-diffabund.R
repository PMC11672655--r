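test_that("alpha diversity matches closed forms", {
  u <- alpha_diversity(rep(0.25, 4))
  expect_equal(u[["richness"]], 4)
  expect_equal(u[["shannon"]], log(4), tolerance = 1e-12)
  expect_equal(u[["simpson"]], 0.75, tolerance = 1e-12)
  s <- alpha_diversity(c(1, 0, 0))
  expect_equal(unname(s), c(1, 0, 0))
  h <- alpha_diversity(c(0.5, 0.25, 0.25))
  expect_equal(h[["shannon"]], 1.5 * log(2), tolerance = 1e-12)
  expect_equal(alpha_diversity(c(0.5, 0.5), variant = "dominance")[["simpson"]],
               0.5)
  expect_error(alpha_diversity(c(0, 0)), "all-zero")
  expect_error(alpha_diversity(c(-1, 2)), "non-negative")
})

test_that("Bray-Curtis matches the hand formula and its metric properties", {
  m <- rbind(a = c(0.5, 0.5, 0), b = c(0, 0.5, 0.5), c = c(0.5, 0.5, 0),
             d = c(1, 0, 0))
  bc <- bray_curtis(m)
  expect_equal(bc["a", "b"], 0.5)
  expect_equal(bc["a", "c"], 0)
  expect_equal(bc["b", "d"], 1)  # disjoint supports
  # independent oracle: direct sum|x-y| / sum(x+y) on random profiles
  set.seed(1)
  for (i in 1:20) {
    x <- runif(10); y <- runif(10)
    expect_equal(bray_curtis(rbind(x, y))[1, 2],
                 sum(abs(x - y)) / sum(x + y), tolerance = 1e-12)
  }
  r <- null_abundance(6, 15, seed = 2)
  bc <- bray_curtis(r)
  expect_true(all(bc >= 0 & bc <= 1))
  expect_equal(bc, t(bc))
  expect_true(all(diag(bc) == 0))
})

test_that("PCoA preserves Euclidean geometry and orders axes", {
  set.seed(3)
  pts <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(pts))
  fit <- pcoa(d, n_axes = 2)
  rec <- as.matrix(dist(fit$coordinates))
  expect_equal(rec, d, tolerance = 1e-8)
  expect_true(all(diff(fit$proportion_explained) <= 1e-12))
  # sign convention: first nonzero loading of each axis positive
  expect_true(all(apply(fit$coordinates, 2, function(v) v[abs(v) > 1e-12][1]) > 0))
  zero <- pcoa(matrix(0, 4, 4))
  expect_true(all(zero$coordinates == 0))
  # three equidistant samples: two equal positive eigenvalues
  tri <- matrix(1, 3, 3) - diag(3)
  eig <- pcoa(tri)$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  expect_gt(eig[1], 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA attains the permutation minimum under perfect separation", {
  set.seed(5)
  ab <- matrix(0, 8, 4)
  ab[1:4, 1:2] <- runif(8, 0.4, 0.6)
  ab[5:8, 3:4] <- runif(8, 0.4, 0.6)
  rownames(ab) <- paste0("s", 1:8)
  ab <- ab / rowSums(ab)
  labs <- rep(c("A", "B"), each = 4)
  d <- bray_curtis(ab)
  res <- permanova(d, labs, n_perm = 199, seed = 1)
  # permutations that happen to preserve the two-group partition tie with the
  # observed F (they occur with probability 2 * 4!4! / 8! ~ 2.9%), so the
  # attainable minimum p is (1 + #ties)/(1 + n_perm); verify no permutation
  # strictly beats the observed statistic and p stays at the tie floor
  pseudo_f_sep <- function(d, g) {
    n <- nrow(d); sst <- sum(d[upper.tri(d)]^2) / n
    ssw <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv); dd <- d[idx, idx]
      ssw <- ssw + sum(dd[upper.tri(dd)]^2) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- pseudo_f_sep(d, labs)
  set.seed(2)
  f_perm <- replicate(500, pseudo_f_sep(d, sample(labs)))
  expect_lte(max(f_perm), f_obs + 1e-12)
  expect_lt(res$p_value, 0.05)
  expect_lte(res$p_value, (1 + qbinom(0.9999, 199, 2 * factorial(4)^2 /
                                        factorial(8))) / 200)
  expect_error(permanova(d, c("A", rep("B", 7))), "at least two")
  expect_error(permanova(bray_curtis(ab), rep("A", 8)), "two groups")
})

test_that("PERMANOVA agrees with a brute-force permutation oracle", {
  # independent oracle: Anderson pseudo-F computed from scratch and the
  # permutation null enumerated by direct resampling
  set.seed(7)
  ab <- null_abundance(8, 12, seed = 7)
  ab[1:4, 1:3] <- ab[1:4, 1:3] * 3
  ab <- ab / rowSums(ab)
  labs <- rep(c("A", "B"), each = 4)
  d <- bray_curtis(ab)
  pseudo_f <- function(d, g) {
    n <- nrow(d); a <- length(unique(g))
    sst <- sum(d[upper.tri(d)]^2) / n
    ssw <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      dd <- d[idx, idx]
      ssw <- ssw + sum(dd[upper.tri(dd)]^2) / length(idx)
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- pseudo_f(d, labs)
  set.seed(11)
  f_perm <- replicate(2000, pseudo_f(d, sample(labs)))
  p_oracle <- (1 + sum(f_perm >= f_obs)) / 2001
  res <- permanova(d, labs, n_perm = 1999, seed = 13)
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 0.03)
})

test_that("paired differential testing recovers planted shifts directionally", {
  planted <- sprintf("MAG%04d", 21:30)
  cfg <- synth_config(seed = 77, n_samples = 8, n_mags = 60, noise_sd = 0.2,
                      group_effects = lapply(planted, function(m)
                        list(mag = m, group = "C", lfc = 1)))
  am <- generate_abundance_matrix(cfg)
  res <- differential_mags(am$abundance, am$groups)
  pl <- res$mag_id %in% planted
  expect_gte(sum(res$significant_t[pl] & res$direction[pl] == "higher_in_C"), 9)
  # no null MAG is called up in C at the Bonferroni-level check
  false_up <- sum(!is.na(res$t_pvalue[!pl]) & res$t_pvalue[!pl] < 0.05 / 50 &
                    res$direction[!pl] == "higher_in_C")
  expect_identical(false_up, 0L)
  expect_true(all(res$t_pvalue >= 0 & res$t_pvalue <= 1, na.rm = TRUE))
})

test_that("degenerate differential inputs are handled, not crashed", {
  ab <- matrix(rep(c(0.6, 0.4), each = 8), 8, 2,
               dimnames = list(paste0("s", 1:8), c("M1", "M2")))
  groups <- data.frame(sample_id = paste0("s", 1:8),
                       group = rep(c("C", "DC"), 4),
                       donkey_id = rep(paste0("D", 1:4), each = 2))
  res <- differential_mags(ab, groups)
  expect_true(all(is.na(res$t_pvalue)))       # zero-variance differences
  expect_true(all(res$mw_pvalue == 1))        # identical groups
  expect_false(any(res$significant_t))
  bad <- groups[-1, ]
  expect_error(differential_mags(ab[-1, ], bad), "both groups")
})

test_that("t-test matches the closed-form statistic on a 3-point example", {
  x <- c(0.30, 0.25, 0.35); y <- c(0.20, 0.24, 0.22)
  dif <- x - y
  t_manual <- mean(dif) / (sd(dif) / sqrt(3))
  p_manual <- 2 * pt(-abs(t_manual), df = 2)
  ab <- rbind(ab1 = c(x[1], 1 - x[1]), ab2 = c(y[1], 1 - y[1]),
              ab3 = c(x[2], 1 - x[2]), ab4 = c(y[2], 1 - y[2]),
              ab5 = c(x[3], 1 - x[3]), ab6 = c(y[3], 1 - y[3]))
  colnames(ab) <- c("M1", "M2")
  groups <- data.frame(sample_id = rownames(ab),
                       group = rep(c("C", "DC"), 3),
                       donkey_id = rep(paste0("D", 1:3), each = 2))
  res <- differential_mags(ab, groups)
  expect_equal(res$t_pvalue[res$mag_id == "M1"], p_manual, tolerance = 1e-12)
})

test_that("pathway set comparison returns the Venn partition deterministically", {
  pt <- matrix(0, 3, 4, dimnames = list(c("M1", "M2", "M3"),
                                        paste0("p", 1:4)))
  pt["M1", c("p1", "p2", "p3")] <- 1
  pt["M2", c("p2", "p4")] <- 1
  pt["M3", "p4"] <- 1
  res <- pathway_set_compare(pt, "M1", c("M2", "M3"))
  expect_identical(res$a_only, c("p1", "p3"))
  expect_identical(res$b_only, "p4")
  expect_identical(res$shared, "p2")
  same <- pathway_set_compare(pt, "M1", "M1")
  expect_length(same$a_only, 0)
  expect_identical(same$shared, c("p1", "p2", "p3"))
  expect_error(pathway_set_compare(pt, "M9", "M1"), "unknown MAG")
})
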