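test_that("node filtering is strict at the abundance floor", {
  ab <- matrix(c(0.00005, 0.001, 0.94, 0.00005, 0.001, 0.94), 2, 3,
               byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("M1", "M2", "M3")))
  groups <- data.frame(sample_id = c("s1", "s2"), group = c("C", "C"))
  keep <- filter_nodes(ab, groups)
  expect_false("M1" %in% keep)   # mean exactly at the floor: dropped
  expect_setequal(keep, c("M2", "M3"))
  expect_error(filter_nodes(ab, data.frame(sample_id = "s1", group = "DC"),
                            group = "C"), "no samples")
  cfg_hi <- network_config(abundance_floor = 0.999)
  expect_warning(filter_nodes(ab, groups, config = cfg_hi), "empty")
  expect_error(network_config(rho_threshold = 1.5), "rho_threshold")
})

test_that("Spearman edge screening applies sign mode and Bonferroni", {
  set.seed(4)
  base <- sort(runif(10))
  ab <- cbind(M1 = base, M2 = base^2 + 1,     # identical rank order
              M3 = rev(base),                 # perfectly reversed
              M4 = runif(10), M5 = runif(10), M6 = rep(0.1, 10))
  rownames(ab) <- paste0("s", 1:10)
  expect_warning(sc <- spearman_edges(ab), "constant")
  expect_identical(sc$n_pairs_tested, 15)
  e12 <- sc$tested[sc$tested$a == "M1" & sc$tested$b == "M2", ]
  expect_equal(e12$rho, 1)
  expect_true(e12$kept)
  e13 <- sc$tested[sc$tested$a == "M1" & sc$tested$b == "M3", ]
  expect_equal(e13$rho, -1)
  expect_false(e13$kept)  # positive_only mode
  abs_mode <- suppressWarnings(
    spearman_edges(ab, network_config(sign_mode = "absolute")))
  e13a <- abs_mode$tested[abs_mode$tested$a == "M1" & abs_mode$tested$b == "M3", ]
  expect_true(e13a$kept)
  expect_false(any(grepl("M6", c(sc$tested$a, sc$tested$b))))
})

test_that("planted blocks yield exactly the within-block edges at n = 26", {
  cfg <- synth_config(seed = 19, n_samples = 26, n_mags = 30,
                      block_spec = list(list(members = sprintf("MAG%04d", 1:5),
                                             strength = 1.0)))
  am <- generate_abundance_matrix(cfg)
  net <- build_network(am$abundance, am$groups, "C")
  expect_identical(nrow(net$edges), 10L)  # choose(5, 2) within-block pairs
  in_block <- net$edges$a %in% sprintf("MAG%04d", 1:5) &
    net$edges$b %in% sprintf("MAG%04d", 1:5)
  expect_true(all(in_block))
})

test_that("raising the correlation threshold never adds edges", {
  am <- generate_abundance_matrix(
    synth_config(seed = 23, n_samples = 26, n_mags = 20,
                 block_spec = list(list(members = sprintf("MAG%04d", 1:6),
                                        strength = 0.95))))
  samp <- am$groups$sample_id[am$groups$group == "C"]
  counts <- vapply(c(0.5, 0.7, 0.85, 0.95), function(th)
    nrow(spearman_edges(am$abundance[samp, ],
                        network_config(rho_threshold = th))$edges), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("module detection recovers planted communities", {
  cliq <- function(v) as.data.frame(t(combn(v, 2)),
                                    col.names = c("a", "b")) |>
    setNames(c("a", "b"))
  edges <- rbind(cliq(paste0("a", 1:4)), cliq(paste0("b", 1:4)))
  part <- detect_modules(edges, seed = 1)
  expect_length(unique(part), 2)
  expect_length(unique(part[paste0("a", 1:4)]), 1)
  expect_length(unique(part[paste0("b", 1:4)]), 1)
  # three dense blocks, no between edges, across seeds
  edges3 <- rbind(cliq(paste0("x", 1:5)), cliq(paste0("y", 1:5)),
                  cliq(paste0("z", 1:5)))
  for (s in 1:5) {
    p <- detect_modules(edges3, seed = s)
    expect_length(unique(p), 3)
    expect_length(unique(p[paste0("x", 1:5)]), 1)
  }
  single <- detect_modules(data.frame(a = "n1", b = "n2"), seed = 1)
  expect_length(unique(single), 1)  # one module of two nodes
  empty <- detect_modules(data.frame(a = character(0), b = character(0)))
  expect_length(empty, 0)
})

test_that("z and c scores match hand computations and conserve degree", {
  # star center in module A with 2 leaves in A and 2 in B
  edges <- data.frame(a = rep("hub", 4), b = c("a1", "a2", "b1", "b2"))
  part <- c(hub = "A", a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  sc <- node_scores(edges, part)
  expect_equal(sc$c[sc$mag_id == "hub"], 0.5)           # 1 - (0.5^2 + 0.5^2)
  expect_equal(sc$c[sc$mag_id == "a1"], 0)              # all links in own module
  k_even <- data.frame(a = rep("n", 3), b = c("m1", "m2", "m3"))
  pe <- c(n = "M1", m1 = "M1", m2 = "M2", m3 = "M3")
  expect_equal(node_scores(k_even, pe)$c[1], 1 - 1 / 3, tolerance = 1e-12)

  cfg <- synth_config(seed = 29, n_samples = 26, n_mags = 25,
                      block_spec = list(
                        list(members = sprintf("MAG%04d", 1:5), strength = 1),
                        list(members = sprintf("MAG%04d", 6:9), strength = 1)))
  am <- generate_abundance_matrix(cfg)
  net <- build_network(am$abundance, am$groups, "C")
  sc <- net$roles
  # module-degree conservation: sum_t k_it = k_i for every node
  ends <- c(net$edges$a, net$edges$b)
  expect_identical(sc$degree, as.integer(table(ends)[sc$mag_id]))
  expect_true(all(sc$c >= 0 & sc$c < 1))
  # z-scores within each module have mean 0 and sd 1 when sd > 0
  for (m in unique(sc$module_id)) {
    z <- sc$z[sc$module_id == m]
    if (any(z != 0)) {
      expect_equal(mean(z), 0, tolerance = 1e-10)
      expect_equal(sd(z), 1, tolerance = 1e-10)
    }
  }
})

test_that("role classification follows the (z, c) rules", {
  sc <- data.frame(mag_id = c("m1", "m2", "m3", "m4"),
                   module_id = "M01", degree = 5,
                   z = c(3.0, 1.0, 0, 2.6), c = c(0.10, 0.70, 0, 0.70))
  roles <- classify_roles(sc)$role
  expect_identical(roles, c("module_hub", "connector", "peripheral",
                            "network_hub"))
})

test_that("designed hubs and connectors are labelled correctly across seeds", {
  edges <- planted_role_graph()
  for (s in 1:20) {
    part <- detect_modules(edges, seed = s)
    roles <- classify_roles(node_scores(edges, part))
    expect_identical(roles$role[roles$mag_id == "A_hub"], "module_hub")
    expect_identical(roles$role[roles$mag_id == "Xconn"], "connector")
  }
})

test_that("network export round-trips through GraphML and is byte-stable", {
  edges <- data.frame(a = c("M1", "M2", "M1"), b = c("M2", "M3", "M3"),
                      rho = c(0.9, 0.95, 0.99), p_raw = c(1e-5, 1e-6, 1e-7),
                      p_adjusted = c(1e-3, 1e-4, 1e-5))
  part <- detect_modules(edges, seed = 2)
  roles <- classify_roles(node_scores(edges, part))
  d1 <- file.path(tempdir(), "net1"); d2 <- file.path(tempdir(), "net2")
  export_network(edges, roles, d1)
  export_network(edges, roles, d2)
  expect_identical(unname(tools::md5sum(list.files(d1, full.names = TRUE))),
                   unname(tools::md5sum(list.files(d2, full.names = TRUE))))
  g <- igraph::read_graph(file.path(d1, "network.graphml"), format = "graphml")
  back <- igraph::as_data_frame(g, what = "edges")
  expect_setequal(paste(pmin(back$from, back$to), pmax(back$from, back$to)),
                  paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b)))
  nodes <- read.delim(file.path(d1, "nodes.tsv"))
  expect_identical(nodes$mag_id, sort(roles$mag_id))

  empty_dir <- file.path(tempdir(), "net0")
  export_network(edges[0, ], roles[0, ], empty_dir)
  e <- read.delim(file.path(empty_dir, "edges.tsv"))
  expect_identical(nrow(e), 0L)
  expect_identical(names(e), c("source", "target", "rho", "p_adjusted"))
})
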