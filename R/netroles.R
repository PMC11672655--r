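#' Configuration for co-occurrence network construction
#'
#' @param abundance_floor minimum mean relative abundance in the target
#'   segment for a MAG to enter the network (default 0.00005, i.e. 0.005%).
#' @param rho_threshold Spearman correlation threshold for an edge.
#' @param alpha significance level on Bonferroni-corrected p-values.
#' @param sign_mode `"positive_only"` keeps edges with `rho > rho_threshold`;
#'   `"absolute"` keeps `|rho| > rho_threshold`.
#' @param seed integer seed for module detection.
#' @return list of class `network_config`.
#' @export
network_config <- function(abundance_floor = 0.00005, rho_threshold = 0.85,
                           alpha = 0.05,
                           sign_mode = c("positive_only", "absolute"),
                           seed = 7L) {
  sign_mode <- match.arg(sign_mode)
  if (rho_threshold <= 0 || rho_threshold >= 1) {
    stop("rho_threshold must lie in (0, 1)")
  }
  if (abundance_floor < 0) stop("abundance_floor must be >= 0")
  structure(list(abundance_floor = abundance_floor,
                 rho_threshold = rho_threshold, alpha = alpha,
                 sign_mode = sign_mode, seed = as.integer(seed)),
            class = "network_config")
}

#' Select network nodes by mean abundance in one segment
#'
#' Retains MAGs whose mean relative abundance over the samples of the target
#' group strictly exceeds the floor.
#'
#' @param abundance samples x MAGs matrix.
#' @param groups data.frame `sample_id`, `group`.
#' @param group segment label (default `"C"`, the cecum).
#' @param config a [network_config()].
#' @return character vector of retained MAG ids.
#' @export
filter_nodes <- function(abundance, groups, group = "C",
                         config = network_config()) {
  samp <- groups$sample_id[groups$group == group]
  if (length(samp) == 0) stop("no samples with group label '", group, "'")
  means <- colMeans(abundance[samp, , drop = FALSE])
  keep <- names(means)[means > config$abundance_floor]
  if (length(keep) == 0) {
    warning("no MAG exceeds the abundance floor; network is empty")
  }
  keep
}

#' Spearman co-occurrence edges with Bonferroni screening
#'
#' Computes Spearman correlations (average ranks on ties) between all pairs
#' of retained MAGs over the given samples, two-sided p-values from the
#' t-approximation `t = rho * sqrt((n-2) / (1-rho^2))`, and Bonferroni
#' adjustment with multiplier equal to the number of tested pairs
#' `m*(m-1)/2`. An edge is kept when the correlation exceeds the threshold
#' (positive-only or absolute per `sign_mode`) and the adjusted p-value is
#' below `alpha`. Pairs involving a constant abundance vector have undefined
#' correlation and are excluded with a warning.
#'
#' @param abundance samples x MAGs matrix restricted to the target samples.
#' @param config a [network_config()].
#' @return list with `edges` (kept edges: `a`, `b`, `rho`, `p_raw`,
#'   `p_adjusted`), `tested` (all testable pairs with a `kept` flag) and
#'   `n_pairs_tested` (the Bonferroni multiplier).
#' @export
spearman_edges <- function(abundance, config = network_config()) {
  m <- ncol(abundance)
  n <- nrow(abundance)
  if (n < 4) stop("need at least 4 samples for correlation screening")
  if (m < 2) {
    return(list(edges = data.frame(a = character(0), b = character(0),
                                   rho = numeric(0), p_raw = numeric(0),
                                   p_adjusted = numeric(0)),
                tested = data.frame(), n_pairs_tested = 0))
  }
  rho <- suppressWarnings(stats::cor(abundance, method = "spearman"))
  n_pairs <- m * (m - 1) / 2
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  bad <- is.na(r)
  if (any(bad)) {
    warning(sum(bad), " pair(s) with undefined correlation ",
            "(constant abundance vector) excluded")
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_raw <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2))
  p_adj <- pmin(1, p_raw * n_pairs)
  pass_rho <- if (config$sign_mode == "absolute") abs(r) > config$rho_threshold
              else r > config$rho_threshold
  kept <- !bad & pass_rho & p_adj < config$alpha
  tested <- data.frame(a = colnames(abundance)[idx[, 1]],
                       b = colnames(abundance)[idx[, 2]],
                       rho = r, p_raw = p_raw, p_adjusted = p_adj,
                       kept = kept, stringsAsFactors = FALSE)
  tested <- tested[!bad, , drop = FALSE]
  rownames(tested) <- NULL
  list(edges = tested[tested$kept,
                      c("a", "b", "rho", "p_raw", "p_adjusted"),
                      drop = FALSE],
       tested = tested, n_pairs_tested = n_pairs)
}

#' Detect network modules by greedy modularity maximization
#'
#' Louvain community detection on the unweighted kept-edge graph, with the
#' vertex order shuffled once under the seed and then fixed, so the partition
#' is reproducible. Connected components that are singletons under the edge
#' list form their own modules. Module labels are canonicalized in order of
#' each module's smallest member id.
#'
#' @param edges data.frame with columns `a`, `b` (kept edges).
#' @param seed integer seed.
#' @return named character vector MAG id -> module id (e.g. `"M01"`).
#' @export
detect_modules <- function(edges, seed = 7L) {
  if (nrow(edges) == 0) return(setNames(character(0), character(0)))
  nodes <- sort(unique(c(edges$a, edges$b)))
  set.seed(seed)
  order_shuffled <- sample(nodes)
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = order_shuffled))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  member <- igraph::membership(comm)
  smallest <- tapply(names(member), as.integer(member), min)
  ord <- order(smallest)
  relabel <- setNames(sprintf("M%02d", seq_along(ord)),
                      names(smallest)[ord])
  setNames(unname(relabel[as.character(member)]), names(member))[nodes]
}

#' Within-module degree z-score and participation coefficient
#'
#' For node i in module s: `z_i = (k_is - mean(k_.s)) / sd(k_.s)` where
#' `k_is` counts i's links inside s and the mean/sd run over the members of
#' s (z = 0 when the sd is zero); `c_i = 1 - sum_t (k_it / k_i)^2` over the
#' modules t its links reach. Isolated nodes get (z = 0, c = 0) and are
#' flagged.
#'
#' @param edges data.frame with columns `a`, `b`.
#' @param partition named vector MAG id -> module id covering all nodes with
#'   an edge.
#' @return data.frame `mag_id`, `module_id`, `degree`, `z`, `c`, `isolated`.
#' @export
node_scores <- function(edges, partition) {
  nodes <- names(partition)
  ends <- rbind(data.frame(node = edges$a, other = edges$b),
                data.frame(node = edges$b, other = edges$a))
  if (!all(unique(c(edges$a, edges$b)) %in% nodes)) {
    stop("partition must cover every node with at least one edge")
  }
  ends$node_module <- partition[ends$node]
  ends$other_module <- partition[ends$other]
  k <- table(factor(ends$node, levels = nodes))
  # links of each node into each module
  k_im <- table(factor(ends$node, levels = nodes), ends$other_module)
  within <- vapply(nodes, function(v) {
    mod <- partition[[v]]
    if (k[[v]] == 0 || !mod %in% colnames(k_im)) 0
    else as.numeric(k_im[v, mod])
  }, 0)
  z <- numeric(length(nodes))
  for (mod in unique(partition)) {
    members <- nodes[partition == mod]
    w <- within[members]
    s <- stats::sd(w)
    z[match(members, nodes)] <- if (is.na(s) || s == 0) 0 else (w - mean(w)) / s
  }
  cc <- vapply(nodes, function(v) {
    kv <- k[[v]]
    if (kv == 0) return(0)
    1 - sum((k_im[v, ] / kv)^2)
  }, 0)
  data.frame(mag_id = nodes, module_id = unname(partition[nodes]),
             degree = as.integer(k[nodes]), z = z, c = unname(cc),
             isolated = as.integer(k[nodes]) == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify node roles from (z, c) scores
#'
#' Cartographic role taxonomy: module (provincial) hubs have high
#' within-module degree (`z >= z_cut`) and low participation, connectors have
#' high participation (`c > c_cut`) without hub-level within-module degree,
#' network hubs have both, and everything else is peripheral.
#'
#' @param scores data.frame from [node_scores()].
#' @param z_cut within-module degree z-score cutoff (default 2.5).
#' @param c_cut participation-coefficient cutoff (default 0.62).
#' @return `scores` with an added `role` column.
#' @export
classify_roles <- function(scores, z_cut = 2.5, c_cut = 0.62) {
  hub <- scores$z >= z_cut
  conn <- scores$c > c_cut
  scores$role <- ifelse(hub & conn, "network_hub",
                 ifelse(hub, "module_hub",
                 ifelse(conn, "connector", "peripheral")))
  scores
}

#' Build the full co-occurrence network for one segment
#'
#' Convenience wrapper chaining [filter_nodes()], [spearman_edges()],
#' [detect_modules()], [node_scores()] and [classify_roles()].
#'
#' @param abundance samples x MAGs matrix.
#' @param groups data.frame `sample_id`, `group`.
#' @param group segment label.
#' @param config a [network_config()].
#' @param z_cut,c_cut role cutoffs, see [classify_roles()].
#' @return list with `nodes`, `edges`, `partition`, `roles`,
#'   `n_pairs_tested`.
#' @export
build_network <- function(abundance, groups, group = "C",
                          config = network_config(), z_cut = 2.5,
                          c_cut = 0.62) {
  nodes <- filter_nodes(abundance, groups, group, config)
  samp <- groups$sample_id[groups$group == group]
  if (length(nodes) < 2) {
    return(list(nodes = nodes, edges = data.frame(), partition = character(0),
                roles = data.frame(), n_pairs_tested = 0))
  }
  sc <- spearman_edges(abundance[samp, nodes, drop = FALSE], config)
  part <- detect_modules(sc$edges, seed = config$seed)
  roles <- if (nrow(sc$edges)) classify_roles(node_scores(sc$edges, part),
                                              z_cut, c_cut)
           else data.frame()
  list(nodes = nodes, edges = sc$edges, partition = part, roles = roles,
       n_pairs_tested = sc$n_pairs_tested)
}

#' Export a network as edge/node TSVs and GraphML
#'
#' Writes `edges.tsv` (source, target, rho, p_adjusted), `nodes.tsv`
#' (mag_id, module, degree, z, c, role) and `network.graphml` carrying the
#' same attributes. Output is byte-stable for fixed inputs. An empty network
#' produces headers-only TSVs and an empty graph.
#'
#' @param edges kept-edge data.frame.
#' @param roles role table from [classify_roles()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_network <- function(edges, roles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(dir, "edges.tsv")
  node_path <- file.path(dir, "nodes.tsv")
  gml_path <- file.path(dir, "network.graphml")
  edf <- if (nrow(edges)) data.frame(source = edges$a, target = edges$b,
                                     rho = edges$rho,
                                     p_adjusted = edges$p_adjusted)
         else data.frame(source = character(0), target = character(0),
                         rho = numeric(0), p_adjusted = numeric(0))
  write_tsv(edf, edge_path)
  ndf <- if (nrow(roles)) roles[order(roles$mag_id),
                                c("mag_id", "module_id", "degree", "z", "c",
                                  "role")]
         else data.frame(mag_id = character(0), module_id = character(0),
                         degree = integer(0), z = numeric(0), c = numeric(0),
                         role = character(0))
  write_tsv(ndf, node_path)
  g <- igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = if (nrow(ndf)) data.frame(name = ndf$mag_id, ndf[-1])
               else data.frame(name = unique(c(edf$source, edf$target))))
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, nodes = node_path, graphml = gml_path))
}
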