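pipeline_defaults <- function() {
  list(
    seed = 1L,
    synthetic = NULL,
    inputs = NULL,
    catalog = list(min_completeness = 50, max_contamination = 10,
                   ani_threshold = 0.99, min_overlap = 0.30,
                   species_ani = 0.95, k = 16L, sketch_size = 5000L),
    annotate = list(max_evalue = 1e-3, identity_cutoff = 95),
    diffabund = list(group_a = "C", group_b = "DC", alpha = 0.05,
                     n_perm = 999L),
    network = list(abundance_floor = 0.00005, rho_threshold = 0.85,
                   alpha = 0.05, sign_mode = "positive_only",
                   group = "C", z_cut = 2.5, c_cut = 0.62))
}

check_range <- function(value, key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(value) || length(value) != 1 || is.na(value) ||
    (if (lo_open) value <= lo else value < lo) ||
    (if (hi_open) value >= hi else value > hi)
  if (bad) {
    stop(sprintf("%s: must be a number in %s%s, %s%s (got %s)", key,
                 if (lo_open) "(" else "[", format(lo), format(hi),
                 if (hi_open) ")" else "]",
                 paste(format(value), collapse = ",")))
  }
  invisible(value)
}

#' Validate a pipeline configuration
#'
#' Accepts a nested list (or a YAML file path) describing a run: either a
#' `synthetic` block of [synth_config()] parameters or an `inputs` block of
#' file paths, plus optional per-stage overrides. Unknown keys are rejected
#' with their key path; thresholds are range-checked; all defaults are
#' injected explicitly into the returned config so the echoed parameter set
#' is complete.
#'
#' @param raw nested list, or path to a YAML file.
#' @return validated config list of class `run_config` with every default
#'   made explicit.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) {
    if (!file.exists(raw)) stop("config file not found: ", raw)
    raw <- yaml::read_yaml(raw)
    if (is.null(raw)) stop("config file is empty")
  }
  if (!is.list(raw) || length(raw) == 0) stop("config must be a non-empty list")
  cfg <- pipeline_defaults()
  known_top <- names(cfg)
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (blk in intersect(names(raw), c("catalog", "annotate", "diffabund",
                                      "network"))) {
    extra <- setdiff(names(raw[[blk]]), names(cfg[[blk]]))
    if (length(extra)) stop("unknown config key(s): ",
                            paste(paste0(blk, ".", extra), collapse = ", "))
    cfg[[blk]][names(raw[[blk]])] <- raw[[blk]]
  }
  for (key in intersect(names(raw), c("seed", "synthetic", "inputs"))) {
    cfg[[key]] <- raw[[key]]
  }
  if (is.null(cfg$synthetic) && is.null(cfg$inputs)) {
    stop("config needs either a 'synthetic' block or an 'inputs' block")
  }
  check_range(cfg$catalog$min_completeness, "catalog.min_completeness", 0, 100)
  check_range(cfg$catalog$max_contamination, "catalog.max_contamination", 0, 100)
  check_range(cfg$catalog$ani_threshold, "catalog.ani_threshold", 0, 1,
              lo_open = TRUE)
  check_range(cfg$catalog$min_overlap, "catalog.min_overlap", 0, 1)
  check_range(cfg$catalog$species_ani, "catalog.species_ani", 0, 1)
  check_range(cfg$annotate$max_evalue, "annotate.max_evalue", 0, 1)
  check_range(cfg$annotate$identity_cutoff, "annotate.identity_cutoff", 0, 100)
  check_range(cfg$diffabund$alpha, "diffabund.alpha", 0, 1, TRUE, TRUE)
  check_range(cfg$network$rho_threshold, "network.rho_threshold", 0, 1,
              TRUE, TRUE)
  check_range(cfg$network$alpha, "network.alpha", 0, 1, TRUE, TRUE)
  check_range(cfg$network$abundance_floor, "network.abundance_floor", 0, 1)
  if (!cfg$network$sign_mode %in% c("positive_only", "absolute")) {
    stop("network.sign_mode: must be 'positive_only' or 'absolute'")
  }
  class(cfg) <- "run_config"
  cfg
}

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(paths))
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes, in dependency order: synthetic-data generation (when a
#' `synthetic` block is present), MAG quality filtering + dereplication +
#' novelty calling, hit-table best-hit filtering + CAZyme summaries,
#' diversity / ordination / PERMANOVA / paired differential abundance, and
#' co-occurrence network construction with node-role classification. Stages
#' whose inputs are absent are skipped and recorded as such. All outputs are
#' written under `outdir`; a machine-readable report (parameters, per-stage
#' output hashes and headline counts) is written to `outdir/report.json` and
#' returned. Identical config and seed give identical output hashes.
#'
#' @param config a `run_config` from [validate_config()] (or a raw list /
#'   YAML path, validated on the way in).
#' @param outdir output directory.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = unclass(cfg), stages = list())
  master <- cfg$seed

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      file.create(file.path(outdir, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  data_dir <- file.path(outdir, "data")
  genomes <- hits <- ab <- groups <- NULL
  if (!is.null(cfg$synthetic)) {
    run_stage("synthgut", function() {
      sc <- do.call(synth_config,
                    c(cfg$synthetic[setdiff(names(cfg$synthetic),
                                            c("n_hit_records", "frac_known"))],
                      list(seed = master)))
      gs <- generate_genome_set(sc)
      genomes <<- gs$genomes
      dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
      write_genome_set(genomes, file.path(data_dir, "genomes"))
      n_hits <- cfg$synthetic$n_hit_records %||% 20000L
      hit_tab <- generate_hit_table(
        n_hits, frac_known = cfg$synthetic$frac_known %||% 0.003,
        seed = master, n_mags = length(genomes) * 10L)
      write_hit_table(hit_tab, file.path(data_dir, "hits.tsv"))
      hits <<- hit_tab
      am <- generate_abundance_matrix(sc)
      ab <<- am$abundance
      groups <<- am$groups
      write_abundance(ab, file.path(data_dir, "abundance.tsv"))
      write_groups(groups, file.path(data_dir, "groups.tsv"))
      jsonlite::write_json(c(list(clusters = as.list(gs$clusters)), am$truth),
                           file.path(data_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$synthgut <<- list(
        status = "ok", seed = master,
        outputs = hash_files(c(
          list.files(file.path(data_dir, "genomes"), full.names = TRUE),
          file.path(data_dir, c("hits.tsv", "abundance.tsv", "groups.tsv",
                                "truth.json")))),
        counts = list(n_genomes = length(genomes), n_hits = nrow(hit_tab),
                      n_samples = nrow(ab)))
    })
  } else {
    inp <- cfg$inputs
    if (!is.null(inp$genomes)) {
      genomes <- read_genome_set(inp$genomes,
                                 inp$quality %||%
                                   file.path(inp$genomes, "quality.tsv"))
    }
    if (!is.null(inp$hits)) hits <- read_hit_table(inp$hits)
    if (!is.null(inp$abundance)) ab <- read_abundance(inp$abundance)
    if (!is.null(inp$groups)) groups <- read_groups(inp$groups)
  }

  if (!is.null(genomes)) {
    run_stage("catalog", function() {
      p <- cfg$catalog
      qf <- quality_filter(genomes, p$min_completeness, p$max_contamination)
      der <- dereplicate(qf$retained, p$ani_threshold, p$min_overlap,
                         k = p$k, sketch_size = p$sketch_size)
      reps <- genomes[der$representatives]
      nov <- call_novelty(reps, list(), species_ani = p$species_ani,
                          min_overlap = p$min_overlap, k = p$k,
                          sketch_size = p$sketch_size)
      summ <- summarize_catalog(der, nov, qf$retained,
                                n_input = length(genomes))
      cat_dir <- file.path(outdir, "catalog")
      dir.create(cat_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(data.frame(mag_id = names(der$clusters),
                           cluster_id = unname(der$clusters),
                           representative = names(der$clusters) %in%
                             der$representatives,
                           score = unname(der$scores[names(der$clusters)])),
                file.path(cat_dir, "clusters.tsv"))
      write_tsv(nov, file.path(cat_dir, "novelty.tsv"))
      jsonlite::write_json(unclass(summ), file.path(cat_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$catalog <<- list(
        status = "ok",
        outputs = hash_files(file.path(cat_dir, c("clusters.tsv",
                                                  "novelty.tsv",
                                                  "summary.json"))),
        counts = list(n_input = summ$n_input, n_retained = summ$n_retained,
                      n_clusters = summ$n_clusters, n_novel = summ$n_novel))
    })
  } else {
    report$stages$catalog <- list(status = "skipped",
                                  reason = "no genome input")
  }

  if (!is.null(hits)) {
    run_stage("annotate", function() {
      p <- cfg$annotate
      best <- filter_best_hits(hits, p$max_evalue)
      dist <- class_distribution(best)
      nov <- novelty_summary(best, p$identity_cutoff)
      ann_dir <- file.path(outdir, "annotate")
      dir.create(ann_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(dist$table, file.path(ann_dir, "class_distribution.tsv"))
      jsonlite::write_json(unclass(nov), file.path(ann_dir, "novelty.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$annotate <<- list(
        status = "ok",
        outputs = hash_files(file.path(ann_dir, c("class_distribution.tsv",
                                                  "novelty.json"))),
        counts = list(n_best_hits = nrow(best), n_known = nov$known,
                      n_novel = nov$novel,
                      mean_identity = nov$mean_identity))
    })
  } else {
    report$stages$annotate <- list(status = "skipped",
                                   reason = "no hit-table input")
  }

  if (!is.null(ab) && !is.null(groups)) {
    run_stage("diffabund", function() {
      p <- cfg$diffabund
      div_dir <- file.path(outdir, "diffabund")
      dir.create(div_dir, showWarnings = FALSE, recursive = TRUE)
      div <- t(apply(ab, 1, alpha_diversity))
      write_tsv(data.frame(sample_id = rownames(div), div),
                file.path(div_dir, "alpha_diversity.tsv"))
      bc <- bray_curtis(ab)
      ord <- pcoa(bc)
      write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                           ord$coordinates,
                           group = groups$group[match(rownames(ord$coordinates),
                                                      groups$sample_id)]),
                file.path(div_dir, "ordination.tsv"))
      sel <- groups$group %in% c(p$group_a, p$group_b)
      perm <- permanova(bc[groups$sample_id[sel], groups$sample_id[sel]],
                        groups$group[sel], n_perm = p$n_perm,
                        seed = derive_seed(master, "permanova"))
      diff <- differential_mags(ab, groups, p$group_a, p$group_b, p$alpha)
      write_tsv(diff, file.path(div_dir, "differential.tsv"))
      jsonlite::write_json(perm, file.path(div_dir, "permanova.json"),
                           auto_unbox = TRUE, digits = NA)
      up_a <- sum(diff$significant_t &
                    diff$direction == paste0("higher_in_", p$group_a))
      up_b <- sum(diff$significant_t &
                    diff$direction == paste0("higher_in_", p$group_b))
      t_only <- sum(diff$significant_t & !diff$significant_mw)
      report$stages$diffabund <<- list(
        status = "ok",
        outputs = hash_files(file.path(div_dir,
                                       c("alpha_diversity.tsv",
                                         "ordination.tsv", "differential.tsv",
                                         "permanova.json"))),
        counts = list(permanova_p = perm$p_value, pseudo_F = perm$pseudo_F,
                      n_sig_t_higher_a = up_a, n_sig_t_higher_b = up_b,
                      n_sig_t_only = t_only))
    })
  } else {
    report$stages$diffabund <- list(status = "skipped",
                                    reason = "no abundance/groups input")
  }

  if (!is.null(ab) && !is.null(groups)) {
    run_stage("netroles", function() {
      p <- cfg$network
      ncfg <- network_config(p$abundance_floor, p$rho_threshold, p$alpha,
                             p$sign_mode,
                             seed = derive_seed(master, "netroles"))
      net <- build_network(ab, groups, p$group, ncfg, p$z_cut, p$c_cut)
      net_dir <- file.path(outdir, "network")
      export_network(if (nrow(as.data.frame(net$edges))) net$edges
                     else data.frame(a = character(0), b = character(0),
                                     rho = numeric(0),
                                     p_adjusted = numeric(0)),
                     net$roles, net_dir)
      report$stages$netroles <<- list(
        status = "ok",
        outputs = hash_files(file.path(net_dir, c("edges.tsv", "nodes.tsv",
                                                  "network.graphml"))),
        counts = list(n_nodes = length(net$nodes),
                      n_edges = nrow(as.data.frame(net$edges)),
                      n_modules = length(unique(net$partition)),
                      roles = if (nrow(as.data.frame(net$roles)))
                        as.list(table(net$roles$role)) else list()))
    })
  } else {
    report$stages$netroles <- list(status = "skipped",
                                   reason = "no abundance/groups input")
  }

  report$wall <- list(finished = format(Sys.time(), tz = "UTC"),
                      r_version = as.character(getRversion()))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the shipped synthetic demo fixture and run everything
#'
#' A compact end-to-end demonstration: three planted genome clusters, a
#' bimodal hit table, and an abundance matrix with two planted
#' co-occurrence blocks and planted cecum/dorsal-colon shifts.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return the run report, invisibly.
#' @export
run_demo <- function(outdir, seed = 1L) {
  config <- list(
    seed = as.integer(seed),
    synthetic = list(
      n_clusters = 3L, genomes_per_cluster = 3L, genome_length = 30000L,
      within_divergence = 0.0025, n_samples = 26L, n_mags = 60L,
      noise_sd = 0.3, n_hit_records = 20000L, frac_known = 0.003,
      block_spec = list(
        list(members = sprintf("MAG%04d", 1:5), strength = 1.0),
        list(members = sprintf("MAG%04d", 11:14), strength = 0.95)),
      group_effects = lapply(sprintf("MAG%04d", 21:30), function(m)
        list(mag = m, group = "C", lfc = 1.5))))
  run_pipeline(validate_config(config), outdir)
}
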