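#' Synthetic hindgut-metagenome fixtures with planted structure
#'
#' `synth_config()` bundles the parameters of the synthetic-data generator.
#' The generator emulates the three downstream inputs of a hindgut MAG study:
#' genome bins with controlled pairwise ANI, protein best-hit tables with a
#' bimodal (known vs novel) identity distribution, and relative-abundance
#' matrices over the cecum (C), ventral colon (VC) and dorsal colon (DC)
#' segments with planted correlated MAG blocks and segment-specific shifts.
#' Every artifact draws from its own RNG stream derived from the master seed,
#' so regenerating one artifact never perturbs another.
#'
#' @param seed master integer seed; fixed seed implies byte-identical outputs.
#' @param n_clusters number of planted species clusters.
#' @param genomes_per_cluster MAGs per cluster.
#' @param genome_length genome length in bp.
#' @param within_divergence per-site substitution probability applied
#'   independently to each cluster member relative to its cluster ancestor;
#'   a within-cluster pair therefore carries two independent mutation loads.
#' @param between_divergence per-site substitution probability separating each
#'   cluster ancestor from a common root sequence.
#' @param n_contigs contigs each genome is split into.
#' @param n_samples number of subjects (donkeys); each contributes one sample
#'   per hindgut segment (C, VC, DC).
#' @param n_mags number of MAG columns in the abundance matrix.
#' @param block_spec list of planted co-occurrence blocks, each a list with
#'   `members` (MAG ids) and `strength` in `[0, 1]`; a block shares a latent
#'   Gaussian factor on the log scale, giving pairwise correlation
#'   `strength^2` (strength 1 means a deterministic shared factor).
#' @param group_effects list of planted differential shifts, each a list with
#'   `mag`, `group` (one of C/VC/DC) and `lfc`, a natural-log fold shift.
#' @param noise_sd log-scale sample noise standard deviation.
#' @param completeness_range,contamination_range uniform sampling ranges for
#'   the per-MAG quality values.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_clusters = 3L,
                         genomes_per_cluster = 3L,
                         genome_length = 50000L,
                         within_divergence = 0.005,
                         between_divergence = 0.10,
                         n_contigs = 5L,
                         n_samples = 8L,
                         n_mags = 60L,
                         block_spec = list(),
                         group_effects = list(),
                         noise_sd = 1,
                         completeness_range = c(50, 100),
                         contamination_range = c(0, 10)) {
  cfg <- list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
              genomes_per_cluster = as.integer(genomes_per_cluster),
              genome_length = as.integer(genome_length),
              within_divergence = within_divergence,
              between_divergence = between_divergence,
              n_contigs = as.integer(n_contigs),
              n_samples = as.integer(n_samples), n_mags = as.integer(n_mags),
              block_spec = block_spec, group_effects = group_effects,
              noise_sd = noise_sd,
              completeness_range = completeness_range,
              contamination_range = contamination_range)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_clusters < 1L) stop("n_clusters must be >= 1")
  if (cfg$genomes_per_cluster < 1L) stop("genomes_per_cluster must be >= 1")
  if (cfg$genome_length < 16L) {
    stop("genome_length must be at least the k-mer size (16 bp)")
  }
  for (d in c(cfg$within_divergence, cfg$between_divergence)) {
    if (!is.numeric(d) || d < 0 || d >= 0.75) {
      stop("divergences must lie in [0, 0.75)")
    }
  }
  if (cfg$n_samples < 4L) stop("n_samples must be >= 4")
  members <- unlist(lapply(cfg$block_spec, `[[`, "members"))
  if (anyDuplicated(members)) stop("block members must be disjoint")
  invisible(cfg)
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-site substitution (no indels), so alignment identity of a mutated pair
# equals 1 minus the observed substitution fraction.
mutate_sequence <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < divergence)
  if (length(hit)) {
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    bases[hit] <- alt[cbind(pick, match(bases[hit], colnames(alt)))]
  }
  paste(bases, collapse = "")
}

split_contigs <- function(seq, n_contigs) {
  n <- nchar(seq)
  if (n_contigs <= 1L || n < 2L * n_contigs) return(seq)
  cuts <- sort(sample(seq_len(n - 1L), n_contigs - 1L))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  substring(seq, starts, ends)
}

#' One MAG: contigs plus quality estimates
#'
#' @param mag_id identifier.
#' @param contigs character vector of contig sequences.
#' @param completeness,contamination CheckM-style quality percentages.
#' @return `genome_record` with derived `total_length` and `n50`.
#' @export
genome_record <- function(mag_id, contigs, completeness, contamination) {
  stopifnot(length(contigs) >= 1, all(nchar(contigs) > 0))
  if (completeness < 0 || completeness > 100) stop("completeness out of [0,100]")
  if (contamination < 0) stop("contamination must be >= 0")
  structure(list(mag_id = mag_id, contigs = contigs,
                 completeness = completeness, contamination = contamination,
                 total_length = sum(nchar(contigs)),
                 n50 = compute_n50(nchar(contigs))),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s: %d contigs, %d bp, N50 %d, comp %.1f%%, cont %.1f%%>\n",
              x$mag_id, length(x$contigs), x$total_length, x$n50,
              x$completeness, x$contamination))
  invisible(x)
}

#' Generate a genome set with planted ANI clusters
#'
#' Each cluster descends from one ancestor sequence: the ancestors themselves
#' are independent `between_divergence` mutants of a common root, and each
#' member is an independent `within_divergence` mutant of its cluster
#' ancestor. With the defaults, within-cluster pairs sit near 99% identity and
#' between-cluster pairs well below 95%, mirroring strain-level vs
#' species-level separation.
#'
#' @param config a [synth_config()].
#' @return list with `genomes` (named list of [genome_record()]) and
#'   `clusters` (named character vector of planted cluster labels).
#' @export
generate_genome_set <- function(config) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "genomes"))
  root <- random_sequence(config$genome_length)
  genomes <- list()
  clusters <- character(0)
  idx <- 0L
  for (ci in seq_len(config$n_clusters)) {
    ancestor <- mutate_sequence(root, config$between_divergence)
    for (gi in seq_len(config$genomes_per_cluster)) {
      idx <- idx + 1L
      mag_id <- sprintf("MAG%04d", idx)
      member <- mutate_sequence(ancestor, config$within_divergence)
      contigs <- split_contigs(member, config$n_contigs)
      genomes[[mag_id]] <- genome_record(
        mag_id, contigs,
        completeness = runif(1, config$completeness_range[1],
                             config$completeness_range[2]),
        contamination = runif(1, config$contamination_range[1],
                              config$contamination_range[2]))
      clusters[mag_id] <- sprintf("cluster%02d", ci)
    }
  }
  list(genomes = genomes, clusters = clusters)
}

# inverse-CDF truncated normal; exact given the uniform draw
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Default CAZy class proportions for synthetic hit tables
#'
#' Shares of the six carbohydrate-active-enzyme classes (glycoside hydrolases,
#' glycosyl transferases, carbohydrate-binding modules, carbohydrate
#' esterases, auxiliary activities, polysaccharide lyases) used by
#' [generate_hit_table()] unless overridden.
#' @export
default_class_probs <- c(GH = 0.4118, GT = 0.3662, CBM = 0.1361,
                         CE = 0.0559, AA = 0.0171, PL = 0.0129)

#' Generate a best-hit table with bimodal identity structure
#'
#' Emulates DIAMOND-style best hits of predicted proteins against a CAZyme or
#' PUL database in which a small "known" fraction matches at high identity
#' (truncated normal, ceiling 100) while the bulk is "novel" at low identity
#' (truncated normal, floor 20). All e-values pass the 1e-3 screen.
#'
#' @param n_records total number of hit records.
#' @param frac_known fraction drawn from the known (high-identity) stratum;
#'   exactly `round(n_records * frac_known)` records.
#' @param known_identity_mean,known_sd known-stratum identity mean / sd (%).
#' @param novel_identity_mean,novel_sd novel-stratum identity mean / sd (%).
#' @param seed integer seed.
#' @param class_probs named class-proportion table for family labels.
#' @param n_mags number of MAGs queries are attributed to.
#' @return data.frame of hit records (`query_id`, `mag_id`, `family`,
#'   `subject_id`, `percent_identity`, `evalue`, `bitscore`,
#'   `planted_known`).
#' @export
generate_hit_table <- function(n_records, frac_known = 0.003,
                               known_identity_mean = 97,
                               novel_identity_mean = 41,
                               seed = 1L,
                               known_sd = 1, novel_sd = 8,
                               class_probs = default_class_probs,
                               n_mags = 50L) {
  if (n_records < 0) stop("n_records must be non-negative")
  if (frac_known < 0 || frac_known > 1) stop("frac_known must be in [0, 1]")
  set.seed(derive_seed(seed, "hits"))
  n_known <- round(n_records * frac_known)
  n_novel <- n_records - n_known
  ident <- c(rtruncnorm(n_known, known_identity_mean, known_sd, upper = 100),
             rtruncnorm(n_novel, novel_identity_mean, novel_sd,
                        lower = 20, upper = 100))
  planted <- rep(c(TRUE, FALSE), c(n_known, n_novel))
  ord <- sample.int(n_records)
  ident <- ident[ord]; planted <- planted[ord]
  cls <- sample(names(class_probs), n_records, replace = TRUE,
                prob = class_probs)
  fam_num <- sample.int(120L, n_records, replace = TRUE)
  sub_fam <- ifelse(runif(n_records) < 0.1,
                    sprintf("_%d", sample.int(5L, n_records, replace = TRUE)),
                    "")
  family <- paste0(cls, fam_num, sub_fam)
  mag <- sprintf("MAG%04d", sample.int(n_mags, n_records, replace = TRUE))
  data.frame(
    query_id = sprintf("%s|prot_%06d", mag, seq_len(n_records)),
    mag_id = mag,
    family = family,
    subject_id = sprintf("%s|ref%06d", family,
                         sample.int(999999L, n_records, replace = TRUE)),
    percent_identity = round(ident, 2),
    evalue = signif(10^(-runif(n_records, 5, 50)), 3),
    bitscore = round(50 + ident * 5, 1),
    planted_known = planted,
    stringsAsFactors = FALSE)
}

#' Generate a relative-abundance matrix with planted structure
#'
#' Base abundances are log-normal. MAGs listed in a block share a latent
#' per-sample Gaussian factor weighted by the block strength `s`, with the
#' residual noise scaled by `sqrt(1 - s^2)` so every log-abundance keeps unit
#' variance and within-block pairs have correlation `s^2` (Gaussian-copula
#' construction, preserving Spearman structure under the log-normal
#' marginal). Group effects add natural-log fold shifts to designated MAGs in
#' designated segments. Rows are renormalized to sum to one.
#'
#' @param config a [synth_config()].
#' @return list with `abundance` (samples x MAGs matrix of relative
#'   abundances), `groups` (data.frame `sample_id`, `group`, `donkey_id`) and
#'   `truth` (planted block memberships and shifted MAGs).
#' @export
generate_abundance_matrix <- function(config) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "abundance"))
  mags <- sprintf("MAG%04d", seq_len(config$n_mags))
  groups <- c("C", "VC", "DC")
  samples <- as.vector(outer(groups, seq_len(config$n_samples),
                             function(g, d) sprintf("D%02d_%s", d, g)))
  meta <- data.frame(
    sample_id = samples,
    group = rep(groups, times = config$n_samples),
    donkey_id = sprintf("D%02d", rep(seq_len(config$n_samples), each = 3)),
    stringsAsFactors = FALSE)
  n_s <- nrow(meta)

  for (b in config$block_spec) {
    if (!all(b$members %in% mags)) {
      stop("block references unknown MAG id: ",
           paste(setdiff(b$members, mags), collapse = ", "))
    }
  }
  mu <- rnorm(config$n_mags, mean = 0, sd = 1)
  eps <- matrix(rnorm(n_s * config$n_mags, 0, config$noise_sd),
                n_s, config$n_mags)
  loga <- sweep(eps, 2, mu, `+`)
  dimnames(loga) <- list(meta$sample_id, mags)
  for (b in config$block_spec) {
    s <- b$strength
    f <- rnorm(n_s)
    j <- match(b$members, mags)
    loga[, j] <- sweep(sqrt(1 - s^2) * eps[, j, drop = FALSE] +
                         outer(s * f, rep(1, length(j))),
                       2, mu[j], `+`)
  }
  for (ge in config$group_effects) {
    if (!ge$mag %in% mags) stop("group effect references unknown MAG id: ", ge$mag)
    rows <- meta$group == ge$group
    loga[rows, ge$mag] <- loga[rows, ge$mag] + ge$lfc
  }
  ab <- exp(loga)
  ab <- ab / rowSums(ab)
  list(abundance = ab, groups = meta,
       truth = list(
         blocks = lapply(config$block_spec, function(b)
           list(members = b$members, strength = b$strength)),
         shifted = lapply(config$group_effects, function(ge)
           list(mag = ge$mag, group = ge$group, lfc = ge$lfc))))
}
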