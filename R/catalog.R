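#' Contig N50
#'
#' The smallest contig length L such that contigs of length >= L cover at
#' least half of the total assembly length.
#'
#' @param contig_lengths numeric vector of contig lengths in bp.
#' @return N50 in bp.
#' @export
#' @examples
#' compute_n50(c(80, 70, 50, 30, 20)) # 70
compute_n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0) stop("contig_lengths must be non-empty")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  len <- sort(contig_lengths, decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1]]
}

#' Quality-filter MAGs on completeness and contamination
#'
#' Retains genomes with completeness >= `min_completeness` and contamination
#' <= `max_contamination` (inclusive boundaries by default; set
#' `strict = TRUE` for strict inequalities).
#'
#' @param genomes named list of [genome_record()].
#' @param min_completeness,max_contamination percentage thresholds.
#' @param strict use strict inequalities at the boundaries.
#' @return list with `retained` (named list of genomes) and `rejections`
#'   (data.frame `mag_id`, `completeness`, `contamination`, `reason`).
#' @export
quality_filter <- function(genomes, min_completeness = 50,
                           max_contamination = 10, strict = FALSE) {
  for (g in genomes) {
    if (is.null(g$completeness) || is.null(g$contamination) ||
        is.na(g$completeness) || is.na(g$contamination)) {
      stop("missing quality values for MAG ", g$mag_id)
    }
  }
  comp_ok <- function(x) if (strict) x > min_completeness else x >= min_completeness
  cont_ok <- function(x) if (strict) x < max_contamination else x <= max_contamination
  keep <- vapply(genomes, function(g) comp_ok(g$completeness) && cont_ok(g$contamination),
                 logical(1))
  rej <- genomes[!keep]
  rejections <- data.frame(
    mag_id = vapply(rej, `[[`, "", "mag_id"),
    completeness = vapply(rej, `[[`, 0, "completeness"),
    contamination = vapply(rej, `[[`, 0, "contamination"),
    reason = vapply(rej, function(g) {
      r <- character(0)
      if (!comp_ok(g$completeness)) r <- c(r, "low_completeness")
      if (!cont_ok(g$contamination)) r <- c(r, "high_contamination")
      paste(r, collapse = ";")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  list(retained = genomes[keep], rejections = rejections)
}

genome_hashes <- function(g, k = 16) {
  if (max(nchar(g$contigs)) < k) {
    stop("genome ", g$mag_id, " has no contig of length >= k = ", k)
  }
  kmer_hash_set(g$contigs, as.integer(k))
}

#' MinHash ANI estimate between two genomes
#'
#' Computes the Jaccard similarity J of bottom-sketch MinHash signatures over
#' canonical k-mers and converts it via the Mash distance
#' D = -(1/k) * ln(2J / (1 + J)) to an average nucleotide identity
#' ANI = 1 - D, clamped to `[0, 1]`. The aligned-fraction proxy is the
#' containment of the full k-mer sets relative to the smaller genome,
#' standing in for alignment-based genome overlap. No shared k-mers in the
#' sketch union gives an undefined (NA) ANI.
#'
#' @param a,b [genome_record()] objects.
#' @param k k-mer size.
#' @param sketch_size bottom-sketch size.
#' @return list of class `ani_result`: `ani` (fraction or NA),
#'   `aligned_fraction`, `jaccard`.
#' @export
estimate_ani <- function(a, b, k = 16, sketch_size = 5000) {
  ha <- genome_hashes(a, k)
  hb <- genome_hashes(b, k)
  sa <- head(ha, sketch_size)
  sb <- head(hb, sketch_size)
  # bottom-s sketch of the union, per the Mash estimator
  u <- sort(unique(c(sa, sb)))
  s <- min(sketch_size, length(u))
  u <- u[seq_len(s)]
  shared <- sum(u %in% sa & u %in% sb)
  j <- shared / s
  ani <- if (shared == 0) NA_real_ else {
    d <- -(1 / k) * log(2 * j / (1 + j))
    min(max(1 - d, 0), 1)
  }
  af <- sorted_intersect_size(ha, hb) / min(length(ha), length(hb))
  structure(list(ani = ani, aligned_fraction = af, jaccard = j),
            class = "ani_result")
}

#' Global-alignment identity oracle
#'
#' Identity of the optimal global (Needleman-Wunsch) alignment of two
#' nucleotide sequences, scored with match +1 / mismatch 0 and affine gap
#' penalties, reported as matches per alignment column. Quadratic in sequence
#' length, so inputs are capped at 100 kb; use [estimate_ani()] beyond that.
#'
#' @param a,b nucleotide sequence strings (<= 100 kb each).
#' @return alignment identity as a fraction in `[0, 1]`.
#' @export
ani_oracle <- function(a, b) {
  if (nchar(a) > 1e5 || nchar(b) > 1e5) {
    stop("sequences exceed 100 kb; use estimate_ani() for genome-scale input")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Windowed alignment-identity oracle for genome-scale pairs
#'
#' Averages [ani_oracle()] identity over matched windows sampled along a pair
#' of equal-coordinate genomes (valid for the substitution-only synthetic
#' model, where coordinates stay aligned).
#'
#' @param a,b full genome sequence strings.
#' @param window window width in bp.
#' @param n_windows number of windows, evenly spaced.
#' @return mean window identity.
#' @export
ani_oracle_windows <- function(a, b, window = 2000L, n_windows = 10L) {
  n <- min(nchar(a), nchar(b))
  window <- min(window, n)
  starts <- unique(round(seq(1, n - window + 1, length.out = n_windows)))
  ids <- vapply(starts, function(s) {
    ani_oracle(substr(a, s, s + window - 1L), substr(b, s, s + window - 1L))
  }, 0)
  mean(ids)
}

mag_score <- function(g) g$completeness - 5 * g$contamination

#' Dereplicate a quality-filtered genome set at an ANI threshold
#'
#' Builds a graph with an edge between two MAGs when estimated ANI >=
#' `ani_threshold` and the aligned-fraction proxy >= `min_overlap`, takes
#' connected components as clusters (single linkage), and picks per cluster
#' the representative maximizing `completeness - 5 * contamination`, breaking
#' ties by larger total length and then lexicographic MAG id.
#'
#' @param genomes named list of [genome_record()] (already quality-filtered).
#' @param ani_threshold ANI clustering threshold (default 0.99).
#' @param min_overlap minimum aligned fraction (default 0.30).
#' @param k,sketch_size passed to [estimate_ani()].
#' @return list of class `derep_result`: `clusters` (named character vector
#'   mag_id -> cluster id), `representatives` (cluster id -> mag_id),
#'   `scores` (per-MAG selection score), `members` (list of cluster member
#'   ids), `ani` (pairwise ANI data.frame).
#' @export
dereplicate <- function(genomes, ani_threshold = 0.99, min_overlap = 0.30,
                        k = 16, sketch_size = 5000) {
  ids <- names(genomes)
  n <- length(ids)
  if (n == 0) {
    return(structure(list(clusters = setNames(character(0), character(0)),
                          representatives = character(0),
                          scores = numeric(0), members = list(),
                          ani = data.frame()),
                     class = "derep_result"))
  }
  hashes <- lapply(genomes, genome_hashes, k = k)
  pairs <- if (n > 1) utils::combn(n, 2) else matrix(nrow = 2, ncol = 0)
  ani_tab <- data.frame(a = character(0), b = character(0),
                        ani = numeric(0), aligned_fraction = numeric(0))
  edges <- matrix(character(0), ncol = 2)
  if (ncol(pairs) > 0) {
    res <- apply(pairs, 2, function(p) {
      ha <- hashes[[p[1]]]; hb <- hashes[[p[2]]]
      sa <- head(ha, sketch_size); sb <- head(hb, sketch_size)
      u <- sort(unique(c(sa, sb)))
      s <- min(sketch_size, length(u))
      u <- u[seq_len(s)]
      shared <- sum(u %in% sa & u %in% sb)
      j <- shared / s
      ani <- if (shared == 0) NA_real_ else
        min(max(1 + (1 / k) * log(2 * j / (1 + j)), 0), 1)
      af <- sorted_intersect_size(ha, hb) / min(length(ha), length(hb))
      c(ani = ani, af = af)
    })
    ani_tab <- data.frame(a = ids[pairs[1, ]], b = ids[pairs[2, ]],
                          ani = res["ani", ], aligned_fraction = res["af", ],
                          stringsAsFactors = FALSE)
    hit <- !is.na(ani_tab$ani) & ani_tab$ani >= ani_threshold &
      ani_tab$aligned_fraction >= min_overlap
    edges <- as.matrix(ani_tab[hit, c("a", "b")])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  # canonical cluster ids ordered by smallest member
  first <- tapply(names(comp), comp, min)
  relabel <- setNames(sprintf("C%03d", seq_along(sort(first))),
                      names(sort(first)))
  clusters <- setNames(relabel[as.character(comp)], names(comp))[ids]
  scores <- vapply(genomes, mag_score, 0)
  members <- split(ids, clusters)
  reps <- vapply(members, function(m) {
    sc <- scores[m]
    len <- vapply(genomes[m], `[[`, 0, "total_length")
    m[order(-sc, -len, m)][1]
  }, "")
  structure(list(clusters = clusters, representatives = reps,
                 scores = scores, members = members, ani = ani_tab),
            class = "derep_result")
}

#' Call species-level novelty of MAGs against a reference set
#'
#' A MAG is novel when its best ANI against any reference meeting the overlap
#' requirement is below `species_ani` (default 0.95) or undefined — including
#' when the reference set is empty.
#'
#' @param mags named list of [genome_record()].
#' @param references named list of reference [genome_record()] (may be empty).
#' @param species_ani species delineation threshold.
#' @param min_overlap minimum aligned fraction for a reference to count.
#' @param k,sketch_size passed to [estimate_ani()].
#' @return data.frame (`mag_id`, `best_reference`, `best_ani`, `novel`).
#' @export
call_novelty <- function(mags, references, species_ani = 0.95,
                         min_overlap = 0.30, k = 16, sketch_size = 5000) {
  rows <- lapply(mags, function(m) {
    best_ref <- NA_character_
    best_ani <- NA_real_
    for (rid in names(references)) {
      r <- estimate_ani(m, references[[rid]], k = k, sketch_size = sketch_size)
      if (!is.na(r$ani) && r$aligned_fraction >= min_overlap &&
          (is.na(best_ani) || r$ani > best_ani)) {
        best_ani <- r$ani
        best_ref <- rid
      }
    }
    data.frame(mag_id = m$mag_id, best_reference = best_ref,
               best_ani = best_ani,
               novel = is.na(best_ani) || best_ani < species_ani,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarize a dereplicated catalog
#'
#' @param derep a `derep_result` from [dereplicate()].
#' @param novelty data.frame from [call_novelty()] over the representatives.
#' @param genomes named list of [genome_record()] backing the result.
#' @param n_input number of genomes before quality filtering (optional).
#' @return list of class `catalog_summary` with counts, length and N50
#'   ranges, and the novel percentage (`novel_pct` two decimals,
#'   `novel_pct_headline` rounded to the nearest integer).
#' @export
summarize_catalog <- function(derep, novelty, genomes,
                              n_input = length(genomes)) {
  n_clusters <- length(derep$representatives)
  n_novel <- if (nrow(novelty)) sum(novelty$novel) else 0L
  lens <- vapply(genomes, `[[`, 0, "total_length")
  n50s <- vapply(genomes, `[[`, 0, "n50")
  pct <- if (n_clusters > 0) 100 * n_novel / n_clusters else 0
  structure(list(
    n_input = n_input,
    n_retained = length(genomes),
    n_clusters = n_clusters,
    length_min = min(lens), length_mean = mean(lens), length_max = max(lens),
    n50_min = min(n50s), n50_max = max(n50s),
    n_novel = n_novel,
    novel_pct = round(pct, 2),
    novel_pct_headline = round(pct)),
    class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf(paste0("MAG catalog: %d input, %d retained, %d non-redundant clusters\n",
                     "  length %.2f-%.2f Mb (mean %.2f), N50 %d-%d bp\n",
                     "  novel species: %d (%d%%)\n"),
              x$n_input, x$n_retained, x$n_clusters,
              x$length_min / 1e6, x$length_max / 1e6, x$length_mean / 1e6,
              x$n50_min, x$n50_max, x$n_novel, x$novel_pct_headline))
  invisible(x)
}
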