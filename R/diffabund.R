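#' Alpha diversity of one abundance profile
#'
#' Richness (count of taxa present), Shannon index (natural log) and Simpson
#' index. The Simpson variant defaults to Gini-Simpson `1 - sum(p^2)`;
#' `variant = "dominance"` returns `sum(p^2)`.
#'
#' @param row non-negative abundance vector with positive sum.
#' @param variant `"gini"` or `"dominance"`.
#' @return named numeric vector `richness`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(row, variant = c("gini", "dominance")) {
  variant <- match.arg(variant)
  if (any(row < 0)) stop("abundances must be non-negative")
  if (sum(row) <= 0) stop("all-zero abundance profile has no diversity")
  p <- row[row > 0] / sum(row)
  simpson <- sum(p^2)
  c(richness = sum(row > 0),
    shannon = -sum(p * log(p)),
    simpson = if (variant == "gini") 1 - simpson else simpson)
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' @param abundance samples x taxa matrix of non-negative abundances.
#' @return symmetric sample x sample dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(abundance) {
  as.matrix(vegan::vegdist(abundance, method = "bray"))
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-d^2/2` and eigendecomposes it. Axes are ordered by
#' eigenvalue; negative eigenvalues are excluded from the
#' proportion-explained denominator. For a reproducible sign convention, each
#' axis is flipped so that its first nonzero coordinate is positive.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes number of axes to return.
#' @return list with `coordinates` (samples x axes), `eigenvalues` and
#'   `proportion_explained` (per returned axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("dissimilarity matrix must be square and symmetric")
  }
  n <- nrow(d)
  k <- min(n_axes, n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig[eig > 1e-12])
  coords <- matrix(0, n, n_axes,
                   dimnames = list(rownames(d), paste0("PCo", seq_len(n_axes))))
  got <- if (is.null(dim(fit$points))) 0L else ncol(fit$points)
  if (got > 0 && pos > 0) {
    coords[, seq_len(min(got, n_axes))] <- fit$points[, seq_len(min(got, n_axes))]
  }
  for (j in seq_len(n_axes)) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  prop <- if (pos > 0) pmax(eig[seq_len(n_axes)], 0) / pos else rep(0, n_axes)
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F on
#' among/within sums of squared dissimilarities), with the permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d dissimilarity matrix.
#' @param labels group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `pseudo_F` and `p_value`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("every group needs at least two samples")
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(group = labels)
  fit <- vegan::adonis2(stats::as.dist(as.matrix(d)) ~ group, data = df,
                        permutations = n_perm)
  list(pseudo_F = fit$F[1], p_value = fit$`Pr(>F)`[1])
}

#' Paired differential-abundance testing of MAGs between two segments
#'
#' For each MAG with nonzero abundance, runs a paired two-sided t-test on the
#' per-subject abundance differences and an (unpaired) two-sided
#' Mann-Whitney test between the two groups, reporting both significance
#' flags independently at raw `p < alpha`. The paired t-test is flagged NA on
#' zero-variance differences. No multiplicity adjustment is applied by
#' default (set `adjust = "BH"` for Benjamini-Hochberg columns).
#'
#' @param abundance samples x MAGs relative-abundance matrix.
#' @param groups data.frame with `sample_id`, `group`, `donkey_id` covering
#'   the rows of `abundance`.
#' @param group_a,group_b segment labels to compare (defaults C vs DC).
#' @param alpha significance level on raw p-values.
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame, one row per tested MAG: means, p-values, direction
#'   and flags.
#' @export
differential_mags <- function(abundance, groups, group_a = "C",
                              group_b = "DC", alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ga <- groups[groups$group == group_a, , drop = FALSE]
  gb <- groups[groups$group == group_b, , drop = FALSE]
  missing_pairs <- c(setdiff(ga$donkey_id, gb$donkey_id),
                     setdiff(gb$donkey_id, ga$donkey_id))
  if (length(missing_pairs)) {
    stop("subjects without a sample in both groups: ",
         paste(unique(missing_pairs), collapse = ", "))
  }
  subj <- sort(unique(ga$donkey_id))
  rows_a <- ga$sample_id[match(subj, ga$donkey_id)]
  rows_b <- gb$sample_id[match(subj, gb$donkey_id)]
  keep <- colSums(abundance[c(rows_a, rows_b), , drop = FALSE]) > 0
  mags <- colnames(abundance)[keep]
  res <- lapply(mags, function(m) {
    x <- abundance[rows_a, m]
    y <- abundance[rows_b, m]
    dif <- x - y
    t_p <- if (stats::sd(dif) == 0) NA_real_ else
      stats::t.test(x, y, paired = TRUE)$p.value
    mw_p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    # fully tied data: zero-variance normal approximation carries no evidence
    if (is.nan(mw_p)) mw_p <- 1
    data.frame(mag_id = m,
               mean_a = mean(x), mean_b = mean(y),
               t_pvalue = t_p, mw_pvalue = mw_p,
               direction = if (mean(x) > mean(y)) paste0("higher_in_", group_a)
                           else if (mean(x) < mean(y)) paste0("higher_in_", group_b)
                           else "equal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  names(out)[names(out) == "mean_a"] <- paste0("mean_", group_a)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", group_b)
  if (adjust == "BH") {
    out$t_padj <- stats::p.adjust(out$t_pvalue, "BH")
    out$mw_padj <- stats::p.adjust(out$mw_pvalue, "BH")
  }
  out$significant_t <- !is.na(out$t_pvalue) & out$t_pvalue < alpha
  out$significant_mw <- !is.na(out$mw_pvalue) & out$mw_pvalue < alpha
  out
}

#' Shared and unique pathway sets of two MAG groups
#'
#' Takes the union of binary pathway flags over each MAG set and returns the
#' Venn partition, each component sorted for deterministic output.
#'
#' @param pathway_table MAGs x pathways binary matrix (rownames = MAG ids).
#' @param set_a,set_b character vectors of MAG ids.
#' @return list with `a_only`, `b_only`, `shared`.
#' @export
pathway_set_compare <- function(pathway_table, set_a, set_b) {
  unknown <- setdiff(c(set_a, set_b), rownames(pathway_table))
  if (length(unknown)) {
    stop("unknown MAG id: ", paste(unknown, collapse = ", "))
  }
  paths_of <- function(set) {
    sub <- pathway_table[set, , drop = FALSE]
    sort(colnames(sub)[colSums(sub) > 0])
  }
  pa <- paths_of(set_a)
  pb <- paths_of(set_b)
  list(a_only = setdiff(pa, pb), b_only = setdiff(pb, pa),
       shared = intersect(pa, pb))
}
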