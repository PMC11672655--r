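#' Filter a hit table to per-query best hits
#'
#' Drops records whose e-value exceeds `max_evalue` (inclusive cutoff: a hit
#' at exactly the cutoff is kept), then keeps for each query only the record
#' with the highest percent identity, breaking ties by smaller e-value and
#' then lexicographic subject id. Idempotent.
#'
#' @param records hit-record data.frame (as from [generate_hit_table()] or
#'   [read_hit_table()]).
#' @param max_evalue e-value screen (default 1e-3).
#' @return filtered data.frame, one row per query.
#' @export
filter_best_hits <- function(records, max_evalue = 1e-3) {
  stopifnot(all(c("query_id", "subject_id", "percent_identity", "evalue")
                %in% names(records)))
  rec <- records[records$evalue <= max_evalue, , drop = FALSE]
  if (nrow(rec) == 0) return(rec)
  ord <- order(rec$query_id, -rec$percent_identity, rec$evalue, rec$subject_id)
  rec <- rec[ord, , drop = FALSE]
  rec <- rec[!duplicated(rec$query_id), , drop = FALSE]
  rec[order(rec$query_id), , drop = FALSE]
}

#' Parse a CAZy family label into class / family / subfamily
#'
#' The class is the leading alphabetic prefix and must be one of GH, GT, PL,
#' CE, AA, CBM; the numeric family and optional `_subfamily` suffix are
#' retained. Unknown prefixes are flagged unparseable rather than erroring,
#' so malformed labels can be tallied in a diagnostics bucket.
#'
#' @param family character vector of family labels (e.g. `"GH13_10"`,
#'   `"PL8_3"`, `"CBM48"`).
#' @return data.frame (`family`, `class`, `family_number`, `subfamily`,
#'   `parseable`).
#' @export
parse_cazy_class <- function(family) {
  stopifnot(is.character(family), all(nzchar(family)))
  m <- regmatches(family,
                  regexec("^([A-Za-z]+)([0-9]+)(?:_([0-9]+))?$", family))
  cls <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, "")
  num <- vapply(m, function(x) if (length(x)) x[3] else NA_character_, "")
  sub <- vapply(m, function(x) if (length(x) && nzchar(x[4])) x[4]
                else NA_character_, "")
  known <- c("GH", "GT", "PL", "CE", "AA", "CBM")
  ok <- !is.na(cls) & cls %in% known
  data.frame(family = family,
             class = ifelse(ok, cls, NA_character_),
             family_number = ifelse(ok, as.integer(num), NA_integer_),
             subfamily = ifelse(ok, suppressWarnings(as.integer(sub)),
                                NA_integer_),
             parseable = ok,
             stringsAsFactors = FALSE)
}

#' Per-class counts and percentages of CAZyme records
#'
#' Percentages are computed over parseable records only and rounded to two
#' decimals; unparseable families are reported separately.
#'
#' @param records hit-record data.frame with a `family` column.
#' @return list with `table` (data.frame `class`, `count`, `pct`, ordered by
#'   count descending) and `n_unparseable`.
#' @export
class_distribution <- function(records) {
  if (nrow(records) == 0) {
    warning("empty hit table; returning empty class distribution")
    return(list(table = data.frame(class = character(0), count = integer(0),
                                   pct = numeric(0)),
                n_unparseable = 0L))
  }
  parsed <- parse_cazy_class(records$family)
  cls <- parsed$class[parsed$parseable]
  tab <- sort(table(cls), decreasing = TRUE)
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    pct = round(100 * as.integer(tab) / length(cls), 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = out, n_unparseable = sum(!parsed$parseable))
}

#' Known/novel split of best-hit records at an identity cutoff
#'
#' A record is "known" when its percent identity strictly exceeds the cutoff
#' (default 95); everything else is novel. The mean identity is the
#' unweighted arithmetic mean over all records, or over novel records only
#' when `exclude_known = TRUE`.
#'
#' @param records best-hit filtered data.frame with `percent_identity`.
#' @param identity_cutoff percent identity cutoff.
#' @param exclude_known exclude known records from the mean.
#' @return list of class `novelty_summary`: `total`, `known`, `novel`,
#'   `mean_identity`.
#' @export
novelty_summary <- function(records, identity_cutoff = 95,
                            exclude_known = FALSE) {
  id <- records$percent_identity
  known <- sum(id > identity_cutoff)
  mean_id <- if (exclude_known) mean(id[id <= identity_cutoff]) else mean(id)
  structure(list(total = length(id), known = known,
                 novel = length(id) - known,
                 mean_identity = mean_id),
            class = "novelty_summary")
}

#' @export
print.novelty_summary <- function(x, ...) {
  cat(sprintf("%d records: %d known (> cutoff), %d novel; mean identity %.1f%%\n",
              x$total, x$known, x$novel, x$mean_identity))
  invisible(x)
}

#' Per-taxon, per-class annotation counts
#'
#' Pools hit records by the taxon their MAG maps to. MAGs missing from the
#' taxonomy are bucketed as "unclassified". Output is ordered by count
#' descending, then taxon and class name, for deterministic tabulation.
#'
#' @param records hit-record data.frame with `mag_id` and `family`.
#' @param mag_taxonomy data.frame with `mag_id` and one column per taxon
#'   level (e.g. `phylum`, `genus`).
#' @param level taxonomy column to pool on (default `"genus"`).
#' @return list with `by_taxon` (data.frame `taxon_level`, `taxon`, `class`,
#'   `count`) and `per_mag` (data.frame `mag_id`, `count`).
#' @export
per_taxon_counts <- function(records, mag_taxonomy, level = "genus") {
  stopifnot(level %in% names(mag_taxonomy))
  parsed <- parse_cazy_class(records$family)
  rec <- records[parsed$parseable, , drop = FALSE]
  cls <- parsed$class[parsed$parseable]
  taxon <- mag_taxonomy[[level]][match(rec$mag_id, mag_taxonomy$mag_id)]
  taxon[is.na(taxon)] <- "unclassified"
  agg <- as.data.frame(table(taxon = taxon, class = cls),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0, , drop = FALSE]
  agg <- data.frame(taxon_level = level, taxon = agg$taxon, class = agg$class,
                    count = agg$Freq, stringsAsFactors = FALSE)
  agg <- agg[order(-agg$count, agg$taxon, agg$class), , drop = FALSE]
  rownames(agg) <- NULL
  per_mag <- as.data.frame(table(mag_id = rec$mag_id),
                           stringsAsFactors = FALSE)
  names(per_mag)[2] <- "count"
  per_mag <- per_mag[order(-per_mag$count, per_mag$mag_id), , drop = FALSE]
  rownames(per_mag) <- NULL
  list(by_taxon = agg, per_mag = per_mag)
}

#' Annotation rate as a percentage
#'
#' @param n_predicted total predicted proteins.
#' @param n_annotated annotated subset.
#' @return `100 * n_annotated / n_predicted`, rounded to two decimals.
#' @export
#' @examples
#' annotation_rate(1656912, 622868) # 37.59
annotation_rate <- function(n_predicted, n_annotated) {
  if (n_predicted == 0) stop("annotation rate undefined for 0 predicted proteins")
  if (n_annotated < 0 || n_annotated > n_predicted) {
    stop("n_annotated must lie in [0, n_predicted]")
  }
  round(100 * n_annotated / n_predicted, 2)
}
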