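write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one multi-record FASTA per MAG plus the quality table
#'
#' @param genomes named list of [genome_record()].
#' @param dir output directory; FASTA files are named `<mag_id>.fa`.
#' @return invisibly, the quality-table path.
#' @export
write_genome_set <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in genomes) {
    seqs <- Biostrings::DNAStringSet(g$contigs)
    names(seqs) <- sprintf("%s_contig%03d", g$mag_id, seq_along(g$contigs))
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(g$mag_id, ".fa")))
  }
  qc <- data.frame(
    mag_id = vapply(genomes, `[[`, "", "mag_id"),
    completeness = vapply(genomes, `[[`, 0, "completeness"),
    contamination = vapply(genomes, `[[`, 0, "contamination"))
  write_tsv(qc, file.path(dir, "quality.tsv"))
}

#' Read a directory of per-MAG FASTA files plus a quality table
#'
#' @param dir directory holding `<mag_id>.fa[.gz]` files.
#' @param quality_path TSV with columns `mag_id`, `completeness`,
#'   `contamination`; every MAG must have a row.
#' @return named list of [genome_record()].
#' @export
read_genome_set <- function(dir, quality_path = file.path(dir, "quality.tsv")) {
  files <- list.files(dir, pattern = "\\.fa(sta)?(\\.gz)?$", full.names = TRUE)
  qc <- utils::read.delim(quality_path, stringsAsFactors = FALSE)
  genomes <- list()
  for (f in files) {
    mag_id <- sub("\\.fa(sta)?(\\.gz)?$", "", basename(f))
    row <- qc[qc$mag_id == mag_id, , drop = FALSE]
    if (nrow(row) == 0) stop("no quality row for MAG ", mag_id)
    seqs <- as.character(Biostrings::readDNAStringSet(f))
    genomes[[mag_id]] <- genome_record(mag_id, unname(seqs),
                                       row$completeness[1],
                                       row$contamination[1])
  }
  genomes
}

#' Write hit records as a 12-column BLAST/DIAMOND tabular file
#'
#' Layout: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore (no header). The MAG id travels in qseqid as
#' `<mag_id>|<protein>` and the family in sseqid as `<family>|<accession>`.
#' Alignment geometry columns not tracked by the hit records are filled with
#' a nominal 300-column gapless alignment consistent with the identity.
#'
#' @param records hit-record data.frame.
#' @param path output path.
#' @export
write_hit_table <- function(records, path) {
  aln_len <- 300L
  out <- data.frame(
    qseqid = records$query_id,
    sseqid = records$subject_id,
    pident = records$percent_identity,
    length = aln_len,
    mismatch = round((100 - records$percent_identity) / 100 * aln_len),
    gapopen = 0L,
    qstart = 1L, qend = aln_len, sstart = 1L, send = aln_len,
    evalue = records$evalue,
    bitscore = records$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column BLAST/DIAMOND tabular best-hit file
#'
#' Inverse of [write_hit_table()]: parses the MAG id out of qseqid and the
#' family label out of sseqid (text before the first `|`; the full qseqid is
#' kept as the query id). Malformed rows raise an error naming the line.
#'
#' @param path tab-separated 12-column file without header.
#' @return hit-record data.frame.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop("malformed hit-table row at line ", bad[1], " of ", path,
         " (expected 12 tab-separated columns, got ",
         lengths(fields)[bad[1]], ")")
  }
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")
  data.frame(
    query_id = tab$qseqid,
    mag_id = sub("\\|.*$", "", tab$qseqid),
    family = sub("\\|.*$", "", tab$sseqid),
    subject_id = tab$sseqid,
    percent_identity = as.numeric(tab$pident),
    evalue = as.numeric(tab$evalue),
    bitscore = as.numeric(tab$bitscore),
    stringsAsFactors = FALSE)
}

#' Write / read an abundance matrix as TSV
#'
#' First column `sample_id`, then one column per MAG.
#' @param abundance samples x MAGs matrix with dimnames.
#' @param path TSV path.
#' @export
write_abundance <- function(abundance, path) {
  df <- data.frame(sample_id = rownames(abundance), abundance,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Write / read the sample-group table as TSV
#'
#' Columns `sample_id`, `group` (C / VC / DC), `donkey_id`.
#' @param groups data.frame.
#' @param path TSV path.
#' @export
write_groups <- function(groups, path) write_tsv(groups, path)

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
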