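# shared fixture builders; everything is generated in code at test time

make_genome <- function(mag_id, seq, completeness = 90, contamination = 1) {
  genome_record(mag_id, seq, completeness, contamination)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution-only mutant with an exact mutated-site count, so the true
# alignment identity is known by construction
mutate_exact <- function(seq, n_sub, seed) {
  set.seed(seed)
  bases <- strsplit(seq, "")[[1]]
  pos <- sample(length(bases), n_sub)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  bases[pos] <- vapply(bases[pos], function(b) sample(alt[[b]], 1), "")
  paste(bases, collapse = "")
}

# null relative-abundance matrix (log-normal, no planted structure)
null_abundance <- function(n_samples, n_mags, seed) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_samples * n_mags), n_samples, n_mags,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              sprintf("MAG%04d", seq_len(n_mags))))
  m / rowSums(m)
}

# three ring-shaped modules with one designed within-module hub and one
# designed inter-module connector, for role-recovery checks
planted_role_graph <- function(ring_size = 10) {
  mods <- c("A", "B", "C")
  edges <- do.call(rbind, lapply(mods, function(m) {
    v <- sprintf("%s%02d", m, seq_len(ring_size))
    ring <- data.frame(a = v, b = v[c(2:ring_size, 1)])
    hub <- data.frame(a = paste0(m, "_hub"), b = v)
    rbind(ring, hub)
  }))
  connector <- data.frame(a = "Xconn", b = c("A01", "B01", "C01"))
  rbind(edges, connector)
}
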