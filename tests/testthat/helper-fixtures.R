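# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (enumeration / exact scan) and never call the code path they check.

make_profile <- function(counts, primer = "V4", sample = "s1", rank = "phylum") {
  taxon_profile(sample, primer, rank, counts = counts)
}

# Brute-force merge oracle: per-taxon max over explicit union enumeration.
oracle_merge <- function(count_list) {
  taxa <- unique(unlist(lapply(count_list, names)))
  rep_reads <- vapply(taxa, function(t) {
    vals <- unlist(lapply(count_list, function(v) v[names(v) == t]))
    max(vals)
  }, numeric(1L))
  stats::setNames(rep_reads, taxa)
}

# Exact scan oracle for primer matching: expand the degenerate primer and
# look for fixed-string occurrences, then apply policy by re-counting
# mismatches of the best-matching expansion at every window.
oracle_match <- function(primer_seq, ref, max_mismatch = 0, anchor = 3,
                         anchor_side = "right") {
  pc <- strsplit(primer_seq, "")[[1L]]
  rc <- strsplit(ref, "")[[1L]]
  m <- length(pc)
  variants <- strsplit(expand_degenerate(primer_seq), "")
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  for (s in seq_len(length(rc) - m + 1L)) {
    win <- rc[s:(s + m - 1L)]
    anchor_idx <- if (anchor == 0) integer(0) else if (anchor_side == "right")
      (m - anchor + 1L):m else seq_len(anchor)
    # best over variants whose anchor bases match the window exactly
    best <- min(c(Inf, vapply(variants, function(v) {
      if (length(anchor_idx) && any(v[anchor_idx] != win[anchor_idx])) return(Inf)
      sum(v != win)
    }, numeric(1L))))
    if (best <= max_mismatch) {
      hits <- rbind(hits, data.frame(start = s - 1L, mismatches = best))
    }
  }
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_degenerate <- function(n, n_ambig = 2) {
  chars <- sample(c("A", "C", "G", "T"), n, TRUE)
  pos <- sample(seq_len(n - 3L), n_ambig)  # keep the 3' anchor unambiguous
  chars[pos] <- sample(c("R", "Y", "S", "W", "K", "M"), n_ambig, TRUE)
  paste(chars, collapse = "")
}
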