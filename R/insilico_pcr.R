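# Degenerate-primer matching with TestPrime-like elongation stringency:
# windows are accepted when total mismatches stay within budget AND the
# 3'-terminal anchor bases match exactly (polymerase extension requires a
# matched 3' end). Coordinates are 0-based half-open at the interface.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a degenerate oligonucleotide primer
#'
#' @param name Primer name.
#' @param sequence Sequence over the IUPAC nucleotide alphabet.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `"degenerate_primer"` with a `degeneracy`
#'   field (product of per-base code sizes).
#' @examples
#' degenerate_primer("515F", "GTGYCAGCMGCCGCGGTAA", "forward")
#' @export
degenerate_primer <- function(name, sequence,
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty primer sequence", call. = FALSE)
  chars <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad)) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         degeneracy = prod(lengths(IUPAC_CODES[chars]))),
    class = "degenerate_primer"
  )
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat("<degenerate_primer> ", x$name, " (", x$orientation, ") ",
      x$sequence, " degeneracy=", x$degeneracy, "\n", sep = "")
  invisible(x)
}

#' Reverse-complement a (possibly degenerate) nucleotide sequence
#'
#' Handles the full IUPAC alphabet (R<->Y, K<->M, B<->V, D<->H, S/W/N fixed).
#'
#' @param x Character sequence.
#' @return Reverse-complemented character sequence.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Expand a degenerate primer into its concrete sequences
#'
#' @param p A [degenerate_primer()] or character sequence.
#' @param cap Refuse expansion above this degeneracy (default 4096).
#' @return Character vector of length equal to the primer's degeneracy.
#' @examples
#' expand_degenerate("AR")  # "AA" "AG"
#' @export
expand_degenerate <- function(p, cap = 4096) {
  if (is.character(p)) p <- degenerate_primer("primer", p)
  stopifnot(inherits(p, "degenerate_primer"))
  if (p$degeneracy > cap) {
    stop("degeneracy ", p$degeneracy, " exceeds cap ", cap, call. = FALSE)
  }
  chars <- strsplit(p$sequence, "")[[1L]]
  grid <- expand.grid(rev(IUPAC_CODES[chars]), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  apply(grid[, rev(seq_along(chars)), drop = FALSE], 1L, paste0, collapse = "")
}

# Core window scan. primer_chars: vector of IUPAC codes; ref_chars: A/C/G/T/N.
# Returns data.frame(start0, mismatches) of accepted windows. anchor_side
# gives where the oligo's 3' end sits in this scan.
scan_windows <- function(primer_chars, ref_chars, max_mismatch, anchor,
                         anchor_side = c("right", "left")) {
  anchor_side <- match.arg(anchor_side)
  m <- length(primer_chars)
  L <- length(ref_chars)
  if (L < m) return(data.frame(start0 = integer(0), mismatches = integer(0)))
  n_win <- L - m + 1L
  # mismatch indicator per primer position, shifted and summed over windows;
  # an N in the reference is in no code set, so it always counts as mismatch
  mm <- matrix(FALSE, nrow = n_win, ncol = m)
  for (j in seq_len(m)) {
    allowed <- IUPAC_CODES[[primer_chars[j]]]
    mm[, j] <- !(ref_chars[seq.int(j, j + n_win - 1L)] %in% allowed)
  }
  total <- rowSums(mm)
  if (anchor > 0L) {
    idx <- if (anchor_side == "right") seq.int(m - anchor + 1L, m)
           else seq_len(anchor)
    anchor_ok <- rowSums(mm[, idx, drop = FALSE]) == 0L
  } else {
    anchor_ok <- rep(TRUE, n_win)
  }
  keep <- which(total <= max_mismatch & anchor_ok)
  data.frame(start0 = keep - 1L, mismatches = as.integer(total[keep]))
}

#' Match a degenerate primer against a reference sequence
#'
#' Slides the primer along the plus strand of the reference and reports
#' every window whose mismatch count is within `max_mismatch` and whose
#' 3'-terminal `anchor_3prime` bases match exactly. IUPAC codes in the
#' primer match their base sets; an `N` in the reference matches nothing
#' (strict mode) and counts as a mismatch.
#'
#' @param p A [degenerate_primer()] or character sequence.
#' @param ref Reference sequence over `A,C,G,T,N`.
#' @param max_mismatch Total mismatch budget for the window (default 0).
#' @param anchor_3prime Number of 3'-terminal bases that must match exactly
#'   (default 3).
#' @param anchor Side of the window holding the primer's 3' end: `"right"`
#'   for a primer annealing in its given orientation, `"left"` when
#'   scanning the reverse-complement of a reverse primer.
#' @return Data frame with `start`, `end` (0-based half-open window on the
#'   reference), `strand` and `mismatches`.
#' @examples
#' match_primer("AYGT", "TTACGTTT")  # hit at start = 2
#' @export
match_primer <- function(p, ref, max_mismatch = 0, anchor_3prime = 3,
                         anchor = c("right", "left")) {
  anchor <- match.arg(anchor)
  if (is.character(p)) p <- degenerate_primer("primer", p)
  stopifnot(inherits(p, "degenerate_primer"),
            is.character(ref), length(ref) == 1L)
  ref <- toupper(ref)
  if (!nzchar(ref)) stop("empty reference sequence", call. = FALSE)
  if (grepl("[^ACGTN]", ref)) {
    stop("reference must be over A,C,G,T,N", call. = FALSE)
  }
  primer_chars <- strsplit(p$sequence, "")[[1L]]
  if (anchor_3prime > length(primer_chars)) {
    stop("anchor longer than primer", call. = FALSE)
  }
  hits <- scan_windows(primer_chars, strsplit(ref, "")[[1L]],
                       max_mismatch, anchor_3prime, anchor)
  data.frame(
    start = hits$start0,
    end = hits$start0 + length(primer_chars),
    strand = rep("+", nrow(hits)),
    mismatches = hits$mismatches
  )
}

#' Construct a primer pair with its match policy
#'
#' @param forward,reverse [degenerate_primer()] objects (or sequences).
#' @param max_mismatch Mismatch budget per primer (default 0).
#' @param anchor_3prime Exact-match 3' anchor length (default 3).
#' @param min_len,max_len Bounds on the inner (primer-exclusive) amplicon
#'   length.
#' @return An object of class `"primer_pair"`.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 0, anchor_3prime = 3,
                        min_len = 1, max_len = 5000) {
  if (is.character(forward)) forward <- degenerate_primer("fwd", forward)
  if (is.character(reverse)) reverse <- degenerate_primer("rev", reverse, "reverse")
  stopifnot(inherits(forward, "degenerate_primer"),
            inherits(reverse, "degenerate_primer"),
            max_mismatch >= 0, anchor_3prime >= 0,
            min_len > 0, max_len >= min_len)
  if (anchor_3prime > min(nchar(forward$sequence), nchar(reverse$sequence))) {
    stop("anchor longer than a primer", call. = FALSE)
  }
  structure(
    list(forward = forward, reverse = reverse, max_mismatch = max_mismatch,
         anchor_3prime = anchor_3prime, min_len = min_len, max_len = max_len),
    class = "primer_pair"
  )
}

#' Find amplicons of a primer pair on a reference sequence
#'
#' The forward primer is matched on the plus strand (3' anchor at the right
#' of its window); the reverse primer is matched as its reverse complement
#' (3' anchor at the left). Sites are paired left to right, each forward
#' site taking the nearest unconsumed reverse site whose inner product
#' length falls within the pair's bounds.
#'
#' @param pair A [primer_pair()].
#' @param ref Reference sequence.
#' @param ref_id Identifier reported in the result.
#' @return Data frame of class `"match_result"`: forward/reverse site
#'   intervals, the inner primer-exclusive amplicon interval (canonical) and
#'   the primer-inclusive one, all 0-based half-open, plus mismatch counts.
#' @export
find_amplicons <- function(pair, ref, ref_id = "ref") {
  stopifnot(inherits(pair, "primer_pair"))
  fwd_hits <- match_primer(pair$forward, ref, pair$max_mismatch,
                           pair$anchor_3prime, anchor = "right")
  if (!nrow(fwd_hits)) return(empty_match_result())
  rev_rc <- degenerate_primer(pair$reverse$name,
                              reverse_complement(pair$reverse$sequence))
  rev_hits <- match_primer(rev_rc, ref, pair$max_mismatch,
                           pair$anchor_3prime, anchor = "left")
  if (!nrow(rev_hits)) return(empty_match_result())

  out <- empty_match_result()
  used_rev <- rep(FALSE, nrow(rev_hits))
  for (i in order(fwd_hits$start)) {
    f_end <- fwd_hits$end[i]
    inner <- rev_hits$start - f_end
    ok <- which(!used_rev & inner >= pair$min_len & inner <= pair$max_len)
    if (!length(ok)) next
    j <- ok[which.min(rev_hits$start[ok])]
    used_rev[j] <- TRUE
    out <- rbind(out, data.frame(
      ref_id = ref_id,
      fwd_start = fwd_hits$start[i], fwd_end = f_end,
      rev_start = rev_hits$start[j], rev_end = rev_hits$end[j],
      amplicon_start = f_end, amplicon_end = rev_hits$start[j],
      inner_length = rev_hits$start[j] - f_end,
      outer_length = rev_hits$end[j] - fwd_hits$start[i],
      fwd_mismatches = fwd_hits$mismatches[i],
      rev_mismatches = rev_hits$mismatches[j]
    ))
  }
  out
}

empty_match_result <- function() {
  data.frame(
    ref_id = character(0),
    fwd_start = integer(0), fwd_end = integer(0),
    rev_start = integer(0), rev_end = integer(0),
    amplicon_start = integer(0), amplicon_end = integer(0),
    inner_length = integer(0), outer_length = integer(0),
    fwd_mismatches = integer(0), rev_mismatches = integer(0)
  )
}

#' Per-taxon amplification coverage of a primer pair
#'
#' Runs [find_amplicons()] over a reference panel and tabulates, for each
#' taxon at the requested rank, the fraction of reference sequences the
#' pair would amplify. References without a name at the rank are pooled as
#' `"Unassigned"`.
#'
#' @param pair A [primer_pair()].
#' @param refs Named character vector of reference sequences (or a
#'   `DNAStringSet`).
#' @param lineages Named character vector of lineage strings, or a data
#'   frame whose first two columns are id and lineage.
#' @param rank Rank at which to aggregate.
#' @return Data frame `taxon`, `n_amplified`, `n_total`, `fraction`, with
#'   the panel-wide coverage in attribute `"overall"`.
#' @export
rank_coverage <- function(pair, refs, lineages, rank) {
  assert_rank(rank)
  if (inherits(refs, "DNAStringSet")) refs <- as.character(refs)
  stopifnot(is.character(refs), !is.null(names(refs)))
  if (is.data.frame(lineages)) {
    lineages <- stats::setNames(as.character(lineages[[2L]]),
                                as.character(lineages[[1L]]))
  }
  missing <- setdiff(names(refs), names(lineages))
  if (length(missing)) {
    stop("no lineage for reference(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  amplified <- vapply(names(refs), function(id) {
    nrow(find_amplicons(pair, refs[[id]], ref_id = id)) > 0L
  }, logical(1L))
  taxon <- vapply(names(refs), function(id) {
    nm <- parse_lineage(lineages[[id]])$ranks[[rank]]
    if (is.na(nm)) "Unassigned" else nm
  }, character(1L))
  tab <- data.frame(
    taxon = sort(unique(taxon)),
    stringsAsFactors = FALSE
  )
  tab$n_amplified <- vapply(tab$taxon, function(t) sum(amplified[taxon == t]),
                            numeric(1L))
  tab$n_total <- vapply(tab$taxon, function(t) sum(taxon == t), numeric(1L))
  tab$fraction <- tab$n_amplified / tab$n_total
  attr(tab, "overall") <- sum(amplified) / length(amplified)
  tab
}

#' Read reference sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Read an id-to-lineage taxonomy map
#'
#' Two-column TSV (reference id, lineage string), no header by default —
#' the shape of Greengenes/SILVA taxonomy files.
#'
#' @param path TSV path.
#' @param header Whether the file has a header row.
#' @return Named character vector, id -> lineage.
#' @export
read_taxonomy_map <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read primer pairs from a YAML config
#'
#' The config maps primer-set names (e.g. `V4`) to blocks with `forward`,
#' `reverse` and optional `max_mismatch`, `anchor_3prime`, `min_len`,
#' `max_len`. Oligo sequences are deliberately user-supplied: no defaults
#' are shipped.
#'
#' @param path YAML path.
#' @return Named list of [primer_pair()] objects.
#' @export
read_primer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(b) {
    primer_pair(
      forward = degenerate_primer(b$forward_name %||% "fwd", b$forward),
      reverse = degenerate_primer(b$reverse_name %||% "rev", b$reverse, "reverse"),
      max_mismatch = b$max_mismatch %||% 0,
      anchor_3prime = b$anchor_3prime %||% 3,
      min_len = b$min_len %||% 1,
      max_len = b$max_len %||% 5000
    )
  })
}
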