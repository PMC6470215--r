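#' Parse a Greengenes-style lineage string
#'
#' Lineage strings are semicolon-delimited with optional single-letter rank
#' prefixes, e.g. `"k__Bacteria;p__Chloroflexi"`. The literal token
#' `"Unassigned"` (the bucket closed-reference OTU picking emits for reads
#' without a database hit) yields a lineage with every rank empty and the
#' unassigned flag set. Blank segments (`"p__"`) leave that rank empty.
#' Segments without a prefix are assigned by position, kingdom first.
#'
#' @param raw A single lineage string.
#' @return An object of class `"lineage"`: a list with `ranks` (named
#'   character vector over kingdom..species, `NA` for empty ranks),
#'   `unassigned` (logical), `depth` (number of segments given) and `raw`.
#' @examples
#' parse_lineage("k__Bacteria;p__Chloroflexi")
#' parse_lineage("Unassigned")
#' @seealso [format_lineage()], [classify_affiliation()]
#' @export
parse_lineage <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("'raw' must be a single lineage string", call. = FALSE)
  }
  ranks <- stats::setNames(rep(NA_character_, length(GG_RANKS)), names(GG_RANKS))
  if (trimws(raw) == "Unassigned") {
    return(structure(
      list(ranks = ranks, unassigned = TRUE, depth = 0L, raw = raw),
      class = "lineage"
    ))
  }
  segs <- trimws(strsplit(raw, ";", fixed = TRUE)[[1L]])
  if (length(segs) > length(GG_RANKS)) {
    stop("lineage has more than ", length(GG_RANKS), " segments: ", raw,
         call. = FALSE)
  }
  for (i in seq_along(segs)) {
    seg <- segs[i]
    if (grepl("^[A-Za-z]__", seg)) {
      letter <- tolower(substr(seg, 1L, 1L))
      idx <- match(letter, GG_RANKS)
      if (is.na(idx)) {
        stop("unknown rank prefix '", substr(seg, 1L, 3L),
             "' in segment '", seg, "'", call. = FALSE)
      }
      value <- substring(seg, 4L)
      if (nzchar(value)) ranks[idx] <- value
    } else if (nzchar(seg)) {
      ranks[i] <- seg
    }
  }
  structure(
    list(ranks = ranks, unassigned = FALSE, depth = length(segs), raw = raw),
    class = "lineage"
  )
}

#' Format a lineage back to its Greengenes string form
#'
#' Inverse of [parse_lineage()] for well-formed prefixed input: only the
#' segments that were present in the original string are emitted, so
#' `format_lineage(parse_lineage(x)) == x`.
#'
#' @param lineage A `"lineage"` object.
#' @return A single character string.
#' @export
format_lineage <- function(lineage) {
  stopifnot(inherits(lineage, "lineage"))
  if (lineage$unassigned) return("Unassigned")
  d <- max(lineage$depth, 1L)
  vals <- lineage$ranks[seq_len(d)]
  vals[is.na(vals)] <- ""
  paste0(GG_RANKS[seq_len(d)], "__", vals, collapse = ";")
}

#' @export
print.lineage <- function(x, ...) {
  cat("<lineage> ", format_lineage(x), "\n", sep = "")
  invisible(x)
}

#' Rules for recognising candidate (provisionally named) taxa
#'
#' Candidate divisions in Greengenes carry code-like names (TM7, OD1, WS3,
#' SAR406, ...) with no reliable grammar. Recognition therefore combines an
#' explicit, overridable name list with an optional pattern fallback: a name
#' made entirely of uppercase letters and digits, at least two characters
#' long, is treated as a candidate code.
#'
#' @param names Character vector of candidate taxon names. Defaults to the
#'   Greengenes candidate divisions observed in sponge microbiome surveys
#'   plus common marine candidate clades; extend or replace freely.
#' @param pattern_enabled Apply the uppercase-code fallback pattern.
#' @return An object of class `"candidate_rules"`.
#' @export
candidate_rules <- function(names = greengenes_candidate_divisions(),
                            pattern_enabled = TRUE) {
  stopifnot(is.character(names), is.logical(pattern_enabled))
  structure(
    list(names = unique(names), pattern_enabled = isTRUE(pattern_enabled)),
    class = "candidate_rules"
  )
}

#' Seed list of Greengenes candidate division names
#'
#' Not claimed complete: candidate nomenclature is open-ended, so
#' [candidate_rules()] accepts arbitrary additions and a pattern fallback.
#'
#' @return Character vector of candidate taxon names.
#' @export
greengenes_candidate_divisions <- function() {
  c(
    "BRC1", "GN02", "GN04", "OD1", "OP1", "OP3", "OP8", "OP9", "OP11",
    "SR1", "TM6", "TM7", "WS1", "WS2", "WS3", "WS4", "WS6", "WWE1",
    "SAR406", "PAUC34f", "SBR1093", "NKB19", "NC10", "LD1", "Kazan-3B-28",
    "Marinimicrobia", "Latescibacteria", "Poribacteria"
  )
}

#' Read candidate rules from a YAML config block
#'
#' Expects a top-level `candidate_rules:` mapping with `names:` (list) and
#' `pattern_enabled:` (logical). Missing fields fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"candidate_rules"` object.
#' @export
read_candidate_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  block <- cfg[["candidate_rules"]] %||% cfg
  candidate_rules(
    names = as.character(block[["names"]] %||% greengenes_candidate_divisions()),
    pattern_enabled = block[["pattern_enabled"]] %||% TRUE
  )
}

#' Classify a taxon's affiliation status at a rank
#'
#' Partitions taxa into three mutually exclusive statuses:
#' * `"unassigned"` — the lineage is the Unassigned bucket, or carries no
#'   name at the requested rank;
#' * `"candidate"` — the name at the rank matches the candidate rules
#'   (provisional divisions such as TM7, OD1, WS3);
#' * `"affiliated"` — a validly named taxon.
#'
#' Unaffiliated means candidate or unassigned.
#'
#' @param lineage A `"lineage"` object or a lineage string.
#' @param rank Rank name (`"kingdom"` .. `"species"`).
#' @param rules A [candidate_rules()] object.
#' @return One of `"affiliated"`, `"candidate"`, `"unassigned"`.
#' @examples
#' classify_affiliation("k__Bacteria;p__Proteobacteria", "phylum")
#' classify_affiliation("k__Bacteria;p__TM7", "phylum")
#' classify_affiliation("Unassigned", "phylum")
#' @export
classify_affiliation <- function(lineage, rank, rules = candidate_rules()) {
  assert_rank(rank)
  if (is.character(lineage)) lineage <- parse_lineage(lineage)
  stopifnot(inherits(lineage, "lineage"), inherits(rules, "candidate_rules"))
  name <- lineage$ranks[[rank]]
  if (lineage$unassigned || is.na(name)) return("unassigned")
  if (name %in% rules$names) return("candidate")
  if (rules$pattern_enabled && grepl("^[A-Z0-9]{2,}$", name)) return("candidate")
  "affiliated"
}

#' Vectorised affiliation classification of lineage labels
#'
#' @param labels Character vector of lineage strings.
#' @inheritParams classify_affiliation
#' @return Character vector of statuses, named by label.
#' @export
classify_labels <- function(labels, rank, rules = candidate_rules()) {
  vapply(labels, classify_affiliation, character(1L),
         rank = rank, rules = rules)
}

# Canonicalise a label set at a rank: every unassigned lineage collapses into
# the single "Unassigned" bucket (the pipeline counts it as one taxon per
# rank); other labels are kept verbatim. Returns unique canonical labels.
canonical_labels <- function(labels, rank, rules = candidate_rules()) {
  status <- classify_labels(labels, rank, rules)
  out <- labels
  out[status == "unassigned"] <- "Unassigned"
  unique(out)
}

#' Construct a per-primer taxon profile
#'
#' The atomic data unit: one primer set, one sample, one taxonomic rank, and
#' either integer read counts or relative abundances per taxon label.
#' Read counts are the canonical unit (throughput arithmetic requires them);
#' fractional tables are accepted but flagged via the absent `counts`.
#'
#' @param sample_id Sample identifier.
#' @param primer_set Primer set label, e.g. `"V4"`.
#' @param rank Rank of the table.
#' @param counts Named non-negative integer vector (taxon label -> reads),
#'   or `NULL` for a fractional profile.
#' @param relative Named numeric vector of fractions summing to 1, or `NULL`
#'   (computed from `counts` when those are given).
#' @return An object of class `"taxon_profile"`.
#' @export
taxon_profile <- function(sample_id, primer_set, rank,
                          counts = NULL, relative = NULL) {
  assert_rank(rank)
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(primer_set), length(primer_set) == 1L)
  if (is.null(counts) && is.null(relative)) {
    stop("one of 'counts' or 'relative' must be given", call. = FALSE)
  }
  if (!is.null(counts)) {
    if (is.null(names(counts)) || anyDuplicated(names(counts))) {
      stop("'counts' must be uniquely named by taxon label", call. = FALSE)
    }
    if (any(counts < 0)) stop("negative read counts", call. = FALSE)
    if (any(abs(counts - round(counts)) > 1e-9)) {
      stop("'counts' must be integers; use 'relative' for fractions",
           call. = FALSE)
    }
    counts <- stats::setNames(as.numeric(round(counts)), names(counts))
    if (is.null(relative) && sum(counts) > 0) relative <- counts / sum(counts)
  }
  if (!is.null(relative)) {
    if (is.null(names(relative)) || anyDuplicated(names(relative))) {
      stop("'relative' must be uniquely named by taxon label", call. = FALSE)
    }
    if (any(relative < 0)) stop("negative relative abundances", call. = FALSE)
    if (abs(sum(relative) - 1) > 1e-6) {
      stop("relative abundances must sum to 1 (got ",
           format(sum(relative)), ")", call. = FALSE)
    }
  }
  structure(
    list(sample_id = sample_id, primer_set = primer_set, rank = rank,
         counts = counts, relative = relative),
    class = "taxon_profile"
  )
}

#' @export
print.taxon_profile <- function(x, ...) {
  n <- length(x$counts %||% x$relative)
  cat("<taxon_profile> sample=", x$sample_id, " primer=", x$primer_set,
      " rank=", x$rank, " taxa=", n,
      if (is.null(x$counts)) " (fractional)" else
        paste0(" reads=", format(sum(x$counts), big.mark = ",")),
      "\n", sep = "")
  invisible(x)
}

profile_labels <- function(p) names(p$counts %||% p$relative)

#' Read a taxa-summary table into per-sample profiles
#'
#' Reads the tab-separated shape produced by rank-collapsed OTU tables:
#' first column the lineage string, one numeric column per sample, header
#' row required. Integer-valued tables are stored as read counts; tables
#' holding fractions are stored in `relative` with counts absent.
#'
#' @param path Path to a TSV file.
#' @param primer_set Primer set label to attach to every profile.
#' @param rank Rank of the table.
#' @return Named list of [taxon_profile()] objects, one per sample column.
#' @export
read_taxa_table <- function(path, primer_set, rank) {
  assert_rank(rank)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxa table needs a lineage column plus >=1 sample",
                          call. = FALSE)
  labels <- as.character(df[[1L]])
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop("duplicated lineage row(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("sample columns must be numeric", call. = FALSE)
  if (any(vals < 0)) stop("negative values in taxa table", call. = FALSE)
  fractional <- any(abs(vals - round(vals)) > 1e-9)
  out <- lapply(colnames(vals), function(s) {
    v <- stats::setNames(vals[, s], labels)
    if (fractional) {
      taxon_profile(s, primer_set, rank, relative = v)
    } else {
      taxon_profile(s, primer_set, rank, counts = v)
    }
  })
  stats::setNames(out, colnames(vals))
}

#' Write per-sample profiles back to a taxa-summary table
#'
#' Inverse of [read_taxa_table()]: rows are the union of taxon labels in
#' first-appearance order, columns the samples. Writing then re-reading is
#' the identity on content.
#'
#' @param profiles List of [taxon_profile()] objects sharing a rank.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  labels <- unique(unlist(lapply(profiles, profile_labels)))
  cols <- lapply(profiles, function(p) {
    v <- p$counts %||% p$relative
    out <- stats::setNames(numeric(length(labels)), labels)
    out[names(v)] <- v
    out
  })
  df <- data.frame(Taxon = labels, check.names = FALSE)
  for (i in seq_along(profiles)) df[[profiles[[i]]$sample_id]] <- cols[[i]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exclude taxa matching a predicate and renormalise
#'
#' Removes every taxon whose parsed lineage satisfies `predicate` and
#' recomputes relative abundances over the retained taxa (the treatment
#' applied to eukaryote OTUs amplified by broad-range primer sets before
#' abundance summaries). Ratios among retained taxa are unchanged.
#'
#' @param profile A [taxon_profile()].
#' @param predicate Function `lineage -> logical`; `TRUE` excludes.
#' @return A new [taxon_profile()].
#' @examples
#' p <- taxon_profile("s1", "V6V9", "phylum",
#'   counts = c("k__Bacteria;p__Chloroflexi" = 90,
#'              "k__Eukaryota;p__Annelida"   = 10))
#' exclude_and_renormalize(p, function(l) identical(l$ranks[["kingdom"]], "Eukaryota"))
#' @export
exclude_and_renormalize <- function(profile, predicate) {
  stopifnot(inherits(profile, "taxon_profile"), is.function(predicate))
  labels <- profile_labels(profile)
  drop <- vapply(labels, function(l) isTRUE(predicate(parse_lineage(l))),
                 logical(1L))
  if (all(drop)) stop("all taxa excluded: empty profile", call. = FALSE)
  keep <- labels[!drop]
  if (!is.null(profile$counts)) {
    counts <- profile$counts[keep]
    taxon_profile(profile$sample_id, profile$primer_set, profile$rank,
                  counts = counts)
  } else {
    rel <- profile$relative[keep]
    taxon_profile(profile$sample_id, profile$primer_set, profile$rank,
                  relative = rel / sum(rel))
  }
}
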