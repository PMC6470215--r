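#' Merge per-primer profiles under the representative-throughput rule
#'
#' Combines the taxon profiles produced by several region-specific primer
#' sets for the same sample and rank into one profile. The union of taxa is
#' taken; a taxon detected by a single primer set keeps its read count
#' (unique reads are added directly), while a taxon detected by several
#' primer sets is assigned the maximum read count observed among them — its
#' representative throughput. Both rules are realised by one per-taxon
#' maximum, since the max over a single detecting set is its only value.
#'
#' @param profiles List of [taxon_profile()] objects with integer counts,
#'   all for the same sample and rank, one per primer set.
#' @param min_reads Detection floor: taxa with fewer reads in a primer set
#'   are treated as undetected by it (default 1, i.e. any positive count).
#' @return An object of class `"merged_profile"`: a list with `sample_id`,
#'   `rank`, `per_primer` (primer -> named count vector over detected taxa),
#'   `representative` (taxon -> max reads), `provenance` (taxon -> primer
#'   sets achieving the maximum; ties keep the full set) and
#'   `member_primers` (taxon -> primer sets detecting it).
#' @examples
#' v13 <- taxon_profile("s1", "V1V3", "phylum",
#'   counts = c("k__Bacteria;p__A" = 80, "k__Bacteria;p__B" = 100))
#' v4  <- taxon_profile("s1", "V4", "phylum",
#'   counts = c("k__Bacteria;p__B" = 250))
#' m <- merge_profiles(list(v13, v4))
#' m$representative   # A = 80 (unique), B = 250 (shared max)
#' @export
merge_profiles <- function(profiles, min_reads = 1) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (!all(vapply(profiles, inherits, logical(1L), "taxon_profile"))) {
    stop("'profiles' must be a list of taxon_profile objects", call. = FALSE)
  }
  if (any(vapply(profiles, function(p) is.null(p$counts), logical(1L)))) {
    stop("fractional profiles cannot be merged: throughput needs read counts",
         call. = FALSE)
  }
  samples <- unique(vapply(profiles, `[[`, character(1L), "sample_id"))
  ranks <- unique(vapply(profiles, `[[`, character(1L), "rank"))
  if (length(samples) != 1L) stop("profiles span several samples: ",
                                  paste(samples, collapse = ", "), call. = FALSE)
  if (length(ranks) != 1L) stop("profiles span several ranks: ",
                                paste(ranks, collapse = ", "), call. = FALSE)
  primers <- vapply(profiles, `[[`, character(1L), "primer_set")
  if (anyDuplicated(primers)) {
    stop("duplicated primer set(s): ",
         paste(unique(primers[duplicated(primers)]), collapse = ", "),
         call. = FALSE)
  }
  per_primer <- lapply(profiles, function(p) {
    v <- p$counts
    v[v >= min_reads]
  })
  names(per_primer) <- primers

  taxa <- unique(unlist(lapply(per_primer, names)))
  if (!length(taxa)) stop("no taxon passes the detection floor", call. = FALSE)
  representative <- stats::setNames(numeric(length(taxa)), taxa)
  provenance <- member <- stats::setNames(vector("list", length(taxa)), taxa)
  for (t in taxa) {
    vals <- vapply(per_primer, function(v) if (t %in% names(v)) v[[t]] else NA_real_,
                   numeric(1L))
    det <- !is.na(vals)
    representative[[t]] <- max(vals[det])
    member[[t]] <- primers[det]
    provenance[[t]] <- primers[det & vals == representative[[t]]]
  }
  structure(
    list(sample_id = samples, rank = ranks, per_primer = per_primer,
         representative = representative, provenance = provenance,
         member_primers = member),
    class = "merged_profile"
  )
}

#' @export
print.merged_profile <- function(x, ...) {
  cat("<merged_profile> sample=", x$sample_id, " rank=", x$rank,
      " primers=", length(x$per_primer),
      " taxa=", length(x$representative),
      " reads=", format(combined_throughput(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Combined sequencing throughput of a merged profile
#'
#' Total representative reads over the union taxon set: unique taxa
#' contribute their single count, shared taxa their across-primer maximum.
#'
#' @param m A [merge_profiles()] result.
#' @return Total read count (numeric scalar).
#' @export
combined_throughput <- function(m) {
  stopifnot(inherits(m, "merged_profile"))
  sum(m$representative)
}

#' Percentage throughput increase over a single-primer baseline
#'
#' @param combined Combined read total.
#' @param baseline Single-primer read total (> 0).
#' @return Percentage, rounded to one decimal (half away from zero).
#' @examples
#' throughput_increase(651704, 100280)  # 549.9
#' @export
throughput_increase <- function(combined, baseline) {
  stopifnot(is.numeric(combined), is.numeric(baseline),
            length(combined) == 1L, length(baseline) == 1L)
  if (baseline <= 0) stop("baseline must be positive", call. = FALSE)
  round_half_away(100 * (combined - baseline) / baseline, 1L)
}
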