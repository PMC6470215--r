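#' Tally taxa by affiliation status per primer set and combined
#'
#' For each primer set the detected taxa at the profile's rank are
#' partitioned into affiliated / candidate / unassigned; every unassigned
#' lineage collapses into a single Unassigned bucket, counted at most once
#' per primer set and once in the combined union. The combined counts are
#' the sizes of the unions of the status-partitioned taxon sets, the shared
#' counts are computed on the across-primer intersection, and the
#' unaffiliated fraction is `100 * U / (U + A)` over the combined counts.
#'
#' @param profiles Named list, primer set -> [taxon_profile()] (or a plain
#'   character vector of lineage labels).
#' @param rules A [candidate_rules()] object.
#' @param rank Rank; taken from the profiles when they carry one.
#' @return An object of class `"coverage_summary"` with elements
#'   `per_primer` (data frame of per-primer status counts), `combined`,
#'   `shared_all` (status counts of taxa found by every primer set),
#'   `per_primer_unique` (taxa found by exactly one set) and
#'   `unaffiliated_fraction` (one-decimal percentage).
#' @export
tally_by_status <- function(profiles, rules = candidate_rules(), rank = NULL) {
  if (!length(profiles)) stop("empty input", call. = FALSE)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("'profiles' must be named by primer set", call. = FALSE)
  }
  is_prof <- vapply(profiles, inherits, logical(1L), "taxon_profile")
  if (any(is_prof)) {
    ranks <- unique(vapply(profiles[is_prof], `[[`, character(1L), "rank"))
    if (length(ranks) != 1L) stop("profiles span several ranks", call. = FALSE)
    rank <- rank %||% ranks
  }
  assert_rank(rank)
  label_sets <- lapply(profiles, function(p) {
    if (inherits(p, "taxon_profile")) profile_labels(p) else as.character(p)
  })
  canon <- lapply(label_sets, canonical_labels, rank = rank, rules = rules)

  status_counts <- function(labels) {
    st <- classify_labels(labels, rank, rules)
    c(n_affiliated = sum(st == "affiliated"),
      n_candidate  = sum(st == "candidate"),
      n_unassigned = sum(st == "unassigned"))
  }
  per <- t(vapply(canon, status_counts, numeric(3L)))
  per_primer <- data.frame(primer_set = rownames(per), per, row.names = NULL)
  per_primer$n_unaffiliated <- per_primer$n_candidate + per_primer$n_unassigned
  per_primer$n_total <- per_primer$n_unaffiliated + per_primer$n_affiliated

  union_all <- unique(unlist(canon))
  combined <- status_counts(union_all)
  shared <- if (length(canon) >= 2L) Reduce(intersect, canon) else canon[[1L]]
  shared_all <- status_counts(shared)

  structure(
    list(
      rank = rank,
      per_primer = per_primer,
      combined = combined,
      shared_all = shared_all,
      per_primer_unique = unique_taxa(canon),
      unaffiliated_fraction = unaffiliated_fraction(
        combined[["n_candidate"]] + combined[["n_unassigned"]],
        combined[["n_affiliated"]]
      )
    ),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat("<coverage_summary> rank=", x$rank, "\n", sep = "")
  print(x$per_primer, row.names = FALSE)
  cat("combined: affiliated=", x$combined[["n_affiliated"]],
      " candidate=", x$combined[["n_candidate"]],
      " unassigned=", x$combined[["n_unassigned"]],
      " | unaffiliated ", x$unaffiliated_fraction, "%\n", sep = "")
  invisible(x)
}

as_label_sets <- function(sets) {
  if (!is.list(sets)) stop("'sets' must be a list of label vectors", call. = FALSE)
  lapply(sets, function(s) {
    if (inherits(s, "taxon_profile")) unique(profile_labels(s)) else
      unique(as.character(s))
  })
}

#' Count taxa unique to one primer set
#'
#' A unique taxon is one revealed by exactly one of the sets.
#'
#' @param sets Named list of taxon label vectors (or profiles), one per
#'   primer set; at least two.
#' @return Named integer vector of unique-taxon counts per set.
#' @export
unique_taxa <- function(sets) {
  sets <- as_label_sets(sets)
  if (length(sets) < 2L) stop("need >= 2 sets", call. = FALSE)
  all_labels <- unlist(sets, use.names = FALSE)
  mult <- table(all_labels)
  singletons <- names(mult)[mult == 1L]
  vapply(sets, function(s) sum(s %in% singletons), integer(1L))
}

#' Fraction of taxa shared by all primer sets
#'
#' @param sets Named list of taxon label vectors; at least two.
#' @return List with `n_shared` (|intersection|), `n_union` (|union|) and
#'   `percentage` (`100 * shared / union`, one decimal).
#' @examples
#' shared_fraction(list(a = c("x", "y"), b = c("y", "z")))  # 1/3 = 33.3
#' @export
shared_fraction <- function(sets) {
  sets <- as_label_sets(sets)
  if (length(sets) < 2L) stop("need >= 2 sets", call. = FALSE)
  inter <- Reduce(intersect, sets)
  uni <- unique(unlist(sets))
  list(
    n_shared = length(inter),
    n_union = length(uni),
    percentage = round_half_away(100 * length(inter) / length(uni), 1L)
  )
}

#' Disjoint Venn partition of up to five taxon sets
#'
#' Assigns every taxon in the union to the cell indexed by the exact subset
#' of sets containing it; cell counts sum to the union size and, summed over
#' the cells containing a set, reproduce that set's size.
#'
#' @param sets Named list of 2--5 taxon label vectors.
#' @return Data frame with one row per non-empty subset: `cell` (set names
#'   joined by `&`), one logical membership column per set, and `count`.
#' @export
venn_partition <- function(sets) {
  sets <- as_label_sets(sets)
  k <- length(sets)
  if (k < 2L || k > 5L) stop("need 2--5 sets", call. = FALSE)
  nm <- names(sets) %||% paste0("set", seq_len(k))
  uni <- unique(unlist(sets))
  membership <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
  if (length(uni) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(r) paste(which(r), collapse = ","))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(subsets) <- nm
  subsets$cell <- apply(subsets[, nm, drop = FALSE], 1L, function(r)
    paste(nm[as.logical(r)], collapse = "&"))
  subsets$count <- vapply(seq_len(nrow(subsets)), function(i) {
    sum(key == paste(which(as.logical(subsets[i, nm])), collapse = ","))
  }, integer(1L))
  rownames(subsets) <- NULL
  subsets[, c("cell", nm, "count")]
}

#' Unaffiliated fraction of a taxon inventory
#'
#' `100 * U / (U + A)` where U counts candidate-plus-unassigned taxa and A
#' the affiliated ones; one decimal, half away from zero.
#'
#' @param n_unaffiliated,n_affiliated Non-negative counts, not both zero.
#' @return Percentage (one decimal).
#' @examples
#' unaffiliated_fraction(30, 27)   # 52.6
#' unaffiliated_fraction(103, 65)  # 61.3
#' @export
unaffiliated_fraction <- function(n_unaffiliated, n_affiliated) {
  stopifnot(n_unaffiliated >= 0, n_affiliated >= 0)
  if (n_unaffiliated + n_affiliated == 0) stop("no taxa", call. = FALSE)
  round_half_away(100 * n_unaffiliated / (n_unaffiliated + n_affiliated), 1L)
}

#' Fraction of taxa missed by a single primer set
#'
#' Relative shortfall of one primer set against the combined inventory:
#' `100 * (combined - single) / single`.
#'
#' @param combined_total Combined taxon count (>= `single_total`).
#' @param single_total Single-primer taxon count (> 0).
#' @return Percentage (one decimal).
#' @examples
#' missed_fraction(57, 44)    # 29.5
#' missed_fraction(168, 124)  # 35.5
#' @export
missed_fraction <- function(combined_total, single_total) {
  if (single_total <= 0) stop("single_total must be positive", call. = FALSE)
  if (combined_total < single_total) {
    stop("combined_total below single_total", call. = FALSE)
  }
  round_half_away(100 * (combined_total - single_total) / single_total, 1L)
}

#' Increase of the combined inventory over the best single primer set
#'
#' @param combined_count Combined taxon count.
#' @param per_primer_counts Per-primer taxon counts (max > 0).
#' @return Percentage (one decimal).
#' @examples
#' increase_vs_best_single(18, c(9, 12, 8, 10, 4))  # 50.0
#' @export
increase_vs_best_single <- function(combined_count, per_primer_counts) {
  if (!length(per_primer_counts)) stop("no per-primer counts", call. = FALSE)
  best <- max(per_primer_counts)
  if (best <= 0) stop("best single-primer count must be positive", call. = FALSE)
  round_half_away(100 * (combined_count - best) / best, 1L)
}

#' Relative-abundance summary by affiliation status
#'
#' Computes, over the representative reads of a merged profile, the number
#' of taxa, total relative abundance (%) and mean per-taxon abundance (%)
#' for each affiliation status. The Unassigned bucket is one taxon.
#'
#' @param m A [merge_profiles()] result.
#' @param rules A [candidate_rules()] object.
#' @return Data frame with columns `status`, `n_taxa`, `total_pct`,
#'   `mean_pct` (unrounded); totals sum to 100.
#' @export
abundance_by_status <- function(m, rules = candidate_rules()) {
  stopifnot(inherits(m, "merged_profile"))
  labels <- names(m$representative)
  status <- classify_labels(labels, m$rank, rules)
  rel <- 100 * m$representative / sum(m$representative)
  # the unassigned bucket is one unit regardless of distinct unassigned labels
  n_taxa <- c(
    affiliated = sum(status == "affiliated"),
    candidate  = sum(status == "candidate"),
    unassigned = as.integer(any(status == "unassigned"))
  )
  total <- vapply(names(n_taxa), function(s) sum(rel[status == s]), numeric(1L))
  data.frame(
    status = names(n_taxa),
    n_taxa = as.integer(n_taxa),
    total_pct = as.numeric(total),
    mean_pct = ifelse(n_taxa > 0, total / n_taxa, NA_real_),
    row.names = NULL
  )
}

#' Taxa shared across sample groups
#'
#' Size of the intersection of taxon sets across groups (e.g. the taxa
#' common to all host species examined).
#'
#' @param groups Named list of >= 2 taxon label vectors.
#' @return Integer intersection size.
#' @export
cross_group_shared <- function(groups) {
  groups <- as_label_sets(groups)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  length(Reduce(intersect, groups))
}
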