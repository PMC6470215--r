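# Synthetic multi-primer data generator. Every stage of the pipeline is
# testable against planted ground truth without any sequence download: the
# generator emulates per-region detection bias across five primer sets, a
# mixture of affiliated / candidate / unassigned taxa, a heavy-tailed
# (log-normal) abundance law, and read totals in the range produced by one
# MiSeq amplicon dataset per primer set.

PRIMER_SETS <- c("V1V3", "V4", "V4V5", "V5V8", "V6V9")

AFFILIATED_PHYLA <- c(
  "Acidobacteria", "Actinobacteria", "Aquificae", "Armatimonadetes",
  "Bacteroidetes", "Chlamydiae", "Chlorobi", "Chloroflexi", "Cyanobacteria",
  "Firmicutes", "Fusobacteria", "Gemmatimonadetes", "Lentisphaerae",
  "Nitrospirae", "Planctomycetes", "Proteobacteria", "Spirochaetes",
  "Synergistetes", "Tenericutes", "Thermotogae", "Verrucomicrobia",
  "Crenarchaeota", "Euryarchaeota"
)

#' Specification for the synthetic multi-primer generator
#'
#' Defaults describe one sponge-like dataset: 27 affiliated and 29
#' candidate phylum-level taxa, an unassigned bucket holding 10.8% of the
#' reads, per-primer detection probabilities that favour broadly
#' conserved-regions for affiliated taxa and vary strongly for candidate
#' taxa, log-normal abundances, and per-primer read budgets in the
#' 5x10^4--3x10^5 range typical of one MiSeq dataset per primer set.
#'
#' @param n_affiliated,n_candidate Numbers of affiliated and candidate taxa.
#' @param unassigned_mass Fraction of each primer's reads in the Unassigned
#'   bucket.
#' @param detect_prob List with elements `affiliated` and `candidate`:
#'   named per-primer detection probabilities.
#' @param read_budget Named per-primer total read counts.
#' @param meanlog,sdlog Log-normal abundance-law parameters.
#' @param n_samples Number of samples.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_affiliated = 27, n_candidate = 29,
                           unassigned_mass = 0.108,
                           detect_prob = list(
                             affiliated = c(V1V3 = 0.85, V4 = 0.80,
                                            V4V5 = 0.85, V5V8 = 0.90,
                                            V6V9 = 0.75),
                             candidate  = c(V1V3 = 0.25, V4 = 0.40,
                                            V4V5 = 0.35, V5V8 = 0.65,
                                            V6V9 = 0.20)
                           ),
                           read_budget = c(V1V3 = 96000, V4 = 100000,
                                           V4V5 = 172000, V5V8 = 299000,
                                           V6V9 = 57000),
                           meanlog = 0, sdlog = 2,
                           n_samples = 1, seed = 1) {
  stopifnot(n_affiliated >= 0, n_candidate >= 0,
            unassigned_mass >= 0, unassigned_mass < 1,
            all(unlist(detect_prob) >= 0), all(unlist(detect_prob) <= 1),
            all(read_budget > 0), n_samples >= 1)
  if (!setequal(names(detect_prob$affiliated), names(read_budget))) {
    stop("detect_prob and read_budget must cover the same primer sets",
         call. = FALSE)
  }
  structure(
    list(n_affiliated = n_affiliated, n_candidate = n_candidate,
         unassigned_mass = unassigned_mass, detect_prob = detect_prob,
         read_budget = read_budget, meanlog = meanlog, sdlog = sdlog,
         n_samples = n_samples, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

synth_candidate_codes <- function(n) {
  # candidate vocabulary first, then synthetic uppercase-digit codes that
  # exercise the pattern fallback (e.g. "ZZ9")
  vocab <- greengenes_candidate_divisions()
  if (n <= length(vocab)) return(vocab[seq_len(n)])
  extra_n <- n - length(vocab)
  letters2 <- apply(expand.grid(LETTERS, LETTERS), 1L, paste0, collapse = "")
  extra <- paste0(letters2[seq_len(extra_n)], (seq_len(extra_n) %% 10))
  c(vocab, extra)
}

#' Generate a taxon pool with planted affiliation statuses
#'
#' Produces `n_affiliated` validly named and `n_candidate` provisional
#' phylum-level lineages (Greengenes syntax). Planted statuses are
#' recoverable via [classify_affiliation()].
#'
#' @param spec A [generator_spec()].
#' @return Data frame with `lineage` and `status`.
#' @export
simulate_pool <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n_aff <- spec$n_affiliated
  n_can <- spec$n_candidate
  aff_names <- if (n_aff <= length(AFFILIATED_PHYLA)) {
    AFFILIATED_PHYLA[seq_len(n_aff)]
  } else {
    c(AFFILIATED_PHYLA,
      paste0("Novelphylia", seq_len(n_aff - length(AFFILIATED_PHYLA))))
  }
  can_names <- synth_candidate_codes(n_can)
  lineage <- c(
    if (n_aff) paste0("k__Bacteria;p__", aff_names),
    if (n_can) paste0("k__Bacteria;p__", can_names)
  )
  data.frame(
    lineage = lineage %||% character(0),
    status = rep(c("affiliated", "candidate"), c(n_aff, n_can)),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-primer taxon profiles with planted ground truth
#'
#' Each (taxon, primer set) detection indicator is drawn independently with
#' the status-specific probability; detected taxa receive log-normal
#' abundance weights scaled to the primer's read budget (minus the
#' Unassigned mass, which is added as one bucket row). The returned ground
#' truth records the detection matrix and the derived unique/shared
#' partition so downstream statistics can be checked exactly.
#'
#' @param pool Output of [simulate_pool()].
#' @param spec A [generator_spec()].
#' @param sample_id Sample identifier.
#' @return List with `profiles` (named list primer set -> [taxon_profile()])
#'   and `truth` (detection matrix, statuses, per-primer unique counts,
#'   all-primer shared count, union size).
#' @export
simulate_profiles <- function(pool, spec, sample_id = "sample1") {
  stopifnot(inherits(spec, "generator_spec"), nrow(pool) >= 1L)
  set.seed(spec$seed)
  primers <- names(spec$read_budget)
  n <- nrow(pool)
  detect <- matrix(FALSE, n, length(primers),
                   dimnames = list(pool$lineage, primers))
  for (p in primers) {
    prob <- vapply(pool$status, function(s) spec$detect_prob[[s]][[p]],
                   numeric(1L))
    detect[, p] <- stats::runif(n) < prob
  }
  if (!any(detect)) stop("zero detection everywhere", call. = FALSE)

  profiles <- stats::setNames(vector("list", length(primers)), primers)
  for (p in primers) {
    idx <- which(detect[, p])
    budget <- spec$read_budget[[p]]
    counts <- numeric(0)
    if (length(idx)) {
      w <- stats::rlnorm(length(idx), spec$meanlog, spec$sdlog)
      taxon_budget <- budget * (1 - spec$unassigned_mass)
      counts <- stats::setNames(pmax(1, round(w / sum(w) * taxon_budget)),
                                pool$lineage[idx])
    }
    counts <- c(counts, Unassigned = max(1, round(budget * spec$unassigned_mass)))
    profiles[[p]] <- taxon_profile(sample_id, p, "phylum", counts = counts)
  }

  detected_any <- rowSums(detect) > 0L
  truth <- list(
    detection = detect,
    status = stats::setNames(pool$status, pool$lineage),
    unique_counts = apply(detect, 2L, function(col) sum(col & rowSums(detect) == 1L)),
    shared_all = sum(rowSums(detect) == length(primers)),
    union_size = sum(detected_any)
  )
  list(profiles = profiles, truth = truth)
}

#' Build label sets satisfying printed overlap marginals
#'
#' Constructs `k` taxon label sets with exact per-set sizes, an exact
#' all-set intersection and an exact union — the quantities printed in
#' primer-comparison tables — so overlap statistics can be recomputed on a
#' concrete instance. Construction is deterministic: the common core is
#' allocated first, then the remaining labels receive multiplicities
#' (capped at `k - 1` so the intersection stays exact) and are assigned
#' greedily to the sets with most remaining capacity.
#'
#' @param sizes Integer vector of per-set sizes (length `k >= 2`).
#' @param n_shared Size of the intersection of all sets.
#' @param n_union Size of the union.
#' @param labels Optional pool of `n_union` labels (generated as
#'   `taxon001...` otherwise).
#' @return Named list of `k` character vectors.
#' @export
fixture_from_marginals <- function(sizes, n_shared, n_union, labels = NULL) {
  k <- length(sizes)
  stopifnot(k >= 2L, all(sizes >= 0), n_shared >= 0, n_union >= 0)
  if (n_shared > min(sizes)) {
    stop("infeasible: intersection ", n_shared, " > smallest set size ",
         min(sizes), call. = FALSE)
  }
  if (n_union < max(sizes)) {
    stop("infeasible: union ", n_union, " < largest set size ", max(sizes),
         call. = FALSE)
  }
  if (n_union > sum(sizes)) {
    stop("infeasible: union ", n_union, " > sum of set sizes ", sum(sizes),
         call. = FALSE)
  }
  n_extra <- n_union - n_shared
  capacity <- sizes - n_shared
  spare <- sum(capacity) - n_extra
  if (spare < 0) {
    stop("infeasible: union ", n_union,
         " exceeds intersection plus total spare capacity ", call. = FALSE)
  }
  if (k > 1L && spare > n_extra * (k - 2L)) {
    stop("infeasible: total set size forces an extra all-shared taxon ",
         "(intersection would exceed ", n_shared, ")", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sprintf("taxon%03d", seq_len(n_union))
  }
  stopifnot(length(labels) >= n_union, !anyDuplicated(labels))
  core <- labels[seq_len(n_shared)]
  extra <- labels[n_shared + seq_len(n_extra)]

  # multiplicities: every extra label in >= 1 set, spare capacity spread
  # left to right up to k - 1 memberships per label
  mult <- rep(1L, n_extra)
  rem <- spare
  j <- 1L
  while (rem > 0L && j <= n_extra) {
    add <- min(k - 1L - mult[j], rem)
    mult[j] <- mult[j] + add
    rem <- rem - add
    j <- j + 1L
  }
  sets <- lapply(seq_len(k), function(i) core)
  cap <- capacity
  for (j in order(mult, decreasing = TRUE)) {
    take <- order(cap, decreasing = TRUE)[seq_len(mult[j])]
    if (any(cap[take] <= 0L)) {
      stop("infeasible: capacity exhausted while placing shared labels",
           call. = FALSE)
    }
    for (i in take) sets[[i]] <- c(sets[[i]], extra[j])
    cap[take] <- cap[take] - 1L
  }
  names(sets) <- names(sizes) %||% paste0("set", seq_len(k))
  sets
}

#' Simulate an observed mock-community profile
#'
#' Perturbs the expected fractions with multiplicative log-normal noise and
#' renormalises; at `noise = 0` the observed fractions equal the expected
#' ones exactly, and concordance degrades in expectation as noise grows.
#'
#' @param expected A [mock_composition()].
#' @param noise Standard deviation of the log-normal perturbation (>= 0).
#' @param seed Integer seed.
#' @param primer_set,sample_id Labels for the returned profile.
#' @return A fractional [taxon_profile()] at genus rank.
#' @export
simulate_mock <- function(expected, noise = 0.1, seed = 1,
                          primer_set = "V4", sample_id = "mock") {
  stopifnot(inherits(expected, "mock_composition"), noise >= 0)
  set.seed(as.integer(seed))
  e <- expected$fractions
  w <- e * exp(stats::rnorm(length(e), 0, noise))
  taxon_profile(sample_id, primer_set, "genus", relative = w / sum(w))
}
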