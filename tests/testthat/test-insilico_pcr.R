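test_that("degenerate expansion enumerates IUPAC combinations", {
  expect_setequal(expand_degenerate("AR"), c("AA", "AG"))
  expect_setequal(expand_degenerate("N"), c("A", "C", "G", "T"))
  v4f <- expand_degenerate("GTGYCAGCMGCCGCGGTAA")
  expect_length(v4f, 4L)  # Y x M = 2 x 2
  expect_true(all(grepl("^GTG[CT]CAGC[AC]GCCGCGGTAA$", v4f)))
  expect_equal(degenerate_primer("x", "NNNNN")$degeneracy, 4^5)
  expect_error(expand_degenerate("NNNNNNN", cap = 256), "cap")
  expect_error(degenerate_primer("x", "ACGU"), "invalid IUPAC")
})

test_that("primer matching honours IUPAC semantics, anchors and strict N", {
  expect_equal(match_primer("ACGT", "TTACGTTT")$start, 2L)
  expect_equal(match_primer("AYGT", "TTACGTTT")$start, 2L)  # Y matches C
  # one mismatch allowed outside the anchor
  hit <- match_primer("TCGT", "TTACGTTT", max_mismatch = 1, anchor_3prime = 3)
  expect_equal(hit$start, 2L)
  expect_equal(hit$mismatches, 1L)
  # same mismatch inside the 3' anchor is rejected
  expect_equal(nrow(match_primer("ACGA", "TTACGTTT", max_mismatch = 1,
                                 anchor_3prime = 3)), 0L)
  # N in the reference matches nothing in strict mode
  expect_equal(nrow(match_primer("ACGT", "TTANGTTT")), 0L)
  expect_error(match_primer("ACGT", ""), "empty")
})

test_that("window matcher agrees with the expand-and-scan oracle", {
  set.seed(19)
  for (rep in 1:15) {
    ref <- random_dna(200)
    primer <- random_degenerate(18, n_ambig = sample(1:3, 1))
    for (mm in 0:1) {
      got <- match_primer(primer, ref, max_mismatch = mm, anchor_3prime = 3)
      exp <- oracle_match(primer, ref, max_mismatch = mm, anchor = 3)
      expect_equal(got$start, exp$start,
                   info = paste("primer", primer, "mm", mm))
      expect_equal(got$mismatches, exp$mismatches,
                   info = paste("primer", primer, "mm", mm))
    }
  }
})

test_that("window matcher agrees with Biostrings on non-degenerate exact search", {
  set.seed(23)
  ref <- random_dna(500)
  primer <- random_dna(12)
  got <- match_primer(primer, ref, max_mismatch = 0, anchor_3prime = 0)
  bs <- Biostrings::matchPattern(primer, Biostrings::DNAString(ref))
  expect_equal(got$start, BiocGenerics::start(bs) - 1L)
})

test_that("matching is reverse-complement symmetric at mirrored coordinates", {
  set.seed(31)
  ref <- random_dna(300)
  primer <- random_degenerate(16)
  fwd <- match_primer(primer, ref, max_mismatch = 1, anchor_3prime = 0)
  rc <- match_primer(reverse_complement(primer), reverse_complement(ref),
                     max_mismatch = 1, anchor_3prime = 0)
  mirrored <- sort(nchar(ref) - (rc$start + 16L))
  expect_equal(sort(fwd$start), mirrored)
})

test_that("amplicon finding pairs nearest valid sites within length bounds", {
  fwd <- "ACGTACGTAC"
  rev <- "GGCCAAGGCC"   # given 5'->3' on the minus strand
  cassette <- paste0(fwd, random_dna(150), reverse_complement(rev))
  pp <- primer_pair(fwd, rev, min_len = 50, max_len = 500)

  one <- find_amplicons(pp, paste0(random_dna(30), cassette, random_dna(30)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$inner_length, 150L)
  expect_equal(one$amplicon_start, 30 + nchar(fwd))
  expect_equal(one$amplicon_end - one$amplicon_start, one$inner_length)

  # missing reverse site gives no amplicon
  none <- find_amplicons(pp, paste0(random_dna(20), fwd, random_dna(100)))
  expect_equal(nrow(none), 0L)

  # tandem cassettes give two non-overlapping amplicons
  two <- find_amplicons(pp, paste0(cassette, random_dna(40), cassette))
  expect_equal(nrow(two), 2L)
  expect_lte(two$rev_end[1], two$fwd_start[2])

  # bounds exclude too-short products
  tight <- primer_pair(fwd, rev, min_len = 200, max_len = 500)
  expect_equal(nrow(find_amplicons(tight, cassette)), 0L)
})

test_that("rank coverage reflects planted primer-site mutations", {
  fwd <- "ACGTACGTAC"
  rev <- "GGCCAAGGCC"
  pp <- primer_pair(fwd, rev, min_len = 50, max_len = 500)
  set.seed(41)
  good <- function() paste0(fwd, random_dna(100), reverse_complement(rev))
  broken <- function() paste0("TTTTTTTTTT", random_dna(100), reverse_complement(rev))
  refs <- c(a1 = good(), a2 = good(), a3 = good(), a4 = broken(),
            b1 = good(), b2 = broken())
  lin <- c(a1 = "k__Bacteria;p__Alpha", a2 = "k__Bacteria;p__Alpha",
           a3 = "k__Bacteria;p__Alpha", a4 = "k__Bacteria;p__Alpha",
           b1 = "k__Bacteria;p__Beta", b2 = "k__Bacteria;p__Beta")
  cov <- rank_coverage(pp, refs, lin, "phylum")
  expect_equal(cov$fraction[cov$taxon == "Alpha"], 0.75)
  expect_equal(cov$fraction[cov$taxon == "Beta"], 0.5)
  expect_equal(attr(cov, "overall"), 4 / 6)
  # all amplifiable: every taxon at 1
  all_good <- c(a1 = good(), b1 = good())
  cov2 <- rank_coverage(pp, all_good, lin[c("a1", "b1")], "phylum")
  expect_true(all(cov2$fraction == 1))
})

test_that("coverage is monotone in the mismatch budget", {
  fwd <- "ACGTACGTAC"
  rev <- "GGCCAAGGCC"
  set.seed(43)
  mutate1 <- function(s, pos) {
    chars <- strsplit(s, "")[[1L]]
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1L]
    paste(chars, collapse = "")
  }
  refs <- vapply(1:8, function(i) {
    f <- if (i %% 2 == 0) mutate1(fwd, 2L) else fwd  # mutation outside anchor
    paste0(f, random_dna(80), reverse_complement(rev))
  }, character(1L))
  names(refs) <- paste0("r", 1:8)
  lin <- stats::setNames(rep("k__Bacteria;p__Alpha", 8), names(refs))
  frac <- vapply(0:2, function(mm) {
    pp <- primer_pair(fwd, rev, max_mismatch = mm, min_len = 10, max_len = 500)
    attr(rank_coverage(pp, refs, lin, "phylum"), "overall")
  }, numeric(1L))
  expect_equal(frac[1], 0.5)
  expect_equal(frac[2], 1)
  expect_true(all(diff(frac) >= 0))
})

test_that("reference FASTA and taxonomy map readers feed rank_coverage", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 desc", "ACGTACGTACGT", ">r2", "GGGGCCCCAAAA"), fa)
  refs <- read_reference_fasta(fa)
  expect_equal(names(refs), c("r1", "r2"))
  expect_equal(unname(refs["r1"]), "ACGTACGTACGT")
  tx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tk__Bacteria;p__Alpha", "r2\tk__Bacteria;p__Beta"), tx)
  lin <- read_taxonomy_map(tx)
  expect_equal(unname(lin["r2"]), "k__Bacteria;p__Beta")
})

test_that("primer pairs load from a YAML config without shipped defaults", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "V4:",
    "  forward: GTGYCAGCMGCCGCGGTAA",
    "  reverse: GGACTACNVGGGTWTCTAAT",
    "  max_mismatch: 1",
    "  min_len: 100",
    "  max_len: 500"
  ), yml)
  pairs <- read_primer_config(yml)
  expect_named(pairs, "V4")
  expect_equal(pairs$V4$max_mismatch, 1)
  expect_equal(pairs$V4$forward$sequence, "GTGYCAGCMGCCGCGGTAA")
})
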