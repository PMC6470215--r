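# Shared internal helpers.

# Rank order and Greengenes prefix letters; fixed for the 7-rank dialect.
GG_RANKS <- c(
  kingdom = "k", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s"
)

# Rounding used for every reported percentage: half away from zero.
# base::round() rounds half to even, which does not reproduce printed
# one-decimal percentages such as 35.5 from 44/124.
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_rank <- function(rank) {
  if (!is.character(rank) || length(rank) != 1L || !rank %in% names(GG_RANKS)) {
    stop("unknown rank name: ", deparse(rank),
         " (expected one of ", paste(names(GG_RANKS), collapse = ", "), ")",
         call. = FALSE)
  }
  rank
}
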