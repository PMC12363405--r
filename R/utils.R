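# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

.assert_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", what, "` must be a single probability in [0, 1]."))
  }
  invisible(x)
}

.assert_pos <- function(x, what, strict = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(if (strict) x > 0 else x >= 0)
  if (!ok) abort(paste0("`", what, "` must be ", if (strict) "positive." else "non-negative."))
  invisible(x)
}

# deterministic sub-seed derivation; keeps results < 2^31 so they are valid R
# integer seeds whatever the caller passes
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(offset)) %% 2147483629)
}

# n random fixed-length UMIs
rand_umis <- function(n, len = 10L) {
  if (n == 0L) return(character())
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# truncated normal by inverse CDF
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# for each base in `cur`, a uniformly chosen different base
other_base <- function(cur) {
  idx <- match(cur, BASES)
  BASES[(idx + sample.int(3L, length(cur), replace = TRUE) - 1L) %% 4L + 1L]
}

# number of molecules whose [start, end] span covers each position;
# pos_chrom/pos must be parallel vectors
span_coverage <- function(mol_chrom, mol_start, mol_end, pos_chrom, pos) {
  out <- integer(length(pos))
  for (ch in unique(pos_chrom)) {
    sel <- mol_chrom == ch
    s <- sort(mol_start[sel])
    e <- sort(mol_end[sel])
    at <- pos_chrom == ch
    p <- pos[at]
    out[at] <- findInterval(p, s) - findInterval(p - 1L, e)
  }
  out
}

# one-sided binomial tail P(X >= k | n, p); exact, vectorised
binom_tail <- function(k, n, p) {
  ifelse(k <= 0, 1, pbinom(k - 1, n, p, lower.tail = FALSE))
}
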