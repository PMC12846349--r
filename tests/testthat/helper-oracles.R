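# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: alignment scores come from explicit enumeration
# of alignments, Fisher p-values from binomial-coefficient enumeration over
# same-margin tables, and frameshift decisions from a direct codon walk.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Maximum global alignment score by exhaustive recursion over all
# alignments (three moves per cell, no memoisation): a true brute force,
# feasible for short sequences only.
bf_align_score <- function(a, b, match, mismatch, gap) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (av[i] == bv[j]) match else mismatch)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(av), length(bv))
}

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, using binomial coefficients (not dhyper).
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  denom <- choose(n, c1)
  probs <- vapply(lo:hi, function(aa)
    choose(r1, aa) * choose(r2, c1 - aa) / denom, numeric(1L))
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Direct -1 frameshift decision by walking codons on the coding strand:
# given the local motif start (0-based) and ORF length, translate the -1
# frame starting right after the slip and report the first stop.
oracle_minus1 <- function(coding_seq, orf_len, motif_start,
                          motif_len = 6L) {
  stop0 <- orf_len - 3L
  slip <- motif_start + motif_len - 1L
  pos <- slip
  stops <- c("TAA", "TAG", "TGA")
  repeat {
    if (pos + 3L > nchar(coding_seq))
      return(list(premature = FALSE, extension = NA_integer_,
                  unterminated = TRUE))
    codon <- substring(coding_seq, pos + 1L, pos + 3L)
    if (codon %in% stops) {
      if (pos < stop0)
        return(list(premature = TRUE, extension = 0L,
                    unterminated = FALSE))
      return(list(premature = FALSE,
                  extension = as.integer(pos + 3L - stop0),
                  unterminated = FALSE))
    }
    pos <- pos + 3L
  }
}

# All DNA sequences over an alphabet up to a maximum length.
all_seqs <- function(alphabet, max_len) {
  out <- character(0)
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}

degap <- function(x) gsub("-", "", x)
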