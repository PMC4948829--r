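# Independent oracles used across the suite. Each is a deliberately
# simple, slow implementation kept separate from the package's code
# paths.

# exhaustive affine-gap semi-global alignment score by memoized
# recursion over (i, j, state); trailing gaps of either sequence are
# free. Gap of length L costs gap_open + L * gap_extend.
oracle_align_score <- function(ref, clone, match = 1, mismatch = -2,
                               gap_open = -4, gap_extend = -1) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(clone, "")[[1]]
  n <- length(a); m <- length(b)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  # best score aligning a[i..n] vs b[j..m], st: 0 fresh, 1 in ref-consuming
  # gap, 2 in clone-consuming gap
  rec <- function(i, j, st) {
    key <- paste(i, j, st)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > n && j > m) {
      res <- 0
    } else if (i > n) {        # remaining clone aligned to free gaps
      res <- 0
    } else if (j > m) {        # remaining ref aligned to free gaps
      res <- 0
    } else {
      s <- if (a[i] == b[j]) match else mismatch
      res <- s + rec(i + 1, j + 1, 0)
      open1 <- if (st == 1) gap_extend else gap_open + gap_extend
      open2 <- if (st == 2) gap_extend else gap_open + gap_extend
      res <- max(res,
                 open1 + rec(i + 1, j, 1),   # gap in clone, consume ref
                 open2 + rec(i, j + 1, 2))   # gap in ref, consume clone
      # free trailing gaps permitted only when one side is exhausted,
      # handled by the boundary cases above
    }
    memo[[key]] <- res
    res
  }
  rec(1, 1, 0)
}

# two-sided Fisher exact p by full hypergeometric enumeration: sum the
# probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed table's
oracle_fisher <- function(k1, n1, k2, n2) {
  kt <- k1 + k2
  lo <- max(0, kt - n2)
  hi <- min(kt, n1)
  xs <- lo:hi
  probs <- dhyper(xs, n1, n2, kt)
  p_obs <- dhyper(k1, n1, n2, kt)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# permutation test for a difference in group means, two-sided
oracle_perm_t <- function(x, y, n_perm = 1e4) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y)
  nx <- length(x)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(z), nx)
    if (abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / n_perm
}

# all strings of a given length over an alphabet
all_strings <- function(len, alphabet = c("T", "G")) {
  if (len == 0) return("")
  grids <- rep(list(alphabet), len)
  apply(do.call(expand.grid, grids), 1, paste, collapse = "")
}
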