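#' Alignment scoring parameters
#'
#' Scoring used by [align_clone()]. The defaults penalize gap placement
#' inside low-complexity TG repeats (a gap must buy at least three matches
#' to beat a mismatch) while leaving distal length differences from
#' end-replication shortening free.
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -2).
#' @param gap_open gap opening penalty (default -4); a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param gap_extend per-base gap extension penalty (default -1).
#' @return An object of class `align_scoring`.
#' @export
#' @examples
#' align_scoring()
align_scoring <- function(match = 1, mismatch = -2,
                          gap_open = -4, gap_extend = -1) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend),
            match > mismatch, gap_extend <= 0, gap_open <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Align a clone against a reference telomere
#'
#' Semi-global pairwise alignment with affine gap penalties. Both sequences
#' are anchored at the proximal (left, centromere-proximal) end; trailing
#' gaps at the distal (right) end of the shorter sequence are free, so
#' clones shortened by the end-replication problem align as exact prefixes.
#' Deterministic: score ties are broken by preferring a match/mismatch
#' column over a gap, then a gap in the reference over a gap in the clone.
#'
#' @param clone clone sequence (character scalar, A/C/G/T).
#' @param reference reference sequence (character scalar, A/C/G/T).
#' @param scoring an [align_scoring()] object.
#' @param clone_id,reference_id identifiers carried into the result.
#' @return An object of class `telo_alignment`: a list with `reference_id`,
#'   `clone_id`, `ref_aln` and `clone_aln` (gapped strings of equal length,
#'   `-` for gaps, never gap against gap), and `score`.
#' @export
#' @examples
#' aln <- align_clone("TGGTGGG", "TGGTGTGGG")
#' aln$score
align_clone <- function(clone, reference, scoring = align_scoring(),
                        clone_id = "clone", reference_id = "reference") {
  stopifnot(is.character(clone), length(clone) == 1L,
            is.character(reference), length(reference) == 1L)
  if (!nzchar(clone) || !nzchar(reference))
    stop("both sequences must be non-empty")
  res <- .align_semiglobal_cpp(reference, clone,
                               scoring$match, scoring$mismatch,
                               scoring$gap_open, scoring$gap_extend)
  structure(list(reference_id = reference_id, clone_id = clone_id,
                 ref_aln = res$ref_aln, clone_aln = res$clone_aln,
                 score = res$score),
            class = "telo_alignment")
}

#' @export
print.telo_alignment <- function(x, ...) {
  cat("Pairwise telomere alignment (", x$clone_id, " vs ",
      x$reference_id, "), score ", x$score, "\n", sep = "")
  w <- 60L
  n <- nchar(x$ref_aln)
  for (s in seq(1L, n, by = w)) {
    e <- min(s + w - 1L, n)
    cat("ref   ", substr(x$ref_aln, s, e), "\n",
        "clone ", substr(x$clone_aln, s, e), "\n\n", sep = "")
  }
  invisible(x)
}

# column classification shared by the caller:
# M = match, S = substitution, D = gap in clone (reference base unmatched),
# I = gap in reference (clone insertion)
.alignment_column_types <- function(aln) {
  r <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  q <- strsplit(aln$clone_aln, "", fixed = TRUE)[[1]]
  if (length(r) != length(q))
    stop("corrupt alignment: unequal gapped lengths")
  if (any(r == "-" & q == "-"))
    stop("corrupt alignment: gap-against-gap column")
  type <- ifelse(r == "-", "I", ifelse(q == "-", "D",
                                       ifelse(r == q, "M", "S")))
  list(ref = r, clone = q, type = type)
}
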