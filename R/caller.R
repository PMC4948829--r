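#' Divergence tolerance rules
#'
#' The classification rules for deciding where a clone stops matching the
#' reference telomere. A clone is non-divergent where it matches the
#' reference perfectly, where it carries isolated point substitutions, and
#' where it carries insertions or deletions of at most `max_indel_nt`
#' nucleotides. Undiverged spans shorter than `truncation_threshold_nt`
#' are flagged as truncation events: end-replication attrition alone
#' (3-4 bp per generation) cannot plausibly produce telomeres that short.
#'
#' In addition to the two explicit rules, an unalignable-tail detector
#' terminates the undiverged span where the distal alignment degrades into
#' the scattered mismatches characteristic of differing degenerate
#' repeats: a likelihood-ratio changepoint on substitution columns
#' contrasts a null per-column mismatch probability
#' (`tail_null_mismatch`) against the column identity that two unrelated
#' TG1-3 repeat stretches reach under this aligner
#' (`tail_diverged_identity`). Gap runs within the tolerated size are
#' masked from this statistic so that a lone 6-nt indel can never look
#' like a divergent tail.
#'
#' @param max_indel_nt longest tolerated insertion/deletion run, in nt
#'   (default 6; the boundary is inclusive, a 6-nt indel is tolerated).
#' @param allow_isolated_substitutions tolerate isolated point mutations
#'   (default `TRUE`). When `FALSE` any substitution terminates the
#'   undiverged span.
#' @param max_substitution_run longest tolerated run of consecutive
#'   substitution columns (default 1, i.e. isolated point mutations only).
#' @param truncation_threshold_nt undiverged spans strictly below this are
#'   flagged as truncations (default 125 nt).
#' @param tail_null_mismatch per-column substitution probability expected
#'   from technical noise alone (default 0.01, deliberately conservative
#'   relative to typical high-fidelity PCR/Sanger error rates).
#' @param tail_diverged_identity column identity two unrelated degenerate
#'   repeat stretches reach when optimally aligned under the default
#'   scoring (default 0.77, measured on simulated unrelated TG1-3
#'   stretches).
#' @param tail_llr_threshold log-likelihood ratio a distal segment must
#'   exceed to be called an unalignable tail (default 7; at the default
#'   probabilities at least three clustered substitution-scored columns
#'   are required, so isolated point mutations can never trigger it).
#' @param tail_refine_margin log-likelihood slack used to refine the
#'   changepoint proximally: the divergence point is placed at the
#'   proximal-most non-match run whose suffix likelihood ratio is within
#'   this margin of the optimum (default 4).
#' @param junction_merge_nt positional-refinement merge distance: once a
#'   divergent tail (or substitution-run violation) is detected, the
#'   junction is re-located by a gap-free positional scan in the frame
#'   set by the proximal alignment, merging mismatches separated by
#'   fewer than this many matching positions (default 16, about the
#'   distance at which a stray technical substitution becomes more
#'   likely than a 0.44-per-position divergent-tail mismatch).
#' @return An object of class `divergence_rules`.
#' @export
#' @examples
#' divergence_rules()
divergence_rules <- function(max_indel_nt = 6L,
                             allow_isolated_substitutions = TRUE,
                             max_substitution_run = 1L,
                             truncation_threshold_nt = 125L,
                             tail_null_mismatch = 0.01,
                             tail_diverged_identity = 0.77,
                             tail_llr_threshold = 7,
                             tail_refine_margin = 4,
                             junction_merge_nt = 16L) {
  max_indel_nt <- as.integer(max_indel_nt)
  max_substitution_run <- as.integer(max_substitution_run)
  truncation_threshold_nt <- as.integer(truncation_threshold_nt)
  stopifnot(max_indel_nt >= 1L, truncation_threshold_nt >= 1L,
            max_substitution_run >= 1L,
            is.logical(allow_isolated_substitutions),
            tail_null_mismatch > 0, tail_null_mismatch < 1,
            tail_diverged_identity > 0, tail_diverged_identity < 1,
            tail_llr_threshold > 0, tail_refine_margin >= 0,
            junction_merge_nt >= 1)
  structure(list(max_indel_nt = max_indel_nt,
                 allow_isolated_substitutions = allow_isolated_substitutions,
                 max_substitution_run = max_substitution_run,
                 truncation_threshold_nt = truncation_threshold_nt,
                 tail_null_mismatch = tail_null_mismatch,
                 tail_diverged_identity = tail_diverged_identity,
                 tail_llr_threshold = tail_llr_threshold,
                 tail_refine_margin = tail_refine_margin,
                 junction_merge_nt = as.integer(junction_merge_nt)),
            class = "divergence_rules")
}

# gap-run evidence in the tail statistic: a gap run contributes at most
# two columns, each at a slightly discounted weight relative to a
# substitution column (gaps inside a divergent tail are common but a
# tolerated small indel is a single event whatever its length); with
# the default threshold a lone small indel plus one flanking
# substitution cannot trigger detection
.TAIL_GAP_CAP <- 2L
.TAIL_GAP_COL_LLR <- 3.0

# unalignable-tail changepoint over the core alignment columns: returns
# the column index where the divergent segment starts, or NA.
# Suffix log-likelihood ratio with per-column scores: substitution and
# (capped) gap columns score log((1-q1)/e0), matches log(q1/(1-e0));
# detection requires the best suffix to exceed the threshold, after which
# the changepoint is refined proximally by merging non-match runs
# separated by fewer than tail_merge_gap_cols matching columns.
.tail_changepoint <- function(core, rules) {
  if (!length(core) || all(core == "M")) return(NULL)
  e0 <- rules$tail_null_mismatch
  q1 <- rules$tail_diverged_identity
  s_mis <- log((1 - q1) / e0)
  s_mat <- log(q1 / (1 - e0))
  sc <- ifelse(core == "M", s_mat, s_mis)
  runs <- rle(core)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  for (q in which(runs$values %in% c("D", "I"))) {
    sc[run_start[q]:run_end[q]] <- 0
    keep <- run_start[q]:min(run_end[q], run_start[q] + .TAIL_GAP_CAP - 1L)
    sc[keep] <- .TAIL_GAP_COL_LLR
  }
  suf <- rev(cumsum(rev(sc)))
  best <- max(suf)
  if (best <= rules$tail_llr_threshold) return(NULL)
  t_hat <- which(suf == best)[1L]  # proximal-most maximizer
  # refine: the divergent segment starts at the proximal-most non-match
  # run whose suffix likelihood is within the refinement margin of the
  # optimum, so a handful of coincidental matches just distal of the
  # true junction cannot push the changepoint away from it
  nm <- which(runs$values != "M")
  cand <- run_start[nm][run_start[nm] <= t_hat]
  ok <- suf[cand] >= best - rules$tail_refine_margin
  cand[which(ok)[1L]]
}

# positional junction refinement. The aligner places gaps liberally
# inside a diverged tail (two unrelated TG1-3 stretches align at high
# identity), which blurs the junction in alignment coordinates; in
# positional coordinates — the frame fixed by the alignment in the
# matching region proximal of the junction — the junction is sharp:
# per-position mismatch density jumps from ~0 to ~0.44. Because
# artifactual gaps between the true junction and the detected
# changepoint can corrupt the frame, two candidate frames are tried:
# the alignment frame well proximal of the candidate (40 nt back) and
# the frame immediately at it. For each frame, the scan starts from the
# most distal mismatch near the candidate and walks proximally across
# mismatches separated by fewer than junction_merge_nt matching
# positions; the landing is validated by requiring its proximal flank
# to be essentially matching (which also guards against frame breaks at
# real indels). The most proximal validated landing wins; NA keeps the
# alignment-based point.
.refine_junction_positional <- function(cols, ref_cum, junction_col,
                                        rules, masked_sub = integer()) {
  ref_chars <- cols$ref[cols$ref != "-"]
  clone_chars <- cols$clone[cols$clone != "-"]
  clone_cum <- cumsum(cols$clone != "-")
  ref_base_cols <- which(cols$ref != "-")
  n_ref <- length(ref_chars)
  n_clone <- length(clone_chars)
  r0 <- if (junction_col > 1L) ref_cum[junction_col - 1L] else 0L
  delta_at <- function(p) {
    if (p < 1L) return(0L)
    clone_cum[ref_base_cols[p]] - p
  }
  deltas <- unique(c(delta_at(max(1L, r0 - 40L)),
                     if (junction_col > 1L)
                       clone_cum[junction_col - 1L] - r0 else 0L))
  p_lo <- max(1L, r0 - 60L)
  p_hi <- min(n_ref, r0 + 30L)
  if (p_hi < p_lo) return(NA_integer_)

  attempt <- function(delta) {
    p <- p_lo:p_hi
    p <- p[p + delta >= 1L & p + delta <= n_clone]
    if (!length(p)) return(NA_integer_)
    mism <- p[ref_chars[p] != clone_chars[p + delta]]
    if (length(masked_sub)) mism <- setdiff(mism, masked_sub)
    if (!length(mism)) return(NA_integer_)
    chain <- integer()
    k <- length(mism)
    chain <- mism[k]
    while (k > 1L &&
           (mism[k] - mism[k - 1L] - 1L) < rules$junction_merge_nt) {
      k <- k - 1L
      chain <- c(mism[k], chain)
    }
    is_match_pos <- function(pp) {
      qq <- pp + delta
      ok <- pp >= 1L & qq >= 1L & qq <= n_clone & pp <= n_ref
      out <- rep(NA, length(pp))
      out[ok] <- ref_chars[pp[ok]] == clone_chars[qq[ok]] |
        pp[ok] %in% masked_sub
      out
    }
    for (c_pos in chain) {
      fl <- is_match_pos((c_pos - 15L):(c_pos - 1L))
      fl <- fl[!is.na(fl)]
      if (length(fl) < 8L || mean(fl) >= 0.8) return(c_pos)
    }
    NA_integer_
  }

  # a landing is spurious when the region just distal of it is
  # explainable as matching sequence under one of the candidate frames
  # (this happens when a stale frame, taken across a real tolerated
  # indel, turns genuinely matching sequence into garbage mismatches);
  # distal of a true junction no frame can restore matching
  match_frac <- function(pp, delta, min_n = 10L) {
    qq <- pp + delta
    ok <- pp >= 1L & pp <= n_ref & qq >= 1L & qq <= n_clone
    if (sum(ok) < min_n) return(NA_real_)
    mean(ref_chars[pp[ok]] == clone_chars[qq[ok]] |
           pp[ok] %in% masked_sub)
  }
  res <- lapply(deltas, function(d) {
    L <- attempt(d)
    if (is.na(L)) NULL else list(landing = L, delta = d)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(NULL)
  res <- res[order(vapply(res, function(x) x$landing, 0L))]
  for (x in res) {
    L <- x$landing
    explained <- vapply(deltas, function(d) {
      f <- match_frac((L + 4L):(L + 28L), d)
      !is.na(f) && f >= 0.75
    }, TRUE)
    if (!any(explained)) {
      # corroboration: distal of a genuine junction, positional
      # mismatches are dense (~0.44 per position between unrelated
      # repeat stretches); an aligner-fragmented small indel near the
      # sequence end leaves only 2-3
      pp <- L:min(n_ref, L + 60L)
      qq <- pp + x$delta
      pp <- pp[qq >= 1L & qq <= n_clone]
      # evidence confined to the last few positions of overlap is
      # indistinguishable from an aligner-fragmented tolerated end
      # indel, so a corroborated call needs a reasonable span as well
      # as dense mismatches
      if (length(pp) < 15L) return(list(dp = L, corroborated = FALSE))
      mm <- sum(ref_chars[pp] != clone_chars[pp + x$delta] &
                  !(pp %in% masked_sub))
      return(list(dp = L,
                  corroborated = mm >= 6L && mm / length(pp) >= 0.2))
    }
  }
  NULL
}

#' Call the divergence point of one aligned clone
#'
#' Scans alignment columns proximal to distal. Tolerated events are
#' substitution runs no longer than `max_substitution_run` (isolated point
#' mutations at the default), gap runs on either side no longer than
#' `max_indel_nt`, and the free trailing gap run of a shorter clone. The
#' first violating event — a longer substitution run, a longer gap run, or
#' the start of an unalignable tail of differing degenerate repeats (see
#' [divergence_rules()]) — sets
#' `diverged = TRUE`; the divergence point is the first reference position
#' of that event (1-based), and the undiverged length is the reference
#' span proximal to it.
#'
#' @param aln a `telo_alignment` from [align_clone()].
#' @param rules a [divergence_rules()] object.
#' @param ref_mask optional reference-error mask from a whole-set
#'   analysis (see [call_set()]): list with `sub` (reference positions
#'   whose mismatch/deletion columns are ignored) and `ins` (reference
#'   boundaries whose insertion columns are ignored). Columns at masked
#'   positions are treated as matches: a shared discrepancy across the
#'   set marks an error in the reference clone itself, not divergence of
#'   the clone under test.
#' @return A one-row data frame with columns `clone_id`, `reference_id`,
#'   `clone_length_nt`, `undiverged_length_nt`, `diverged`,
#'   `divergence_point_1based` (`NA` when non-divergent), `truncation`,
#'   and `reason`.
#' @export
#' @examples
#' ref <- strrep("TGGTGTGGG", 20)
#' aln <- align_clone(substr(ref, 1, 150), ref)
#' call_divergence(aln)
call_divergence <- function(aln, rules = divergence_rules(),
                            ref_mask = NULL) {
  stopifnot(inherits(aln, "telo_alignment"),
            inherits(rules, "divergence_rules"))
  cols <- .alignment_column_types(aln)
  type <- cols$type
  L <- length(type)
  ref_len <- sum(cols$ref != "-")
  clone_len <- sum(cols$clone != "-")
  ref_cum <- cumsum(cols$ref != "-")
  masked_sub <- integer()
  if (!is.null(ref_mask)) {
    masked_sub <- as.integer(ref_mask$sub)
    recode <- (type %in% c("S", "D") & ref_cum %in% masked_sub) |
      (type == "I" & (ref_cum + 1L) %in% as.integer(ref_mask$ins))
    type[recode] <- "M"
  }

  # free trailing gap run: maximal distal run of pure D (clone shorter)
  # or pure I (clone extends beyond the reference)
  tail_start <- L + 1L
  if (type[L] %in% c("D", "I")) {
    k <- L
    while (k >= 1L && type[k] == type[L]) k <- k - 1L
    tail_start <- k + 1L
  }
  free_tail_type <- if (tail_start <= L) type[L] else NA_character_
  core <- if (tail_start > 1L) type[seq_len(tail_start - 1L)] else character()

  max_sub <- if (rules$allow_isolated_substitutions)
    rules$max_substitution_run else 0L

  viol_col <- NA_integer_
  viol_type <- NA_character_
  has_sub <- FALSE
  has_indel <- FALSE
  if (length(core)) {
    runs <- rle(core)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    for (q in seq_along(runs$lengths)) {
      v <- runs$values[q]
      len <- runs$lengths[q]
      if (v == "S") {
        if (len > max_sub + 1L) {
          viol_col <- run_start[q]; viol_type <- "S"; break
        }
        has_sub <- TRUE
      } else if (v %in% c("D", "I")) {
        if (len > rules$max_indel_nt) {
          viol_col <- run_start[q]; viol_type <- v; break
        }
        has_indel <- TRUE
      }
    }
  }

  # unalignable tail within the aligned core (the free trailing gap run
  # is shortening, not sequence divergence); a changepoint detection
  # must be corroborated by dense positional mismatches distal of its
  # refined landing, otherwise it is an aligner-fragmented tolerated
  # indel, not a divergent tail
  win_col <- .tail_changepoint(core, rules)
  if (is.null(win_col)) win_col <- NA_integer_
  win_ref <- NULL
  if (!is.na(win_col)) {
    win_ref <- .refine_junction_positional(cols, ref_cum, win_col, rules,
                                           masked_sub)
    if (!is.null(win_ref) && !win_ref$corroborated) {
      win_col <- NA_integer_
      win_ref <- NULL
    }
  }

  diverged <- !is.na(viol_col) || !is.na(win_col)
  if (diverged) {
    tail_first <- !is.na(win_col) && (is.na(viol_col) || win_col < viol_col)
    j <- min(viol_col, win_col, na.rm = TRUE)
    dp <- if (j > 1L) ref_cum[j - 1L] + 1L else 1L
    reason_final <- if (tail_first) "diverged_unalignable_tail"
    else if (viol_type == "S") "diverged_substitution_run"
    else "diverged_long_indel"
    # re-locate the junction positionally (for a genuine isolated long
    # indel the positional mismatch chain starts exactly at the indel,
    # so the refined point coincides with the first gap column)
    ref_pos <- if (tail_first) win_ref
    else .refine_junction_positional(cols, ref_cum, j, rules, masked_sub)
    if (!is.null(ref_pos)) dp <- ref_pos$dp
    dp <- max(1L, min(dp, ref_len))
    undiv <- dp - 1L
  }
  if (!diverged) {
    dp <- NA_integer_
    # reference positions covered by the clone's aligned span
    undiv <- if (length(core)) ref_cum[tail_start - 1L] else 0L
    reason_final <- if (has_indel) "tolerated_indel"
    else if (has_sub) "tolerated_substitutions"
    else if (identical(free_tail_type, "D")) "shorter_matching"
    else "perfect"
  }

  data.frame(clone_id = aln$clone_id,
             reference_id = aln$reference_id,
             clone_length_nt = clone_len,
             undiverged_length_nt = as.integer(undiv),
             diverged = diverged,
             divergence_point_1based = as.integer(dp),
             truncation = undiv < rules$truncation_threshold_nt,
             reason = reason_final,
             stringsAsFactors = FALSE)
}

# shared indel signature: a technical indel in the candidate reference
# makes most clones of the set gap at (nearly) the same reference
# position. Gap placement jitters a few nt inside repeats, so each
# clone's gap runs are smeared over +-2 nt before voting. Free trailing
# gap runs (shorter clones) do not vote.
.shared_indel_signature <- function(alns, ref_len, min_fraction = 0.6) {
  if (!length(alns) || ref_len < 1L) return(FALSE)
  cover <- votes <- numeric(ref_len)
  for (aln in alns) {
    cols <- .alignment_column_types(aln)
    type <- cols$type
    L <- length(type)
    tail_start <- L + 1L
    if (type[L] %in% c("D", "I")) {
      k <- L
      while (k >= 1L && type[k] == type[L]) k <- k - 1L
      tail_start <- k + 1L
    }
    ref_cum <- cumsum(cols$ref != "-")
    core <- seq_len(tail_start - 1L)
    span <- if (length(core)) ref_cum[tail_start - 1L] else 0L
    if (span < 1L) next
    cover[seq_len(span)] <- cover[seq_len(span)] + 1
    gp <- core[type[core] %in% c("D", "I")]
    if (length(gp)) {
      pos <- unique(pmax(1L, ref_cum[gp]))
      marked <- unique(unlist(lapply(pos, function(p)
        max(1L, p - 2L):min(ref_len, p + 2L))))
      votes[marked] <- votes[marked] + 1
    }
  }
  ok <- cover >= pmax(3, length(alns) / 4)
  any(ok & votes / pmax(cover, 1) > min_fraction)
}

#' Select the reference telomere of a clone set
#'
#' The reference is the longest telomere without divergent sequence.
#' Candidates are ranked by length (ties broken lexicographically by clone
#' id). The longest is provisionally the reference; all other clones are
#' called against it; the candidate is demoted if more than half of them
#' are called diverged (a clean reference cannot make the majority of its
#' siblings look divergent) or if the set shows a shared gap signature
#' against it (most clones gapping at the same position marks a
#' technical indel in the candidate itself). The procedure repeats down
#' the ranking; if every candidate is demoted the longest clone is
#' returned with a warning.
#'
#' @param set a [telomere_set()].
#' @param rules a [divergence_rules()] object.
#' @param scoring an [align_scoring()] object.
#' @return The `clone_id` of the selected reference.
#' @export
select_reference <- function(set, rules = divergence_rules(),
                             scoring = align_scoring()) {
  stopifnot(inherits(set, "telomere_set"))
  cl <- set$clones
  if (nrow(cl) < 2L)
    stop("reference selection needs at least 2 clones")
  ord <- order(-nchar(cl$bases), cl$clone_id)
  cl <- cl[ord, , drop = FALSE]
  for (i in seq_len(nrow(cl))) {
    cand_id <- cl$clone_id[i]
    cand_seq <- cl$bases[i]
    cand_len <- nchar(cand_seq)
    others <- cl[-i, , drop = FALSE]
    alns <- lapply(seq_len(nrow(others)), function(k)
      align_clone(others$bases[k], cand_seq, scoring,
                  clone_id = others$clone_id[k],
                  reference_id = cand_id))
    calls <- do.call(rbind, lapply(alns, call_divergence, rules = rules))
    if (sum(calls$diverged) <= nrow(others) / 2 &&
        !.shared_indel_signature(alns, cand_len))
      return(cand_id)
  }
  warning("every candidate reference was demoted; ",
          "falling back to the longest clone")
  cl$clone_id[1L]
}

# reference-error mask: reference positions at which most clones of the
# set disagree with the reference in the same way, with clean flanks,
# mark technical errors in the reference clone itself (a shared isolated
# substitution or small indel) rather than divergence of the clones.
# Flank cleanliness keeps genuinely divergent distal regions (where many
# clones disagree broadly, e.g. past a common re-extension zone) out of
# the mask. Free trailing gap runs (shorter clones) never count.
.reference_error_mask <- function(alns, ref_len,
                                  min_fraction = 0.6,
                                  max_flank_fraction = 0.2) {
  cover <- mis <- ins <- numeric(ref_len)
  for (aln in alns) {
    cols <- .alignment_column_types(aln)
    type <- cols$type
    L <- length(type)
    tail_start <- L + 1L
    if (type[L] %in% c("D", "I")) {
      k <- L
      while (k >= 1L && type[k] == type[L]) k <- k - 1L
      tail_start <- k + 1L
    }
    ref_cum <- cumsum(cols$ref != "-")
    core <- seq_len(tail_start - 1L)
    span <- ref_cum[tail_start - 1L]
    if (is.na(span) || span < 1L) next
    cover[seq_len(span)] <- cover[seq_len(span)] + 1
    bad <- core[type[core] %in% c("S", "D")]
    mis[unique(ref_cum[bad])] <- mis[unique(ref_cum[bad])] + 1
    insb <- core[type[core] == "I"]
    ins[unique(ref_cum[insb] + 1L)] <- ins[unique(ref_cum[insb] + 1L)] + 1
  }
  ok_cov <- cover >= pmax(5, length(alns) / 3)
  mfrac <- ifelse(cover > 0, mis / cover, 0)
  ifrac <- ifelse(cover > 0, ins / cover, 0)
  cand_sub <- which(ok_cov & mfrac > min_fraction)
  cand_ins <- which(ok_cov & ifrac > min_fraction)
  # candidate positions form runs (a shared reference indel spans several
  # positions); judge each run as a unit by the cleanliness of the three
  # flanking positions on each side, and never mask runs longer than a
  # tolerable indel — broad shared disagreement is real divergence
  keep_runs <- function(cand, max_run) {
    if (!length(cand)) return(integer())
    grp <- cumsum(c(1L, diff(cand) != 1L))
    keep <- unlist(lapply(split(cand, grp), function(run) {
      if (length(run) > max_run) return(integer())
      fl <- c(max(1L, min(run) - 3L):(min(run) - 1L),
              (max(run) + 1L):min(ref_len, max(run) + 3L))
      fl <- setdiff(fl[fl >= 1L & fl <= ref_len], cand)
      if (length(fl) && mean(mfrac[fl]) < max_flank_fraction) run
      else integer()
    }), use.names = FALSE)
    as.integer(keep)
  }
  list(sub = keep_runs(cand_sub, 6L), ins = keep_runs(cand_ins, 6L))
}

#' Call divergence for every clone of a telomere set
#'
#' Selects the reference with [select_reference()], aligns every other
#' clone against it, masks shared reference-error columns (positions at
#' which most clones disagree with the reference identically — technical
#' errors in the reference clone, not divergence), calls every clone,
#' and gives the reference itself a non-diverged call over its full
#' length. Output rows are sorted by undiverged length, descending (the
#' bar order of divergence profile plots), with ties broken by clone id.
#'
#' @param set a [telomere_set()].
#' @param rules a [divergence_rules()] object.
#' @param scoring an [align_scoring()] object.
#' @param mask_reference_errors apply the shared reference-error column
#'   mask (default `TRUE`).
#' @return A data frame of divergence calls, one row per clone, carrying
#'   the set's metadata columns (`telomere_id`, `strain_id`, `genotype`,
#'   `generations`) plus the columns of [call_divergence()].
#' @export
call_set <- function(set, rules = divergence_rules(),
                     scoring = align_scoring(),
                     mask_reference_errors = TRUE) {
  stopifnot(inherits(set, "telomere_set"))
  ref_id <- select_reference(set, rules, scoring)
  cl <- set$clones
  ref_seq <- cl$bases[cl$clone_id == ref_id]
  others <- which(cl$clone_id != ref_id)
  alns <- lapply(others, function(k)
    align_clone(cl$bases[k], ref_seq, scoring,
                clone_id = cl$clone_id[k], reference_id = ref_id))
  ref_mask <- if (mask_reference_errors && length(alns) >= 5L)
    .reference_error_mask(alns, nchar(ref_seq)) else NULL
  calls <- lapply(alns, call_divergence, rules = rules,
                  ref_mask = ref_mask)
  calls <- c(calls, list(
    data.frame(clone_id = ref_id, reference_id = ref_id,
               clone_length_nt = nchar(ref_seq),
               undiverged_length_nt = nchar(ref_seq),
               diverged = FALSE,
               divergence_point_1based = NA_integer_,
               truncation = nchar(ref_seq) < rules$truncation_threshold_nt,
               reason = "perfect", stringsAsFactors = FALSE)))
  calls <- do.call(rbind, calls)
  calls <- calls[order(-calls$undiverged_length_nt, calls$clone_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  meta <- data.frame(telomere_id = set$telomere_id,
                     strain_id = set$strain_id,
                     genotype = set$genotype,
                     generations = set$generations,
                     stringsAsFactors = FALSE)
  cbind(calls[, "clone_id", drop = FALSE],
        meta[rep(1L, nrow(calls)), , drop = FALSE],
        calls[, setdiff(names(calls), "clone_id"), drop = FALSE],
        row.names = NULL)
}

#' Count truncation events among divergence calls
#'
#' A truncation event is an undiverged span strictly below the threshold
#' (default 125 nt): in a telomerase-positive strain such a span records a
#' telomere that became abnormally short before telomerase re-extended it,
#' which end-replication attrition alone cannot explain.
#'
#' @param calls a data frame of divergence calls with an
#'   `undiverged_length_nt` column.
#' @param rules a [divergence_rules()] object.
#' @return Integer count of calls with
#'   `undiverged_length_nt < truncation_threshold_nt`.
#' @export
#' @examples
#' call_truncations(data.frame(undiverged_length_nt = c(124, 125, 126)))
call_truncations <- function(calls, rules = divergence_rules()) {
  stopifnot(is.data.frame(calls), "undiverged_length_nt" %in% names(calls))
  sum(calls$undiverged_length_nt < rules$truncation_threshold_nt)
}
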