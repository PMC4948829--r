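# fixed non-telomeric proximal anchor shared by all simulated clones;
# stands in for the subtelomeric primer-anchored segment of telomere PCR
.TELO_ANCHOR <- "ACTCAGGTACCATCGAGGATCCTAACGCAT"

# derive a 32-bit sub-seed for one emitted artifact from the master seed;
# k is a small per-artifact offset (1 = clone set, 2 = density fixture)
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 44488 * 48271 + k) %% 2147483399)
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Degenerate telomeric repeat grammar
#'
#' Yeast telomerase adds imperfect repeats of the form T-G(k) with
#' k in 1..3 on the G-rich strand (the C1-3A/TG1-3 repeat family). Units
#' are drawn independently with probabilities `p1`, `p2`, `p3`.
#'
#' @param p1,p2,p3 probabilities of TG, TGG, TGGG units; must sum to 1
#'   (defaults 0.2 / 0.5 / 0.3).
#' @return An object of class `repeat_grammar`.
#' @export
repeat_grammar <- function(p1 = 0.2, p2 = 0.5, p3 = 0.3) {
  stopifnot(p1 >= 0, p2 >= 0, p3 >= 0)
  if (abs(p1 + p2 + p3 - 1) > 1e-9)
    stop("unit probabilities must sum to 1")
  structure(list(p = c(p1, p2, p3)), class = "repeat_grammar")
}

#' Sample a degenerate telomeric repeat string
#'
#' Concatenates grammar units and clips to exactly `length_nt`
#' nucleotides; emitted on the G-rich strand, proximal end first. Uses the
#' current RNG state.
#'
#' @param length_nt target length in nt (>= 1).
#' @param grammar a [repeat_grammar()].
#' @return A character scalar of length `length_nt` over T/G.
#' @export
#' @examples
#' set.seed(1); sample_telomere(24)
sample_telomere <- function(length_nt, grammar = repeat_grammar()) {
  length_nt <- as.integer(length_nt)
  stopifnot(length_nt >= 1L)
  units <- c("TG", "TGG", "TGGG")
  n <- ceiling(length_nt / 2) + 4L
  s <- paste(units[sample.int(3L, n, replace = TRUE, prob = grammar$p)],
             collapse = "")
  while (nchar(s) < length_nt)
    s <- paste0(s, units[sample.int(3L, 1L, prob = grammar$p)])
  substr(s, 1L, length_nt)
}

#' Simulation configuration
#'
#' Study conditions for the lineage simulator: telomeres start at
#' `initial_length_nt` (including the 30-nt proximal anchor), shorten by
#' 3-4 nt per generation through the end-replication problem, suffer rare
#' recombination-style divergence events at `divergence_rate` per telomere
#' per generation, optional abrupt truncations, and — when telomerase is
#' active — re-extension with freshly sampled degenerate repeats once the
#' telomere drops below `reextension_threshold_nt`. Defaults mirror the
#' assay conditions: 30 generations of clonal expansion, 35 clones per
#' set, a 0.3% per-generation event rate.
#'
#' @param seed master seed; every emitted artifact derives its own RNG
#'   stream from it, so identical configs give byte-identical output.
#' @param telomerase_active telomerase on/off (default `FALSE`).
#' @param initial_length_nt founder telomere length incl. anchor
#'   (default 300).
#' @param generations generations of clonal expansion (default 30).
#' @param clones_per_set sequenced clones per set (default 35).
#' @param divergence_rate per-telomere per-generation divergence event
#'   rate (default 0.003).
#' @param truncation_rate per-telomere per-generation truncation rate
#'   (default 0).
#' @param reextension_threshold_nt telomerase re-extends below this length
#'   (default 160).
#' @param mean_extension_nt mean of the geometric extension length
#'   (default 50).
#' @param proximal_anchor fixed non-telomeric proximal sequence shared by
#'   all clones.
#' @param grammar a [repeat_grammar()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       telomerase_active = FALSE,
                       initial_length_nt = 300L,
                       generations = 30L,
                       clones_per_set = 35L,
                       divergence_rate = 0.003,
                       truncation_rate = 0,
                       reextension_threshold_nt = 160L,
                       mean_extension_nt = 50,
                       proximal_anchor = .TELO_ANCHOR,
                       grammar = repeat_grammar()) {
  stopifnot(divergence_rate >= 0, divergence_rate <= 1,
            truncation_rate >= 0, truncation_rate <= 1,
            initial_length_nt > nchar(proximal_anchor),
            generations >= 0, clones_per_set >= 1,
            mean_extension_nt >= 1,
            grepl("^[ACGT]+$", proximal_anchor))
  structure(list(seed = as.integer(seed),
                 telomerase_active = isTRUE(telomerase_active),
                 initial_length_nt = as.integer(initial_length_nt),
                 generations = as.integer(generations),
                 clones_per_set = as.integer(clones_per_set),
                 divergence_rate = divergence_rate,
                 truncation_rate = truncation_rate,
                 reextension_threshold_nt =
                   as.integer(reextension_threshold_nt),
                 mean_extension_nt = mean_extension_nt,
                 proximal_anchor = proximal_anchor,
                 grammar = grammar),
            class = "sim_config")
}

#' Technical artifact model
#'
#' Errors introduced by PCR amplification, cloning in E. coli, and Sanger
#' sequencing. With probability `p_artifact` a clone acquires an
#' artifactual divergence event (distal replacement from a uniform
#' breakpoint — indistinguishable from an in-vivo event); on top, each
#' clone receives background point substitutions and small indels of at
#' most 6 nt. Background substitutions are placed non-adjacent and
#' background indels well separated, matching their tolerated
#' classification in the calling rules. The ~4% default artifact
#' probability reflects control re-cloning experiments in which 3.8-4.2%
#' of clones of a defined telomere sequence diverged.
#'
#' @param p_artifact per-clone artifactual divergence probability
#'   (default 0.04).
#' @param substitution_rate per-base substitution rate (default 1e-3).
#' @param indel_rate per-base small-indel rate (default 2e-4); indel sizes
#'   uniform on 1..6 nt.
#' @return An object of class `technical_error_model`.
#' @export
technical_error_model <- function(p_artifact = 0.04,
                                  substitution_rate = 1e-3,
                                  indel_rate = 2e-4) {
  stopifnot(p_artifact >= 0, p_artifact <= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  structure(list(p_artifact = p_artifact,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate),
            class = "technical_error_model")
}

#' Evolve one telomere lineage
#'
#' Runs `generations` rounds over a starting sequence using the current
#' RNG state. Each generation: shorten by 3 or 4 nt (uniform; the
#' end-replication problem); with probability `divergence_rate` replace
#' the sequence distal to a uniformly chosen breakpoint (at or beyond the
#' anchor end) with freshly sampled repeats of the same length; with
#' probability `truncation_rate` truncate to a uniform shorter length;
#' and, if telomerase is active and the telomere is below the
#' re-extension threshold, append a geometric-length stretch of fresh
#' degenerate repeats. Lineages driven down to the anchor are floored
#' there and flagged eroded.
#'
#' @param initial_seq starting sequence (anchor + telomeric repeats).
#' @param config a [sim_config()].
#' @return List with `sequence`, `events` (data frame: `generation`,
#'   `type` in divergence/truncation/extension, `position` = first
#'   affected base, 1-based, `length_nt`), and `eroded`.
#' @export
evolve_lineage <- function(initial_seq, config) {
  stopifnot(inherits(config, "sim_config"))
  seqc <- initial_seq
  alen <- nchar(config$proximal_anchor)
  ev_gen <- integer(); ev_type <- character()
  ev_pos <- integer(); ev_len <- integer(); ev_eff <- integer()
  eroded <- FALSE
  for (gen in seq_len(config$generations)) {
    # end-replication shortening
    s <- .sample1(3:4)
    newlen <- nchar(seqc) - s
    if (newlen <= alen) { newlen <- alen; eroded <- TRUE }
    seqc <- substr(seqc, 1L, newlen)
    # recombination-style divergence: distal tail replacement
    if (runif(1) < config$divergence_rate && nchar(seqc) > alen) {
      b <- .sample1((alen + 1L):nchar(seqc))
      tail_len <- nchar(seqc) - b + 1L
      seqc <- paste0(substr(seqc, 1L, b - 1L),
                     sample_telomere(tail_len, config$grammar))
      ev_gen <- c(ev_gen, gen); ev_type <- c(ev_type, "divergence")
      ev_pos <- c(ev_pos, b); ev_len <- c(ev_len, tail_len)
      ev_eff <- c(ev_eff, .effective_breakpoint(initial_seq, seqc, b))
    }
    # abrupt truncation
    if (config$truncation_rate > 0 && runif(1) < config$truncation_rate &&
        nchar(seqc) > alen + 1L) {
      newlen <- .sample1(alen:(nchar(seqc) - 1L))
      ev_gen <- c(ev_gen, gen); ev_type <- c(ev_type, "truncation")
      ev_pos <- c(ev_pos, newlen + 1L)
      ev_len <- c(ev_len, nchar(seqc) - newlen)
      ev_eff <- c(ev_eff, NA_integer_)
      seqc <- substr(seqc, 1L, newlen)
    }
    # telomerase re-extension of a short telomere
    if (config$telomerase_active &&
        nchar(seqc) < config$reextension_threshold_nt) {
      ext <- rgeom(1L, 1 / config$mean_extension_nt) + 1L
      ev_gen <- c(ev_gen, gen); ev_type <- c(ev_type, "extension")
      p_ext <- nchar(seqc) + 1L
      ev_pos <- c(ev_pos, p_ext); ev_len <- c(ev_len, ext)
      seqc <- paste0(seqc, sample_telomere(ext, config$grammar))
      ev_eff <- c(ev_eff, .effective_breakpoint(initial_seq, seqc, p_ext))
    }
  }
  list(sequence = seqc,
       events = data.frame(generation = ev_gen, type = ev_type,
                           position = ev_pos, length_nt = ev_len,
                           position_effective = ev_eff,
                           stringsAsFactors = FALSE),
       eroded = eroded)
}

#' Divergence incidence across many lineages
#'
#' Samples, for `n_lineages` independent telomere lineages, whether at
#' least one divergence event occurred over `g` generations at
#' per-generation rate `r`. Event counts per lineage are Binomial(g, r)
#' by construction of the per-generation process (a property unit-tested
#' on full [evolve_lineage()] event logs); this helper samples that count
#' distribution directly so incidence can be simulated at large n.
#'
#' @param n_lineages number of lineages.
#' @param r per-generation divergence rate.
#' @param g generations.
#' @return Logical vector: lineage had at least one event.
#' @export
#' @examples
#' set.seed(1); mean(simulate_divergence_incidence(1e4, 0.003, 30))
simulate_divergence_incidence <- function(n_lineages, r, g) {
  stopifnot(n_lineages >= 1, r >= 0, r <= 1, g >= 0)
  rbinom(n_lineages, size = g, prob = r) > 0L
}

# effective breakpoint of a replacement event: the first position at or
# beyond the raw breakpoint p where the post-event sequence differs from
# the founder. Freshly sampled repeats can coincidentally reproduce the
# founder over their first few bases, in which case nothing observable is
# planted there; NA when the event left no observable change at all.
.effective_breakpoint <- function(founder, seq_after, p) {
  n <- min(nchar(founder), nchar(seq_after))
  if (p <= n) {
    a <- utf8ToInt(substring(founder, p, n))
    b <- utf8ToInt(substring(seq_after, p, n))
    d <- which(a != b)
    if (length(d)) return(p - 1L + d[1L])
  }
  if (nchar(seq_after) > nchar(founder)) return(nchar(founder) + 1L)
  NA_integer_
}

# replacement-type events (divergence / extension / technical artifact)
# whose effective breakpoint still lies within the final sequence
# determine the observable divergence point: the proximal-most survivor
.surviving_divergence <- function(positions, types, final_len) {
  keep <- !is.na(positions) & positions <= final_len &
    types != "truncation"
  if (!any(keep)) return(list(point = NA_integer_, type = NA_character_))
  i <- which(keep)[which.min(positions[keep])]
  list(point = positions[i], type = types[i])
}

.OTHER_BASE <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

# apply the technical artifact layer to one clone sequence
.apply_technical <- function(seqc, model, alen, grammar) {
  art_pos <- NA_integer_
  art_sequence <- NA_character_
  len <- nchar(seqc)
  if (model$p_artifact > 0 && runif(1) < model$p_artifact && len > alen) {
    art_pos <- .sample1((alen + 1L):len)
    seqc <- paste0(substr(seqc, 1L, art_pos - 1L),
                   sample_telomere(len - art_pos + 1L, grammar))
    art_sequence <- seqc
  }
  # small indels (1-6 nt), kept >= 30 nt apart so runs never merge;
  # recorded (position in the pre-indel frame, +ins/-del size) so that
  # downstream evaluation can map between founder and clone coordinates
  len <- nchar(seqc)
  indel_pos <- integer(); indel_size <- integer()
  n_ind <- rbinom(1L, len, model$indel_rate)
  if (n_ind > 0) {
    pos <- sort(sample.int(len, n_ind))
    pos <- pos[c(TRUE, diff(pos) >= 30L)]
    for (p in rev(pos)) {  # distal to proximal keeps positions valid
      size <- sample.int(6L, 1L)
      if (runif(1) < 0.5) {  # insertion of repeat-like bases
        seqc <- paste0(substr(seqc, 1L, p),
                       sample_telomere(size, grammar),
                       substr(seqc, p + 1L, nchar(seqc)))
        indel_pos <- c(p, indel_pos); indel_size <- c(size, indel_size)
      } else {               # deletion
        seqc <- paste0(substr(seqc, 1L, p - 1L),
                       substr(seqc, p + size, nchar(seqc)))
        indel_pos <- c(p, indel_pos); indel_size <- c(-size, indel_size)
      }
    }
  }
  # isolated point substitutions (non-adjacent by construction)
  len <- nchar(seqc)
  n_sub <- rbinom(1L, len, model$substitution_rate)
  if (n_sub > 0) {
    pos <- sort(sample.int(len, n_sub))
    pos <- pos[c(TRUE, diff(pos) >= 2L)]
    ch <- strsplit(seqc, "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- .sample1(.OTHER_BASE[[ch[p]]])
    seqc <- paste(ch, collapse = "")
  }
  list(sequence = seqc, artifact_position = art_pos,
       art_sequence = art_sequence,
       indel_spec = paste(sprintf("%d:%d", indel_pos, indel_size),
                          collapse = ";"))
}

#' Emit a simulated clone set with ground truth
#'
#' One clonal population: a founder telomere (anchor + degenerate
#' repeats) is sampled once, then each sequenced clone evolves
#' independently from the founder for `generations` generations under
#' [evolve_lineage()] — the founder supplies the shared stable proximal
#' sequence, the per-clone histories the independent distal events.
#' Each clone then passes through the technical error model. Output is
#' deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param error_model a [technical_error_model()]; use
#'   `technical_error_model(0, 0, 0)` for error-free output.
#' @param telomere_id,strain_id labels stamped on the output
#'   (genotype is derived from `telomerase_active`).
#' @param out_dir if non-NULL, write `clones.fasta`, `samples.tsv` and
#'   `truth.tsv` there.
#' @return List with `set` (a [telomere_set()]), `sheet` (sample sheet
#'   data frame), and `truth` (data frame: `clone_id`, `true_diverged`,
#'   `true_divergence_point` (founder coordinates), `true_tail_nt`,
#'   `true_truncation`, `event_type` in in_vivo/technical/none,
#'   `final_length_nt`, `eroded`, and `tech_indels`, the clone's
#'   technical indel record as `position:signed_size` pairs used by
#'   [reference_coordinate()]).
#' @export
#' @examples
#' sim <- emit_clone_set(sim_config(seed = 7, clones_per_set = 6))
#' sim$truth
emit_clone_set <- function(config,
                           error_model = technical_error_model(),
                           telomere_id = "TEL06R",
                           strain_id = "sim",
                           out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(error_model, "technical_error_model"))
  set.seed(.substream(config$seed, 1L))
  alen <- nchar(config$proximal_anchor)
  founder <- paste0(config$proximal_anchor,
                    sample_telomere(config$initial_length_nt - alen,
                                    config$grammar))
  n <- config$clones_per_set
  ids <- sprintf("clone%04d", seq_len(n))
  bases <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    lin <- evolve_lineage(founder, config)
    tech <- .apply_technical(lin$sequence, error_model, alen,
                             config$grammar)
    pos <- lin$events$position_effective
    typ <- lin$events$type
    if (!is.na(tech$artifact_position)) {
      pos <- c(pos, .effective_breakpoint(founder, tech$art_sequence,
                                          tech$artifact_position))
      typ <- c(typ, "technical")
    }
    final_len <- nchar(tech$sequence)
    surv <- .surviving_divergence(pos, typ, final_len)
    bases[i] <- tech$sequence
    truth[[i]] <- data.frame(
      clone_id = ids[i],
      true_diverged = !is.na(surv$point),
      true_divergence_point = surv$point,
      true_tail_nt = if (is.na(surv$point)) 0L
                     else final_len - surv$point + 1L,
      true_truncation = any(typ == "truncation"),
      event_type = if (is.na(surv$type)) "none"
                   else if (surv$type == "technical") "technical"
                   else "in_vivo",
      final_length_nt = final_len,
      eroded = lin$eroded,
      tech_indels = tech$indel_spec,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  genotype <- if (config$telomerase_active) "WT" else "est2"
  set <- telomere_set(telomere_id, strain_id, genotype,
                      config$generations,
                      data.frame(clone_id = ids, bases = bases,
                                 stringsAsFactors = FALSE))
  sheet <- data.frame(clone_id = ids, telomere_id = telomere_id,
                      strain_id = strain_id, genotype = genotype,
                      generations = config$generations,
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_clone_fasta(set, file.path(out_dir, "clones.fasta"))
    write_sample_sheet(sheet, file.path(out_dir, "samples.tsv"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(set = set, sheet = sheet, truth = truth)
}

#' Senescence profile for the density fixture generator
#'
#' @param genotype genotype label.
#' @param n_replicates replicates (spore isolates).
#' @param n_days passages (default 10).
#' @param trough_day passage of programmed maximum senescence (default 7).
#' @param trough_pd programmed cumulative PD at the trough (default 40).
#' @param pd_sd between-replicate SD of the trough PD (default 1).
#' @param pre_slope decline of the daily PD increment before the trough,
#'   PD/passage (default 1).
#' @param post_slope recovery of the daily increment after the trough
#'   (default 1.5).
#' @param noise_sd per-measurement density noise, log2 units (default 0).
#' @return An object of class `senescence_profile`.
#' @export
senescence_profile <- function(genotype, n_replicates, n_days = 10L,
                               trough_day = 7L, trough_pd = 40,
                               pd_sd = 1, pre_slope = 1,
                               post_slope = 1.5, noise_sd = 0) {
  stopifnot(n_replicates >= 1, n_days >= 2,
            trough_day >= 1, trough_day <= n_days,
            pre_slope > 0, post_slope > 0, pd_sd >= 0, noise_sd >= 0)
  structure(list(genotype = genotype,
                 n_replicates = as.integer(n_replicates),
                 n_days = as.integer(n_days),
                 trough_day = as.integer(trough_day),
                 trough_pd = trough_pd, pd_sd = pd_sd,
                 pre_slope = pre_slope, post_slope = post_slope,
                 noise_sd = noise_sd),
            class = "senescence_profile")
}

#' Emit a density-table fixture with programmed senescence troughs
#'
#' Generates daily cell densities for each replicate of each profile:
#' daily PD increments decline linearly to the programmed trough passage
#' (total cumulative PD at the trough drawn from
#' Normal(trough_pd, pd_sd)), then recover, so the trough is the day of
#' minimum density and is recoverable by [build_curve()]. Densities are
#' `dilution_density * 2^increment`, with optional log2-scale
#' measurement noise.
#'
#' @param profiles list of [senescence_profile()] objects.
#' @param seed master seed (per-artifact stream derived from it).
#' @param dilution_density daily dilution target (default 2e5).
#' @return A density data frame as produced by [read_density_table()].
#' @export
emit_density_fixture <- function(profiles, seed = 1L,
                                 dilution_density = 2e5) {
  if (inherits(profiles, "senescence_profile")) profiles <- list(profiles)
  set.seed(.substream(seed, 2L))
  out <- list()
  for (pr in profiles) {
    stopifnot(inherits(pr, "senescence_profile"))
    k <- pr$trough_day
    for (rep_i in seq_len(pr$n_replicates)) {
      target <- pr$trough_pd + rnorm(1L, 0, pr$pd_sd)
      a_k <- (target - pr$pre_slope * k * (k - 1) / 2) / k
      inc <- numeric(pr$n_days)
      inc[seq_len(k)] <- a_k + (k - seq_len(k)) * pr$pre_slope
      if (k < pr$n_days)
        inc[(k + 1):pr$n_days] <- a_k +
          seq_len(pr$n_days - k) * pr$post_slope
      if (pr$noise_sd > 0)
        inc <- inc + rnorm(pr$n_days, 0, pr$noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        strain_id = pr$genotype,
        genotype = pr$genotype,
        replicate_id = sprintf("rep%02d", rep_i),
        day = seq_len(pr$n_days),
        density = dilution_density * 2^inc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Map founder-coordinate positions onto a reference clone's coordinates
#'
#' Divergence points in the simulator's truth table are founder
#' coordinates, while the caller reports positions on the selected
#' reference clone. The two differ wherever the reference carries
#' technical indels proximal of the position. This helper applies the
#' reference clone's recorded indels (`tech_indels` in the truth table)
#' to convert founder positions to reference positions for evaluation.
#'
#' @param truth truth data frame from [emit_clone_set()].
#' @param reference_id clone id of the selected reference.
#' @param positions founder-coordinate positions (may contain NA).
#' @return Positions on the reference coordinate system.
#' @export
reference_coordinate <- function(truth, reference_id, positions) {
  spec <- truth$tech_indels[truth$clone_id == reference_id]
  if (length(spec) != 1L)
    stop("reference clone not found in truth table: ", reference_id)
  out <- as.numeric(positions)
  if (!nzchar(spec)) return(out)
  for (part in strsplit(spec, ";", fixed = TRUE)[[1L]]) {
    ps <- as.integer(strsplit(part, ":", fixed = TRUE)[[1L]])
    shift <- ifelse(!is.na(out) & out > ps[1L], ps[2L], 0L)
    out <- out + shift
  }
  out
}
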