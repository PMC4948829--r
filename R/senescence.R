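#' Population doublings over one passage
#'
#' A culture diluted to `dilution_density` (default 2e5 cells/ml) and
#' measured after 24 h of growth has undergone
#' log2(density / dilution_density) population doublings. Senescence is
#' tracked in doublings rather than days because telomere shortening is a
#' function of cell division, not time. Negative values (shrinking
#' cultures) are returned as-is.
#'
#' @param density measured density, cells/ml, > 0.
#' @param dilution_density density after dilution, cells/ml, > 0
#'   (default 2e5).
#' @return Population doublings for the passage (may be negative).
#' @export
#' @examples
#' population_doublings(1.6e6)  # log2(8) = 3
population_doublings <- function(density, dilution_density = 2e5) {
  stopifnot(is.numeric(density), is.numeric(dilution_density))
  if (any(density <= 0) || any(dilution_density <= 0))
    stop("densities must be positive (cells/ml)")
  log2(density / dilution_density)
}

#' Build a senescence curve for one replicate
#'
#' Converts one replicate's daily densities into per-passage doubling
#' increments and cumulative population doublings (PD). The point of
#' maximum senescence is the passage of minimum density — the trough of
#' the senescence curve before survivor outgrowth — with ties resolved to
#' the earliest passage. Survivors are conventionally sampled at the first
#' passage after that trough (`recovery_day`).
#'
#' @param rows data frame with columns `day` (consecutive from 1) and
#'   `density`; optionally `strain_id`, `genotype`, `replicate_id`.
#' @param dilution_density daily dilution target, cells/ml (default 2e5).
#' @return An object of class `senescence_curve`: list with the identifier
#'   fields, a `days` data frame (`day`, `density`, `pd_increment`,
#'   `cumulative_pd`, `shrinking`), `trough_day`, `max_senescence_pd`,
#'   `recovery_day`, and `dilution_density`.
#' @export
#' @examples
#' d <- data.frame(day = 1:5, density = c(2e6, 8e5, 3e5, 9e5, 4e6))
#' build_curve(d)$trough_day
build_curve <- function(rows, dilution_density = 2e5) {
  stopifnot(is.data.frame(rows), all(c("day", "density") %in% names(rows)))
  rows <- rows[order(rows$day), , drop = FALSE]
  if (!identical(as.integer(rows$day), seq_len(nrow(rows))))
    stop("days must be consecutive from 1")
  inc <- population_doublings(rows$density, dilution_density)
  cum <- cumsum(inc)
  trough <- which.min(rows$density)  # earliest on ties
  days <- data.frame(day = as.integer(rows$day), density = rows$density,
                     pd_increment = inc, cumulative_pd = cum,
                     shrinking = inc < 0)
  structure(list(strain_id = if ("strain_id" %in% names(rows))
                   rows$strain_id[1L] else NA_character_,
                 genotype = if ("genotype" %in% names(rows))
                   rows$genotype[1L] else NA_character_,
                 replicate_id = if ("replicate_id" %in% names(rows))
                   rows$replicate_id[1L] else NA_character_,
                 days = days,
                 trough_day = as.integer(trough),
                 max_senescence_pd = cum[trough],
                 recovery_day = as.integer(trough) + 1L,
                 dilution_density = dilution_density),
            class = "senescence_curve")
}

#' @export
print.senescence_curve <- function(x, ...) {
  cat("Senescence curve", x$strain_id, "/", x$replicate_id,
      sprintf("(%s): %d passages, trough at passage %d (%.1f cumulative PD)\n",
              x$genotype, nrow(x$days), x$trough_day, x$max_senescence_pd))
  invisible(x)
}

#' Build one curve per replicate from a density table
#'
#' @param densities data frame from [read_density_table()].
#' @param dilution_density daily dilution target (default 2e5).
#' @return Named list of [build_curve()] results, one per
#'   (strain, replicate).
#' @export
build_curves <- function(densities, dilution_density = 2e5) {
  key <- paste(densities$strain_id, densities$replicate_id, sep = "\r")
  out <- lapply(split(densities, factor(key, levels = unique(key))),
                build_curve, dilution_density = dilution_density)
  names(out) <- gsub("\r", "_", names(out))
  out
}

#' Compare two genotypes at the point of maximum senescence
#'
#' Welch unpaired two-tailed t-test on the replicate-level cumulative PD
#' at maximum senescence. The unequal-variance form is used because
#' replicate counts typically differ between genotypes.
#'
#' @param curves_a,curves_b lists of `senescence_curve` objects (at least
#'   two replicates each).
#' @return List with `p_value`, `mean_a`, `mean_b`, `estimate_diff`,
#'   `t_statistic` and `df`.
#' @export
compare_genotypes <- function(curves_a, curves_b) {
  pd_a <- vapply(curves_a, function(x) x$max_senescence_pd, 0)
  pd_b <- vapply(curves_b, function(x) x$max_senescence_pd, 0)
  if (length(pd_a) < 2L || length(pd_b) < 2L)
    stop("need at least 2 replicates per genotype")
  if (sd(pd_a) == 0 && sd(pd_b) == 0) {
    # degenerate case (identical constant groups): no evidence of a
    # difference when means agree, certain difference otherwise
    p <- if (isTRUE(all.equal(mean(pd_a), mean(pd_b)))) 1 else 0
    return(list(p_value = p, mean_a = mean(pd_a), mean_b = mean(pd_b),
                estimate_diff = mean(pd_a) - mean(pd_b),
                t_statistic = NA_real_, df = NA_real_))
  }
  tt <- t.test(pd_a, pd_b, alternative = "two.sided", var.equal = FALSE)
  list(p_value = tt$p.value,
       mean_a = mean(pd_a), mean_b = mean(pd_b),
       estimate_diff = mean(pd_a) - mean(pd_b),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter))
}

#' Per-passage summary of a genotype's senescence curves
#'
#' Replicates are aligned by passage number (each daily passage is one
#' measurement event); per passage, the mean and standard error of both
#' cumulative PD and density are computed across the replicates measured
#' at that passage. SE is reported only where n >= 2.
#'
#' @param curves list of `senescence_curve` objects for one genotype.
#' @return An object of class `genotype_summary`: list with `genotype`,
#'   `n_replicates`, and `per_passage` (data frame with columns `day`,
#'   `n`, `mean_cumulative_pd`, `se_cumulative_pd`, `mean_density`,
#'   `se_density`).
#' @export
summarize_genotype <- function(curves) {
  if (!length(curves)) stop("no curves supplied")
  long <- do.call(rbind, lapply(curves, function(x)
    cbind(x$days[, c("day", "density", "cumulative_pd")],
          replicate_id = x$replicate_id)))
  per <- lapply(split(long, long$day), function(d) {
    n <- nrow(d)
    data.frame(day = d$day[1L], n = n,
               mean_cumulative_pd = mean(d$cumulative_pd),
               se_cumulative_pd = if (n >= 2L)
                 sd(d$cumulative_pd) / sqrt(n) else NA_real_,
               mean_density = mean(d$density),
               se_density = if (n >= 2L) sd(d$density) / sqrt(n)
               else NA_real_)
  })
  per <- do.call(rbind, per)
  per <- per[order(per$day), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(genotype = curves[[1L]]$genotype,
                 n_replicates = length(curves),
                 per_passage = per),
            class = "genotype_summary")
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat("Genotype", x$genotype, "-", x$n_replicates, "replicates,",
      nrow(x$per_passage), "passages\n")
  print(x$per_passage, digits = 4)
  invisible(x)
}
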