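#' Divergence bar profile of a clone set
#'
#' One horizontal bar per clone, sorted by undiverged length: the black
#' proximal segment is the undiverged region, the light-gray distal
#' segment the diverged region, and an optional red line marks the
#' truncation threshold (125 nt by default).
#'
#' @param calls data frame from [call_set()].
#' @param rules a [divergence_rules()] (for the threshold line).
#' @param threshold_line draw the truncation threshold (default `TRUE`).
#' @param main plot title.
#' @return Invisibly, the calls, ordered as plotted.
#' @export
plot_divergence_bars <- function(calls, rules = divergence_rules(),
                                 threshold_line = TRUE, main = NULL) {
  stopifnot(is.data.frame(calls),
            all(c("undiverged_length_nt", "clone_length_nt") %in%
                  names(calls)))
  calls <- calls[order(-calls$undiverged_length_nt), , drop = FALSE]
  n <- nrow(calls)
  xmax <- max(calls$clone_length_nt)
  op <- graphics::par(mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  plot(NA, xlim = c(0, xmax * 1.02), ylim = c(0, n + 1),
       xlab = "Telomere length (nt)", ylab = "Clone",
       yaxt = "n", bty = "n",
       main = if (is.null(main)) "Telomere sequence divergence" else main)
  for (i in seq_len(n)) {
    y <- n - i + 1
    graphics::rect(0, y - 0.4, calls$clone_length_nt[i], y + 0.4,
                   col = "grey80", border = NA)
    graphics::rect(0, y - 0.4, calls$undiverged_length_nt[i], y + 0.4,
                   col = "black", border = NA)
  }
  if (threshold_line)
    graphics::abline(v = rules$truncation_threshold_nt, col = "red",
                     lwd = 2)
  invisible(calls)
}

#' Senescence curves by genotype
#'
#' Mean cell density (log scale) against mean cumulative population
#' doublings per passage, with standard-error bars, one line per
#' genotype summary.
#'
#' @param summaries list of [summarize_genotype()] results.
#' @param main plot title.
#' @return Invisibly, `summaries`.
#' @export
plot_senescence <- function(summaries, main = "Senescence assay") {
  if (inherits(summaries, "genotype_summary")) summaries <- list(summaries)
  all_pd <- unlist(lapply(summaries, function(s)
    s$per_passage$mean_cumulative_pd))
  all_d <- unlist(lapply(summaries, function(s) s$per_passage$mean_density))
  plot(NA, xlim = range(all_pd), ylim = range(all_d), log = "y",
       xlab = "Population doublings", ylab = "Cell density (cells/ml)",
       main = main, bty = "l")
  cols <- seq_along(summaries)
  for (i in seq_along(summaries)) {
    pp <- summaries[[i]]$per_passage
    graphics::lines(pp$mean_cumulative_pd, pp$mean_density, col = cols[i],
                    type = "b", pch = 19)
    se <- pp$se_density
    ok <- !is.na(se) & se > 0
    if (any(ok))
      graphics::arrows(pp$mean_cumulative_pd[ok],
                       pmax(pp$mean_density[ok] - se[ok],
                            min(all_d) / 10),
                       pp$mean_cumulative_pd[ok],
                       pp$mean_density[ok] + se[ok],
                       angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("topright",
                   legend = vapply(summaries, function(s) s$genotype, ""),
                   col = cols, lty = 1, pch = 19, bty = "n")
  invisible(summaries)
}
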