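#' Construct a telomere clone set
#'
#' A telomere set holds every sequenced clone of one telomere locus from
#' one clonal population — the unit on which divergence is called.
#' Sequences are stored 5'->3' on the G-rich strand with the
#' centromere-proximal end at position 1.
#'
#' @param telomere_id telomere locus, e.g. `"TEL06R"`.
#' @param strain_id strain identifier.
#' @param genotype genotype label, e.g. `"est2"`.
#' @param generations population doublings since clonal isolation
#'   (non-negative).
#' @param clones data frame with columns `clone_id` (unique) and `bases`
#'   (non-empty A/C/G/T strings).
#' @return An object of class `telomere_set`.
#' @export
#' @examples
#' telomere_set("TEL06R", "CCY16-1", "est2", 30,
#'              data.frame(clone_id = c("c1", "c2"),
#'                         bases = c("TGTGGGTG", "TGTGGGTG")))
telomere_set <- function(telomere_id, strain_id, genotype, generations,
                         clones) {
  stopifnot(is.character(telomere_id), length(telomere_id) == 1L,
            is.character(strain_id), length(strain_id) == 1L,
            is.character(genotype), length(genotype) == 1L,
            is.numeric(generations), length(generations) == 1L,
            is.data.frame(clones),
            all(c("clone_id", "bases") %in% names(clones)))
  if (generations < 0) stop("generations must be non-negative")
  if (anyDuplicated(clones$clone_id))
    stop("duplicate clone_id in telomere set")
  bases <- toupper(clones$bases)
  bad <- grepl("[^ACGT]", bases)
  if (any(bad))
    stop("non-ACGT characters in clone(s): ",
         paste(clones$clone_id[bad], collapse = ", "))
  if (any(!nzchar(bases)))
    stop("empty sequence in clone(s): ",
         paste(clones$clone_id[!nzchar(bases)], collapse = ", "))
  clones$bases <- bases
  structure(list(telomere_id = telomere_id, strain_id = strain_id,
                 genotype = genotype, generations = as.numeric(generations),
                 clones = clones[, c("clone_id", "bases")]),
            class = "telomere_set")
}

#' @export
print.telomere_set <- function(x, ...) {
  cat("Telomere clone set ", x$telomere_id, " / ", x$strain_id,
      " (", x$genotype, "), ", x$generations, " generations, ",
      nrow(x$clones), " clones\n", sep = "")
  cat("  clone lengths: ",
      paste(range(nchar(x$clones$bases)), collapse = "-"), " nt\n", sep = "")
  invisible(x)
}

.SHEET_COLS <- c("clone_id", "telomere_id", "strain_id", "genotype",
                 "generations")

#' Read or write a sample sheet
#'
#' The sample sheet maps each FASTA record to its telomere locus, strain,
#' genotype and generations of clonal expansion. Tab-separated with header
#' columns `clone_id`, `telomere_id`, `strain_id`, `genotype`,
#' `generations`.
#'
#' @param path file path.
#' @return `read_sample_sheet()` returns a validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
  missing <- setdiff(.SHEET_COLS, names(sheet))
  if (length(missing))
    stop("sample sheet misses column(s): ", paste(missing, collapse = ", "))
  sheet <- sheet[, .SHEET_COLS]
  sheet$generations <- as.numeric(sheet$generations)
  if (anyNA(sheet$generations) || any(sheet$generations < 0))
    stop("generations must be non-negative numbers")
  if (anyDuplicated(sheet$clone_id))
    stop("duplicate clone_id in sample sheet: ",
         paste(unique(sheet$clone_id[duplicated(sheet$clone_id)]),
               collapse = ", "))
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(is.data.frame(sheet), all(.SHEET_COLS %in% names(sheet)))
  write.table(sheet[, .SHEET_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read cloned telomere sequences into telomere sets
#'
#' Reads a clone FASTA (G-rich strand, centromere-proximal end first) and
#' groups records into [telomere_set()] objects by
#' `(telomere_id, strain_id, generations)` using the sample sheet. Record
#' descriptions after the first whitespace are ignored for id matching;
#' sequences are upper-cased on ingest. Singleton groups are excluded with
#' a warning since divergence needs at least two clones.
#'
#' @param path FASTA file of clone sequences.
#' @param sample_sheet data frame from [read_sample_sheet()], or a path.
#' @param revcomp reverse-complement sequences on ingest (for C-rich
#'   strand submissions). Default `FALSE`.
#' @return Named list of `telomere_set` objects; clone order within each
#'   set follows the file.
#' @export
read_clone_fasta <- function(path, sample_sheet, revcomp = FALSE) {
  if (is.character(sample_sheet) && length(sample_sheet) == 1L)
    sample_sheet <- read_sample_sheet(sample_sheet)
  seqs <- Biostrings::readDNAStringSet(path)
  if (revcomp) seqs <- Biostrings::reverseComplement(seqs)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  unknown <- setdiff(ids, sample_sheet$clone_id)
  if (length(unknown))
    stop("FASTA record(s) absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  bases <- toupper(as.character(seqs))
  if (any(!nzchar(bases)))
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(bases)], collapse = ", "))
  rows <- sample_sheet[match(ids, sample_sheet$clone_id), ]
  key <- paste(rows$telomere_id, rows$strain_id, rows$generations,
               sep = "\r")
  sets <- lapply(split(seq_along(ids), factor(key, levels = unique(key))),
                 function(ii) {
    r1 <- rows[ii[1L], ]
    telomere_set(r1$telomere_id, r1$strain_id, r1$genotype, r1$generations,
                 data.frame(clone_id = ids[ii], bases = bases[ii],
                            stringsAsFactors = FALSE))
  })
  names(sets) <- vapply(sets, function(s)
    paste(s$telomere_id, s$strain_id, s$generations, sep = "_"), "")
  n1 <- vapply(sets, function(s) nrow(s$clones), 0L) < 2L
  if (any(n1)) {
    warning("excluding singleton group(s) with a single clone: ",
            paste(names(sets)[n1], collapse = ", "))
    sets <- sets[!n1]
  }
  sets
}

#' Write clone sequences as FASTA
#'
#' @param sets a list of [telomere_set()] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(sets, path) {
  if (inherits(sets, "telomere_set")) sets <- list(sets)
  ids <- unlist(lapply(sets, function(s) s$clones$clone_id))
  bases <- unlist(lapply(sets, function(s) s$clones$bases))
  x <- Biostrings::DNAStringSet(bases)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.CALL_COLS <- c("clone_id", "telomere_id", "strain_id", "genotype",
                "generations", "clone_length_nt", "undiverged_length_nt",
                "diverged", "divergence_point_1based", "truncation",
                "reason")

#' Read or write a divergence-call table
#'
#' Tab-separated table of per-clone divergence calls, one row per clone,
#' with all reported positions and lengths 1-based in nucleotides. The
#' writer and reader round-trip losslessly.
#'
#' @param calls non-empty data frame of calls (from [call_set()]).
#' @param path file path.
#' @return `write_calls_table()` returns `path` invisibly;
#'   `read_calls_table()` returns the calls data frame.
#' @export
write_calls_table <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  if (!nrow(calls)) stop("refusing to write an empty calls table")
  missing <- setdiff(.CALL_COLS, names(calls))
  if (length(missing))
    stop("calls table misses column(s): ", paste(missing, collapse = ", "))
  write.table(calls[, .CALL_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_calls_table
#' @export
read_calls_table <- function(path) {
  calls <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  missing <- setdiff(.CALL_COLS, names(calls))
  if (length(missing))
    stop("calls table misses column(s): ", paste(missing, collapse = ", "))
  calls$diverged <- as.logical(calls$diverged)
  calls$truncation <- as.logical(calls$truncation)
  calls$divergence_point_1based <- as.integer(calls$divergence_point_1based)
  calls[, .CALL_COLS]
}

.DENSITY_COLS <- c("strain_id", "genotype", "replicate_id", "day",
                   "density")

#' Read or write a daily cell-density table
#'
#' Tab-separated table of liquid-culture senescence measurements: one row
#' per strain, replicate and day, density in cells/ml measured after 24 h
#' of growth. Within each (strain, replicate) series days must be
#' consecutive from 1 and densities strictly positive.
#'
#' @param path file path.
#' @return `read_density_table()` returns a validated data frame.
#' @export
read_density_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.DENSITY_COLS, names(d))
  if (length(missing))
    stop("density table misses column(s): ", paste(missing, collapse = ", "))
  d <- d[, .DENSITY_COLS]
  d$day <- as.integer(d$day)
  d$density <- as.numeric(d$density)
  if (anyNA(d$day) || anyNA(d$density))
    stop("non-numeric day or density")
  if (any(d$density <= 0))
    stop("non-positive density (cells/ml must be > 0)")
  key <- paste(d$strain_id, d$replicate_id, d$day, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (strain_id, replicate_id, day) row(s)")
  by_rep <- split(d$day, paste(d$strain_id, d$replicate_id, sep = "\r"))
  for (nm in names(by_rep)) {
    days <- sort(by_rep[[nm]])
    if (!identical(days, seq_len(length(days))))
      stop("days not consecutive from 1 for replicate: ",
           gsub("\r", " / ", nm))
  }
  d
}

#' @rdname read_density_table
#' @param densities a density data frame.
#' @export
write_density_table <- function(densities, path) {
  stopifnot(is.data.frame(densities),
            all(.DENSITY_COLS %in% names(densities)))
  write.table(densities[, .DENSITY_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
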