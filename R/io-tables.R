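#' Read a peptide report
#'
#' Imports peptide-level search-engine exports into the internal report
#' layout: one row per peptide with columns `peptide`, `protein`, `start`,
#' `end`, `prev_aa`, `next_aa`, `fdr` and one intensity column per sample.
#' Three dialects are supported:
#' \describe{
#'   \item{generic}{already in the internal layout; intensity columns are
#'     every column not otherwise claimed (or those named in `samples`).}
#'   \item{pd}{Proteome Discoverer style: `Annotated Sequence`,
#'     `Master Protein Accessions`, `Percolator q-Value`, and
#'     `Abundance: <sample>` columns. Coordinates are absent and left NA
#'     ("to be mapped").}
#'   \item{fragpipe}{FragPipe/MSFragger combined peptide report: `Peptide
#'     Sequence`, `Protein ID`, `Start`, `End`, `Prev AA`, `Next AA`,
#'     `Probability`, and `<sample> Intensity` columns.}
#' }
#' Zeros and blanks in intensity columns are read as missing by default
#' (identification without quantification); set `zero_is_missing = FALSE`
#' to keep zeros as values. Rows above the peptide FDR threshold are
#' retained -- filtering is the caller's decision.
#'
#' @param path TSV file (UTF-8, tab separated, header row).
#' @param dialect one of `"generic"`, `"pd"`, `"fragpipe"`.
#' @param samples optional character vector naming the sample/intensity
#'   columns, in design order.
#' @param zero_is_missing replace 0 intensities with NA.
#' @return data frame in the internal report layout; attribute `"samples"`
#'   holds the intensity column names.
#' @export
read_peptide_report <- function(path, dialect = c("generic", "pd", "fragpipe"),
                                samples = NULL, zero_is_missing = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  req <- switch(dialect,
    generic = c("peptide", "protein"),
    pd = c("Annotated Sequence", "Master Protein Accessions"),
    fragpipe = c("Peptide Sequence", "Protein ID")
  )
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("peptide report (", dialect, ") is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- switch(dialect,
    generic = parse_generic_report(raw, samples),
    pd = parse_pd_report(raw, samples),
    fragpipe = parse_fragpipe_report(raw, samples)
  )
  smp <- attr(out, "samples")
  for (s in smp) {
    v <- suppressWarnings(as.numeric(out[[s]]))
    if (zero_is_missing) v[!is.na(v) & v == 0] <- NA_real_
    out[[s]] <- v
  }
  out
}

parse_generic_report <- function(raw, samples) {
  fixed <- c("peptide", "protein", "start", "end", "prev_aa", "next_aa", "fdr")
  if (is.null(samples)) samples <- setdiff(names(raw), fixed)
  out <- data.frame(
    peptide = toupper(raw$peptide),
    protein = raw$protein,
    start = if ("start" %in% names(raw)) as.integer(raw$start) else NA_integer_,
    end = if ("end" %in% names(raw)) as.integer(raw$end) else NA_integer_,
    prev_aa = if ("prev_aa" %in% names(raw)) raw$prev_aa else NA_character_,
    next_aa = if ("next_aa" %in% names(raw)) raw$next_aa else NA_character_,
    fdr = if ("fdr" %in% names(raw)) as.numeric(raw$fdr) else 0,
    stringsAsFactors = FALSE
  )
  out[samples] <- raw[samples]
  structure(out, samples = samples)
}

parse_pd_report <- function(raw, samples) {
  # annotated sequence looks like "[K].AAAGTK.[L]" -- flanks in brackets
  ann <- raw[["Annotated Sequence"]]
  core <- toupper(sub("^\\[.?\\]\\.", "", sub("\\.\\[.?\\]$", "", ann)))
  prev <- ifelse(grepl("^\\[(.)\\]\\.", ann), sub("^\\[(.)\\]\\..*$", "\\1", ann),
                 NA_character_)
  nxt <- ifelse(grepl("\\.\\[(.)\\]$", ann), sub("^.*\\.\\[(.)\\]$", "\\1", ann),
                NA_character_)
  if (is.null(samples)) {
    ab <- grep("^Abundance", names(raw), value = TRUE)
    samples <- ab
  }
  out <- data.frame(
    peptide = core,
    protein = raw[["Master Protein Accessions"]],
    start = NA_integer_, end = NA_integer_,
    prev_aa = toupper(prev), next_aa = toupper(nxt),
    fdr = if ("Percolator q-Value" %in% names(raw)) {
      as.numeric(raw[["Percolator q-Value"]])
    } else 0,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  out[samples] <- raw[samples]
  structure(out, samples = samples)
}

parse_fragpipe_report <- function(raw, samples) {
  if (is.null(samples)) {
    samples <- grep(" Intensity$", names(raw), value = TRUE)
  }
  out <- data.frame(
    peptide = toupper(raw[["Peptide Sequence"]]),
    protein = raw[["Protein ID"]],
    start = if ("Start" %in% names(raw)) as.integer(raw$Start) else NA_integer_,
    end = if ("End" %in% names(raw)) as.integer(raw$End) else NA_integer_,
    prev_aa = if ("Prev AA" %in% names(raw)) toupper(raw[["Prev AA"]]) else NA_character_,
    next_aa = if ("Next AA" %in% names(raw)) toupper(raw[["Next AA"]]) else NA_character_,
    fdr = if ("Probability" %in% names(raw)) 1 - as.numeric(raw$Probability) else 0,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  out[samples] <- raw[samples]
  structure(out, samples = samples)
}

#' Write a peptide report in the generic dialect
#'
#' @param report internal-layout report (see [read_peptide_report()]).
#' @param path output TSV path.
#' @export
write_peptide_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample` and `group`; exactly two groups,
#'   each non-empty.
#' @return data frame of class `"sample_design"` with columns `sample`,
#'   `group` (factor with two levels; the first level is the case group as
#'   ordered in the file).
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(d)))
  sample_design(d$sample, d$group)
}

#' @rdname read_design
#' @param sample character vector of sample identifiers.
#' @param group group label per sample.
#' @export
sample_design <- function(sample, group) {
  if (anyDuplicated(sample)) stop("duplicate sample identifiers in design")
  lev <- unique(group)
  if (length(lev) != 2) {
    stop("design must contain exactly two groups, found ", length(lev))
  }
  d <- data.frame(sample = as.character(sample),
                  group = factor(group, levels = lev),
                  stringsAsFactors = FALSE)
  if (any(table(d$group) == 0)) stop("both design groups must be non-empty")
  class(d) <- c("sample_design", "data.frame")
  d
}

design_groups <- function(design) levels(design$group)

design_samples <- function(design, group = NULL) {
  if (is.null(group)) design$sample else design$sample[design$group == group]
}

#' Read a signal-peptide annotation table
#'
#' @param path TSV with columns `accession`, `signal_end`.
#' @return data frame with those columns.
#' @export
read_signal_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "signal_end") %in% names(d)))
  d$signal_end <- as.integer(d$signal_end)
  d
}

#' Read a cleavage-site database
#'
#' A local stand-in for protease knowledge-base lookups: one row per known
#' cleavage event, identified by protein accession and P1 position (the
#' residue N-terminal to the scissile bond, 1-based).
#'
#' @param path TSV with columns `accession`, `p1_position`, `protease` and
#'   optionally `evidence`.
#' @return data frame with those columns (`evidence` NA-filled if absent).
#' @export
read_cleavage_db <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "p1_position", "protease") %in% names(d)))
  d$p1_position <- as.integer(d$p1_position)
  if (any(d$p1_position < 1, na.rm = TRUE)) {
    stop("cleavage DB p1_position must be >= 1")
  }
  if (!"evidence" %in% names(d)) d$evidence <- NA_character_
  d[c("accession", "p1_position", "protease", "evidence")]
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: tab-separated lines of term, description, then
#'   member identifiers.
#' @return named list of character vectors (term -> members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                     paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Check a peptide report against a design
#'
#' @param report internal-layout peptide report.
#' @param design a `sample_design`.
#' @return invisibly `TRUE`; errors when a design sample has no intensity
#'   column.
#' @export
check_report_design <- function(report, design) {
  smp <- attr(report, "samples")
  if (is.null(smp)) smp <- intersect(design$sample, names(report))
  missing_samples <- setdiff(design$sample, smp)
  if (length(missing_samples) > 0) {
    stop("design sample(s) absent from peptide report: ",
         paste(missing_samples, collapse = ", "))
  }
  extra <- setdiff(smp, design$sample)
  if (length(extra) > 0) {
    stop("report sample(s) absent from design: ",
         paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}
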