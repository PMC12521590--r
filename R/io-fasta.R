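#' Read a protein FASTA file
#'
#' Parses a protein database into a proteome table. Accessions are taken
#' from the first whitespace-delimited token of the header; the UniProt
#' `sp|ACC|NAME` / `tr|ACC|NAME` dialect is recognised and yields the
#' central accession. Sequences are uppercased; the ambiguity codes
#' U, B and Z are mapped to `X` silently, any other non-standard letter is
#' mapped to `X` with a warning.
#'
#' @param path FASTA file.
#' @param signal_table optional data frame (or TSV path) with columns
#'   `accession` and `signal_end` giving the last residue of the signal
#'   peptide; merged into the result.
#' @return data frame with columns `accession`, `sequence`, `length`,
#'   `signal_end` (NA when unannotated) and `description`.
#' @export
read_fasta <- function(path, signal_table = NULL) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  first <- sub("\\s.*$", "", headers)
  acc <- ifelse(grepl("^(sp|tr)\\|", first),
                vapply(strsplit(first, "|", fixed = TRUE), `[`, "", 2L),
                first)
  dup <- acc[duplicated(acc)]
  if (length(dup) > 0) {
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues found; sequences uppercased")
    seqs <- toupper(seqs)
  }
  seqs <- gsub("[UBZ]", "X", seqs)
  nonstd <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seqs)
  if (any(nonstd)) {
    warning("non-standard residues mapped to 'X' in ",
            sum(nonstd), " sequence(s)")
    seqs <- gsub(sprintf("[^%sX]", paste(AA20, collapse = "")), "X", seqs)
  }
  desc <- sub("^\\S+\\s*", "", headers)
  prot <- data.frame(
    accession = acc, sequence = seqs, length = nchar(seqs),
    signal_end = NA_integer_, description = desc,
    stringsAsFactors = FALSE
  )
  if (!is.null(signal_table)) prot <- add_signal_annotation(prot, signal_table)
  prot
}

#' @rdname read_fasta
#' @param proteome a proteome data frame as returned by [read_fasta()].
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    hdr <- proteome$accession[i]
    if (!is.na(proteome$description[i]) && nzchar(proteome$description[i])) {
      hdr <- paste(hdr, proteome$description[i])
    }
    writeLines(paste0(">", hdr), con)
    s <- proteome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Attach signal-peptide annotation to a proteome
#'
#' @param proteome proteome data frame.
#' @param signal_table data frame or TSV path with columns `accession`,
#'   `signal_end`.
#' @return the proteome with `signal_end` filled where annotated.
#' @export
add_signal_annotation <- function(proteome, signal_table) {
  if (is.character(signal_table)) signal_table <- read_signal_table(signal_table)
  stopifnot(all(c("accession", "signal_end") %in% names(signal_table)))
  idx <- match(proteome$accession, signal_table$accession)
  se <- signal_table$signal_end[idx]
  bad <- !is.na(se) & (se < 1 | se >= proteome$length)
  if (any(bad)) {
    stop("signal_end out of range for: ",
         paste(proteome$accession[bad], collapse = ", "))
  }
  proteome$signal_end <- as.integer(se)
  proteome
}

# the 20 canonical residues, alphabetical
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
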