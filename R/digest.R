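#' In-silico tryptic digestion
#'
#' Enumerates the peptides produced by trypsin cleavage (after K or R)
#' of a protein sequence. With the proline rule on (the Sequest
#' "Trypsin (full)" convention, default), cleavage is suppressed when the
#' residue following K/R is proline; MSFragger's "stricttrypsin" ignores
#' the rule, so it is switchable. Peptides spanning up to
#' `missed_cleavages` internal sites are enumerated; the length filter is
#' applied last.
#'
#' @param sequence protein sequence (single string).
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param length_range `c(min, max)` peptide length filter, or `NULL` for
#'   no filter.
#' @param proline_rule suppress cleavage before proline.
#' @return data frame with columns `start`, `end`, `peptide`, `n_missed`,
#'   sorted by (start, end).
#' @export
digest_protein <- function(sequence, missed_cleavages = 2L,
                           length_range = NULL, proline_rule = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a non-empty string")
  }
  stopifnot(missed_cleavages >= 0)
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence, proline_rule)
  bounds <- c(0L, sites, n)
  bounds <- unique(bounds[order(bounds)])
  k <- length(bounds) - 1L  # number of base fragments
  rows <- list()
  for (i in seq_len(k)) {
    for (mc in 0:min(missed_cleavages, k - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + mc]
      rows[[length(rows) + 1L]] <- c(s, e, mc)
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(start = m[, 1], end = m[, 2],
                    peptide = substring(sequence, m[, 1], m[, 2]),
                    n_missed = m[, 3], stringsAsFactors = FALSE)
  if (!is.null(length_range)) {
    if (length_range[2] < length_range[1]) stop("invalid length_range")
    len <- out$end - out$start + 1L
    out <- out[len >= length_range[1] & len <= length_range[2], , drop = FALSE]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# positions i such that trypsin cleaves between i and i+1
cleavage_sites <- function(sequence, proline_rule = TRUE) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  i <- which(res %in% c("K", "R"))
  i <- i[i < n]
  if (proline_rule && length(i) > 0) i <- i[res[i + 1L] != "P"]
  i
}

#' Locate a peptide within a proteome
#'
#' Finds every exact occurrence of a peptide sequence across all proteins
#' and fills the flanking residues (`'-'` at protein boundaries). The
#' `unique` flag is `TRUE` only when the peptide occurs exactly once in
#' exactly one protein.
#'
#' @param peptide peptide sequence.
#' @param proteome proteome data frame (see [read_fasta()]).
#' @return data frame with columns `accession`, `start`, `end`, `prev_aa`,
#'   `next_aa`, `unique`; zero rows when the peptide does not occur.
#' @export
map_peptide <- function(peptide, proteome) {
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  hits <- lapply(seq_len(nrow(proteome)), function(i) {
    s <- proteome$sequence[i]
    m <- gregexpr(peptide, s, fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    starts <- as.integer(m)
    ends <- starts + nchar(peptide) - 1L
    data.frame(
      accession = proteome$accession[i],
      start = starts, end = ends,
      prev_aa = ifelse(starts == 1L, "-", substring(s, starts - 1L, starts - 1L)),
      next_aa = ifelse(ends == nchar(s), "-", substring(s, ends + 1L, ends + 1L)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(accession = character(), start = integer(),
                      end = integer(), prev_aa = character(),
                      next_aa = character(), unique = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$unique <- nrow(out) == 1L
  rownames(out) <- NULL
  out
}

#' Classify the tryptic status of a located peptide
#'
#' The N-boundary of a peptide is tryptic-compatible when the preceding
#' residue is K or R, or when the peptide starts at position 1 or 2 of the
#' protein (position 2 covers initiator-methionine removal). The
#' C-boundary is tryptic when the last residue is K or R, or when the
#' peptide ends at the protein's last residue. A peptide is `full` when
#' both boundaries are tryptic, `semi_N` when only the N-boundary is
#' non-tryptic (evidence of an endogenous N-terminus), `semi_C` when only
#' the C-boundary is non-tryptic, and `non_tryptic` otherwise.
#'
#' @param location one-row data frame or list with `start`, `end`,
#'   `prev_aa` (use `'-'` at the protein start).
#' @param protein one-row proteome entry (needs `sequence`).
#' @return one of `"full"`, `"semi_N"`, `"semi_C"`, `"non_tryptic"`.
#' @export
classify_tryptic <- function(location, protein) {
  classify_tryptic_vec(
    start = location$start, end = location$end, prev_aa = location$prev_aa,
    last_aa = substring(protein$sequence, location$end, location$end),
    protein_length = nchar(protein$sequence)
  )
}

classify_tryptic_vec <- function(start, end, prev_aa, last_aa, protein_length) {
  n_tryptic <- prev_aa %in% c("K", "R") | start %in% c(1L, 2L)
  c_tryptic <- last_aa %in% c("K", "R") | end == protein_length
  out <- rep("non_tryptic", length(start))
  out[n_tryptic & c_tryptic] <- "full"
  out[!n_tryptic & c_tryptic] <- "semi_N"
  out[n_tryptic & !c_tryptic] <- "semi_C"
  out
}
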