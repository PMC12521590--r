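#' Call endogenous termini from a peptide report
#'
#' Applies the degradomics calling rules to a located peptide report.
#' For N-termini, a peptide evidences an endogenous N-terminus only when
#' the residue flanking its N-boundary is not K or R (otherwise the
#' boundary is attributable to the trypsin digest); the terminus is
#' `mature` when the peptide starts at protein position 1 or 2 (database
#' N-terminus, initiator-Met removal) or immediately after the annotated
#' signal peptide, and `neo` otherwise. For C-termini the peptide's last
#' residue must not be K or R; a peptide ending at the protein's last
#' residue is the `database` C-terminus, anything else a `neo` C-terminus.
#' By default the opposite boundary must be tryptic-compatible (pure
#' semi-tryptic evidence); relax with `allow_non_tryptic` in the config.
#'
#' Rows above the peptide FDR threshold and rows without a unique location
#' are skipped (counted in the `skipped` element). Events from distinct
#' peptides sharing (accession, P1) are merged: presence vectors are OR-ed
#' and intensities summed per sample. P1 is `start - 1` for N-termini and
#' `end` for C-termini (the residue N-terminal to the scissile bond).
#'
#' @param report located peptide report (generic layout; see
#'   [read_peptide_report()]).
#' @param proteome proteome data frame with `signal_end`.
#' @param design a [sample_design()].
#' @param config a [pipeline_config()].
#' @param type `"N"` or `"C"`.
#' @return object of class `"terminome"`: list with `events` (one row per
#'   merged terminus: accession, terminus, category, db_terminus, p1,
#'   p1_prime, window, peptides, per-group presence counts), `presence`
#'   (logical events x samples), `intensity` (raw-scale events x samples),
#'   `design`, `type`, `skipped`.
#' @export
call_termini <- function(report, proteome, design, config = pipeline_config(),
                         type = c("N", "C")) {
  type <- match.arg(type)
  check_report_design(report, design)
  samples <- design$sample
  skipped <- c(fdr = 0L, unmapped = 0L, non_unique = 0L)

  keep <- is.na(report$fdr) | report$fdr <= config$peptide_fdr_max
  skipped["fdr"] <- sum(!keep)
  report <- report[keep, , drop = FALSE]

  report <- resolve_locations(report, proteome, skipped)
  skipped <- attr(report, "skipped")

  pidx <- match(report$protein, proteome$accession)
  seqs <- proteome$sequence[pidx]
  plen <- proteome$length[pidx]
  sig <- proteome$signal_end[pidx]
  last_aa <- substring(seqs, report$end, report$end)
  sub <- substring(seqs, report$start, report$end)
  bad <- sub != report$peptide
  if (any(bad)) {
    stop("peptide/coordinate mismatch for row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }

  n_tryptic <- report$prev_aa %in% c("K", "R") | report$start %in% c(1L, 2L)
  c_tryptic <- last_aa %in% c("K", "R") | report$end == plen

  if (type == "N") {
    endo <- !(report$prev_aa %in% c("K", "R"))
    if (!config$allow_non_tryptic) endo <- endo & c_tryptic
    category <- ifelse(report$start %in% c(1L, 2L) |
                         (!is.na(sig) & report$start == sig + 1L),
                       "mature", "neo")
    db_flag <- report$start %in% c(1L, 2L)
    p1 <- report$start - 1L
  } else {
    endo <- !(last_aa %in% c("K", "R"))
    if (!config$allow_non_tryptic) endo <- endo & n_tryptic
    category <- ifelse(report$end == plen, "database", "neo")
    db_flag <- report$end == plen
    p1 <- report$end
  }

  report <- report[endo, , drop = FALSE]
  category <- category[endo]; db_flag <- db_flag[endo]; p1 <- p1[endo]
  seqs <- seqs[endo]; plen <- plen[endo]

  if (nrow(report) == 0) {
    ev <- data.frame(accession = character(), terminus = character(),
                     category = character(), db_terminus = logical(),
                     p1 = integer(), p1_prime = character(),
                     window = character(), peptides = character(),
                     stringsAsFactors = FALSE)
    for (g in design_groups(design)) ev[[paste0("n_", g)]] <- integer()
    empty <- matrix(NA_real_, 0, length(samples),
                    dimnames = list(NULL, samples))
    return(structure(list(events = ev, presence = empty > 0,
                          intensity = empty, design = design, type = type,
                          skipped = skipped),
                     class = "terminome"))
  }

  intens <- as.matrix(report[samples])
  storage.mode(intens) <- "double"

  key <- paste(report$protein, p1, sep = "@")
  grp <- factor(key, levels = unique(key))
  first <- !duplicated(key)
  ev <- data.frame(
    accession = report$protein[first],
    terminus = rep(type, sum(first)),
    category = category[first],
    db_terminus = db_flag[first],
    p1 = p1[first],
    stringsAsFactors = FALSE
  )
  ev$p1_prime <- ifelse(ev$p1 < plen[first],
                        substring(seqs[first], ev$p1 + 1L, ev$p1 + 1L),
                        NA_character_)
  ev$window <- vapply(which(first), function(i) {
    if (p1[i] >= 1L && p1[i] < nchar(seqs[i])) {
      paste(extract_window(seqs[i], p1[i], config$window_half_width),
            collapse = "")
    } else NA_character_
  }, "")
  ev$peptides <- vapply(split(report$peptide, grp), function(p) {
    paste(unique(p), collapse = ";")
  }, "")

  pres <- rowsum((!is.na(intens)) * 1, grp, reorder = FALSE) > 0
  isum <- rowsum(ifelse(is.na(intens), 0, intens), grp, reorder = FALSE)
  isum[!pres] <- NA_real_
  colnames(pres) <- colnames(isum) <- samples

  for (g in design_groups(design)) {
    ev[[paste0("n_", g)]] <- as.integer(
      rowSums(pres[, design_samples(design, g), drop = FALSE])
    )
  }
  rownames(ev) <- NULL

  structure(list(events = ev, presence = pres, intensity = isum,
                 design = design, type = type, skipped = skipped),
            class = "terminome")
}

# fill missing coordinates by exact mapping; drop unmapped and ambiguous
# rows, incrementing the skip counters
resolve_locations <- function(report, proteome, skipped) {
  need <- is.na(report$start) | is.na(report$end)
  drop <- rep(FALSE, nrow(report))
  if (any(need)) {
    for (i in which(need)) {
      loc <- map_peptide(report$peptide[i], proteome)
      if (nrow(loc) == 0) {
        skipped["unmapped"] <- skipped["unmapped"] + 1L
        drop[i] <- TRUE
      } else if (nrow(loc) > 1) {
        skipped["non_unique"] <- skipped["non_unique"] + 1L
        drop[i] <- TRUE
      } else {
        report$protein[i] <- loc$accession
        report$start[i] <- loc$start
        report$end[i] <- loc$end
        report$prev_aa[i] <- loc$prev_aa
        report$next_aa[i] <- loc$next_aa
      }
    }
  }
  # peptides reported under several accessions are ambiguous
  tab <- unique(report[c("peptide", "protein")])
  multi <- tab$peptide[duplicated(tab$peptide)]
  amb <- report$peptide %in% multi
  skipped["non_unique"] <- skipped["non_unique"] + sum(amb & !drop)
  drop <- drop | amb
  if ("unique" %in% names(report)) {
    flagged <- !is.na(report$unique) & !report$unique
    skipped["non_unique"] <- skipped["non_unique"] + sum(flagged & !drop)
    drop <- drop | flagged
  }
  out <- report[!drop, , drop = FALSE]
  attr(out, "samples") <- attr(report, "samples")
  attr(out, "skipped") <- skipped
  out
}

#' Call a single N- or C-terminus
#'
#' Row-level versions of the calling rules in [call_termini()]; useful for
#' tracing individual peptides. No merging is performed.
#'
#' @param row one-row data frame or list with `peptide`, `start`, `end`,
#'   `prev_aa`, `fdr`, and intensity values.
#' @param protein one-row proteome entry (`sequence`, `signal_end`).
#' @param config a [pipeline_config()].
#' @return a list describing the terminus event, or `NULL` when the row is
#'   not terminus evidence.
#' @export
call_n_terminus <- function(row, protein, config = pipeline_config()) {
  if (!is.na(row$fdr) && row$fdr > config$peptide_fdr_max) return(NULL)
  if (row$prev_aa %in% c("K", "R")) return(NULL)
  plen <- nchar(protein$sequence)
  last_aa <- substring(protein$sequence, row$end, row$end)
  if (!config$allow_non_tryptic &&
      !(last_aa %in% c("K", "R") || row$end == plen)) return(NULL)
  sig <- protein$signal_end
  mature <- row$start %in% c(1L, 2L) || (!is.na(sig) && row$start == sig + 1L)
  list(accession = protein$accession, terminus = "N",
       category = if (mature) "mature" else "neo",
       db_terminus = row$start %in% c(1L, 2L),
       p1 = row$start - 1L,
       p1_prime = substring(protein$sequence, row$start, row$start),
       peptide = row$peptide)
}

#' @rdname call_n_terminus
#' @export
call_c_terminus <- function(row, protein, config = pipeline_config()) {
  if (!is.na(row$fdr) && row$fdr > config$peptide_fdr_max) return(NULL)
  plen <- nchar(protein$sequence)
  last_aa <- substring(protein$sequence, row$end, row$end)
  if (last_aa %in% c("K", "R")) return(NULL)
  if (!config$allow_non_tryptic &&
      !(row$prev_aa %in% c("K", "R") || row$start %in% c(1L, 2L))) return(NULL)
  db <- row$end == plen
  list(accession = protein$accession, terminus = "C",
       category = if (db) "database" else "neo",
       db_terminus = db, p1 = row$end,
       p1_prime = if (db) NA_character_ else {
         substring(protein$sequence, row$end + 1L, row$end + 1L)
       },
       peptide = row$peptide)
}

#' Presence filter for terminus events
#'
#' Retains events identified and quantified (non-missing raw intensity) in
#' at least `min_count` samples of at least one group. Counting happens on
#' raw presence, before any imputation.
#'
#' @param terminome a `"terminome"` object.
#' @param min_count minimum per-group sample count; defaults to the
#'   config value used at call time (3).
#' @return the filtered `"terminome"`.
#' @export
presence_filter <- function(terminome, min_count = 3) {
  cols <- paste0("n_", design_groups(terminome$design))
  keep <- do.call(pmax, terminome$events[cols]) >= min_count
  subset_terminome(terminome, keep)
}

subset_terminome <- function(tm, keep) {
  tm$events <- tm$events[keep, , drop = FALSE]
  rownames(tm$events) <- NULL
  tm$presence <- tm$presence[keep, , drop = FALSE]
  tm$intensity <- tm$intensity[keep, , drop = FALSE]
  tm
}

#' Label group exclusivity of terminus events
#'
#' An event is `exclusive_<G>` when present in at least `fraction` of
#' group G's samples and in zero samples of the other group; `shared` when
#' present in both groups; `neither` otherwise (e.g. exclusive presence
#' below the fraction).
#'
#' @param terminome a `"terminome"` object (or its events data frame with
#'   per-group count columns plus the design).
#' @param fraction required fraction of the group's samples (0.50 for
#'   discussion-level exclusivity, 0.75 for group-specific assignment).
#' @return character vector of labels, one per event.
#' @export
exclusivity_label <- function(terminome, fraction = 0.5) {
  design <- terminome$design
  gs <- design_groups(design)
  n1 <- terminome$events[[paste0("n_", gs[1])]]
  n2 <- terminome$events[[paste0("n_", gs[2])]]
  s1 <- length(design_samples(design, gs[1]))
  s2 <- length(design_samples(design, gs[2]))
  out <- rep("neither", length(n1))
  out[n1 > 0 & n2 > 0] <- "shared"
  out[n1 >= fraction * s1 & n2 == 0] <- paste0("exclusive_", gs[1])
  out[n2 >= fraction * s2 & n1 == 0] <- paste0("exclusive_", gs[2])
  out
}

#' Venn partition of two feature sets
#'
#' @param set_a,set_b character vectors of feature identifiers present in
#'   each group (any-sample presence).
#' @param labels group labels for printing.
#' @return object of class `"venn_partition"`: list with `common`,
#'   `only_a`, `only_b`, `labels` and a `sizes()`-style numeric summary in
#'   `$sizes`.
#' @export
partition_venn <- function(set_a, set_b, labels = c("A", "B")) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  out <- list(
    common = intersect(set_a, set_b),
    only_a = setdiff(set_a, set_b),
    only_b = setdiff(set_b, set_a),
    labels = labels
  )
  out$sizes <- c(common = length(out$common),
                 only_a = length(out$only_a),
                 only_b = length(out$only_b),
                 total = length(union(set_a, set_b)))
  structure(out, class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition (", x$labels[1], " vs ", x$labels[2], ")\n", sep = "")
  cat("  common:            ", x$sizes["common"], "\n")
  cat("  exclusive ", x$labels[1], ": ", x$sizes["only_a"], "\n", sep = "")
  cat("  exclusive ", x$labels[2], ": ", x$sizes["only_b"], "\n", sep = "")
  cat("  total:             ", x$sizes["total"], "\n")
  invisible(x)
}

#' Venn partition of a terminome by group presence
#'
#' @param terminome a `"terminome"` object.
#' @return a [partition_venn()] result over event keys `accession@p1`.
#' @export
terminome_venn <- function(terminome) {
  gs <- design_groups(terminome$design)
  key <- paste(terminome$events$accession, terminome$events$p1, sep = "@")
  a <- key[terminome$events[[paste0("n_", gs[1])]] > 0]
  b <- key[terminome$events[[paste0("n_", gs[2])]] > 0]
  partition_venn(a, b, labels = gs)
}

#' @export
print.terminome <- function(x, ...) {
  cat("terminome:", nrow(x$events), x$type, "terminus events,",
      nrow(x$design), "samples\n")
  print(table(category = x$events$category))
  cat("skipped rows:", paste(names(x$skipped), x$skipped, sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Filter master proteins
#'
#' Applies the master-protein thresholds: at least
#' `config$min_unique_peptides` unique peptides, identification FDR at or
#' below `config$protein_fdr_max`, and removal of listed technical
#' contaminants regardless of scores.
#'
#' @param protein_table data frame with columns `accession`,
#'   `unique_peptides`, `fdr`.
#' @param config a [pipeline_config()].
#' @param contaminants character vector of contaminant accessions.
#' @return the filtered protein table.
#' @export
filter_master_proteins <- function(protein_table, config = pipeline_config(),
                                   contaminants = character()) {
  keep <- protein_table$unique_peptides >= config$min_unique_peptides &
    protein_table$fdr <= config$protein_fdr_max &
    !(protein_table$accession %in% contaminants)
  out <- protein_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(protein_table, "samples")
  out
}

#' Summarize a peptide report at the protein level
#'
#' Produces the per-protein table used for master-protein filtering and
#' protein-level quantification: distinct peptide counts, unique-peptide
#' counts (peptides observed under a single accession), an identification
#' FDR (the best peptide FDR), and per-sample intensities as the sum of
#' unique peptide intensities.
#'
#' @param report located peptide report.
#' @param design a [sample_design()].
#' @return protein table with attribute `"samples"`.
#' @export
summarize_proteins <- function(report, design) {
  samples <- design$sample
  tab <- unique(report[c("peptide", "protein")])
  multi <- tab$peptide[duplicated(tab$peptide)]
  is_unique <- !(report$peptide %in% multi)
  prot <- factor(report$protein, levels = unique(report$protein))
  n_pep <- vapply(split(report$peptide, prot),
                  function(p) length(unique(p)), 1L)
  n_unique <- vapply(split(report$peptide[is_unique],
                           factor(report$protein[is_unique],
                                  levels = levels(prot))),
                     function(p) length(unique(p)), 1L)
  fdr <- vapply(split(report$fdr, prot), min, 1)
  u <- report[is_unique, , drop = FALSE]
  intens <- as.matrix(u[samples])
  storage.mode(intens) <- "double"
  pres <- rowsum((!is.na(intens)) * 1, u$protein, reorder = FALSE) > 0
  isum <- rowsum(ifelse(is.na(intens), 0, intens), u$protein, reorder = FALSE)
  isum[!pres] <- NA_real_
  # proteins with no unique peptides keep an all-NA intensity row
  full <- matrix(NA_real_, nlevels(prot), length(samples),
                 dimnames = list(levels(prot), samples))
  full[rownames(isum), ] <- isum
  out <- data.frame(accession = levels(prot), n_peptides = n_pep,
                    unique_peptides = n_unique, fdr = fdr,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(full, optional = TRUE))
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}
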