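#' Run the full degradome analysis
#'
#' Orchestrates the pipeline in a fixed order: protein-level summary and
#' master filtering, protein Venn partition, protein differential
#' abundance (class-specific quantile normalization, CART imputation,
#' moderated t with Storey q, DEP calling), N- and C-terminus calling with
#' presence and exclusivity filters and Venn partitions, terminus-level
#' differential analysis (p-value convention), neo-N cleavage-window
#' profiling per group, and -- when a cleavage database is supplied --
#' known-site annotation and per-group protease enrichment. Optional
#' over-representation analysis of the DEPs against a GMT gene-set list.
#'
#' @param proteome proteome data frame (with `signal_end` annotation).
#' @param report located peptide report (generic layout).
#' @param design a [sample_design()].
#' @param config a [pipeline_config()].
#' @param cleavage_db optional data frame from [read_cleavage_db()].
#' @param gmt optional named list from [read_gmt()].
#' @param contaminants character vector of contaminant accessions.
#' @param out_dir optional directory: stage outputs are written as TSV
#'   plus a JSON run report.
#' @return list of class `"degradome_run"`; see the `report` element for
#'   the per-stage counts.
#' @export
run_degradome_analysis <- function(proteome, report, design,
                                   config = pipeline_config(),
                                   cleavage_db = NULL, gmt = NULL,
                                   contaminants = character(),
                                   out_dir = NULL) {
  gs <- design_groups(design)

  # protein level, quantified from fully tryptic evidence only (the
  # semi-tryptic terminus rows are degradome evidence, not abundance)
  pidx <- match(report$protein, proteome$accession)
  tryptic_full <- classify_tryptic_vec(
    report$start, report$end, report$prev_aa,
    substring(proteome$sequence[pidx], report$end, report$end),
    proteome$length[pidx]
  ) == "full"
  trep <- report[tryptic_full, , drop = FALSE]
  attr(trep, "samples") <- attr(report, "samples")
  protein_table <- summarize_proteins(trep, design)
  master <- filter_master_proteins(protein_table, config, contaminants)
  pmat_raw <- intensity_matrix(master, design)
  pres <- !is.na(pmat_raw)
  prot_venn <- partition_venn(
    rownames(pres)[rowSums(pres[, design_samples(design, gs[1]), drop = FALSE]) > 0],
    rownames(pres)[rowSums(pres[, design_samples(design, gs[2]), drop = FALSE]) > 0],
    labels = gs
  )
  identified <- rownames(pres)[rowSums(pres) > 0]
  pmat <- pmat_raw[identified, , drop = FALSE]
  protein_dea <- run_dea(pmat, design, config)

  # terminome
  tm_n <- call_termini(report, proteome, design, config, type = "N")
  tm_c <- call_termini(report, proteome, design, config, type = "C")
  tm_n_f <- presence_filter(tm_n, config$min_presence)
  tm_c_f <- presence_filter(tm_c, config$min_presence)
  tm_n_f$events$exclusivity <- exclusivity_label(tm_n_f,
                                                 config$exclusivity_fraction)
  tm_c_f$events$exclusivity <- exclusivity_label(tm_c_f,
                                                 config$exclusivity_fraction)
  venn_n <- terminome_venn(tm_n_f)
  venn_c <- terminome_venn(tm_c_f)

  # terminus-level differential analysis (p-value convention)
  tcfg <- config
  tcfg$dep_mode <- "p"
  term_dea <- if (nrow(tm_n_f$events) >= 2) {
    run_dea(intensity_matrix(tm_n_f, design), design, tcfg)
  } else NULL

  # cleavage-window profiling of neo N-termini per group
  pfms <- list()
  for (i in 1:2) {
    neo <- tm_n_f$events$category == "neo" &
      tm_n_f$events[[paste0("n_", gs[i])]] > 0
    w <- tm_n_f$events$window[neo]
    pfms[[gs[i]]] <- if (sum(!is.na(w)) > 0) build_pfm(w) else NULL
  }
  pfm_cmp <- if (!is.null(pfms[[gs[1]]]) && !is.null(pfms[[gs[2]]])) {
    compare_group_preferences(pfms[[gs[1]]], pfms[[gs[2]]])
  } else NULL

  # protease attribution
  annotations <- enrichment <- NULL
  if (!is.null(cleavage_db) && nrow(tm_n_f$events) > 0) {
    annotations <- match_known_sites(tm_n_f, cleavage_db)
    enrichment <- list()
    for (i in 1:2) {
      fg <- enrichment_foreground(tm_n_f, term_dea, gs[i], gs, config)
      enrichment[[gs[i]]] <- if (nrow(fg) > 0) {
        protease_enrichment(fg, tm_n_f$events, cleavage_db)
      } else NULL
    }
  }

  ora_res <- if (!is.null(gmt)) {
    hits <- protein_dea$feature[protein_dea$status != "ns"]
    ora(hits, rownames(pmat), gmt)
  } else NULL

  run_report <- build_run_report(config, design, protein_table, master,
                                 prot_venn, protein_dea, tm_n_f, tm_c_f,
                                 venn_n, venn_c, term_dea)

  out <- structure(list(
    protein_table = protein_table, master = master, prot_venn = prot_venn,
    protein_dea = protein_dea, terminome_n = tm_n_f, terminome_c = tm_c_f,
    terminome_n_raw = tm_n, terminome_c_raw = tm_c,
    venn_n = venn_n, venn_c = venn_c, term_dea = term_dea,
    pfms = pfms, pfm_comparison = pfm_cmp,
    annotations = annotations, enrichment = enrichment, ora = ora_res,
    design = design, config = config, report = run_report
  ), class = "degradome_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# foreground for protease enrichment: termini exclusive to the group plus
# termini significantly changed in its direction (up for group 1, down for
# group 2); background is the full called terminome
enrichment_foreground <- function(tm, term_dea, group, gs, config) {
  ev <- tm$events
  excl <- ev$exclusivity == paste0("exclusive_", group)
  sig <- rep(FALSE, nrow(ev))
  if (!is.null(term_dea)) {
    key <- paste(ev$accession, ev$p1, sep = "@")
    want <- if (group == gs[1]) "up" else "down"
    sig_feats <- term_dea$feature[term_dea$status == want]
    sig <- key %in% sig_feats
  }
  ev[excl | sig, , drop = FALSE]
}

build_run_report <- function(config, design, protein_table, master,
                             prot_venn, protein_dea, tm_n, tm_c,
                             venn_n, venn_c, term_dea) {
  gs <- design_groups(design)
  list(
    version = as.character(utils::packageVersion("degradomics")),
    seed = config$seed,
    config = unclass(config),
    groups = as.list(table(design$group)),
    proteins = list(
      reported = nrow(protein_table),
      master = nrow(master),
      venn = as.list(prot_venn$sizes),
      dep_up = sum(protein_dea$status == "up"),
      dep_down = sum(protein_dea$status == "down"),
      dep_total = sum(protein_dea$status != "ns"),
      pca_variance = as.list(attr(protein_dea, "pca"))
    ),
    n_termini = terminome_counts(tm_n, venn_n, gs),
    c_termini = terminome_counts(tm_c, venn_c, gs),
    term_dep_up = if (is.null(term_dea)) 0L else sum(term_dea$status == "up"),
    term_dep_down = if (is.null(term_dea)) 0L else sum(term_dea$status == "down")
  )
}

terminome_counts <- function(tm, venn, gs) {
  ev <- tm$events
  list(
    events = nrow(ev),
    mature = sum(ev$category == "mature"),
    neo = sum(ev$category == "neo"),
    database = sum(ev$category == "database"),
    venn = as.list(venn$sizes),
    per_group = stats::setNames(lapply(gs, function(g) {
      sum(ev[[paste0("n_", g)]] > 0)
    }), gs)
  )
}

#' @export
print.degradome_run <- function(x, ...) {
  r <- x$report
  cat("degradome analysis run (seed", r$seed, ")\n")
  cat("proteins: ", r$proteins$reported, " reported, ", r$proteins$master,
      " master; venn ", r$proteins$venn$common, "/",
      r$proteins$venn$only_a, "/", r$proteins$venn$only_b,
      "; DEPs ", r$proteins$dep_total, " (", r$proteins$dep_up, " up, ",
      r$proteins$dep_down, " down)\n", sep = "")
  cat("N-termini: ", r$n_termini$events, " events (",
      r$n_termini$mature, " mature, ", r$n_termini$neo, " neo); venn ",
      r$n_termini$venn$common, "/", r$n_termini$venn$only_a, "/",
      r$n_termini$venn$only_b, "\n", sep = "")
  cat("C-termini: ", r$c_termini$events, " events; venn ",
      r$c_termini$venn$common, "/", r$c_termini$venn$only_a, "/",
      r$c_termini$venn$only_b, "\n", sep = "")
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          na = "")
  wt(run$master, "master_proteins.tsv")
  wt(run$protein_dea, "protein_dea.tsv")
  wt(run$terminome_n$events, "n_termini.tsv")
  wt(run$terminome_c$events, "c_termini.tsv")
  if (!is.null(run$term_dea)) wt(run$term_dea, "terminus_dea.tsv")
  for (g in names(run$pfms)) {
    pfm <- run$pfms[[g]]
    if (is.null(pfm)) next
    long <- data.frame(
      position = rep(colnames(pfm$freq), each = nrow(pfm$freq)),
      residue = rep(rownames(pfm$freq), ncol(pfm$freq)),
      count = as.vector(pfm$counts), frequency = as.vector(pfm$freq)
    )
    wt(long, paste0("pfm_", g, ".tsv"))
  }
  if (!is.null(run$annotations)) wt(run$annotations, "annotations.tsv")
  for (g in names(run$enrichment %||% list())) {
    if (!is.null(run$enrichment[[g]])) {
      wt(run$enrichment[[g]], paste0("protease_enrichment_", g, ".tsv"))
    }
  }
  if (!is.null(run$ora)) wt(run$ora, "ora.tsv")
  jsonlite::write_json(run$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a cohort and analyze it end to end
#'
#' @param sim_config a [simulation_config()].
#' @param config a [pipeline_config()]; its seed defaults to the
#'   simulation seed.
#' @param ... passed to [run_degradome_analysis()].
#' @return a `"degradome_run"` with the simulation attached as
#'   `$simulation`.
#' @export
run_all <- function(sim_config, config = NULL, ...) {
  sim <- simulate_degradome(sim_config)
  if (is.null(config)) config <- pipeline_config(seed = sim_config$seed)
  run <- run_degradome_analysis(sim$proteome, sim$report, sim$design,
                                config, ...)
  run$simulation <- sim
  run$recovery <- evaluate_recovery(run$terminome_n, sim$truth)
  run$report$recovery <- run$recovery
  run
}

#' Recovery of planted cleavage events
#'
#' Compares the called neo N-termini of a terminome against the
#' generator's truth sites: recall is the fraction of planted (accession,
#' P1) sites recovered, precision the fraction of called neo N-termini
#' that are planted sites.
#'
#' @param terminome N-terminome (after presence filtering).
#' @param truth truth table from [plant_cleavages()].
#' @return list with `recall`, `precision`, `n_truth`, `n_called`,
#'   `n_recovered`.
#' @export
evaluate_recovery <- function(terminome, truth) {
  ev <- terminome$events
  called <- unique(paste(ev$accession, ev$p1, sep = "@")[ev$category == "neo"])
  planted <- unique(paste(truth$accession, truth$p1_position, sep = "@"))
  hit <- called %in% planted
  list(
    recall = if (length(planted) > 0) sum(planted %in% called) / length(planted)
             else NA_real_,
    precision = if (length(called) > 0) mean(hit) else NA_real_,
    n_truth = length(planted), n_called = length(called),
    n_recovered = sum(hit)
  )
}
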