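#' Protease positional specificity model
#'
#' Describes a protease's residue preferences over the ten Schechter-Berger
#' subsites P5..P1 and P1'..P5'. Each position carries a probability
#' distribution over the 20 residues; positions without a stated preference
#' are uniform. The distribution actually sampled is
#' `softmax(log_odds / temperature)`, so `temperature -> 0` makes the
#' preference degenerate on the top residue.
#'
#' @param name protease name.
#' @param preferences named list, e.g. `list(P1p = c(G = 0.8))`: position
#'   labels among `P5..P1, P1p..P5p`; each entry a named probability
#'   vector for selected residues (the remaining mass is spread uniformly
#'   over the other residues).
#' @param temperature sampling temperature (> 0).
#' @return object of class `"specificity_model"` with the 20 x 10
#'   probability matrix and the implied log-odds against uniform.
#' @export
specificity_model <- function(name, preferences = list(), temperature = 1) {
  stopifnot(temperature > 0)
  pos <- subsite_labels()
  q <- matrix(1 / 20, nrow = 20, ncol = 10, dimnames = list(AA20, pos))
  for (p in names(preferences)) {
    if (!p %in% pos) stop("unknown subsite label: ", p)
    pref <- preferences[[p]]
    if (any(!names(pref) %in% AA20)) stop("unknown residue in preference")
    if (sum(pref) > 1) stop("preference probabilities exceed 1 at ", p)
    rest <- setdiff(AA20, names(pref))
    q[, p] <- (1 - sum(pref)) / length(rest)
    q[names(pref), p] <- pref
  }
  log_odds <- log(q * 20)
  # temperature-adjusted sampling distribution (softmax over log-odds,
  # stabilized so temperature -> 0 degenerates cleanly)
  lo <- log_odds / temperature
  lo <- sweep(lo, 2, apply(lo, 2, max))
  z <- exp(lo)
  qt <- sweep(z, 2, colSums(z), "/")
  structure(list(name = name, prob = qt, log_odds = log(qt * 20),
                 temperature = temperature),
            class = "specificity_model")
}

subsite_labels <- function(half_width = 5) {
  c(paste0("P", half_width:1), paste0("P", 1:half_width, "p"))
}

#' Simulation configuration for the synthetic degradome generator
#'
#' Defines the cohort the generator emulates: a two-group label-free
#' experiment (8 + 8 samples by default) over a synthetic proteome, with
#' trypsin digestion, endogenous cleavage events planted by proteases with
#' distinct positional specificities and group-dependent occurrence,
#' log-normal intensities with group effects, intensity-dependent
#' missingness, and sporadic decoy semi-tryptic identifications.
#'
#' @param n_proteins number of synthetic proteins.
#' @param length_range protein length range (uniform draw).
#' @param signal_fraction fraction of proteins carrying a signal peptide.
#' @param signal_end_range residue range for the signal-peptide end.
#' @param proteases list of protease entries, each a list with elements
#'   `model` (a [specificity_model()]), `site_rate` (per-site baseline
#'   acceptance rate) and `occurrence` (length-2 vector: per-sample
#'   occurrence probability of an accepted cleavage in group 1 and 2).
#' @param missed_cleavage_prob probability a tryptic site is missed in the
#'   realized digest.
#' @param peptide_length_range emitted peptide length range.
#' @param intensity_mu,intensity_mu_sd mean and SD of per-feature baseline
#'   log2 intensity.
#' @param intensity_sd residual SD of log2 intensities.
#' @param terminus_effect log2 group effect applied to affected termini.
#' @param terminus_effect_fraction fraction of planted termini affected.
#' @param protein_effect,protein_effect_fraction log2 effect (random sign)
#'   applied to all peptides of a fraction of proteins.
#' @param miss_intercept,miss_slope logistic missingness model
#'   `P(missing) = plogis(intercept + slope * log2_intensity)`; defaults
#'   give about 20% missing cells at baseline intensity.
#' @param mature_occurrence per-sample occurrence probability of the
#'   mature N-terminal peptide of signal-bearing proteins.
#' @param decoy_rate decoy semi-tryptic rows as a fraction of tryptic rows.
#' @param decoy_max_samples decoy identifications appear in 1..this many
#'   randomly chosen samples (sporadic noise).
#' @param seed mandatory integer master seed.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_proteins = 100,
                              length_range = c(200, 400),
                              signal_fraction = 0.5,
                              signal_end_range = c(15, 30),
                              proteases = default_proteases(),
                              missed_cleavage_prob = 0.1,
                              peptide_length_range = c(7, 50),
                              intensity_mu = 20,
                              intensity_mu_sd = 2,
                              intensity_sd = 1,
                              terminus_effect = 2,
                              terminus_effect_fraction = 0.1,
                              protein_effect = 2,
                              protein_effect_fraction = 0.05,
                              miss_intercept = 4.6137,
                              miss_slope = -0.3,
                              mature_occurrence = 0.9,
                              decoy_rate = 0.02,
                              decoy_max_samples = 2,
                              seed) {
  if (missing(seed)) stop("seed is mandatory in simulation_config()")
  cfg <- list(
    n_proteins = n_proteins, length_range = length_range,
    signal_fraction = signal_fraction, signal_end_range = signal_end_range,
    proteases = proteases, missed_cleavage_prob = missed_cleavage_prob,
    peptide_length_range = peptide_length_range,
    intensity_mu = intensity_mu, intensity_mu_sd = intensity_mu_sd,
    intensity_sd = intensity_sd,
    terminus_effect = terminus_effect,
    terminus_effect_fraction = terminus_effect_fraction,
    protein_effect = protein_effect,
    protein_effect_fraction = protein_effect_fraction,
    miss_intercept = miss_intercept, miss_slope = miss_slope,
    mature_occurrence = mature_occurrence,
    decoy_rate = decoy_rate, decoy_max_samples = decoy_max_samples,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_proteins >= 1,
    cfg$signal_fraction >= 0, cfg$signal_fraction <= 1,
    cfg$missed_cleavage_prob >= 0, cfg$missed_cleavage_prob <= 1,
    cfg$terminus_effect_fraction >= 0, cfg$terminus_effect_fraction <= 1,
    cfg$protein_effect_fraction >= 0, cfg$protein_effect_fraction <= 1,
    cfg$mature_occurrence >= 0, cfg$mature_occurrence <= 1,
    cfg$decoy_rate >= 0,
    vapply(cfg$proteases, function(p) {
      p$site_rate >= 0 && all(p$occurrence >= 0) && all(p$occurrence <= 1)
    }, TRUE)
  )
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @details `default_proteases()` plants three enzymes, each with a 0.8
#'   P1' preference: a shared protease preferring glycine (active in both
#'   groups), a case-exclusive protease preferring valine and a
#'   control-exclusive protease preferring serine -- a cohort where each
#'   group carries a proteolytic activity with its own P1' signature, so
#'   group logos differ and both groups have exclusive termini.
#' @export
default_proteases <- function() {
  list(
    list(model = specificity_model("GLY-P1p", list(P1p = c(G = 0.8))),
         site_rate = 0.01, occurrence = c(0.9, 0.9)),
    list(model = specificity_model("VAL-P1p", list(P1p = c(V = 0.8))),
         site_rate = 0.01, occurrence = c(0.9, 0.0)),
    list(model = specificity_model("SER-P1p", list(P1p = c(S = 0.8))),
         site_rate = 0.01, occurrence = c(0.0, 0.9))
  )
}

# stage-specific substream of the master seed (kept below 2^31)
substream <- function(seed, k) (seed %% 268435456L) * 8L + as.integer(k)

#' Generate a synthetic proteome
#'
#' Residues are drawn uniformly over the 20 canonical amino acids (so that
#' positional composition is flat and planted cleavage preferences are
#' recovered without compositional correction); a configured fraction of
#' proteins carries a signal peptide whose end falls in
#' `signal_end_range`.
#'
#' @param config a [simulation_config()].
#' @return proteome data frame (see [read_fasta()]) with `signal_end`
#'   filled for signal-bearing proteins.
#' @export
generate_proteome <- function(config) {
  if (config$length_range[2] < config$length_range[1]) {
    stop("degenerate length distribution: max < min")
  }
  withr::with_seed(substream(config$seed, 1), {
    n <- config$n_proteins
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, "")
    has_signal <- stats::rbinom(n, 1, config$signal_fraction) == 1
    se <- ifelse(has_signal,
                 sample(config$signal_end_range[1]:config$signal_end_range[2],
                        n, replace = TRUE),
                 NA_integer_)
    data.frame(
      accession = sprintf("SYNP%04d", seq_len(n)),
      sequence = seqs, length = lens, signal_end = as.integer(se),
      description = "synthetic protein", stringsAsFactors = FALSE
    )
  })
}

#' Plant endogenous cleavage events
#'
#' Every interior position whose P1 residue is not K/R (a tryptic boundary
#' would be indistinguishable), whose resulting N-terminal fragment has an
#' emittable length, and which does not coincide with a database or mature
#' protein start is a candidate site. Each protease scores the P5-P5'
#' window by its log-odds and accepts the site with probability
#' `min(1, site_rate * exp(score))` -- monotone in the score, and chosen so
#' that with a compositionally flat proteome the accepted sites reproduce
#' the planted positional preferences exactly in expectation. A site is
#' claimed by at most one protease (roster order).
#'
#' @param proteome proteome data frame.
#' @param config a [simulation_config()].
#' @return data frame of planted truth events: `site_id`, `accession`,
#'   `p1_position`, `protease`, `occ1`, `occ2` (per-group per-sample
#'   occurrence probabilities) and `effect` (log2 group-1 minus group-2
#'   shift applied to the affected termini).
#' @export
plant_cleavages <- function(proteome, config) {
  if (length(config$proteases) == 0) stop("at least one protease required")
  withr::with_seed(substream(config$seed, 2), {
    out <- list()
    for (i in seq_len(nrow(proteome))) {
      seqc <- proteome$sequence[i]
      len <- proteome$length[i]
      sites <- cleavage_sites(seqc)
      bounds <- c(sites, len)
      res <- strsplit(seqc, "", fixed = TRUE)[[1]]
      p1 <- seq_len(len - 1L)
      # fragment from p1+1 to the next canonical tryptic boundary
      frag_end <- bounds[findInterval(p1, bounds) + 1L]
      frag_len <- frag_end - p1
      ok <- !(res[p1] %in% c("K", "R")) &
        frag_len >= config$peptide_length_range[1] &
        frag_len <= config$peptide_length_range[2] &
        !(p1 %in% c(0L, 1L))
      se <- proteome$signal_end[i]
      if (!is.na(se)) ok <- ok & p1 != se
      cand <- p1[ok]
      if (length(cand) == 0) next
      claimed <- rep(FALSE, length(cand))
      for (pr in config$proteases) {
        open <- which(!claimed)
        if (length(open) == 0) break
        sc <- score_windows(res, cand[open], pr$model$log_odds)
        p_acc <- pmin(1, pr$site_rate * exp(sc))
        acc <- stats::runif(length(open)) < p_acc
        if (any(acc)) {
          idx <- open[acc]
          claimed[idx] <- TRUE
          out[[length(out) + 1L]] <- data.frame(
            accession = proteome$accession[i],
            p1_position = cand[idx],
            protease = pr$model$name,
            occ1 = pr$occurrence[1], occ2 = pr$occurrence[2],
            stringsAsFactors = FALSE
          )
        }
      }
    }
    truth <- if (length(out) > 0) do.call(rbind, out) else {
      data.frame(accession = character(), p1_position = integer(),
                 protease = character(), occ1 = numeric(), occ2 = numeric(),
                 stringsAsFactors = FALSE)
    }
    affected <- stats::rbinom(nrow(truth), 1, config$terminus_effect_fraction) == 1
    truth$effect <- ifelse(affected, config$terminus_effect, 0)
    truth$site_id <- if (nrow(truth) > 0) {
      sprintf("T%05d", seq_len(nrow(truth)))
    } else character(0)
    rownames(truth) <- NULL
    truth[c("site_id", "accession", "p1_position", "protease",
            "occ1", "occ2", "effect")]
  })
}

# sum of per-position log-odds over the P5-P5' window at each p1;
# positions outside the protein contribute 0 (uninformative pad)
score_windows <- function(res, p1, log_odds, half_width = 5) {
  n <- length(res)
  sc <- numeric(length(p1))
  offs <- c(-(half_width - 1):0, 1:half_width) # positions relative to p1
  for (j in seq_along(offs)) {
    pos <- p1 + offs[j]
    inside <- pos >= 1 & pos <= n
    r <- res[pos[inside]]
    sc[inside] <- sc[inside] + log_odds[cbind(match(r, AA20), j)]
  }
  sc
}

#' Simulate a peptide report for a two-group cohort
#'
#' Emits (a) the realized tryptic digest of every protein (each canonical
#' site independently missed with `missed_cleavage_prob`), (b) the mature
#' N-terminal peptide of signal-bearing proteins, (c) semi-tryptic
#' fragments on both sides of every planted cleavage (the N-terminal
#' fragment starting at P1'; the C-terminal fragment ending at P1), and
#' (d) sporadic decoy semi-tryptic rows at random non-K/R boundaries.
#' Log2 intensities are Normal(mu_feature + group effect, sd) with
#' mu_feature ~ Normal(`intensity_mu`, `intensity_mu_sd`); cells are then
#' removed by the logistic missingness model and per-group occurrence
#' draws. Reported intensities are on the raw (2^x) scale.
#'
#' @param proteome proteome data frame.
#' @param truth planted events from [plant_cleavages()].
#' @param design a [sample_design()].
#' @param config a [simulation_config()].
#' @return list with `report` (generic-dialect peptide report; attribute
#'   `"samples"`) and `sidecar` (per-row provenance: `row_id`,
#'   `provenance` in tryptic/mature/truth_N/truth_C/decoy, `site_id`,
#'   `protease`, `effect`).
#' @export
simulate_peptide_report <- function(proteome, truth, design, config) {
  stopifnot(inherits(design, "sample_design"))
  withr::with_seed(substream(config$seed, 3), {
    lr <- config$peptide_length_range
    rows <- list()
    add_row <- function(acc, start, end, prev, nxt, prov, site_id = NA,
                        protease = NA, occ = c(1, 1), effect = 0,
                        decoy_samples = NULL) {
      rows[[length(rows) + 1L]] <<- list(
        acc = acc, start = start, end = end, prev = prev, nxt = nxt,
        prov = prov, site_id = site_id, protease = protease,
        occ1 = occ[1], occ2 = occ[2], effect = effect,
        decoy_samples = decoy_samples
      )
    }

    # protein-level differential abundance: a fraction of proteins get a
    # +/- protein_effect shift on all their tryptic/mature peptides
    pa <- stats::rbinom(nrow(proteome), 1, config$protein_effect_fraction) == 1
    psign <- sample(c(-1, 1), nrow(proteome), replace = TRUE)
    prot_effect <- ifelse(pa, psign * config$protein_effect, 0)

    for (i in seq_len(nrow(proteome))) {
      seqc <- proteome$sequence[i]
      len <- proteome$length[i]
      acc <- proteome$accession[i]
      res_first <- function(p) substring(seqc, p, p)
      sites <- cleavage_sites(seqc)
      # realized digest: each site independently missed
      kept <- sites[stats::runif(length(sites)) >= config$missed_cleavage_prob]
      b <- c(0L, kept, len)
      starts <- b[-length(b)] + 1L
      ends <- b[-1]
      okl <- (ends - starts + 1L) >= lr[1] & (ends - starts + 1L) <= lr[2]
      for (j in which(okl)) {
        add_row(acc, starts[j], ends[j],
                ifelse(starts[j] == 1L, "-", res_first(starts[j] - 1L)),
                ifelse(ends[j] == len, "-", res_first(ends[j] + 1L)),
                "tryptic", effect = prot_effect[i])
      }
      # mature N-terminal peptide after the signal peptide
      se <- proteome$signal_end[i]
      if (!is.na(se) && !(res_first(se) %in% c("K", "R"))) {
        fb <- c(sites, len)
        fe <- fb[findInterval(se, fb) + 1L]
        if ((fe - se) >= lr[1] && (fe - se) <= lr[2]) {
          add_row(acc, se + 1L, fe, res_first(se),
                  ifelse(fe == len, "-", res_first(fe + 1L)),
                  "mature", occ = c(config$mature_occurrence,
                                    config$mature_occurrence),
                  effect = prot_effect[i])
        }
      }
    }

    # semi-tryptic fragments flanking each planted cleavage
    for (j in seq_len(nrow(truth))) {
      i <- match(truth$accession[j], proteome$accession)
      seqc <- proteome$sequence[i]
      len <- proteome$length[i]
      sites <- cleavage_sites(seqc)
      fb <- c(sites, len)
      p1 <- truth$p1_position[j]
      occ <- c(truth$occ1[j], truth$occ2[j])
      # N-terminal fragment of the cleaved protein: starts at P1'
      fe <- fb[findInterval(p1, fb) + 1L]
      add_row(truth$accession[j], p1 + 1L, fe,
              substring(seqc, p1, p1),
              ifelse(fe == len, "-", substring(seqc, fe + 1L, fe + 1L)),
              "truth_N", truth$site_id[j], truth$protease[j], occ,
              truth$effect[j])
      # C-terminal fragment of the upstream piece: ends at P1
      prevb <- c(0L, sites)
      fs <- max(prevb[prevb < p1]) + 1L
      if ((p1 - fs + 1L) >= lr[1] && (p1 - fs + 1L) <= lr[2]) {
        add_row(truth$accession[j], fs, p1,
                ifelse(fs == 1L, "-", substring(seqc, fs - 1L, fs - 1L)),
                substring(seqc, p1 + 1L, p1 + 1L),
                "truth_C", truth$site_id[j], truth$protease[j], occ,
                truth$effect[j])
      }
    }

    n_tryptic <- sum(vapply(rows, function(r) r$prov == "tryptic", TRUE))
    n_decoy <- round(config$decoy_rate * n_tryptic)
    n_samples <- nrow(design)
    if (n_decoy > 0) {
      wt <- proteome$length / sum(proteome$length)
      pick <- sample(seq_len(nrow(proteome)), n_decoy, replace = TRUE,
                     prob = wt)
      for (i in pick) {
        seqc <- proteome$sequence[i]
        len <- proteome$length[i]
        sites <- cleavage_sites(seqc)
        fb <- c(sites, len)
        res <- strsplit(seqc, "", fixed = TRUE)[[1]]
        p1c <- seq(2L, len - 1L)
        fe <- fb[findInterval(p1c, fb) + 1L]
        okd <- !(res[p1c] %in% c("K", "R")) &
          (fe - p1c) >= lr[1] & (fe - p1c) <= lr[2]
        if (!any(okd)) next
        p1 <- sample(rep(p1c[okd], 2), 1) # rep() guards length-1 sample()
        fe1 <- fb[findInterval(p1, fb) + 1L]
        add_row(proteome$accession[i], p1 + 1L, fe1, res[p1],
                ifelse(fe1 == len, "-", res[fe1 + 1L]),
                "decoy",
                decoy_samples = sample(n_samples,
                                       sample(config$decoy_max_samples, 1)))
      }
    }

    build_report_rows(rows, proteome, design, config)
  })
}

# turn the accumulated row list into the report + sidecar tables
build_report_rows <- function(rows, proteome, design, config) {
  n <- length(rows)
  acc <- vapply(rows, `[[`, "", "acc")
  start <- vapply(rows, function(r) as.integer(r$start), 1L)
  end <- vapply(rows, function(r) as.integer(r$end), 1L)
  prev <- vapply(rows, `[[`, "", "prev")
  nxt <- vapply(rows, `[[`, "", "nxt")
  prov <- vapply(rows, `[[`, "", "prov")
  site_id <- vapply(rows, function(r) as.character(r$site_id), "")
  protease <- vapply(rows, function(r) as.character(r$protease), "")
  occ1 <- vapply(rows, `[[`, 1, "occ1")
  occ2 <- vapply(rows, `[[`, 1, "occ2")
  effect <- vapply(rows, `[[`, 1, "effect")

  pep <- substring(proteome$sequence[match(acc, proteome$accession)], start, end)
  mu <- stats::rnorm(n, config$intensity_mu, config$intensity_mu_sd)
  grp1 <- design$group == levels(design$group)[1]
  n_s <- nrow(design)

  x <- matrix(stats::rnorm(n * n_s, sd = config$intensity_sd), n, n_s)
  x <- x + mu + outer(effect, as.numeric(grp1))
  p_miss <- stats::plogis(config$miss_intercept + config$miss_slope * x)
  missing <- matrix(stats::runif(n * n_s), n, n_s) < p_miss
  occ <- matrix(rep(ifelse(grp1, 1, 0), each = n), n, n_s)
  occ_p <- occ * occ1 + (1 - occ) * occ2
  present <- matrix(stats::runif(n * n_s), n, n_s) < occ_p
  for (k in seq_len(n)) {
    ds <- rows[[k]]$decoy_samples
    if (!is.null(ds)) {
      present[k, ] <- FALSE
      present[k, ds] <- TRUE
    }
  }
  intensity <- ifelse(present & !missing, 2^x, NA_real_)
  colnames(intensity) <- design$sample

  report <- data.frame(
    row_id = sprintf("R%06d", seq_len(n)),
    peptide = pep, protein = acc, start = start, end = end,
    prev_aa = prev, next_aa = nxt,
    fdr = stats::runif(n, 0, 0.009),
    stringsAsFactors = FALSE
  )
  report <- cbind(report, as.data.frame(intensity, optional = TRUE))
  attr(report, "samples") <- design$sample
  sidecar <- data.frame(
    row_id = report$row_id, provenance = prov,
    site_id = ifelse(site_id == "NA", NA, site_id),
    protease = ifelse(protease == "NA", NA, protease),
    effect = effect, stringsAsFactors = FALSE
  )
  list(report = report, sidecar = sidecar)
}

#' Simulate a complete degradome cohort
#'
#' Runs [generate_proteome()], [plant_cleavages()] and
#' [simulate_peptide_report()] under one master seed.
#'
#' @param config a [simulation_config()].
#' @param design a [sample_design()]; defaults to 8 CASE + 8 CONTROL.
#' @return list of class `"degradome_sim"` with elements `proteome`,
#'   `truth`, `report`, `sidecar`, `design`, `config`.
#' @export
simulate_degradome <- function(config, design = NULL) {
  if (is.null(design)) {
    design <- sample_design(sprintf("S%02d", 1:16),
                            rep(c("CASE", "CONTROL"), each = 8))
  }
  proteome <- generate_proteome(config)
  truth <- plant_cleavages(proteome, config)
  sim <- simulate_peptide_report(proteome, truth, design, config)
  structure(list(proteome = proteome, truth = truth, report = sim$report,
                 sidecar = sim$sidecar, design = design, config = config),
            class = "degradome_sim")
}

#' Write a simulated cohort to disk
#'
#' @param sim a `degradome_sim`.
#' @param dir output directory (created if needed). Writes
#'   `proteome.fasta`, `signal_peptides.tsv`, `peptides.tsv`, `design.tsv`,
#'   `truth_sites.tsv`, `truth_rows.tsv`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteome, file.path(dir, "proteome.fasta"))
  sig <- sim$proteome[!is.na(sim$proteome$signal_end),
                      c("accession", "signal_end")]
  utils::write.table(sig, file.path(dir, "signal_peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_peptide_report(sim$report, file.path(dir, "peptides.tsv"))
  utils::write.table(data.frame(sample = sim$design$sample,
                                group = as.character(sim$design$group)),
                     file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$sidecar, file.path(dir, "truth_rows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
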