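# shared fixtures and independent oracles

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

protein_df <- function(sequence, accession = "P1", signal_end = NA) {
  data.frame(accession = accession, sequence = sequence,
             length = nchar(sequence), signal_end = as.integer(signal_end),
             description = "", stringsAsFactors = FALSE)
}

# independent digestion oracle: enumerate every substring and keep those
# whose boundaries satisfy the cleavage rule with <= mc internal sites
brute_digest <- function(sequence, mc, proline_rule = TRUE) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n]
  if (proline_rule && length(sites) > 0) sites <- sites[res[sites + 1] != "P"]
  valid_start <- c(1L, sites + 1L)
  valid_end <- c(sites, n)
  out <- list()
  for (s in valid_start) {
    for (e in valid_end[valid_end >= s]) {
      internal <- sum(sites >= s & sites < e)
      if (internal <= mc) out[[length(out) + 1L]] <- c(s, e, internal)
    }
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2], n_missed = m[, 3])
}

# small generic peptide report builder; intensities is a matrix with one
# row per peptide row and one column per sample
make_report <- function(peptide, protein, start, end, prev_aa, next_aa,
                        intensities, samples, fdr = 0) {
  rep <- data.frame(peptide = peptide, protein = protein,
                    start = as.integer(start), end = as.integer(end),
                    prev_aa = prev_aa, next_aa = next_aa,
                    fdr = fdr, stringsAsFactors = FALSE)
  intensities <- matrix(intensities, nrow = nrow(rep),
                        dimnames = list(NULL, samples))
  rep <- cbind(rep, as.data.frame(intensities, optional = TRUE))
  attr(rep, "samples") <- samples
  rep
}

design_44 <- function() {
  sample_design(paste0("s", 1:8), rep(c("CASE", "CONTROL"), each = 4))
}

design_88 <- function() {
  sample_design(paste0("s", 1:16), rep(c("CASE", "CONTROL"), each = 8))
}

# direct evaluation of the step-down minimum that defines the q-value
brute_storey_q <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    min(vapply(which(p >= p[i]), function(j) {
      min(1, pi0 * m * p[j] / rank(p, ties.method = "max")[j])
    }, 1))
  }, 1)
}

# exact hypergeometric upper tail by summing point masses
brute_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
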