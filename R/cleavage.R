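#' Extract a cleavage window around a scissile bond
#'
#' Returns the residues at Schechter-Berger subsites P\{hw\}..P1 and
#' P1'..P\{hw\}' around the bond between residues `p1_position` and
#' `p1_position + 1`, padded with `'X'` where subsites fall outside the
#' protein.
#'
#' @param protein protein sequence (string) or one-row proteome entry.
#' @param p1_position residue index (1-based) N-terminal to the scissile
#'   bond; must satisfy `1 <= p1 <= length - 1` (interior bond; database
#'   termini are excluded upstream).
#' @param half_width subsites on each side (default 5: P5-P5').
#' @return named character vector of length `2 * half_width` (names
#'   `P5..P1, P1p..P5p` for the default width).
#' @export
extract_window <- function(protein, p1_position, half_width = 5) {
  seqc <- if (is.character(protein)) protein else protein$sequence
  n <- nchar(seqc)
  if (p1_position < 1 || p1_position > n - 1) {
    stop("p1_position must lie in [1, protein length - 1]")
  }
  pos <- (p1_position - half_width + 1):(p1_position + half_width)
  res <- ifelse(pos >= 1 & pos <= n, substring(seqc, pos, pos), "X")
  names(res) <- subsite_labels(half_width)
  res
}

#' Position frequency matrix over cleavage windows
#'
#' Counts residues per subsite across a set of cleavage windows and
#' normalizes to frequencies, excluding the `'X'` pad from each position's
#' denominator (so protein-edge windows do not distort the logo).
#'
#' @param windows character vector of window strings (as stored in a
#'   terminome's `window` column) or a list of vectors from
#'   [extract_window()].
#' @return object of class `"pfm"`: list with `counts` (20 x positions
#'   integer matrix), `freq` (per-position frequencies summing to 1),
#'   `n_windows`, `top` (top-ranked residue per position).
#' @export
build_pfm <- function(windows) {
  if (is.list(windows)) {
    windows <- vapply(windows, paste, "", collapse = "")
  }
  windows <- windows[!is.na(windows)]
  if (length(windows) == 0) stop("no cleavage windows supplied")
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1) stop("windows must share a common width")
  half_width <- wlen / 2
  pos <- subsite_labels(half_width)
  counts <- matrix(0L, nrow = 20, ncol = wlen, dimnames = list(AA20, pos))
  for (j in seq_len(wlen)) {
    r <- substring(windows, j, j)
    t <- table(factor(r[r != "X"], levels = AA20))
    counts[, j] <- as.integer(t)
  }
  denom <- colSums(counts)
  freq <- sweep(counts, 2, pmax(denom, 1L), "/")
  top <- rownames(freq)[apply(freq, 2, which.max)]
  names(top) <- pos
  structure(list(counts = counts, freq = freq,
                 n_windows = length(windows), top = top),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("position frequency matrix over", x$n_windows, "cleavage windows\n")
  cat("top residue per subsite:\n")
  print(x$top)
  invisible(x)
}

#' Annotate terminus events against a cleavage-site database
#'
#' Exact join on (accession, P1 position): every database protease record
#' at the event's scissile bond is attached; events without a match are
#' annotated `"novel"`. An off-by-one position is not a match.
#'
#' @param events data frame with `accession` and `p1` (e.g. a terminome's
#'   `events`), or a `"terminome"`.
#' @param cleavage_db data frame from [read_cleavage_db()].
#' @return the events with a `proteases` column (`;`-collapsed names or
#'   `"novel"`).
#' @export
match_known_sites <- function(events, cleavage_db) {
  if (inherits(events, "terminome")) events <- events$events
  key <- paste(events$accession, events$p1, sep = "@")
  dbkey <- paste(cleavage_db$accession, cleavage_db$p1_position, sep = "@")
  events$proteases <- vapply(key, function(k) {
    hit <- cleavage_db$protease[dbkey == k]
    if (length(hit) == 0) "novel" else paste(unique(hit), collapse = ";")
  }, "", USE.NAMES = FALSE)
  events
}

#' Protease enrichment among foreground termini
#'
#' For each protease in the database, builds the 2x2 table of
#' annotated/not-annotated versus foreground/background termini and tests
#' enrichment in the foreground with a one-sided Fisher exact test,
#' followed by Benjamini-Hochberg correction across proteases. Termini are
#' deduplicated by (accession, P1); foreground termini absent from the
#' background are added to the universe. Proteases annotating no terminus
#' in either set are omitted.
#'
#' @param foreground,background event data frames (or terminomes) with
#'   `accession`, `p1`.
#' @param cleavage_db data frame from [read_cleavage_db()].
#' @return data frame of class with columns `protease`, `k` (annotated in
#'   foreground), `n` (foreground size), `K` (annotated in universe), `N`
#'   (universe size), `p`, `q_bh`, sorted by p.
#' @export
protease_enrichment <- function(foreground, background, cleavage_db) {
  if (inherits(foreground, "terminome")) foreground <- foreground$events
  if (inherits(background, "terminome")) background <- background$events
  fg <- unique(paste(foreground$accession, foreground$p1, sep = "@"))
  if (length(fg) == 0) stop("empty foreground")
  bg <- unique(paste(background$accession, background$p1, sep = "@"))
  uni <- union(fg, bg)
  dbkey <- paste(cleavage_db$accession, cleavage_db$p1_position, sep = "@")
  rows <- lapply(unique(cleavage_db$protease), function(pr) {
    ann <- unique(dbkey[cleavage_db$protease == pr])
    k <- sum(fg %in% ann)
    K <- sum(uni %in% ann)
    if (K == 0) return(NULL)
    n <- length(fg); N <- length(uni)
    m <- matrix(c(k, n - k, K - k, (N - K) - (n - k)), nrow = 2)
    p <- stats::fisher.test(m, alternative = "greater")$p.value
    data.frame(protease = pr, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(protease = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q_bh = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare positional residue preferences between two groups
#'
#' Per-subsite, per-residue log2 ratio of the two groups' frequencies with
#' a pseudo-frequency of `1 / (2 * min(n_windows))`, so rarely observed
#' residues do not explode the ratio. Swapping the groups negates every
#' entry.
#'
#' @param pfm_a,pfm_b `"pfm"` objects over identical subsite sets.
#' @return list of class `"pfm_comparison"`: `log_ratio` (20 x positions),
#'   `epsilon`, and `top` (residue with the largest absolute log-ratio per
#'   position).
#' @export
compare_group_preferences <- function(pfm_a, pfm_b) {
  stopifnot(identical(colnames(pfm_a$freq), colnames(pfm_b$freq)))
  eps <- 1 / (2 * min(pfm_a$n_windows, pfm_b$n_windows))
  lr <- log2((pfm_a$freq + eps) / (pfm_b$freq + eps))
  top <- rownames(lr)[apply(abs(lr), 2, which.max)]
  names(top) <- colnames(lr)
  structure(list(log_ratio = lr, epsilon = eps, top = top),
            class = "pfm_comparison")
}

#' @export
print.pfm_comparison <- function(x, ...) {
  cat("group preference comparison (log2 ratio, epsilon =",
      signif(x$epsilon, 3), ")\n")
  cat("most differential residue per subsite:\n")
  print(x$top)
  invisible(x)
}
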