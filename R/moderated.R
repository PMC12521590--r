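#' Empirical-Bayes moderated t-test
#'
#' Two-group moderated t-statistics in the empirical-Bayes style: the
#' per-feature pooled variance s_g^2 (df = n1 + n2 - 2) is shrunk towards
#' a prior variance s0^2 with prior degrees of freedom d0, both estimated
#' by moment-matching the scaled-F distribution of the observed variances
#' on the log scale (digamma/trigamma inversion). The moderated statistic
#' is
#' \deqn{t_g = \frac{\bar x_{1g} - \bar x_{2g}}
#'   {\tilde s_g \sqrt{1/n_1 + 1/n_2}}, \quad
#'   \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' with two-sided p-values on d0 + dg degrees of freedom. Forcing
#' `d0 = 0` recovers the ordinary pooled two-sample t-test.
#'
#' The log2 fold change is group 1 minus group 2 in the design's level
#' order (case minus control when the case group is listed first).
#'
#' @param mat complete log2 features x samples matrix.
#' @param design a [sample_design()]; both groups need >= 2 samples.
#' @param d0 optional prior df override (`NULL` = estimate; `0` = ordinary
#'   t; `Inf` = full shrinkage to s0^2).
#' @param s0_sq optional prior variance override (used with `d0`).
#' @return data frame of class `"moderated_fit"` with columns `feature`,
#'   `log2fc`, `t_mod`, `p_mod`, `df_total`, `s2`; attribute `"moderation"`
#'   carries the hyperparameters (`d0`, `s0_sq`, `dg`).
#' @export
moderated_t <- function(mat, design, d0 = NULL, s0_sq = NULL) {
  stopifnot(all(design$sample %in% colnames(mat)))
  if (anyNA(mat)) stop("moderated_t requires a complete matrix; impute first")
  gs <- design_groups(design)
  x1 <- mat[, design_samples(design, gs[1]), drop = FALSE]
  x2 <- mat[, design_samples(design, gs[2]), drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  dg <- n1 + n2 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / dg
  if (all(s2 == 0)) {
    stop("all features have zero variance; hyperparameters not estimable")
  }
  if (is.null(d0)) {
    hp <- fit_f_dist(s2[s2 > 0], dg)
    d0 <- hp$d0
    s0_sq <- hp$s0_sq
  } else if (is.null(s0_sq)) {
    s0_sq <- if (is.finite(d0) && d0 > 0) stats::median(s2) else mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  fc <- m1 - m2
  t_mod <- ifelse(se > 0, fc / se, 0)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[se == 0 & fc == 0] <- 1
  out <- data.frame(feature = rownames(mat) %||% as.character(seq_along(fc)),
                    log2fc = fc, t_mod = t_mod, p_mod = p,
                    df_total = df_total, s2 = s2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "moderation") <- list(d0 = d0, s0_sq = s0_sq, dg = dg)
  class(out) <- c("moderated_fit", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# moment-match a scaled F distribution to the sample variances on the log
# scale: E[log s2] and Var[log s2] identify (d0, s0^2) through digamma /
# trigamma relations
fit_f_dist <- function(s2, dg) {
  s2 <- pmax(s2, 1e-5 * stats::median(s2)) # guard near-zero variances
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(dg / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

# Newton inversion of the trigamma function
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Storey q-values
#'
#' Computes q-values with the single-lambda estimate of the null
#' proportion, pi0 = min(1, #\{p > lambda\} / (m (1 - lambda))), and the
#' step-down minimum q(p_(i)) = min_{j >= i} pi0 m p_(j) / j. With
#' pi0 = 1 this reduces to Benjamini-Hochberg adjusted p-values; q-values
#' never exceed the corresponding BH values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda tuning parameter for the pi0 estimate.
#' @return q-values in the input order; attribute `"pi0"`.
#' @export
storey_q <- function(p, lambda = 0.5) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Call differential features
#'
#' Applies the fold-change and significance thresholds to a moderated-t
#' result: `up` requires log2FC >= +`lfc_threshold` and p_mod <= `alpha_p`
#' (and q_mod <= `alpha_q` when `dep_mode = "q"`, the protein-level
#' convention); `down` is symmetric; everything else is `ns`. All
#' inequalities are inclusive. Terminus-level lists conventionally use
#' `dep_mode = "p"`.
#'
#' @param results a `"moderated_fit"` (or data frame with `log2fc`,
#'   `p_mod`); a `q_mod` column is added with [storey_q()] if absent.
#' @param config a [pipeline_config()].
#' @return `results` with columns `q_mod` and `status` (up/down/ns).
#' @export
call_deps <- function(results, config = pipeline_config()) {
  if (!"q_mod" %in% names(results)) {
    results$q_mod <- as.numeric(storey_q(results$p_mod))
  }
  sig <- results$p_mod <= config$alpha_p
  if (config$dep_mode == "q") sig <- sig & results$q_mod <= config$alpha_q
  status <- rep("ns", nrow(results))
  status[sig & results$log2fc >= config$lfc_threshold] <- "up"
  status[sig & results$log2fc <= -config$lfc_threshold] <- "down"
  results$status <- status
  results
}

#' PCA variance summary
#'
#' Centers each feature, performs a singular value decomposition over
#' samples and returns the fraction of variance explained by each
#' principal component (over min(n_samples - 1, n_features) components,
#' summing to 1).
#'
#' @param mat complete features x samples matrix.
#' @return named numeric vector of variance fractions (`PC1`, `PC2`, ...).
#' @export
pca_variance <- function(mat) {
  if (anyNA(mat)) stop("pca_variance requires a complete matrix")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) stop("constant matrix: no variance to decompose")
  k <- min(ncol(mat) - 1, nrow(mat))
  v <- v[seq_len(k)]
  out <- v / sum(v)
  names(out) <- paste0("PC", seq_along(out))
  out
}

#' Over-representation analysis
#'
#' Hypergeometric upper-tail test of a hit set against each gene set,
#' intersected with the universe, with Benjamini-Hochberg correction
#' across terms. The gene ratio k/n is reported alongside the counts.
#'
#' @param hits character vector of hit identifiers (subset of `universe`).
#' @param universe character vector of all tested identifiers.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @return data frame with `term`, `k`, `K`, `n`, `N`, `gene_ratio`, `p`,
#'   `q_bh`, sorted by p.
#' @export
ora <- function(hits, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(intersect(hits, universe))
  n <- length(hits)
  N <- length(universe)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], universe)
    K <- length(members)
    k <- length(intersect(hits, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               gene_ratio = if (n > 0) k / n else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the differential-abundance stage
#'
#' Convenience wrapper: class-specific quantile normalization, CART
#' imputation, moderated t, Storey q and threshold calling, in that order,
#' on a log2 matrix.
#'
#' @param mat log2 features x samples matrix (missing cells allowed).
#' @param design a [sample_design()].
#' @param config a [pipeline_config()]; `dep_mode` selects the
#'   protein-level (p and q) or terminus-level (p only) convention.
#' @return a `"moderated_fit"` with `q_mod` and `status`; attribute
#'   `"pca"` holds the post-imputation PCA variance fractions.
#' @export
run_dea <- function(mat, design, config = pipeline_config()) {
  norm <- quantile_normalize_by_class(mat, design)
  imp <- impute_cart(norm, seed = config$seed)
  fit <- moderated_t(imp, design)
  fit$q_mod <- as.numeric(storey_q(fit$p_mod))
  fit <- call_deps(fit, config)
  attr(fit, "pca") <- pca_variance(imp)
  fit
}
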