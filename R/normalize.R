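#' Build a log2 intensity matrix
#'
#' Extracts the per-sample intensity columns of a protein table or
#' terminome into a features x samples matrix and log2-transforms once
#' (tracked through the `"log2"` attribute, so a transformed matrix is
#' never transformed again).
#'
#' @param x protein table (with attribute `"samples"`) or `"terminome"`.
#' @param design a [sample_design()].
#' @return numeric matrix (features x samples) with attribute
#'   `log2 = TRUE`; rownames are feature identifiers.
#' @export
intensity_matrix <- function(x, design) {
  if (inherits(x, "terminome")) {
    m <- x$intensity
    rownames(m) <- paste(x$events$accession, x$events$p1, sep = "@")
  } else {
    m <- as.matrix(x[attr(x, "samples")])
    storage.mode(m) <- "double"
    rownames(m) <- x$accession
  }
  m <- m[, design$sample, drop = FALSE]
  if (isTRUE(attr(m, "log2"))) return(m)
  m <- log2(m)
  attr(m, "log2") <- TRUE
  m
}

#' Class-specific quantile normalization
#'
#' Quantile-normalizes each design class independently: within a class,
#' every sample's observed values are replaced by the mean of the class's
#' order statistics at the same quantile, ties receiving the average of
#' their tied targets; missing cells remain missing and are excluded from
#' rank computation. After normalization the sorted observed vectors of
#' all samples in a class coincide (up to interpolation when samples have
#' unequal numbers of observed values). A class with a single sample is
#' left unchanged with a warning.
#'
#' @param mat numeric features x samples matrix (any scale; typically
#'   log2).
#' @param design a [sample_design()].
#' @return normalized matrix with the same dimensions and NA pattern.
#' @export
quantile_normalize_by_class <- function(mat, design) {
  stopifnot(all(design$sample %in% colnames(mat)))
  out <- mat
  for (g in design_groups(design)) {
    s <- design_samples(design, g)
    if (length(s) < 2) {
      warning("class ", g, " has a single sample; left unchanged")
      next
    }
    out[, s] <- limma::normalizeQuantiles(mat[, s, drop = FALSE], ties = TRUE)
  }
  out
}

#' Regression-tree (CART) imputation with predictive matching
#'
#' Single imputation of missing cells, column by column in order of
#' increasing missingness. For each sample-column with missing values a
#' regression tree predicting that column from all other columns is fitted
#' on the rows where it is observed; each missing cell is dropped down the
#' tree and its value drawn uniformly from the observed donor values in
#' its terminal node. Deterministic for a given seed. Features missing in
#' every sample are dropped with a warning; a column with no observed
#' values at all is an error.
#'
#' @param mat numeric features x samples matrix with missing cells.
#' @param seed integer seed for the donor draws.
#' @param minbucket,cp tree controls (defaults follow common
#'   predictive-matching practice: minbucket 5, cp 1e-4).
#' @return completed matrix (possibly with fewer rows if all-missing
#'   features were dropped).
#' @export
impute_cart <- function(mat, seed = 1L, minbucket = 5, cp = 1e-4) {
  if (!anyNA(mat)) return(mat)
  all_na_row <- rowSums(!is.na(mat)) == 0
  if (any(all_na_row)) {
    warning("dropping ", sum(all_na_row), " feature(s) with no observed value")
    mat <- mat[!all_na_row, , drop = FALSE]
  }
  if (any(colSums(!is.na(mat)) == 0)) {
    stop("column(s) with no observed values cannot be imputed")
  }
  withr::with_seed(seed, {
    out <- mat
    ord <- order(colSums(is.na(mat)))
    for (j in ord) {
      miss <- is.na(out[, j])
      if (!any(miss)) next
      if (ncol(out) == 1) { # no predictors: donors are all observed values
        out[miss, j] <- sample(out[!miss, j], sum(miss), replace = TRUE)
        next
      }
      df <- as.data.frame(out[, -j, drop = FALSE])
      names(df) <- paste0("X", seq_len(ncol(df)))
      df$.y <- out[, j]
      fit <- rpart::rpart(.y ~ ., data = df[!miss, , drop = FALSE],
                          method = "anova",
                          control = rpart::rpart.control(
                            minsplit = 2 * minbucket, minbucket = minbucket,
                            cp = cp, xval = 0))
      node_pred <- predict(fit, df)
      # donors share the terminal node (identified by its fitted mean);
      # rows that cannot be routed to a leaf (all predictors missing)
      # fall back to the root node, i.e. all observed values
      obs_y <- out[!miss, j]
      obs_pred <- node_pred[!miss]
      for (i in which(miss)) {
        donors <- obs_y[obs_pred == node_pred[i]]
        if (length(donors) == 0) donors <- obs_y
        out[i, j] <- if (length(donors) == 1) donors else sample(donors, 1)
      }
    }
    for (a in setdiff(names(attributes(mat)), names(attributes(out)))) {
      attr(out, a) <- attr(mat, a)
    }
    out
  })
}
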