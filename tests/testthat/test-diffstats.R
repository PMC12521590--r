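test_that("class-specific quantile normalization matches hand computation", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6), c = c(10, 20, 30),
             d = c(40, 50, 60))
  des <- sample_design(c("a", "b", "c", "d"), c("G1", "G1", "G2", "G2"))
  out <- quantile_normalize_by_class(m, des)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "c"]), c(25, 35, 45))

  # identical samples are a fixed point
  m2 <- cbind(a = c(1, 5, 9), b = c(1, 5, 9), c = c(2, 2, 2), d = c(3, 3, 3))
  out2 <- quantile_normalize_by_class(m2, des)
  expect_equal(out2[, c("a", "b")], m2[, c("a", "b")])
})

test_that("normalization equalizes sorted vectors and preserves ranks", {
  set.seed(41)
  m <- matrix(rnorm(50 * 8, 20, 3), 50, 8)
  m[sample(length(m), 60)] <- NA
  colnames(m) <- paste0("s", 1:8)
  des <- design_44()
  out <- quantile_normalize_by_class(m, des)
  expect_identical(is.na(out), is.na(m))  # NA pattern untouched
  for (g in c("CASE", "CONTROL")) {
    s <- des$sample[des$group == g]
    full <- s[colSums(!is.na(m[, s])) == nrow(m)]
    if (length(full) >= 2) {
      sorted <- apply(out[, full], 2, sort)
      expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
    }
    for (j in s) {
      obs <- !is.na(m[, j])
      expect_equal(order(out[obs, j]), order(m[obs, j]))
    }
  }
})

test_that("single-sample classes are left unchanged with a warning", {
  m <- cbind(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  des <- sample_design(c("a", "b", "c"), c("G1", "G1", "G2"))
  expect_warning(out <- quantile_normalize_by_class(m, des), "single sample")
  expect_equal(out[, "c"], m[, "c"])
})

test_that("CART imputation is a seeded, donor-based completion", {
  set.seed(42)
  m <- matrix(rnorm(40 * 8, 20, 2), 40, 8, dimnames = list(NULL, paste0("s", 1:8)))
  expect_identical(impute_cart(m, seed = 7), m)  # complete matrix no-op

  m2 <- m
  m2[sample(length(m2), 40)] <- NA
  i1 <- impute_cart(m2, seed = 7)
  i2 <- impute_cart(m2, seed = 7)
  expect_identical(i1, i2)                       # deterministic given seed
  expect_false(anyNA(i1))
  expect_equal(i1[!is.na(m2)], m2[!is.na(m2)])   # observed cells untouched
  # imputed values are observed donor values from the same column
  for (j in seq_len(ncol(m2))) {
    miss <- is.na(m2[, j])
    expect_true(all(i1[miss, j] %in% m2[!miss, j]))
  }

  # single-split trace: Y == X, singleton leaves donate a neighbour
  x <- as.numeric(1:20)
  y <- x; y[7] <- NA
  imp <- impute_cart(cbind(X = x, Y = y), seed = 3, minbucket = 1, cp = 0)
  expect_true(imp[7, "Y"] %in% c(6, 8))

  mm <- m2
  mm[3, ] <- NA
  expect_warning(out <- impute_cart(mm, seed = 1), "no observed value")
  expect_equal(nrow(out), nrow(mm) - 1)
  bad <- m2
  bad[, 2] <- NA
  expect_error(impute_cart(bad, seed = 1), "cannot be imputed")
})

test_that("moderated t with d0 = 0 is the ordinary pooled t-test", {
  des <- sample_design(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  m <- matrix(c(1, 2, 3, 2, 3, 4), 1, 6,
              dimnames = list("f1", des$sample))
  fit <- moderated_t(m, des, d0 = 0)
  expect_equal(fit$log2fc, -1)
  expect_equal(fit$t_mod, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(fit$t_mod, -1.2247, tolerance = 1e-4)
  expect_equal(fit$df_total, 4)
  expect_equal(fit$p_mod, 2 * pt(-abs(-1 / sqrt(2 / 3)), 4), tolerance = 1e-12)

  # 100 random features against the direct pooled-t formula
  set.seed(43)
  des2 <- design_88()
  mm <- matrix(rnorm(100 * 16), 100, 16, dimnames = list(NULL, des2$sample))
  fit2 <- moderated_t(mm, des2, d0 = 0)
  g1 <- mm[, 1:8]; g2 <- mm[, 9:16]
  sp <- sqrt((rowSums((g1 - rowMeans(g1))^2) +
                rowSums((g2 - rowMeans(g2))^2)) / 14)
  t_ref <- (rowMeans(g1) - rowMeans(g2)) / (sp * sqrt(1 / 8 + 1 / 8))
  expect_lt(max(abs(fit2$t_mod - t_ref)), 1e-10)
})

test_that("moderation limits behave as shrinkage predicts", {
  des <- design_88()
  set.seed(44)
  m <- matrix(rnorm(50 * 16), 50, 16, dimnames = list(NULL, des$sample))
  m[1, ] <- rep(c(1, 2), 8)  # a feature with equal group means
  m[1, 1:8] <- m[1, 9:16]
  fit <- moderated_t(m, des)
  expect_equal(fit$log2fc[1], 0)
  expect_equal(fit$t_mod[1], 0)
  expect_equal(fit$p_mod[1], 1)

  fit_inf <- moderated_t(m, des, d0 = 1e8, s0_sq = 0.7)
  md <- attr(fit_inf, "moderation")
  s2_post <- (1e8 * 0.7 + 14 * fit_inf$s2) / (1e8 + 14)
  expect_true(all(abs(s2_post - 0.7) < 1e-5))

  cm <- matrix(5, 4, 16, dimnames = list(NULL, des$sample))
  expect_error(moderated_t(cm, des), "zero variance")
})

test_that("moderated t agrees with an independent empirical-Bayes implementation", {
  des <- design_88()
  set.seed(45)
  v <- 0.5 / rchisq(200, 5) * 5
  m <- matrix(rnorm(200 * 16, sd = sqrt(rep(v, 16))), 200, 16,
              dimnames = list(paste0("f", 1:200), des$sample))
  fit <- moderated_t(m, des)
  md <- attr(fit, "moderation")
  dm <- cbind(1, as.numeric(des$group == "CASE"))
  lf <- limma::eBayes(limma::lmFit(m, dm))
  expect_equal(md$d0, unname(lf$df.prior), tolerance = 1e-10)
  expect_equal(md$s0_sq, unname(lf$s2.prior), tolerance = 1e-10)
  expect_lt(max(abs(fit$t_mod - lf$t[, 2])), 1e-10)
  expect_lt(max(abs(fit$p_mod - lf$p.value[, 2])), 1e-10)
})

test_that("Storey q-values match BH at pi0 = 1 and the defining minimum", {
  p <- c(0.01, 0.02, 0.03, 0.9, 0.95, 0.99)
  # pi0 = min(1, 3 / (6 * 0.5)) = 1
  q <- storey_q(p, lambda = 0.5)
  expect_equal(attr(q, "pi0"), 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(as.numeric(q), brute_storey_q(p), tolerance = 1e-12)

  expect_equal(as.numeric(storey_q(rep(1, 5))), rep(1, 5))
  expect_error(storey_q(numeric(0)), "empty")

  set.seed(46)
  for (i in 1:10) {
    pp <- runif(50)^sample(1:3, 1)
    q <- as.numeric(storey_q(pp))
    expect_equal(q, as.numeric(brute_storey_q(pp)), tolerance = 1e-12)
    expect_true(all(q <= p.adjust(pp, "BH") + 1e-12))
    expect_true(all(diff(q[order(pp)]) > -1e-12))  # monotone in p
  }
})

test_that("DEP calling applies inclusive thresholds in both modes", {
  res <- data.frame(
    feature = c("a", "b", "c", "d"),
    log2fc = c(1.0, -0.3, 0.57, -0.8),
    p_mod = c(0.01, 0.001, 0.05, 0.01),
    q_mod = c(0.01, 0.001, 0.05, 0.5)
  )
  out <- call_deps(res, pipeline_config())
  expect_equal(out$status, c("up", "ns", "up", "ns"))
  outp <- call_deps(res, pipeline_config(dep_mode = "p"))
  expect_equal(outp$status, c("up", "ns", "up", "down"))
})

test_that("PCA variance fractions behave on canonical geometries", {
  # all samples on a line through the centroid
  base <- c(1, 2, 3)
  m <- cbind(s1 = base, s2 = 2 * base, s3 = 3 * base, s4 = 4 * base)
  v <- pca_variance(m)
  expect_equal(unname(v[1]), 1)

  # two orthogonal directions with equal variance
  m2 <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  colnames(m2) <- paste0("s", 1:4)
  v2 <- pca_variance(m2)
  expect_equal(unname(v2), c(0.5, 0.5))
  expect_equal(sum(v2), 1)

  expect_error(pca_variance(matrix(7, 3, 4)), "constant")
})

test_that("ORA p-values are exact hypergeometric tails", {
  universe <- letters[1:10]
  hits <- letters[1:5]
  sets <- list(T1 = letters[1:5], T2 = letters[6:10], T3 = letters[4:8])
  res <- ora(hits, universe, sets)
  expect_equal(res$p[res$term == "T1"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p[res$term == "T2"], 1)
  expect_equal(res$gene_ratio[res$term == "T1"], 1)

  # brute-force: enumerate all C(10,5) draws and count overlap >= k
  draws <- combn(10, 5)
  for (term in names(sets)) {
    K <- length(sets[[term]])
    k <- length(intersect(hits, sets[[term]]))
    tail_bf <- mean(apply(draws, 2, function(d) {
      length(intersect(universe[d], sets[[term]])) >= k
    }))
    expect_equal(res$p[res$term == term], tail_bf, tolerance = 1e-12)
  }
  expect_error(ora(hits, character(0), sets), "empty universe")
})

test_that("null simulations hold the nominal type-I error (spot check)", {
  # a single-replicate spot check; the full 100-rep sweep runs in the
  # acceptance suite
  des <- design_88()
  set.seed(47)
  m <- matrix(rnorm(2000 * 16), 2000, 16, dimnames = list(NULL, des$sample))
  fit <- moderated_t(m, des)
  frac <- mean(fit$p_mod <= 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("planted group effects are detected with the expected power", {
  des <- design_88()
  set.seed(48)
  m <- matrix(rnorm(2000 * 16), 2000, 16, dimnames = list(paste0("f", 1:2000),
                                                          des$sample))
  truth <- rep(FALSE, 2000)
  truth[sample(2000, 100)] <- TRUE
  m[truth, 1:8] <- m[truth, 1:8] + 2
  fit <- call_deps(moderated_t(m, des), pipeline_config())
  called <- fit$status == "up"
  sens <- sum(called & truth) / sum(truth)
  expect_gte(sens, 0.8)
  fdp <- if (any(called)) sum(called & !truth) / sum(called) else 0
  expect_lte(fdp, 0.10)
  expect_lt(abs(mean(fit$log2fc[called & truth]) - 2), 0.2)
})

test_that("run_dea chains the stages and reports PCA variance", {
  des <- design_44()
  set.seed(49)
  m <- matrix(rnorm(60 * 8, 20, 2), 60, 8,
              dimnames = list(paste0("f", 1:60), des$sample))
  m[sample(length(m), 30)] <- NA
  fit <- run_dea(m, des, pipeline_config(seed = 5))
  expect_true(all(c("q_mod", "status") %in% names(fit)))
  pca <- attr(fit, "pca")
  expect_equal(sum(pca), 1)
  expect_false(anyNA(fit$p_mod))
})
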