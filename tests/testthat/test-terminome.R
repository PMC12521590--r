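# a 200-residue protein with a controlled neighborhood around residue 186,
# emulating an osteopontin-like internal cleavage at 185 | 186
ostp_like <- function() {
  seqc <- random_protein(200, seed = 21)
  # peptide at 186..193 with prev T (non-tryptic N-boundary) and K at 193
  substr(seqc, 185, 194) <- "TAIPVKGQDS"
  # make sure 186..193 ends with a tryptic C-boundary
  substr(seqc, 193, 193) <- "K"
  protein_df(seqc, "P10451")
}

test_that("N-terminus calling applies the flanking-residue rule", {
  prot <- ostp_like()
  pep <- substring(prot$sequence, 186, 193)
  ev <- call_n_terminus(list(peptide = pep, start = 186, end = 193,
                             prev_aa = "T", fdr = 0.001), prot)
  expect_equal(ev$category, "neo")
  expect_equal(ev$p1, 185L)
  expect_equal(ev$p1_prime, "A")

  expect_null(call_n_terminus(list(peptide = pep, start = 186, end = 193,
                                   prev_aa = "K", fdr = 0.001), prot))
  expect_null(call_n_terminus(list(peptide = pep, start = 186, end = 193,
                                   prev_aa = "T", fdr = 0.05), prot))

  sigp <- protein_df(random_protein(100, seed = 22), "A2", signal_end = 20)
  substr(sigp$sequence, 20, 20) <- "A"
  substr(sigp$sequence, 30, 30) <- "R"
  pep2 <- substring(sigp$sequence, 21, 30)
  ev2 <- call_n_terminus(list(peptide = pep2, start = 21, end = 30,
                              prev_aa = "A", fdr = 0.001), sigp)
  expect_equal(ev2$category, "mature")
  expect_equal(ev2$p1, 20L)
  expect_false(ev2$db_terminus)
})

test_that("C-terminus calling distinguishes neo from database termini", {
  seqc <- random_protein(150, seed = 23)
  substr(seqc, 120, 120) <- "G"
  substr(seqc, 100, 100) <- "R"
  substr(seqc, 150, 150) <- "G"
  prot <- protein_df(seqc, "A1")
  row <- list(peptide = substring(seqc, 101, 120), start = 101, end = 120,
              prev_aa = "R", fdr = 0.001)
  ev <- call_c_terminus(row, prot)
  expect_equal(ev$category, "neo")
  expect_equal(ev$p1, 120L)

  substr(seqc, 120, 120) <- "R"
  prot$sequence <- seqc
  expect_null(call_c_terminus(row, prot))

  rowdb <- list(peptide = substring(seqc, 101, 150), start = 101, end = 150,
                prev_aa = "R", fdr = 0.001)
  evdb <- call_c_terminus(rowdb, prot)
  expect_equal(evdb$category, "database")
  expect_true(evdb$db_terminus)
})

test_that("events sharing (accession, P1) merge with OR-ed presence and summed intensities", {
  seqc <- random_protein(60, seed = 24)
  substr(seqc, 10, 10) <- "T"  # prev residue of peptide starting at 11
  substr(seqc, 20, 20) <- "K"
  substr(seqc, 25, 25) <- "K"
  prot <- protein_df(seqc, "A1")
  des <- design_44()
  pepA <- substring(seqc, 11, 20)
  pepB <- substring(seqc, 11, 25)
  rep <- make_report(c(pepA, pepB), "A1", c(11, 11), c(20, 25), "T",
                     c(substring(seqc, 21, 21), substring(seqc, 26, 26)),
                     rbind(c(10, NA, NA, NA, 5, NA, NA, NA),
                           c(NA, 20, NA, NA, NA, NA, NA, NA)),
                     des$sample)
  tm <- call_termini(rep, prot, des, type = "N")
  expect_equal(nrow(tm$events), 1)
  expect_equal(tm$events$p1, 10L)
  expect_equal(unname(tm$intensity[1, 1:2]), c(10, 20))
  expect_equal(unname(tm$presence[1, 1:4]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tm$events$n_CASE, 2L)   # s1, s2 present
  expect_equal(tm$events$n_CONTROL, 1L) # s5

  # idempotence: doubling the report doubles intensities, keeps presence
  rep2 <- rbind(rep, rep)
  attr(rep2, "samples") <- des$sample
  tm2 <- call_termini(rep2, prot, des, type = "N")
  expect_identical(tm2$presence, tm$presence)
  expect_equal(tm2$intensity, tm$intensity * 2)
  expect_identical(tm2$events, tm$events)
})

test_that("ambiguous and high-FDR rows are skipped with counters", {
  des <- design_44()
  two <- rbind(protein_df("MAKRGGGGTLLLK", "A1"),
               protein_df("WWWGGGGTLLLKWW", "A2"))
  pep <- "GGGTLLLK"
  rep <- make_report(c(pep, pep), c("A1", "A2"), c(6, 5), c(13, 12),
                     c("G", "G"), c("-", "W"),
                     matrix(1, 2, 8), des$sample)
  tm <- call_termini(rep, two, des, type = "N")
  expect_equal(nrow(tm$events), 0)
  expect_equal(unname(tm$skipped["non_unique"]), 2L)

  rep2 <- make_report("GGGTLLLK", "A1", 6, 13, "G", "-", matrix(1, 1, 8),
                      des$sample, fdr = 0.5)
  tm2 <- call_termini(rep2, two, des, type = "N")
  expect_equal(unname(tm2$skipped["fdr"]), 1L)
  expect_equal(nrow(tm2$events), 0)
})

test_that("rows lacking coordinates are mapped before calling", {
  seqc <- "MAKRGGGGTLLLKWWW"
  prot <- protein_df(seqc, "A1")
  des <- design_44()
  rep <- make_report("GGGTLLLK", "A1", NA, NA, NA, NA, matrix(1, 1, 8),
                     des$sample)
  tm <- call_termini(rep, prot, des, type = "N")
  expect_equal(nrow(tm$events), 1)
  expect_equal(tm$events$p1, 5L)  # peptide occupies 6..13, prev G
})

test_that("presence filter keeps events quantified in >= k samples of a group", {
  des <- design_88()
  tm <- structure(list(
    events = data.frame(accession = c("A", "B", "C"), terminus = "N",
                        category = "neo", db_terminus = FALSE, p1 = 1:3,
                        n_CASE = c(2L, 3L, 0L), n_CONTROL = c(2L, 0L, 3L)),
    presence = matrix(FALSE, 3, 16), intensity = matrix(NA_real_, 3, 16),
    design = des, type = "N", skipped = c(fdr = 0L)
  ), class = "terminome")
  expect_equal(presence_filter(tm, 3)$events$accession, c("B", "C"))
  expect_equal(presence_filter(tm, 0)$events$accession, c("A", "B", "C"))
  expect_equal(nrow(presence_filter(tm, 9)$events), 0)
})

test_that("exclusivity labels follow the fraction-and-zero rule", {
  des <- design_88()
  mk <- function(n1, n2) {
    structure(list(events = data.frame(accession = "A", p1 = 1,
                                       n_CASE = n1, n_CONTROL = n2),
                   design = des), class = "terminome")
  }
  expect_equal(exclusivity_label(mk(6L, 0L), 0.75), "exclusive_CASE")
  expect_equal(exclusivity_label(mk(4L, 0L), 0.75), "neither")
  expect_equal(exclusivity_label(mk(4L, 0L), 0.50), "exclusive_CASE")
  expect_equal(exclusivity_label(mk(1L, 1L), 0.75), "shared")
  expect_equal(exclusivity_label(mk(0L, 6L), 0.50), "exclusive_CONTROL")
})

test_that("venn partition is a disjoint cover of the union", {
  v <- partition_venn(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(unname(v$sizes[c("common", "only_a", "only_b")]), c(2, 1, 1))
  expect_equal(length(intersect(v$common, v$only_a)), 0)

  v2 <- partition_venn(c("x", "y"), character(0))
  expect_equal(unname(v2$sizes["only_a"]), 2)
  expect_equal(unname(v2$sizes["common"]), 0)

  set.seed(31)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    v3 <- partition_venn(a, b)
    expect_equal(unname(sum(v3$sizes[c("common", "only_a", "only_b")])),
                 length(union(a, b)))
  }
})

test_that("master-protein filtering enforces all thresholds", {
  pt <- data.frame(
    accession = c("A", "B", "C", "D"),
    unique_peptides = c(0L, 2L, 5L, 3L),
    fdr = c(0.01, 0.03, 0.2, 0.01),
    stringsAsFactors = FALSE
  )
  out <- filter_master_proteins(pt, pipeline_config(), contaminants = "D")
  expect_equal(out$accession, "B")  # A: no unique peptides; C: FDR; D: contaminant
})

test_that("protein summaries count unique peptides and sum their intensities", {
  des <- design_44()
  rep <- make_report(
    c("AAAGTK", "AAAGTK", "CCWPTK", "DDDYNK"),
    c("P1", "P2", "P1", "P1"),
    1, 6, "-", "-",
    rbind(c(1, 1, 1, 1, 1, 1, 1, 1),
          c(1, 1, 1, 1, 1, 1, 1, 1),
          c(2, NA, 2, 2, 2, 2, 2, 2),
          c(3, 3, 3, 3, 3, 3, 3, 3)),
    des$sample
  )
  pt <- summarize_proteins(rep, des)
  p1 <- pt[pt$accession == "P1", ]
  expect_equal(p1$n_peptides, 3L)
  expect_equal(p1$unique_peptides, 2L)    # shared AAAGTK excluded
  expect_equal(p1$s1, 5)                  # 2 + 3
  expect_equal(p1$s2, 3)                  # NA treated as absent, 3 remains
  expect_equal(pt[pt$accession == "P2", ]$unique_peptides, 0L)
})
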