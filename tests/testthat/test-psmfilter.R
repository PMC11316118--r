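# small helper: build a PSM data.frame in the shape read_psm_table returns
psm_df <- function(peptide, score, proteins, label,
                   spectrum_id = sprintf("s%03d", seq_along(score))) {
  df <- data.frame(spectrum_id = spectrum_id, peptide = peptide,
                   charge = 2L, score = score, proteins = proteins,
                   label = label, stringsAsFactors = FALSE)
  df$protein_ids <- strsplit(df$proteins, ";", fixed = TRUE)
  df$is_decoy <- df$label == -1L
  df
}

test_that("target-decoy q-values follow the +1 estimator with running minimum", {
  # no decoys: FDR-hat = 1/k, running minimum propagates the smallest up
  expect_equal(qvalues_target_decoy(c(10, 9, 8), c(FALSE, FALSE, FALSE)),
               rep(1 / 3, 3))
  # all decoys above all targets saturate at 1
  q <- qvalues_target_decoy(c(10, 9, 5, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(q[3:4], c(1, 1))
  # hand-computed interleaved list: T10 D9 T8 T7 D6 T5
  # fdr at ranks: 1/1, 2/1, 2/2, 2/3, 3/3, 3/4 -> capped
  # q from bottom: 3/4, 3/4, 2/3, 2/3, 1, 3/4 -> running min:
  q <- qvalues_target_decoy(c(10, 9, 8, 7, 6, 5),
                            c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(q, c(2 / 3, 2 / 3, 2 / 3, 2 / 3, 3 / 4, 3 / 4))
  # ties share the q-value of the whole tie block
  q <- qvalues_target_decoy(c(9, 9, 9, 3), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(q[1], q[2])
  expect_equal(q[1], q[3])
  expect_error(qvalues_target_decoy(numeric(0), logical(0)), "empty")
  expect_error(qvalues_target_decoy(c(1, 2), c(TRUE, TRUE)), "no target")
})

test_that("q-values are monotone in score and bounded on random inputs", {
  set.seed(21)
  for (i in 1:20) {
    n <- 200
    score <- c(rnorm(n, 8, 2), rnorm(n, 3, 2))
    dec <- rep(c(FALSE, TRUE), each = n)
    q <- qvalues_target_decoy(score, dec)
    expect_true(all(q >= 0 & q <= 1))
    ord <- order(-score)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("picked-protein competition keeps the higher-scoring pair member", {
  db <- build_custom_db(c(A = "MAAAK", B = "MCCCK", C = "MDDDK",
                          D = "MGGGK", E = "MEEEK", F = "MFFFK"))
  psms <- psm_df(
    peptide = c("MAAAK", "AAAK", "MCCCK", "CCCK", "MDDDK", "MEEEK",
                "EEEK", "MFFFK", "FFFK", "DDDK"),
    score = c(12, 7, 5, 9, 8, 10, 2, 3, 1, 6),
    proteins = c("A", "rev_A", "B", "rev_B", "C", "E", "rev_E", "F",
                 "rev_F", "rev_D"),
    label = c(1, -1, 1, -1, 1, 1, -1, 1, -1, -1))
  res <- picked_protein_qvalues(psms, db)
  # pair (A 12, rev_A 7): target kept; pair (B 5, rev_B 9): decoy kept
  expect_true("A" %in% res$entry_id && !"rev_A" %in% res$entry_id)
  expect_true("rev_B" %in% res$entry_id && !"B" %in% res$entry_id)
  # unpaired decoy rev_D enters and counts against the FDR
  expect_true("rev_D" %in% res$entry_id)
  # hand-computed q-values on the picked list
  # ranked: A12 E10 rev_B9 C8 rev_D6 F3
  # fdr: 1/1, 1/2, 2/2, 2/3, 3/3, 3/4; running min from bottom:
  expected <- c(A = 0.5, E = 0.5, rev_B = 2 / 3, C = 2 / 3,
                rev_D = 0.75, F = 0.75)
  expect_equal(setNames(res$q_value, res$entry_id), expected)
  # single target protein with no decoy hit: q = (1+0)/1 = 1
  solo <- psm_df("MAAAK", 10, "A", 1)
  expect_equal(picked_protein_qvalues(solo, db)$q_value, 1)
})

test_that("picked-protein competition controls the FDP on simulated pairs", {
  set.seed(31)
  fdp <- replicate(10, {
    n <- 300
    prots <- setNames(
      vapply(seq_len(n), function(i) random_protein_str(30), ""),
      sprintf("P%03d", seq_len(n)))
    db <- build_custom_db(prots)
    true_idx <- seq_len(n / 2)
    tgt_scores <- c(rnorm(n / 2, 12, 1.5), rnorm(n / 2, 4, 1.5))
    dec_scores <- rnorm(n, 4, 1.5)
    psms <- psm_df(
      peptide = c(substr(prots, 1, 8), substr(prots, 10, 18)),
      score = c(tgt_scores, dec_scores),
      proteins = c(names(prots), paste0("rev_", names(prots))),
      label = rep(c(1, -1), each = n))
    res <- picked_protein_qvalues(psms, db)
    acc <- res$entry_id[!res$is_decoy & res$q_value <= 0.05]
    if (!length(acc)) 0 else
      mean(!acc %in% sprintf("P%03d", true_idx))
  })
  expect_lt(mean(fdp), 0.05 + 0.03)
})

test_that("peptide-level q-values use the best PSM per peptide", {
  psms <- psm_df(c("AAA", "AAA", "CCC", "DDD"), c(5, 9, 7, 6),
                 c("A", "A", "rev_A", "A"), c(1, 1, -1, 1))
  res <- peptide_qvalues(psms)
  expect_identical(nrow(res), 3L)
  expect_equal(res$best_score[res$unit_id == "AAA"], 9)
  expect_true(res$is_decoy[res$unit_id == "CCC"])
})

test_that("grouped FDR partitions are independent and merge back to global", {
  db <- build_custom_db(setNames(paste0("MAA", LETTERS[1:4], "K"),
                                 paste0("m", 1:4)),
                        setNames(paste0("MCC", LETTERS[1:4], "K"),
                                 paste0("c", 1:4)))
  # identical score lists in both groups -> identical q-values
  psms <- psm_df(
    peptide = c(paste0("MAA", LETTERS[1:4], "K"),
                paste0("MCC", LETTERS[1:4], "K")),
    score = rep(c(10, 8, 6, 4), 2),
    proteins = c("m1", "m2", "rev_m3", "m4", "c1", "c2", "rev_c3", "c4"),
    label = rep(c(1, 1, -1, 1), 2))
  res <- grouped_fdr(psms, db, level = "protein")
  expect_setequal(names(res), c("microprotein", "canonical"))
  expect_equal(sort(res$microprotein$q_value), sort(res$canonical$q_value))
  # concatenating partitions and recomputing globally equals the
  # global pipeline output
  glob <- picked_protein_qvalues(psms, db)
  merged <- rbind(res$microprotein, res$canonical)
  q_glob <- qvalues_target_decoy(merged$best_score, merged$is_decoy)
  expect_equal(sort(q_glob),
               sort(qvalues_target_decoy(glob$best_score, glob$is_decoy)))
})

test_that("annotated-peptide removal keeps multi-predicted matches only", {
  db <- build_custom_db(c(p1 = "MAAAKGGG", p2 = "MAAAKCCC"),
                        c(a1 = "WWWDDDD"))
  psms <- psm_df(c("MAAAK", "WDDD", "ZZZZ"), c(9, 8, 7),
                 c("p1;p2", "a1", "p1"), c(1, 1, 1))
  # ZZZZ maps to p1 in the table but does not occur in any sequence
  kept <- filter_unannotated(psms, db)
  expect_identical(kept$peptide, "MAAAK")
  # peptide present in predicted AND annotated is dropped
  db2 <- build_custom_db(c(p1 = "MAAAK"), c(a1 = "XMAAAKX"))
  psms2 <- psm_df("MAAAK", 9, "p1;a1", 1)
  expect_identical(nrow(filter_unannotated(psms2, db2)), 0L)
  # idempotence
  expect_identical(filter_unannotated(kept, db), kept)
  expect_identical(nrow(filter_unannotated(psms[0, ], db)), 0L)
})

test_that("perfect-match exclusion removes substrings of annotated proteins", {
  micro <- data.frame(entry_id = c("p1", "p2", "p3"),
                      protein = c("MAAAK", "AAAK", "MAAVK"),
                      category = "predicted", stringsAsFactors = FALSE)
  anno <- c("WWMAAAKWW")
  out <- exclude_perfect_matches(micro, anno)
  # p1 exact, p2 proper substring -> both removed; p3 one mismatch -> kept
  expect_identical(out$entry_id, "p3")
})

test_that("re-scoring database contains only first-pass hits plus reference", {
  hits <- data.frame(entry_id = paste0("p", 1:10),
                     protein = vapply(1:10, function(i) {
                       set.seed(i); random_protein_str(25)
                     }, ""),
                     category = "predicted", stringsAsFactors = FALSE)
  ref <- setNames(vapply(1:100, function(i) {
    set.seed(100 + i); random_protein_str(30)
  }, ""), paste0("a", 1:100))
  cont <- setNames(vapply(1:5, function(i) {
    set.seed(200 + i); random_protein_str(20)
  }, ""), paste0("c", 1:5))
  db <- build_rescoring_db(hits, ref, cont)
  expect_identical(nrow(db), 230L)
  expect_setequal(db$entry_id[db$category == "predicted"], hits$entry_id)
  expect_error(build_rescoring_db(
    data.frame(entry_id = "a", protein = "MK", category = "annotated"),
    ref), "predicted")
})

test_that("HLA filter bounds are inclusive at 100 nM, 0.02 and 7-12 aa", {
  tab <- data.frame(
    sequence = c("AAAAAAAAA", "CCCCCCCCCCCC", "DDDDDDD", "EEEEEEEEEEEEE",
                 "FFFFFFFFF", "GGGGGG"),
    affinity = c(99, 100, 100, 50, 101, 100),
    percentile = c(0.01, 0.02, 0.02, 0.01, 0.02, 0.02),
    stringsAsFactors = FALSE)
  out <- hla_filter(tab)
  expect_identical(out$sequence,
                   c("AAAAAAAAA", "CCCCCCCCCCCC", "DDDDDDD"))
  expect_error(hla_filter(tab[, 1:2]), "missing columns")
})

test_that("nonspecific peptide space equals the brute-force double loop", {
  expect_identical(nonspecific_peptide_space(random_protein_str(7)),
                   character(0))
  p8 <- "ACDEFGHI"
  sp <- nonspecific_peptide_space(p8)
  expect_lte(length(sp), 1L)
  set.seed(17)
  for (i in 1:30) {
    prot <- random_protein_str(sample(10:40, 1))
    got <- sort(nonspecific_peptide_space(prot))
    brute <- character(0)
    for (s in seq_len(nchar(prot)))
      for (e in s:min(nchar(prot), s + 24L)) {
        if (e - s + 1L < 8L) next
        pep <- substr(prot, s, e)
        m <- monoisotopic_mass(pep)
        if (m >= 500 && m <= 1500) brute <- c(brute, pep)
      }
    expect_identical(got, sort(unique(brute)))
  }
})
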