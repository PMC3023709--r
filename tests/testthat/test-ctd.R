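# Hybrid-property featurization: translation, C/T/D, AAC, the full
# 132-feature descriptor and the dataset filtering rules.

alphas <- ctd_alphabets()
hyd <- alphas$hydrophobicity

test_that("the 50-residue reference sequence reproduces every printed quantity", {
  rec <- protein_record("wx", WORKED_SEQ)
  tr <- translate_sequence(rec, hyd)
  expect_equal(tr, WORKED_TRANSLATION)

  chars <- strsplit(tr, "")[[1]]
  expect_equal(sum(chars == "H"), 10)
  expect_equal(sum(chars == "N"), 16)
  expect_equal(sum(chars == "P"), 24)

  C <- composition_features(tr, hyd)
  expect_equal(unname(C), c(48, 32, 20))  # P, N, H

  Tv <- transition_features(tr, hyd)
  # 31 transitions: 16 N<->P, 7 P<->H, 8 N<->H
  expect_equal(unname(Tv), 100 * c(16, 7, 8) / 31, tolerance = 1e-12)

  D <- distribution_features(tr, hyd)
  expect_equal(unname(D[paste0("H.", c(1, 25, 50, 75, 100))]),
               c(2, 20, 36, 74, 92))
  expect_equal(unname(D[paste0("N.", c(1, 25, 50, 75, 100))]),
               c(4, 28, 54, 78, 98))
  expect_equal(unname(D[paste0("P.", c(1, 25, 50, 75, 100))]),
               c(6, 24, 44, 64, 100))
})

test_that("translation follows the group tables and drops noncanonical residues", {
  expect_equal(translate_sequence(protein_record("x", "AAAA"), hyd), "NNNN")
  expect_equal(translate_sequence(protein_record("x", "RC"), hyd), "PH")
  # X is dropped from the output and from position numbering
  rec <- protein_record("x", "MXDK")
  expect_equal(translate_sequence(rec, hyd), "HPP")
  d <- distribution_features(translate_sequence(rec, hyd), hyd)
  expect_equal(unname(d["H.1"]), 100 * 1 / 3)
})

test_that("sequence-intrinsic alphabets partition the 20 canonical residues", {
  for (a in alphas) {
    if (a$source != "sequence") next
    expect_setequal(names(a$mapping), protfun:::CANONICAL_AA)
    expect_true(all(a$mapping %in% a$groups))
    expect_length(a$groups, 3L)
  }
  expect_length(alphas$solvent_accessibility$groups, 2L)
})

test_that("composition, transition and distribution handle boundary strings", {
  expect_equal(unname(composition_features("HHHH", hyd)), c(0, 0, 100))
  expect_equal(unname(composition_features("HNP", hyd)),
               rep(100 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(transition_features("HHHH", hyd)), c(0, 0, 0))
  expect_equal(unname(transition_features("HNH", hyd)), c(0, 0, 100))
  expect_equal(unname(transition_features("H", hyd)), c(0, 0, 0))
  expect_equal(unname(distribution_features("HHHH", hyd)[11:15]),
               c(25, 25, 50, 75, 100))
  expect_equal(unname(distribution_features("HHHH", hyd)[1:10]), rep(0, 10))
  expect_error(composition_features("", hyd), "empty")
})

test_that("amino-acid composition excludes noncanonical residues from both sides", {
  expect_equal(unname(aac_features(protein_record("x", "AAAA"))["A"]), 100)
  v <- aac_features(protein_record("x", "ACDE"))
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(25, 4))
  expect_equal(sum(v), 100)
  expect_equal(unname(aac_features(protein_record("x", "AXA"))["A"]), 100)
  expect_error(aac_features(protein_record("x", "XX")), "no canonical")
})

test_that("the full descriptor has 132 features in the fixed block layout", {
  rec <- random_annotated_record("r1", 80)
  v <- featurize(rec)
  expect_length(v, 132)
  prefix <- sub("\\..*$", "", names(v))
  expect_equal(as.integer(table(prefix)[c("hydrophobicity",
                                          "secondary_structure",
                                          "solvent_accessibility",
                                          "vdw_volume", "polarity",
                                          "polarizability", "aac")]),
               c(21L, 21L, 7L, 21L, 21L, 21L, 20L))
  expect_equal(unique(prefix),
               c("hydrophobicity", "secondary_structure",
                 "solvent_accessibility", "vdw_volume", "polarity",
                 "polarizability", "aac"))
  expect_true(all(v >= 0 & v <= 100))
  expect_identical(v, featurize(rec))
})

test_that("C/T blocks sum to 100 and D tuples are monotone on random sequences", {
  withr::with_seed(11, {
    for (i in 1:10) {
      rec <- random_annotated_record(paste0("r", i), sample(2:200, 1))
      for (a in alphas) {
        gs <- translate_sequence(rec, a)
        expect_equal(sum(composition_features(gs, a)), 100, tolerance = 1e-9)
        Tv <- transition_features(gs, a)
        expect_true(abs(sum(Tv) - 100) < 1e-9 || all(Tv == 0))
        D <- distribution_features(gs, a)
        for (g in a$groups) {
          tup <- D[paste0(g, ".", c(1, 25, 50, 75, 100))]
          expect_true(all(diff(tup) >= -1e-12))
          expect_true(all(tup <= 100 + 1e-12))
        }
      }
    }
  })
})

test_that("the descriptor matches a brute-force single-pass oracle on random sequences", {
  withr::with_seed(7, {
    for (i in 1:8) {
      rec <- random_annotated_record(paste0("o", i), sample(5:200, 1))
      v <- featurize(rec)
      for (a in alphas) {
        gs <- translate_sequence(rec, a)
        ora <- oracle_ctd(gs, a$groups)
        keepC <- if (length(a$groups) == 2L) 1L else seq_along(a$groups)
        keepD <- if (length(a$groups) == 2L) 1:5 else seq_along(ora$D)
        got <- v[startsWith(names(v), paste0(a$name, "."))]
        expect_equal(unname(got),
                     unname(c(ora$C[keepC], ora$T, ora$D[keepD])),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("permuting a sequence preserves C and AAC but generally changes T and D", {
  withr::with_seed(21, {
    rec <- random_annotated_record("p1", 120)
    shuffled_seq <- paste(sample(strsplit(rec$sequence, "")[[1]]),
                          collapse = "")
    rec2 <- protein_record("p2", shuffled_seq)
    expect_equal(unname(aac_features(rec)), unname(aac_features(rec2)))
    g1 <- translate_sequence(rec, hyd)
    g2 <- translate_sequence(rec2, hyd)
    expect_equal(composition_features(g1, hyd), composition_features(g2, hyd))
    expect_false(isTRUE(all.equal(distribution_features(g1, hyd),
                                  distribution_features(g2, hyd))))
  })
})

test_that("annotation-backed properties require annotations unless the fallback is enabled", {
  rec <- protein_record("x", "MSDKAAA")
  expect_error(translate_sequence(rec, alphas$secondary_structure),
               "fallback disabled")
  expect_message(
    lab <- fallback_residue_annotation(rec, "secondary_structure"),
    "heuristic")
  expect_equal(nchar(lab), nchar(rec$sequence))
  expect_true(all(strsplit(lab, "")[[1]] %in% c("H", "E", "C")))
  expect_identical(lab, fallback_residue_annotation(rec, "secondary_structure",
                                                    quiet = TRUE))
  # poly-isoleucine: strongly hydrophobic window => buried
  acc <- fallback_residue_annotation(protein_record("i", strrep("I", 9)),
                                     "solvent_accessibility", quiet = TRUE)
  expect_equal(acc, strrep("B", 9))
  # annotation labels outside the alphabet are rejected
  bad <- protein_record("y", "MSD",
                        residue_annotations = list(secondary_structure = "HQC"))
  expect_error(translate_sequence(bad, alphas$secondary_structure),
               "outside")
})

test_that("length-1 sequences featurize with a degenerate distribution", {
  rec <- random_annotated_record("one", 1)
  v <- featurize(rec)
  expect_length(v, 132)
  occupied <- v[grepl("^hydrophobicity\\.D\\.", names(v))]
  expect_true(all(occupied %in% c(0, 100)))
})

test_that("vector filtering removes contradictory duplicates and keeps one concordant representative", {
  m <- rbind(p1 = c(1, 2, 3), p2 = c(1, 2, 3), p3 = c(9, 9, 9))
  colnames(m) <- c("f1", "f2", "f3")
  ann <- annotation_set(list(p1 = 1L, p2 = 2L, p3 = 5L))
  out <- dedupe_vectors(m, ann)
  expect_equal(rownames(out$features), "p3")
  expect_setequal(out$report$id, c("p1", "p2"))
  expect_true(all(out$report$reason == "identical_vector_conflicting_functions"))

  ann2 <- annotation_set(list(p1 = c(1L, 7L), p2 = c(1L, 7L), p3 = 5L))
  out2 <- dedupe_vectors(m, ann2)
  expect_setequal(rownames(out2$features), c("p1", "p3"))
  expect_equal(out2$report$id, "p2")
  expect_equal(out2$report$reason, "identical_vector_same_functions")

  m3 <- rbind(a = c(1, 0), b = c(0, 1))
  out3 <- dedupe_vectors(m3, annotation_set(list(a = 1L, b = 2L)))
  expect_equal(nrow(out3$features), 2L)
  expect_equal(nrow(out3$report), 0L)
})
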