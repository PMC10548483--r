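edit_row <- function(id, pos, ref, alt, csq = "missense", ps = NA) {
  data.frame(id = id, protein_pos = pos, aa_ref = ref, aa_alt = alt,
             consequence = csq, phase_set = ps, stringsAsFactors = FALSE)
}

test_that("phased variants land on one haplotype, unphased on separate ones", {
  set.seed(7)
  wt <- random_protein(60)
  ed <- rbind(edit_row("a", 10, substr(wt, 10, 10), "W", ps = "ps1"),
              edit_row("b", 12, substr(wt, 12, 12), "M", ps = "ps1"))
  muts <- apply_phasing(wt, ed)
  expect_length(muts, 1)
  expect_equal(substr(muts[[1]], 10, 10), "W")
  expect_equal(substr(muts[[1]], 12, 12), "M")
  # unphased: two sequences, one edit each
  ed$phase_set <- NA
  muts2 <- apply_phasing(wt, ed)
  expect_length(muts2, 2)
  expect_equal(substr(muts2[[1]], 10, 10), "W")
  expect_equal(substr(muts2[[1]], 12, 12), substr(wt, 12, 12))
  expect_equal(substr(muts2[[2]], 12, 12), "M")
})

test_that("frameshift truncates and appends the novel tail", {
  set.seed(8)
  wt <- random_protein(50)
  ed <- edit_row("fs", 20, substr(wt, 20, 20), "WWWMMM",
                 csq = "frameshift")
  mut <- apply_phasing(wt, ed)[[1]]
  expect_equal(nchar(mut), 19 + 6)
  expect_equal(substr(mut, 1, 19), substr(wt, 1, 19))
  expect_equal(substr(mut, 20, 25), "WWWMMM")
})

test_that("conflicting overlapping edits in a phase set are rejected", {
  set.seed(9)
  wt <- random_protein(40)
  ed <- rbind(edit_row("a", 10, substr(wt, 10, 12), "A",
                       csq = "inframe_indel", ps = "ps1"),
              edit_row("b", 11, substr(wt, 11, 11), "W", ps = "ps1"))
  expect_error(apply_phasing(wt, ed), "overlapping")
  expect_error(apply_phasing(wt, edit_row("c", 5, "X", "Y")),
               "do not match")
  expect_error(apply_phasing(wt, edit_row("d", 5, substr(wt, 5, 5), "Y",
                                          csq = "start_lost")),
               "unsupported consequence")
})

test_that("window counts follow the stated combinatorics", {
  set.seed(10)
  wt <- random_protein(100)
  mut <- wt
  old <- substr(wt, 15, 15)
  new <- if (old == "W") "M" else "W"
  substr(mut, 15, 15) <- new
  w9 <- enumerate_windows(mut, wt, lengths = 9L)
  expect_equal(nrow(w9), 9L)
  expect_equal(w9$window_start, 7:15)
  w910 <- enumerate_windows(mut, wt)
  expect_equal(nrow(w910), 19L)
  # substitution at residue 1: single window
  mut1 <- wt
  substr(mut1, 1, 1) <- if (substr(wt, 1, 1) == "W") "M" else "W"
  expect_equal(enumerate_windows(mut1, wt, lengths = 9L)$window_start, 1L)
  expect_error(enumerate_windows("", wt), "non-empty")
})

test_that("enumeration matches the brute-force oracle on random edits", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(20:200, 1)
    wt <- random_protein(n)
    kind <- sample(c("sub", "double", "fs", "indel"), 1)
    ed <- switch(kind,
      sub = edit_row("e1", sample(n, 1), NA, "X"),
      double = {
        ps <- sort(sample(n, 2))
        rbind(edit_row("e1", ps[1], NA, "X", ps = "p"),
              edit_row("e2", ps[2], NA, "X", ps = "p"))
      },
      fs = edit_row("e1", sample(n, 1), NA,
                    random_protein(sample(1:20, 1)), csq = "frameshift"),
      indel = edit_row("e1", sample(n - 3, 1), NA,
                       random_protein(sample(1:4, 1)),
                       csq = "inframe_indel"))
    ed$aa_ref <- substring(wt, ed$protein_pos, ed$protein_pos)
    if (kind == "double" && diff(ed$protein_pos) < 1) next
    mut <- apply_phasing(wt, ed)[[1]]
    got <- enumerate_windows(mut, wt)
    want <- oracle_windows(mut, wt)
    expect_equal(got[c("sequence", "window_start", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("phasing composes: joint edit equals enumeration on jointly edited sequence", {
  set.seed(12)
  wt <- random_protein(80)
  ed <- rbind(edit_row("a", 20, substr(wt, 20, 20), "W", ps = "ps"),
              edit_row("b", 24, substr(wt, 24, 24), "M", ps = "ps"))
  joint <- apply_phasing(wt, ed)[[1]]
  manual <- wt
  substr(manual, 20, 20) <- "W"
  substr(manual, 24, 24) <- "M"
  expect_identical(joint, manual)
  expect_equal(enumerate_windows(joint, wt), enumerate_windows(manual, wt))
})

test_that("fusion junction windows match their combinatorics and oracle", {
  f <- list(id = "f1", gene5 = "G5", gene3 = "G3",
            junction_seq5 = random_protein(12),
            junction_seq3 = random_protein(12), frame = "in_frame")
  w9 <- fusion_junction_peptides(f, lengths = 9L)
  expect_equal(nrow(w9), 8L)   # >= 1 residue each side
  w10 <- fusion_junction_peptides(f, lengths = 10L)
  expect_equal(nrow(w10), 9L)
  set.seed(13)
  for (rep in 1:40) {
    f <- list(id = "fx", gene5 = "A", gene3 = "B",
              junction_seq5 = random_protein(sample(1:15, 1)),
              junction_seq3 = random_protein(sample(1:15, 1)),
              frame = sample(c("in_frame", "out_of_frame"), 1))
    got <- fusion_junction_peptides(f)
    want <- oracle_fusion_windows(f$junction_seq5, f$junction_seq3,
                                  f$frame)
    expect_equal(got[c("sequence", "window_start", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("uniqueness filter removes wild-type-matching peptides", {
  prot <- c(P1 = "ACDEFGHIKLMNPQRSTVWY", P2 = "YWVTSRQPNMLKIHGFEDCA")
  kmers <- build_reference_kmers(prot, lengths = 9L)
  peps <- data.frame(sequence = c("ACDEFGHIK", "WWWWWWWWW"),
                     stringsAsFactors = FALSE)
  kept <- uniqueness_filter(peps, kmers)
  expect_identical(kept$sequence, "WWWWWWWWW")
  expect_identical(uniqueness_filter(peps, character(0)), peps)
})

test_that("scoring expands peptide x HLA-A/B and honours the contract", {
  peps <- data.frame(sequence = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
                     window_start = 1L, length = 9L,
                     altered_positions = "1", protein_id = "P1",
                     source_variant_ids = "v1", stringsAsFactors = FALSE)
  const <- structure(list(score = function(p, a) rep(0.7, length(p)),
                          deterministic = TRUE), class = "neo_scorer")
  cand <- score_candidates(peps, c("A*02:01", "B*07:02"), const)
  expect_equal(nrow(cand), 6L)
  expect_true(all(cand$ap_score == 0.7))
  # HLA-C ignored under default policy
  candC <- score_candidates(peps, c("C*07:01"), const)
  expect_equal(nrow(candC), 0L)
  candC2 <- score_candidates(peps, c("C*07:01"), const,
                             include_hla_c = TRUE)
  expect_equal(nrow(candC2), 3L)
  # surrogate scorer is deterministic and in range
  sc <- surrogate_scorer()
  s1 <- score_candidates(peps, c("A*02:01", "B*07:02"), sc)
  s2 <- score_candidates(peps, c("A*02:01", "B*07:02"), sc)
  expect_identical(s1, s2)
  expect_true(all(s1$ap_score >= 0 & s1$ap_score <= 1))
  expect_length(unique(s1$ap_score), 6L)
  bad <- structure(list(score = function(p, a) rep(1.5, length(p))),
                   class = "neo_scorer")
  expect_error(score_candidates(peps, "A*02:01", bad), "outside")
  expect_error(score_candidates(peps, character(0), const), "empty")
  # duplicates by (sequence, protein) collapse before expansion
  peps2 <- rbind(peps, peps[1, ])
  expect_equal(nrow(score_candidates(peps2, "A*02:01", const)), 3L)
})

test_that("peptide abundance is summed isoform TPM times RNA VAF", {
  expect_equal(peptide_abundance(c(10, 5), 0.5), 7.5)
  expect_equal(peptide_abundance(c(10, 5), 0), 0)
  expect_equal(peptide_abundance(8, 1), 8)
  expect_error(peptide_abundance(5, 1.2), "vaf_rna")
})
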