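test_that("extract_cterm returns terminal windows and exclusion reasons", {
  expect_identical(extract_cterm("MKLRMAAAALVS", 9), "RMAAAALVS")
  expect_identical(extract_cterm("MKLV", 4), "MKLV")  # k = full length
  short <- extract_cterm("MKLVA", 10)
  expect_true(is.na(short))
  expect_identical(attr(short, "exclusion_reason"), "too short")
  masked <- extract_cterm("MKLVAAAAXA", 10)
  expect_identical(attr(masked, "exclusion_reason"), "X in window")
})

test_that("positional_frequency counts terminal residues correctly", {
  # degenerate family: one residue per position at frequency 1
  fam <- seq_family(paste0("s", 1:10), rep("MKLRMSAYGLAAA", 10))
  prof <- positional_frequency(fam, 10)
  expect_identical(prof$n_sequences, 10L)
  expect_true(all(apply(prof$frequencies, 1, max) == 1))

  # hand count: termini AAA, AAG, AAA at k = 3
  fam2 <- seq_family(c("a", "b", "c"), c("WAAA", "WAAG", "WAAA"))
  prof2 <- positional_frequency(fam2, 3)
  expect_equal(prof2$frequencies[3, "A"], 2 / 3)
  expect_equal(prof2$frequencies[3, "G"], 1 / 3)
  expect_equal(unname(prof2$counts[1, "A"]), 3L)

  # all-or-none exclusion keeps position denominators equal
  fam3 <- seq_family(c("a", "b", "c"), c("WAAA", "WA", "WAXA"))
  prof3 <- positional_frequency(fam3, 3)
  expect_identical(prof3$n_sequences, 1L)
  expect_setequal(prof3$excluded$reason, c("too short", "X in window"))
  expect_error(positional_frequency(seq_family("a", "MK"), 10),
               "no includable")
})

test_that("frequencies sum to one at every position on varied fixtures", {
  for (seed in 1:5) {
    fam <- simulate_family(family_sim_config(n_taxa = 12, root_length = 50,
                                             n_exact_duplicates = 3,
                                             seed = seed))
    prof <- positional_frequency(fam, 10)
    expect_true(all(abs(rowSums(prof$frequencies) - 1) < 1e-9))
    expect_true(all(rowSums(prof$counts) == prof$n_sequences))
  }
})

test_that("consensus_motif applies the strict > threshold rule", {
  fam <- seq_family(paste0("s", 1:4), rep("MKLRMSAYGLAAA", 4))
  cons <- consensus_motif(positional_frequency(fam, 10))
  expect_identical(cons$residues, "RMSAYGLAAA")
  expect_true(all(cons$conserved_flags))
  expect_false(any(cons$ambiguity_flags))

  # exactly 50% does NOT pass a 0.5 threshold ("larger than" is strict)
  fam2 <- seq_family(c("a", "b"), c("WWA", "WWG"))
  prof2 <- positional_frequency(fam2, 1)
  cons2 <- consensus_motif(prof2, 0.5)
  expect_equal(cons2$per_position_frequency, 0.5)
  expect_false(cons2$conserved_flags)
  expect_true(cons2$ambiguity_flags)   # A/G tie, A wins lexicographically
  expect_identical(cons2$residues, "A")
})

test_that("consensus of n copies of one sequence is its terminal k-mer", {
  for (n in c(1, 3, 7)) {
    fam <- seq_family(paste0("s", seq_len(n)), rep("MARMSAYGLREV", n))
    cons <- consensus_motif(positional_frequency(fam, 10))
    expect_identical(cons$residues, "RMSAYGLREV")
    expect_false(any(cons$ambiguity_flags))
  }
})

test_that("right-anchored identity matches the hand comparisons", {
  expect_equal(right_anchored_identity("RMSAYGLAAA", "RMSAYGLREV"), 0.7)
  expect_equal(right_anchored_identity("RMSAYGLAAA", "CAANDENYALAA"), 0.2)
  expect_equal(right_anchored_identity("RMSAYGLAAA", "RMSAYGLAAA"), 1)
  expect_error(right_anchored_identity("", "AA"), "non-empty")
  # symmetric when lengths are equal
  set.seed(5)
  for (i in 1:10) {
    a <- paste(sample(c("A", "L", "V", "S", "R"), 8, TRUE), collapse = "")
    b <- paste(sample(c("A", "L", "V", "S", "R"), 8, TRUE), collapse = "")
    expect_equal(right_anchored_identity(a, b),
                 right_anchored_identity(b, a))
  }
})

test_that("composition_score and dipeptide_present match hand counts", {
  expect_equal(composition_score("RMAAAALVS"), 7 / 9)
  expect_equal(composition_score("AAAA"), 1)
  expect_equal(composition_score("RRRR"), 0)
  expect_error(composition_score(""), "non-empty")

  hit <- dipeptide_present("RMSAYGLAAA", "AA")
  expect_true(hit$present)
  expect_identical(hit$positions, c(8L, 9L))
  expect_false(dipeptide_present("RMSAYGLREV", "AA")$present)
  expect_identical(dipeptide_present("AA", "AA")$positions, 1L)
  expect_error(dipeptide_present("AAA", "AAA"), "length 2")
})

test_that("the bundled reference catalogue is intact and scorable", {
  refs <- reference_degrons()
  expect_identical(unname(refs["ADcon"]), "RMSAYGLAAA")
  expect_identical(unname(refs["ssrA"]), "CAANDENYALAA")
  sc <- degron_score("RMSAYGLAAA")
  expect_equal(unname(sc$right_anchored_identity["ADcon"]), 1)
  expect_equal(unname(sc$right_anchored_identity["Euhalothece"]), 0.7)
  expect_true(all(sc$right_anchored_identity >= 0 &
                    sc$right_anchored_identity <= 1))
})

test_that("profile TSV export carries percent values", {
  fam <- seq_family(c("a", "b"), c("WWAG", "WWAA"))
  prof <- positional_frequency(fam, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  tab <- utils::read.delim(path, check.names = FALSE)
  expect_equal(tab[1, "A"], 100)
  expect_equal(tab[2, "A"], 50)
  expect_equal(tab[2, "G"], 50)
})
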