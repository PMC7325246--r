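test_that("nj_tree solves the 3-taxon case in closed form", {
  dm <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3, dimnames = list(letters[1:3],
                                                 letters[1:3]))
  tr <- nj_tree(dm)
  expect_identical(length(tr$tip.label), 3L)
  expect_identical(nrow(tr$edge), 3L)
  # x_a = (d_ab + d_ac - d_bc)/2 = 1, x_b = 2, x_c = 3
  bl <- tr$edge.length[match(match(letters[1:3], tr$tip.label),
                             tr$edge[, 2L])]
  expect_equal(bl, c(1, 2, 3))
})

test_that("nj_tree validates its input", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_error(nj_tree(m), "at least 3")
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "symmetric")
  neg <- matrix(c(0, -1, 2, -1, 0, 3, 2, 3, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(neg), "nonnegative")
})

test_that("NJ is exact on additive matrices (path-summation oracle)", {
  # The module's primary oracle: distances computed by path summation over a
  # known tree must be reconstructed exactly, topology and branch lengths.
  for (seed in 1:20) {
    n <- sample(5:8, 1)
    fix <- additive_matrix(n, seed)
    est <- nj_tree(fix$dm)
    expect_identical(length(est$tip.label), n)
    expect_identical(nrow(est$edge), 2L * n - 3L)
    expect_equal(ape::dist.topo(est, fix$tree), unname(c(PH85 = 0)),
                 ignore_attr = TRUE)
    coph <- ape::cophenetic.phylo(est)[rownames(fix$dm), colnames(fix$dm)]
    expect_lt(max(abs(coph - fix$dm)), 1e-9)
  }
})

test_that("NJ output shape and clamping invariants hold on noisy input", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    fix <- additive_matrix(n, i + 100)
    noisy <- fix$dm * matrix(stats::runif(n * n, 0.7, 1.3), n, n)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    tr <- nj_tree(noisy)
    expect_identical(nrow(tr$edge), 2L * n - 3L)
    expect_true(all(tr$edge.length >= 0))
    expect_gte(attr(tr, "clamped_deficit"), 0)
  }
})

test_that("nj_tree tie-breaking is invariant to input row order", {
  fix <- additive_matrix(6, 77)
  perm <- c(3, 1, 6, 2, 5, 4)
  t1 <- nj_tree(fix$dm)
  t2 <- nj_tree(fix$dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), unname(c(PH85 = 0)),
               ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(t1)[fix$tree$tip.label,
                                              fix$tree$tip.label] -
                    ape::cophenetic.phylo(t2)[fix$tree$tip.label,
                                              fix$tree$tip.label])), 1e-9)
})

test_that("bootstrap_support is seeded, bounded, and column-order invariant", {
  fam <- simulate_family(family_sim_config(n_taxa = 7, root_length = 60,
                                           n_exact_duplicates = 0,
                                           seed = 4))
  msa <- progressive_msa(fam)
  b1 <- bootstrap_support(msa, n_replicates = 30, seed = 9)
  b2 <- bootstrap_support(msa, n_replicates = 30, seed = 9)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
  s <- attr(b1, "supports")
  expect_true(all(s >= 0 & s <= 100))
  expect_identical(length(s), length(fam$id) - 3L)  # internal edges

  # permuting alignment columns leaves supports unchanged (column-iid
  # resampling); same seed, same column draw indices
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  set.seed(1); perm <- sample(ncol(m))
  msa_p <- multiple_alignment(msa$row_ids,
                              apply(m[, perm], 1, paste, collapse = ""))
  b3 <- bootstrap_support(msa_p, n_replicates = 30, seed = 9)
  expect_identical(sort(unname(attr(b3, "supports"))),
                   sort(unname(attr(b1, "supports"))))
  expect_error(bootstrap_support(progressive_msa(
    seq_family(c("a", "b"), c("MK", "MV"))), 10), "at least 4")
})

test_that("a bipartition held by a divergent block gets support 100", {
  # two blocks of identical-within, very different-between sequences
  fam <- seq_family(paste0("s", 1:6),
                    c(rep("AAAAAAAAAALLLLLLLLLL", 3),
                      rep("WWWWWWWWWWFFFFFFFFFF", 3)))
  dd <- dedup_exact(fam)  # 2 sequences -> cannot bootstrap; use raw family
  msa <- progressive_msa(fam, unit_scheme())
  bt <- bootstrap_support(msa, n_replicates = 50, seed = 3)
  s <- attr(bt, "supports")
  # the s1s2s3 | s4s5s6 split is present in every replicate
  expect_true(any(s == 100))
})

test_that("select_representatives picks one medoid per clade", {
  expect_true(nrow(dedup_exact(toy_family())) >= 1)  # fixture sanity
  # two well-separated simulated clades
  fam <- seq_family(paste0("s", 1:6),
                    c("AAAAAAAAGL", "AAAAAAAVGL", "AAAAAAAAGV",
                      "WWWWWWWWFY", "WWWWWWWYFY", "WWWWWWWWFV"))
  msa <- progressive_msa(fam, unit_scheme())
  dm <- msa_distances(msa)
  tr <- nj_tree(dm)
  reps <- select_representatives(tr, dm, 2)
  expect_identical(length(reps), 2L)
  expect_true(any(reps %in% paste0("s", 1:3)) &&
                any(reps %in% paste0("s", 4:6)))
  # degenerate cut: n_groups = leaf count returns every leaf
  expect_identical(select_representatives(tr, dm, 6), paste0("s", 1:6))
  expect_error(select_representatives(tr, dm, 0), "n_groups")
  expect_error(select_representatives(tr, dm, 7), "n_groups")
})
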