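test_that("self-alignment scores are the BLOSUM62 diagonal sums", {
  aln <- pairwise_align("MKR", "MKR")
  expect_equal(aln$score,
               sum(diag(blosum62_matrix[c("M", "K", "R"), c("M", "K", "R")])))
  expect_equal(aln$a_aligned, "MKR")
})

test_that("a single-residue deletion costs gap open plus one extension", {
  aln <- pairwise_align("MKR", "MR")
  expect_equal(aln$score,
               blosum62_matrix["M", "M"] + blosum62_matrix["R", "R"] - 12)
  expect_equal(aln$score, oracle_align_score("MKR", "MR"))
})

test_that("alignment scores are symmetric", {
  set.seed(5)
  for (r in 1:20) {
    a <- paste(sample(irpannot:::AA_ALPHABET, 8, TRUE), collapse = "")
    b <- paste(sample(irpannot:::AA_ALPHABET, 8, TRUE), collapse = "")
    expect_equal(pairwise_align(a, b)$score, pairwise_align(b, a)$score)
  }
})

test_that("non-amino-acid input other than X is rejected", {
  expect_error(pairwise_align("MKZ", "MK"), "non-amino-acid")
  expect_error(pairwise_align("", "MK"), "non-empty")
  expect_silent(pairwise_align("MKX", "MK"))
})

test_that("distances follow the p and Poisson corrections", {
  expect_equal(seq_distance("MKR", "MKR"), 0)
  expect_equal(seq_distance("MKR", "MKR", "p"), 0)
  expect_equal(seq_distance("AAAA", "AABB"), -log(0.5))
  expect_equal(seq_distance("AAAA", "GGGG"), 5)  # capped as p -> 1
  expect_error(seq_distance("XX", "XX"), "no aligned columns")
  expect_error(seq_distance("--", "AA"), "no aligned columns")
})

test_that("three-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens, c(A = 1, B = 1, C = 3))
})

test_that("an additive four-taxon matrix is recovered exactly", {
  ref <- read_newick("((A:1,B:2):1,C:3,D:4);")
  d <- ape::cophenetic.phylo(ref)
  tr <- neighbor_joining(d[LETTERS[1:4], LETTERS[1:4]])
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]],
               d[LETTERS[1:4], LETTERS[1:4]], tolerance = 1e-9)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(8)
  for (r in 1:20) {
    n <- sample(5:9, 1)
    d <- as.matrix(stats::dist(matrix(runif(n * 4), n)))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    mine <- neighbor_joining(d)
    apes <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine), ape::unroot(apes))), 0)
  }
})

test_that("neighbor joining validates its input and is deterministic", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(d2), "at least 3")
  d3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(neighbor_joining(d3), "symmetric")

  # fully tied distances: the stated tie-break still gives one fixed tree
  dt <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(dt) <- 0
  expect_identical(write_newick(neighbor_joining(dt)),
                   write_newick(neighbor_joining(dt)))
})

test_that("family trees require three annotatable records", {
  two <- make_precursor_batch(1, 1, families = c("GSS", "IGF"))
  expect_error(family_tree(two), "at least 3")
  batch <- make_precursor_batch(1, 1, families = c("GSS", "IGF", "dilp7"))
  batch$junk <- irpannot:::new_seq_record("junk", strrep("A", 60))
  expect_warning(ft <- family_tree(batch), "excluded")
  expect_equal(ft$excluded, "junk")
  expect_equal(sort(ft$tree$tip.label), c("GSS_r1", "IGF_r1", "dilp7_r1"))
})

test_that("similarity trees group the families as expected", {
  batch <- make_precursor_batch(4, 13, noise_rate = 0.05)
  ft <- family_tree(batch)
  fam_of <- sub("_r\\d+$", "", ft$tree$tip.label)
  mid <- phangorn::midpoint(ft$tree)
  for (f in unique(fam_of)) {
    expect_true(ape::is.monophyletic(mid, ft$tree$tip.label[fam_of == f]),
                info = f)
  }
  co <- ape::cophenetic.phylo(ft$tree)
  gss <- ft$tree$tip.label[fam_of == "GSS"]
  igf <- ft$tree$tip.label[fam_of == "IGF"]
  d7 <- ft$tree$tip.label[fam_of == "dilp7"]
  expect_lt(mean(co[gss, igf]), mean(co[gss, d7]))
})
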