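test_that("clustered layouts give one multi-gene cluster plus a distant GSS", {
  loci <- make_synteny_layout("echinozoa_clustered", 1)
  cl <- cluster_loci(loci)
  sizes <- sort(vapply(cl, function(x) nrow(x$members), 0L))
  expect_equal(sizes, c(1L, 4L))
  big <- cl[[which.max(vapply(cl, function(x) nrow(x$members), 0L))]]
  expect_equal(conserved_arrangement_check(big), "triplet_with_IGF_middle")
  single <- cl[[which.min(vapply(cl, function(x) nrow(x$members), 0L))]]
  expect_equal(single$members$family_label, "GSS")
  # generator gaps are 20-50 kb inside the cluster
  expect_true(all(big$gaps_kb >= 20 & big$gaps_kb <= 50))
})

test_that("scattered layouts cluster as singletons only", {
  loci <- make_synteny_layout("asterozoa_scattered", 2)
  cl <- cluster_loci(loci)
  expect_length(cl, 5L)
  expect_true(all(vapply(cl, function(x) nrow(x$members), 0L) == 1L))
})

test_that("an infinite gap yields one cluster per sequence region", {
  loci <- rbind(make_synteny_layout("echinozoa_clustered", 3),
                make_synteny_layout("asterozoa_scattered", 3))
  cl <- cluster_loci(loci, max_gap = Inf)
  expect_length(cl, length(unique(loci$seq_region)))
})

test_that("the arrangement check needs IGF strictly between the flankers", {
  mk <- function(fams) {
    structure(list(seq_region = "chr1",
                   members = data.frame(gene_id = seq_along(fams),
                                        family_label = fams,
                                        start = seq_along(fams) * 1000),
                   gaps_kb = rep(1, length(fams) - 1)),
              class = "synteny_cluster")
  }
  expect_equal(conserved_arrangement_check(mk(c("octinsulin", "IGF", "dilp7"))),
               "triplet_with_IGF_middle")
  expect_equal(conserved_arrangement_check(mk(c("dilp7", "IGF", "octinsulin"))),
               "triplet_with_IGF_middle")
  expect_equal(conserved_arrangement_check(mk(c("IGF", "octinsulin", "dilp7"))),
               "other")
  expect_equal(conserved_arrangement_check(mk(c("octinsulin", "IGF", "GSS"))),
               "other")
  expect_equal(conserved_arrangement_check(mk(c("gonadulin", "IGF", "dilp7"))),
               "triplet_with_IGF_middle")
})

test_that("clustering partitions the loci and is monotone in max_gap", {
  set.seed(9)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    loci <- data.frame(
      gene_id = paste0("g", seq_len(n)),
      family_label = sample(family_set, n, replace = TRUE),
      seq_region = sample(paste0("chr", 1:3), n, replace = TRUE),
      start = sample.int(1e7, n), strand = "+", stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(1000:20000, n, replace = TRUE)

    gaps <- c(1e4, 1e5, 1e6, 1e7)
    n_clusters <- vapply(gaps, function(g) length(cluster_loci(loci, g)), 0L)
    expect_true(all(diff(n_clusters) <= 0))  # larger gap, fewer clusters

    cl <- cluster_loci(loci, 1e5)
    seen <- unlist(lapply(cl, function(x) x$members$gene_id))
    expect_setequal(seen, loci$gene_id)
    expect_equal(length(seen), n)  # each locus in exactly one cluster

    # reported gaps equal direct coordinate subtraction
    for (x in cl) {
      if (nrow(x$members) > 1) {
        direct <- pmax(x$members$start[-1] -
                         x$members$end[-nrow(x$members)], 0) / 1000
        expect_equal(x$gaps_kb, direct)
      }
    }
  }
})

test_that("layout comparison reports shared and lost cluster compositions", {
  a <- cluster_loci(make_synteny_layout("echinozoa_clustered", 4))
  b <- cluster_loci(make_synteny_layout("echinozoa_clustered", 5))
  sc <- cluster_loci(make_synteny_layout("asterozoa_scattered", 4))

  same <- compare_layouts(list(sp1 = a, sp2 = b))
  comp <- "IGF+IGF+dilp7+octinsulin"
  expect_equal(same$verdict[same$composition == comp], "shared")

  diff_tab <- compare_layouts(list(sp1 = a, sp3 = sc))
  expect_false(any(diff_tab$verdict[diff_tab$composition == comp] == "shared"))

  expect_error(compare_layouts(list(sp1 = a)), ">=2 species")
})

test_that("cluster tables serialize with members, gaps and arrangement", {
  cl <- cluster_loci(make_synteny_layout("echinozoa_clustered", 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(cl, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), length(cl))
  expect_true("triplet_with_IGF_middle" %in% tab$arrangement)
})
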