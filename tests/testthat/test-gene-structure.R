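gene_from_lengths <- function(lens, strand = "+", gap = 100L) {
  starts <- cumsum(c(0L, head(lens, -1) + gap))
  irpannot:::new_gene_model("g", "chr1", strand,
                            cbind(starts, starts + lens))
}

test_that("intron phases follow the coding-offset arithmetic", {
  ph <- compute_intron_phases(gene_from_lengths(c(10L, 20L)))
  expect_equal(ph$cds_offset, 10L)
  expect_equal(ph$phase, 1L)
  expect_equal(ph$aa_pos, 3L)

  expect_equal(compute_intron_phases(gene_from_lengths(c(9L, 12L, 21L)))$phase,
               c(0L, 0L))
  lens <- c(8L, 9L, 10L)
  expect_equal(compute_intron_phases(gene_from_lengths(lens))$phase,
               oracle_phases(lens))
  expect_equal(compute_intron_phases(gene_from_lengths(lens))$phase, c(2L, 2L))
})

test_that("single-exon and incomplete genes are handled per contract", {
  expect_equal(nrow(compute_intron_phases(gene_from_lengths(21L))), 0L)
  expect_error(compute_intron_phases(gene_from_lengths(c(10L, 12L))),
               "incomplete CDS")
})

test_that("phases equal the codon-walking oracle on random exon partitions", {
  set.seed(20)
  for (r in 1:300) {
    n_nt <- 3L * sample(20:150, 1)
    k <- sample(2:6, 1)
    lens <- random_partition(n_nt, k)
    expect_equal(compute_intron_phases(gene_from_lengths(lens))$phase,
                 oracle_phases(lens))
  }
})

test_that("phases are invariant under a genomic strand flip", {
  for (fam in family_set) {
    gm <- make_gene_model(fam, 2)
    flipped <- flip_gene_model(gm$gene)
    expect_equal(compute_intron_phases(flipped)$phase,
                 compute_intron_phases(gm$gene)$phase, info = fam)
  }
  set.seed(33)
  for (r in 1:50) {
    lens <- random_partition(3L * sample(20:80, 1), sample(2:5, 1))
    g <- gene_from_lengths(lens)
    expect_equal(compute_intron_phases(flip_gene_model(g))$phase,
                 compute_intron_phases(g)$phase)
  }
})

test_that("introns map onto the precursor domains", {
  gm <- make_gene_model("GSS", 1)
  ann <- annotate_precursor(gm$record, gene = gm$gene)
  expect_equal(ann$introns$domain_tag, "C")

  # an intron placed inside the A domain maps to A
  ann0 <- annotate_precursor(gm$record)
  a_aa <- ann0$annotation$intervals$A[1] + 3L
  lens <- c(3L * a_aa + 0L, nchar(gm$cds) - 3L * a_aa)
  g <- gene_from_lengths(lens)
  introns <- compute_intron_phases(g)
  mapped <- map_introns_to_domains(introns, ann0$annotation, g,
                                   nchar(gm$record$residues))
  expect_equal(mapped$domain_tag, "A")

  bad <- gene_from_lengths(c(30L, 30L))
  expect_error(map_introns_to_domains(compute_intron_phases(bad),
                                      ann0$annotation, bad,
                                      nchar(gm$record$residues)),
               "protein has")
})

sig_from <- function(phases, domains, offsets = NULL, cds_length = 400L) {
  introns <- data.frame(index = seq_along(phases),
                        cds_offset = if (is.null(offsets))
                          seq(30L, by = 50L, length.out = length(phases))
                        else offsets,
                        phase = phases, aa_pos = 0L, domain_tag = domains,
                        stringsAsFactors = FALSE)
  gene_signature(introns, cds_length)
}

test_that("gene signatures implement the family-diagnostic intron rules", {
  expect_equal(sig_from(1L, "C")$token, "GSS_or_octinsulin")
  expect_equal(sig_from(c(1L, 2L), c("C", "B"))$token, "dilp7")
  expect_equal(sig_from(c(1L, 1L, 2L), c("B", "C", "B"))$token, "multinsulin")
  expect_equal(sig_from(c(1L, 0L), c("C", "E"), offsets = c(100L, 350L))$token,
               "IGF")
  # the C-domain phase-1 intron is required for any call
  expect_equal(sig_from(2L, "B")$token, "unknown")
  expect_equal(sig_from(1L, "A")$token, "unknown")
  expect_equal(sig_from(c(1L, 0L), c("C", "B"), offsets = c(100L, 150L))$token,
               "GSS_or_octinsulin")  # phase-0 intron not near the end
})

test_that("generator gene models yield their family's signature token", {
  expected <- c(IGF = "IGF", GSS = "GSS_or_octinsulin",
                octinsulin = "GSS_or_octinsulin", dilp7 = "dilp7",
                multinsulin = "multinsulin")
  for (fam in family_set) {
    gm <- make_gene_model(fam, 6)
    ann <- annotate_precursor(gm$record, gene = gm$gene)
    expect_equal(ann$gene_sig$token, unname(expected[fam]), info = fam)
  }
})
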