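annotate_template <- function(fam, seed = 1, noise = 0) {
  annotate_precursor(make_precursor(fam, seed, noise))
}

test_that("family templates segment into their expected domain layouts", {
  gss <- annotate_template("GSS")
  expect_equal(gss$annotation$chain_mode, "two_chain")
  expect_setequal(names(gss$annotation$intervals), c("signal", "B", "C", "A"))

  igf <- annotate_template("IGF")
  expect_equal(igf$annotation$chain_mode, "single_chain")
  expect_true(all(c("D", "E") %in% names(igf$annotation$intervals)))

  d7 <- annotate_template("dilp7")
  f_iv <- d7$annotation$intervals$F
  expect_equal(f_iv[2] - f_iv[1], 25)
})

test_that("domain intervals are disjoint, ordered and cover the precursor", {
  order_ref <- c("signal", "F", "B", "C", "A", "D", "E")
  for (fam in family_set) {
    for (s in 1:5) {
      ann <- annotate_template(fam, s, noise = 0.05)
      if (is.null(ann$annotation)) next
      iv <- ann$annotation$intervals
      expect_equal(names(iv), intersect(order_ref, names(iv)))
      bounds <- unname(do.call(rbind, iv))
      # contiguous cover: each interval starts where the previous ended
      expect_equal(bounds[1, 1], 0)
      expect_equal(bounds[nrow(bounds), 2],
                   nchar(make_precursor(fam, s, 0.05)$residues))
      if (nrow(bounds) > 1) {
        expect_equal(bounds[-1, 1], bounds[-nrow(bounds), 2])
      }
    }
  }
})

test_that("B contains the B-chain cysteines and A the A-chain cysteines", {
  for (fam in family_set) {
    ann <- annotate_template(fam, 4)
    fw <- ann$framework
    bi <- ann$annotation$intervals$B
    ai <- ann$annotation$intervals$A
    expect_true(fw$cb1 >= bi[1] && fw$cb2 < bi[2], info = fam)
    expect_true(fw$ca1 >= ai[1] && fw$ca4 < ai[2], info = fam)
  }
})

test_that("two-chain mode corresponds to accepted sites flanking C", {
  for (fam in family_set) {
    ann <- annotate_template(fam, 2)
    acc <- ann$sites[ann$sites$verdict == "accepted" &
                       ann$sites$kind %in% c("dibasic", "furin_strong",
                                             "furin_weak"), ]
    fw <- ann$framework
    inside <- acc$pos[acc$pos > fw$cb2 & acc$pos < fw$ca1]
    flanked <- length(inside) >= 2 && min(inside) < max(inside)
    expect_equal(ann$annotation$chain_mode == "two_chain", flanked, info = fam)
  }
})

test_that("segmentation requires a framework", {
  expect_error(segment_domains(strrep("A", 50), 15L, NULL, NULL),
               "cannot segment")
})

test_that("tail features count basic and charged residues", {
  fake <- structure(list(intervals = list(D = c(0L, 6L)),
                         chain_mode = "single_chain"),
                    class = "domain_annotation")
  tf <- tail_features("KRKRDE", fake)
  expect_equal(tf$tail_len, 6L)
  expect_equal(tf$basic_fraction, 4 / 6)
  expect_equal(tf$charged_fraction, 1)

  tf0 <- tail_features("AAAAA",
    structure(list(intervals = list(D = c(0L, 5L))), class = "domain_annotation"))
  expect_equal(tf0$basic_fraction, 0)
  expect_equal(tf0$charged_fraction, 0)

  gss <- annotate_template("GSS")
  expect_equal(gss$tail$tail_len, 0L)
  expect_true(gss$tail$absent)
})

test_that("the IGF tail is long and charged by construction", {
  igf <- annotate_template("IGF")
  expect_gte(igf$tail$tail_len, 25L)
  expect_gte(igf$tail$charged_fraction, 0.3)
})

test_that("F-domain metrics report length and reference identity", {
  d7 <- make_precursor("dilp7", 1)
  ann <- annotate_precursor(d7)
  f_iv <- ann$annotation$intervals$F
  f_ref <- substr(d7$residues, f_iv[1] + 1, f_iv[2])

  with_ref <- annotate_precursor(d7, f_references = f_ref)
  expect_equal(with_ref$f_metrics$f_identity, 1.0)

  mult <- annotate_template("multinsulin")
  expect_equal(mult$f_metrics$f_len, 0L)
  expect_null(mult$f_metrics$f_identity)

  # mutate 20% of F positions: identity ~ 0.8 up to alignment effects
  res <- strsplit(d7$residues, "")[[1]]
  idx <- f_iv[1] + c(2, 7, 12, 17, 22)
  res[idx + 1] <- c("W", "K", "T", "S", "H")
  mut <- paste(res, collapse = "")
  ann_mut <- annotate_precursor(mut, f_references = f_ref)
  expect_gt(ann_mut$f_metrics$f_identity, 0.72)
  expect_lt(ann_mut$f_metrics$f_identity, 0.88)
})

test_that("domain annotations serialize to GFF3-style feature lines", {
  ann <- annotate_template("dilp7")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_domain_gff3(list(dilp7_s1 = ann$annotation), path)
  lines <- readLines(path)
  expect_match(lines[2], "signal_peptide\t1\t15")
  expect_true(any(grepl("F_domain\t16\t40", lines)))
})
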