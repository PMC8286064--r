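test_that("signal cleavage is recovered on all family templates", {
  for (fam in family_set) {
    rec <- make_precursor(fam, 1)
    expect_equal(predict_signal_cleavage(rec$residues), 15L, info = fam)
  }
})

test_that("a user-supplied cleavage position always wins", {
  rec <- make_precursor("GSS", 1)
  expect_equal(predict_signal_cleavage(rec$residues, override = 20), 20L)
  expect_equal(predict_signal_cleavage(strrep("D", 60), override = 17), 17L)
})

test_that("sequences without a hydrophobic h-region are rejected", {
  expect_error(predict_signal_cleavage(strrep("D", 60)),
               "no signal peptide detected")
  expect_error(predict_signal_cleavage("MKR"), "too short")
})

test_that("furin tiers distinguish full consensus from the relaxed form", {
  strong <- find_furin_sites(paste0(strrep("G", 10), "RSKR", "A", strrep("G", 5)))
  expect_equal(nrow(strong), 1L)
  expect_equal(strong$kind, "furin_strong")
  expect_equal(strong$verdict, "accepted")
  expect_equal(strong$pos, 13L)

  for (motif in c("KSAR", "KSER")) {
    weak <- find_furin_sites(paste0(strrep("G", 10), motif, strrep("G", 10)))
    expect_equal(nrow(weak), 1L, info = motif)
    expect_equal(weak$kind, "furin_weak", info = motif)
    expect_equal(weak$verdict, "accepted", info = motif)
  }

  pro <- find_furin_sites(paste0(strrep("G", 10), "RSKRP", strrep("G", 5)))
  expect_equal(pro$verdict, "rejected")
  expect_match(pro$reasons, "P1'-proline")
})

test_that("dibasic sites honor the contextual exclusion rules", {
  ok <- find_dibasic_sites(paste0(strrep("A", 10), "KRGA", strrep("A", 5)))
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$verdict, "accepted")
  expect_equal(ok$pos, 11L)

  bulky <- find_dibasic_sites(paste0(strrep("A", 10), "KRWA", strrep("A", 5)))
  expect_equal(bulky$verdict, "rejected")
  expect_match(bulky$reasons, "bulky-P1'")

  pro <- find_dibasic_sites(paste0(strrep("A", 10), "KRPA", strrep("A", 5)))
  expect_match(pro$reasons, "P1'-proline")

  pre <- find_dibasic_sites(paste0(strrep("A", 8), "PAKRGA", strrep("A", 5)))
  expect_equal(pre$verdict, "rejected")
  expect_match(pre$reasons, "pre-site-proline")
})

test_that("a core cysteine near P1 triggers the disulfide-proximity rule", {
  seq <- paste0(strrep("A", 10), "KRGA", strrep("A", 10))
  fake_fw <- structure(list(core = c(13L)), class = "cys_framework")
  sites <- find_dibasic_sites(seq, framework = fake_fw)
  expect_equal(sites$verdict, "rejected")  # |13 - 11| = 2 <= 3
  expect_match(sites$reasons, "disulfide-proximity")

  far_fw <- structure(list(core = c(20L)), class = "cys_framework")
  expect_equal(find_dibasic_sites(seq, framework = far_fw)$verdict, "accepted")
})

test_that("optional motifs stay off by default and activate via config", {
  seq <- paste0(strrep("A", 10), "RRGA", strrep("A", 5))
  expect_equal(nrow(find_dibasic_sites(seq)), 0L)
  cfg <- irp_config(list(`cleavage.dibasic_rr` = TRUE))
  expect_equal(nrow(find_dibasic_sites(seq, config = cfg)), 1L)
})

test_that("no accepted dibasic site carries a forbidden P1' residue", {
  bulky <- strsplit(irp_config()$`cleavage.bulky`, "")[[1]]
  for (fam in family_set) {
    for (s in 1:10) {
      rec <- make_precursor(fam, s, noise_rate = 0.1)
      res <- strsplit(rec$residues, "")[[1]]
      sites <- find_cleavage_sites(rec$residues, 15L,
                                   find_core_framework(rec$residues))
      acc <- sites[sites$verdict == "accepted" & sites$kind == "dibasic", ]
      if (nrow(acc)) {
        p1prime <- res[acc$pos + 2L]
        expect_false(any(p1prime %in% c(bulky, "P")))
      }
    }
  }
})

test_that("planted sites are recovered and planted decoys rejected", {
  for (fam in c("GSS", "octinsulin", "dilp7", "multinsulin")) {
    rec <- make_precursor(fam, 3)
    tpl <- attr(rec, "template")
    sites <- find_cleavage_sites(rec$residues, 15L,
                                 find_core_framework(rec$residues))
    acc_kr <- sites$pos[sites$verdict == "accepted" & sites$kind == "dibasic"]
    expect_setequal(acc_kr, tpl$kr_p1)
    decoy <- sites[sites$pos %in% tpl$decoy_p1, ]
    expect_equal(decoy$verdict, "rejected", info = fam)
  }
  igf <- make_precursor("IGF", 3)
  tpl <- attr(igf, "template")
  sites <- find_cleavage_sites(igf$residues, 15L,
                               find_core_framework(igf$residues))
  furin <- sites[sites$kind %in% c("furin_weak", "furin_strong"), ]
  expect_equal(furin$pos, tpl$furin_p1)
  expect_equal(furin$verdict, "accepted")
})

test_that("site prediction is deterministic", {
  rec <- make_precursor("dilp7", 9, noise_rate = 0.05)
  fw <- find_core_framework(rec$residues)
  s1 <- find_cleavage_sites(rec$residues, 15L, fw)
  s2 <- find_cleavage_sites(rec$residues, 15L, fw)
  expect_identical(s1, s2)
})
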