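test_that("contribution reproduces the hand-evaluated formula", {
  ## local(anchors 2, pets 100), trans(anchors 3, pets 1000):
  ## frac_trans = (3*3) / (2*2 + 3*3) = 9/13
  p <- make_profile("G", al = 2, pl = 100, at = 3, pt = 1000)
  rec <- contribution(p)
  expect_equal(rec$frac_trans, 9 / 13, tolerance = 1e-12)
  expect_true(rec$is_trans_hijack)
  expect_false(rec$is_cis_hijack)

  ## all activity local
  rec2 <- contribution(make_profile("G", al = 4, pl = 50))
  expect_equal(rec2$frac_trans, 0)
  expect_equal(rec2$frac_cis, 0)
  expect_equal(rec2$frac_local, 1)
  expect_false(rec2$is_trans_hijack || rec2$is_cis_hijack)

  ## only trans activity
  rec3 <- contribution(make_profile("G", at = 5, pt = 60))
  expect_equal(rec3$frac_trans, 1)
})

test_that("fractions normalize to 1 and match the oracle on random profiles", {
  set.seed(61)
  for (i in 1:200) {
    al <- sample(0:10, 1); ac <- sample(0:10, 1); at <- sample(0:10, 1)
    pl <- if (al > 0) sample(3:500, 1) else 0
    pc <- if (ac > 0) sample(3:500, 1) else 0
    pt <- if (at > 0) sample(3:500, 1) else 0
    rec <- contribution(make_profile("G", al, pl, ac, pc, at, pt))
    o <- oracle_contribution(al, pl, ac, pc, at, pt)
    expect_equal(rec$frac_local, o[["local"]], tolerance = 1e-12)
    expect_equal(rec$frac_cis, o[["cis"]], tolerance = 1e-12)
    expect_equal(rec$frac_trans, o[["trans"]], tolerance = 1e-12)
    if (al + ac + at > 0) {
      expect_equal(rec$frac_local + rec$frac_cis + rec$frac_trans, 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("adding a trans loop never decreases frac_trans", {
  set.seed(71)
  for (i in 1:50) {
    al <- sample(1:10, 1); pl <- sample(3:300, 1)
    at <- sample(0:5, 1); pt <- if (at > 0) sample(3:300, 1) else 0
    before <- contribution(make_profile("G", al, pl, at = at, pt = pt))
    after <- contribution(make_profile("G", al, pl, at = at + 1,
                                       pt = pt + sample(3:50, 1)))
    expect_gte(after$frac_trans, before$frac_trans - 1e-12)
  }
})

test_that("hijacking calls gate on HAPI status with strict > threshold", {
  hapi <- dt(gene = c("A", "B", "C"), p_chrom = "chr1", p_start = 0L,
             p_end = 2000L, C = c(10L, 10L, 2L), I = c(100, 100, 5),
             cutoff_C = 5, cutoff_I = 50,
             is_hapi = c(TRUE, TRUE, FALSE))
  rec <- data.table::rbindlist(list(
    contribution(make_profile("A", al = 3, pl = 100, at = 3, pt = 100)),
    contribution(make_profile("B", al = 9, pl = 1000, at = 1, pt = 10)),
    contribution(make_profile("C", at = 5, pt = 500))))  # frac_trans = 0.9+
  cand <- call_hijacking(rec, hapi)
  expect_equal(cand$gene, "A")
  expect_equal(cand$label, "trans")
  ## candidate set is a subset of the HAPI set
  expect_true(all(cand$gene %in% hapi[is_hapi == TRUE]$gene))
})

test_that("frac exactly 0.25 is not a candidate; 0.26 is", {
  hapi <- dt(gene = c("EXACT", "OVER"), p_chrom = "chr1", p_start = 0L,
             p_end = 2000L, C = 10L, I = 100, cutoff_C = 1, cutoff_I = 1,
             is_hapi = TRUE)
  ## term_trans = log10(10)*1 = 1; term_local = log10(10)*3 = 3 -> 0.25 exact
  exact <- contribution(make_profile("EXACT", al = 3, pl = 10, at = 1, pt = 10))
  expect_equal(exact$frac_trans, 0.25)
  over <- contribution(make_profile("OVER", al = 140, pl = 10, at = 49, pt = 100))
  expect_gt(over$frac_trans, 0.25)
  cand <- call_hijacking(data.table::rbindlist(list(exact, over)), hapi)
  expect_equal(cand$gene, "OVER")
})

test_that("partition_by_locus assigns own/donor/other with own precedence", {
  ## gene promoter at chr1:100 kb; reference (MYC-style) promoter chr8:128 Mb
  ep <- dt(gene = "G", p_chrom = "chr1", p_start = 99000L, p_end = 101000L,
           e_chrom = c("chr1", "chr8", "chr2"),
           e_start = c(1099000L, 128499000L, 50000000L),
           e_end = c(1101000L, 128501000L, 50001000L),
           pets = c(10L, 20L, 30L),
           class = c("NORMAL", "TRANS", "TRANS"))
  ref <- list(chrom = "chr8", start = 127999000L, end = 128001000L)
  part <- partition_by_locus("G", ep, ref)
  expect_equal(part$n_own, 1L)     # 1 Mb from own promoter
  expect_equal(part$n_donor, 1L)   # 0.5 Mb from the reference promoter
  expect_equal(part$n_other, 1L)   # 10+ Mb from both
  ## hand evaluation with the same weighting
  t_own <- log10(10) * 1; t_donor <- log10(20) * 1; t_other <- log10(30) * 1
  tot <- t_own + t_donor + t_other
  expect_equal(part$frac_own, t_own / tot, tolerance = 1e-12)
  expect_equal(part$frac_donor, t_donor / tot, tolerance = 1e-12)
  expect_equal(part$frac_other, t_other / tot, tolerance = 1e-12)
  expect_equal(part$frac_own + part$frac_donor + part$frac_other, 1,
               tolerance = 1e-9)

  ## reference = own promoter: the donor criterion coincides with the own
  ## criterion, so own precedence leaves the donor category empty and the
  ## remaining anchors all fall into "other"
  own_ref <- list(chrom = "chr1", start = 99000L, end = 101000L)
  part2 <- partition_by_locus("G", ep, own_ref)
  expect_equal(part2$n_donor, 0L)
  expect_equal(part2$frac_donor, 0)
  t_own2 <- log10(10) * 1
  t_other2 <- log10(20 + 30) * 2  # chr8 and chr2 anchors pool into "other"
  expect_equal(part2$frac_own, t_own2 / (t_own2 + t_other2), tolerance = 1e-12)
  expect_equal(part2$frac_own + part2$frac_other, 1, tolerance = 1e-9)

  expect_error(partition_by_locus("NOPE", ep, ref), "no enhancer-promoter")
})

test_that("attach_copy_number uses the TSS-containing segment, half-open", {
  tss <- make_tss(c("A", "B", "C"), "chr1", c(1000000, 3000000, 7000000))
  seg <- dt(sample = "S", chrom = "chr1",
            start = c(0L, 2000000L, 3000000L), end = c(2000000L, 3000000L, 4000000L),
            log2cn = c(3.2, 0.5, 1.0))
  pr <- data.table::rbindlist(lapply(seq_len(nrow(tss)), function(i) {
    make_profile(tss$gene[i], al = 2, pl = 20, chrom = "chr1",
                 p_start = as.integer(tss$tss[i] - 1000),
                 p_end = as.integer(tss$tss[i] + 1000))
  }))
  rec <- attach_copy_number(contribution(pr), seg, tss)
  expect_equal(rec[gene == "A"]$log2cn, 3.2)
  expect_true(rec[gene == "A"]$high_copy)
  ## TSS exactly at a segment start belongs to that segment (half-open)
  expect_equal(rec[gene == "B"]$log2cn, 1.0)
  expect_false(rec[gene == "B"]$high_copy)
  ## coverage gap -> NA, not high copy
  expect_true(is.na(rec[gene == "C"]$log2cn))
  expect_false(rec[gene == "C"]$high_copy)

  multi <- dt(sample = c("S1", "S2"), chrom = "chr1", start = 0L,
              end = 100L, log2cn = 1)
  expect_error(attach_copy_number(contribution(pr), multi, tss),
               "single sample")
})

test_that("candidate_links returns one row per candidate E-P loop", {
  fx <- small_fixture(seed = 19)
  res <- run_fixture_pipeline(fx)
  links <- candidate_links(res$candidates, res$ep_loops)
  expect_setequal(unique(links$gene), res$candidates$gene)
  expect_true(all(links$pets >= 3))
})
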