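test_that("filter_loops applies the PET >= 3 rule and 1 bp blacklist overlap", {
  loops <- make_loops(
    list("chr1", 0, 1000, "chr1", 10000, 11000, 1),
    list("chr1", 0, 1000, "chr1", 10000, 11000, 2),
    list("chr1", 0, 1000, "chr1", 10000, 11000, 3),
    list("chr1", 0, 1000, "chr1", 10000, 11000, 5))
  res <- filter_loops(loops, blacklist = NULL)
  expect_equal(res$report$kept, 2L)
  expect_equal(sort(res$kept$pets), c(3L, 5L))

  ## 1 bp overlap of anchor1 with a blacklist interval removes the loop
  bl <- dt(chrom = "chr1", start = 999L, end = 2000L)
  res2 <- filter_loops(make_loops(list("chr1", 0, 1000, "chr1", 9000, 9500, 4)),
                       bl)
  expect_equal(res2$report$blacklist_removed, 1L)
  expect_equal(nrow(res2$kept), 0L)
  ## no overlap when the blacklist starts exactly at the half-open anchor end
  bl2 <- dt(chrom = "chr1", start = 1000L, end = 2000L)
  expect_equal(filter_loops(make_loops(
    list("chr1", 0, 1000, "chr1", 9000, 9500, 4)), bl2)$report$kept, 1L)
})

test_that("filter report matches a naive per-loop scan", {
  loops <- make_loops(
    list("chr1", 0, 1000, "chr1", 10000, 11000, 1),
    list("chr1", 0, 1000, "chr1", 10000, 11000, 2),
    list("chr1", 500000, 501000, "chr1", 600000, 601000, 4),
    list("chr1", 0, 1000, "chr1", 10000, 11000, 6),
    list("chr2", 0, 1000, "chr2", 10000, 11000, 9))
  bl <- dt(chrom = "chr1", start = 500500L, end = 500600L)
  res <- filter_loops(loops, bl)
  ## oracle: scan each loop by hand
  oracle_pet <- sum(loops$pets < 3)
  surv <- loops[pets >= 3]
  hit <- logical(nrow(surv))
  for (i in seq_len(nrow(surv))) {
    for (j in seq_len(nrow(bl))) {
      ov1 <- surv$chrom1[i] == bl$chrom[j] &&
        max(surv$start1[i], bl$start[j]) < min(surv$end1[i], bl$end[j])
      ov2 <- surv$chrom2[i] == bl$chrom[j] &&
        max(surv$start2[i], bl$start[j]) < min(surv$end2[i], bl$end[j])
      if (ov1 || ov2) hit[i] <- TRUE
    }
  }
  expect_equal(res$report$pet_removed, oracle_pet)
  expect_equal(res$report$blacklist_removed, sum(hit))
  expect_equal(res$report$kept, nrow(loops) - oracle_pet - sum(hit))
  expect_equal(res$report$kept, 2L)
})

test_that("classification boundaries follow open/closed span semantics", {
  ## inter-chromosomal -> TRANS
  expect_equal(classify_loops(make_loops(
    list("chr1", 0, 1000, "chr2", 0, 1000, 3)))$class, "TRANS")
  ## midpoints 1,500 and 3,500: span 2,000 <= 5,000 -> dropped
  expect_equal(classify_loops(make_loops(
    list("chr1", 1000, 2000, "chr1", 3000, 4000, 3)))$class, "DROPPED_SHORT")
  ## span exactly 5,000 is still dropped ("more than 5 kb")
  expect_equal(classify_loops(make_loops(
    list("chr1", 0, 1000, "chr1", 5000, 6000, 3)))$class, "DROPPED_SHORT")
  ## span 5,001 -> NORMAL
  expect_equal(classify_loops(make_loops(
    list("chr1", 0, 1000, "chr1", 5001, 6001, 3)))$class, "NORMAL")
  ## span exactly 2,000,000 -> ABNORMAL_CIS ("at least 2 mb")
  expect_equal(classify_loops(make_loops(
    list("chr1", 99500, 100500, "chr1", 2099500, 2100500, 3)))$class,
    "ABNORMAL_CIS")
  ## span 1,999,999 -> NORMAL
  expect_equal(classify_loops(make_loops(
    list("chr1", 99500, 100500, "chr1", 2099499, 2100499, 3)))$class,
    "NORMAL")
})

test_that("classification conserves loop counts and ignores PETs", {
  loops <- random_loops(500, seed = 9)
  cl <- classify_loops(loops)
  expect_equal(sum(table(cl$class)), nrow(loops))
  expect_setequal(unique(cl$class),
                  intersect(c("NORMAL", "ABNORMAL_CIS", "TRANS",
                              "DROPPED_SHORT"), cl$class))
  loops2 <- data.table::copy(loops)
  loops2$pets <- loops2$pets + 100L
  expect_equal(classify_loops(loops2)$class, cl$class)
})

test_that("annotate_anchors applies the TSS +/- 2.5 kb window", {
  loops <- make_loops(list("chr1", 99000, 101000, "chr1", 500000, 501000, 3))
  tss <- make_tss("GENE1", "chr1", 100000)
  ann <- annotate_anchors(loops, tss)
  p <- ann[aid == "chr1:99000-101000"]
  expect_equal(p$role, "PROMOTER")
  expect_equal(p$genes[[1]], "GENE1")
  e <- ann[aid == "chr1:500000-501000"]
  expect_equal(e$role, "ENHANCER")
  expect_length(e$genes[[1]], 0)

  ## multi-gene promoter anchor
  tss2 <- make_tss(c("GENE1", "GENE2"), "chr1", c(100000, 101500))
  ann2 <- annotate_anchors(loops, tss2)
  expect_equal(ann2[aid == "chr1:99000-101000"]$genes[[1]],
               c("GENE1", "GENE2"))
})

test_that("annotate_anchors matches a brute-force window scan", {
  set.seed(21)
  loops <- random_loops(80, seed = 21, chroms = "chr1")
  tss <- make_tss(sprintf("G%02d", 1:40), "chr1",
                  round(runif(40, 0, 5e7)))
  ann <- annotate_anchors(loops, tss, promoter_halfwidth = 2500)
  for (i in sample(nrow(ann), 25)) {
    expected <- character(0)
    for (j in seq_len(nrow(tss))) {
      ws <- max(0, tss$tss[j] - 2500)
      we <- tss$tss[j] + 2500
      if (max(ann$start[i], ws) < min(ann$end[i], we)) {
        expected <- c(expected, tss$gene[j])
      }
    }
    expect_setequal(ann$genes[[i]], unique(expected))
    expect_equal(ann$role[i],
                 if (length(expected)) "PROMOTER" else "ENHANCER")
  }
})

test_that("extract_ep_loops keeps single-promoter loops and fans out genes", {
  tss <- make_tss(c("GENE1", "GENE2", "GENE3"), "chr1",
                  c(100000, 101500, 900000))
  loops <- classify_loops(make_loops(
    list("chr1", 99000, 101000, "chr1", 500000, 501000, 7),   # P{G1,G2} - E
    list("chr1", 99000, 101000, "chr1", 899000, 901000, 4),   # P - P
    list("chr1", 500000, 501000, "chr1", 600000, 601000, 5))) # E - E
  ann <- annotate_anchors(loops, tss)
  res <- extract_ep_loops(loops, ann)
  expect_equal(res$excluded[["promoter_promoter"]], 1L)
  expect_equal(res$excluded[["enhancer_enhancer"]], 1L)
  expect_equal(nrow(res$ep_loops), 2L)  # fan-out to GENE1 and GENE2
  expect_setequal(res$ep_loops$gene, c("GENE1", "GENE2"))
  expect_equal(unique(res$ep_loops$pets), 7L)
  expect_equal(unique(res$ep_loops$e_start), 500000L)
  expect_equal(unique(res$ep_loops$class), "NORMAL")

  expect_error(extract_ep_loops(classify_loops(make_loops(
    list("chr1", 1000, 2000, "chr1", 3000, 4000, 3))), ann), "DROPPED_SHORT")
})

test_that("anchor order never changes downstream results", {
  fx <- small_fixture(seed = 13)
  tss <- fx$tss
  base <- classify_loops(fx$loops[pets >= 3])
  swapped <- data.table::copy(fx$loops[pets >= 3])
  data.table::setnames(swapped,
                       c("chrom1", "start1", "end1", "chrom2", "start2", "end2"),
                       c("chrom2", "start2", "end2", "chrom1", "start1", "end1"))
  swapped <- classify_loops(canonicalize_loops(swapped))
  expect_equal(base$class, swapped$class)
  p1 <- build_gene_profiles(
    extract_ep_loops(base[class != "DROPPED_SHORT"],
                     annotate_anchors(base, tss))$ep_loops)
  p2 <- build_gene_profiles(
    extract_ep_loops(swapped[class != "DROPPED_SHORT"],
                     annotate_anchors(swapped, tss))$ep_loops)
  expect_equal(p1, p2)
})
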