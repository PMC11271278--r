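## In-code builders for small fixtures used across the tests.

dt <- data.table::data.table

make_loops <- function(...) {
  ## each argument: c(chrom1, start1, end1, chrom2, start2, end2, pets)
  rows <- lapply(list(...), function(x) {
    dt(chrom1 = as.character(x[[1]]), start1 = as.integer(x[[2]]),
       end1 = as.integer(x[[3]]), chrom2 = as.character(x[[4]]),
       start2 = as.integer(x[[5]]), end2 = as.integer(x[[6]]),
       pets = as.integer(x[[7]]))
  })
  data.table::rbindlist(rows)
}

make_tss <- function(genes, chroms, positions, strands = "+") {
  dt(gene = genes, chrom = chroms, tss = as.integer(positions),
     strand = strands)
}

## random loop table for property tests
random_loops <- function(n, seed, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  s1 <- as.integer(round(runif(n, 0, 5e7)))
  s2 <- as.integer(round(runif(n, 0, 5e7)))
  dt(chrom1 = sample(chroms, n, TRUE), start1 = s1, end1 = s1 + 2000L,
     chrom2 = sample(chroms, n, TRUE), start2 = s2, end2 = s2 + 2000L,
     pets = sample(1:50, n, TRUE))
}

write_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## a small profile table for score-level tests
make_profile <- function(gene, al = 0, pl = 0, ac = 0, pc = 0, at = 0, pt = 0,
                         chrom = "chr1", p_start = 1000L, p_end = 3000L) {
  dt(gene = gene, p_chrom = chrom, p_start = p_start, p_end = p_end,
     anchors_local = as.integer(al), pets_local = pl,
     anchors_cis = as.integer(ac), pets_cis = pc,
     anchors_trans = as.integer(at), pets_trans = pt,
     C = as.integer(al + ac + at), I = pl + pc + pt)
}

## independent hand-coded evaluation of the enhancer-contribution formula:
## Contribution_x = log10(pets_x)*anchors_x / sum over classes of the same
oracle_contribution <- function(al, pl, ac, pc, at, pt) {
  term <- function(p, a) if (a > 0 && p > 0) log10(p) * a else 0
  tl <- term(pl, al); tc <- term(pc, ac); tt <- term(pt, at)
  tot <- tl + tc + tt
  if (tot == 0) c(local = 0, cis = 0, trans = 0)
  else c(local = tl / tot, cis = tc / tot, trans = tt / tot)
}

## independent exhaustive-scan oracle for the inflection cutoff
oracle_inflection <- function(values) {
  v <- sort(values)
  n <- length(v)
  s <- (v[n] - v[1]) / n
  best_i <- 1L
  best_f <- Inf
  for (i in seq_len(n)) {
    f <- v[i] - s * i
    if (f <= best_f) {  # ties -> largest index
      best_f <- f
      best_i <- i
    }
  }
  v[best_i]
}

small_fixture <- function(seed = 11L) {
  generate_fixture(
    fixture_config(n_genes = 60L, n_boosted = 8L, n_hijack = 2L,
                   n_decoy_lowpet = 5L, n_decoy_blacklist = 4L, seed = seed),
    dir = tempfile("fx_"))
}

run_fixture_pipeline <- function(fx, out_dir = tempfile("out_")) {
  run_pipeline(list(loops = fx$files$loops, tss = fx$files$tss,
                    blacklist = fx$files$blacklist, seg = fx$files$seg,
                    seg_sample = "SIM", out_dir = out_dir))
}
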