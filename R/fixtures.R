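## Synthetic-data generator. Emits a TSS table, hichipper-style loop BEDPE,
## blacklist BED, SEG copy-number file, and a truth table with the exact
## class-wise anchor/PET counts implanted per gene, so every pipeline stage
## can be tested against a known answer without any downloads.
##
## The stated world: a small genome of a few ~60 Mb chromosomes; several
## hundred background genes with a handful of local (5 kb - 2 Mb) E-P loops
## each and modest PET support; a minority of "boosted" genes with many more
## enhancer anchors and stronger PETs (the hockey-stick tail); and a few
## boosted genes that additionally receive clustered trans (or far-cis)
## loops from a 2 Mb donor window -- the implanted hijacking events. PETs
## are drawn from a negative binomial shifted to a minimum of 3 so the PET
## filter is exercised only by separately injected low-PET decoy loops.

#' Fixture generator configuration
#'
#' Defaults give 500 background genes, 30 boosted genes and 3 implanted
#' trans-hijacking events, with loop spans, anchor widths (2 kb) and PET
#' levels chosen to mimic hichipper loop calls at moderate sequencing depth.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes background gene count.
#' @param n_boosted genes given elevated contact and intensity (the first
#'   `n_boosted` gene ids).
#' @param n_hijack how many boosted genes receive implanted hijack events
#'   (ignored when `hijack_events` is supplied).
#' @param hijack_events optional list of events, each a list with `gene`,
#'   `donor_chrom`, `donor_center`, `n_anchors`, `pet_mu`.
#' @param bg_loop_mean mean local-loop count per background gene (>= 1).
#' @param pet_size negative-binomial size parameter for PET draws.
#' @param bg_pet_mu,boost_pet_mu,hijack_pet_mu mean PET count above the
#'   minimum of 3 for background / boosted / hijack loops.
#' @param boost_anchor_range integer range of enhancer-anchor counts for
#'   boosted genes.
#' @param hijack_anchors trans (or far-cis) donor anchors per hijack event.
#' @param n_decoy_lowpet loops injected with PETs < 3 (must be filtered).
#' @param n_decoy_blacklist loops injected with an anchor inside a
#'   blacklist interval (must be filtered).
#' @param n_blacklist blacklist intervals, placed in a reserved gene-free
#'   zone.
#' @param anchor_halfwidth anchor half-width in bp.
#' @param min_offset,max_offset local enhancer distance range from the TSS
#'   (midpoint to midpoint), kept inside the open (5 kb, 2 Mb) normal-span
#'   band.
#' @param seed integer seed; fixed seed implies identical outputs.
#' @return a `hapi_fixture_config` list.
#' @export
fixture_config <- function(n_chroms = 4L, chrom_length = 6e7,
                           n_genes = 500L, n_boosted = 30L, n_hijack = 3L,
                           hijack_events = NULL,
                           bg_loop_mean = 2.5, pet_size = 2,
                           bg_pet_mu = 3, boost_pet_mu = 25,
                           hijack_pet_mu = 30,
                           boost_anchor_range = c(15L, 25L),
                           hijack_anchors = 12L,
                           n_decoy_lowpet = 20L, n_decoy_blacklist = 10L,
                           n_blacklist = 6L, anchor_halfwidth = 1000L,
                           min_offset = 10000, max_offset = 1.8e6,
                           seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              n_boosted = as.integer(n_boosted), n_hijack = as.integer(n_hijack),
              hijack_events = hijack_events, bg_loop_mean = bg_loop_mean,
              pet_size = pet_size, bg_pet_mu = bg_pet_mu,
              boost_pet_mu = boost_pet_mu, hijack_pet_mu = hijack_pet_mu,
              boost_anchor_range = as.integer(boost_anchor_range),
              hijack_anchors = as.integer(hijack_anchors),
              n_decoy_lowpet = as.integer(n_decoy_lowpet),
              n_decoy_blacklist = as.integer(n_decoy_blacklist),
              n_blacklist = as.integer(n_blacklist),
              anchor_halfwidth = as.integer(anchor_halfwidth),
              min_offset = min_offset, max_offset = max_offset,
              seed = as.integer(seed))
  if (cfg$chrom_length < 2 * (4e6 + cfg$max_offset)) {
    stop("chrom_length too small for the configured loop spans", call. = FALSE)
  }
  if (cfg$n_boosted > cfg$n_genes || cfg$n_hijack > cfg$n_boosted) {
    stop("need n_hijack <= n_boosted <= n_genes", call. = FALSE)
  }
  if (cfg$min_offset <= 5000 + 2 * cfg$anchor_halfwidth ||
      cfg$max_offset >= 2e6) {
    stop("local offsets must stay strictly inside the (5 kb, 2 Mb) band",
         call. = FALSE)
  }
  class(cfg) <- "hapi_fixture_config"
  cfg
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## draw n enhancer-anchor midpoints on `chrom` from `sampler()`, rejecting
## any midpoint whose 2 kb anchor would touch a promoter window (so implanted
## enhancers never annotate as promoters) and enforcing distinct anchors
.sample_clear_mids <- function(n, sampler, tss_positions, clearance,
                               lo, hi, taken = numeric(0)) {
  mids <- numeric(0)
  tsssort <- sort(tss_positions)
  for (i in seq_len(n)) {
    for (try in 1:2000) {
      m <- round(sampler())
      if (m < lo || m > hi) next
      if (length(tsssort)) {
        j <- findInterval(m, tsssort)
        near <- c(if (j >= 1L) tsssort[j], if (j < length(tsssort)) tsssort[j + 1L])
        if (min(abs(near - m)) < clearance) next
      }
      if (any(abs(c(mids, taken) - m) < 10)) next
      mids <- c(mids, m)
      break
    }
    if (length(mids) < i) {
      stop("fixture generation failed to place an enhancer anchor; ",
           "configuration too dense", call. = FALSE)
    }
  }
  mids
}

.shifted_nb <- function(n, size, mu) 3L + stats::rnbinom(n, size = size, mu = mu)

#' Generate a complete synthetic fixture with ground truth
#'
#' Writes a TSS table, loop BEDPE (8 columns, PETs in column 8), blacklist
#' BED, single-sample SEG file and a truth table into `dir`. Hijack genes
#' get a copy-number segment with log2 ratio 3.2 (high copy) around their
#' TSS; one boosted non-hijack gene gets 1.5 (modest amplification); the
#' rest of the genome sits at 0.2. All outputs parse cleanly through the
#' package readers, and the truth table's class-wise counts reproduce the
#' emitted (non-decoy) loops exactly.
#'
#' @param config a [fixture_config()] object.
#' @param dir output directory (created if needed).
#' @return list with `dir`, `files` (named paths), the in-memory `tss`,
#'   `loops`, `blacklist`, `seg` and `truth` tables, and `config`.
#' @export
generate_fixture <- function(config = fixture_config(),
                             dir = tempfile("hapi_fixture_")) {
  stopifnot(inherits(config, "hapi_fixture_config"))
  .with_seed(config$seed, {
    cfg <- config
    hw <- cfg$anchor_halfwidth
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    L <- cfg$chrom_length
    gene_lo <- 4e6
    gene_hi <- L - 4e6

    genes <- data.table::data.table(
      gene = sprintf("G%04d", seq_len(cfg$n_genes)),
      chrom = sample(chroms, cfg$n_genes, replace = TRUE),
      tss = round(runif(cfg$n_genes, gene_lo, gene_hi)),
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE))
    ## keep promoter windows disjoint so every gene owns its anchor
    repeat {
      genes <- genes[order(chrom, tss)]
      clash <- genes[, c(FALSE, diff(tss) < 12000), by = chrom]$V1
      if (!any(clash)) break
      genes$tss[clash] <- round(runif(sum(clash), gene_lo, gene_hi))
    }
    genes <- genes[order(gene)]
    tss_by_chrom <- split(genes$tss, genes$chrom)

    boosted <- genes$gene[seq_len(cfg$n_boosted)]
    events <- cfg$hijack_events
    if (is.null(events)) {
      events <- lapply(seq_len(cfg$n_hijack), function(j) {
        g <- genes[gene == boosted[j]]
        donor <- chroms[(match(g$chrom, chroms) %% length(chroms)) + 1L]
        list(gene = g$gene,
             donor_chrom = donor,
             donor_center = round(runif(1, gene_lo, gene_hi)),
             n_anchors = cfg$hijack_anchors,
             pet_mu = cfg$hijack_pet_mu)
      })
    }
    hijack_genes <- vapply(events, `[[`, "", "gene")

    clearance <- 2500 + hw + 100  # promoter window + anchor half-width + slack
    loop_rows <- vector("list", cfg$n_genes + length(events) + 2L)
    truth_rows <- vector("list", cfg$n_genes)

    for (i in seq_len(cfg$n_genes)) {
      g <- genes[i]
      is_boost <- g$gene %in% boosted
      n_loc <- if (is_boost) {
        sample(seq(cfg$boost_anchor_range[1], cfg$boost_anchor_range[2]), 1L)
      } else {
        max(1L, stats::rpois(1L, cfg$bg_loop_mean))
      }
      mu <- if (is_boost) cfg$boost_pet_mu else cfg$bg_pet_mu
      sampler <- function() g$tss + sample(c(-1, 1), 1) *
        runif(1, cfg$min_offset, cfg$max_offset)
      mids <- .sample_clear_mids(n_loc, sampler, tss_by_chrom[[g$chrom]],
                                 clearance, hw, L - hw)
      pets <- .shifted_nb(n_loc, cfg$pet_size, mu)
      loop_rows[[i]] <- data.table::data.table(
        chrom1 = g$chrom, start1 = g$tss - hw, end1 = g$tss + hw,
        chrom2 = g$chrom, start2 = as.integer(mids - hw),
        end2 = as.integer(mids + hw), pets = pets)
      truth_rows[[i]] <- data.table::data.table(
        gene = g$gene, chrom = g$chrom, tss = g$tss,
        boosted = is_boost, hijack = g$gene %in% hijack_genes,
        anchors_local = n_loc, pets_local = sum(pets),
        anchors_cis = 0L, pets_cis = 0, anchors_trans = 0L, pets_trans = 0)
    }

    ## implant hijack events: clustered donor anchors in a 2 Mb window
    truth <- data.table::rbindlist(truth_rows)
    for (k in seq_along(events)) {
      ev <- events[[k]]
      g <- genes[gene == ev$gene]
      if (!nrow(g)) stop("hijack event names unknown gene ", ev$gene,
                         call. = FALSE)
      sampler <- function() runif(1, ev$donor_center - 1e6,
                                  ev$donor_center + 1e6)
      mids <- .sample_clear_mids(ev$n_anchors, sampler,
                                 tss_by_chrom[[ev$donor_chrom]],
                                 clearance, hw, L - hw)
      is_trans <- ev$donor_chrom != g$chrom
      if (!is_trans && any(abs(mids - g$tss) < 2e6 + hw)) {
        stop("cis hijack donor window too close to the target gene",
             call. = FALSE)
      }
      pets <- .shifted_nb(ev$n_anchors, cfg$pet_size, ev$pet_mu)
      loop_rows[[cfg$n_genes + k]] <- data.table::data.table(
        chrom1 = g$chrom, start1 = g$tss - hw, end1 = g$tss + hw,
        chrom2 = ev$donor_chrom, start2 = as.integer(mids - hw),
        end2 = as.integer(mids + hw), pets = pets)
      if (is_trans) {
        truth[gene == ev$gene,
              `:=`(anchors_trans = ev$n_anchors, pets_trans = sum(pets))]
      } else {
        truth[gene == ev$gene,
              `:=`(anchors_cis = ev$n_anchors, pets_cis = sum(pets))]
      }
    }

    ## blacklist intervals live in a reserved zone ([1 Mb, 2 Mb)) that no
    ## gene-derived anchor can reach
    blacklist <- data.table::data.table(
      chrom = chroms[((seq_len(cfg$n_blacklist) - 1L) %% length(chroms)) + 1L],
      start = as.integer(1e6 + (seq_len(cfg$n_blacklist) - 1L) * 50000),
      end = as.integer(1e6 + (seq_len(cfg$n_blacklist) - 1L) * 50000 + 10000))

    ## decoys: low-PET loops and blacklist-overlapping loops, both of which
    ## the filter must remove before any truth comparison
    decoy <- list()
    if (cfg$n_decoy_lowpet > 0) {
      gi <- sample(cfg$n_genes, cfg$n_decoy_lowpet, replace = TRUE)
      off <- sample(c(-1, 1), cfg$n_decoy_lowpet, TRUE) *
        runif(cfg$n_decoy_lowpet, cfg$min_offset, cfg$max_offset)
      mid <- round(genes$tss[gi] + off)
      decoy$lowpet <- data.table::data.table(
        chrom1 = genes$chrom[gi], start1 = genes$tss[gi] - hw,
        end1 = genes$tss[gi] + hw, chrom2 = genes$chrom[gi],
        start2 = as.integer(mid - hw), end2 = as.integer(mid + hw),
        pets = sample(1:2, cfg$n_decoy_lowpet, replace = TRUE))
    }
    if (cfg$n_decoy_blacklist > 0) {
      gi <- sample(cfg$n_genes, cfg$n_decoy_blacklist, replace = TRUE)
      bi <- sample(nrow(blacklist), cfg$n_decoy_blacklist, replace = TRUE)
      decoy$bl <- data.table::data.table(
        chrom1 = genes$chrom[gi], start1 = genes$tss[gi] - hw,
        end1 = genes$tss[gi] + hw, chrom2 = blacklist$chrom[bi],
        start2 = blacklist$start[bi] + 1000L,
        end2 = blacklist$start[bi] + 3000L,
        pets = .shifted_nb(cfg$n_decoy_blacklist, cfg$pet_size, cfg$bg_pet_mu))
    }

    loops <- canonicalize_loops(
      data.table::rbindlist(c(loop_rows[lengths(loop_rows) > 0], decoy)))

    ## copy number: flat 0.2 background, 3.2 around hijack TSS (high copy),
    ## 1.5 around one boosted non-hijack gene (modest amplification)
    carve <- data.table::rbindlist(list(
      if (length(hijack_genes)) {
        hj <- genes[gene %in% hijack_genes]
        data.table::data.table(chrom = hj$chrom,
                               start = pmax(0, hj$tss - 1e6),
                               end = pmin(L, hj$tss + 1e6), log2cn = 3.2)
      },
      {
        mod <- genes[gene == setdiff(boosted, hijack_genes)[1L]]
        data.table::data.table(chrom = mod$chrom,
                               start = pmax(0, mod$tss - 1e6),
                               end = pmin(L, mod$tss + 1e6), log2cn = 1.5)
      }))
    seg_rows <- list()
    for (cc in chroms) {
      cv <- carve[chrom == cc][order(start)]
      ## merge overlapping carves (first value wins)
      if (nrow(cv) > 1L) {
        keep <- rep(TRUE, nrow(cv))
        for (j in 2:nrow(cv)) if (cv$start[j] < max(cv$end[seq_len(j - 1)])) {
          keep[j] <- FALSE
        }
        cv <- cv[keep]
      }
      pos <- 0
      for (j in seq_len(nrow(cv))) {
        if (cv$start[j] > pos) {
          seg_rows[[length(seg_rows) + 1L]] <- data.table::data.table(
            sample = "SIM", chrom = cc, start = pos, end = cv$start[j],
            log2cn = 0.2)
        }
        seg_rows[[length(seg_rows) + 1L]] <- data.table::data.table(
          sample = "SIM", chrom = cc, start = cv$start[j], end = cv$end[j],
          log2cn = cv$log2cn[j])
        pos <- cv$end[j]
      }
      if (pos < L) {
        seg_rows[[length(seg_rows) + 1L]] <- data.table::data.table(
          sample = "SIM", chrom = cc, start = pos, end = L, log2cn = 0.2)
      }
    }
    seg <- data.table::rbindlist(seg_rows)

    ## analytic contributions from the truth counts (the Methods formula)
    tl <- .activity_term(truth$pets_local, truth$anchors_local)
    tc <- .activity_term(truth$pets_cis, truth$anchors_cis)
    tt <- .activity_term(truth$pets_trans, truth$anchors_trans)
    tot <- tl + tc + tt
    truth[, `:=`(C = anchors_local + anchors_cis + anchors_trans,
                 I = pets_local + pets_cis + pets_trans,
                 frac_local = ifelse(tot > 0, tl / tot, 0),
                 frac_cis = ifelse(tot > 0, tc / tot, 0),
                 frac_trans = ifelse(tot > 0, tt / tot, 0))]

    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      tss = file.path(dir, "tss.tsv"),
      loops = file.path(dir, "loops.bedpe"),
      blacklist = file.path(dir, "blacklist.bed"),
      seg = file.path(dir, "copy_number.seg"),
      truth = file.path(dir, "truth.tsv"))
    .write_table(genes, files$tss, "tss", list(seed = cfg$seed))
    writeLines(.header_line("loops", list(seed = cfg$seed)), files$loops)
    bedpe <- data.table::copy(loops)
    bedpe[, `:=`(name = sprintf("loop_%d", .I), score = pets)]
    data.table::fwrite(
      bedpe[, .(chrom1, start1, end1, chrom2, start2, end2, name, score)],
      files$loops, sep = "\t", append = TRUE, col.names = FALSE)
    writeLines(.header_line("blacklist", list(seed = cfg$seed)),
               files$blacklist)
    data.table::fwrite(blacklist, files$blacklist, sep = "\t", append = TRUE,
                       col.names = FALSE)
    seg_out <- data.table::data.table(
      Sample = seg$sample, Chromosome = seg$chrom,
      Start = format(seg$start + 1L, scientific = FALSE, trim = TRUE),
      End = format(seg$end, scientific = FALSE, trim = TRUE),
      Num_Probes = 50L, Segment_Mean = seg$log2cn)
    writeLines(.header_line("seg", list(seed = cfg$seed)), files$seg)
    data.table::fwrite(seg_out, files$seg, sep = "\t", append = TRUE,
                       col.names = TRUE)
    .write_table(truth, files$truth, "truth", list(seed = cfg$seed))

    list(dir = dir, files = files, tss = genes, loops = loops,
         blacklist = blacklist, seg = seg, truth = truth, config = cfg)
  })
}

#' Generate synthetic HiC-Pro valid pairs with a per-bin ledger
#'
#' Emulates the virtual-4C input: a fraction of pairs have one end uniform
#' in the 2 kb anchor window and the other end drawn from implanted peak
#' regions (plus uniform background); the rest are background pairs that
#' never touch the window. A ledger of qualifying-pair counts per bin,
#' computed record by record during generation, is returned as the expected
#' raw track.
#'
#' @param chrom anchor chromosome.
#' @param tss anchor TSS position.
#' @param peak_regions data.table of peak intervals (`chrom,start,end`),
#'   outside the anchor window.
#' @param n_pairs total pairs to emit.
#' @param frac_anchor fraction of pairs with one end in the anchor window.
#' @param peak_prob probability that a qualifying pair's other end falls in
#'   a peak rather than uniform background.
#' @param chrom_length chromosome length for background draws.
#' @param window anchor window width (default 2000).
#' @param bin_width bin width used for the ledger (default 10).
#' @param seed integer seed.
#' @param path output validPairs path (default: under `tempdir()`).
#' @return list with `file`, `pairs` (data.table), `ledger` (expected raw
#'   bins, `chrom,start,count`), `total`.
#' @export
generate_valid_pairs <- function(chrom, tss, peak_regions,
                                 n_pairs = 10000L, frac_anchor = 0.6,
                                 peak_prob = 0.8, chrom_length = 6e7,
                                 window = 2000L, bin_width = 10L, seed = 1L,
                                 path = tempfile("pairs_", fileext = ".validPairs")) {
  peak_regions <- data.table::as.data.table(peak_regions)
  .with_seed(seed, {
    ws <- tss - window / 2
    we <- tss + window / 2
    draw_outside <- function(cc) {
      repeat {
        p <- round(runif(1, 0, chrom_length - 1))
        if (!(cc == chrom && p >= ws && p < we)) return(p)
      }
    }
    n_anchor <- round(frac_anchor * n_pairs)
    rows <- vector("list", n_pairs)
    ledger <- new.env(parent = emptyenv())
    for (i in seq_len(n_pairs)) {
      if (i <= n_anchor) {
        a_pos <- round(runif(1, ws, we - 1))
        if (nrow(peak_regions) && runif(1) < peak_prob) {
          j <- sample(nrow(peak_regions), 1L)
          o_chrom <- peak_regions$chrom[j]
          o_pos <- round(runif(1, peak_regions$start[j],
                               peak_regions$end[j] - 1))
        } else {
          o_chrom <- chrom
          o_pos <- draw_outside(chrom)
        }
        flip <- runif(1) < 0.5
        rows[[i]] <- list(
          chrom1 = if (flip) o_chrom else chrom,
          pos1 = if (flip) o_pos else a_pos,
          chrom2 = if (flip) chrom else o_chrom,
          pos2 = if (flip) a_pos else o_pos)
        ## ledger: this pair qualifies (exactly one end in-window) unless the
        ## other end also landed in-window, which draw_outside/peaks preclude
        key <- sprintf("%s:%d", o_chrom,
                       as.integer(floor(o_pos / bin_width) * bin_width))
        ledger[[key]] <- (if (is.null(ledger[[key]])) 0L else ledger[[key]]) + 1L
      } else {
        cc1 <- chrom
        cc2 <- chrom
        rows[[i]] <- list(
          chrom1 = cc1, pos1 = draw_outside(cc1),
          chrom2 = cc2, pos2 = draw_outside(cc2))
      }
    }
    pairs <- data.table::rbindlist(rows)
    keys <- ls(ledger)
    led <- if (length(keys)) {
      parts <- data.table::tstrsplit(keys, ":", fixed = TRUE)
      data.table::data.table(chrom = parts[[1]],
                             start = as.integer(parts[[2]]),
                             count = vapply(keys, function(k) ledger[[k]], 0L))[
                               order(chrom, start)]
    } else {
      data.table::data.table(chrom = character(), start = integer(),
                             count = integer())
    }
    writeLines(.header_line("validPairs", list(seed = seed)), path)
    out <- data.table::data.table(
      id = sprintf("r%06d", seq_len(n_pairs)),
      chrom1 = pairs$chrom1, pos1 = pairs$pos1, strand1 = "+",
      chrom2 = pairs$chrom2, pos2 = pairs$pos2, strand2 = "-")
    data.table::fwrite(out, path, sep = "\t", append = TRUE,
                       col.names = FALSE)
    list(file = path, pairs = pairs, ledger = led, total = n_pairs)
  })
}
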