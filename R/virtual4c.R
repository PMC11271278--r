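## Virtual 4C: one-vs-all contact profile anchored at a promoter window,
## built from HiC-Pro valid read pairs, binned at fixed resolution and
## library-scaled to counts per million pairs.

#' Build a raw virtual-4C track
#'
#' Pairs with exactly one end inside the anchor window
#' `[tss - window/2, tss + window/2)` contribute one count to the bin
#' (of width `bin_width`, bins aligned to multiples of `bin_width`)
#' containing the other end. Pairs with both ends inside the window are
#' counted once toward the bin of the end farther from the TSS
#' (`both_in = "farther"`, default) or dropped (`both_in = "drop"`).
#' `total_pairs` records the full stream size for library scaling.
#'
#' @param pairs valid-pairs table from [read_valid_pairs()].
#' @param chrom anchor chromosome.
#' @param tss anchor TSS position (0-based).
#' @param window anchor window width in bp (default 2000; must be an even
#'   multiple of `bin_width`).
#' @param bin_width bin width in bp (default 10).
#' @param both_in policy for pairs with both ends in-window.
#' @return object of class `v4c_track`: list with `anchor`
#'   (`chrom,start,end`), `tss`, `bin_width`, `bins`
#'   (data.table `chrom,start,value`), `total_pairs`, `scaled`.
#' @export
build_v4c_track <- function(pairs, chrom, tss, window = 2000L,
                            bin_width = 10L, both_in = c("farther", "drop")) {
  both_in <- match.arg(both_in)
  pairs <- data.table::as.data.table(pairs)
  stopifnot(window > 0, bin_width > 0, window %% bin_width == 0,
            window %% 2 == 0)
  ws <- tss - window / 2
  we <- tss + window / 2
  in1 <- pairs$chrom1 == chrom & pairs$pos1 >= ws & pairs$pos1 < we
  in2 <- pairs$chrom2 == chrom & pairs$pos2 >= ws & pairs$pos2 < we
  one <- xor(in1, in2)
  both <- in1 & in2
  o_chrom <- c(ifelse(in1[one], pairs$chrom2[one], pairs$chrom1[one]),
               if (both_in == "farther" && any(both)) pairs$chrom1[both])
  o_pos <- c(ifelse(in1[one], pairs$pos2[one], pairs$pos1[one]),
             if (both_in == "farther" && any(both)) {
               d1 <- abs(pairs$pos1[both] - tss)
               d2 <- abs(pairs$pos2[both] - tss)
               ifelse(d1 >= d2, pairs$pos1[both], pairs$pos2[both])
             })
  bins <- if (length(o_pos)) {
    dt <- data.table::data.table(
      chrom = o_chrom,
      start = as.integer(floor(o_pos / bin_width) * bin_width))
    dt[, .(value = as.numeric(.N)), by = .(chrom, start)][order(chrom, start)]
  } else {
    data.table::data.table(chrom = character(), start = integer(),
                           value = numeric())
  }
  structure(list(anchor = list(chrom = chrom, start = as.integer(ws),
                               end = as.integer(we)),
                 tss = tss, bin_width = as.integer(bin_width), bins = bins,
                 total_pairs = nrow(pairs), scaled = FALSE),
            class = "v4c_track")
}

#' Scale a virtual-4C track to counts per million pairs
#'
#' Multiplies every bin by `1e6 / total_pairs`, making tracks comparable
#' across libraries of different depth (duplicating every input pair leaves
#' the scaled track unchanged).
#'
#' @param track raw `v4c_track` from [build_v4c_track()].
#' @return the scaled track (`scaled = TRUE`).
#' @export
scale_track <- function(track) {
  stopifnot(inherits(track, "v4c_track"))
  if (track$scaled) stop("track is already scaled", call. = FALSE)
  if (track$total_pairs == 0) {
    stop("cannot scale a track with total_pairs = 0", call. = FALSE)
  }
  track$bins <- data.table::copy(track$bins)
  track$bins[, value := value * 1e6 / track$total_pairs]
  track$scaled <- TRUE
  track
}

#' @export
print.v4c_track <- function(x, ...) {
  cat(sprintf("v4c_track: anchor %s:%d-%d, bin %d bp, %d non-empty bins, %s\n",
              x$anchor$chrom, x$anchor$start, x$anchor$end, x$bin_width,
              nrow(x$bins),
              if (x$scaled) "scaled (CPM)" else
                sprintf("raw (total_pairs=%d)", x$total_pairs)))
  invisible(x)
}

#' Average virtual-4C signal over top-ranked interacting regions
#'
#' Selects the top `k` regions by interaction rank (PETs with the anchor
#' promoter; ties broken by coordinate), re-centers the track on each
#' region's midpoint, and averages the signal per offset on a common grid
#' spanning the widest selected region.
#'
#' @param track a `v4c_track`.
#' @param regions data.table of intervals (`chrom,start,end`), one
#'   chromosome.
#' @param ranks numeric vector, one value per region (e.g. PET counts with
#'   the anchor promoter).
#' @param k number of top regions to average (default 50); if larger than
#'   the region count, all regions are used with a warning.
#' @return data.table with columns `offset,mean,sem`.
#' @export
average_anchor_signal <- function(track, regions, ranks, k = 50L) {
  stopifnot(inherits(track, "v4c_track"))
  regions <- data.table::as.data.table(regions)
  stopifnot(nrow(regions) > 0, length(ranks) == nrow(regions),
            data.table::uniqueN(regions$chrom) == 1L)
  if (k > nrow(regions)) {
    warning("k = ", k, " exceeds number of regions (", nrow(regions),
            "); using all")
    k <- nrow(regions)
  }
  ord <- order(-ranks, regions$start, regions$end)[seq_len(k)]
  sel <- regions[ord]
  bw <- track$bin_width
  half_bins <- ceiling(max(sel$end - sel$start) / 2 / bw)
  offsets <- seq.int(-half_bins, half_bins) * bw
  chr <- sel$chrom[1L]
  tb <- track$bins[chrom == chr]
  lookup <- function(starts) {
    v <- tb$value[match(starts, tb$start)]
    v[is.na(v)] <- 0
    v
  }
  sig <- vapply(seq_len(k), function(i) {
    mid <- floor((sel$start[i] + sel$end[i]) / 2)
    mid_bin <- floor(mid / bw) * bw
    lookup(mid_bin + offsets)
  }, numeric(length(offsets)))
  sig <- matrix(sig, nrow = length(offsets))
  data.table::data.table(
    offset = offsets,
    mean = rowMeans(sig),
    sem = apply(sig, 1L, stats::sd) / sqrt(k))
}
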