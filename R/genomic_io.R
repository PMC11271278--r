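## Readers and writers for the external formats the pipeline touches.
## Internal convention everywhere: 0-based half-open intervals, as in
## BED/BEDPE. SEG (1-based inclusive) is shifted on read.

.apply_chr_prefix <- function(chrom, chr_prefix) {
  switch(chr_prefix,
         asis  = chrom,
         add   = ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom)),
         strip = sub("^chr", "", chrom))
}

.split_data_lines <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & !grepl("^track", lines) &
                  nzchar(trimws(lines)))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = keep)
}

.parse_int <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad)) {
    stop(sprintf("line %d: malformed %s '%s' (expected an integer)",
                 lineno[bad[1]], what, x[bad[1]]), call. = FALSE)
  }
  as.integer(v)
}

#' Canonicalize loop anchor order
#'
#' Orders each loop's anchors so that anchor1 <= anchor2 by chromosome, then
#' start, then end. Idempotent; applied automatically by [read_loops()].
#'
#' @param loops data.table with columns `chrom1,start1,end1,chrom2,start2,end2`
#'   (plus any others, carried through).
#' @return the same data.table with anchors in canonical order.
#' @export
canonicalize_loops <- function(loops) {
  loops <- data.table::as.data.table(loops)
  swap <- (loops$chrom2 < loops$chrom1) |
    (loops$chrom2 == loops$chrom1 & loops$start2 < loops$start1) |
    (loops$chrom2 == loops$chrom1 & loops$start2 == loops$start1 &
       loops$end2 < loops$end1)
  if (any(swap)) {
    a <- loops[swap, .(chrom1, start1, end1)]
    loops[swap, `:=`(chrom1 = chrom2, start1 = start2, end1 = end2)]
    loops[swap, `:=`(chrom2 = a$chrom1, start2 = a$start1, end2 = a$end1)]
  }
  loops[]
}

#' Read hichipper-style BEDPE loop calls
#'
#' Expects at least 7 tab-separated columns
#' `chrom1 start1 end1 chrom2 start2 end2 ...`, with a PET-count column.
#' Files with >= 8 columns (e.g. a name column before the count, as emitted
#' by hichipper) default to column 8 for PETs; 7-column files use column 7.
#' Comment (`#`), `track` and blank lines are skipped. Anchors are returned
#' in canonical order; no filtering is performed here.
#'
#' @param path BEDPE file path.
#' @param pet_col 1-based index of the PET-count column, or `NULL` to use the
#'   default rule above.
#' @param chr_prefix `"asis"` (default), `"add"` or `"strip"`: harmonize the
#'   chromosome naming style across mixed input sources.
#' @return data.table with columns `chrom1,start1,end1,chrom2,start2,end2,pets`.
#' @export
read_loops <- function(path, pet_col = NULL,
                       chr_prefix = c("asis", "add", "strip")) {
  chr_prefix <- match.arg(chr_prefix)
  stopifnot(file.exists(path))
  d <- .split_data_lines(path)
  if (!length(d$fields)) {
    return(data.table::data.table(chrom1 = character(), start1 = integer(),
                                  end1 = integer(), chrom2 = character(),
                                  start2 = integer(), end2 = integer(),
                                  pets = integer()))
  }
  n <- lengths(d$fields)
  if (any(n < 7L)) {
    stop(sprintf("line %d: expected >= 7 tab-separated columns, found %d",
                 d$lineno[which(n < 7L)[1]], min(n)), call. = FALSE)
  }
  if (is.null(pet_col)) pet_col <- if (min(n) >= 8L) 8L else 7L
  if (pet_col > min(n)) {
    stop(sprintf("PET column %d not present in all rows (min %d columns)",
                 pet_col, min(n)), call. = FALSE)
  }
  col <- function(i) vapply(d$fields, `[[`, "", i)
  dt <- data.table::data.table(
    chrom1 = .apply_chr_prefix(col(1L), chr_prefix),
    start1 = .parse_int(col(2L), d$lineno, "start1"),
    end1   = .parse_int(col(3L), d$lineno, "end1"),
    chrom2 = .apply_chr_prefix(col(4L), chr_prefix),
    start2 = .parse_int(col(5L), d$lineno, "start2"),
    end2   = .parse_int(col(6L), d$lineno, "end2"),
    pets   = .parse_int(col(pet_col), d$lineno, "PET count"))
  bad <- which(dt$start1 >= dt$end1 | dt$start2 >= dt$end2 |
                 dt$start1 < 0L | dt$start2 < 0L)
  if (length(bad)) {
    stop(sprintf("line %d: invalid interval (need 0 <= start < end)",
                 d$lineno[bad[1]]), call. = FALSE)
  }
  if (any(dt$pets < 1L)) {
    stop(sprintf("line %d: PET count must be >= 1",
                 d$lineno[which(dt$pets < 1L)[1]]), call. = FALSE)
  }
  canonicalize_loops(dt)
}

#' Read a TSS annotation table
#'
#' Tab-separated table of transcription start sites, one row per
#' (gene, TSS); duplicated (gene, TSS) rows are collapsed. Genes may carry
#' several TSS records.
#'
#' @param path file path.
#' @param col_map named integer vector giving the 1-based columns of
#'   `gene`, `chrom`, `tss` and `strand`.
#' @inheritParams read_loops
#' @return data.table with columns `gene,chrom,tss,strand`.
#' @export
read_tss <- function(path,
                     col_map = c(gene = 1L, chrom = 2L, tss = 3L, strand = 4L),
                     chr_prefix = c("asis", "add", "strip")) {
  chr_prefix <- match.arg(chr_prefix)
  stopifnot(file.exists(path),
            all(c("gene", "chrom", "tss", "strand") %in% names(col_map)))
  d <- .split_data_lines(path)
  if (!length(d$fields)) {
    return(data.table::data.table(gene = character(), chrom = character(),
                                  tss = integer(), strand = character()))
  }
  ## skip a header row if the tss field is not numeric there
  first_tss <- d$fields[[1]][[col_map[["tss"]]]]
  if (is.na(suppressWarnings(as.numeric(first_tss)))) {
    d$fields <- d$fields[-1]
    d$lineno <- d$lineno[-1]
  }
  col <- function(i) vapply(d$fields, `[[`, "", i)
  dt <- data.table::data.table(
    gene   = col(col_map[["gene"]]),
    chrom  = .apply_chr_prefix(col(col_map[["chrom"]]), chr_prefix),
    tss    = .parse_int(col(col_map[["tss"]]), d$lineno, "tss"),
    strand = col(col_map[["strand"]]))
  if (any(dt$tss < 0L)) {
    stop(sprintf("line %d: negative TSS position",
                 d$lineno[which(dt$tss < 0L)[1]]), call. = FALSE)
  }
  unique(dt, by = c("gene", "chrom", "tss"))
}

#' Read a BED file of intervals (e.g. the ENCODE blacklist)
#'
#' @param path BED file path (>= 3 columns).
#' @inheritParams read_loops
#' @return data.table with columns `chrom,start,end` (0-based half-open).
#' @export
read_bed <- function(path, chr_prefix = c("asis", "add", "strip")) {
  chr_prefix <- match.arg(chr_prefix)
  d <- .split_data_lines(path)
  if (!length(d$fields)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  col <- function(i) vapply(d$fields, `[[`, "", i)
  dt <- data.table::data.table(
    chrom = .apply_chr_prefix(col(1L), chr_prefix),
    start = .parse_int(col(2L), d$lineno, "start"),
    end   = .parse_int(col(3L), d$lineno, "end"))
  if (any(dt$start >= dt$end)) {
    stop(sprintf("line %d: invalid interval",
                 d$lineno[which(dt$start >= dt$end)[1]]), call. = FALSE)
  }
  dt
}

#' Read SEG-format copy-number segments
#'
#' Standard SEG columns: sample, chromosome, start, end, probe count,
#' segment mean. The segment mean is interpreted as a log2 copy-number
#' ratio. SEG coordinates are 1-based inclusive and are converted to the
#' internal 0-based half-open convention. Multi-sample files must be
#' narrowed with `sample` before single-sample use; overlapping segments
#' within one sample are an input error.
#'
#' @param path SEG file path.
#' @param sample optional sample identifier to select.
#' @inheritParams read_loops
#' @return data.table with columns `sample,chrom,start,end,log2cn`.
#' @export
read_cn_segments <- function(path, sample = NULL,
                             chr_prefix = c("asis", "add", "strip")) {
  chr_prefix <- match.arg(chr_prefix)
  d <- .split_data_lines(path)
  if (!length(d$fields)) {
    return(data.table::data.table(sample = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  log2cn = numeric()))
  }
  if (is.na(suppressWarnings(as.numeric(d$fields[[1]][[3]])))) {
    d$fields <- d$fields[-1]  # header row
    d$lineno <- d$lineno[-1]
  }
  col <- function(i) vapply(d$fields, `[[`, "", i)
  dt <- data.table::data.table(
    sample = col(1L),
    chrom  = .apply_chr_prefix(col(2L), chr_prefix),
    start  = .parse_int(col(3L), d$lineno, "start") - 1L,  # 1-based -> 0-based
    end    = .parse_int(col(4L), d$lineno, "end"),
    log2cn = as.numeric(col(6L)))
  if (anyNA(dt$log2cn)) {
    stop(sprintf("line %d: malformed segment mean",
                 d$lineno[which(is.na(dt$log2cn))[1]]), call. = FALSE)
  }
  if (!is.null(sample)) {
    mask <- dt$sample == sample  # masked outside: 'sample' is also a column
    dt <- dt[mask]
    if (!nrow(dt)) stop("sample '", sample, "' not found in SEG file",
                        call. = FALSE)
  }
  .validate_segments(dt)
  dt[order(sample, chrom, start)]
}

.validate_segments <- function(dt) {
  if (!nrow(dt)) return(invisible(TRUE))
  bad <- dt[order(start),
            .(ov = any(start[-1] < end[-.N])), by = .(sample, chrom)]
  bad <- bad[bad$ov == TRUE]
  if (nrow(bad)) {
    stop("overlapping copy-number segments within one sample: ",
         paste(sprintf("%s/%s", bad$sample, bad$chrom), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read HiC-Pro validPairs
#'
#' Consumes the text validPairs output of HiC-Pro
#' (`readID chrom1 pos1 strand1 chrom2 pos2 strand2 ...`); only chromosomes
#' and positions are used. The returned table carries the total pair count
#' (used for library-size scaling) as attribute `total_pairs`.
#'
#' @param path validPairs file path.
#' @return data.table with columns `chrom1,pos1,chrom2,pos2`.
#' @export
read_valid_pairs <- function(path) {
  d <- .split_data_lines(path)
  if (!length(d$fields)) {
    out <- data.table::data.table(chrom1 = character(), pos1 = integer(),
                                  chrom2 = character(), pos2 = integer())
    data.table::setattr(out, "total_pairs", 0L)
    return(out)
  }
  n <- lengths(d$fields)
  if (any(n < 7L)) {
    stop(sprintf("line %d: truncated validPairs record (%d fields, need >= 7)",
                 d$lineno[which(n < 7L)[1]], min(n)), call. = FALSE)
  }
  col <- function(i) vapply(d$fields, `[[`, "", i)
  dt <- data.table::data.table(
    chrom1 = col(2L),
    pos1   = .parse_int(col(3L), d$lineno, "pos1"),
    chrom2 = col(5L),
    pos2   = .parse_int(col(6L), d$lineno, "pos2"))
  if (any(dt$pos1 < 0L | dt$pos2 < 0L)) {
    stop("negative mapped position in validPairs input", call. = FALSE)
  }
  data.table::setattr(dt, "total_pairs", nrow(dt))
  dt
}

#' Write a virtual-4C track as bedgraph
#'
#' Four columns (chrom, bin start, bin end, value) at the track's bin width;
#' zero-valued bins are omitted. A provenance comment line is written first.
#'
#' @param track a `v4c_track` object from [build_v4c_track()] or
#'   [scale_track()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "v4c_track"))
  bins <- track$bins[value != 0]
  bins <- bins[order(chrom, start)]
  if (nrow(bins) && any(bins[, is.unsorted(start), by = chrom]$V1)) {
    stop("internal error: unsorted bins", call. = FALSE)  # unreachable guard
  }
  hdr <- .header_line("bedgraph", list(
    anchor = sprintf("%s:%d-%d", track$anchor$chrom, track$anchor$start,
                     track$anchor$end),
    bin_width = track$bin_width, total_pairs = track$total_pairs,
    scaled = track$scaled))
  writeLines(hdr, path)
  if (nrow(bins)) {
    out <- data.table::data.table(chrom = bins$chrom, start = bins$start,
                                  end = bins$start + track$bin_width,
                                  value = bins$value)
    data.table::fwrite(out, path, sep = "\t", append = TRUE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a bedgraph file
#'
#' Counterpart of [write_bedgraph()]; comment and `track` lines are skipped.
#'
#' @param path bedgraph path.
#' @return data.table with columns `chrom,start,end,value`.
#' @export
read_bedgraph <- function(path) {
  d <- .split_data_lines(path)
  if (!length(d$fields)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), value = numeric()))
  }
  col <- function(i) vapply(d$fields, `[[`, "", i)
  data.table::data.table(
    chrom = col(1L),
    start = .parse_int(col(2L), d$lineno, "start"),
    end   = .parse_int(col(3L), d$lineno, "end"),
    value = as.numeric(col(4L)))
}
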