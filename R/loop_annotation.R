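## Loop filtering, span classification, and promoter/enhancer annotation.
##
## Loop classes follow the three-way grouping used throughout: NORMAL
## (intra-chromosomal, span strictly between 5 kb and 2 Mb), ABNORMAL_CIS
## (intra-chromosomal, span >= 2 Mb), TRANS (inter-chromosomal). Spans at or
## below the minimum are self-ligation-scale artifacts and are DROPPED_SHORT.

.anchor_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Filter loops by PET support and blacklist overlap
#'
#' Removes loops with fewer than `min_pets` paired-end tags, then removes
#' loops with either anchor overlapping (>= 1 bp) a blacklist interval.
#' The report accounts for every input loop: `pet_removed + blacklist_removed
#' + kept` equals the input count.
#'
#' @param loops loop data.table as returned by [read_loops()].
#' @param blacklist data.table of intervals (`chrom,start,end`) or `NULL`.
#' @param min_pets minimum PET count (default 3).
#' @return list with `kept` (filtered loops) and `report`
#'   (`pet_removed`, `blacklist_removed`, `kept`).
#' @export
filter_loops <- function(loops, blacklist = NULL, min_pets = 3L) {
  loops <- data.table::as.data.table(loops)
  pet_ok <- loops$pets >= min_pets
  surv <- loops[pet_ok]
  if (nrow(surv)) {
    bl_hit <- .overlaps_any0(surv$chrom1, surv$start1, surv$end1, blacklist) |
      .overlaps_any0(surv$chrom2, surv$start2, surv$end2, blacklist)
  } else {
    bl_hit <- logical(0)
  }
  kept <- surv[!bl_hit]
  list(kept = kept,
       report = list(pet_removed = sum(!pet_ok),
                     blacklist_removed = sum(bl_hit),
                     kept = nrow(kept)))
}

#' Classify loops by genomic span
#'
#' Inter-chromosomal loops are `TRANS`. For intra-chromosomal loops the span
#' is the distance between the two anchor midpoints: spans strictly between
#' `min_span` and `max_normal_span` are `NORMAL`; spans of at least
#' `max_normal_span` are `ABNORMAL_CIS`; spans at or below `min_span` are
#' `DROPPED_SHORT`. Classification depends only on the anchors, never on
#' PET counts.
#'
#' @param loops loop data.table.
#' @param min_span loops must span more than this many bp (default 5000).
#' @param max_normal_span spans at least this large are abnormal cis
#'   (default 2e6, the upper bound of typical TADs).
#' @return the loops with an added `class` column.
#' @export
classify_loops <- function(loops, min_span = 5000, max_normal_span = 2e6) {
  loops <- data.table::as.data.table(loops)
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  span <- abs(mid2 - mid1)
  cls <- rep("NORMAL", nrow(loops))
  cls[span >= max_normal_span] <- "ABNORMAL_CIS"
  cls[span <= min_span] <- "DROPPED_SHORT"
  cls[loops$chrom1 != loops$chrom2] <- "TRANS"
  loops$class <- cls
  loops[]
}

#' Annotate loop anchors as promoters or enhancers
#'
#' An anchor is a promoter for every gene with a TSS whose window
#' `[tss - halfwidth, tss + halfwidth)` overlaps the anchor by >= 1 bp;
#' anchors touching no promoter window are enhancers. One anchor can be a
#' promoter for several genes. The role is anchor-global: a promoter anchor
#' never doubles as an enhancer for another gene.
#'
#' @param loops loop data.table (both anchors are collected).
#' @param tss TSS table from [read_tss()].
#' @param promoter_halfwidth half-width of the promoter window in bp
#'   (default 2500, i.e. TSS +/- 2.5 kb).
#' @return data.table of distinct anchors with columns
#'   `chrom,start,end,aid,role,genes` (`genes` is a list column of gene
#'   symbols, empty for enhancers).
#' @export
annotate_anchors <- function(loops, tss, promoter_halfwidth = 2500) {
  loops <- data.table::as.data.table(loops)
  stopifnot(nrow(tss) > 0)
  anchors <- unique(rbind(
    loops[, .(chrom = chrom1, start = start1, end = end1)],
    loops[, .(chrom = chrom2, start = start2, end = end2)]))
  if (!nrow(anchors)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), aid = character(),
                                  role = character(), genes = list()))
  }
  win_start <- pmax(0L, tss$tss - as.integer(promoter_halfwidth))
  win_end <- tss$tss + as.integer(promoter_halfwidth)
  qa <- .gr0(anchors$chrom, anchors$start, anchors$end)
  sw <- .gr0(tss$chrom, win_start, win_end)
  lev <- union(GenomeInfoDb::seqlevels(qa), GenomeInfoDb::seqlevels(sw))
  GenomeInfoDb::seqlevels(qa) <- lev
  GenomeInfoDb::seqlevels(sw) <- lev
  hits <- GenomicRanges::findOverlaps(qa, sw)
  gene_sets <- vector("list", nrow(anchors))
  if (length(hits)) {
    hit_dt <- data.table::data.table(a = S4Vectors::queryHits(hits),
                                     gene = tss$gene[S4Vectors::subjectHits(hits)])
    hit_dt <- unique(hit_dt)
    agg <- hit_dt[, .(genes = list(sort(unique(gene)))), by = a]
    gene_sets[agg$a] <- agg$genes
  }
  empty <- vapply(gene_sets, is.null, TRUE)
  gene_sets[empty] <- list(character(0))
  anchors$aid <- .anchor_id(anchors$chrom, anchors$start, anchors$end)
  anchors$role <- ifelse(lengths(gene_sets) > 0L, "PROMOTER", "ENHANCER")
  anchors$genes <- gene_sets
  anchors[]
}

#' Extract enhancer-promoter loops
#'
#' A loop with a promoter in exactly one anchor is an enhancer-promoter
#' (E-P) loop; it fans out to one record per gene annotated on the promoter
#' anchor. Promoter-promoter and enhancer-enhancer loops are excluded and
#' counted. Loops must already be classified and contain no `DROPPED_SHORT`
#' class.
#'
#' @param loops classified loop data.table (see [classify_loops()]).
#' @param annotations anchor annotation from [annotate_anchors()].
#' @return list with `ep_loops` (data.table: `gene`, promoter anchor
#'   `p_chrom,p_start,p_end`, enhancer anchor `e_chrom,e_start,e_end`,
#'   `pets`, `class`) and `excluded`
#'   (named counts: `promoter_promoter`, `enhancer_enhancer`).
#' @export
extract_ep_loops <- function(loops, annotations) {
  loops <- data.table::as.data.table(loops)
  if (!"class" %in% names(loops)) {
    stop("loops must be classified first (see classify_loops())", call. = FALSE)
  }
  if (any(loops$class == "DROPPED_SHORT")) {
    stop("DROPPED_SHORT loops must be removed before E-P extraction",
         call. = FALSE)
  }
  empty <- data.table::data.table(
    gene = character(), p_chrom = character(), p_start = integer(),
    p_end = integer(), e_chrom = character(), e_start = integer(),
    e_end = integer(), pets = integer(), class = character())
  if (!nrow(loops)) {
    return(list(ep_loops = empty,
                excluded = c(promoter_promoter = 0L, enhancer_enhancer = 0L)))
  }
  aid1 <- .anchor_id(loops$chrom1, loops$start1, loops$end1)
  aid2 <- .anchor_id(loops$chrom2, loops$start2, loops$end2)
  idx1 <- match(aid1, annotations$aid)
  idx2 <- match(aid2, annotations$aid)
  if (anyNA(idx1) || anyNA(idx2)) {
    stop("internal error: loop anchor missing from annotations", call. = FALSE)
  }
  p1 <- annotations$role[idx1] == "PROMOTER"
  p2 <- annotations$role[idx2] == "PROMOTER"
  pp <- p1 & p2
  ee <- !p1 & !p2
  ep <- xor(p1, p2)
  rows <- which(ep)
  if (length(rows)) {
    prom_idx <- ifelse(p1[rows], idx1[rows], idx2[rows])
    gsets <- annotations$genes[prom_idx]
    nrep <- lengths(gsets)
    src <- rep(rows, nrep)
    prom_first <- rep(p1[rows], nrep)
    ep_dt <- data.table::data.table(
      gene = unlist(gsets),
      p_chrom = ifelse(prom_first, loops$chrom1[src], loops$chrom2[src]),
      p_start = ifelse(prom_first, loops$start1[src], loops$start2[src]),
      p_end   = ifelse(prom_first, loops$end1[src], loops$end2[src]),
      e_chrom = ifelse(prom_first, loops$chrom2[src], loops$chrom1[src]),
      e_start = ifelse(prom_first, loops$start2[src], loops$start1[src]),
      e_end   = ifelse(prom_first, loops$end2[src], loops$end1[src]),
      pets = loops$pets[src],
      class = loops$class[src])
  } else {
    ep_dt <- empty
  }
  list(ep_loops = ep_dt,
       excluded = c(promoter_promoter = sum(pp), enhancer_enhancer = sum(ee)))
}
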