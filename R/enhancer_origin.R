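## Where does each gene's enhancer activity come from? The contribution of
## each loop class is log10(summed PETs) * distinct enhancer anchors; the
## three class terms are normalized to fractions. Genes with more than 25%
## of activity in trans or in abnormal cis are enhancer-hijacking candidates.

.activity_term <- function(pets, anchors) {
  ifelse(anchors > 0 & pets > 0, log10(pets) * anchors, 0)
}

#' Enhancer-contribution fractions per gene
#'
#' For each loop class c in \{local, cis, trans\} the activity term is
#' `log10(pets_c) * anchors_c` (0 when the class is empty); fractions are the
#' terms normalized by their sum (all 0 when total activity is 0). The
#' minimum-PET loop filter guarantees `pets_c >= 3` whenever `anchors_c >= 1`,
#' so non-empty terms are strictly positive and no pseudocount is needed.
#' Hijack flags use a strict inequality ("over 25%").
#'
#' @param profiles gene profiles from [build_gene_profiles()].
#' @param threshold hijack fraction threshold (default 0.25, strict).
#' @return data.table with per-gene columns `gene,p_chrom,p_start,p_end,
#'   term_local,term_cis,term_trans,frac_local,frac_cis,frac_trans,
#'   is_trans_hijack,is_cis_hijack,log2cn,high_copy` (`log2cn` is `NA` until
#'   [attach_copy_number()] fills it).
#' @export
contribution <- function(profiles, threshold = 0.25) {
  p <- data.table::as.data.table(profiles)
  term_local <- .activity_term(p$pets_local, p$anchors_local)
  term_cis <- .activity_term(p$pets_cis, p$anchors_cis)
  term_trans <- .activity_term(p$pets_trans, p$anchors_trans)
  tot <- term_local + term_cis + term_trans
  safe_frac <- function(x) ifelse(tot > 0, x / tot, 0)
  data.table::data.table(
    gene = p$gene, p_chrom = p$p_chrom, p_start = p$p_start, p_end = p$p_end,
    term_local = term_local, term_cis = term_cis, term_trans = term_trans,
    frac_local = safe_frac(term_local),
    frac_cis = safe_frac(term_cis),
    frac_trans = safe_frac(term_trans),
    is_trans_hijack = safe_frac(term_trans) > threshold,
    is_cis_hijack = safe_frac(term_cis) > threshold,
    log2cn = NA_real_, high_copy = FALSE)
}

#' Call enhancer-hijacking candidate genes
#'
#' Candidates are HAPI genes with over `threshold` of their enhancer
#' activity contributed in trans or in abnormal cis; each is labeled
#' `trans`, `cis` or `both` and the table is sorted by the larger of the two
#' fractions, descending. The candidate set is always a subset of the HAPI
#' set.
#'
#' @param records contribution records from [contribution()].
#' @param hapi HAPI calls from [call_hapi_genes()].
#' @param threshold hijack fraction threshold (default 0.25, strict).
#' @return data.table of candidates: `gene,C,I,frac_local,frac_cis,
#'   frac_trans,label,log2cn,high_copy`.
#' @export
call_hijacking <- function(records, hapi, threshold = 0.25) {
  records <- data.table::as.data.table(records)
  hapi <- data.table::as.data.table(hapi)
  m <- merge(records, hapi[, .(gene, C, I, is_hapi)], by = "gene")
  cand <- m[is_hapi & (frac_trans > threshold | frac_cis > threshold)]
  if (!nrow(cand)) {
    return(data.table::data.table(
      gene = character(), C = integer(), I = numeric(),
      frac_local = numeric(), frac_cis = numeric(), frac_trans = numeric(),
      label = character(), log2cn = numeric(), high_copy = logical()))
  }
  cand[, label := data.table::fifelse(
    frac_trans > threshold & frac_cis > threshold, "both",
    data.table::fifelse(frac_trans > threshold, "trans", "cis"))]
  cand[, rankkey := pmax(frac_trans, frac_cis)]
  out <- cand[order(-rankkey, gene),
              .(gene, C, I, frac_local, frac_cis, frac_trans, label,
                log2cn, high_copy)]
  out[]
}

#' Partition a gene's enhancer activity by donor locus
#'
#' Splits the gene's enhancer anchors into "own" enhancers (cis, midpoint
#' within `window` of the gene's primary promoter midpoint), "donor"
#' enhancers (midpoint within `window` of a reference promoter, e.g. the MYC
#' promoter on a shared amplicon), and "other" enhancers. Own takes
#' precedence over donor when both apply. Fractions use the same
#' `log10(summed PETs) * distinct anchors` weighting per category.
#'
#' @param gene gene symbol present in `ep_loops`.
#' @param ep_loops E-P loop table from [extract_ep_loops()].
#' @param reference_promoter list or vector with `chrom`, `start`, `end`
#'   (0-based half-open) of the donor reference promoter anchor.
#' @param window distance cutoff in bp from a promoter midpoint
#'   (default 2e6).
#' @return one-row data.table: `gene,n_own,n_donor,n_other,frac_own,
#'   frac_donor,frac_other`.
#' @export
partition_by_locus <- function(gene, ep_loops, reference_promoter,
                               window = 2e6) {
  ep <- data.table::as.data.table(ep_loops)
  g <- gene
  sub <- ep[ep$gene == g]
  if (!nrow(sub)) stop("gene '", g, "' has no enhancer-promoter loops",
                       call. = FALSE)
  prim <- .primary_promoter(sub)
  sub <- merge(sub, prim, by = c("gene", "p_chrom", "p_start", "p_end"))
  pmid <- (prim$p_start + prim$p_end) / 2
  ref <- as.list(reference_promoter)
  rmid <- (as.numeric(ref$start) + as.numeric(ref$end)) / 2
  emid <- (sub$e_start + sub$e_end) / 2
  own <- sub$e_chrom == prim$p_chrom & abs(emid - pmid) <= window
  donor <- !own & sub$e_chrom == ref$chrom & abs(emid - rmid) <= window
  cat <- ifelse(own, "own", ifelse(donor, "donor", "other"))
  sub[, aid := .anchor_id(e_chrom, e_start, e_end)]
  term <- numeric(3)
  names(term) <- c("own", "donor", "other")
  nanch <- integer(3)
  names(nanch) <- names(term)
  for (cc in names(term)) {
    rows <- cat == cc
    if (any(rows)) {
      nanch[cc] <- data.table::uniqueN(sub$aid[rows])
      term[cc] <- .activity_term(sum(sub$pets[rows]), nanch[cc])
    }
  }
  tot <- sum(term)
  frac <- if (tot > 0) term / tot else term * 0
  data.table::data.table(
    gene = g, n_own = nanch[["own"]], n_donor = nanch[["donor"]],
    n_other = nanch[["other"]], frac_own = frac[["own"]],
    frac_donor = frac[["donor"]], frac_other = frac[["other"]])
}

#' Annotate contribution records with copy number
#'
#' Sets `log2cn` to the segment mean of the copy-number segment containing
#' the gene's primary TSS (the TSS inside the primary promoter anchor when
#' one is recorded, otherwise the gene's smallest-coordinate TSS), and flags
#' `high_copy` when `log2cn > 2`. Genes whose TSS falls in a coverage gap
#' keep `log2cn = NA` and `high_copy = FALSE`.
#'
#' @param records contribution records from [contribution()].
#' @param segments single-sample segment table from [read_cn_segments()].
#' @param tss TSS table from [read_tss()].
#' @return the records with `log2cn` and `high_copy` filled.
#' @export
attach_copy_number <- function(records, segments, tss) {
  records <- data.table::copy(data.table::as.data.table(records))
  segments <- data.table::as.data.table(segments)
  tss <- data.table::as.data.table(tss)
  if ("sample" %in% names(segments) &&
      data.table::uniqueN(segments$sample) > 1L) {
    stop("segments must come from a single sample; use read_cn_segments(sample=)",
         call. = FALSE)
  }
  pick_tss <- function(g, p_chrom, p_start, p_end) {
    mask <- tss$gene == g  # masked outside: 'tss' is also a column name
    cand <- tss[mask]
    if (!nrow(cand)) return(list(chrom = NA_character_, pos = NA_integer_))
    if (!is.na(p_chrom)) {
      inside <- cand$chrom == p_chrom & cand$tss >= p_start & cand$tss < p_end
      if (any(inside)) cand <- cand[inside]
    }
    cand <- cand[order(chrom, tss)][1L]
    list(chrom = cand$chrom, pos = cand$tss)
  }
  cn_vals <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    ts <- pick_tss(records$gene[i], records$p_chrom[i],
                   records$p_start[i], records$p_end[i])
    if (is.na(ts$pos)) next
    hit <- segments[segments$chrom == ts$chrom & segments$start <= ts$pos &
                      ts$pos < segments$end]
    if (nrow(hit)) cn_vals[i] <- hit$log2cn[1L]
  }
  records[, log2cn := cn_vals]
  records[, high_copy := !is.na(log2cn) & log2cn > 2]
  records[]
}

#' Circos-style link table for candidate genes
#'
#' One row per E-P loop of each candidate gene (promoter anchor, enhancer
#' anchor, PETs, class), suitable for chord/arc plotting of hijacked
#' enhancer origins.
#'
#' @param candidates candidate table from [call_hijacking()].
#' @param ep_loops E-P loop table from [extract_ep_loops()].
#' @return data.table of links.
#' @export
candidate_links <- function(candidates, ep_loops) {
  ep <- data.table::as.data.table(ep_loops)
  ep[ep$gene %in% candidates$gene,
     .(gene, p_chrom, p_start, p_end, e_chrom, e_start, e_end, pets, class)]
}
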