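## Per-gene aggregation of E-P loops into the two HAPI scores, and the
## hockey-stick inflection-point cutoffs that define HAPI genes.

.CLASS_KEY <- c(NORMAL = "local", ABNORMAL_CIS = "cis", TRANS = "trans")

## pick, per gene, the promoter anchor with the largest summed PETs;
## ties go to the 5'-most anchor (smallest chrom, then start)
.primary_promoter <- function(ep) {
  ptot <- ep[, .(tot = sum(pets)), by = .(gene, p_chrom, p_start, p_end)]
  data.table::setorder(ptot, gene, -tot, p_chrom, p_start, p_end)
  ptot[, .SD[1L], by = gene][, .(gene, p_chrom, p_start, p_end)]
}

#' Aggregate enhancer-promoter loops into per-gene profiles
#'
#' For genes with several promoter anchors only the primary anchor -- the
#' one with the most PETs stemming from it -- is used. Within each loop
#' class (`local` = NORMAL, `cis` = ABNORMAL_CIS, `trans` = TRANS), distinct
#' enhancer anchors are counted once and PETs are summed over loops. The
#' enhancer contact value `C` is the total number of distinct enhancer
#' anchors; the interaction intensity `I` is the total PET sum.
#'
#' @param ep_loops E-P loop table from [extract_ep_loops()].
#' @return data.table with one row per gene: `gene`, primary promoter
#'   (`p_chrom,p_start,p_end`), `anchors_local,pets_local,anchors_cis,
#'   pets_cis,anchors_trans,pets_trans`, `C`, `I`.
#' @export
build_gene_profiles <- function(ep_loops) {
  ep <- data.table::as.data.table(ep_loops)
  empty <- data.table::data.table(
    gene = character(), p_chrom = character(), p_start = integer(),
    p_end = integer(), anchors_local = integer(), pets_local = numeric(),
    anchors_cis = integer(), pets_cis = numeric(), anchors_trans = integer(),
    pets_trans = numeric(), C = integer(), I = numeric())
  if (!nrow(ep)) return(empty)
  prim <- .primary_promoter(ep)
  sub <- merge(ep, prim, by = c("gene", "p_chrom", "p_start", "p_end"))
  sub[, aid := .anchor_id(e_chrom, e_start, e_end)]
  agg <- sub[, .(anchors = data.table::uniqueN(aid), pets = sum(pets)),
             by = .(gene, class)]
  agg[, cls := .CLASS_KEY[class]]
  wide <- data.table::dcast(agg, gene ~ cls,
                            value.var = c("anchors", "pets"), fill = 0)
  for (cl in c("local", "cis", "trans")) {
    for (pref in c("anchors_", "pets_")) {
      nm <- paste0(pref, cl)
      if (!nm %in% names(wide)) wide[, (nm) := 0]
    }
  }
  out <- merge(prim, wide, by = "gene")
  out[, `:=`(C = as.integer(anchors_local + anchors_cis + anchors_trans),
             I = pets_local + pets_cis + pets_trans)]
  data.table::setcolorder(out, names(empty))
  out[order(gene)][]
}

#' Hockey-stick inflection-point cutoff
#'
#' Values are sorted ascending into a curve `v_1..v_N`. A line with slope
#' `s = (max - min) / N` is translated until it is tangent to the curve from
#' below; the cutoff is the curve value at the tangency point, i.e. `v_k`
#' with `k = argmin_i (v_i - s * i)`. Ties are broken toward the largest
#' index (the more stringent cutoff). If all values are equal the cutoff is
#' that common value. This is the standard discrete realization of the
#' ranked-curve construction used to call super-enhancers.
#'
#' @param values non-empty numeric vector of non-negative scores.
#' @return the cutoff value.
#' @export
inflection_cutoff <- function(values) {
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  v <- sort(values)
  n <- length(v)
  s <- (v[n] - v[1]) / n
  f <- v - s * seq_len(n)
  k <- max(which(f == min(f)))
  v[k]
}

#' Call HAPI genes from gene profiles
#'
#' Computes the inflection-point cutoff over all enhancer contact values and,
#' separately, over all interaction intensities; genes with both scores
#' greater than or equal to their respective cutoffs are HAPI genes.
#'
#' @param profiles gene profiles from [build_gene_profiles()] (>= 2 rows).
#' @return data.table sorted by `I` descending with columns
#'   `gene,p_chrom,p_start,p_end,C,I,cutoff_C,cutoff_I,is_hapi`.
#' @export
call_hapi_genes <- function(profiles) {
  profiles <- data.table::as.data.table(profiles)
  if (nrow(profiles) < 2L) {
    stop("need at least 2 gene profiles to derive cutoffs", call. = FALSE)
  }
  cut_c <- inflection_cutoff(profiles$C)
  cut_i <- inflection_cutoff(profiles$I)
  out <- profiles[, .(gene, p_chrom, p_start, p_end, C, I,
                      cutoff_C = cut_c, cutoff_I = cut_i,
                      is_hapi = C >= cut_c & I >= cut_i)]
  out[order(-I, gene)][]
}

#' Ranked hockey-stick plot data
#'
#' Convenience export of the two ranked score curves (rank ascending,
#' value), as plotted to visualize the inflection cutoffs.
#'
#' @param profiles gene profiles from [build_gene_profiles()].
#' @return list of two data.tables (`contact`, `intensity`) with columns
#'   `rank,gene,value`.
#' @export
hockey_stick_data <- function(profiles) {
  profiles <- data.table::as.data.table(profiles)
  mk <- function(col) {
    o <- order(profiles[[col]], profiles$gene)
    data.table::data.table(rank = seq_len(nrow(profiles)),
                           gene = profiles$gene[o],
                           value = profiles[[col]][o])
  }
  list(contact = mk("C"), intensity = mk("I"))
}
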