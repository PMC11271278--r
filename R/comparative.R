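## Multi-sample comparison: interaction-score matrix over HAPI genes and
## Spearman-correlation clustering of samples.

#' Interaction score
#'
#' `score = log10(I) * C`, combining a gene's interaction intensity `I`
#' (summed PETs) and enhancer contact value `C` into one number used for
#' cross-sample clustering.
#'
#' @param I interaction intensity (>= 1).
#' @param C enhancer contact value.
#' @return numeric score(s).
#' @export
interaction_score <- function(I, C) {
  if (any(I < 1)) stop("interaction intensity must be >= 1", call. = FALSE)
  log10(I) * C
}

#' Assemble a gene x sample interaction-score matrix
#'
#' Rows are the union of HAPI genes over all samples; an entry is the
#' gene's interaction score where it is a HAPI gene in that sample and 0
#' elsewhere (sub-threshold scores are deliberately zeroed so the matrix
#' reflects HAPI status).
#'
#' @param per_sample_calls named list (>= 2 samples) of HAPI call tables
#'   from [call_hapi_genes()].
#' @return numeric matrix, genes x samples.
#' @export
build_score_matrix <- function(per_sample_calls) {
  if (length(per_sample_calls) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  if (is.null(names(per_sample_calls)) ||
      any(!nzchar(names(per_sample_calls)))) {
    stop("per_sample_calls must be a named list", call. = FALSE)
  }
  hapi_genes <- sort(unique(unlist(lapply(per_sample_calls, function(x) {
    x <- data.table::as.data.table(x)
    x$gene[x$is_hapi]
  }))))
  mat <- matrix(0, nrow = length(hapi_genes), ncol = length(per_sample_calls),
                dimnames = list(hapi_genes, names(per_sample_calls)))
  for (s in names(per_sample_calls)) {
    x <- data.table::as.data.table(per_sample_calls[[s]])
    x <- x[x$is_hapi & x$gene %in% hapi_genes]
    if (nrow(x)) mat[x$gene, s] <- interaction_score(x$I, x$C)
  }
  mat
}

#' Spearman correlation and sample clustering
#'
#' Computes pairwise Spearman correlation (ties mid-ranked) between the
#' sample columns, then orders samples by average-linkage hierarchical
#' clustering on `1 - rho`. Constant columns have undefined correlations;
#' their entries are `NA` and those samples are placed last in the ordering.
#'
#' @param matrix gene x sample matrix from [build_score_matrix()].
#' @return list with `correlation` (symmetric matrix, unit diagonal) and
#'   `order` (character vector of sample names).
#' @export
spearman_cluster <- function(matrix) {
  if (ncol(matrix) < 2L) stop("need at least 2 samples", call. = FALSE)
  rk <- apply(matrix, 2L, rank)            # mid-ranks; Spearman = Pearson(ranks)
  rho <- suppressWarnings(stats::cor(rk))
  diag(rho) <- 1
  constant <- apply(matrix, 2L, function(x) length(unique(x)) == 1L)
  valid <- which(!constant)
  ord <- if (length(valid) >= 2L) {
    sub <- rho[valid, valid, drop = FALSE]
    hc <- stats::hclust(stats::as.dist(1 - sub), method = "average")
    colnames(sub)[hc$order]
  } else {
    colnames(matrix)[valid]
  }
  list(correlation = rho,
       order = c(ord, colnames(matrix)[constant]))
}
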