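#' Rank marker genes for one domain by Welch t-test
#'
#' For every gene, tests the spots of `domain` against all other spots
#' with a two-sided Welch (unequal-variance) t-test on the normalized
#' expression values. P values are Benjamini-Hochberg adjusted across
#' genes within the domain, and genes are ranked by decreasing `|t|`
#' (ties broken by gene id). Genes with zero variance in both groups get
#' `t = 0`, `p = 1` by convention.
#'
#' @param ds a normalized [spot_dataset()].
#' @param labels integer domain label per spot.
#' @param domain the domain label to test (must be present in `labels`).
#' @return A data.frame with columns `gene`, `t`, `p`, `p_adj`, `lfc`
#'   (difference of group means on the log scale) and `rank`, ordered by
#'   rank.
#' @export
rank_genes_ttest <- function(ds, labels, domain) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (!ds$normalized) stop("rank_genes_ttest expects normalized data")
  if (length(labels) != nrow(ds$X)) stop("labels length != number of spots")
  in_grp <- labels == domain
  if (!any(in_grp)) stop("domain ", domain, " not present in labels")
  n1 <- sum(in_grp); n0 <- sum(!in_grp)
  if (n1 < 2 || n0 < 2)
    stop("both groups need at least 2 spots (got ", n1, " vs ", n0, ")")
  X1 <- ds$X[in_grp, , drop = FALSE]
  X0 <- ds$X[!in_grp, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- apply(X1, 2L, stats::var); v0 <- apply(X0, 2L, stats::var)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  p_adj <- stats::p.adjust(p, method = "BH")
  ord <- order(-abs(t_stat), ds$gene_ids)
  out <- data.frame(gene = ds$gene_ids, t = t_stat, p = p, p_adj = p_adj,
                    lfc = m1 - m0, row.names = NULL)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank marker genes for every domain
#'
#' Applies [rank_genes_ttest()] to each distinct label and binds the
#' results with a `domain` column.
#'
#' @inheritParams rank_genes_ttest
#' @return A data.frame of per-domain marker tables.
#' @export
rank_all_domains <- function(ds, labels) {
  doms <- sort(unique(labels))
  do.call(rbind, lapply(doms, function(d) {
    tab <- rank_genes_ttest(ds, labels, d)
    cbind(domain = d, tab)
  }))
}
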