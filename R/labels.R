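#' Call differentially expressed genes with a moderated t-test
#'
#' For real datasets without generating truth, regulation-class labels come
#' from a limma moderated t-statistic comparing expression replicates on a
#' given day against day 0, with Benjamini-Hochberg control; genes with
#' q-value at most `q` are labelled `up` or `down` by the sign of the fitted
#' log change, all others `stable`.
#'
#' @param expr_table Expression table with replicates.
#' @param day Day to compare against day 0.
#' @param q BH q-value cutoff.
#' @return data.frame with `gene_id`, `label`, `logfc`, `qvalue`.
#' @export
call_differential <- function(expr_table, day, q = 0.05) {
  e0 <- expr_table[expr_table$day == 0, ]
  et <- expr_table[expr_table$day == day, ]
  if (nrow(et) == 0L) stop(sprintf("day %s not in table", day), call. = FALSE)
  genes <- sort(intersect(unique(e0$gene_id), unique(et$gene_id)))
  wide <- function(df) {
    reps <- sort(unique(df$replicate))
    sapply(reps, function(r) {
      sub <- df[df$replicate == r, ]
      stats::setNames(sub$expression, sub$gene_id)[genes]
    })
  }
  m <- cbind(wide(e0), wide(et))
  n0 <- length(unique(e0$replicate))
  nt <- length(unique(et$replicate))
  design <- cbind(intercept = 1, dayT = c(rep(0, n0), rep(1, nt)))
  fit <- limma::eBayes(limma::lmFit(m, design))
  tab <- limma::topTable(fit, coef = "dayT", number = Inf, sort.by = "none",
                         adjust.method = "BH")
  label <- ifelse(tab$adj.P.Val <= q, ifelse(tab$logFC > 0, "up", "down"),
                  "stable")
  data.frame(gene_id = genes, label = label, logfc = tab$logFC,
             qvalue = tab$adj.P.Val, stringsAsFactors = FALSE)
}
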