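#' Call cohort-level differentially expressed genes
#'
#' Compares tumor against control expression (both already on the log2
#' scale) gene by gene with two independent tests — a Welch two-sample
#' t-test and a one-way ANOVA F-test — and intersects their calls to reduce
#' single-method bias. Each p-value vector is Benjamini-Hochberg adjusted
#' separately. A gene is a DEG when both adjusted p-values fall below
#' `deg_alpha` and the absolute log2 fold change (difference of group means,
#' since inputs are log2) exceeds `deg_lfc`.
#'
#' Genes with zero variance in both groups get p = 1 from both tests, with
#' a warning.
#'
#' @param tumor_expression samples x genes numeric matrix (log2).
#' @param control_expression control-samples x genes numeric matrix (log2),
#'   same gene columns.
#' @param deg_alpha BH-adjusted significance cutoff (default 0.05).
#' @param deg_lfc absolute log2 fold-change cutoff (default 2).
#' @return object of class `deg_result`: data.frame with columns `gene`,
#'   `log2fc`, `pvalue_welch`, `pvalue_anova`, `adj_pvalue_welch`,
#'   `adj_pvalue_anova`, `is_deg`.
#' @export
call_degs <- function(tumor_expression, control_expression,
                      deg_alpha = 0.05, deg_lfc = 2.0) {
  if (!identical(colnames(tumor_expression), colnames(control_expression)))
    dg_stop("tumor and control matrices must share identical gene columns")
  n1 <- nrow(tumor_expression)
  n2 <- nrow(control_expression)
  if (n1 < 2L || n2 < 2L)
    dg_stop("insufficient replicates: need >= 2 samples per group (got ",
            n1, " tumor, ", n2, " control)")

  m1 <- colMeans(tumor_expression)
  m2 <- colMeans(control_expression)
  v1 <- apply(tumor_expression, 2L, stats::var)
  v2 <- apply(control_expression, 2L, stats::var)
  log2fc <- m1 - m2

  # Welch two-sample t-test, vectorized over genes
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p_welch <- 2 * pt(-abs(t_stat), df_w)

  # One-way ANOVA F-test (two groups), pooled variance
  n <- n1 + n2
  grand <- (n1 * m1 + n2 * m2) / n
  ss_between <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ss_within <- (n1 - 1) * v1 + (n2 - 1) * v2
  f_stat <- ss_between / (ss_within / (n - 2))
  p_anova <- pf(f_stat, 1, n - 2, lower.tail = FALSE)

  flat <- v1 == 0 & v2 == 0
  if (any(flat)) {
    warning(sum(flat), " gene(s) with zero variance in both groups; p set to 1",
            call. = FALSE)
    p_welch[flat] <- 1
    p_anova[flat] <- 1
  }

  adj_welch <- p.adjust(p_welch, method = "BH")
  adj_anova <- p.adjust(p_anova, method = "BH")
  is_deg <- adj_welch < deg_alpha & adj_anova < deg_alpha & abs(log2fc) > deg_lfc

  out <- data.frame(gene = colnames(tumor_expression),
                    log2fc = log2fc,
                    pvalue_welch = p_welch,
                    pvalue_anova = p_anova,
                    adj_pvalue_welch = adj_welch,
                    adj_pvalue_anova = adj_anova,
                    is_deg = is_deg,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_result", "data.frame")
  dg_log(sum(is_deg), " DEGs called of ", nrow(out), " genes (alpha ",
         deg_alpha, ", |log2FC| > ", deg_lfc, ")")
  out
}

#' Extract the DEG set from a result
#' @param degs a `deg_result`.
#' @return character vector of DEG symbols.
#' @export
deg_set <- function(degs) {
  stopifnot(inherits(degs, "deg_result"))
  degs$gene[degs$is_deg]
}
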