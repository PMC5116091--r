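#' Relative expression from Ct values
#'
#' `2^-(Ct_gene - Ct_housekeeping)`, assuming 100% amplification efficiency.
#'
#' @param ct_gene,ct_housekeeping cycle-threshold values.
#' @return relative expression in arbitrary units.
#' @export
relative_expression <- function(ct_gene, ct_housekeeping) {
  2^-(ct_gene - ct_housekeeping)
}

check_expression_table <- function(table) {
  need <- c("donor", "cell_type", "gene", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("expression table missing columns: ", paste(miss, collapse = ", "))
  if (any(table$value <= 0)) stop("expression values must be > 0")
  invisible(table)
}

#' Log2 fold change versus the non-risk genotype group
#'
#' Per cell type and gene, each donor's linear expression is divided by the
#' mean linear value of the non-risk (CC) donors in that cell type and
#' log2-transformed. Cell types without any CC donor are skipped with a
#' warning.
#'
#' @param table long expression data.frame (`donor`, `cell_type`, `gene`,
#'   `value` in linear units).
#' @param genotypes named character vector donor -> genotype
#'   ("TT"/"TC"/"CC").
#' @param nonrisk genotype label defining the reference group.
#' @return the table with an added `log2fc` column (skipped cell types
#'   removed).
#' @export
log2fc_vs_nonrisk <- function(table, genotypes, nonrisk = "CC") {
  check_expression_table(table)
  table$genotype <- unname(genotypes[table$donor])
  parts <- split(table, list(table$cell_type, table$gene), drop = TRUE)
  out <- lapply(parts, function(part) {
    ref <- part$value[part$genotype == nonrisk]
    if (length(ref) == 0) {
      warning("no ", nonrisk, " donors for ", part$cell_type[1], "/",
              part$gene[1], "; skipped")
      return(NULL)
    }
    part$log2fc <- log2(part$value / mean(ref))
    part
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-group Student t-test on linear expression
#'
#' Equal-variance unpaired two-tailed t-test comparing two genotype groups
#' (TT vs CC by default) on linear values in one cell type / gene.
#'
#' @param table long expression data.frame.
#' @param genotypes named donor -> genotype vector.
#' @param cell_type,gene stratum to test.
#' @param groups the two genotype labels compared.
#' @return list with `t_statistic`, `p_value`, `group_means`, `n`.
#' @export
group_ttest <- function(table, genotypes, cell_type, gene,
                        groups = c("TT", "CC")) {
  check_expression_table(table)
  sel <- table[table$cell_type == cell_type & table$gene == gene, ]
  g <- unname(genotypes[sel$donor])
  x <- sel$value[g == groups[1]]
  y <- sel$value[g == groups[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 donors in each compared group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
  }
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       group_means = stats::setNames(c(mean(x), mean(y)), groups),
       n = stats::setNames(c(length(x), length(y)), groups))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive midranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(rank(x), rank(y))
}
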