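#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the per-gene geometric-mean reference, using only
#' genes with nonzero counts in all samples. Factors are rescaled so their
#' geometric mean is 1. If no gene is nonzero everywhere, total-count
#' scaling is used instead, with a warning.
#'
#' @param counts Gene x sample count matrix (unit counts).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (!is.null(attr(counts, "unit")) && attr(counts, "unit") != "counts")
    stop("size factors require a counts matrix, not ", attr(counts, "unit"))
  if (any(counts < 0)) stop("negative counts")
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    warning("no gene with nonzero counts in every sample; ",
            "falling back to total-count scaling")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total counts")
  } else {
    ref <- exp(rowMeans(log(counts[all_nonzero, , drop = FALSE])))
    sf <- apply(counts[all_nonzero, , drop = FALSE], 2,
                function(x) stats::median(x / ref))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input vector.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\], same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues)) stop("p-values must not be NA")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' DEG/HDEG class from fold change and FDR
#'
#' The two-tier significance scheme: a gene is a DEG when FDR < 0.05 and
#' |log2FC| > 1.5, and an HDEG (highly significant DEG) when FDR < 0.01 and
#' |log2FC| > 2. Both fold-change cuts are strict. HDEGs are a subset of
#' DEGs by construction. Direction follows the sign of log2FC.
#'
#' @param log2fc Numeric vector of log2 fold changes (cold vs control).
#' @param fdr Numeric vector of adjusted p-values (NA allowed; maps to NS).
#' @param thresholds List with `deg = list(fdr, lfc)` and
#'   `hdeg = list(fdr, lfc)`.
#' @return Character vector over
#'   \{NS, DEG_up, DEG_down, HDEG_up, HDEG_down\}.
#' @export
classify_de <- function(log2fc, fdr, thresholds = de_thresholds()) {
  cls <- rep("NS", length(log2fc))
  ok <- !is.na(fdr) & !is.na(log2fc)
  deg <- ok & fdr < thresholds$deg$fdr & abs(log2fc) > thresholds$deg$lfc
  hdeg <- ok & fdr < thresholds$hdeg$fdr & abs(log2fc) > thresholds$hdeg$lfc
  cls[deg & log2fc > 0] <- "DEG_up"
  cls[deg & log2fc < 0] <- "DEG_down"
  cls[hdeg & log2fc > 0] <- "HDEG_up"
  cls[hdeg & log2fc < 0] <- "HDEG_down"
  cls
}

#' Default DEG/HDEG thresholds
#'
#' @return Nested list: DEG at FDR < 0.05 & |log2FC| > 1.5; HDEG at
#'   FDR < 0.01 & |log2FC| > 2.
#' @export
de_thresholds <- function() {
  list(deg = list(fdr = 0.05, lfc = 1.5),
       hdeg = list(fdr = 0.01, lfc = 2.0))
}

#' Negative-binomial Wald test for cold vs control
#'
#' A self-contained NB differential-expression caller: median-of-ratios
#' normalization, per-gene method-of-moments NB dispersion pooled within
#' condition, a Wald statistic on the log2 fold change of normalized
#' condition means (pseudocount 0.5) with a delta-method standard error,
#' and BH FDR over expressed genes. The Wald statistic is referred to a t
#' distribution with n1 + n2 - 2 degrees of freedom to keep type-I error
#' calibrated at the small replicate numbers typical of these designs.
#' Classes are assigned with [classify_de()].
#'
#' @param counts Gene x sample count matrix (unit counts).
#' @param samples Sample sheet restricted to this species; must contain the
#'   matrix columns and both conditions with >= 2 replicates.
#' @param expressed_min_mean Minimum normalized mean (over all samples) for
#'   a gene to count as expressed; non-expressed genes get class NS and NA
#'   p-values. Default 1.0.
#' @param thresholds DEG/HDEG thresholds, see [de_thresholds()].
#' @return data.frame of class `de_result`: `gene_id`, `baseMean`,
#'   `log2fc`, `se`, `pvalue`, `fdr`, `class`, `expressed`.
#' @export
de_test <- function(counts, samples, expressed_min_mean = 1.0,
                    thresholds = de_thresholds()) {
  samples <- samples[samples$sample_id %in% colnames(counts), , drop = FALSE]
  missing_samp <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_samp))
    stop("samples not in matrix: ", paste(missing_samp, collapse = ", "))
  counts <- counts[, samples$sample_id, drop = FALSE]
  is_ctrl <- samples$condition == "control"
  is_cold <- samples$condition == "cold"
  n1 <- sum(is_ctrl); n2 <- sum(is_cold)
  if (n1 < 2L || n2 < 2L)
    stop("each condition needs >= 2 replicates (control: ", n1,
         ", cold: ", n2, ")")

  sf <- size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(nc)
  expressed <- base_mean >= expressed_min_mean

  m1 <- rowMeans(nc[, is_ctrl, drop = FALSE])
  m2 <- rowMeans(nc[, is_cold, drop = FALSE])
  v1 <- apply(nc[, is_ctrl, drop = FALSE], 1, stats::var)
  v2 <- apply(nc[, is_cold, drop = FALSE], 1, stats::var)

  # method-of-moments NB dispersion, pooled across the two conditions
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA_real_)
  w1 <- ifelse(is.na(a1), 0, n1 - 1L)
  w2 <- ifelse(is.na(a2), 0, n2 - 1L)
  alpha_num <- ifelse(is.na(a1), 0, w1 * a1) + ifelse(is.na(a2), 0, w2 * a2)
  alpha <- ifelse(w1 + w2 > 0, alpha_num / (w1 + w2), 0)
  alpha <- pmax(alpha, 1e-8)

  pc <- 0.5
  log2fc <- log2((m2 + pc) / (m1 + pc))
  var_m1 <- (m1 + alpha * m1^2) / n1
  var_m2 <- (m2 + alpha * m2^2) / n2
  se <- sqrt(var_m1 / (m1 + pc)^2 + var_m2 / (m2 + pc)^2) / log(2)

  pvalue <- rep(NA_real_, nrow(counts))
  idx <- expressed & se > 0
  pvalue[idx] <- 2 * stats::pt(-abs(log2fc[idx] / se[idx]), df = n1 + n2 - 2L)
  pvalue[expressed & se == 0] <- 1  # constant identical counts across groups

  fdr <- rep(NA_real_, nrow(counts))
  fdr[expressed] <- bh_adjust(pvalue[expressed])

  res <- data.frame(gene_id = rownames(counts),
                    baseMean = base_mean,
                    log2fc = log2fc,
                    se = se,
                    pvalue = pvalue,
                    fdr = fdr,
                    class = classify_de(log2fc, fdr, thresholds),
                    expressed = expressed,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  class(res) <- c("de_result", class(res))
  res
}

#' Is a DE class significant (DEG or stronger)?
#'
#' @param cls Character vector of DE classes.
#' @return Logical vector: TRUE for DEG_up/DEG_down/HDEG_up/HDEG_down.
#' @export
is_deg <- function(cls) cls %in% c("DEG_up", "DEG_down", "HDEG_up", "HDEG_down")

#' Is a DE class highly significant (HDEG)?
#'
#' @param cls Character vector of DE classes.
#' @return Logical vector: TRUE for HDEG_up/HDEG_down.
#' @export
is_hdeg <- function(cls) cls %in% c("HDEG_up", "HDEG_down")
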