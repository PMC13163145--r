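#' EG/DEG/HDEG counts and proportions per phylostratum
#'
#' The gene-age x transcriptional-plasticity table: over expressed genes
#' (EGs) of the focal species, counts and proportions of DEGs and HDEGs in
#' each age class, oldest to youngest. Genes without a stratum (orthogroups
#' absent from the focal species cannot occur here, but genes missing from
#' the assignment can) are excluded and their number reported in the
#' `n_excluded` attribute.
#'
#' @param assign A `stratum_assignment` for the focal species.
#' @param de A `de_result` data.frame for the same species.
#' @return data.frame of class `plasticity_table`: `stratum`, `n_eg`,
#'   `n_deg`, `n_hdeg`, `prop_deg`, `prop_hdeg`, ordered oldest to
#'   youngest.
#' @export
plasticity_table <- function(assign, de) {
  stopifnot(inherits(assign, "stratum_assignment"))
  m <- merge(assign$genes, de, by = "gene_id")
  if (nrow(m) == 0L)
    stop("no shared gene IDs between stratum assignment and DE results")
  n_excluded <- sum(!de$gene_id %in% assign$genes$gene_id)
  m <- m[m$expressed & !is.na(m$stratum), , drop = FALSE]
  strata <- assign$strata
  n_eg <- n_deg <- n_hdeg <- integer(length(strata))
  for (i in seq_along(strata)) {
    sub <- m[m$stratum == strata[i], , drop = FALSE]
    n_eg[i] <- nrow(sub)
    n_deg[i] <- sum(is_deg(sub$class))
    n_hdeg[i] <- sum(is_hdeg(sub$class))
  }
  out <- data.frame(stratum = strata, n_eg = n_eg, n_deg = n_deg,
                    n_hdeg = n_hdeg,
                    prop_deg = ifelse(n_eg > 0, n_deg / n_eg, NA_real_),
                    prop_hdeg = ifelse(n_eg > 0, n_hdeg / n_eg, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("plasticity_table", class(out))
  out
}

#' Cochran-Armitage trend test over ordered age classes
#'
#' Tests whether the proportion of responsive genes (DEGs or HDEGs among
#' EGs) changes linearly across phylostrata scored 1..S from oldest to
#' youngest. The signed statistic is positive when the proportion rises
#' toward younger strata; the two-sided p-value uses the normal reference.
#' `monotone_flag` records whether the observed proportions are
#' non-decreasing oldest to youngest — the descriptive "progressively
#' increasing" pattern.
#'
#' @param pt A `plasticity_table`.
#' @param metric `"deg"` or `"hdeg"`.
#' @return List `statistic` (signed z), `pvalue` (two-sided), `direction`
#'   (`increasing`, `decreasing` or `flat`), `monotone_flag`.
#' @export
age_trend_test <- function(pt, metric = c("deg", "hdeg")) {
  metric <- match.arg(metric)
  x <- if (metric == "deg") pt$n_deg else pt$n_hdeg
  n <- pt$n_eg
  drop_idx <- n == 0
  if (any(drop_idx)) {
    warning(sum(drop_idx), " stratum/strata with no expressed genes dropped")
    x <- x[!drop_idx]; n <- n[!drop_idx]
  }
  if (length(n) < 2L) stop("need >= 2 strata with expressed genes")
  s <- seq_along(n)  # integer scores, oldest -> youngest
  N <- sum(n)
  pbar <- sum(x) / N
  tstat <- sum(s * x) - pbar * sum(s * n)
  v <- pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / N)
  if (v <= 0 || pbar %in% c(0, 1)) {
    z <- 0; p <- 1
  } else {
    z <- tstat / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  prop <- x / n
  list(statistic = z, pvalue = p,
       direction = if (z > 0) "increasing" else if (z < 0) "decreasing" else "flat",
       monotone_flag = all(diff(prop) >= 0))
}

#' Per-stratum fold of responsive proportion vs the pooled proportion
#'
#' For each age class, the ratio of its DEG (or HDEG) proportion to the
#' proportion pooled over all included strata — the "proportional increase
#' relative to all expressed genes" view of the age gradient.
#'
#' @param pt A `plasticity_table`.
#' @param metric `"deg"` or `"hdeg"`.
#' @return data.frame `stratum`, `prop`, `pooled_prop`, `fold` (NA when the
#'   pooled proportion is zero).
#' @export
stratum_fold_change <- function(pt, metric = c("deg", "hdeg")) {
  metric <- match.arg(metric)
  x <- if (metric == "deg") pt$n_deg else pt$n_hdeg
  pooled <- sum(x) / sum(pt$n_eg)
  prop <- ifelse(pt$n_eg > 0, x / pt$n_eg, NA_real_)
  data.frame(stratum = pt$stratum, prop = prop, pooled_prop = pooled,
             fold = if (pooled > 0) prop / pooled else NA_real_,
             stringsAsFactors = FALSE)
}
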