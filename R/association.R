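#' Build a 2x2 allele table from severe and mild dosage vectors
#'
#' Counts alternate and reference alleles per group, two alleles per diploid
#' genotype. Missing genotypes contribute nothing: they reduce the allele
#' denominator rather than being imputed.
#'
#' @param dosages_severe,dosages_mild integer dosages in `{0,1,2}` or `NA`.
#' @return object of class `allele_table`: list with `a` (alt, severe),
#'   `b` (ref, severe), `c` (alt, mild), `d` (ref, mild).
#' @export
allele_table <- function(dosages_severe, dosages_mild) {
  check_dosage <- function(x, lab) {
    if (!all(is.na(x) | x %in% 0:2))
      stop_validation("dosages must be 0, 1, 2 or NA (", lab, " group)")
    if (all(is.na(x)))
      stop_validation("degenerate table: all genotypes missing in ", lab, " group")
  }
  check_dosage(dosages_severe, "severe")
  check_dosage(dosages_mild, "mild")
  ns <- sum(!is.na(dosages_severe))
  nm <- sum(!is.na(dosages_mild))
  a <- sum(dosages_severe, na.rm = TRUE)
  c_ <- sum(dosages_mild, na.rm = TRUE)
  structure(list(a = a, b = 2L * ns - a, c = c_, d = 2L * nm - c_),
            class = "allele_table")
}

#' Allelic odds ratio with Pearson chi-squared test
#'
#' Computes the alternate-allele odds ratio severe vs mild from a 2x2 allele
#' table. If any cell is zero the Haldane-Anscombe correction (add 0.5 to all
#' four cells) is applied for the odds ratio only; the chi-squared statistic
#' (1 df, no continuity correction — the PLINK-style allelic test) is always
#' computed on the uncorrected table. A monomorphic table (both alt cells or
#' both ref cells zero) yields `chi2 = 0`, `p = 1`.
#'
#' @param table an [allele_table()] or a list with fields `a`, `b`, `c`, `d`.
#' @return list with `odds_ratio`, `chi2`, `p_value`, and `direction`
#'   (`"pro-severe"` if OR > 1, `"pro-mild"` if OR < 1, else `"neutral"`).
#' @examples
#' odds_ratio(allele_table(c(2, 1, 0), c(0, 0, 1)))
#' @export
odds_ratio <- function(table) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (any(c(a, b, c_, d) < 0)) stop_validation("allele counts must be non-negative")
  if (a + b == 0 || c_ + d == 0)
    stop_validation("degenerate table: zero allele margin in one group")
  corr <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
  or <- ((a + corr) * (d + corr)) / ((b + corr) * (c_ + corr))
  n <- a + b + c_ + d
  col1 <- a + c_
  col2 <- b + d
  chi2 <- if (col1 == 0 || col2 == 0) 0 else
    n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * col1 * col2)
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  direction <- if (or > 1) "pro-severe" else if (or < 1) "pro-mild" else "neutral"
  list(odds_ratio = or, chi2 = chi2, p_value = p, direction = direction)
}

#' Per-variant association scan between severe and mild samples
#'
#' Vectorized allelic odds-ratio scan over all variants of a genotype matrix,
#' mirroring a PLINK `.assoc` table. Variants with all genotypes missing in
#' either group get `NA` statistics (and are skipped by [rank_variants()]).
#'
#' @param genotypes samples x variants dosage matrix.
#' @param annotations annotation data frame aligned to the matrix columns
#'   (needs `variant_id`, `chrom`, `pos`, `alt`).
#' @param severity character vector, `"severe"`/`"mild"`, one per sample.
#' @param fisher if `TRUE`, p-values come from Fisher's exact test instead of
#'   the chi-squared statistic (useful for very sparse tables).
#' @return data frame with columns `variant_id`, `chrom`, `pos`, `alt`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `chi2`, `p_value`, `direction`.
#' @export
assoc_scan <- function(genotypes, annotations, severity, fisher = FALSE) {
  if (nrow(genotypes) != length(severity))
    stop_validation("severity must have one entry per genotype row")
  if (ncol(genotypes) != nrow(annotations))
    stop_validation("annotations must have one row per genotype column")
  sev <- severity == "severe"
  if (!any(sev) || !all(severity %in% c("severe", "mild")) || all(sev))
    stop_validation("severity must contain both 'severe' and 'mild'")
  gs <- genotypes[sev, , drop = FALSE]
  gm <- genotypes[!sev, , drop = FALSE]
  ns <- colSums(!is.na(gs))
  nm <- colSums(!is.na(gm))
  a <- colSums(gs, na.rm = TRUE)
  b <- 2 * ns - a
  c_ <- colSums(gm, na.rm = TRUE)
  d <- 2 * nm - c_
  ok <- ns > 0 & nm > 0

  corr <- ifelse(a == 0 | b == 0 | c_ == 0 | d == 0, 0.5, 0)
  or <- ((a + corr) * (d + corr)) / ((b + corr) * (c_ + corr))
  n <- a + b + c_ + d
  chi2 <- ifelse((a + c_) == 0 | (b + d) == 0, 0,
                 n * (a * d - b * c_)^2 /
                   pmax((a + b) * (c_ + d) * (a + c_) * (b + d), 1))
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  if (fisher) {
    p <- vapply(seq_along(a), function(i) {
      if (!ok[i]) return(NA_real_)
      stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2L, byrow = TRUE))$p.value
    }, numeric(1))
  }
  or[!ok] <- NA_real_; chi2[!ok] <- NA_real_; p[!ok] <- NA_real_
  data.frame(variant_id = annotations$variant_id,
             chrom = annotations$chrom,
             pos = annotations$pos,
             alt = annotations$alt,
             a = a, b = b, c = c_, d = d,
             odds_ratio = or, chi2 = chi2, p_value = p,
             direction = ifelse(is.na(or), NA_character_,
                                ifelse(or > 1, "pro-severe",
                                       ifelse(or < 1, "pro-mild", "neutral"))),
             stringsAsFactors = FALSE)
}

#' Rank variants by association significance
#'
#' Orders variants by ascending p-value; ties are broken by descending
#' absolute log odds ratio, then by `(chrom, pos, alt)` lexicographic order,
#' giving a fully deterministic total order. Variants with `NA` statistics
#' (degenerate tables) are dropped.
#'
#' @param results an [assoc_scan()] data frame.
#' @return character vector of `variant_id` in rank order.
#' @export
rank_variants <- function(results) {
  if (nrow(results) == 0L) stop_validation("rank_variants needs a nonempty result set")
  keep <- !is.na(results$p_value)
  res <- results[keep, , drop = FALSE]
  ord <- order(res$p_value, -abs(log(res$odds_ratio)),
               res$chrom, res$pos, res$alt, method = "radix")
  res$variant_id[ord]
}

#' Take the top-k ranked variants
#'
#' @param ranked character vector from [rank_variants()].
#' @param k number of variants to keep, `1 <= k <= length(ranked)`.
#' @return the first `k` IDs, order preserved.
#' @export
select_top_k <- function(ranked, k) {
  if (!is_count(k, 1L) || k > length(ranked))
    stop_validation("k must satisfy 1 <= k <= ", length(ranked))
  ranked[seq_len(k)]
}
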