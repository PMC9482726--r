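# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and vectorized shortcuts) so they can vouch for them.

# AUC as the exhaustive average over all severe x mild pairs.
brute_auc <- function(risks, truths) {
  pos <- risks[truths == "severe"]
  neg <- risks[truths == "mild"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# NRI/IDI by explicit per-sample tallying.
brute_nri_idi <- function(old, new, truths, cutpoints = c(0, 0.5, 1)) {
  cat_of <- function(r) {
    for (i in seq_len(length(cutpoints) - 1L)) {
      hi <- cutpoints[i + 1L]
      if (r < hi || (i == length(cutpoints) - 1L && r <= hi)) return(i)
    }
    stop("risk outside cutpoints")
  }
  up_ev <- down_ev <- n_ev <- up_ne <- down_ne <- n_ne <- 0
  sum_ev <- sum_ne <- 0
  for (i in seq_along(old)) {
    co <- cat_of(old[i]); cn <- cat_of(new[i])
    if (truths[i] == "severe") {
      n_ev <- n_ev + 1
      if (cn > co) up_ev <- up_ev + 1
      if (cn < co) down_ev <- down_ev + 1
      sum_ev <- sum_ev + (new[i] - old[i])
    } else {
      n_ne <- n_ne + 1
      if (cn > co) up_ne <- up_ne + 1
      if (cn < co) down_ne <- down_ne + 1
      sum_ne <- sum_ne + (new[i] - old[i])
    }
  }
  list(nri = (up_ev - down_ev) / n_ev - (up_ne - down_ne) / n_ne,
       idi = sum_ev / n_ev - sum_ne / n_ne)
}

# O(n^3) UPGMA on scalar points; returns the sorted merge heights.
brute_upgma_heights <- function(x) {
  clusters <- as.list(seq_along(x))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- 0; cnt <- 0
      for (a in clusters[[i]]) for (b in clusters[[j]]) {
        d <- d + abs(x[a] - x[b]); cnt <- cnt + 1
      }
      d <- d / cnt
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

# Venn region sizes by per-gene exhaustive membership enumeration.
brute_venn_sizes <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  for (g in universe) {
    key <- paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
                 collapse = "&")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}

# Selection sort with an explicit pairwise comparator: the ranking oracle.
brute_rank <- function(res) {
  less <- function(i, j) {
    if (res$p_value[i] != res$p_value[j]) return(res$p_value[i] < res$p_value[j])
    li <- abs(log(res$odds_ratio[i])); lj <- abs(log(res$odds_ratio[j]))
    if (li != lj) return(li > lj)
    if (res$chrom[i] != res$chrom[j]) return(res$chrom[i] < res$chrom[j])
    if (res$pos[i] != res$pos[j]) return(res$pos[i] < res$pos[j])
    res$alt[i] < res$alt[j]
  }
  idx <- seq_len(nrow(res))
  for (i in seq_along(idx)) {
    m <- i
    for (j in seq_along(idx)) {
      if (j > i && less(idx[j], idx[m])) m <- j
    }
    tmp <- idx[i]; idx[i] <- idx[m]; idx[m] <- tmp
  }
  res$variant_id[idx]
}

# Exact tail probability of the all-sets intersection of independent uniform
# random subsets of fixed sizes, via nested hypergeometrics: |A1 n A2| is
# hypergeometric, and conditioning forward one set at a time stays
# hypergeometric.
exact_intersection_tail <- function(sizes, universe, observed) {
  # distribution over the size of the running intersection
  probs <- stats::setNames(1, as.character(sizes[1]))
  for (s in sizes[-1]) {
    nxt <- numeric(0)
    for (m_chr in names(probs)) {
      m <- as.integer(m_chr)
      for (k in 0:min(m, s)) {
        pr <- probs[[m_chr]] * stats::dhyper(k, m, universe - m, s)
        key <- as.character(k)
        nxt[key] <- (nxt[key] %||% 0) + pr
      }
    }
    probs <- nxt
  }
  sum(probs[as.integer(names(probs)) >= observed])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# Small cohort shortcut for expensive loops.
small_cohort <- function(...) {
  simulate_cohort(cohort_spec(n_variants = 300L, n_genes = 60L, ...))
}

# Minimal hand-written VCF fixture (3 variants x 2 samples).
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"s\">",
    "##INFO=<ID=POLYPHEN,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=AAF_1KG,Number=1,Type=Float,Description=\"f\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampleA\tsampleB",
    "1\t100\tva\tA\tG\t.\tPASS\tGENE=GENE1;SIFT=deleterious;POLYPHEN=probably_damaging;AAF_1KG=0.1\tGT\t0/0\t0/1",
    "1\t200\tvb\tC\tT\t.\tPASS\tGENE=GENE2\tGT\t1/1\t./.",
    "2\t100\tvc\tG\tA\t.\tPASS\tSIFT=tolerated;POLYPHEN=benign;AAF_1KG=0.5\tGT\t0/1\t1/0"),
    path)
  path
}

write_phen <- function(path, df) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
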