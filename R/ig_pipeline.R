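qualifying_sift <- c("deleterious", "deleterious_low_confidence")
qualifying_polyphen <- c("possibly_damaging", "probably_damaging")

#' Per-sample qualifying deleterious homozygous variants
#'
#' A variant qualifies for a sample iff its dosage is 2 (homozygous for the
#' alternate allele) and it is flagged simultaneously by SIFT as
#' `deleterious` or `deleterious_low_confidence` and by PolyPhen as
#' `possibly_damaging` or `probably_damaging` (token matching is
#' case-insensitive). Variants lacking either label never qualify.
#'
#' @param genotypes samples x variants dosage matrix.
#' @param annotations annotation data frame aligned to the matrix columns
#'   (`variant_id`, `sift`, `polyphen`).
#' @param sift_labels,polyphen_labels qualifying token sets, exposed so the
#'   rule can be relaxed or tightened.
#' @return named list: sample ID -> character vector of qualifying
#'   variant IDs (possibly empty).
#' @export
qualifying_variants <- function(genotypes, annotations,
                                sift_labels = qualifying_sift,
                                polyphen_labels = qualifying_polyphen) {
  if (ncol(genotypes) != nrow(annotations))
    stop_validation("annotations must align to genotype columns")
  damaging <- !is.na(annotations$sift) & !is.na(annotations$polyphen) &
    tolower(annotations$sift) %in% tolower(sift_labels) &
    tolower(annotations$polyphen) %in% tolower(polyphen_labels)
  ids <- annotations$variant_id
  out <- lapply(seq_len(nrow(genotypes)), function(i) {
    hom <- !is.na(genotypes[i, ]) & genotypes[i, ] == 2L
    ids[hom & damaging]
  })
  names(out) <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  out
}

#' Per-sample important-gene sets
#'
#' Maps each sample's qualifying variants to distinct gene symbols.
#' Qualifying variants without a gene symbol are dropped (their count is
#' reported via a message), since the gene is the unit of this analysis.
#'
#' @param qualifying output of [qualifying_variants()].
#' @param annotations annotation data frame (`variant_id`, `gene`).
#' @return named list: sample ID -> character vector of gene symbols.
#' @export
sample_gene_sets <- function(qualifying, annotations) {
  gene_of <- annotations$gene
  names(gene_of) <- annotations$variant_id
  dropped <- 0L
  out <- lapply(qualifying, function(vids) {
    g <- gene_of[vids]
    miss <- is.na(g) | g == ""
    dropped <<- dropped + sum(miss)
    sort(unique(unname(g[!miss])))
  })
  if (dropped > 0L)
    message(sprintf("sample_gene_sets: dropped %d qualifying variant(s) without a gene symbol", dropped))
  out
}

#' Group important genes by the at-least-(n-2) commonality rule
#'
#' A gene is an important gene (IG) of a sub-phenotype group when it appears
#' in the gene sets of at least `n - 2` of the group's `n` members.
#'
#' @param gene_sets named list of per-sample gene sets
#'   (from [sample_gene_sets()]).
#' @param members character vector of sample IDs forming the group
#'   (`length(members) >= 3` so the threshold is at least 1).
#' @param group optional label (e.g. `"iq_severe"`) carried into the result.
#' @return object of class `group_ig_set`: list with `group`, `n`,
#'   `threshold`, `genes` (character vector), `counts` (named integer vector
#'   of per-gene membership counts, all genes observed in the group).
#' @export
group_ig_set <- function(gene_sets, members, group = NULL) {
  absent <- setdiff(members, names(gene_sets))
  if (length(absent) > 0L)
    stop_validation("no gene set for sample: ", absent[1L])
  n <- length(members)
  if (n < 3L) stop_validation("group must have at least 3 members (threshold n-2 >= 1)")
  threshold <- n - 2L
  counts <- table(unlist(gene_sets[members], use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  genes <- sort(names(counts)[counts >= threshold])
  structure(list(group = group, n = n, threshold = threshold,
                 genes = genes, counts = counts),
            class = "group_ig_set")
}

#' @exportS3Method base::print
print.group_ig_set <- function(x, ...) {
  cat(sprintf("IG set%s: %d genes common to >= %d of %d samples\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$genes), x$threshold, x$n))
  invisible(x)
}

#' Partition genes by exact set membership (Venn regions)
#'
#' Assigns every gene in the union of the input sets to exactly one region
#' keyed by the subset of sets containing it (region keys join set names
#' with `"&"` in input order). The regions are pairwise disjoint and their
#' union reconstructs each input set.
#'
#' @param sets named list of 2 to 8 character vectors.
#' @return object of class `venn_partition`: list with `set_names` and
#'   `regions` (named list region key -> sorted gene vector).
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_validation("sets must be named")
  if (length(sets) < 2L || length(sets) > 8L)
    stop_validation("venn_partition supports 2 to 8 sets")
  set_names <- names(sets)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0L)
    return(structure(list(set_names = set_names, regions = list()),
                     class = "venn_partition"))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  keys <- apply(membership, 1L, function(row)
    paste(set_names[row], collapse = "&"))
  regions <- split(universe, keys)
  regions <- lapply(regions, sort)
  structure(list(set_names = set_names, regions = regions),
            class = "venn_partition")
}

#' @exportS3Method base::print
print.venn_partition <- function(x, ...) {
  sizes <- vapply(x$regions, length, integer(1))
  cat(sprintf("Venn partition of %d sets: %d non-empty regions, %d genes total\n",
              length(x$set_names), length(x$regions), sum(sizes)))
  print(sort(sizes, decreasing = TRUE))
  invisible(x)
}

#' Genes present in every input set
#'
#' Convenience accessor for the all-sets region of a [venn_partition()],
#' e.g. the severity-independent genes when fed all eight
#' sub-phenotype-by-severity IG sets.
#'
#' @param partition a `venn_partition`.
#' @return character vector (possibly empty).
#' @export
venn_core <- function(partition) {
  key <- paste(partition$set_names, collapse = "&")
  partition$regions[[key]] %||% character(0)
}

#' Multi-set intersection enrichment by Monte Carlo
#'
#' Compares the observed size of the intersection of all sets against the
#' closed-form expectation under independent uniform draws from a common
#' gene universe, `expected = N * prod(|set_i| / N)`, and estimates a
#' p-value as the fraction of seeded same-size random draws whose all-set
#' overlap is at least the observed one (with the standard `+1/(n+1)`
#' continuity correction).
#'
#' @param sets named list of character vectors, each a subset of the
#'   universe.
#' @param universe_size size of the gene universe (at least the largest set).
#' @param n_draws number of Monte Carlo draws.
#' @param seed RNG seed for the draws.
#' @return list with `observed`, `expected`, `fold_enrichment`
#'   (`NA` when the expectation is 0) and `p_value`.
#' @export
intersection_enrichment <- function(sets, universe_size, n_draws = 10000L,
                                    seed = 1L) {
  sizes <- vapply(sets, length, integer(1))
  if (any(sizes > universe_size))
    stop_validation("a set exceeds the universe size")
  if (!is_count(n_draws, 1L)) stop_validation("n_draws must be >= 1")
  observed <- length(Reduce(intersect, sets))
  expected <- universe_size * prod(sizes / universe_size)
  fold <- if (expected == 0) NA_real_ else observed / expected
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_draws), function(i) {
      draws <- lapply(sizes, function(s) sample.int(universe_size, s))
      length(Reduce(intersect, draws)) >= observed
    }, logical(1)))
  })
  list(observed = observed, expected = expected, fold_enrichment = fold,
       p_value = (hits + 1) / (n_draws + 1))
}

#' Run the full important-gene arm on a cohort
#'
#' Derives per-sample gene sets, the eight sub-phenotype-by-severity IG sets
#' (threshold n-2), their Venn partition with the severity-independent core,
#' and the severity-pooled comparison (union of per-sample gene sets within
#' each overall-severity class, partitioned into mild-only / shared /
#' severe-only).
#'
#' @param genotypes,annotations,phenotypes as in [run_loocv()].
#' @return list with `sample_genes`, `group_igs` (named list of
#'   `group_ig_set`, keys like `"iq_severe"`), `venn` (`venn_partition` of
#'   the eight IG sets), `severity_independent` (character vector),
#'   `severity_pooled` (`venn_partition` of the pooled mild/severe unions).
#' @export
ig_analysis <- function(genotypes, annotations, phenotypes) {
  qual <- qualifying_variants(genotypes, annotations)
  gene_sets <- sample_gene_sets(qual, annotations)
  groups <- list()
  for (ax in subphenotype_axes()) {
    for (side in c("severe", "mild")) {
      members <- phenotypes$sample_id[phenotypes[[ax]] == side]
      key <- paste(ax, side, sep = "_")
      groups[[key]] <- group_ig_set(gene_sets, members, group = key)
    }
  }
  venn <- venn_partition(lapply(groups, `[[`, "genes"))
  pooled <- lapply(c(mild = "mild", severe = "severe"), function(side) {
    members <- phenotypes$sample_id[phenotypes$severity == side]
    sort(unique(unlist(gene_sets[members], use.names = FALSE)))
  })
  list(sample_genes = gene_sets,
       group_igs = groups,
       venn = venn,
       severity_independent = venn_core(venn),
       severity_pooled = venn_partition(pooled))
}
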