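toy_ann <- function() {
  data.frame(variant_id = c("v1", "v2", "v3", "v4"),
             chrom = "1", pos = 1:4 * 100, ref = "A", alt = "G",
             gene = c("GENE1", "GENE1", "GENE7", NA),
             sift = c("deleterious", "tolerated",
                      "deleterious_low_confidence", "Deleterious"),
             polyphen = c("probably_damaging", "probably_damaging",
                          "possibly_damaging", "probably_damaging"),
             stringsAsFactors = FALSE)
}

test_that("qualifying variants require hom-alt plus both damaging flags", {
  ann <- toy_ann()
  geno <- rbind(sA = c(1L, 2L, 2L, 2L),
                sB = c(2L, 2L, 0L, NA))
  colnames(geno) <- ann$variant_id
  q <- qualifying_variants(geno, ann)
  # sA: v1 het -> out; v2 tolerated -> out; v3 hom + low-confidence labels -> in;
  #     v4 hom + damaging (case-folded) but gene NA handled downstream -> in
  expect_equal(q$sA, c("v3", "v4"))
  # sB: v1 hom + damaging -> in; v4 missing genotype -> out
  expect_equal(q$sB, "v1")
})

test_that("sample gene sets de-duplicate and drop symbol-less variants", {
  ann <- toy_ann()
  q <- list(sA = c("v1", "v2", "v3", "v4"), sB = character(0))
  expect_message(gs <- sample_gene_sets(q, ann), "1 qualifying")
  expect_equal(gs$sA, c("GENE1", "GENE7"))
  expect_equal(gs$sB, character(0))
})

test_that("the n-2 commonality rule sits at its boundary", {
  sets <- list(s1 = c("A", "B"), s2 = c("A", "B"), s3 = c("A", "C"),
               s4 = c("C"), s5 = c("C"))
  g <- group_ig_set(sets, names(sets), group = "toy")
  # n = 5, threshold 3: A in 3 -> in; B in 2 -> out; C in 3 -> in
  expect_equal(g$genes, c("A", "C"))
  expect_equal(g$threshold, 3L)
  expect_equal(unname(g$counts["B"]), 2L)
  expect_error(group_ig_set(sets, names(sets)[1:2]), class = "rg_validation_error")
})

test_that("threshold 1 gives the union, threshold n the intersection, n-2 between", {
  set.seed(50)
  sets <- lapply(1:6, function(i) sample(LETTERS, 8))
  names(sets) <- paste0("s", 1:6)
  counts <- table(unlist(sets))
  union_all <- sort(names(counts))
  inter_all <- sort(names(counts)[counts == 6])
  g <- group_ig_set(sets, names(sets))
  expect_true(all(inter_all %in% g$genes))
  expect_true(all(g$genes %in% union_all))
})

test_that("Venn partition matches exhaustive membership enumeration", {
  p <- venn_partition(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(p$regions, list(A = "x", `A&B` = "y", B = "z"))

  disj <- venn_partition(list(A = c("a"), B = c("b"), C = c("c")))
  expect_false(any(grepl("&", names(disj$regions))))

  set.seed(61)
  sets <- lapply(1:5, function(i) sample(sprintf("G%03d", 1:200), 80))
  names(sets) <- paste0("S", 1:5)
  part <- venn_partition(sets)
  want <- brute_venn_sizes(sets)
  got <- lapply(part$regions, length)
  expect_equal(got[order(names(got))], want[order(names(want))])
  # regions are disjoint and reconstruct every input set
  expect_equal(sum(unlist(got)), length(unique(unlist(sets))))
  for (nm in names(sets)) {
    rebuilt <- sort(unlist(part$regions[grepl(nm, names(part$regions))],
                           use.names = FALSE))
    expect_equal(rebuilt, sort(unique(sets[[nm]])))
  }
  expect_error(venn_partition(list(A = "a")), class = "rg_validation_error")
  expect_error(venn_partition(rep(list(A = "a"), 9)), class = "rg_validation_error")
})

test_that("relaxing the deleteriousness rule never shrinks a gene set", {
  co <- small_cohort(seed = 17)
  strict <- sample_gene_sets(
    qualifying_variants(co$genotypes, co$annotations,
                        sift_labels = "deleterious",
                        polyphen_labels = "probably_damaging"),
    co$annotations)
  relaxed <- sample_gene_sets(
    qualifying_variants(co$genotypes, co$annotations), co$annotations)
  for (s in names(strict))
    expect_true(all(strict[[s]] %in% relaxed[[s]]))
})

test_that("intersection enrichment matches closed forms and exact enumeration", {
  two <- intersection_enrichment(list(a = letters[1:10], b = letters[1:10]),
                                 universe_size = 100, n_draws = 200, seed = 4)
  expect_equal(two$observed, 10)
  expect_equal(two$expected, 1)
  expect_equal(two$fold_enrichment, 10)

  disj <- intersection_enrichment(list(a = letters[1:4], b = letters[5:8]),
                                  universe_size = 50, n_draws = 100, seed = 4)
  expect_equal(disj$observed, 0)
  expect_equal(disj$fold_enrichment, 0)
  expect_error(intersection_enrichment(list(a = letters[1:5]), universe_size = 3),
               class = "rg_validation_error")

  # 3 sets on a reduced universe of 12: Monte-Carlo vs exact nested
  # hypergeometric tail
  sets <- list(a = sprintf("g%02d", 1:6), b = sprintf("g%02d", 3:9),
               c = sprintf("g%02d", c(1:4, 8:9)))
  obs <- length(Reduce(intersect, sets))
  n_draws <- 4000
  got <- intersection_enrichment(sets, universe_size = 12,
                                 n_draws = n_draws, seed = 8)
  exact <- exact_intersection_tail(sapply(sets, length), 12, obs)
  se <- sqrt(exact * (1 - exact) / n_draws)
  expect_lt(abs(got$p_value - exact), 3 * se + 1 / n_draws)
})

test_that("planted IG genes are recovered end-to-end with zero false negatives", {
  co <- simulate_cohort(cohort_spec(n_variants = 600, seed = 23))
  res <- ig_analysis(co$genotypes, co$annotations, co$phenotypes)
  truth <- co$truth$ig_genes
  for (r in seq_len(nrow(truth))) {
    if (truth$group[r] == "all") {
      expect_true(truth$gene[r] %in% res$severity_independent)
    } else {
      key <- paste(truth$group[r], truth$side[r], sep = "_")
      expect_true(truth$gene[r] %in% res$group_igs[[key]]$genes)
    }
  }
  # false positives can only be genes genuinely qualifying in >= n-2 members
  for (key in names(res$group_igs)) {
    g <- res$group_igs[[key]]
    expect_true(all(g$counts[g$genes] >= g$threshold))
  }
  # every union-of-samples gene traces back to a qualifying variant
  qual <- qualifying_variants(co$genotypes, co$annotations)
  universe <- unique(co$annotations$gene[match(unique(unlist(qual)),
                                               co$annotations$variant_id)])
  expect_setequal(unique(unlist(res$sample_genes)), universe[!is.na(universe)])
})
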