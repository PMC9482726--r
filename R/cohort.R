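#' Specify a synthetic autism-severity exome cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' reproduce the structure of the study cohort the package targets: 33
#' children split 15 severe / 18 mild on overall (non-verbal IQ) severity,
#' with sub-phenotype severe/mild margins IQ 15/18, verbal 14/19, attention
#' 24/9 and memory 15/18, biallelic exome variants under Hardy-Weinberg
#' sampling, a set of planted case-enriched risk variants, and a set of
#' planted "important" genes carrying homozygous-alternate damaging variants
#' in a target sub-phenotype group.
#'
#' @param n_severe number of samples graded severe on overall severity.
#' @param n_mild number of samples graded mild.
#' @param n_variants total number of biallelic variants.
#' @param n_genes size of the gene universe; variants are assigned to genes
#'   `GENE0001` ... uniformly at random.
#' @param background_aaf baseline alternate-allele frequency in (0,1) shared
#'   by both groups at non-planted variants.
#' @param planted_risk_variants number of variants whose alternate-allele
#'   frequency is raised by `risk_delta` in the severe group only.
#' @param risk_delta additive alternate-allele-frequency increase for planted
#'   risk variants in severe samples; `background_aaf + risk_delta` must not
#'   exceed 1.
#' @param planted_ig_genes data frame with columns `gene` (1-based index into
#'   the gene universe), `group` (one of `"iq"`, `"memory"`, `"attention"`,
#'   `"verbal"`, or `"all"`) and `side` (`"severe"`, `"mild"`, or `"all"`).
#'   Each row plants one variant of that gene as homozygous-alternate and
#'   SIFT/PolyPhen-damaging in every member of the target group.
#' @param deleterious_rate_background probability that a non-planted variant
#'   carries a damaging SIFT + PolyPhen annotation pair.
#' @param missing_rate per-genotype missingness probability in `[0,1)`.
#' @param subphenotype_severe_counts named integer vector giving the number
#'   of severe samples on each of the four sub-phenotype axes.
#' @param subphenotype_discordance named numeric vector; per-axis fraction of
#'   samples whose axis label is swapped away from maximal concordance with
#'   overall severity (marginal counts are preserved). The IQ axis defaults
#'   to 0 because overall severity is itself the non-verbal IQ grading.
#' @param seed integer seed; one seed yields one bitwise-identical cohort.
#' @return an object of class `cohort_spec` (a validated list).
#' @seealso [simulate_cohort()], [write_cohort()]
#' @export
cohort_spec <- function(n_severe = 15L,
                        n_mild = 18L,
                        n_variants = 2000L,
                        n_genes = 400L,
                        background_aaf = 0.2,
                        planted_risk_variants = 20L,
                        risk_delta = 0.35,
                        planted_ig_genes = default_planted_ig_genes(),
                        deleterious_rate_background = 0.05,
                        missing_rate = 0.02,
                        subphenotype_severe_counts = c(iq = 15L, verbal = 14L,
                                                       attention = 24L, memory = 15L),
                        subphenotype_discordance = c(iq = 0, verbal = 0.1,
                                                     attention = 0.1, memory = 0.1),
                        seed = 1L) {
  spec <- structure(
    list(n_severe = as.integer(n_severe), n_mild = as.integer(n_mild),
         n_variants = as.integer(n_variants), n_genes = as.integer(n_genes),
         background_aaf = background_aaf,
         planted_risk_variants = as.integer(planted_risk_variants),
         risk_delta = risk_delta,
         planted_ig_genes = planted_ig_genes,
         deleterious_rate_background = deleterious_rate_background,
         missing_rate = missing_rate,
         subphenotype_severe_counts = subphenotype_severe_counts,
         subphenotype_discordance = subphenotype_discordance,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
default_planted_ig_genes <- function() {
  data.frame(
    gene = c(1L, 2L, 3L, 4L, 5L),
    group = c("all", "iq", "memory", "attention", "verbal"),
    side = c("all", "severe", "mild", "severe", "severe"),
    stringsAsFactors = FALSE
  )
}

validate_cohort_spec <- function(spec) {
  if (!is_count(spec$n_severe, 1L)) stop_validation("n_severe must be a positive integer")
  if (!is_count(spec$n_mild, 1L)) stop_validation("n_mild must be a positive integer")
  if (!is_count(spec$n_variants, 1L)) stop_validation("n_variants must be a positive integer")
  if (!is_count(spec$n_genes, 1L)) stop_validation("n_genes must be a positive integer")
  if (!is_prob(spec$background_aaf) || spec$background_aaf <= 0 || spec$background_aaf >= 1)
    stop_validation("background_aaf must lie strictly inside (0,1)")
  if (!is_prob(spec$risk_delta))
    stop_validation("risk_delta must be a probability in [0,1]")
  if (spec$background_aaf + spec$risk_delta > 1)
    stop_validation("background_aaf + risk_delta must not exceed 1")
  if (!is_count(spec$planted_risk_variants))
    stop_validation("planted_risk_variants must be a non-negative integer")
  if (spec$planted_risk_variants > spec$n_variants)
    stop_validation("planted_risk_variants must not exceed n_variants")
  if (!is_prob(spec$deleterious_rate_background))
    stop_validation("deleterious_rate_background must be a probability")
  if (!is_prob(spec$missing_rate) || spec$missing_rate >= 1)
    stop_validation("missing_rate must lie in [0,1)")
  ig <- spec$planted_ig_genes
  if (!is.null(ig) && nrow(ig) > 0L) {
    if (!all(c("gene", "group", "side") %in% names(ig)))
      stop_validation("planted_ig_genes needs columns gene, group, side")
    if (any(ig$gene < 1L | ig$gene > spec$n_genes))
      stop_validation("planted_ig_genes: every gene index must lie in 1..n_genes")
    if (!all(ig$group %in% c(subphenotype_axes(), "all")))
      stop_validation("planted_ig_genes: group must be iq/memory/attention/verbal/all")
    if (!all(ig$side %in% c("severe", "mild", "all")))
      stop_validation("planted_ig_genes: side must be severe/mild/all")
    if (nrow(ig) > spec$n_variants - spec$planted_risk_variants)
      stop_validation("not enough variants to host the planted IG genes")
  }
  n <- spec$n_severe + spec$n_mild
  cnt <- spec$subphenotype_severe_counts
  if (!all(subphenotype_axes() %in% names(cnt)))
    stop_validation("subphenotype_severe_counts must name iq, verbal, attention, memory")
  if (any(cnt < 0L | cnt > n))
    stop_validation("subphenotype_severe_counts must lie in 0..n_samples")
  if (!is_count(spec$seed)) stop_validation("seed must be a single non-negative integer")
  invisible(spec)
}

subphenotype_axes <- function() c("iq", "memory", "attention", "verbal")

# Assign one sub-phenotype axis: start maximally concordant with overall
# severity, adjust to hit the target severe margin, then apply label swaps
# (severe <-> mild pairs) so the margin is preserved while concordance drops.
assign_axis <- function(severity, m_severe, discordance) {
  lab <- severity
  sev_idx <- which(severity == "severe")
  mild_idx <- which(severity == "mild")
  n_sev <- length(sev_idx)
  if (m_severe < n_sev) {
    lab[sample(sev_idx, n_sev - m_severe)] <- "mild"
  } else if (m_severe > n_sev) {
    lab[sample(mild_idx, m_severe - n_sev)] <- "severe"
  }
  n_swaps <- round(discordance * length(severity) / 2)
  if (n_swaps > 0L) {
    s_pool <- which(lab == "severe")
    m_pool <- which(lab == "mild")
    n_swaps <- min(n_swaps, length(s_pool), length(m_pool))
    if (n_swaps > 0L) {
      s_pick <- sample(s_pool, n_swaps)
      m_pick <- sample(m_pool, n_swaps)
      lab[s_pick] <- "mild"
      lab[m_pick] <- "severe"
    }
  }
  lab
}

#' Simulate a synthetic exome cohort with planted structure
#'
#' Draws diploid genotypes per variant per sample as Binomial(2, f) under
#' Hardy-Weinberg equilibrium. Non-planted variants share
#' `background_aaf` across groups; planted risk variants use
#' `background_aaf + risk_delta` in severe samples only. Each planted
#' important gene receives one dedicated variant, annotated
#' SIFT `"deleterious"` / PolyPhen `"probably_damaging"`, set
#' homozygous-alternate in every member of its target sub-phenotype group
#' (those planted cells are exempt from missingness so the planted signal
#' stays crisp). Sub-phenotype labels reproduce the configured severe/mild
#' margins while staying as concordant with overall severity as the
#' configured discordance allows.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `genotypes` (samples x variants integer matrix, entries 0/1/2 or `NA`),
#'   `annotations` (data frame: `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `sift`, `polyphen`, `aaf_1kg`), `phenotypes` (data frame:
#'   `sample_id`, `severity`, `iq`, `memory`, `attention`, `verbal`),
#'   `truth` (list: `risk_variants` character vector, `ig_genes` data frame
#'   with `gene`, `group`, `side`, `variant_id`), and the `spec` itself.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_variants = 200, seed = 7))
#' dim(cohort$genotypes)
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_severe + spec$n_mild
  v <- spec$n_variants
  sample_ids <- sprintf("S%03d", seq_len(n))
  severity <- c(rep("severe", spec$n_severe), rep("mild", spec$n_mild))

  # Sub-phenotype labels first: IG planting targets these groups.
  axes <- subphenotype_axes()
  labels <- lapply(axes, function(ax) {
    assign_axis(severity,
                m_severe = spec$subphenotype_severe_counts[[ax]],
                discordance = spec$subphenotype_discordance[[ax]])
  })
  names(labels) <- axes
  phenotypes <- data.frame(sample_id = sample_ids, severity = severity,
                           iq = labels$iq, memory = labels$memory,
                           attention = labels$attention, verbal = labels$verbal,
                           stringsAsFactors = FALSE)

  # Variant scaffolding: gene assignment, loci, alleles.
  gene_universe <- sprintf("GENE%04d", seq_len(spec$n_genes))
  gene <- gene_universe[sample.int(spec$n_genes, v, replace = TRUE)]
  variant_ids <- sprintf("v%05d", seq_len(v))
  chrom <- as.character(rep(1:22, each = ceiling(v / 22))[seq_len(v)])
  pos <- integer(v)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 1000L * seq_along(idx)
  }
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, v, replace = TRUE)]
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  # Planted indices: risk variants, then one dedicated variant per IG row.
  risk_idx <- if (spec$planted_risk_variants > 0L)
    sort(sample.int(v, spec$planted_risk_variants)) else integer(0)
  ig <- spec$planted_ig_genes
  n_ig <- if (is.null(ig)) 0L else nrow(ig)
  ig_idx <- if (n_ig > 0L) sort(sample(setdiff(seq_len(v), risk_idx), n_ig)) else integer(0)
  if (n_ig > 0L) gene[ig_idx] <- gene_universe[ig$gene]

  # Genotypes under Hardy-Weinberg: Binomial(2, f) per variant per sample.
  f <- matrix(spec$background_aaf, nrow = n, ncol = v)
  if (length(risk_idx) > 0L && spec$risk_delta > 0)
    f[severity == "severe", risk_idx] <- spec$background_aaf + spec$risk_delta
  geno <- matrix(stats::rbinom(n * v, size = 2L, prob = f), nrow = n, ncol = v,
                 dimnames = list(sample_ids, variant_ids))

  # Annotations: planted IG variants always damaging; background variants
  # damaging with the configured rate (labels drawn over the qualifying
  # token pairs), otherwise benign.
  sift <- rep("tolerated", v)
  polyphen <- rep("benign", v)
  bg_dmg <- stats::runif(v) < spec$deleterious_rate_background
  sift[bg_dmg] <- sample(c("deleterious", "deleterious_low_confidence"),
                         sum(bg_dmg), replace = TRUE)
  polyphen[bg_dmg] <- sample(c("probably_damaging", "possibly_damaging"),
                             sum(bg_dmg), replace = TRUE)
  aaf_1kg <- round(pmin(pmax(f[1L, ] + stats::rnorm(v, 0, 0.02), 0), 1), 4)

  # Plant IG genes: hom-alt damaging variant in every member of the target
  # group; protect those cells from missingness.
  protected <- matrix(FALSE, nrow = n, ncol = v)
  truth_ig <- NULL
  if (n_ig > 0L) {
    sift[ig_idx] <- "deleterious"
    polyphen[ig_idx] <- "probably_damaging"
    # side "all": both severities, i.e. every sample. group "all" with a
    # fixed side: samples on that side of every axis simultaneously.
    members_of <- function(group, side) {
      if (side == "all") return(seq_len(n))
      ax <- if (group == "all") axes else group
      keep <- rep(TRUE, n)
      for (a in ax) keep <- keep & labels[[a]] == side
      which(keep)
    }
    truth_ig <- data.frame(gene = gene_universe[ig$gene], group = ig$group,
                           side = ig$side, variant_id = variant_ids[ig_idx],
                           stringsAsFactors = FALSE)
    for (r in seq_len(n_ig)) {
      mem <- members_of(ig$group[r], ig$side[r])
      geno[mem, ig_idx[r]] <- 2L
      protected[mem, ig_idx[r]] <- TRUE
    }
  }

  # Missingness injected uniformly at random after sampling.
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(n * v) < spec$missing_rate, nrow = n, ncol = v)
    miss[protected] <- FALSE
    geno[miss] <- NA_integer_
  }

  annotations <- data.frame(variant_id = variant_ids, chrom = chrom, pos = pos,
                            ref = ref, alt = alt, gene = gene, sift = sift,
                            polyphen = polyphen, aaf_1kg = aaf_1kg,
                            stringsAsFactors = FALSE)
  structure(
    list(genotypes = geno, annotations = annotations, phenotypes = phenotypes,
         truth = list(risk_variants = variant_ids[risk_idx],
                      ig_genes = truth_ig),
         spec = spec),
    class = "synthetic_cohort")
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic exome cohort: %d samples (%d severe / %d mild), %d variants\n",
              nrow(x$genotypes), x$spec$n_severe, x$spec$n_mild, ncol(x$genotypes)))
  cat(sprintf("  planted risk variants: %d; planted IG genes: %d; seed %d\n",
              length(x$truth$risk_variants),
              if (is.null(x$truth$ig_genes)) 0L else nrow(x$truth$ig_genes),
              x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits a multi-sample VCF 4.2 (INFO keys `GENE`, `SIFT`, `POLYPHEN`,
#' `AAF_1KG`; FORMAT `GT` only), a tab-delimited phenotype table, and two
#' truth files listing the planted risk variants and planted important genes.
#' The files round-trip losslessly through [read_vcf()] and
#' [read_phenotypes()], and are byte-identical across runs for a fixed spec.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the written paths
#'   (`vcf`, `phenotypes`, `truth_variants`, `truth_genes`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop_validation("write_cohort expects a synthetic_cohort")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io("cannot create output directory: ", dir)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth_variants = file.path(dir, "truth_variants.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"))

  geno <- cohort$genotypes
  ann <- cohort$annotations
  gt_tok <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  not_na <- !is.na(geno)
  gt[not_na] <- gt_tok[geno[not_na] + 1L]

  info <- sprintf("GENE=%s;SIFT=%s;POLYPHEN=%s;AAF_1KG=%.4f",
                  ann$gene, ann$sift, ann$polyphen, ann$aaf_1kg)
  body <- paste(ann$chrom, ann$pos, ann$variant_id, ann$ref, ann$alt,
                ".", "PASS", info, "GT",
                apply(gt, 2L, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=riskgrader %s seed=%d",
            as.character(utils::packageVersion("riskgrader")), cohort$spec$seed),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT label\">",
    "##INFO=<ID=POLYPHEN,Number=1,Type=String,Description=\"PolyPhen label\">",
    "##INFO=<ID=AAF_1KG,Number=1,Type=Float,Description=\"Population alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  writeLines(c(header, body), paths[["vcf"]])

  write_tsv_prov(cohort$phenotypes, paths[["phenotypes"]], seed = cohort$spec$seed)
  write_tsv_prov(data.frame(variant_id = cohort$truth$risk_variants,
                            stringsAsFactors = FALSE),
                 paths[["truth_variants"]], seed = cohort$spec$seed)
  ig <- cohort$truth$ig_genes
  if (is.null(ig))
    ig <- data.frame(gene = character(0), group = character(0),
                     side = character(0), variant_id = character(0))
  write_tsv_prov(ig, paths[["truth_genes"]], seed = cohort$spec$seed)
  invisible(paths)
}
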