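#' Read an annotated multi-sample VCF into the pipeline's data model
#'
#' Parses a VCF 4.x file (via the vcfR reader) into a samples-by-variants
#' dosage matrix and a per-variant annotation table. Genotypes map as
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`; half-calls
#' (e.g. `0/.`) are treated as missing. Phased separators (`|`) are accepted.
#' The four annotation INFO keys are configurable so real-world VCFs with
#' different key names can be consumed; absent keys are recorded as `NA`.
#'
#' Only biallelic records are supported: a record with a comma in ALT raises
#' an error naming the locus, instructing upstream decomposition
#' (e.g. `bcftools norm -m-`).
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param info_keys named character vector mapping the canonical annotation
#'   names `gene`, `sift`, `polyphen`, `aaf_1kg` to the INFO keys used in
#'   the file.
#' @return a list with `genotypes` (integer matrix, samples x variants,
#'   entries 0/1/2 or `NA`, dimnames set) and `annotations` (data frame with
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `sift`, `polyphen`,
#'   `aaf_1kg`), variant order as in the file.
#' @export
read_vcf <- function(path,
                     info_keys = c(gene = "GENE", sift = "SIFT",
                                   polyphen = "POLYPHEN", aaf_1kg = "AAF_1KG")) {
  if (!file.exists(path)) stop_io("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1L]
    stop_validation(sprintf(
      "multi-allelic record at %s:%s (ALT=%s); decompose upstream (e.g. bcftools norm -m-) before loading",
      fix[i, "CHROM"], fix[i, "POS"], alt[i]))
  }
  ref <- fix[, "REF"]
  if (any(ref == alt))
    stop_validation("record with REF equal to ALT at index ",
                    which(ref == alt)[1L])
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"], ":",
                       ref[no_id], ":", alt[no_id])
  if (anyDuplicated(ids)) stop_validation("duplicate variant IDs in VCF")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dosage[gt_clean %in% c("0/0")] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean %in% c("1/1")] <- 2L
  # anything else: missing if it contains '.', malformed otherwise
  unmapped <- is.na(dosage) & !is.na(gt_clean) & !grepl(".", gt_clean, fixed = TRUE)
  if (any(unmapped)) {
    bad <- which(unmapped, arr.ind = TRUE)[1L, ]
    stop_io(sprintf("malformed GT '%s' at record %d, sample %d",
                    gt[bad[1L], bad[2L]], bad[1L], bad[2L]))
  }
  geno <- t(dosage)
  dimnames(geno) <- list(colnames(gt), ids)

  pull_info <- function(key, as_num = FALSE) {
    val <- vcfR::extract.info(vcf, element = key, as.numeric = as_num)
    if (is.null(val)) val <- rep(NA, nrow(fix))
    val
  }
  annotations <- data.frame(
    variant_id = ids,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref,
    alt = alt,
    gene = as.character(pull_info(info_keys[["gene"]])),
    sift = as.character(pull_info(info_keys[["sift"]])),
    polyphen = as.character(pull_info(info_keys[["polyphen"]])),
    aaf_1kg = suppressWarnings(as.numeric(pull_info(info_keys[["aaf_1kg"]], as_num = TRUE))),
    stringsAsFactors = FALSE)
  if (any(annotations$pos < 1L)) stop_validation("VCF position < 1")
  list(genotypes = geno, annotations = annotations)
}

#' Read a phenotype table aligned to the genotype samples
#'
#' Expects a tab-delimited file with header columns `sample_id`, `severity`,
#' `iq`, `memory`, `attention`, `verbal` and values `severe`/`mild`
#' (case-insensitive). Leading `#` comment lines are skipped. The returned
#' table is reordered to match `samples`.
#'
#' @param path path to the TSV file.
#' @param samples ordered character vector of sample IDs (typically the
#'   rownames of the genotype matrix); every sample must appear exactly once.
#' @param aliases optional named character vector renaming columns before
#'   validation, e.g. `c(language = "verbal")` for tables using the
#'   "language" naming of the verbal axis.
#' @return data frame with one row per requested sample, severity columns
#'   normalized to lower-case `"severe"`/`"mild"`.
#' @export
read_phenotypes <- function(path, samples, aliases = NULL) {
  if (!file.exists(path)) stop_io("phenotype table not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  for (old in names(aliases))
    names(tab)[names(tab) == old] <- aliases[[old]]
  required <- c("sample_id", "severity", "iq", "memory", "attention", "verbal")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop_validation("phenotype table lacks column(s): ",
                    paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop_validation("duplicate sample in phenotype table: ",
                    tab$sample_id[duplicated(tab$sample_id)][1L])
  absent <- setdiff(samples, tab$sample_id)
  if (length(absent) > 0L)
    stop_validation("sample missing from phenotype table: ", absent[1L])
  tab <- tab[match(samples, tab$sample_id), required, drop = FALSE]
  for (col in required[-1L]) {
    val <- tolower(trimws(tab[[col]]))
    bad <- !(val %in% c("severe", "mild"))
    if (any(bad))
      stop_validation(sprintf("unknown severity token '%s' in column %s (sample %s)",
                              tab[[col]][bad][1L], col, tab$sample_id[bad][1L]))
    tab[[col]] <- val
  }
  rownames(tab) <- NULL
  tab
}
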