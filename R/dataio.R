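# Readers and writers for the external formats: VCF genotypes, TSV
# count/taxonomy/covariate tables, BED gene annotation, and the
# summary-statistics TSV.

#' Read genotypes from a VCF file
#'
#' Parses biallelic SNP records into a [GenotypeMatrix-class].
#' Dosage is the alternative-allele count from the GT field ("./." and
#' ".|." become missing). When `prefer_dosage = TRUE` and a record has
#' no GT call, the DS field rounded to the nearest integer is used
#' instead (the association models code genotypes 0/1/2). Imputation
#' quality is taken from the INFO key named by `info_key` when
#' present.
#'
#' @param path VCF file (plain or bgzipped).
#' @param prefer_dosage use rounded DS where GT is absent.
#' @param info_key INFO key holding imputation R2 (default `"R2"`).
#' @return A [GenotypeMatrix-class].
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "mbGWAS")
#' g <- readGenotypes(vcf)
#' dosage(g)
#' @export
readGenotypes <- function(path, prefer_dosage = FALSE, info_key = "R2") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # CHROM POS ID REF ALT QUAL FILTER INFO
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multiallelic record(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt_avail <- any(grepl("(^|:)GT(:|$)", v@gt[, 1]))
  ds_avail <- any(grepl("(^|:)DS(:|$)", v@gt[, 1]))
  if (!gt_avail && !ds_avail)
    stop("VCF has neither GT nor DS fields")
  n_var <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  dos <- matrix(NA_real_, length(samples), n_var)
  if (gt_avail) {
    gts <- vcfR::extract.gt(v, element = "GT")
    a1 <- substr(gts, 1, 1)
    a2 <- substr(gts, 3, 3)
    d <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
    dos <- t(matrix(d, nrow = n_var))
  }
  if (ds_avail && prefer_dosage) {
    dsv <- suppressWarnings(
      as.numeric(vcfR::extract.gt(v, element = "DS")))
    dsm <- t(matrix(dsv, nrow = n_var))
    fill <- is.na(dos) & !is.na(dsm)
    # only where GT was truly absent (no GT field or "." call)
    dos[fill] <- round(dsm[fill])
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  info <- fix[, "INFO"]
  r2 <- suppressWarnings(as.numeric(
    sub(paste0(".*(?:^|;)", info_key, "=([^;]+).*"), "\\1",
        info, perl = TRUE)))
  r2[!grepl(paste0("(^|;)", info_key, "="), info)] <- NA_real_
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ids, ref = fix[, "REF"], alt = alt,
    stringsAsFactors = FALSE)
  if (any(!is.na(r2))) variants$impR2 <- r2
  dimnames(dos) <- list(samples, ids)
  GenotypeMatrix(dos, variants)
}

#' Write a GenotypeMatrix as VCF
#'
#' Emits a minimal VCF 4.2 file with GT fields (and the imputation R2
#' as an INFO key when present), so simulated cohorts round-trip
#' through the standard format.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file.
#' @param info_key INFO key name for imputation R2.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path, info_key = "R2") {
  d <- dosage(g)
  v <- as.data.frame(variantInfo(g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation quality\">",
            info_key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    gt <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1])
    info <- if (!is.null(v$impR2) && !is.na(v$impR2[j]))
      sprintf("%s=%.6g", info_key, v$impR2[j]) else "."
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j],
                       v$alt[j], ".", "PASS", info, "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a count table and its taxonomy
#'
#' The count TSV has one row per sample and one column per feature;
#' the taxonomy TSV has a `feature_id` column plus the seven rank
#' columns. Every feature in the counts must have a taxonomy row.
#'
#' @param count_path TSV of counts (samples x features).
#' @param taxonomy_path TSV of lineages.
#' @return A [TaxaCounts-class].
#' @export
readCounts <- function(count_path, taxonomy_path) {
  cnt <- read.table(count_path, header = TRUE, sep = "\t",
                    row.names = 1, check.names = FALSE)
  tax <- read.table(taxonomy_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(cnt)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(m))) stop("duplicate feature ids")
  if (!"feature_id" %in% colnames(tax))
    stop("taxonomy file needs a feature_id column")
  if (anyDuplicated(tax$feature_id)) stop("duplicate feature ids in taxonomy")
  TaxaCounts(t(m), tax)
}

#' @rdname readCounts
#' @param tc a [TaxaCounts-class] to write.
#' @param count_path,taxonomy_path output TSV paths.
#' @export
writeCounts <- function(tc, count_path, taxonomy_path) {
  m <- t(counts(tc))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, count_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tax <- taxonomy(tc)
  tax <- data.frame(feature_id = rownames(tax), tax, check.names = FALSE)
  write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(count_path)
}

#' Read / write the per-sample covariate table
#'
#' Expected columns: `sample_id`, `sex`, `age`, `bmi`, `smoking`,
#' `alcohol`, `glycemic_state`, `seq_run`, `pc1`..`pc10`. Categorical
#' columns are kept as character; the design builder one-hot encodes
#' them with the first level as reference.
#'
#' @param path TSV path.
#' @return `readCovariates`: a data.frame with sample ids as rownames.
#' @export
readCovariates <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% colnames(x))
    stop("covariate file needs a sample_id column")
  if (anyDuplicated(x$sample_id)) stop("duplicate sample ids")
  rownames(x) <- x$sample_id
  x$sample_id <- NULL
  miss <- setdiff(COVARIATE_COLS, colnames(x))
  if (length(miss))
    stop("covariate table missing columns: ", paste(miss, collapse = ", "))
  x
}

#' @rdname readCovariates
#' @param covariates data.frame with sample ids as rownames.
#' @export
writeCovariates <- function(covariates, path) {
  df <- data.frame(sample_id = rownames(covariates), covariates,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SUMSTATS_COLS <- c("Chromosome", "Position", "P", "EffectSize", "A1",
                   "A2", "StandardError", "rsID", "TaxonName",
                   "TaxonLevel")

#' Write / read association summary statistics
#'
#' Tab-separated with one header line and the columns Chromosome,
#' Position, P, EffectSize, A1, A2, StandardError, rsID, TaxonName,
#' TaxonLevel. The effect size is reported for the A2 (counted,
#' alternative) allele. Numeric values are written with 12 significant
#' digits so a read-back reproduces them.
#'
#' @param assoc data.frame with (at least) columns `chrom`, `pos`,
#'   `p`, `beta`, `a1`, `a2`, `se`, `id`, `feature_name`,
#'   `feature_rank`.
#' @param path output TSV.
#' @return `path` invisibly; `readSumstats` returns the table with the
#'   internal column names.
#' @export
writeSumstats <- function(assoc, path) {
  need <- c("chrom", "pos", "p", "beta", "a1", "a2", "se", "id",
            "feature_name", "feature_rank")
  miss <- setdiff(need, colnames(assoc))
  if (length(miss))
    stop("association table missing columns: ",
         paste(miss, collapse = ", "))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))
  out <- data.frame(
    Chromosome = assoc$chrom, Position = assoc$pos,
    P = fmt(assoc$p), EffectSize = fmt(assoc$beta),
    A1 = assoc$a1, A2 = assoc$a2, StandardError = fmt(assoc$se),
    rsID = assoc$id, TaxonName = assoc$feature_name,
    TaxonLevel = assoc$feature_rank, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSumstats
#' @export
readSumstats <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(SUMSTATS_COLS, colnames(x))
  if (length(miss))
    stop("summary statistics missing columns: ",
         paste(miss, collapse = ", "))
  data.frame(
    chrom = as.character(x$Chromosome), pos = x$Position, p = x$P,
    beta = x$EffectSize, a1 = x$A1, a2 = x$A2, se = x$StandardError,
    id = x$rsID, feature_name = x$TaxonName,
    feature_rank = x$TaxonLevel, stringsAsFactors = FALSE)
}

#' Read gene annotation from BED
#'
#' BED intervals (0-based, half-open) are converted to 1-based closed
#' coordinates on read and returned as a
#' [GenomicRanges::GRanges] with a `name` column, for nearest-gene
#' locus naming.
#'
#' @param path BED file (>= 4 columns: chrom, start, end, name).
#' @return A `GRanges`.
#' @export
readGenesBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) gr$name <- paste0("gene", seq_along(gr))
  gr
}
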