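# Readers and writers for the formats the pipeline touches: VCF and
# delimited genotype matrices in, results/calibration TSVs and a JSON run
# record out. Internal matrices are position-agnostic; VCF coordinates stay
# 1-based as in the format.

#' Read a genotype dosage matrix
#'
#' VCF input keeps biallelic SNVs only (multiallelic records are skipped and
#' counted); the dosage is the count of ALT alleles in the GT field, `NA`
#' for missing calls. Matrix input is a whitespace- or comma-delimited
#' subjects x variants table with a header row of variant IDs (and an
#' optional leading `sample_id` column).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"`.
#' @return List with `genotypes` (subjects x variants numeric matrix),
#'   `variants` (tibble: chrom, pos, id, ref, alt — NAs for matrix input)
#'   and `n_skipped` (multiallelic records dropped).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  }
  if (format == "vcf") read_vcf_genotypes(path) else read_matrix_genotypes(path)
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_skipped <- sum(multi)
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(as.numeric(a1 == "1") + as.numeric(a2 == "1"),
                nrow = nrow(gt), dimnames = dimnames(gt))
  dos[a1 == "." | is.na(gt)] <- NA
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  if (anyDuplicated(colnames(gt))) abort("duplicate sample IDs in VCF.")
  g <- t(dos)
  colnames(g) <- ids
  list(
    genotypes = g,
    variants = tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids,
                      ref = fix$REF, alt = fix$ALT),
    n_skipped = n_skipped
  )
}

read_matrix_genotypes <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  rn <- NULL
  if (ncol(df) > 0 && (colnames(df)[1] %in% c("sample_id", "sample"))) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  g <- as.matrix(df)
  storage.mode(g) <- "double"
  if (!is.null(rn)) rownames(g) <- rn
  list(
    genotypes = g,
    variants = tibble(chrom = NA_character_, pos = NA_integer_,
                      id = colnames(g), ref = NA_character_,
                      alt = NA_character_),
    n_skipped = 0L
  )
}

#' Write a genotype matrix (delimited or VCF)
#'
#' @param genotypes Subjects x variants numeric matrix.
#' @param path Output file; a `.vcf` extension writes a minimal VCFv4.2
#'   file (hard calls only; `NA` becomes `./.`), anything else a
#'   tab-delimited matrix with a `sample_id` column and variant-ID header.
#' @param variants Optional tibble (chrom, pos, id, ref, alt) for VCF
#'   output; placeholders are generated when absent.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, variants = NULL) {
  g <- as_dosage_matrix(genotypes)
  if (grepl("\\.vcf$", path)) {
    write_vcf(g, path, variants)
  } else {
    df <- data.frame(sample_id = rownames(g) %||% paste0("s", seq_len(nrow(g))),
                     g, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

write_vcf <- function(g, path, variants = NULL) {
  V <- ncol(g)
  if (is.null(variants)) {
    variants <- tibble(chrom = "1", pos = seq_len(V),
                       id = variant_ids(g), ref = "A", alt = "C")
  }
  samples <- rownames(g) %||% paste0("s", seq_len(nrow(g)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=iecatrc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(V)) {
    gt <- code[as.character(g[, j])]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(variants$chrom[j], variants$pos[j], variants$id[j],
                       variants$ref[j], variants$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Basic per-variant quality control
#'
#' Removes variants whose missing rate exceeds `missing_max` or whose
#' (folded) minor allele frequency among non-missing calls is below
#' `maf_min`, then mean-imputes any remaining missingness so downstream
#' calibration and testing never see NAs.
#'
#' @param genotypes Subjects x variants matrix, possibly with NAs.
#' @param maf_min Minimum MAF (default 0 keeps all polymorphic handling to
#'   the dispatch layer).
#' @param missing_max Maximum tolerated per-variant missing rate.
#' @return List with `genotypes` (filtered, imputed) and `report` (tibble:
#'   variant_id, reason) listing removals.
#' @export
apply_basic_qc <- function(genotypes, maf_min = 0, missing_max = 1) {
  g <- as_dosage_matrix(genotypes)
  ids <- variant_ids(g)
  miss <- colMeans(is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  drop_miss <- miss > missing_max
  drop_maf <- !drop_miss & maf < maf_min
  report <- bind_rows(
    tibble(variant_id = ids[drop_miss], reason = "missingness"),
    tibble(variant_id = ids[drop_maf], reason = "MAF")
  )
  keep <- !(drop_miss | drop_maf)
  g <- g[, keep, drop = FALSE]
  if (anyNA(g)) {
    cm <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- cm[idx[, 2]]
  }
  list(genotypes = g, report = report)
}

#' Write a results table as TSV
#'
#' Deterministic column order, full-precision p-values (shortest
#' round-trip representation, scientific notation where needed). List
#' columns are dropped.
#'
#' @param table A results tibble/data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  tb <- as_tibble(table)
  tb <- tb[, !vapply(tb, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Write a JSON run record
#'
#' Records the configuration, seed, package and R versions, and a hash of
#' the configuration, so a run is reproducible from its metadata alone.
#'
#' @param config A named list (e.g. an [sim_config()] or CLI options).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  cfg <- unclass(config)
  jsonlite::write_json(
    list(
      config = cfg,
      config_hash = rlang::hash(cfg),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("iecatrc")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab- or comma-delimited with columns `sample_id`, `phenotype`, and any
#' number of covariate columns.
#'
#' @param path Input file.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
}
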