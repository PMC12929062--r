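#' Read a genotype matrix from VCF or TSV
#'
#' Loads biallelic SNP genotypes as minor-allele dosage codes (0/1/2) together
#' with a marker map. Codes are recoded at load time so that the counted allele
#' has frequency <= 0.5 in the loaded samples; at a tie (frequency exactly 0.5)
#' the ALT allele stays the counted allele. Missing calls are mean-imputed per
#' marker and the imputed fraction is recorded in the `imputed_fraction`
#' attribute.
#'
#' The TSV dialect is a tab-delimited table with columns
#' `marker`, `chrom`, `pos`, then one column per sample holding 0/1/2 codes
#' (`NA` allowed). Positions are 1-based bp.
#'
#' @param path Path to a `.vcf` or tab-delimited file.
#' @param dialect `"vcf"` or `"tsv"`. Guessed from the extension when `NULL`.
#' @return A `GenotypeMatrix`: list with `codes` (sample x marker numeric
#'   matrix, dimnames set), `map` (data.frame `marker`, `chrom`, `pos`),
#'   `sample_ids`, `marker_ids`, and attribute `imputed_fraction`.
#' @export
read_genotype_matrix <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  dialect <- match.arg(dialect, c("vcf", "tsv"))
  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
    if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
      stop("multi-allelic VCF record found; only biallelic SNPs are supported")
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    # count ALT alleles per call; tolerate / and | separators
    raw <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
      alleles <- strsplit(x, "[/|]")[[1]]
      sum(alleles == "1")
    })
    marker_ids <- fix[, "ID"]
    no_id <- is.na(marker_ids) | marker_ids == "."
    marker_ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
    codes <- t(raw)  # samples x markers
    colnames(codes) <- marker_ids
    map <- data.frame(marker = marker_ids, chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("marker", "chrom", "pos")
    if (!all(need %in% names(tab))) {
      stop("genotype TSV must have columns marker, chrom, pos")
    }
    sample_cols <- setdiff(names(tab), need)
    if (length(sample_cols) == 0L) stop("genotype TSV has no sample columns")
    codes <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
    storage.mode(codes) <- "double"
    colnames(codes) <- tab$marker
    rownames(codes) <- sample_cols
    map <- data.frame(marker = tab$marker, chrom = as.character(tab$chrom),
                      pos = as.integer(tab$pos), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(map$marker)) stop("duplicate marker id in genotype input")
  if (anyDuplicated(rownames(codes))) stop("duplicate sample id in genotype input")
  bad <- codes[!is.na(codes) & !(codes %in% c(0, 1, 2))]
  if (length(bad)) stop("genotype codes must be 0, 1, 2 or missing")
  new_genotype_matrix(codes, map)
}

#' Construct a validated GenotypeMatrix
#'
#' Recodes to minor-allele counts, mean-imputes missing calls, and sorts the
#' map by chromosome then position.
#'
#' @param codes sample x marker numeric matrix of allele counts (0/1/2/NA),
#'   dimnames required.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (1-based bp).
#' @param recode_minor flip codes (2 - x) wherever the counted-allele
#'   frequency exceeds 0.5. Default TRUE.
#' @return GenotypeMatrix (list with class `"GenotypeMatrix"`).
#' @export
new_genotype_matrix <- function(codes, map, recode_minor = TRUE) {
  stopifnot(is.matrix(codes), !is.null(rownames(codes)), !is.null(colnames(codes)))
  if (!identical(colnames(codes), map$marker)) {
    map <- map[match(colnames(codes), map$marker), , drop = FALSE]
  }
  if (anyNA(map$pos)) stop("marker map incomplete")
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("marker positions must be strictly increasing within chromosome ", ch)
  }
  n_missing <- sum(is.na(codes))
  freq <- colMeans(codes, na.rm = TRUE) / 2
  if (recode_minor) {
    flip <- which(!is.na(freq) & freq > 0.5)
    if (length(flip)) codes[, flip] <- 2 - codes[, flip]
  }
  if (n_missing > 0L) {
    for (j in which(colSums(is.na(codes)) > 0L)) {
      m <- mean(codes[, j], na.rm = TRUE)
      if (is.nan(m)) m <- 0  # all-missing marker
      codes[is.na(codes[, j]), j] <- m
    }
  }
  out <- list(codes = codes, map = map,
              sample_ids = rownames(codes), marker_ids = map$marker)
  attr(out, "imputed_fraction") <- n_missing / length(codes)
  class(out) <- "GenotypeMatrix"
  out
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers on %d chromosome(s); imputed fraction %.4f\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom)),
              attr(x, "imputed_fraction")))
  invisible(x)
}

#' Read a typed pipeline table
#'
#' Reads tab-delimited inputs with schema validation. BED gene coordinates
#' (0-based half-open) are converted to the internal 1-based inclusive
#' convention at this boundary; all downstream code is 1-based inclusive.
#'
#' @param path file path.
#' @param schema one of `"plot_phenotype"` (columns genotype, environment,
#'   replicate, block, value), `"asv_counts"` (column sample + one column per
#'   ASV, non-negative integer counts), `"feature_matrix"` (column genotype +
#'   one numeric column per feature), `"bed_coordinates"` (BED3+1: chrom,
#'   start, end, name; no header).
#' @return A validated data.frame (plot_phenotype, bed_coordinates) or numeric
#'   matrix with row names (asv_counts, feature_matrix).
#' @export
read_table <- function(path,
                       schema = c("plot_phenotype", "asv_counts",
                                  "feature_matrix", "bed_coordinates")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("schema error: empty file ", path)
  if (schema == "bed_coordinates") {
    bed <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4L) stop("schema error: BED input needs chrom,start,end,name")
    out <- data.frame(feature = as.character(bed[[4]]),
                      chrom = as.character(bed[[1]]),
                      start = as.integer(bed[[2]]) + 1L,  # 0-based -> 1-based
                      end = as.integer(bed[[3]]),
                      stringsAsFactors = FALSE)
    if (any(out$start > out$end)) stop("schema error: empty/negative BED interval")
    return(out)
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("schema error: no data rows in ", path)
  if (schema == "plot_phenotype") {
    need <- c("genotype", "environment", "replicate", "block", "value")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
    if (!is.numeric(tab$value)) stop("parse error: non-numeric phenotype value")
    return(tab[, need])
  }
  key <- if (schema == "asv_counts") "sample" else "genotype"
  if (!key %in% names(tab)) stop("schema error: missing column ", key)
  m <- as.matrix(tab[, setdiff(names(tab), key), drop = FALSE])
  if (!is.numeric(m)) stop("parse error: non-numeric value in ", schema)
  rownames(m) <- tab[[key]]
  if (schema == "asv_counts" && any(m < 0 | m != round(m)))
    stop("parse error: counts must be non-negative integers")
  m
}

#' Write a result table as TSV
#'
#' Serializes pipeline result tables with floats at 6 significant digits so a
#' round trip reproduces values to serialization precision.
#'
#' @param obj data.frame or matrix (matrices are written with a leading id
#'   column named `id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  if (is.matrix(obj)) {
    obj <- data.frame(id = rownames(obj), obj, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(obj))
  fmt <- obj
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.5e", fmt[[j]])
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("IO error writing ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Convert internal 1-based inclusive intervals to BED (0-based half-open)
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally a
#'   name column.
#' @param name_col column to use as the BED name field.
#' @return data.frame in BED column order.
#' @export
to_bed <- function(df, name_col = NULL) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    stringsAsFactors = FALSE)
  if (!is.null(name_col)) out$name <- df[[name_col]]
  out
}
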