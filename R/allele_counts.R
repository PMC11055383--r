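#' Sparse per-cell allele counts
#'
#' Container for cellSNP-style sparse allele count matrices: `AD`
#' (alternative-allele read depth) and `DP` (total read depth), both
#' variants x cells, together with the variant records and the barcode
#' list.
#'
#' @param AD,DP Sparse (or dense) non-negative integer matrices, variants
#'   as rows, cells as columns, with `0 <= AD <= DP` entrywise.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (and optionally `id`); one row per AD/DP row.
#' @param barcodes Character vector, one per column.
#' @return An object of class `allele_count_set`: list with `AD`, `DP`
#'   (`dgCMatrix`), `variants` (with a `key` column `chrom:pos_ref/alt`)
#'   and `barcodes`.
#' @export
allele_count_set <- function(AD, DP, variants, barcodes) {
  AD <- methods::as(methods::as(AD, "CsparseMatrix"), "generalMatrix")
  DP <- methods::as(methods::as(DP, "CsparseMatrix"), "generalMatrix")
  if (!identical(dim(AD), dim(DP))) stop("AD and DP must have identical shapes")
  if (nrow(AD) != nrow(variants)) stop("variant list length must match matrix rows")
  if (ncol(AD) != length(barcodes)) stop("barcode list length must match matrix columns")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in allele count set")
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table misses column(s): ", paste(miss, collapse = ", "))
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  variants$key <- variant_key(variants)
  if (anyDuplicated(variants$key)) stop("duplicate (chrom, pos, ref, alt) variant records")
  if (any(AD@x < 0) || any(DP@x < 0)) stop("negative allele counts")
  if (max_entry(AD - DP) > 0) stop("AD must be <= DP entrywise")
  rownames(AD) <- rownames(DP) <- variants$key
  colnames(AD) <- colnames(DP) <- barcodes
  structure(list(AD = AD, DP = DP, variants = variants,
                 barcodes = as.character(barcodes)),
            class = "allele_count_set")
}

max_entry <- function(m) if (length(m@x)) max(m@x) else 0

#' @export
print.allele_count_set <- function(x, ...) {
  cat(sprintf("allele_count_set: %d variant(s) x %d cell(s), %d non-zero DP entries\n",
              nrow(x$DP), ncol(x$DP), length(x$DP@x)))
  invisible(x)
}

#' Canonical variant keys
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector `chrom:pos_ref/alt`.
#' @export
variant_key <- function(variants) {
  paste0(variants$chrom, ":", variants$pos, "_", variants$ref, "/", variants$alt)
}

#' Read a cellSNP-style allele count set
#'
#' @param ad_path,dp_path MatrixMarket (`.mtx`) files, variants x cells.
#' @param variants_path VCF file (extension `.vcf`), or a TSV fallback with
#'   header columns `CHROM,POS,REF,ALT` (optional `ID`).
#' @param barcodes_path One barcode per line.
#' @return An `allele_count_set`.
#' @export
read_allele_counts <- function(ad_path, dp_path, variants_path, barcodes_path) {
  for (p in c(ad_path, dp_path, variants_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  AD <- Matrix::readMM(ad_path)
  DP <- Matrix::readMM(dp_path)
  variants <- read_variant_records(variants_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  allele_count_set(AD, DP, variants, barcodes)
}

read_variant_records <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
               id = fix$ID, ref = fix$REF, alt = fix$ALT,
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df) <- sub("^X\\.", "", names(df))  # tolerate '#CHROM'
    need <- c("CHROM", "POS", "REF", "ALT")
    miss <- setdiff(need, toupper(names(df)))
    if (length(miss)) {
      stop("variant TSV misses column(s) ", paste(miss, collapse = ", "),
           " (expected header 'CHROM,POS,REF,ALT')")
    }
    names(df) <- toupper(names(df))
    data.frame(chrom = as.character(df$CHROM), pos = as.integer(df$POS),
               id = if ("ID" %in% names(df)) as.character(df$ID) else NA_character_,
               ref = df$REF, alt = df$ALT, stringsAsFactors = FALSE)
  }
}

#' Write an allele count set in cellSNP-like dialect
#'
#' Writes `AD.mtx`, `DP.mtx`, `variants.vcf` (site-only VCF v4.2) and
#' `barcodes.tsv` into a directory.
#'
#' @param counts An `allele_count_set`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_allele_counts <- function(counts, dir) {
  stopifnot(inherits(counts, "allele_count_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(ad = file.path(dir, "AD.mtx"), dp = file.path(dir, "DP.mtx"),
         variants = file.path(dir, "variants.vcf"),
         barcodes = file.path(dir, "barcodes.tsv"))
  Matrix::writeMM(counts$AD, f[["ad"]])
  Matrix::writeMM(counts$DP, f[["dp"]])
  write_variant_vcf(counts$variants, f[["variants"]])
  writeLines(counts$barcodes, f[["barcodes"]])
  invisible(f)
}

#' Write a site-only VCF v4.2 variant list
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, optional
#'   `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  id <- if ("id" %in% names(variants)) ifelse(is.na(variants$id), ".", variants$id) else "."
  header <- c("##fileformat=VCFv4.2",
              "##source=demuxrescue",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(variants$chrom, variants$pos)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$chrom[ord], as.integer(variants$pos[ord]), id[ord],
                  variants$ref[ord], variants$alt[ord])
  writeLines(c(header, body), path)
  invisible(path)
}
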