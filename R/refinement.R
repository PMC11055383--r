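#' Configuration of the genotype-refinement filters
#'
#' Thresholds for calling an overrepresented allele from pooled per-group
#' read counts.  A variant is callable in a cell group only when its
#' aggregated read depth strictly exceeds `depth_threshold` reads, and an
#' allele is overrepresented when its pooled frequency strictly exceeds
#' `freq_threshold`.  When `require_inconsistent_support` is on, a variant
#' called from the consistently assigned cells is kept only if the
#' inconsistently assigned cells (rescued or conflicting) either lack
#' coverage (aggregated depth not exceeding `inconsistent_depth_threshold`)
#' or show the same overrepresented allele.
#'
#' @param depth_threshold Aggregated read depth cutoff (strict `>`;
#'   default 10 reads).
#' @param freq_threshold Pooled allele-frequency cutoff (strict `>`;
#'   default 0.90; must be in (0.5, 1)).
#' @param require_inconsistent_support Check agreement with the
#'   inconsistent cell group (default `TRUE`).
#' @param inconsistent_depth_threshold Depth above which the inconsistent
#'   group's call is required to agree (default 10 reads).
#' @param inconsistent_freq_threshold Frequency cutoff (strict `>`) for
#'   the inconsistent group's overrepresented allele (default 0.5, i.e.
#'   its majority allele).  The agreement check exists to detect
#'   contradiction between the two cell groups, and the inconsistent
#'   group is typically small and shallow: re-applying the 90% calling
#'   cutoff there would reject genuine variants by binomial noise alone.
#'   Set it to `freq_threshold` for a symmetric, stricter check.
#' @param keep_uncovered_inconsistent Keep variants where the inconsistent
#'   group lacks coverage, on consistent-group evidence alone (default
#'   `TRUE`); `FALSE` drops them instead.
#' @param specific_mode `"unique_call"` (default): a variant is
#'   donor-specific when no other donor carries the same (variant, allele)
#'   call; `"exclusive"`: the variant must pass the filters in exactly one
#'   donor.
#' @return A list of class `refinement_config`.
#' @export
refinement_config <- function(depth_threshold = 10L,
                              freq_threshold = 0.90,
                              require_inconsistent_support = TRUE,
                              inconsistent_depth_threshold = 10L,
                              inconsistent_freq_threshold = 0.5,
                              keep_uncovered_inconsistent = TRUE,
                              specific_mode = c("unique_call", "exclusive")) {
  specific_mode <- match.arg(specific_mode)
  if (!(freq_threshold > 0.5 && freq_threshold < 1)) {
    stop("'freq_threshold' must lie in (0.5, 1)")
  }
  if (!(inconsistent_freq_threshold >= 0.5 && inconsistent_freq_threshold < 1)) {
    stop("'inconsistent_freq_threshold' must lie in [0.5, 1)")
  }
  if (depth_threshold < 1) stop("'depth_threshold' must be >= 1")
  structure(list(depth_threshold = as.integer(depth_threshold),
                 freq_threshold = freq_threshold,
                 require_inconsistent_support = isTRUE(require_inconsistent_support),
                 inconsistent_depth_threshold = as.integer(inconsistent_depth_threshold),
                 inconsistent_freq_threshold = inconsistent_freq_threshold,
                 keep_uncovered_inconsistent = isTRUE(keep_uncovered_inconsistent),
                 specific_mode = specific_mode),
            class = "refinement_config")
}

#' Split a donor's cells by assignment consistency
#'
#' The consistent group holds cells where hashing and genetic
#' demultiplexing agreed (`confirmed`); the inconsistent group holds cells
#' carried by genetics alone (`rescued`) or against the hashing call
#' (`conflict`).
#'
#' @param joint A `joint_assignment`.
#' @param donor A final singlet label present in `joint`.
#' @return List with character vectors `consistent` and `inconsistent`.
#' @export
partition_cells <- function(joint, donor) {
  stopifnot(inherits(joint, "joint_assignment"))
  labs <- joint$label[joint$kind == "singlet"]
  if (!donor %in% labs) stop("unknown donor label: ", donor)
  of_donor <- joint$kind == "singlet" & joint$label == donor
  list(consistent = joint$barcode[of_donor & joint$provenance == "confirmed"],
       inconsistent = joint$barcode[of_donor &
                                      joint$provenance %in% c("rescued", "conflict")])
}

#' Aggregate allele counts over a cell group
#'
#' @param counts An `allele_count_set`.
#' @param cells Barcodes to aggregate over (must all be in the set).
#' @return data.frame with columns `key`, `row`, `sumAD`, `sumDP`,
#'   restricted to variants with non-zero aggregated depth.
#' @export
aggregate_counts <- function(counts, cells) {
  stopifnot(inherits(counts, "allele_count_set"))
  cells <- as.character(cells)
  idx <- match(cells, counts$barcodes)
  if (anyNA(idx)) stop("unknown barcode(s): ",
                       paste(utils::head(cells[is.na(idx)], 5L), collapse = ", "))
  if (!length(idx)) {
    return(data.frame(key = character(), row = integer(),
                      sumAD = numeric(), sumDP = numeric()))
  }
  sAD <- Matrix::rowSums(counts$AD[, idx, drop = FALSE])
  sDP <- Matrix::rowSums(counts$DP[, idx, drop = FALSE])
  keep <- which(sDP > 0)
  data.frame(key = counts$variants$key[keep], row = keep,
             sumAD = sAD[keep], sumDP = sDP[keep],
             stringsAsFactors = FALSE)
}

#' Overrepresented-allele call from pooled counts
#'
#' Vectorized: returns `"none"` when the aggregated depth does not exceed
#' `depth_threshold`; otherwise `"ALT"` when `sumAD / sumDP >
#' freq_threshold`, `"REF"` when `(sumDP - sumAD) / sumDP > freq_threshold`,
#' else `"none"`.
#'
#' @param sumAD,sumDP Aggregated alternative and total read depths.
#' @param cfg A `refinement_config`.
#' @return Character vector over `{"REF", "ALT", "none"}`.
#' @export
overrepresented_allele <- function(sumAD, sumDP, cfg = refinement_config()) {
  if (length(sumAD) != length(sumDP)) stop("sumAD and sumDP lengths differ")
  if (any(sumAD > sumDP)) stop("sumAD exceeds sumDP")
  if (any(sumAD < 0)) stop("negative counts")
  out <- rep("none", length(sumDP))
  deep <- sumDP > cfg$depth_threshold
  f_alt <- ifelse(sumDP > 0, sumAD / sumDP, 0)
  out[deep & f_alt > cfg$freq_threshold] <- "ALT"
  out[deep & (1 - f_alt) > cfg$freq_threshold] <- "REF"
  out
}

#' Informative variants for one donor
#'
#' Calls the overrepresented allele per variant from the donor's
#' consistently assigned cells, then (optionally) checks that the
#' inconsistently assigned cells support the same allele wherever they have
#' sufficient coverage.  Variants where the inconsistent group lacks
#' coverage are kept on consistent-group evidence alone (configurable).
#'
#' @param counts An `allele_count_set`.
#' @param joint A `joint_assignment`.
#' @param donor Final singlet label to profile.
#' @param cfg A `refinement_config`.
#' @return Named character vector (variant key -> `"REF"`/`"ALT"`), with a
#'   `counters` attribute (variants examined / passed per filter).
#' @export
informative_variants <- function(counts, joint, donor,
                                 cfg = refinement_config()) {
  parts <- partition_cells(joint, donor)
  if (!length(parts$consistent)) {
    stop("donor ", donor, " has no consistently assigned cells; cannot be profiled")
  }
  cons <- aggregate_counts(counts, parts$consistent)
  call <- overrepresented_allele(cons$sumAD, cons$sumDP, cfg)
  keep <- call != "none"
  n_cons <- sum(keep)
  n_checked <- 0L; n_dropped <- 0L
  if (cfg$require_inconsistent_support && length(parts$inconsistent) && any(keep)) {
    inc <- aggregate_counts(counts, parts$inconsistent)
    iAD <- stats::setNames(inc$sumAD, inc$key)
    iDP <- stats::setNames(inc$sumDP, inc$key)
    k <- cons$key[keep]
    idp <- ifelse(is.na(iDP[k]), 0, iDP[k])
    iad <- ifelse(is.na(iAD[k]), 0, iAD[k])
    covered <- idp > cfg$inconsistent_depth_threshold
    f_alt <- ifelse(idp > 0, iad / idp, 0)
    icall <- rep("none", length(idp))
    icall[covered & f_alt > cfg$inconsistent_freq_threshold] <- "ALT"
    icall[covered & (1 - f_alt) > cfg$inconsistent_freq_threshold] <- "REF"
    agree <- icall == call[keep]
    ok <- if (cfg$keep_uncovered_inconsistent) !covered | agree else covered & agree
    n_checked <- sum(covered)
    n_dropped <- sum(!ok)
    keep[keep] <- ok
  }
  out <- stats::setNames(call[keep], cons$key[keep])
  attr(out, "counters") <- c(n_variants_with_depth = nrow(cons),
                             n_pass_consistent = n_cons,
                             n_checked_inconsistent = n_checked,
                             n_dropped_inconsistent = n_dropped)
  out
}

#' Donor-specific variant calls
#'
#' Keeps, for each donor, the calls that set it apart from the rest of the
#' pool.  Default (`unique_call`): a (variant, allele) call is retained iff
#' no other donor carries the same call — so a variant called `ALT` in one
#' donor and `REF` in another is kept for both.  `exclusive`: a variant is
#' retained only for a donor in which it passed the filters when it passed
#' in no other donor.
#'
#' @param per_donor_calls Named list: donor -> named call vector as
#'   returned by [informative_variants()].
#' @param cfg A `refinement_config`.
#' @return Named list of the same shape, with attribute `counts` (named
#'   integer vector of retained variants per donor).
#' @export
donor_specific_variants <- function(per_donor_calls, cfg = refinement_config()) {
  if (length(per_donor_calls) < 2L) {
    stop("need calls for at least 2 donors to determine donor specificity")
  }
  donors <- names(per_donor_calls)
  long <- do.call(rbind, lapply(donors, function(d) {
    v <- per_donor_calls[[d]]
    if (!length(v)) return(NULL)
    data.frame(donor = d, key = names(v), allele = unname(v),
               stringsAsFactors = FALSE)
  }))
  out <- stats::setNames(vector("list", length(donors)), donors)
  for (d in donors) out[[d]] <- stats::setNames(character(0), character(0))
  if (!is.null(long) && nrow(long)) {
    token <- if (cfg$specific_mode == "unique_call") {
      paste(long$key, long$allele, sep = "|")
    } else {
      long$key
    }
    uniq <- long[token %in% names(which(table(token) == 1L)), , drop = FALSE]
    for (d in donors) {
      dd <- uniq[uniq$donor == d, , drop = FALSE]
      out[[d]] <- stats::setNames(dd$allele, dd$key)
    }
  }
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}

#' Reconstruct minimal donor genotypes from a joint assignment
#'
#' Convenience wrapper: profiles every final singlet label that has at
#' least one confirmed cell with [informative_variants()], then restricts
#' to donor-specific calls with [donor_specific_variants()].
#'
#' @param counts An `allele_count_set`.
#' @param joint A `joint_assignment`.
#' @param cfg A `refinement_config`.
#' @return An object of class `donor_genotype_set`: list with `donors`,
#'   `calls` (donor-specific calls: donor -> variant key -> allele),
#'   `full_calls` (every donor's informative call at the union of the
#'   donor-specific variants — so a private variant of one donor carries
#'   the explicit REF calls of the others, which is what serialization and
#'   re-demultiplexing use), `variants` (records for all keys), and a
#'   `counters` data.frame.
#' @export
reconstruct_genotypes <- function(counts, joint, cfg = refinement_config()) {
  stopifnot(inherits(counts, "allele_count_set"),
            inherits(joint, "joint_assignment"))
  donors <- sort(unique(joint$label[joint$kind == "singlet" &
                                      joint$provenance == "confirmed"]))
  if (length(donors) < 2L) stop("fewer than 2 donors have confirmed cells")
  per <- lapply(stats::setNames(donors, donors), function(d) {
    informative_variants(counts, joint, d, cfg)
  })
  specific <- donor_specific_variants(per, cfg)
  union_keys <- sort(unique(unlist(lapply(specific, names), use.names = FALSE)))
  full <- lapply(per, function(v) v[names(v) %in% union_keys])
  counters <- data.frame(
    donor = donors,
    n_informative = vapply(per, length, integer(1)),
    n_specific = attr(specific, "counts")[donors],
    stringsAsFactors = FALSE)
  rownames(counters) <- NULL
  structure(list(donors = donors, calls = specific[donors],
                 full_calls = full[donors],
                 variants = counts$variants, counters = counters),
            class = "donor_genotype_set")
}

#' @export
print.donor_genotype_set <- function(x, ...) {
  cat(sprintf("donor_genotype_set: %d donor(s), %d variant call(s) total\n",
              length(x$donors), sum(vapply(x$calls, length, integer(1)))))
  print(x$counters, row.names = FALSE)
  invisible(x)
}

#' Write reconstructed donor genotypes as VCF
#'
#' Emits a VCF v4.2 with a GT-only FORMAT and one sample column per donor.
#' Calls are serialized as homozygous diploid genotypes (`0/0` for REF,
#' `1/1` for ALT; a pooled-read frequency above 90% is inconsistent with
#' heterozygosity) and `./.` where a donor has no call at a variant in the
#' union.  Records are sorted by (chrom, pos).  Sample columns use the
#' matched hashtag names when `match` is given; donors without a match keep
#' their anonymous name.
#'
#' @param genotypes A `donor_genotype_set`, or a named list donor -> call
#'   vector (then `variants` must be supplied).
#' @param path Output VCF path.
#' @param match Optional `donor_match` used to rename samples.
#' @param variants Variant records (data.frame with `chrom`, `pos`, `ref`,
#'   `alt`, `key`) when `genotypes` is a plain list.
#' @return `path`, invisibly.
#' @export
write_donor_vcf <- function(genotypes, path, match = NULL, variants = NULL) {
  if (inherits(genotypes, "donor_genotype_set")) {
    calls <- genotypes$full_calls %||% genotypes$calls
    variants <- genotypes$variants
  } else {
    calls <- genotypes
    if (is.null(variants)) stop("'variants' required for plain call lists")
    if (!"key" %in% names(variants)) variants$key <- variant_key(variants)
  }
  donors <- names(calls)
  samples <- donors
  if (!is.null(match)) {
    map <- matched_pairs(match)
    hit <- donors %in% names(map)
    samples[hit] <- unname(map[donors[hit]])
    if (any(!hit)) {
      message(sprintf("write_donor_vcf: %d donor(s) without a matched hashtag keep their anonymous name",
                      sum(!hit)))
    }
  }
  if (anyDuplicated(samples)) stop("duplicate sample names in donor VCF")
  keys <- sort(unique(unlist(lapply(calls, names), use.names = FALSE)))
  if (!length(keys)) stop("no variant calls to write")
  vr <- variants[match(keys, variants$key), , drop = FALSE]
  if (anyNA(vr$pos)) stop("variant records missing for some calls")
  ord <- order(vr$chrom, vr$pos)
  vr <- vr[ord, , drop = FALSE]
  gt <- matrix("./.", nrow = nrow(vr), ncol = length(donors))
  for (j in seq_along(donors)) {
    v <- calls[[donors[j]]]
    if (!length(v)) next
    i <- match(names(v), vr$key)
    gt[i, j] <- ifelse(v == "ALT", "1/1", "0/0")
  }
  id <- if ("id" %in% names(vr)) ifelse(is.na(vr$id), ".", vr$id) else rep(".", nrow(vr))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=demuxrescue",
    "##note=minimal donor genotypes reconstructed from pooled single-cell allele counts; calls are emitted as homozygous diploid genotypes because the overrepresented-allele frequency cutoff excludes heterozygous sites",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(vr$chrom, as.integer(vr$pos), id, vr$ref, vr$alt,
                ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only donor genotype VCF
#'
#' Inverse of [write_donor_vcf()]: `0/0` and `1/1` genotypes become REF /
#' ALT calls; `./.` entries are absent calls.
#'
#' @param path VCF path.
#' @return A `donor_genotype_set`.
#' @export
read_donor_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  variants$key <- variant_key(variants)
  gt <- vcfR::extract.gt(v, element = "GT")
  donors <- colnames(gt)
  calls <- lapply(stats::setNames(donors, donors), function(d) {
    g <- gt[, d]
    called <- !is.na(g) & g %in% c("0/0", "1/1", "0|0", "1|1")
    stats::setNames(ifelse(g[called] %in% c("1/1", "1|1"), "ALT", "REF"),
                    variants$key[called])
  })
  counters <- data.frame(donor = donors,
                         n_informative = NA_integer_,
                         n_specific = vapply(calls, length, integer(1)),
                         stringsAsFactors = FALSE)
  structure(list(donors = donors, calls = calls, full_calls = calls,
                 variants = variants, counters = counters),
            class = "donor_genotype_set")
}

#' Per-donor variant count table
#'
#' @param genotypes A `donor_genotype_set`.
#' @param path Optional CSV output (`Donor,NInformative,NSpecific`).
#' @return The counter data.frame, invisibly if written.
#' @export
variant_count_table <- function(genotypes, path = NULL) {
  stopifnot(inherits(genotypes, "donor_genotype_set"))
  out <- genotypes$counters
  names(out) <- c("Donor", "NInformative", "NSpecific")
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
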