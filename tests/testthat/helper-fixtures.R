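# Small in-code fixtures shared across test files.

tbl <- function(barcodes, assignments, method = "m", family = "hashing") {
  assignment_table(barcodes, assignments, method, family)
}

write_tbl_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Independent closed-form 2x2 contingency phi coefficient (scalar).
phi_contingency <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  den <- as.double(n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  if (den == 0) return(0)
  (n11 * n00 - n10 * n01) / sqrt(den)
}

# A donor_match carrying the given bijection at the given correlations,
# for exercising rescue logic with a controlled map.
fake_match <- function(donors, hashtags, correlations = 1) {
  pairs <- data.frame(donor = donors, hashtag = hashtags,
                      correlation = rep(correlations, length.out = length(donors)),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 all_donors_matched = all(pairs$correlation > 0),
                 phi_score = sum(pmax(pairs$correlation, 0)) / length(donors),
                 n_expected_donors = length(donors),
                 genetic_method = "g", hashing_method = "h",
                 n_common_barcodes = NA_integer_),
            class = "donor_match")
}

# Tiny allele count set with explicit dense inputs.
dense_counts <- function(AD, DP, barcodes = NULL, chrom = "1") {
  if (is.null(barcodes)) barcodes <- paste0("c", seq_len(ncol(DP)))
  variants <- data.frame(chrom = chrom, pos = seq_len(nrow(DP)) * 10L,
                         id = paste0("v", seq_len(nrow(DP))),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  allele_count_set(Matrix::Matrix(AD, sparse = TRUE),
                   Matrix::Matrix(DP, sparse = TRUE), variants, barcodes)
}

# Checks whether a donor match recovered the simulator's hidden
# donor -> hashtag bijection (in anonymous-label space).
recovered_permutation <- function(match, permutation) {
  want <- stats::setNames(permutation$hashtag, permutation$anonymous)
  got <- matched_pairs(match)
  length(got) == length(want) &&
    all(names(want) %in% names(got)) &&
    all(got[names(want)] == want)
}

small_cfg <- function(...) {
  sim_config(n_variants = 20L, n_private_per_donor = 5L, n_cells = 1000L, ...)
}
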