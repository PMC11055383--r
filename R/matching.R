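#' Pairwise phi correlation of two binary assignment matrices
#'
#' Computes, for every (donor, hashtag) column pair, the Pearson correlation
#' of the two 0/1 indicator vectors.  On binary data this is the phi
#' coefficient of the 2x2 contingency table, and it is computed here in
#' exact integer arithmetic,
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) /
#'              \sqrt{n_{1+} n_{0+} n_{+1} n_{+0}},}
#' so identical indicator columns score exactly 1.  Columns with zero
#' variance (all 0 or all 1) have no defined correlation; their entries are
#' set to 0 by convention and flagged, so empty donors can never match.
#'
#' @param genetic Binary matrix (barcodes x donors), e.g. from [binarize()].
#' @param hashing Binary matrix (barcodes x hashtags) with identical row
#'   order (use [align_on_common_barcodes()]).
#' @return An object of class `phi_correlation`: list with `matrix` (donors
#'   as rows, hashtags as columns), `zero_variance_donors` and
#'   `zero_variance_hashtags` (named logicals).
#' @export
pairwise_phi <- function(genetic, hashing) {
  if (nrow(genetic) != nrow(hashing) ||
      !identical(rownames(genetic), rownames(hashing))) {
    stop("row (barcode) order differs between the two matrices; ",
         "use align_on_common_barcodes() first")
  }
  n <- nrow(genetic)
  if (n < 2L) stop("need at least 2 common barcodes")
  A <- genetic; B <- hashing
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  n11 <- crossprod(A, B)                       # donors x hashtags
  ra <- colSums(A); rb <- colSums(B)
  n10 <- outer(ra, rep(1, ncol(B))) - n11
  n01 <- outer(rep(1, ncol(A)), rb) - n11
  n00 <- n - n11 - n10 - n01
  num <- n11 * n00 - n10 * n01
  den2 <- outer(ra * (n - ra), rb * (n - rb))  # exact for counts < ~2^13
  phi <- matrix(0, nrow(num), ncol(num), dimnames = dimnames(n11))
  ok <- den2 > 0
  phi[ok] <- num[ok] / sqrt(den2[ok])
  zr <- ra == 0 | ra == n
  zc <- rb == 0 | rb == n
  names(zr) <- colnames(A); names(zc) <- colnames(B)
  structure(list(matrix = phi, zero_variance_donors = zr,
                 zero_variance_hashtags = zc),
            class = "phi_correlation")
}

#' @export
as.matrix.phi_correlation <- function(x, ...) x$matrix

#' @export
print.phi_correlation <- function(x, ...) {
  cat(sprintf("phi_correlation: %d donor(s) x %d hashtag(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Mutual-best matching of donors and hashtags
#'
#' A pair `(d, h)` is returned iff `h` maximizes row `d` of the correlation
#' matrix and `d` maximizes column `h` — the "highest mutual correlation"
#' rule.  Ties in an argmax are broken lexicographically by partner label,
#' then mutuality is re-checked, so results are deterministic.  Unmatched
#' labels are omitted.
#'
#' @param corr A `phi_correlation` or a plain correlation matrix with
#'   dimnames (donors as rows, hashtags as columns).
#' @return data.frame with columns `donor`, `hashtag`, `correlation`,
#'   ordered by donor.
#' @export
mutual_best_match <- function(corr) {
  M <- if (inherits(corr, "phi_correlation")) corr$matrix else as.matrix(corr)
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop("correlation matrix must carry donor rownames and hashtag colnames")
  }
  argmax_lex <- function(v) {
    # index of max value; ties -> lexicographically smallest name
    i <- which(v == max(v))
    i[order(names(v)[i])][1L]
  }
  best_h <- vapply(rownames(M), function(d) argmax_lex(M[d, ]), integer(1))
  best_d <- vapply(colnames(M), function(h) argmax_lex(M[, h]), integer(1))
  keep <- which(best_d[best_h[rownames(M)]] == seq_len(nrow(M)))
  out <- data.frame(
    donor = rownames(M)[keep],
    hashtag = colnames(M)[best_h[keep]],
    correlation = M[cbind(keep, best_h[keep])],
    stringsAsFactors = FALSE)
  out[order(out$donor), , drop = FALSE]
}

#' Phi matching score
#'
#' Sum of the non-negative correlations of the mutually matched pairs,
#' divided by the number of expected donors.  Unmatched donors contribute
#' nothing; negative correlations are clamped to zero, so the score lies in
#' `[0, 1]`.
#'
#' @param pairs data.frame with a `correlation` column (as returned by
#'   [mutual_best_match()]) or a numeric vector of matched correlations.
#' @param n_expected_donors Number of donors expected in the pool (>= 1).
#' @return Numeric scalar in `[0, 1]`.
#' @export
phi_score <- function(pairs, n_expected_donors) {
  if (is.data.frame(pairs)) {
    corr <- pairs$correlation
    ndon <- length(unique(pairs$donor))
  } else {
    corr <- as.numeric(pairs)
    ndon <- length(corr)
  }
  n_expected_donors <- as.integer(n_expected_donors)
  if (is.na(n_expected_donors) || n_expected_donors < 1L) {
    stop("'n_expected_donors' must be a positive integer")
  }
  if (n_expected_donors < ndon) {
    warning(sprintf("n_expected_donors (%d) < number of matched donor labels (%d)",
                    n_expected_donors, ndon))
  }
  sum(pmax(corr, 0)) / n_expected_donors
}

#' Match anonymous genetic donors to hashtags
#'
#' End-to-end donor matching for one (genetic, hashing) method pair:
#' binarizes both tables, aligns them on their common barcodes, computes
#' the pairwise phi correlation matrix, extracts mutual-best pairs and the
#' Phi matching score.  A donor counts as matched only if its pair has a
#' strictly positive correlation (zero-variance columns are defined as 0,
#' so an empty donor can be paired by tie-breaking but never *matched*).
#'
#' @param genetic_table,hashing_table `assignment_table`s.
#' @param n_expected_donors Expected number of donors in the pool.
#' @param genetic_labels,hashing_labels Optional explicit label sets
#'   (needed e.g. when one table has no singlets at all).
#' @return An object of class `donor_match`: list with `correlations`
#'   (`phi_correlation`), `pairs` (donor/hashtag/correlation data.frame),
#'   `all_donors_matched`, `phi_score`, `n_expected_donors`,
#'   `genetic_method`, `hashing_method`, `n_common_barcodes`.
#' @export
match_methods <- function(genetic_table, hashing_table, n_expected_donors,
                          genetic_labels = NULL, hashing_labels = NULL) {
  stopifnot(inherits(genetic_table, "assignment_table"),
            inherits(hashing_table, "assignment_table"))
  if (is.null(genetic_labels) && !length(singlet_names(genetic_table))) {
    stop("genetic table has no singlet labels (unusable); supply 'genetic_labels'")
  }
  if (is.null(hashing_labels) && !length(singlet_names(hashing_table))) {
    stop("hashing table has no singlet labels (unusable); supply 'hashing_labels'")
  }
  G <- binarize(genetic_table, genetic_labels)
  H <- binarize(hashing_table, hashing_labels)
  al <- align_on_common_barcodes(G, H)
  corr <- pairwise_phi(al$a, al$b)
  pairs <- mutual_best_match(corr)
  confident <- pairs$donor[pairs$correlation > 0]
  structure(
    list(correlations = corr,
         pairs = pairs,
         all_donors_matched = all(colnames(G) %in% confident),
         phi_score = phi_score(pairs, n_expected_donors),
         n_expected_donors = as.integer(n_expected_donors),
         genetic_method = genetic_table$method_name,
         hashing_method = hashing_table$method_name,
         n_common_barcodes = nrow(al$a)),
    class = "donor_match")
}

#' @export
print.donor_match <- function(x, ...) {
  cat(sprintf("donor_match %s ~ %s: phi score %.4f, %d pair(s), all donors matched: %s (%d common barcodes)\n",
              x$genetic_method, x$hashing_method, x$phi_score, nrow(x$pairs),
              x$all_donors_matched, x$n_common_barcodes))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Donor-to-hashtag map of a match
#'
#' Named character vector `donor -> hashtag` restricted to confidently
#' matched pairs (correlation > 0).
#'
#' @param match A `donor_match`.
#' @return Named character vector.
#' @export
matched_pairs <- function(match) {
  stopifnot(inherits(match, "donor_match"))
  p <- match$pairs[match$pairs$correlation > 0, , drop = FALSE]
  stats::setNames(p$hashtag, p$donor)
}

#' Select the best (genetic, hashing) method pair by Phi score
#'
#' Evaluates every combination of the supplied tables with
#' [match_methods()].  Pairs in which every donor is matched are preferred
#' over partial matches; within a group the maximal Phi score wins; exact
#' ties are broken lexicographically by (genetic, hashing) method name.
#'
#' @param genetic_tables,hashing_tables Lists of `assignment_table`s.
#' @param n_expected_donors Expected number of donors.
#' @return List with `best` (`donor_match`), `pair` (named character
#'   vector: genetic/hashing method names), `partial` (TRUE if no pair
#'   fully matched) and `ranking` (data.frame over all pairs).
#' @export
select_best_pair <- function(genetic_tables, hashing_tables, n_expected_donors) {
  if (!length(genetic_tables) || !length(hashing_tables)) {
    stop("need at least one table per family")
  }
  if (inherits(genetic_tables, "assignment_table")) genetic_tables <- list(genetic_tables)
  if (inherits(hashing_tables, "assignment_table")) hashing_tables <- list(hashing_tables)
  res <- list(); rows <- list(); k <- 0L
  for (g in genetic_tables) for (h in hashing_tables) {
    k <- k + 1L
    m <- match_methods(g, h, n_expected_donors)
    res[[k]] <- m
    rows[[k]] <- data.frame(genetic = m$genetic_method, hashing = m$hashing_method,
                            phi_score = m$phi_score,
                            all_donors_matched = m$all_donors_matched,
                            stringsAsFactors = FALSE)
  }
  rk <- do.call(rbind, rows)
  ord <- order(!rk$all_donors_matched, -rk$phi_score, rk$genetic, rk$hashing)
  rk <- rk[ord, , drop = FALSE]
  rownames(rk) <- NULL
  best <- res[[ord[1L]]]
  list(best = best,
       pair = c(genetic = best$genetic_method, hashing = best$hashing_method),
       partial = !best$all_donors_matched,
       ranking = rk)
}

#' Rename genetic donors by their matched hashtags
#'
#' Produces a new assignment table in which singlet labels of matched
#' donors are replaced by the corresponding hashtag.  Singlets of unmatched
#' donors keep their anonymous label (their count is reported via
#' [message()]); doublet and negative calls are unchanged.
#'
#' @param genetic_table An `assignment_table` (family `genetic`).
#' @param match A `donor_match` with a non-empty pair set.
#' @return A relabeled `assignment_table`.
#' @export
relabel_genetic <- function(genetic_table, match) {
  stopifnot(inherits(genetic_table, "assignment_table"))
  map <- matched_pairs(match)
  if (!length(map)) stop("match has no confident pairs to relabel by")
  calls <- genetic_table$calls
  is_sing <- calls$kind == "singlet"
  hit <- is_sing & calls$label %in% names(map)
  n_un <- sum(is_sing & !hit)
  if (n_un) {
    message(sprintf("relabel_genetic: %d singlet(s) of unmatched donor(s) keep their anonymous label", n_un))
  }
  new_label <- calls$label
  new_label[hit] <- unname(map[calls$label[hit]])
  assignment <- ifelse(is_sing, new_label, calls$kind)
  assignment_table(calls$barcode, assignment, genetic_table$method_name,
                   genetic_table$family)
}

#' Write donor-matching artifacts
#'
#' Writes the correlation matrix (donors as rows, hashtags as columns; the
#' input of correlation heat maps), the matched pairs
#' (`Donor,Hashtag,Correlation`) and a one-line score file.
#'
#' @param match A `donor_match`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_match_result <- function(match, dir) {
  stopifnot(inherits(match, "donor_match"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_corr <- file.path(dir, "donor_correlations.csv")
  f_pairs <- file.path(dir, "donor_match.csv")
  f_score <- file.path(dir, "phi_score.txt")
  utils::write.csv(as.data.frame(match$correlations$matrix), f_corr,
                   row.names = TRUE, quote = FALSE)
  pr <- match$pairs
  names(pr) <- c("Donor", "Hashtag", "Correlation")
  utils::write.csv(pr, f_pairs, row.names = FALSE, quote = FALSE)
  writeLines(format(match$phi_score, digits = 15), f_score)
  invisible(c(correlations = f_corr, pairs = f_pairs, score = f_score))
}
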