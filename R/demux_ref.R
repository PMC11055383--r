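#' Configuration of the reference re-demultiplexer
#'
#' A transparent binomial-likelihood assigner over homozygous donor
#' genotypes, used as the sanity check after genotype refinement.  Each
#' read at a called site is an independent Bernoulli draw of the ALT
#' allele with probability `error_rate` at REF-called sites and
#' `1 - error_rate` at ALT-called sites; doublet models average the
#' per-donor probabilities.
#'
#' @param error_rate Per-read allele error `eps` (default 0.01; must be in
#'   (0, 0.5)).
#' @param min_informative_sites Minimum number of covered, called sites
#'   for a cell to be assignable (default 10); below it the cell is
#'   `negative`.
#' @param loglik_margin Required log-likelihood margin `tau` (nats,
#'   default 2) of the best model over the runner-up; smaller margins give
#'   `negative` (ambiguous collapses into negative).
#' @param doublet_models Evaluate all donor-pair models (default `TRUE`).
#' @param complete_sites_only Use only variants at which every donor has
#'   an explicit homozygous call (default `TRUE`).  Sites where some donor
#'   is uncalled are usually sites where that donor is heterozygous, and a
#'   heterozygous cell's reads at such a site mimic a doublet under any
#'   homozygous model; restricting to completely genotyped sites removes
#'   that failure mode.
#' @param uncalled When incomplete sites are used
#'   (`complete_sites_only = FALSE`), how donors without a call are
#'   handled: `"ref"` imputes homozygous REF, `"skip"` makes the site
#'   contribute 0 to that model.
#' @return A list of class `demux_config`.
#' @export
demux_config <- function(error_rate = 0.01, min_informative_sites = 10L,
                         loglik_margin = 2.0, doublet_models = TRUE,
                         complete_sites_only = TRUE,
                         uncalled = c("ref", "skip")) {
  uncalled <- match.arg(uncalled)
  if (!(error_rate > 0 && error_rate < 0.5)) {
    stop("'error_rate' must lie in (0, 0.5)")
  }
  if (loglik_margin < 0) stop("'loglik_margin' must be >= 0")
  structure(list(error_rate = error_rate,
                 min_informative_sites = as.integer(min_informative_sites),
                 loglik_margin = loglik_margin,
                 doublet_models = isTRUE(doublet_models),
                 complete_sites_only = isTRUE(complete_sites_only),
                 uncalled = uncalled),
            class = "demux_config")
}

#' Genotype log-likelihood of one cell
#'
#' Sum over covered, called variants of `log Binomial(AD; DP, p)` with
#' `p = error_rate` for REF calls and `1 - error_rate` for ALT calls.
#' Uncalled or uncovered variants contribute 0; an empty sum is 0.
#'
#' @param AD,DP Named numeric vectors (variant key -> count) of the cell's
#'   alternative and total read depth, with `0 <= AD <= DP`.
#' @param calls Named character vector (variant key -> `"REF"`/`"ALT"`).
#' @param cfg A `demux_config`.
#' @return Log-likelihood in nats.
#' @export
genotype_loglik <- function(AD, DP, calls, cfg = demux_config()) {
  if (any(AD > DP) || any(AD < 0)) stop("need 0 <= AD <= DP per variant")
  keys <- intersect(names(calls), names(DP)[DP > 0])
  if (!length(keys)) return(0)
  p <- ifelse(calls[keys] == "ALT", 1 - cfg$error_rate, cfg$error_rate)
  ad <- AD[keys]; ad[is.na(ad)] <- 0
  sum(stats::dbinom(ad, DP[keys], p, log = TRUE))
}

#' Re-demultiplex cells against reconstructed donor genotypes
#'
#' Evaluates, per cell, all `K` singlet models and (optionally) all
#' `K(K-1)/2` doublet models over the union of called variants, and emits
#' a standard assignment table: the best model's label when it leads the
#' runner-up by at least `loglik_margin` nats and the cell covers at least
#' `min_informative_sites` called sites; otherwise `negative`.
#' Deterministic: no randomness is involved, and model order (donors
#' sorted, then sorted pairs) breaks exact ties.
#'
#' @param counts An `allele_count_set`.
#' @param genotypes A `donor_genotype_set` (>= 2 donors).
#' @param cfg A `demux_config`.
#' @param method_name Method name for the output table (default
#'   `"refined"`).
#' @return An `assignment_table` (family `genetic`) over all barcodes of
#'   `counts`.
#' @export
assign_cells <- function(counts, genotypes, cfg = demux_config(),
                         method_name = "refined") {
  stopifnot(inherits(counts, "allele_count_set"),
            inherits(genotypes, "donor_genotype_set"))
  donors <- sort(genotypes$donors)
  K <- length(donors)
  if (K < 2L) stop("need genotypes for at least 2 donors")
  calls <- genotypes$full_calls
  if (is.null(calls)) calls <- genotypes$calls
  keys <- sort(unique(unlist(lapply(calls, names), use.names = FALSE)))
  rows <- match(keys, counts$variants$key)
  if (anyNA(rows)) {
    keys <- keys[!is.na(rows)]; rows <- rows[!is.na(rows)]
  }
  if (!length(keys)) stop("no genotyped variants present in the allele count set")
  eps <- cfg$error_rate

  # per-donor ALT-read probability at each union site; NA = uncalled
  P <- matrix(NA_real_, nrow = length(keys), ncol = K,
              dimnames = list(keys, donors))
  for (d in donors) {
    v <- calls[[d]]
    v <- v[names(v) %in% keys]
    if (length(v)) P[names(v), d] <- ifelse(v == "ALT", 1 - eps, eps)
  }
  if (cfg$complete_sites_only) {
    complete <- rowSums(is.na(P)) == 0L
    if (!any(complete)) stop("no variant is genotyped in every donor")
    P <- P[complete, , drop = FALSE]
    keys <- keys[complete]
    rows <- rows[complete]
  } else if (cfg$uncalled == "ref") {
    P[is.na(P)] <- eps
  }

  models <- as.list(donors)
  labels <- donors
  kinds <- rep("singlet", K)
  if (cfg$doublet_models && K >= 2L) {
    pr <- utils::combn(donors, 2L, simplify = FALSE)
    models <- c(models, pr)
    labels <- c(labels, rep("doublet", length(pr)))
    kinds <- c(kinds, rep("doublet", length(pr)))
  }
  Pm <- vapply(models, function(m) rowMeans(P[, m, drop = FALSE], na.rm = TRUE),
               numeric(length(keys)))
  logp <- log(Pm); logq <- log1p(-Pm)
  logp[!is.finite(logp)] <- 0  # uncalled under 'skip': contribute 0
  logq[!is.finite(logq)] <- 0

  ADs <- counts$AD[rows, , drop = FALSE]
  DPs <- counts$DP[rows, , drop = FALSE]
  L <- as.matrix(Matrix::crossprod(ADs, logp) +
                   Matrix::crossprod(DPs - ADs, logq))
  n_info <- Matrix::colSums(DPs > 0)

  best <- max.col(L, ties.method = "first")
  L2 <- L
  L2[cbind(seq_len(nrow(L)), best)] <- -Inf
  second <- max.col(L2, ties.method = "first")
  margin <- L[cbind(seq_len(nrow(L)), best)] - L[cbind(seq_len(nrow(L)), second)]

  ok <- n_info >= cfg$min_informative_sites & margin >= cfg$loglik_margin
  assignment <- rep("negative", ncol(ADs))
  assignment[ok] <- ifelse(kinds[best[ok]] == "doublet", "doublet",
                           labels[best[ok]])
  assignment_table(counts$barcodes, assignment, method_name, "genetic")
}

#' Singlet concordance between two assignment tables
#'
#' Over the barcodes classified as singlets in both tables, the fraction
#' with identical singlet labels.
#'
#' @param a,b `assignment_table`s sharing barcodes.
#' @return List with `concordance` (`NA` when no barcode is a singlet in
#'   both) and `n_singlets_both`.
#' @export
concordance <- function(a, b) {
  stopifnot(inherits(a, "assignment_table"), inherits(b, "assignment_table"))
  common <- intersect(a$calls$barcode, b$calls$barcode)
  if (!length(common)) stop("no shared barcodes between the tables")
  ca <- a$calls[match(common, a$calls$barcode), ]
  cb <- b$calls[match(common, b$calls$barcode), ]
  both <- ca$kind == "singlet" & cb$kind == "singlet"
  n <- sum(both)
  list(concordance = if (n) mean(ca$label[both] == cb$label[both]) else NA_real_,
       n_singlets_both = n)
}
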