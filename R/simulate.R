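#' Simulation settings for a pooled multiplexed experiment
#'
#' Defaults describe a deliberately adverse but realistic nuclei-hashing
#' pool: six genetically distinct donors, a high hashing failure rate
#' (30% unstained droplets, the regime joint deconvolution exists for),
#' shallow genetic coverage (each variant seen in ~5% of cells at ~2
#' reads), a hashing demultiplexer that is noisier (5% label error) than
#' the genetic one (2%), and 5% doublets.
#'
#' @param n_donors Number of pooled donors `K` (>= 2).
#' @param n_variants Number of shared (population) variants.
#' @param n_private_per_donor Planted donor-private homozygous-ALT
#'   variants per donor.
#' @param n_cells Number of droplets `N`.
#' @param doublet_rate Probability a droplet holds two donors.
#' @param stain_fail_rate Probability a droplet's hashing signal is
#'   replaced by background (unstained).
#' @param coverage_rate Per (variant, cell) coverage probability `q`.
#' @param mean_depth Mean reads per covered entry (`DP ~ 1 +
#'   Poisson(mean_depth - 1)`).
#' @param base_error Per-read allele error.
#' @param hto_signal_mean,hto_background_mean Negative-binomial means of
#'   the HTO counts on a cell's own hashtag(s) vs the rest.
#' @param hto_size Negative-binomial dispersion (size) of HTO counts.
#' @param genetic_misassign_rate,hashing_misassign_rate Probability a
#'   singlet is reported as a wrong donor / hashtag by the respective
#'   method.
#' @param seed Integer seed; stage seeds are derived from it (`seed`,
#'   `seed + 1`, `seed + 2`) so every stage is individually reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 6L, n_variants = 500L,
                       n_private_per_donor = 50L, n_cells = 5000L,
                       doublet_rate = 0.05, stain_fail_rate = 0.30,
                       coverage_rate = 0.05, mean_depth = 2,
                       base_error = 0.01,
                       hto_signal_mean = 200, hto_background_mean = 10,
                       hto_size = 5,
                       genetic_misassign_rate = 0.02,
                       hashing_misassign_rate = 0.05,
                       seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              n_variants = as.integer(n_variants),
              n_private_per_donor = as.integer(n_private_per_donor),
              n_cells = as.integer(n_cells),
              doublet_rate = doublet_rate, stain_fail_rate = stain_fail_rate,
              coverage_rate = coverage_rate, mean_depth = mean_depth,
              base_error = base_error,
              hto_signal_mean = hto_signal_mean,
              hto_background_mean = hto_background_mean, hto_size = hto_size,
              genetic_misassign_rate = genetic_misassign_rate,
              hashing_misassign_rate = hashing_misassign_rate,
              seed = as.integer(seed))
  if (cfg$n_donors < 2L) stop("'n_donors' must be >= 2")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) stop("'doublet_rate' must be in [0, 1)")
  if (cfg$stain_fail_rate < 0 || cfg$stain_fail_rate >= 1) stop("'stain_fail_rate' must be in [0, 1)")
  if (cfg$mean_depth < 1) stop("'mean_depth' must be >= 1")
  if (any(c(cfg$hto_signal_mean, cfg$hto_background_mean, cfg$hto_size) <= 0)) {
    stop("HTO negative-binomial parameters must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' Donor names, hashtag names and planted hashtag of a donor
#' @param cfg A `sim_config`.
#' @return Character vector of donor / hashtag names.
#' @export
sim_donor_names <- function(cfg) paste0("D", seq_len(cfg$n_donors))

#' @rdname sim_donor_names
#' @export
sim_hashtag_names <- function(cfg) paste0("Hash", seq_len(cfg$n_donors))

#' Simulate pooled donor genotypes
#'
#' Draws `n_variants` shared variants with per-variant minor-allele
#' frequency uniform on \[0.05, 0.5\] and diploid dosage
#' `~ Binomial(2, maf)` per donor, plus `n_private_per_donor` planted
#' variants per donor that are homozygous-ALT in that donor and
#' homozygous-REF in all others.  Deterministic under `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return An object of class `sim_genotypes`: list with `variants`
#'   (records incl. `key`), `dosage` (variants x donors, values 0/1/2),
#'   `maf`, and `private_rows` (donor -> row indices of its planted
#'   variants).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_donors; M <- cfg$n_variants; P <- cfg$n_private_per_donor
  donors <- sim_donor_names(cfg)
  Mtot <- M + K * P
  maf <- stats::runif(M, 0.05, 0.5)
  shared <- matrix(stats::rbinom(M * K, 2L, maf), nrow = M, ncol = K)
  priv <- matrix(0L, nrow = K * P, ncol = K)
  private_rows <- stats::setNames(vector("list", K), donors)
  for (k in seq_len(K)) {
    r <- (k - 1L) * P + seq_len(P)
    priv[r, k] <- 2L
    private_rows[[k]] <- M + r
  }
  dosage <- rbind(shared, priv)
  colnames(dosage) <- donors
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, Mtot, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  variants <- data.frame(chrom = "1", pos = seq_len(Mtot) * 10L,
                         id = paste0("v", seq_len(Mtot)),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  variants$key <- variant_key(variants)
  rownames(dosage) <- variants$key
  structure(list(variants = variants, dosage = dosage, maf = maf,
                 private_rows = private_rows),
            class = "sim_genotypes")
}

#' Simulate droplets: allele counts, HTO counts and ground truth
#'
#' Each droplet draws a donor uniformly and, with probability
#' `doublet_rate`, a second distinct donor.  Each variant is covered with
#' probability `coverage_rate`; covered entries draw
#' `DP ~ 1 + Poisson(mean_depth - 1)` reads and
#' `AD ~ Binomial(DP, p)` with
#' `p = (g/2)(1 - eps) + (1 - g/2) eps` for dosage `g` (averaged over the
#' two donors of a doublet).  HTO rows are negative-binomial signal on the
#' droplet's own hashtag(s) and background elsewhere; with probability
#' `stain_fail_rate` the droplet is unstained and its signal is replaced
#' by background.  Deterministic under `cfg$seed + 1`.
#'
#' @param cfg A `sim_config`.
#' @param genotypes A `sim_genotypes` from [simulate_genotypes()].
#' @return List with `counts` (`allele_count_set`), `hto` (barcodes x
#'   hashtags integer matrix) and `truth` (data.frame `barcode`, `donor`,
#'   `donor2`, `doublet`, `stained`).
#' @export
simulate_cells <- function(cfg, genotypes) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genotypes, "sim_genotypes"))
  set.seed(cfg$seed + 1L)
  K <- cfg$n_donors; N <- cfg$n_cells
  Mtot <- nrow(genotypes$dosage)
  donors <- sim_donor_names(cfg)
  barcodes <- sprintf("BC%06d", seq_len(N))

  d1 <- sample.int(K, N, replace = TRUE)
  is_dbl <- stats::runif(N) < cfg$doublet_rate
  d2 <- rep(NA_integer_, N)
  if (any(is_dbl)) {
    shift <- sample.int(K - 1L, sum(is_dbl), replace = TRUE)
    d2[is_dbl] <- (d1[is_dbl] + shift - 1L) %% K + 1L
  }
  stained <- stats::runif(N) >= cfg$stain_fail_rate

  covered <- which(stats::runif(as.double(N) * Mtot) < cfg$coverage_rate)
  ri <- as.integer((covered - 1L) %% Mtot + 1L)   # variant row
  ci <- as.integer((covered - 1L) %/% Mtot + 1L)  # cell column
  DPx <- 1L + stats::rpois(length(covered), cfg$mean_depth - 1)
  eps <- cfg$base_error
  g1 <- genotypes$dosage[cbind(ri, d1[ci])]
  p <- (g1 / 2) * (1 - eps) + (1 - g1 / 2) * eps
  dbl_e <- is_dbl[ci]
  if (any(dbl_e)) {
    g2 <- genotypes$dosage[cbind(ri[dbl_e], d2[ci[dbl_e]])]
    p2 <- (g2 / 2) * (1 - eps) + (1 - g2 / 2) * eps
    p[dbl_e] <- (p[dbl_e] + p2) / 2
  }
  ADx <- stats::rbinom(length(covered), DPx, p)
  DP <- Matrix::sparseMatrix(i = ri, j = ci, x = DPx, dims = c(Mtot, N))
  AD <- Matrix::drop0(Matrix::sparseMatrix(i = ri, j = ci, x = ADx,
                                           dims = c(Mtot, N)))
  counts <- allele_count_set(AD, DP, genotypes$variants, barcodes)

  hto <- matrix(stats::rnbinom(N * K, mu = cfg$hto_background_mean,
                               size = cfg$hto_size),
                nrow = N, ncol = K,
                dimnames = list(barcodes, sim_hashtag_names(cfg)))
  own1 <- which(stained)
  if (length(own1)) {
    hto[cbind(own1, d1[own1])] <-
      stats::rnbinom(length(own1), mu = cfg$hto_signal_mean, size = cfg$hto_size)
  }
  own2 <- which(stained & is_dbl)
  if (length(own2)) {
    hto[cbind(own2, d2[own2])] <-
      stats::rnbinom(length(own2), mu = cfg$hto_signal_mean, size = cfg$hto_size)
  }

  truth <- data.frame(barcode = barcodes,
                      donor = donors[d1],
                      donor2 = ifelse(is_dbl, donors[d2], NA_character_),
                      doublet = is_dbl, stained = stained,
                      stringsAsFactors = FALSE)
  list(counts = counts, hto = hto, truth = truth)
}

#' Simulate noisy demultiplexer output tables
#'
#' The genetic table reports the truth with donor names replaced by
#' anonymous cluster labels via a hidden random permutation, singlets
#' corrupted to a wrong donor at `genetic_misassign_rate`, and doublets
#' labeled `doublet`.  The hashing table reports the truth hashtags with
#' unstained droplets labeled `negative` and stained singlets corrupted
#' at `hashing_misassign_rate`.  Deterministic under `cfg$seed + 2`.
#'
#' @param truth Truth data.frame from [simulate_cells()].
#' @param cfg A `sim_config`.
#' @return List with `hashing` and `genetic` (`assignment_table`s) and
#'   `permutation`: data.frame `donor`, `anonymous`, `hashtag` — the
#'   hidden donor-label map and planted donor-hashtag bijection, for test
#'   oracles.
#' @export
simulate_method_outputs <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  K <- cfg$n_donors
  donors <- sim_donor_names(cfg)
  hashtags <- sim_hashtag_names(cfg)
  perm <- sample.int(K)
  anon <- stats::setNames(paste0("donor", perm - 1L), donors)
  N <- nrow(truth)
  di <- match(truth$donor, donors)

  corrupt <- function(idx, rate) {
    # returns donor indices with singlets flipped to a wrong donor at 'rate'
    flip <- stats::runif(N) < rate
    shift <- sample.int(K - 1L, N, replace = TRUE)
    ifelse(flip, (idx + shift - 1L) %% K + 1L, idx)
  }

  g_idx <- corrupt(di, cfg$genetic_misassign_rate)
  g_assign <- ifelse(truth$doublet, "doublet", anon[donors[g_idx]])
  genetic <- assignment_table(truth$barcode, g_assign, "sim_genetic", "genetic")

  h_idx <- corrupt(di, cfg$hashing_misassign_rate)
  h_assign <- ifelse(!truth$stained, "negative",
              ifelse(truth$doublet, "doublet", hashtags[h_idx]))
  hashing <- assignment_table(truth$barcode, h_assign, "sim_hashing", "hashing")

  list(hashing = hashing, genetic = genetic,
       permutation = data.frame(donor = donors, anonymous = unname(anon),
                                hashtag = hashtags, stringsAsFactors = FALSE))
}

#' Simulate a full multiplexed experiment
#'
#' Chains [simulate_genotypes()], [simulate_cells()] and
#' [simulate_method_outputs()]; optionally writes every input dialect the
#' other modules consume (AD/DP MTX, variant VCF, barcodes TSV, HTO CSV,
#' truth CSV, method-output CSVs).  Byte-identical across reruns with the
#' same `cfg`.
#'
#' @param cfg A `sim_config`.
#' @param dir Optional output directory.
#' @return List with `genotypes`, `counts`, `hto`, `truth`, `hashing`,
#'   `genetic`, `permutation`, and (when written) `files`.
#' @export
simulate_experiment <- function(cfg = sim_config(), dir = NULL) {
  genotypes <- simulate_genotypes(cfg)
  cells <- simulate_cells(cfg, genotypes)
  methods <- simulate_method_outputs(cells$truth, cfg)
  out <- list(genotypes = genotypes, counts = cells$counts, hto = cells$hto,
              truth = cells$truth, hashing = methods$hashing,
              genetic = methods$genetic, permutation = methods$permutation)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_allele_counts(cells$counts, dir)
    f_hto <- file.path(dir, "hto_counts.csv")
    utils::write.csv(data.frame(Barcode = rownames(cells$hto), cells$hto,
                                check.names = FALSE),
                     f_hto, row.names = FALSE, quote = FALSE)
    f_truth <- file.path(dir, "truth.csv")
    utils::write.csv(cells$truth, f_truth, row.names = FALSE, quote = FALSE)
    f_h <- file.path(dir, "hashing.csv")
    f_g <- file.path(dir, "genetic.csv")
    write_assignment_table(methods$hashing, f_h)
    write_assignment_table(methods$genetic, f_g)
    out$files <- c(files, hto = f_hto, truth = f_truth,
                   hashing = f_h, genetic = f_g)
  }
  out
}
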