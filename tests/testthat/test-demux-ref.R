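test_that("genotype log-likelihood matches the closed-form binomial terms", {
  cfg <- demux_config(error_rate = 0.01)
  expect_equal(genotype_loglik(c(v1 = 5), c(v1 = 5), c(v1 = "ALT"), cfg),
               5 * log(0.99), tolerance = 1e-12)
  expect_equal(genotype_loglik(c(v1 = 5), c(v1 = 5), c(v1 = "REF"), cfg),
               5 * log(0.01), tolerance = 1e-12)
  # uncovered and uncalled variants contribute nothing
  expect_equal(genotype_loglik(c(v1 = 0), c(v1 = 0), c(v1 = "ALT"), cfg), 0)
  expect_equal(genotype_loglik(c(v2 = 3), c(v2 = 3), c(v1 = "ALT"), cfg), 0)
  expect_error(genotype_loglik(c(v1 = 6), c(v1 = 5), c(v1 = "ALT"), cfg), "AD")
})

test_that("evidence for a donor never lowers its likelihood advantage", {
  cfg <- demux_config()
  calls_a <- c(v1 = "ALT", v2 = "ALT")
  calls_b <- c(v1 = "REF", v2 = "REF")
  base_ad <- c(v1 = 4); base_dp <- c(v1 = 4)
  d0 <- genotype_loglik(base_ad, base_dp, calls_a, cfg) -
    genotype_loglik(base_ad, base_dp, calls_b, cfg)
  # add a covered variant whose reads favor donor a
  ad2 <- c(v1 = 4, v2 = 3); dp2 <- c(v1 = 4, v2 = 3)
  d1 <- genotype_loglik(ad2, dp2, calls_a, cfg) -
    genotype_loglik(ad2, dp2, calls_b, cfg)
  expect_gt(d1, d0)
})

# 2-donor fixture with 12 fully genotyped discriminating sites
demux_fixture <- function(n_sites = 12L, depth = 4L) {
  half <- n_sites / 2
  # donor A: ALT at v1..v6, REF at v7..v12; donor B opposite
  ga <- stats::setNames(rep(c("ALT", "REF"), each = half), paste0("s", 1:n_sites))
  gb <- stats::setNames(rep(c("REF", "ALT"), each = half), paste0("s", 1:n_sites))
  variants <- data.frame(chrom = "1", pos = seq_len(n_sites) * 5L,
                         id = paste0("s", 1:n_sites), ref = "A", alt = "T",
                         stringsAsFactors = FALSE)
  variants$key <- variant_key(variants)
  # rename call keys to canonical variant keys
  names(ga) <- names(gb) <- variants$key
  DP <- matrix(depth, n_sites, 3)
  # cellA matches A; cellB matches B; cellAB is an even mixture
  AD <- cbind(c(rep(depth, half), rep(0, half)),
              c(rep(0, half), rep(depth, half)),
              rep(depth / 2, n_sites))
  counts <- dense_counts(AD, DP, barcodes = c("cellA", "cellB", "cellAB"))
  counts$variants <- variants
  rownames(counts$AD) <- rownames(counts$DP) <- variants$key
  genotypes <- structure(list(donors = c("A", "B"),
                              calls = list(A = ga, B = gb),
                              full_calls = list(A = ga, B = gb),
                              variants = variants,
                              counters = NULL),
                         class = "donor_genotype_set")
  list(counts = counts, genotypes = genotypes)
}

test_that("cells are assigned to the dominant donor model", {
  fx <- demux_fixture()
  t <- assign_cells(fx$counts, fx$genotypes, demux_config(min_informative_sites = 5))
  calls <- stats::setNames(ifelse(t$calls$kind == "singlet", t$calls$label,
                                  t$calls$kind), t$calls$barcode)
  expect_equal(unname(calls["cellA"]), "A")
  expect_equal(unname(calls["cellB"]), "B")
  expect_equal(unname(calls["cellAB"]), "doublet")
})

test_that("cells below the informative-site floor are negative", {
  fx <- demux_fixture()
  # cell covering only 3 sites
  fx$counts$DP[4:12, 1] <- 0
  fx$counts$AD[4:12, 1] <- 0
  cs <- allele_count_set(fx$counts$AD, fx$counts$DP, fx$counts$variants,
                         c("cellA", "cellB", "cellAB"))
  t <- assign_cells(cs, fx$genotypes, demux_config(min_informative_sites = 10))
  expect_equal(t$calls$kind[t$calls$barcode == "cellA"], "negative")
})

test_that("assignment is deterministic", {
  fx <- demux_fixture()
  t1 <- assign_cells(fx$counts, fx$genotypes)
  t2 <- assign_cells(fx$counts, fx$genotypes)
  expect_identical(t1$calls, t2$calls)
})

test_that("concordance counts identical singlet labels on shared barcodes", {
  a <- tbl(paste0("c", 1:5), c("H1", "H2", "H3", "H4", "doublet"), "a", "genetic")
  expect_equal(concordance(a, a)$concordance, 1)
  b <- tbl(paste0("c", 1:5), c("H1", "H2", "H3", "H9", "doublet"), "b", "genetic")
  r <- concordance(a, b)
  expect_equal(r$concordance, 0.75)
  expect_equal(r$n_singlets_both, 4L)
  # disjoint singlet sets -> not applicable
  c1 <- tbl(c("c1", "c2"), c("H1", "negative"), "c1t", "genetic")
  c2 <- tbl(c("c1", "c2"), c("negative", "H1"), "c2t", "genetic")
  expect_true(is.na(concordance(c1, c2)$concordance))
  expect_error(concordance(a, tbl("zz", "H1", "z", "genetic")), "shared")
})

test_that("rescued and refined assignments concord on simulated data", {
  res <- run_pipeline(sim_config(seed = 31))
  expect_gte(res$concordance$concordance, 0.95)
  expect_gt(res$concordance$n_singlets_both, 500)
})
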