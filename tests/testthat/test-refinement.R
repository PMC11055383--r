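test_that("overrepresented-allele calls follow the depth and frequency gates", {
  cfg <- refinement_config()
  expect_equal(overrepresented_allele(19, 20, cfg), "ALT")   # freq 0.95 > 0.9
  expect_equal(overrepresented_allele(1, 20, cfg), "REF")    # ref freq 0.95
  expect_equal(overrepresented_allele(10, 20, cfg), "none")  # 0.5 ambiguous
  expect_equal(overrepresented_allele(8, 8, cfg), "none")    # depth 8 <= 10
  expect_equal(overrepresented_allele(11, 11, cfg), "ALT")   # strict > 10
  expect_error(overrepresented_allele(5, 4, cfg), "exceeds")
  expect_error(refinement_config(freq_threshold = 0.4), "freq")
})

test_that("aggregation matches a dense brute-force sum", {
  set.seed(8)
  DP <- matrix(rpois(300, 1.2), 30, 10)
  AD <- matrix(rbinom(300, DP, 0.4), 30, 10)
  cs <- dense_counts(AD, DP)
  cells <- c("c2", "c5", "c9")
  agg <- aggregate_counts(cs, cells)
  idx <- c(2, 5, 9)
  expect_equal(agg$sumAD, rowSums(AD[, idx])[agg$row])
  expect_equal(agg$sumDP, rowSums(DP[, idx])[agg$row])
  expect_true(all(rowSums(DP[, idx])[agg$row] > 0))
  expect_setequal(agg$row, which(rowSums(DP[, idx]) > 0))
  # degenerate and invalid inputs
  expect_equal(nrow(aggregate_counts(cs, character(0))), 0L)
  expect_error(aggregate_counts(cs, "nope"), "unknown barcode")
})

test_that("cell partition follows provenance", {
  fx_joint <- structure(
    data.frame(barcode = paste0("c", 1:6),
               kind = c(rep("singlet", 5), "doublet"),
               label = c("H1", "H1", "H1", "H1", "H2", NA),
               provenance = c("confirmed", "confirmed", "rescued", "conflict",
                              "confirmed", "doublet"),
               stringsAsFactors = FALSE),
    class = c("joint_assignment", "data.frame"))
  p <- partition_cells(fx_joint, "H1")
  expect_setequal(p$consistent, c("c1", "c2"))
  expect_setequal(p$inconsistent, c("c3", "c4"))
  expect_equal(partition_cells(fx_joint, "H2")$inconsistent, character(0))
  expect_error(partition_cells(fx_joint, "H9"), "unknown donor")
})

# Fixture: 4 variants x 6 cells, donor H1 = cells c1..c3 consistent,
# c4..c5 inconsistent; variant behaviour differs by row.
refine_fixture <- function() {
  #        c1 c2 c3 | c4 c5 c6
  DP <- rbind(c(10, 10, 10, 10, 10, 0),   # v1: ALT everywhere
              c(10, 10, 10, 10, 10, 0),   # v2: cons ALT, incons REF
              c(10, 10, 10,  0,  0, 0),   # v3: cons ALT, incons uncovered
              c( 4,  4,  0,  0,  0, 0))   # v4: cons depth 8 <= 10
  AD <- rbind(c(10, 10, 10, 10, 10, 0),
              c(10, 10, 10,  0,  0, 0),
              c(10, 10, 10,  0,  0, 0),
              c( 4,  4,  0,  0,  0, 0))
  counts <- dense_counts(AD, DP)
  joint <- structure(
    data.frame(barcode = paste0("c", 1:6),
               kind = "singlet", label = "H1",
               provenance = c("confirmed", "confirmed", "confirmed",
                              "rescued", "rescued", "rescued"),
               stringsAsFactors = FALSE),
    class = c("joint_assignment", "data.frame"))
  list(counts = counts, joint = joint)
}

test_that("informative variants require inconsistent-group agreement", {
  fx <- refine_fixture()
  v <- informative_variants(fx$counts, fx$joint, "H1")
  keys <- fx$counts$variants$key
  expect_equal(unname(v[keys[1]]), "ALT")     # agreement
  expect_false(keys[2] %in% names(v))         # disagreement -> dropped
  expect_equal(unname(v[keys[3]]), "ALT")     # uncovered -> kept
  expect_false(keys[4] %in% names(v))         # consistent depth too low
  # dropping uncovered variants instead is configurable
  v2 <- informative_variants(fx$counts, fx$joint, "H1",
                             refinement_config(keep_uncovered_inconsistent = FALSE))
  expect_false(keys[3] %in% names(v2))
  # the check can be disabled entirely
  v3 <- informative_variants(fx$counts, fx$joint, "H1",
                             refinement_config(require_inconsistent_support = FALSE))
  expect_setequal(names(v3), keys[1:3])
})

test_that("donor specificity keeps calls not shared by any other donor", {
  calls <- list(
    H1 = c(v1 = "ALT", v2 = "ALT", v3 = "ALT"),
    H2 = c(v2 = "ALT", v3 = "REF"),
    H3 = c(v4 = "REF"))
  sp <- donor_specific_variants(calls)
  expect_equal(sp$H1, c(v1 = "ALT", v3 = "ALT"))  # v2 shared ALT dropped
  expect_equal(sp$H2, c(v3 = "REF"))              # differs from H1's ALT: kept
  expect_equal(sp$H3, c(v4 = "REF"))
  # exclusive mode: the variant itself must pass in exactly one donor
  spx <- donor_specific_variants(calls, refinement_config(specific_mode = "exclusive"))
  expect_equal(names(spx$H1), "v1")
  expect_equal(names(spx$H2), character(0))
  expect_error(donor_specific_variants(calls["H1"]), "2 donors")
})

test_that("donor VCF round trip reproduces calls exactly", {
  variants <- data.frame(chrom = c("1", "1", "2"), pos = c(100L, 50L, 7L),
                         id = paste0("v", 1:3), ref = c("A", "C", "G"),
                         alt = c("G", "T", "A"), stringsAsFactors = FALSE)
  variants$key <- variant_key(variants)
  calls <- list(H1 = stats::setNames(c("ALT", "REF"), variants$key[c(1, 2)]),
                H2 = stats::setNames("ALT", variants$key[3]))
  p <- tempfile(fileext = ".vcf")
  write_donor_vcf(calls, p, variants = variants)
  lines <- readLines(p)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 3L)
  # sorted by chrom, pos and './.' at the 3 uncalled donor cells
  expect_match(body[1], "^1\t50\t")
  expect_equal(sum(vapply(strsplit(body, "\t"), function(f)
    sum(f[10:11] == "./."), integer(1))), 3L)
  g <- read_donor_vcf(p)
  expect_equal(g$calls$H1[order(names(g$calls$H1))],
               calls$H1[order(names(calls$H1))])
  expect_equal(g$calls$H2, calls$H2)
  expect_error(write_donor_vcf(stats::setNames(calls, c("H1", "H1")), p,
                               variants = variants), "duplicate sample")
})

test_that("reconstruction recovers planted private variants end to end", {
  cfg <- sim_config(n_variants = 100, n_private_per_donor = 20,
                    n_cells = 3000, seed = 123)
  sim <- simulate_experiment(cfg)
  m <- match_methods(sim$genetic, sim$hashing, cfg$n_donors)
  joint <- joint_assign(sim$hashing, sim$genetic, m)
  g <- reconstruct_genotypes(sim$counts, joint)
  hash_of <- stats::setNames(sim$permutation$hashtag, sim$permutation$donor)
  for (d in names(sim$genotypes$private_rows)) {
    planted <- sim$genotypes$variants$key[sim$genotypes$private_rows[[d]]]
    own <- g$calls[[hash_of[[d]]]]
    hit <- planted %in% names(own)[own == "ALT"]
    expect_gte(mean(hit), 0.9)
    # no planted private of d is ALT-called as specific for another donor
    for (o in setdiff(g$donors, hash_of[[d]])) {
      oth <- g$calls[[o]]
      expect_length(intersect(planted, names(oth)[oth == "ALT"]), 0L)
    }
  }
  # every emitted call re-verifies its thresholds from raw counts
  rcfg <- refinement_config()
  for (d in g$donors) {
    cons <- partition_cells(joint, d)$consistent
    agg <- aggregate_counts(sim$counts, cons)
    recheck <- stats::setNames(overrepresented_allele(agg$sumAD, agg$sumDP, rcfg),
                               agg$key)
    expect_identical(unname(recheck[names(g$calls[[d]])]),
                     unname(g$calls[[d]]))
  }
})

test_that("raising thresholds never enlarges the kept variant set", {
  fx <- refine_fixture()
  base <- informative_variants(fx$counts, fx$joint, "H1")
  for (cfg in list(refinement_config(depth_threshold = 20),
                   refinement_config(freq_threshold = 0.99),
                   refinement_config(depth_threshold = 25, freq_threshold = 0.95))) {
    v <- informative_variants(fx$counts, fx$joint, "H1", cfg)
    expect_true(all(names(v) %in% names(base)))
  }
})
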