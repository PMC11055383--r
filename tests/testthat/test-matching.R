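mat <- function(x, donors = NULL, tags = NULL) {
  donors <- donors %||% paste0("d", seq_len(nrow(x)))
  tags <- tags %||% paste0("h", seq_len(ncol(x)))
  dimnames(x) <- list(donors, tags)
  x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

bin1 <- function(v, name) {
  m <- matrix(as.integer(v), ncol = 1, dimnames = list(paste0("c", seq_along(v)), name))
  m
}

test_that("pairwise phi reproduces hand-computed binary correlations", {
  phi_of <- function(x, y) {
    pairwise_phi(bin1(x, "d"), bin1(y, "h"))$matrix[1, 1]
  }
  expect_identical(phi_of(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)   # exact
  expect_equal(phi_of(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0)
  expect_identical(phi_of(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)  # exact
  r <- pairwise_phi(bin1(c(0, 0, 0, 0), "d"), bin1(c(1, 0, 1, 0), "h"))
  expect_equal(r$matrix[1, 1], 0)
  expect_true(r$zero_variance_donors[["d"]])
  expect_false(r$zero_variance_hashtags[["h"]])
})

test_that("pairwise phi agrees with Pearson correlation on binary vectors", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(10:200, 1)
    x <- rbinom(n, 1, runif(1, 0.1, 0.9))
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    got <- pairwise_phi(bin1(x, "d"), bin1(y, "h"))$matrix[1, 1]
    expect_equal(got, phi_contingency(x, y), tolerance = 1e-12)
    if (var(x) > 0 && var(y) > 0) {
      expect_equal(got, stats::cor(x, y), tolerance = 1e-12)
    }
  }
})

test_that("pairwise phi is transpose-symmetric and validates row order", {
  set.seed(5)
  A <- matrix(rbinom(60, 1, 0.3), 20, 3,
              dimnames = list(paste0("c", 1:20), paste0("d", 1:3)))
  B <- matrix(rbinom(40, 1, 0.4), 20, 2,
              dimnames = list(paste0("c", 1:20), paste0("h", 1:2)))
  expect_equal(pairwise_phi(A, B)$matrix, t(pairwise_phi(B, A)$matrix))
  expect_error(pairwise_phi(A, B[20:1, ]), "row")
})

test_that("mutual-best matching keeps only mutually maximal pairs", {
  p <- mutual_best_match(mat(rbind(c(0.9, 0.1), c(0.2, 0.8))))
  expect_equal(p$donor, c("d1", "d2"))
  expect_equal(p$hashtag, c("h1", "h2"))
  # d2's best is h1, but h1 prefers d1: only (d1, h1) is mutual
  p2 <- mutual_best_match(mat(rbind(c(0.9, 0.8), c(0.85, 0.1))))
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$donor, "d1")
  expect_equal(p2$hashtag, "h1")
  # all-zero: ties resolve lexicographically, one zero-confidence pair
  p3 <- mutual_best_match(mat(matrix(0, 2, 2)))
  expect_equal(p3$donor, "d1")
  expect_equal(p3$hashtag, "h1")
  expect_equal(p3$correlation, 0)
})

test_that("phi score sums clamped correlations over expected donors", {
  expect_equal(phi_score(c(0.9, 0.8), 3), 0.5667, tolerance = 1e-4)
  expect_equal(phi_score(c(1, 1, 1), 3), 1)
  expect_equal(phi_score(c(1, 1, -0.2), 3), 0.6667, tolerance = 1e-4)
  expect_warning(phi_score(data.frame(donor = c("a", "b"), hashtag = c("x", "y"),
                                      correlation = c(1, 1)), 1),
                 "n_expected_donors")
  expect_error(phi_score(c(0.5), 0), "positive")
})

test_that("a renamed bijection matches perfectly", {
  set.seed(1)
  don <- sample(paste0("donor", 0:3), 400, replace = TRUE)
  map <- c(donor0 = "H3", donor1 = "H1", donor2 = "H4", donor3 = "H2")
  g <- tbl(paste0("c", 1:400), don, "vireo", "genetic")
  h <- tbl(paste0("c", 1:400), unname(map[don]), "multiseq", "hashing")
  m <- match_methods(g, h, 4)
  expect_true(m$all_donors_matched)
  expect_identical(unname(m$pairs$correlation), rep(1, 4))
  expect_equal(m$phi_score, 1)
  expect_equal(matched_pairs(m)[names(map)], map)
  # phi score scales with the expected donor count
  expect_equal(match_methods(g, h, 8)$phi_score, 0.5)
})

test_that("donor renaming permutes correlation rows but not the score", {
  set.seed(2)
  don <- sample(paste0("donor", 0:2), 300, replace = TRUE)
  noise <- ifelse(runif(300) < 0.1,
                  sample(c("H1", "H2", "H3", "negative"), 300, replace = TRUE),
                  c(donor0 = "H1", donor1 = "H2", donor2 = "H3")[don])
  g <- tbl(paste0("c", 1:300), don, "g", "genetic")
  h <- tbl(paste0("c", 1:300), noise, "h", "hashing")
  m <- match_methods(g, h, 3)
  # bijective rename of the anonymous donor labels
  ren <- c(donor0 = "zz", donor1 = "aa", donor2 = "mm")
  g2 <- tbl(paste0("c", 1:300), unname(ren[don]), "g", "genetic")
  m2 <- match_methods(g2, h, 3)
  expect_equal(m2$phi_score, m$phi_score)
  expect_equal(m2$correlations$matrix[ren[rownames(m$correlations$matrix)], ],
               m$correlations$matrix, ignore_attr = TRUE)
  # induced barcode-level relabeling is unchanged
  r1 <- relabel_genetic(g, m)
  r2 <- relabel_genetic(g2, m2)
  expect_identical(r1$calls$label, r2$calls$label)
})

test_that("all-negative hashing gives zero-variance columns and no match", {
  g <- tbl(paste0("c", 1:40), rep(paste0("donor", 0:1), 20), "g", "genetic")
  h <- tbl(paste0("c", 1:40), rep("negative", 40), "h", "hashing")
  m <- match_methods(g, h, 2, hashing_labels = c("H1", "H2"))
  expect_true(all(m$correlations$zero_variance_hashtags))
  expect_false(m$all_donors_matched)
  expect_equal(m$phi_score, 0)
})

test_that("best-pair selection prefers full matches, then score, then names", {
  set.seed(3)
  don <- sample(paste0("donor", 0:2), 600, replace = TRUE)
  map <- c(donor0 = "H1", donor1 = "H2", donor2 = "H3")
  g <- tbl(paste0("c", 1:600), don, "vireo", "genetic")
  # noisy but complete hashing; 35% corrupted
  noisy <- ifelse(runif(600) < 0.35, sample(c("H1", "H2", "H3"), 600, TRUE),
                  unname(map[don]))
  h_full <- tbl(paste0("c", 1:600), noisy, "a_noisy", "hashing")
  # clean hashing that never sees donor2's hashtag
  part <- ifelse(don == "donor2", "negative", unname(map[don]))
  h_part <- tbl(paste0("c", 1:600), part, "b_partial", "hashing")
  m_full <- match_methods(g, h_full, 3)
  m_part <- match_methods(g, h_part, 3)
  stopifnot(m_full$all_donors_matched, !m_part$all_donors_matched,
            m_part$phi_score > m_full$phi_score)
  sel <- select_best_pair(list(g), list(h_full, h_part), 3)
  expect_equal(unname(sel$pair), c("vireo", "a_noisy"))
  expect_false(sel$partial)
  expect_equal(nrow(sel$ranking), 2L)
  # identical scores break ties lexicographically by method name
  h_b <- tbl(paste0("c", 1:600), unname(map[don]), "b_clean", "hashing")
  h_a <- tbl(paste0("c", 1:600), unname(map[don]), "a_clean", "hashing")
  sel2 <- select_best_pair(list(g), list(h_b, h_a), 3)
  expect_equal(unname(sel2$pair["hashing"]), "a_clean")
  # single pair: identity
  sel3 <- select_best_pair(list(g), list(h_b), 3)
  expect_equal(unname(sel3$pair["hashing"]), "b_clean")
})

test_that("relabeling maps matched donors and keeps the rest", {
  g <- tbl(c("c1", "c2", "c3"), c("donor0", "donor5", "doublet"), "g", "genetic")
  m <- fake_match("donor0", "H2")
  r <- suppressMessages(relabel_genetic(g, m))
  expect_equal(r$calls$label, c("H2", "donor5", NA))
  expect_equal(r$calls$kind, c("singlet", "singlet", "doublet"))
})
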