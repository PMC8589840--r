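test_that("growth normalisation and classification follow the thresholds", {
  expect_equal(normalize_growth(2, 2), 0)
  expect_equal(normalize_growth(4, 2), 1)
  expect_equal(normalize_growth(1, 2), -1)
  expect_error(normalize_growth(0, 2), "positive")

  expect_equal(classify_growth(0.5), "inferior")
  expect_equal(classify_growth(1.2), "highly_inferior")
  expect_equal(classify_growth(0), "neutral")
  expect_equal(classify_growth(-0.5), "superior")
  expect_equal(classify_growth(-1.7), "highly_superior")
  # boundary conventions: inner bounds join the milder class, outer bounds
  # the highly- classes
  expect_equal(classify_growth(c(0.25, 1, -0.25, -1)),
               c("inferior", "highly_inferior", "superior", "highly_superior"))
  expect_equal(classify_growth(c(0.249, -0.249)), c("neutral", "neutral"))
  expect_error(classify_growth(NA_real_), "finite")

  # the labels partition the line: exactly one label per value
  probe <- seq(-2, 2, by = 0.01)
  expect_true(all(nchar(classify_growth(probe)) > 0))
})

test_that("heterosis calls need parents and significance against both", {
  expect_equal(heterosis(rnorm(5), NULL, rnorm(5)), "not_evaluable")
  expect_equal(heterosis(c(1, 1.1), c(0.9, 1.2, 1), c(1, 1.05, 0.95)), "none")

  # clone 2 replicate-SD worse than the worse parent, n = 5: the one-sided
  # Welch test has closed-form power 0.89 here
  # (power.t.test(n = 5, delta = 2, sd = 1, alternative = "one.sided")),
  # so the detection rate should sit in its binomial 3-sigma band
  set.seed(51)
  calls <- vapply(1:200, function(i) {
    p1 <- rnorm(5, 0, 0.1)
    p2 <- rnorm(5, 0.5, 0.1)           # the worse parent
    clone <- rnorm(5, 0.7, 0.1)        # 2 SD worse than the worse parent
    heterosis(clone, p1, p2)
  }, "")
  expect_gt(mean(calls == "worse_parent"), 0.89 - 3 * sqrt(0.89 * 0.11 / 200))
  expect_true(all(calls %in% c("worse_parent", "none")))

  set.seed(52)
  best <- vapply(1:50, function(i) {
    heterosis(rnorm(5, -1, 0.1), rnorm(5, 0, 0.1), rnorm(5, 0.5, 0.1))
  }, "")
  expect_gte(mean(best == "best_parent"), 0.9)
})

test_that("marker filtering drops uncalled and single-homozygote markers", {
  g <- rbind(c1 = c(0, 1, NA, 0, 1),
             c2 = c(0, -1, NA, 0, 1),
             c3 = c(0, 0, NA, 1, 0))
  colnames(g) <- paste0("m", 1:5)
  f <- filter_markers(g)
  expect_equal(colnames(f), c("m2", "m5"))
  removed <- attr(f, "removed")
  expect_equal(removed$reason[removed$marker == "m3"], "no_genotype")
  expect_equal(removed$reason[removed$marker == "m1"],
               "homozygous_in_fewer_than_2")   # all-HET
  expect_equal(removed$reason[removed$marker == "m4"],
               "homozygous_in_fewer_than_2")   # one homozygote
  expect_error(filter_markers(g[, 1, drop = FALSE]), "survive")
  expect_error(filter_markers(g[1, , drop = FALSE]), "2 clones")
})

test_that("LOD values match a brute-force least-squares oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(10:20, 1)
    M <- 10
    G <- matrix(sample(c(-1, 0, 1), n * M, replace = TRUE), n, M,
                dimnames = list(paste0("c", 1:n), paste0("m", 1:M)))
    y <- stats::rnorm(n)
    names(y) <- rownames(G)
    scan <- lod_scan(G, y)
    oracle <- vapply(1:M, function(j) {
      fit0 <- lm(y ~ 1)
      fit1 <- lm(y ~ G[, j])
      (n / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
    }, 0)
    expect_lt(max(abs(scan$lod - oracle)), 1e-9)

    # factor model against lm with a genotype factor
    scanf <- lod_scan(G, y, model = "factor")
    oraclef <- vapply(1:M, function(j) {
      fit0 <- lm(y ~ 1)
      fit1 <- lm(y ~ factor(G[, j]))
      (n / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
    }, 0)
    expect_lt(max(abs(scanf$lod - oraclef)), 1e-9)
  }

  # missing genotypes: per-marker complete cases
  G <- matrix(sample(c(-1, 0, 1), 60, replace = TRUE), 12, 5,
              dimnames = list(paste0("c", 1:12), paste0("m", 1:5)))
  G[1:3, 2] <- NA
  y <- rnorm(12); names(y) <- rownames(G)
  scan <- lod_scan(G, y)
  ok <- !is.na(G[, 2])
  fit0 <- lm(y[ok] ~ 1); fit1 <- lm(y[ok] ~ G[ok, 2])
  expect_equal(scan$lod[2],
               (sum(ok) / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2)),
               tolerance = 1e-12)
  expect_equal(scan$n[2], sum(ok))

  # constant phenotype and zero-variance genotype give LOD 0
  G[, 1] <- 0
  expect_equal(lod_scan(G, setNames(rep(1, 12), rownames(G)))$lod,
               rep(0, 5))
  expect_equal(lod_scan(G, y)$lod[1], 0)
})

test_that("permutation threshold is the stated order statistic and is stable", {
  set.seed(62)
  G <- matrix(sample(c(-1, 0, 1), 50 * 20, replace = TRUE), 50, 20,
              dimnames = list(paste0("c", 1:50), paste0("m", 1:20)))
  y <- rnorm(50); names(y) <- rownames(G)
  thr <- permutation_threshold(G, y, n_perm = 200, seed = 7)
  maxima <- attr(thr, "maxima")
  expect_equal(as.numeric(thr), sort(maxima)[ceiling(0.95 * 200)])
  expect_identical(as.numeric(permutation_threshold(G, y, n_perm = 200,
                                                    seed = 7)),
                   as.numeric(thr))
  # quantile monotonicity
  thr99 <- permutation_threshold(G, y, n_perm = 200, quantile = 0.99,
                                 seed = 7)
  expect_gte(as.numeric(thr99), as.numeric(thr))
  expect_error(permutation_threshold(G, y, n_perm = 50), ">= 100")

  # the vectorised additive path agrees with the per-marker fallback
  G2 <- G; G2[1, 1] <- NA
  set.seed(11); thr_a <- permutation_threshold(G, y, n_perm = 100)
  set.seed(11); thr_b <- permutation_threshold(G2, y, n_perm = 100)
  expect_lt(abs(as.numeric(thr_a) - as.numeric(thr_b)), 0.5)
})

test_that("LOD-drop intervals bracket peaks, plateaus and edges", {
  scan <- tibble::tibble(
    marker = paste0("m", 1:7), chrom = "chrI",
    pos = seq(100, 700, by = 100),
    lod = c(0.1, 0.2, 0.4, 5, 0.4, 0.2, 0.1), n = 20)
  ci <- qtl_interval(scan, drop = 1.5)
  expect_equal(ci$peak_pos, 400)
  expect_equal(c(ci$ci_lo, ci$ci_hi), c(300, 500))  # spike + flanks
  expect_false(ci$at_edge)

  plateau <- scan; plateau$lod <- c(0.1, 4, 4, 4, 4, 0.2, 0.1)
  ci <- qtl_interval(plateau, drop = 1.5)
  expect_equal(c(ci$ci_lo, ci$ci_hi), c(100, 600))  # plateau + flanks

  edge <- scan; edge$lod <- c(5, 4.2, 0.3, 0.2, 0.1, 0.1, 0.1)
  ci <- qtl_interval(edge, drop = 1.5)
  expect_true(ci$at_edge)
  expect_equal(ci$ci_lo, 100)  # one-sided at the scan edge
})

test_that("a planted QTL is mapped and its interval covers the true marker", {
  set.seed(63)
  n <- 125; M <- 60
  G <- matrix(sample(c(-1, 0, 1), n * M, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), n, M,
              dimnames = list(paste0("c", 1:n), NULL))
  colnames(G) <- paste0("chr", rep(1:3, each = 20), ":",
                        rep(seq(1e4, 20e4, by = 1e4), 3))
  info <- tibble::tibble(marker = colnames(G),
                         chrom = rep(paste0("chr", 1:3), each = 20),
                         pos = rep(seq(1e4, 20e4, by = 1e4), 3))
  attr(G, "markers") <- info
  y <- G[, 30] * 1 + rnorm(n)   # additive effect = 1 phenotype SD unit
  names(y) <- rownames(G)
  res <- map_qtl(G, y, n_perm = 200, seed = 9, environment = "test")
  expect_s3_class(res, "qtl_scan")
  expect_gt(res$threshold, 0)
  expect_true(nrow(res$peaks) >= 1)
  pk <- res$peaks[res$peaks$chrom == "chr2", ]
  expect_equal(nrow(pk), 1)
  expect_true(pk$ci_lo <= info$pos[30] & pk$ci_hi >= info$pos[30])

  expect_equal(nrow(glance(res)), 1)
  expect_equal(nrow(tidy(res)), nrow(res$scan))
})

test_that("encode_genotypes produces the additive coding with metadata", {
  g <- tibble::tibble(
    clone = rep(c("a", "b"), each = 3),
    chrom = rep("chrI", 6), pos = rep(c(100, 200, 300), 2),
    genotype = c("HET", "HOM_P1", "MISSING", "HOM_P2", "HET", "HOM_P1"))
  m <- encode_genotypes(g)
  expect_equal(dim(m), c(2, 3))
  expect_equal(unname(m["a", ]), c(0, 1, NA))
  expect_equal(unname(m["b", ]), c(-1, 0, 1))
  expect_equal(attr(m, "markers")$pos, c(100, 200, 300))
})
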