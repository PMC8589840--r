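test_that("homozygous runs are segmented, classified and located as defined", {
  layout <- one_chrom_layout(len = 1000, cen = c(450, 460))
  map <- mk_map(c(100, 200, 300, 400, 500))

  # interstitial run of two markers
  segs <- call_loh(mk_track(map, c("HET", "HET", "HOM_P1", "HOM_P1", "HET")),
                   map, layout)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$parent, "P1")
  expect_equal(segs$n_markers, 2)
  expect_equal(segs$class, "interstitial")
  expect_equal(c(segs$first, segs$last), c(300, 400))
  expect_equal(c(segs$start, segs$end), c(250, 450))

  # run reaching the last marker of the arm is terminal
  map3 <- mk_map(c(100, 200, 300))
  segs <- call_loh(mk_track(map3, c("HET", "HOM_P2", "HOM_P2")), map3, layout)
  expect_equal(segs$class, "terminal")
  expect_equal(segs$end, 300)  # clamped at the arm end

  # single-marker events are genuine calls
  segs <- call_loh(mk_track(map3, c("HET", "HOM_P1", "HET")), map3, layout)
  expect_equal(segs$n_markers, 1)
  expect_equal(segs$class, "interstitial")

  # all-HET track yields nothing
  expect_equal(nrow(call_loh(mk_track(map3, rep("HET", 3)), map3, layout)), 0)
})

test_that("start/end midpoints follow the adjacent-marker rule", {
  layout <- one_chrom_layout(len = 1000, cen = c(450, 460))
  map <- mk_map(c(100, 200, 300, 400))
  segs <- call_loh(mk_track(map, c("HET", "HOM_P1", "HOM_P1", "HET")),
                   map, layout)
  expect_equal(c(segs$first, segs$last), c(200, 300))
  expect_equal(c(segs$start, segs$end), c(150, 350))

  map2 <- mk_map(c(400, 500, 800))
  segs <- call_loh(mk_track(map2, c("HET", "HOM_P2", "HET")), map2, layout)
  expect_equal(c(segs$first, segs$last), c(500, 500))
  expect_equal(c(segs$start, segs$end), c(450, 650))

  # terminal segment starting at the first marker: start clamps to first
  segs <- call_loh(mk_track(map2, c("HOM_P2", "HOM_P2", "HET")), map2, layout)
  expect_equal(segs$start, segs$first)

  # segment_coordinates recomputes the same values
  rec <- segment_coordinates(segs[, setdiff(names(segs), c("start", "end"))],
                             map2)
  expect_equal(rec$start, segs$start)
  expect_equal(rec$end, segs$end)
})

test_that("parent switches split runs and whole-chromosome LOH is flagged", {
  layout <- one_chrom_layout(len = 1000, cen = c(450, 460))
  map <- mk_map(c(100, 200, 300, 400, 500))
  segs <- call_loh(mk_track(map, c("HET", "HOM_P1", "HOM_P1", "HOM_P2", "HET")),
                   map, layout)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$parent, c("P1", "P2"))
  # shared breakpoint at the midpoint of the opposite-parent neighbours
  expect_equal(segs$end[1], 350)
  expect_equal(segs$start[2], 350)

  segs <- call_loh(mk_track(map, rep("HOM_P1", 5)), map, layout)
  expect_equal(segs$class, "whole_chromosome")
  expect_equal(nrow(segs), 1)
})

test_that("MISSING is transparent, gap-limited, and masked markers are ignored", {
  layout <- one_chrom_layout(len = 1000, cen = c(450, 460))
  map <- mk_map(c(100, 200, 300, 400, 500))
  g <- c("HET", "HOM_P1", "MISSING", "HOM_P1", "HET")
  segs <- call_loh(mk_track(map, g), map, layout)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_markers, 2)  # MISSING does not add support
  expect_equal(c(segs$first, segs$last), c(200, 400))

  # a gap limit breaks the bridge
  segs <- call_loh(mk_track(map, g), map, layout, max_gap = 150)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_markers, c(1, 1))

  # an all-MISSING stretch is no event
  segs <- call_loh(mk_track(map, c("HET", "MISSING", "MISSING", "HET", "HET")),
                   map, layout)
  expect_equal(nrow(segs), 0)

  # a masked terminal marker does not define the arm end
  layout_m <- one_chrom_layout(len = 1000, cen = c(450, 460), mask = 150)
  map_m <- apply_masks(mk_map(c(100, 500, 600, 900)), layout_m)
  expect_equal(map_m$masked, c(TRUE, FALSE, FALSE, TRUE))
  segs <- call_loh(mk_track(map_m, c("HET", "HET", "HOM_P1", "HOM_P1")),
                   map_m, layout_m)
  expect_equal(segs$class, "terminal")  # reaches last non-masked marker (600)
  expect_equal(segs$last, 600)

  expect_error(call_loh(mk_track(mk_map(c(1, 2)), c("HET", "HET")),
                        map, layout), "does not match")
})

test_that("clone summaries count classes and partition marker fractions", {
  layout <- genome_layout(c("chrI", "chrII"), c(1000, 1000), c(450, 450),
                          c(460, 460), mask_left = 0, mask_right = 0)
  map <- marker_map(tibble::tibble(
    chrom = rep(c("chrI", "chrII"), c(9, 1)),
    pos = c(seq(100, 900, by = 100), 500),
    allele1 = "A", allele2 = "T"))
  g <- c("HET", "HOM_P1", "HOM_P1", "HET", "HET", "HOM_P2", "HET", "HET",
         "HET", "HOM_P2")
  segs <- call_loh(mk_track(map, g), map, layout)
  s <- summarize_loh(segs, map, layout)
  expect_equal(s$n_interstitial, 2)
  expect_equal(s$n_terminal, 0)
  expect_equal(s$n_whole_chromosome, 1)  # chrII single-marker chromosome
  expect_equal(s$frac_markers_loh, 0.4)
  expect_equal(s$frac_p1 + s$frac_p2, s$frac_markers_loh)

  none <- summarize_loh(segs[0, ], map, layout, clones = "c9")
  expect_equal(none$frac_markers_loh, 0)
  expect_equal(none$n_interstitial + none$n_terminal, 0)

  # chrII holds 10% of markers; covering it fully gives fraction 0.10
  g2 <- c(rep("HET", 9), "HOM_P1")
  s2 <- summarize_loh(call_loh(mk_track(map, g2), map, layout), map, layout)
  expect_equal(s2$frac_markers_loh, 0.1)
})

test_that("breakpoint regions span homozygous-to-flank intervals", {
  layout <- one_chrom_layout(len = 2000, cen = c(950, 960))
  map <- mk_map(seq(100, 1900, by = 100))  # 19 markers
  g <- rep("HET", 19)
  g[8:10] <- "HOM_P1"    # interstitial at 800-1000
  g[17:19] <- "HOM_P2"   # terminal at 1700-1900
  segs <- call_loh(mk_track(map, g), map, layout)
  br <- breakpoint_regions(segs, map, k = 5)
  expect_equal(nrow(br), 3)  # two for interstitial, one for terminal
  left <- br[br$side == "left" & br$end == 800, ]
  expect_equal(c(left$start, left$end), c(700, 800))
  expect_equal(left$hom_markers[[1]], c(800, 900, 1000))  # truncated at 3 HOM
  expect_equal(length(left$het_markers[[1]]), 5)
  expect_equal(max(left$het_markers[[1]]), 700)
  # terminal event: only the proximal side has a region
  term <- br[br$start == 1600 | br$end == 1700, ]
  expect_equal(nrow(term), 1)
  expect_equal(term$side, "left")
})

test_that("inter-marker distances are computed genome-wide and in windows", {
  layout <- one_chrom_layout(len = 1000, cen = c(450, 460))
  map <- mk_map(c(100, 200, 400))
  d <- inter_marker_distances(map)
  expect_setequal(d$distance, c(100, 200))

  expect_equal(nrow(inter_marker_distances(mk_map(100))), 0)

  # a marker desert at a breakpoint inflates window distances
  pos <- c(seq(100, 2000, by = 100), seq(52000, 60000, by = 100))
  layout2 <- one_chrom_layout(len = 100000, cen = c(30000, 30100))
  map2 <- mk_map(pos)
  g <- rep("HET", length(pos))
  g[pos >= 52000] <- "HOM_P1"
  segs <- call_loh(mk_track(map2, g), map2, layout2)
  br <- breakpoint_regions(segs, map2, k = 5)
  dd <- inter_marker_distances(map2, br)
  expect_gt(mean(dd$distance[dd$scope == "breakpoint"]),
            mean(dd$distance[dd$scope == "genome"]))
})

test_that("reciprocity flags only dosage-violating markers", {
  map <- mk_map(c(100, 200, 300))
  mo <- mk_track(map, c("HET", "HOM_P1", "HET"), clone = "m")
  da <- mk_track(map, c("HET", "HOM_P2", "HET"), clone = "d")
  expect_equal(nrow(reciprocity(mo, da)), 0)  # reciprocal CO pattern

  da2 <- mk_track(map, c("HET", "HET", "HET"), clone = "d")
  nr <- reciprocity(mo, da2)                  # one-sided conversion
  expect_equal(nr$pos, 200)
  expect_equal(nr$dosage_p1, 3)

  expect_equal(nrow(reciprocity(da2, da2)), 0)
  # MISSING markers are not assessable
  mo3 <- mk_track(map, c("MISSING", "HOM_P1", "HET"))
  expect_equal(reciprocity(mo3, da2)$pos, 200)
  expect_error(reciprocity(mo, mk_track(mk_map(c(1, 2, 3)), rep("HET", 3))),
               "different marker sets")
})

test_that("clone-set comparisons detect shifts and handle degenerate input", {
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    a <- rnorm(24, mean = 1)   # shifted by 1 SD
    b <- rnorm(22, mean = 0)
    compare_clone_sets(a, b, test = "wilcoxon",
                       alternative = "greater")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  expect_warning(res <- compare_clone_sets(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(res$p_value, 1)
  expect_error(compare_clone_sets(1, 1:5), ">= 2 clones")

  # Fligner-Killeen: equal-variance null rejects at ~ alpha
  set.seed(32)
  rej <- vapply(1:200, function(i) {
    compare_clone_sets(rnorm(20), rnorm(20),
                       test = "fligner")$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
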