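#' Call LOH segments from genotype tracks
#'
#' Stretches of consecutive markers with the same homozygous genotype are
#' grouped into LOH segments. No minimum-marker filter is applied: events
#' supported by a single marker are genuine calls. `MISSING` genotypes are
#' transparent (they neither extend nor break a run and do not count toward
#' its marker support) unless two informative markers of the run lie more
#' than `max_gap` bp apart. Masked markers are ignored entirely. A run
#' containing both parents is split at the parent switch.
#'
#' Each segment carries two coordinate systems: `first`/`last` are the
#' positions of its terminal markers; `start`/`end` average the terminal
#' marker with the nearest informative marker outside the segment, clamped to
#' the terminal marker at a chromosome-arm end. Classification: a segment
#' reaching the last non-masked marker of a chromosome arm is `terminal`,
#' one flanked by heterozygous markers on both sides is `interstitial`, and
#' a run covering every informative marker of a chromosome is flagged
#' `whole_chromosome` (RTG predicts heterozygous centromeres, so such events
#' are surfaced, not silently split).
#'
#' @param genotypes Long genotype tibble (`clone`, `chrom`, `pos`,
#'   `genotype` in `HET`, `HOM_P1`, `HOM_P2`, `MISSING`); one or many clones,
#'   each covering exactly the markers of `map`.
#' @param map A [marker_map()] with masks applied.
#' @param layout A [genome_layout()] (used for validation of chromosomes).
#' @param max_gap Maximum distance (bp) bridged between consecutive
#'   informative markers of one run; default `Inf` (never break).
#' @return A tibble with one row per segment: `clone`, `chrom`, `parent`,
#'   `first`, `last`, `start`, `end`, `n_markers`, `class`.
#' @export
call_loh <- function(genotypes, map, layout, max_gap = Inf) {
  layout_row(layout, unique(map$chrom))
  key_map <- paste(map$chrom, map$pos)
  out <- lapply(split(genotypes, genotypes$clone), function(tr) {
    if (nrow(tr) != nrow(map) ||
        !setequal(paste(tr$chrom, tr$pos), key_map)) {
      stop("genotype track of clone '", tr$clone[1],
           "' does not match the marker map", call. = FALSE)
    }
    tr <- tr[match(key_map, paste(tr$chrom, tr$pos)), ]
    segs <- lapply(unique(map$chrom), function(ch) {
      i <- which(map$chrom == ch)
      call_loh_chrom(tr$genotype[i], map$pos[i], map$masked[i], max_gap)
    })
    segs <- dplyr::bind_rows(stats::setNames(segs, unique(map$chrom)),
                             .id = "chrom")
    if (nrow(segs) > 0) dplyr::mutate(segs, clone = tr$clone[1], .before = 1)
    else NULL
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(clone = character(), chrom = character(),
                          parent = character(), first = numeric(),
                          last = numeric(), start = numeric(), end = numeric(),
                          n_markers = integer(), class = character())
  }
  res
}

# One clone, one chromosome. geno/pos/masked aligned vectors.
call_loh_chrom <- function(geno, pos, masked, max_gap) {
  keep <- !masked & geno != "MISSING"
  g <- geno[keep]; p <- pos[keep]
  m <- length(g)
  if (m == 0) return(NULL)
  code <- integer(m)
  code[g == "HOM_P1"] <- 1L
  code[g == "HOM_P2"] <- 2L
  gap_break <- if (is.finite(max_gap) && m > 1) c(FALSE, diff(p) > max_gap)
               else rep(FALSE, m)
  run_id <- cumsum(c(TRUE, code[-1] != code[-m]) | gap_break)
  hom <- code > 0
  if (!any(hom)) return(NULL)
  i1 <- tapply(seq_len(m)[hom], run_id[hom], min)
  i2 <- tapply(seq_len(m)[hom], run_id[hom], max)
  i1 <- as.integer(i1); i2 <- as.integer(i2)
  first <- p[i1]; last <- p[i2]
  start <- ifelse(i1 > 1, (first + p[pmax(i1 - 1, 1)]) / 2, first)
  end <- ifelse(i2 < m, (last + p[pmin(i2 + 1, m)]) / 2, last)
  cls <- ifelse(i1 == 1 & i2 == m, "whole_chromosome",
                ifelse(i1 == 1 | i2 == m, "terminal", "interstitial"))
  tibble::tibble(parent = c("P1", "P2")[code[i1]],
                 first = first, last = last, start = start, end = end,
                 n_markers = i2 - i1 + 1, class = cls)
}

#' Recompute start/end coordinates for LOH segments
#'
#' Given segments with `first`/`last` marker positions, recomputes the
#' `start`/`end` midpoint coordinates against the map: `start` is the average
#' of the first segment marker and the nearest non-masked marker before it
#' (clamped to `first` at an arm end), `end` symmetrically. Idempotent on
#' [call_loh()] output when no genotypes are `MISSING`.
#'
#' @param segments Segment tibble with `chrom`, `first`, `last`.
#' @param map A [marker_map()] with masks applied.
#' @return `segments` with `start` and `end` (re)computed.
#' @export
segment_coordinates <- function(segments, map) {
  keep <- !map$masked
  pos_by <- split(map$pos[keep], map$chrom[keep])
  n <- nrow(segments)
  start <- numeric(n); end <- numeric(n)
  for (i in seq_len(n)) {
    p <- pos_by[[segments$chrom[i]]]
    f <- segments$first[i]; l <- segments$last[i]
    before <- p[p < f]
    after <- p[p > l]
    start[i] <- if (length(before) > 0) (f + max(before)) / 2 else f
    end[i] <- if (length(after) > 0) (l + min(after)) / 2 else l
  }
  segments$start <- start
  segments$end <- end
  segments
}

#' Per-clone LOH summary
#'
#' Counts events by class and computes the fraction of (non-masked) markers
#' in LOH, split by parent of origin, plus the fraction of the genome (bp,
#' using start/end extents) in LOH.
#'
#' @param segments Output of [call_loh()].
#' @param map A [marker_map()] with masks applied.
#' @param layout A [genome_layout()] (for the genome-size denominator).
#' @param clones Optional character vector of clone ids to report (so clones
#'   with zero events appear with zero rows); defaults to the clones present
#'   in `segments`.
#' @return A tibble with one row per clone: `clone`, `n_interstitial`,
#'   `n_terminal`, `n_whole_chromosome`, `frac_markers_loh`, `frac_p1`,
#'   `frac_p2`, `frac_genome_loh`.
#' @export
summarize_loh <- function(segments, map, layout, clones = NULL) {
  if (is.null(clones)) clones <- unique(segments$clone)
  n_inf <- sum(!map$masked)
  genome_bp <- sum(layout$length)
  rows <- lapply(clones, function(cl) {
    s <- segments[segments$clone == cl, ]
    tibble::tibble(
      clone = cl,
      n_interstitial = sum(s$class == "interstitial"),
      n_terminal = sum(s$class == "terminal"),
      n_whole_chromosome = sum(s$class == "whole_chromosome"),
      frac_markers_loh = sum(s$n_markers) / n_inf,
      frac_p1 = sum(s$n_markers[s$parent == "P1"]) / n_inf,
      frac_p2 = sum(s$n_markers[s$parent == "P2"]) / n_inf,
      frac_genome_loh = sum(s$end - s$start + 1) / genome_bp
    )
  })
  dplyr::bind_rows(rows)
}

#' LOH breakpoint regions and flanking marker windows
#'
#' For every segment side that has a heterozygous flank, returns the genomic
#' interval between the first (last) homozygous marker of the segment and the
#' closest non-masked marker outside it, together with the `k` homozygous
#' markers inside and the `k` heterozygous markers outside that are nearest
#' to the breakpoint (fewer when the chromosome runs out of markers).
#' Interstitial segments yield two regions, terminal segments one (the
#' chromosome-end side has no flank), whole-chromosome events none.
#'
#' @param segments Output of [call_loh()].
#' @param map A [marker_map()] with masks applied.
#' @param k Flanking window size in markers (default 5).
#' @return A tibble: `clone`, `chrom`, `side` (`left`/`right`), `start`,
#'   `end`, and list-columns `hom_markers`, `het_markers` of window
#'   positions.
#' @export
breakpoint_regions <- function(segments, map, k = 5) {
  stopifnot(k >= 1)
  keep <- !map$masked
  pos_by <- split(map$pos[keep], map$chrom[keep])
  out <- list()
  for (i in seq_len(nrow(segments))) {
    if (segments$class[i] == "whole_chromosome") next
    p <- pos_by[[segments$chrom[i]]]
    f <- segments$first[i]; l <- segments$last[i]
    inside <- p[p >= f & p <= l]
    before <- p[p < f]; after <- p[p > l]
    if (length(before) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        clone = segments$clone[i], chrom = segments$chrom[i], side = "left",
        start = max(before), end = f,
        hom_markers = list(utils::head(inside, k)),
        het_markers = list(utils::tail(before, k)))
    }
    if (length(after) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        clone = segments$clone[i], chrom = segments$chrom[i], side = "right",
        start = l, end = min(after),
        hom_markers = list(utils::tail(inside, k)),
        het_markers = list(utils::head(after, k)))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(clone = character(), chrom = character(),
                          side = character(), start = numeric(),
                          end = numeric(), hom_markers = list(),
                          het_markers = list()))
  }
  dplyr::bind_rows(out)
}

#' Inter-marker distance distributions
#'
#' Distances between consecutive non-masked markers, genome-wide and (when
#' breakpoint regions are supplied) inside the breakpoint windows formed by
#' each region's homozygous + heterozygous flanking markers. Breakpoint
#' windows in regions of low local heterozygosity show systematically larger
#' distances than the genome-wide background.
#'
#' @param map A [marker_map()] with masks applied.
#' @param regions Optional output of [breakpoint_regions()].
#' @return A tibble with columns `scope` (`genome` or `breakpoint`) and
#'   `distance` (bp); empty for chromosomes with fewer than 2 markers.
#' @export
inter_marker_distances <- function(map, regions = NULL) {
  keep <- !map$masked
  gw <- unlist(lapply(split(map$pos[keep], map$chrom[keep]), function(p) {
    if (length(p) < 2) numeric() else diff(sort(p))
  }), use.names = FALSE)
  out <- tibble::tibble(scope = rep("genome", length(gw)), distance = gw)
  if (!is.null(regions) && nrow(regions) > 0) {
    bp <- unlist(lapply(seq_len(nrow(regions)), function(i) {
      w <- sort(c(regions$hom_markers[[i]], regions$het_markers[[i]]))
      if (length(w) < 2) numeric() else diff(w)
    }), use.names = FALSE)
    out <- dplyr::bind_rows(
      out, tibble::tibble(scope = rep("breakpoint", length(bp)),
                          distance = bp))
  }
  out
}

#' Non-reciprocal markers between an RTG mother and daughter
#'
#' RTG crossovers are reciprocal: across the mother/daughter pair each marker
#' keeps a 2:2 parental allele dosage (HET contributes 1+1, a homozygous call
#' 2+0). Gene-conversion tracts break this balance (3:1 or 4:0). This
#' function returns the markers whose combined dosage deviates from 2:2;
#' markers `MISSING` in either cell are excluded (dosage unknown).
#'
#' @param mother,daughter Genotype tibbles over the same marker set.
#' @return A tibble of non-reciprocal markers: `chrom`, `pos`, `dosage_p1`
#'   (combined P1 allele count out of 4). The non-reciprocal marker count is
#'   `nrow()` of the result.
#' @export
reciprocity <- function(mother, daughter) {
  if (nrow(mother) != nrow(daughter) ||
      !setequal(paste(mother$chrom, mother$pos),
                paste(daughter$chrom, daughter$pos))) {
    stop("mother and daughter tracks cover different marker sets",
         call. = FALSE)
  }
  d <- daughter[match(paste(mother$chrom, mother$pos),
                      paste(daughter$chrom, daughter$pos)), ]
  dose <- function(g) ifelse(g == "HET", 1, ifelse(g == "HOM_P1", 2, 0))
  ok <- mother$genotype != "MISSING" & d$genotype != "MISSING"
  total <- dose(mother$genotype) + dose(d$genotype)
  bad <- ok & total != 2
  tibble::tibble(chrom = mother$chrom[bad], pos = mother$pos[bad],
                 dosage_p1 = total[bad])
}

#' Compare an LOH summary metric between two clone sets
#'
#' Location comparison by the Wilcoxon rank-sum test (normal approximation
#' with continuity correction, one- or two-tailed) or variance-homogeneity
#' comparison by the two-sided Fligner-Killeen test.
#'
#' @param a,b Summary tibbles (e.g. from [summarize_loh()]) or numeric
#'   vectors.
#' @param metric Column name to compare when `a`/`b` are data frames.
#' @param test `"wilcoxon"` or `"fligner"`.
#' @param alternative For the rank-sum test: `"greater"`, `"less"`,
#'   `"two.sided"` (is `a` shifted relative to `b`?).
#' @return A one-row tibble: `method`, `metric`, `statistic`, `p_value`,
#'   `alternative`, `n_a`, `n_b`.
#' @export
compare_clone_sets <- function(a, b, metric = "frac_markers_loh",
                               test = c("wilcoxon", "fligner"),
                               alternative = "greater") {
  test <- match.arg(test)
  x <- if (is.data.frame(a)) a[[metric]] else a
  y <- if (is.data.frame(b)) b[[metric]] else b
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 clones per set", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied; comparison is degenerate", call. = FALSE)
    return(tibble::tibble(method = test, metric = metric, statistic = NA_real_,
                          p_value = 1, alternative = alternative,
                          n_a = length(x), n_b = length(y)))
  }
  if (test == "wilcoxon") {
    ht <- stats::wilcox.test(x, y, alternative = alternative,
                             exact = FALSE, correct = TRUE)
  } else {
    ht <- stats::fligner.test(list(x, y))
    alternative <- "two.sided"
  }
  tibble::tibble(method = test, metric = metric,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 alternative = alternative, n_a = length(x), n_b = length(y))
}
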