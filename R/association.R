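#' Permutation test for overlap between two region sets
#'
#' Tests whether regions `a` (e.g. LOH breakpoint regions) overlap regions
#' `b` (e.g. meiotic DSB hotspots) more often than expected by chance. The
#' statistic is the number of `a` regions intersecting at least one `b`
#' region (closed intervals, >= 1 bp shared). The null is built by re-placing
#' each `a` region uniformly at random on its own chromosome, preserving its
#' length and never crossing the chromosome ends (randomised regions may
#' overlap each other). The empirical p-value uses the +1 correction
#' `p = (1 + #(null >= observed)) / (1 + ntimes)` for alternative
#' `"greater"`, so it is never smaller than `1/(ntimes + 1)`.
#'
#' @param a,b Region tibbles (`chrom`, `start`, `end`; 1-based inclusive),
#'   e.g. from [breakpoint_regions()] and [read_intervals()].
#' @param layout A [genome_layout()] covering all chromosomes of `a`.
#' @param ntimes Number of permutations (default 10000).
#' @param alternative `"greater"` (enrichment) or `"less"` (depletion).
#' @param seed Optional seed.
#' @return An object of class `perm_overlap_test`: a list with `observed`,
#'   `null` (the permuted statistics), `null_mean`, `null_sd`, `z`
#'   (`NA` and `degenerate = TRUE` when the null has zero variance),
#'   `p_value`, `ntimes`, `alternative`.
#' @export
permutation_overlap_test <- function(a, b, layout, ntimes = 10000,
                                     alternative = c("greater", "less"),
                                     seed = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(a) || nrow(a) == 0) stop("region set 'a' is empty", call. = FALSE)
  if (is.null(b) || nrow(b) == 0) stop("region set 'b' is empty", call. = FALSE)
  li <- layout_row(layout, a$chrom)
  if (any(a$end > layout$length[li])) {
    stop("region in 'a' exceeds its chromosome length", call. = FALSE)
  }
  if (any(a$end - a$start + 1 > layout$length[li])) {
    stop("region in 'a' longer than its chromosome", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  observed <- count_overlapping(a, b)
  null <- null_overlap_counts(a, b, layout, ntimes)
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else (observed - null_mean) / null_sd
  p <- if (alternative == "greater") {
    (1 + sum(null >= observed)) / (1 + ntimes)
  } else {
    (1 + sum(null <= observed)) / (1 + ntimes)
  }
  structure(list(observed = observed, null = null, null_mean = null_mean,
                 null_sd = null_sd, z = z, p_value = p, ntimes = ntimes,
                 alternative = alternative, degenerate = degenerate,
                 n_a = nrow(a), n_b = nrow(b)),
            class = "perm_overlap_test")
}

# Vectorised null: ntimes overlap counts for uniformly re-placed `a`.
null_overlap_counts <- function(a, b, layout, ntimes) {
  mb <- merged_by_chrom(b)
  counts <- integer(ntimes)
  for (ch in unique(a$chrom)) {
    i <- which(a$chrom == ch)
    len <- layout$length[layout_row(layout, ch)]
    w <- a$end[i] - a$start[i] + 1
    m <- mb[[ch]]
    if (is.null(m)) next                      # no b on this chromosome
    max_start <- len - w + 1
    n <- length(i)
    s <- floor(stats::runif(ntimes * n) * rep(max_start, each = ntimes)) + 1
    e <- s + rep(w, each = ntimes) - 1
    hit <- overlaps_any(s, e, m$start, m$end)
    counts <- counts + rowSums(matrix(hit, nrow = ntimes))
  }
  counts
}

#' @export
print.perm_overlap_test <- function(x, ...) {
  cat("Permutation overlap test (", x$ntimes, " permutations, alternative ",
      x$alternative, ")\n", sep = "")
  cat(sprintf("  observed: %d of %d regions overlap (null %.2f +/- %.2f)\n",
              x$observed, x$n_a, x$null_mean, x$null_sd))
  if (x$degenerate) {
    cat("  Z: undefined (degenerate null, zero variance)\n")
  } else {
    cat(sprintf("  Z = %.3f\n", x$z))
  }
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Local Z-score profile of a region association
#'
#' Probes how local an association between `a` and `b` is by re-running the
#' permutation test with `b` shifted along the genome. Shifts span
#' `[-W/2, +W/2]` in steps of `T`, where `W = 10 * S_m`, `T = S_m / 2` and
#' `S_m` is the mean length of the `b` regions; a genuinely local
#' association peaks at shift 0 and decays with distance. Shifted regions
#' are clamped (truncated) at chromosome ends, or wrapped around when
#' `circular = TRUE`.
#'
#' @inheritParams permutation_overlap_test
#' @param ntimes Permutations per shift (the default is lighter than the
#'   headline test because the profile runs 21 tests).
#' @param circular Wrap shifted regions around chromosome ends instead of
#'   truncating.
#' @return A tibble of class `local_z_profile` with columns `shift`, `z`,
#'   `p_value`, `observed`; attributes `s_m`, `window` (W) and `step` (T).
#' @export
local_z_profile <- function(a, b, layout, ntimes = 1000, circular = FALSE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s_m <- mean(b$end - b$start + 1)
  step <- s_m / 2
  shifts <- (-10:10) * step
  rows <- lapply(shifts, function(s) {
    bs <- shift_regions(b, s, layout, circular = circular)
    if (nrow(bs) == 0) {
      return(tibble::tibble(shift = s, z = NA_real_, p_value = NA_real_,
                            observed = NA_integer_))
    }
    pt <- permutation_overlap_test(a, bs, layout, ntimes = ntimes)
    tibble::tibble(shift = s, z = pt$z, p_value = pt$p_value,
                   observed = pt$observed)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "s_m") <- s_m
  attr(out, "window") <- 10 * s_m
  attr(out, "step") <- step
  class(out) <- c("local_z_profile", class(out))
  out
}

# Shift regions by s bp; truncate at chromosome ends (dropping regions
# pushed entirely off) or wrap around when circular.
shift_regions <- function(b, s, layout, circular = FALSE) {
  li <- layout_row(layout, b$chrom)
  len <- layout$length[li]
  start <- b$start + s
  end <- b$end + s
  if (circular) {
    w <- end - start
    start <- ((start - 1) %% len) + 1
    # wrapped regions that would straddle the origin are re-anchored whole
    start <- pmin(start, len - w)
    start <- pmax(start, 1)
    end <- start + w
    end <- pmin(end, len)
  } else {
    start <- pmax(start, 1)
    end <- pmin(end, len)
  }
  keep <- end >= start & start <= len & end >= 1
  out <- b[keep, ]
  out$start <- start[keep]
  out$end <- end[keep]
  out
}

#' Relative intensity of hotspots at LOH breakpoints
#'
#' Partitions hotspots into those overlapping and those not overlapping the
#' breakpoint regions (extended by each padding value on both sides) and
#' compares their relative intensities `RI = H / max(H)` (the maximum taken
#' over all hotspots, so `RI` is in `[0, 1]` and the strongest hotspot has
#' `RI = 1`) with a one-sided rank-sum test of
#' `RI(overlapping) > RI(non-overlapping)`. The choice of the rank-sum test
#' for this comparison is this package's and is recorded in the output.
#'
#' @param hotspots An [interval_track()] with intensity `hits`.
#' @param breakpoints Breakpoint region tibble (`chrom`, `start`, `end`).
#' @param paddings Paddings (bp) applied to the breakpoint regions; default
#'   `c(0, 500, 1000, 2000, 5000)`.
#' @return A tibble with one row per padding: `padding`, `n_overlap`,
#'   `n_nonoverlap`, `mean_ri_overlap`, `mean_ri_nonoverlap`, `statistic`,
#'   `p_value`, `test`, plus list-columns `ri_overlap`, `ri_nonoverlap`.
#'   `p_value` is `NA` (with a warning) when either partition is empty.
#' @export
relative_intensity_compare <- function(hotspots, breakpoints,
                                       paddings = c(0, 500, 1000, 2000, 5000)) {
  if (!"hits" %in% names(hotspots) || anyNA(hotspots$hits)) {
    stop("hotspots must carry an intensity 'hits' column", call. = FALSE)
  }
  ri <- hotspots$hits / max(hotspots$hits)
  rows <- lapply(paddings, function(pad) {
    bp <- breakpoints
    bp$start <- pmax(1, bp$start - pad)
    bp$end <- bp$end + pad
    mb <- merged_by_chrom(bp)
    over <- rep(FALSE, nrow(hotspots))
    for (ch in unique(hotspots$chrom)) {
      i <- which(hotspots$chrom == ch)
      m <- mb[[ch]]
      if (is.null(m)) next
      over[i] <- overlaps_any(hotspots$start[i], hotspots$end[i],
                              m$start, m$end)
    }
    x <- ri[over]; y <- ri[!over]
    if (length(x) == 0 || length(y) == 0) {
      warning("padding ", pad, ": empty hotspot partition, p = NA",
              call. = FALSE)
      stat <- NA_real_; p <- NA_real_
    } else if (length(unique(c(x, y))) == 1) {
      stat <- NA_real_; p <- 1
    } else {
      ht <- stats::wilcox.test(x, y, alternative = "greater",
                               exact = FALSE, correct = TRUE)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    tibble::tibble(padding = pad, n_overlap = length(x),
                   n_nonoverlap = length(y),
                   mean_ri_overlap = if (length(x)) mean(x) else NA_real_,
                   mean_ri_nonoverlap = if (length(y)) mean(y) else NA_real_,
                   statistic = stat, p_value = p,
                   test = "one-sided Wilcoxon rank-sum",
                   ri_overlap = list(x), ri_nonoverlap = list(y))
  })
  dplyr::bind_rows(rows)
}
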