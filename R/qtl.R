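#' Normalised log2 doubling time
#'
#' `D_r = log2(D) - log2(D_control_local)`: the doubling time of a clone
#' relative to its spatially local control, in doublings (log2 units).
#' Positive values mean slower growth than the control.
#'
#' @param d,d_control Doubling times (> 0), vectorised.
#' @return Numeric vector of `D_r` values.
#' @examples
#' normalize_growth(2, 1)  # 1: twice the control's doubling time
#' @export
normalize_growth <- function(d, d_control) {
  if (any(d <= 0) || any(d_control <= 0)) {
    stop("doubling times must be positive", call. = FALSE)
  }
  log2(d) - log2(d_control)
}

#' Qualitative growth classification
#'
#' Classifies `D_r` (normalised to the ancestral hybrid) into five classes:
#' `highly_inferior` when `D_r >= 1`, `inferior` when `0.25 <= D_r < 1`,
#' `superior` when `-1 < D_r <= -0.25`, `highly_superior` when `D_r <= -1`
#' and `neutral` when `|D_r| < 0.25`. Boundary conventions: the inner
#' boundaries (0.25 and -0.25) belong to the inferior/superior classes, the
#' outer boundaries (1 and -1) to the highly-inferior/highly-superior
#' classes. Every finite value maps to exactly one label.
#'
#' @param d_r Numeric vector of `D_r` values (relative to the ancestral
#'   hybrid).
#' @return Character vector of labels.
#' @examples
#' classify_growth(c(0.5, 1.2, 0, -0.3, -2))
#' @export
classify_growth <- function(d_r) {
  if (any(!is.finite(d_r))) stop("D_r must be finite", call. = FALSE)
  dplyr::case_when(
    d_r >= 1 ~ "highly_inferior",
    d_r >= 0.25 ~ "inferior",
    d_r <= -1 ~ "highly_superior",
    d_r <= -0.25 ~ "superior",
    TRUE ~ "neutral"
  )
}

#' Best-/worse-parent heterosis call
#'
#' A clone shows worse-parent heterosis when its growth is significantly
#' worse than both parents, and best-parent heterosis when significantly
#' better than both (one-sided Welch t-tests on replicate `D_r` values at
#' level `alpha`; larger `D_r` = slower growth = worse). Missing parent data
#' makes the call `not_evaluable`.
#'
#' @param clone,parent1,parent2 Numeric vectors of replicate `D_r` values.
#' @param alpha Significance level per parent comparison.
#' @return One of `"worse_parent"`, `"best_parent"`, `"none"`,
#'   `"not_evaluable"`.
#' @export
heterosis <- function(clone, parent1, parent2, alpha = 0.05) {
  if (is.null(parent1) || is.null(parent2) ||
      all(is.na(parent1)) || all(is.na(parent2))) {
    return("not_evaluable")
  }
  clone <- clone[is.finite(clone)]
  parent1 <- parent1[is.finite(parent1)]
  parent2 <- parent2[is.finite(parent2)]
  if (length(clone) < 2 || length(parent1) < 2 || length(parent2) < 2) {
    return("not_evaluable")
  }
  p_worse <- c(stats::t.test(clone, parent1, alternative = "greater")$p.value,
               stats::t.test(clone, parent2, alternative = "greater")$p.value)
  if (all(p_worse < alpha)) return("worse_parent")
  p_best <- c(stats::t.test(clone, parent1, alternative = "less")$p.value,
              stats::t.test(clone, parent2, alternative = "less")$p.value)
  if (all(p_best < alpha)) return("best_parent")
  "none"
}

#' Encode genotype calls as a clones-by-markers matrix
#'
#' Additive coding: `HET = 0`, `HOM_P1 = +1`, `HOM_P2 = -1`, `MISSING = NA`.
#' Marker columns are named `chrom:pos` and ordered by position; the marker
#' metadata travels in the `"markers"` attribute.
#'
#' @param genotypes Long genotype tibble (`clone`, `chrom`, `pos`,
#'   `genotype`).
#' @return Numeric matrix (clones x markers) with attribute `markers`
#'   (a tibble `marker`, `chrom`, `pos`).
#' @export
encode_genotypes <- function(genotypes) {
  g <- dplyr::arrange(tibble::as_tibble(genotypes), .data$chrom, .data$pos)
  g$marker <- paste0(g$chrom, ":", format(g$pos, scientific = FALSE,
                                          trim = TRUE))
  code <- c(HET = 0, HOM_P1 = 1, HOM_P2 = -1, MISSING = NA_real_)
  g$code <- unname(code[g$genotype])
  wide <- tidyr::pivot_wider(g[, c("clone", "marker", "code")],
                             names_from = "marker", values_from = "code")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$clone
  info <- dplyr::distinct(g[, c("marker", "chrom", "pos")])
  info <- info[match(colnames(mat), info$marker), ]
  attr(mat, "markers") <- tibble::as_tibble(info)
  mat
}

#' Filter markers for QTL mapping
#'
#' Removes markers with no assigned genotype in any clone and markers
#' homozygous in fewer than two clones (a marker homozygous in a single
#' sample carries no mappable signal; an all-heterozygous marker none at
#' all). The removal log is attached as attribute `"removed"`.
#'
#' @param geno Coded genotype matrix from [encode_genotypes()].
#' @return The filtered matrix (markers attribute subset accordingly).
#' @export
filter_markers <- function(geno) {
  if (nrow(geno) < 2) stop("need >= 2 clones", call. = FALSE)
  n_called <- colSums(!is.na(geno))
  n_hom <- colSums(geno != 0, na.rm = TRUE)
  reason <- rep(NA_character_, ncol(geno))
  reason[n_called == 0] <- "no_genotype"
  reason[is.na(reason) & n_hom < 2] <- "homozygous_in_fewer_than_2"
  keep <- is.na(reason)
  if (!any(keep)) stop("no markers survive filtering", call. = FALSE)
  removed <- tibble::tibble(marker = colnames(geno)[!keep],
                            reason = reason[!keep])
  out <- geno[, keep, drop = FALSE]
  info <- attr(geno, "markers")
  if (!is.null(info)) attr(out, "markers") <- info[keep, ]
  attr(out, "removed") <- removed
  out
}

#' Single-marker LOD scan
#'
#' Regresses the phenotype on each marker genotype and reports
#' `LOD = (n/2) * log10(RSS0 / RSS1)`, where `RSS0` is the residual sum of
#' squares of the intercept-only model and `RSS1` that of the one-marker
#' model, over the clones with both a phenotype and a genotype at that
#' marker. The additive model uses the -1/0/+1 coding directly; the factor
#' model fits a genotype-class mean per level (2 df when all three classes
#' occur). Markers with zero genotype variance get `LOD = 0`.
#'
#' @param geno Coded genotype matrix (clones x markers), e.g. from
#'   [encode_genotypes()] / [filter_markers()].
#' @param phenotype Tibble (`clone`, `phenotype`) or named numeric vector;
#'   clones with missing phenotype are dropped.
#' @param model `"additive"` (default) or `"factor"`.
#' @return A tibble: `marker`, `chrom`, `pos` (when marker metadata is
#'   available), `lod`, `n`.
#' @export
lod_scan <- function(geno, phenotype, model = c("additive", "factor")) {
  model <- match.arg(model)
  y <- phenotype_vector(phenotype, rownames(geno))
  ok <- is.finite(y)
  if (sum(ok) < 8) stop("need >= 8 clones with phenotype", call. = FALSE)
  G <- geno[ok, , drop = FALSE]
  y <- y[ok]
  fit <- if (model == "additive") lod_additive(y, G) else lod_factor(y, G)
  info <- attr(geno, "markers")
  out <- tibble::tibble(marker = colnames(geno), lod = fit$lod, n = fit$n)
  if (!is.null(info)) {
    out$chrom <- info$chrom
    out$pos <- info$pos
    out <- out[, c("marker", "chrom", "pos", "lod", "n")]
  }
  out
}

phenotype_vector <- function(phenotype, clones) {
  if (is.data.frame(phenotype)) {
    y <- stats::setNames(phenotype$phenotype, phenotype$clone)[clones]
  } else {
    y <- phenotype[clones]
  }
  if (length(y) != length(clones)) {
    stop("phenotype does not cover the genotyped clones", call. = FALSE)
  }
  unname(y)
}

lod_additive <- function(y, G) {
  M <- ncol(G)
  lod <- numeric(M); nn <- integer(M)
  has_na <- colSums(is.na(G)) > 0
  if (any(!has_na)) {
    j <- which(!has_na)
    n <- length(y)
    yc <- y - mean(y)
    rss0 <- sum(yc^2)
    Gc <- sweep(G[, j, drop = FALSE], 2, colMeans(G[, j, drop = FALSE]))
    sxx <- colSums(Gc^2)
    sxy <- as.numeric(crossprod(Gc, yc))
    rss1 <- rss0 - ifelse(sxx > 0, sxy^2 / sxx, 0)
    lod[j] <- ifelse(sxx > 0 & rss1 > 0 & rss0 > 0,
                     (n / 2) * log10(rss0 / rss1), 0)
    lod[j][sxx == 0] <- 0
    nn[j] <- n
  }
  for (j in which(has_na)) {
    g <- G[, j]
    ok <- !is.na(g)
    n <- sum(ok)
    nn[j] <- n
    if (n < 3 || stats::var(g[ok]) == 0) { lod[j] <- 0; next }
    yy <- y[ok]; gg <- g[ok]
    rss0 <- sum((yy - mean(yy))^2)
    gc <- gg - mean(gg)
    sxy <- sum(gc * (yy - mean(yy)))
    rss1 <- rss0 - sxy^2 / sum(gc^2)
    lod[j] <- if (rss1 > 0 && rss0 > 0) (n / 2) * log10(rss0 / rss1) else 0
  }
  list(lod = pmax(lod, 0), n = nn)
}

lod_factor <- function(y, G) {
  M <- ncol(G)
  lod <- numeric(M); nn <- integer(M)
  for (j in seq_len(M)) {
    g <- G[, j]
    ok <- !is.na(g)
    n <- sum(ok)
    nn[j] <- n
    yy <- y[ok]; gg <- factor(g[ok])
    if (n < 3 || nlevels(gg) < 2) { lod[j] <- 0; next }
    rss0 <- sum((yy - mean(yy))^2)
    mu <- tapply(yy, gg, mean)
    rss1 <- sum((yy - mu[gg])^2)
    lod[j] <- if (rss1 > 0 && rss0 > 0) (n / 2) * log10(rss0 / rss1) else 0
  }
  list(lod = pmax(lod, 0), n = nn)
}

#' Genome-wide LOD significance threshold by permutation
#'
#' Permutes the phenotype rows against the genotype rows `n_perm` times,
#' records the genome-wide maximum LOD of each permutation, and returns the
#' `quantile` order statistic (type-1 quantile, so the default 0.95 with
#' 1000 permutations is the 950th sorted maximum). The permuted maxima are
#' attached as attribute `"maxima"`.
#'
#' @inheritParams lod_scan
#' @param n_perm Number of permutations (>= 100).
#' @param quantile Quantile of the null maxima used as threshold.
#' @param seed Optional seed.
#' @return The threshold (scalar) with attribute `maxima`.
#' @export
permutation_threshold <- function(geno, phenotype, n_perm = 1000,
                                  quantile = 0.95, seed = NULL,
                                  model = c("additive", "factor")) {
  model <- match.arg(model)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- phenotype_vector(phenotype, rownames(geno))
  ok <- is.finite(y)
  G <- geno[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  no_na <- !anyNA(G)
  if (model == "additive" && no_na) {
    # all permutations in one BLAS call
    P <- replicate(n_perm, sample.int(n))
    Y <- matrix(y[P], nrow = n)
    Yc <- sweep(Y, 2, colMeans(Y))
    rss0 <- colSums(Yc^2)
    Gc <- sweep(G, 2, colMeans(G))
    sxx <- colSums(Gc^2)
    sxy <- crossprod(Gc, Yc)                      # M x n_perm
    keep <- sxx > 0
    rss1 <- matrix(rep(rss0, each = sum(keep)), nrow = sum(keep)) -
      sxy[keep, , drop = FALSE]^2 / sxx[keep]
    lodm <- (n / 2) * log10(pmax(
      sweep(1 / rss1, 2, rss0, `*`), 1))
    maxima <- apply(lodm, 2, max)
  } else {
    maxima <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      fit <- if (model == "additive") lod_additive(yp, G) else lod_factor(yp, G)
      max(fit$lod)
    }, 0)
  }
  thr <- sort(maxima)[ceiling(quantile * n_perm)]
  attr(thr, "maxima") <- maxima
  thr
}

#' LOD-drop support interval for a QTL peak
#'
#' The support interval is the widest contiguous run of markers around the
#' peak whose LOD stays within `drop` units of the peak LOD, expanded to the
#' flanking markers just outside the run; at a chromosome edge the interval
#' is one-sided and flagged.
#'
#' @param scan LOD scan tibble for one environment (from [lod_scan()], with
#'   `chrom` and `pos`).
#' @param peak_marker Marker id of the peak; default: the genome-wide
#'   maximum.
#' @param drop LOD-drop (default 1.5).
#' @return One-row tibble: `chrom`, `peak_marker`, `peak_pos`, `peak_lod`,
#'   `ci_lo`, `ci_hi` (bp), `at_edge`.
#' @export
qtl_interval <- function(scan, peak_marker = NULL, drop = 1.5) {
  if (is.null(peak_marker)) peak_marker <- scan$marker[which.max(scan$lod)]
  pk <- which(scan$marker == peak_marker)
  if (length(pk) != 1) stop("peak marker not found in scan", call. = FALSE)
  ch <- scan$chrom[pk]
  s <- scan[scan$chrom == ch, ]
  s <- s[order(s$pos), ]
  i <- which(s$marker == peak_marker)
  lim <- s$lod[i] - drop
  lo <- i
  while (lo > 1 && s$lod[lo - 1] >= lim) lo <- lo - 1
  hi <- i
  while (hi < nrow(s) && s$lod[hi + 1] >= lim) hi <- hi + 1
  at_edge <- (lo == 1) || (hi == nrow(s))
  ci_lo <- if (lo > 1) s$pos[lo - 1] else s$pos[lo]
  ci_hi <- if (hi < nrow(s)) s$pos[hi + 1] else s$pos[hi]
  tibble::tibble(chrom = ch, peak_marker = peak_marker, peak_pos = s$pos[i],
                 peak_lod = s$lod[i], ci_lo = ci_lo, ci_hi = ci_hi,
                 at_edge = at_edge)
}

#' Map QTLs in one environment
#'
#' Full single-environment pipeline: marker filtering, LOD scan,
#' permutation threshold, and one peak with LOD-drop interval per
#' chromosome whose maximum exceeds the threshold.
#'
#' @inheritParams lod_scan
#' @inheritParams permutation_threshold
#' @param drop LOD-drop for the support intervals.
#' @param environment Label stored in the result.
#' @return An object of class `qtl_scan`: list with `scan` (per-marker LOD),
#'   `threshold`, `peaks` (tibble of significant peaks with intervals),
#'   `model`, `environment`, `removed` (marker filter log).
#' @export
map_qtl <- function(geno, phenotype, n_perm = 1000, quantile = 0.95,
                    drop = 1.5, seed = NULL,
                    model = c("additive", "factor"), environment = "env") {
  model <- match.arg(model)
  geno <- filter_markers(geno)
  scan <- lod_scan(geno, phenotype, model = model)
  thr <- permutation_threshold(geno, phenotype, n_perm = n_perm,
                               quantile = quantile, seed = seed,
                               model = model)
  peaks <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, ]
    if (max(s$lod) > thr) {
      peaks[[ch]] <- qtl_interval(scan, s$marker[which.max(s$lod)],
                                  drop = drop)
    }
  }
  peaks <- if (length(peaks) > 0) dplyr::bind_rows(peaks) else
    tibble::tibble(chrom = character(), peak_marker = character(),
                   peak_pos = numeric(), peak_lod = numeric(),
                   ci_lo = numeric(), ci_hi = numeric(), at_edge = logical())
  structure(list(scan = scan, threshold = as.numeric(thr),
                 maxima = attr(thr, "maxima"), peaks = peaks, model = model,
                 environment = environment,
                 removed = attr(geno, "removed")),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("QTL scan (", x$model, " model), environment: ", x$environment, "\n",
      sep = "")
  cat(sprintf("  %d markers scanned; genome-wide threshold %.3f (LOD)\n",
              nrow(x$scan), x$threshold))
  cat(sprintf("  %d significant peak(s)\n", nrow(x$peaks)))
  if (nrow(x$peaks) > 0) print(x$peaks)
  invisible(x)
}
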