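#' LOH rate from colony-forming-unit counts
#'
#' The URA3-loss assay plates the same culture on counter-selective 5-FOA
#' (only cells that lost URA3, here through LOH, form colonies) and on
#' permissive YPD. The LOH rate at a timepoint is the percentage of plated
#' cells that lost the marker:
#' `R_T = 100 * CFU_5FOA / CFU_YPD`.
#' The rate is invariant under common rescaling of both counts (dilution
#' factors cancel).
#'
#' @param cfu Tibble with columns `cfu_5foa` and `cfu_ypd` (CFU/mL), plus
#'   any identifier columns (`strain`, `timepoint`, `replicate`, ...).
#' @return `cfu` with a `rate` column (% of plated cells).
#' @examples
#' loh_rate(data.frame(cfu_5foa = 10, cfu_ypd = 1000))$rate  # 1
#' @export
loh_rate <- function(cfu) {
  need <- c("cfu_5foa", "cfu_ypd")
  if (!all(need %in% names(cfu))) {
    stop("cfu table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(cfu$cfu_5foa < 0) || any(cfu$cfu_ypd < 0)) {
    stop("negative CFU counts", call. = FALSE)
  }
  if (any(cfu$cfu_ypd == 0)) {
    stop("CFU_YPD = 0: rate undefined", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(cfu),
                rate = 100 * .data$cfu_5foa / .data$cfu_ypd)
}

#' LOH ratio and LOH difference metrics
#'
#' Summarises replicate LOH rates per strain into the two RTG-efficiency
#' metrics: the LOH ratio `R_T6 / R_T0` and the LOH difference
#' `R_T6 - R_T0`, both computed on replicate means, plus the natural log of
#' the ratio (so `ln_loh_ratio = ln(mean R_T6) - ln(mean R_T0)` exactly).
#' The T6-vs-T0 increase is tested one-sided: a Welch t-test on
#' log-transformed replicate rates (the log stabilises the multiplicative
#' replicate CV), falling back to the Wilcoxon rank-sum test whenever a zero
#' rate makes the log undefined; `paired = TRUE` pairs replicates by their
#' `replicate` index instead. Strains whose mean difference is negative are
#' flagged `negative_difference`; a strain with all-zero T0 rates gets
#' `ratio = NA` (flag `zero_t0`) while the difference is still reported.
#'
#' @param rates Tibble with columns `strain`, `timepoint` (`"T0"`, `"T6"`,
#'   optionally later timepoints, which are ignored here), `replicate`,
#'   `rate` (e.g. from [loh_rate()]).
#' @param paired Pair replicates across timepoints by `replicate` index?
#' @return A tibble with one row per strain: replicate counts, mean and SD
#'   rates at T0/T6, `loh_ratio`, `loh_difference`, `ln_loh_ratio`, the test
#'   used, its one-sided `p_value`, and a `flag`.
#' @export
loh_metrics <- function(rates, paired = FALSE) {
  need <- c("strain", "timepoint", "replicate", "rate")
  if (!all(need %in% names(rates))) {
    stop("rates table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(split(rates, rates$strain), function(df) {
    t0 <- df[df$timepoint == "T0", ]
    t6 <- df[df$timepoint == "T6", ]
    if (nrow(t0) == 0 || nrow(t6) == 0) {
      stop("strain ", df$strain[1], ": need rates at both T0 and T6",
           call. = FALSE)
    }
    if (paired) {
      t0 <- t0[order(t0$replicate), ]
      t6 <- t6[order(t6$replicate), ]
      if (!identical(t0$replicate, t6$replicate)) {
        stop("strain ", df$strain[1], ": replicates do not pair", call. = FALSE)
      }
    }
    r0 <- mean(t0$rate); r6 <- mean(t6$rate)
    ratio <- if (r0 > 0) r6 / r0 else NA_real_
    diff <- r6 - r0
    any_zero <- any(c(t0$rate, t6$rate) == 0)
    one_rep <- nrow(t0) < 2 || nrow(t6) < 2
    if (one_rep) {
      test <- "none"; p <- NA_real_
    } else if (any_zero) {
      test <- if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum"
      p <- if (paired) {
        stats::wilcox.test(t6$rate, t0$rate, paired = TRUE,
                           alternative = "greater", exact = FALSE)$p.value
      } else {
        stats::wilcox.test(t6$rate, t0$rate, alternative = "greater",
                           exact = FALSE, correct = TRUE)$p.value
      }
    } else {
      test <- if (paired) "paired t (log rates)" else "welch t (log rates)"
      p <- tryCatch(
        stats::t.test(log(t6$rate), log(t0$rate), paired = paired,
                      alternative = "greater")$p.value,
        error = function(e) NA_real_)
      if (is.na(p)) {  # zero-variance replicates: the t statistic degenerates
        test <- if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum"
        p <- suppressWarnings(
          stats::wilcox.test(t6$rate, t0$rate, paired = paired,
                             alternative = "greater", exact = FALSE,
                             correct = TRUE)$p.value)
        if (is.na(p)) p <- 1  # all values tied across both timepoints
      }
    }
    flag <- if (r0 == 0) "zero_t0"
            else if (diff < 0) "negative_difference"
            else "ok"
    tibble::tibble(strain = df$strain[1],
                   n_t0 = nrow(t0), n_t6 = nrow(t6),
                   r_t0 = r0, r_t6 = r6,
                   sd_t0 = stats::sd(t0$rate), sd_t6 = stats::sd(t6$rate),
                   loh_ratio = ratio, loh_difference = diff,
                   ln_loh_ratio = if (is.na(ratio) || ratio <= 0) NA_real_
                                  else log(ratio),
                   test = test, p_value = p, flag = flag)
  })
  dplyr::bind_rows(rows)
}

#' Correlation between meiotic progression and RTG LOH induction
#'
#' Pearson correlation (two-sided) between the fraction of cells past the
#' meiotic divisions (MI + MII at 12 h) and the LOH induction metrics.
#' Strains with a negative LOH difference (no detectable induction) are
#' excluded first to avoid biasing the correlation; the difference is
#' correlated on a log10 scale (which additionally drops zero differences),
#' the log-ratio as is.
#'
#' @param records Tibble with columns `strain`, `progression` (% of cells,
#'   0-100), `loh_difference`, `ln_loh_ratio`.
#' @return A tibble with one row per metric (`log10_loh_difference`,
#'   `ln_loh_ratio`): `r`, `p_value`, `n`.
#' @export
progression_correlation <- function(records) {
  need <- c("strain", "progression", "loh_difference", "ln_loh_ratio")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(records$progression < 0 | records$progression > 100)) {
    stop("progression must be in [0, 100]", call. = FALSE)
  }
  keep <- records[records$loh_difference >= 0, ]
  one <- function(x, y, label) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      stop("fewer than 3 usable records for ", label, call. = FALSE)
    }
    ct <- stats::cor.test(x[ok], y[ok], alternative = "two.sided")
    tibble::tibble(metric = label, r = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
  }
  dplyr::bind_rows(
    one(keep$progression, log10(keep$loh_difference), "log10_loh_difference"),
    one(keep$progression, keep$ln_loh_ratio, "ln_loh_ratio")
  )
}
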