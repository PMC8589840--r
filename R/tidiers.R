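#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a permutation overlap test
#'
#' @param x A `perm_overlap_test`.
#' @param ... Unused.
#' @return A one-row tibble: `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_value`, `ntimes`, `alternative`, `degenerate`.
#' @method tidy perm_overlap_test
#' @export
tidy.perm_overlap_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = x$null_mean,
                 null_sd = x$null_sd, z = x$z, p_value = x$p_value,
                 ntimes = x$ntimes, alternative = x$alternative,
                 degenerate = x$degenerate)
}

#' @rdname tidy.perm_overlap_test
#' @method glance perm_overlap_test
#' @export
glance.perm_overlap_test <- function(x, ...) tidy.perm_overlap_test(x, ...)

#' Tidy a QTL scan
#'
#' `tidy()` returns the per-marker LOD curve, `glance()` a one-row summary.
#'
#' @param x A `qtl_scan` from [map_qtl()].
#' @param ... Unused.
#' @method tidy qtl_scan
#' @export
tidy.qtl_scan <- function(x, ...) x$scan

#' @rdname tidy.qtl_scan
#' @method glance qtl_scan
#' @export
glance.qtl_scan <- function(x, ...) {
  tibble::tibble(environment = x$environment, model = x$model,
                 n_markers = nrow(x$scan), threshold = x$threshold,
                 max_lod = max(x$scan$lod), n_peaks = nrow(x$peaks))
}
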