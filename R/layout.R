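#' Construct a genome layout
#'
#' A genome layout describes the chromosome scaffold everything else is
#' anchored to: chromosome lengths, centromere intervals and the subtelomeric
#' mask applied at each chromosome end. All coordinates in the package are
#' 1-based and inclusive.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Chromosome lengths in bp.
#' @param cen_start,cen_end Centromere interval (bp, inclusive), one per
#'   chromosome, inside `[1, length]`.
#' @param mask_left,mask_right Length (bp) of the subtelomeric mask at the
#'   left/right chromosome end. Markers falling inside a mask are excluded
#'   from LOH calling and from terminal-extent determination. Defaults to
#'   20 kb per end.
#'
#' @return A tibble of class `genome_layout` with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`, `mask_left`, `mask_right`.
#' @examples
#' genome_layout("chrI", 2e5, 9e4, 9.2e4)
#' @export
genome_layout <- function(chrom, length, cen_start, cen_end,
                          mask_left = 20000, mask_right = 20000) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    length = as.numeric(length),
    cen_start = as.numeric(cen_start),
    cen_end = as.numeric(cen_end),
    mask_left = as.numeric(rep_len(mask_left, base::length(chrom))),
    mask_right = as.numeric(rep_len(mask_right, base::length(chrom)))
  )
  validate_genome_layout(out)
}

validate_genome_layout <- function(x) {
  if (anyDuplicated(x$chrom)) {
    stop("duplicate chromosome names in genome layout", call. = FALSE)
  }
  if (any(x$length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  bad <- x$cen_start < 1 | x$cen_end > x$length | x$cen_start > x$cen_end
  if (any(bad)) {
    stop("centromere interval outside [1, length] for: ",
         paste(x$chrom[bad], collapse = ", "), call. = FALSE)
  }
  if (any(x$mask_left < 0) || any(x$mask_right < 0)) {
    stop("mask lengths must be >= 0", call. = FALSE)
  }
  if (any(x$mask_left + x$mask_right >= x$length)) {
    stop("left + right masks must be shorter than the chromosome", call. = FALSE)
  }
  class(x) <- c("genome_layout", class(tibble::tibble()))
  x
}

#' Read / write a genome layout TSV
#'
#' The on-disk format is a TSV with header columns `chrom`, `length`,
#' `cen_start`, `cen_end` and optional `mask_left`, `mask_right`
#' (default 20 kb when absent).
#'
#' @param path File path.
#' @return `read_genome_layout()` returns a validated [genome_layout()];
#'   `write_genome_layout()` invisibly returns `x`.
#' @export
read_genome_layout <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(df))) {
    stop("layout file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  genome_layout(
    chrom = df$chrom, length = df$length,
    cen_start = df$cen_start, cen_end = df$cen_end,
    mask_left = if ("mask_left" %in% names(df)) df$mask_left else 20000,
    mask_right = if ("mask_right" %in% names(df)) df$mask_right else 20000
  )
}

#' @rdname read_genome_layout
#' @param x A `genome_layout`.
#' @export
write_genome_layout <- function(x, path) {
  readr::write_tsv(dplyr::arrange(tibble::as_tibble(x), .data$chrom), path)
  invisible(x)
}

#' Toy multi-chromosome layout for simulations and examples
#'
#' Builds a compact yeast-like genome: `n_chrom` chromosomes of equal
#' `chrom_length` with a centromere at the midpoint and the default
#' subtelomeric masks.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param cen_width Width of the centromere interval (bp).
#' @inheritParams genome_layout
#' @return A [genome_layout()].
#' @examples
#' toy_layout(4, 5e5)
#' @export
toy_layout <- function(n_chrom = 8, chrom_length = 750000, cen_width = 2000,
                       mask_left = 20000, mask_right = 20000) {
  mid <- floor(chrom_length / 2)
  genome_layout(
    chrom = sprintf("chr%02d", seq_len(n_chrom)),
    length = rep(chrom_length, n_chrom),
    cen_start = rep(mid - floor(cen_width / 2), n_chrom),
    cen_end = rep(mid + ceiling(cen_width / 2), n_chrom),
    mask_left = mask_left, mask_right = mask_right
  )
}

layout_row <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("chromosome not in layout: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}
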