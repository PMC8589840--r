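#' Construct a marker map
#'
#' A marker map is the ordered set of biallelic positions distinguishing the
#' two parental subgenomes of a hybrid. Every marker is heterozygous in the
#' ancestral hybrid, so a homozygous call at a marker is evidence of LOH.
#'
#' @param df Data frame with columns `chrom`, `pos`, `allele1`, `allele2`
#'   and optionally `masked` (logical; default `FALSE`).
#' @return A tibble of class `marker_map`, sorted by `(chrom, pos)`.
#' @examples
#' marker_map(data.frame(chrom = "chrI", pos = c(100, 500),
#'                       allele1 = c("A", "G"), allele2 = c("T", "C")))
#' @export
marker_map <- function(df) {
  need <- c("chrom", "pos", "allele1", "allele2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("marker map needs columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)[, c(need, intersect("masked", names(df)))]
  if (!"masked" %in% names(out)) out$masked <- FALSE
  out$chrom <- as.character(out$chrom)
  out$pos <- as.numeric(out$pos)
  if (nrow(out) == 0) {
    warning("empty marker map", call. = FALSE)
  } else {
    out <- dplyr::arrange(out, .data$chrom, .data$pos)
    dup <- duplicated(out[, c("chrom", "pos")])
    if (any(dup)) {
      i <- which(dup)[1]
      stop(sprintf("duplicate marker position at %s:%s (row %d)",
                   out$chrom[i], format(out$pos[i], scientific = FALSE), i),
           call. = FALSE)
    }
    mono <- out$allele1 == out$allele2
    if (any(mono)) {
      i <- which(mono)[1]
      stop(sprintf("non-biallelic marker (allele1 == allele2) at %s:%s (row %d)",
                   out$chrom[i], format(out$pos[i], scientific = FALSE), i),
           call. = FALSE)
    }
  }
  class(out) <- c("marker_map", class(tibble::tibble()))
  out
}

#' Read / write a marker map TSV
#'
#' On-disk format: TSV with header `chrom`, `pos`, `allele1`, `allele2`
#' (optional `masked`). Rows are normalised to `(chrom, pos)` order;
#' duplicated positions and monoallelic rows are rejected with the offending
#' row named.
#'
#' @param path File path.
#' @return `read_marker_map()` returns a validated [marker_map()].
#' @export
read_marker_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(chrom = readr::col_character()))
  marker_map(df)
}

#' @rdname read_marker_map
#' @param x A `marker_map`.
#' @export
write_marker_map <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(x)
}

#' Flag markers inside the subtelomeric masks
#'
#' Markers within `mask_left` bp of the left end or `mask_right` bp of the
#' right end of their chromosome are flagged `masked = TRUE`. Masked markers
#' are ignored by the LOH caller and never define the terminal extent of a
#' chromosome arm. The operation is idempotent and recomputes the flag from
#' scratch on every call.
#'
#' @param map A [marker_map()].
#' @param layout A [genome_layout()] covering every chromosome in `map`.
#' @return The map with its `masked` column set.
#' @export
apply_masks <- function(map, layout) {
  if (nrow(map) == 0) return(map)
  i <- layout_row(layout, map$chrom)
  left <- layout$mask_left[i]
  right <- layout$mask_right[i]
  len <- layout$length[i]
  map$masked <- map$pos <= left | map$pos > (len - right)
  map
}
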