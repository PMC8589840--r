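#' Read genomic intervals from a BED file
#'
#' BED records are half-open and 0-based on disk; internally the package
#' uses 1-based inclusive coordinates, so a BED line `chr 0 100` becomes the
#' interval `[1, 100]` (length is preserved: end - start on disk equals
#' end - start + 1 internally). When a score column is present it is parsed
#' as the intensity hit count `H` of a recombination hotspot; otherwise
#' `H = 1`.
#'
#' @param path BED file (3+ columns, no header).
#' @param score_column Index of the column holding `H` (conventionally 5);
#'   `NULL` to take all `H = 1`.
#' @return A tibble of class `interval_track` with columns `chrom`, `start`,
#'   `end` (1-based inclusive) and `hits`.
#' @export
read_intervals <- function(path, score_column = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(interval_track(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields",
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) {
    stop("malformed BED line ", which(bad)[1], ": non-numeric coordinates",
         call. = FALSE)
  }
  if (any(start0 < 0)) {
    stop("malformed BED line ", which(start0 < 0)[1], ": negative coordinate",
         call. = FALSE)
  }
  if (any(start0 >= end0)) {
    stop("malformed BED line ", which(start0 >= end0)[1], ": start >= end",
         call. = FALSE)
  }
  hits <- rep(1, length(lines))
  if (!is.null(score_column)) {
    has <- nf >= score_column
    hits[has] <- suppressWarnings(as.numeric(
      vapply(fields[has], `[[`, "", score_column)))
    if (anyNA(hits)) {
      stop("malformed BED line ", which(is.na(hits))[1],
           ": non-numeric score", call. = FALSE)
    }
  }
  interval_track(chrom, start0 + 1, end0, hits)
}

#' Construct an interval track (1-based inclusive coordinates)
#'
#' @param chrom,start,end Interval coordinates (1-based, inclusive).
#' @param hits Intensity hit count `H` per interval (default 1).
#' @return A tibble of class `interval_track`.
#' @export
interval_track <- function(chrom, start, end, hits = 1) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    hits = as.numeric(rep_len(hits, length(chrom)))
  )
  if (any(out$end < out$start)) stop("interval with end < start", call. = FALSE)
  if (any(out$start < 1)) stop("interval with start < 1", call. = FALSE)
  if (any(out$hits < 0)) stop("negative intensity hits", call. = FALSE)
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
  class(out) <- c("interval_track", class(tibble::tibble()))
  out
}

#' @rdname read_intervals
#' @param x An `interval_track`.
#' @param keep_score Write `hits` as BED columns 4 (name) and 5 (score)?
#' @export
write_intervals <- function(x, path, keep_score = TRUE) {
  df <- dplyr::arrange(tibble::as_tibble(x), .data$chrom, .data$start)
  out <- data.frame(chrom = df$chrom,
                    start = format(df$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE))
  if (keep_score && "hits" %in% names(df)) {
    out$name <- sprintf("iv%d", seq_len(nrow(df)))
    out$score <- df$hits
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

# ---- internal overlap machinery ------------------------------------------
# Intervals are flat vectors throughout; the permutation tests call these
# thousands of times per analysis.

# Merge possibly-overlapping sorted intervals on ONE chromosome into a
# disjoint increasing set. start/end are 1-based inclusive.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  n <- length(start)
  if (n <= 1) return(list(start = start, end = end))
  cmax <- cummax(end)
  new_run <- c(TRUE, start[-1] > cmax[-n] + 0)
  grp <- cumsum(new_run)
  list(start = as.numeric(tapply(start, grp, min)),
       end = as.numeric(tapply(end, grp, max)))
}

# For query intervals [qs, qe] and a merged disjoint interval set (ms, me)
# on the same chromosome, return logical: does each query hit >= 1 interval?
# Closed-interval overlap (>= 1 bp shared).
overlaps_any <- function(qs, qe, ms, me) {
  if (length(ms) == 0 || length(qs) == 0) return(rep(FALSE, length(qs)))
  idx <- findInterval(qe, ms)        # rightmost merged start <= qe
  hit <- idx >= 1
  hit[hit] <- me[idx[hit]] >= qs[hit]
  hit
}

# Split an interval tibble by chromosome into a named list of
# list(start=, end=) merged structures.
merged_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) merge_intervals(x$start[i], x$end[i]))
}

# Count how many intervals of `a` overlap >= 1 interval of `b`
# (both tibbles with chrom/start/end).
count_overlapping <- function(a, b) {
  mb <- merged_by_chrom(b)
  total <- 0L
  for (ch in unique(a$chrom)) {
    i <- which(a$chrom == ch)
    m <- mb[[ch]]
    if (is.null(m)) next
    total <- total + sum(overlaps_any(a$start[i], a$end[i], m$start, m$end))
  }
  total
}
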