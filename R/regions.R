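# All internal coordinates are 0-based half-open [start, end).
# 1-based conversion happens only at the VCF boundary.

#' Construct a genomic region
#'
#' Regions are 0-based, half-open intervals `[start, end)` on a named
#' chromosome -- the BED convention, used by every data structure in this
#' package.
#'
#' @param chrom Chromosome name, e.g. `"chr6"`.
#' @param start 0-based inclusive start position (bp).
#' @param end 0-based exclusive end position (bp); must exceed `start`.
#'
#' @return An object of class `GenomicRegion` (a named list with elements
#'   `chrom`, `start`, `end`).
#' @examples
#' genomic_region("chr6", 28.5e6, 33.5e6)
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing numbers")
  if (start < 0 || end <= start)
    stop("invalid region: need 0 <= start < end")
  structure(list(chrom = chrom, start = start, end = end),
            class = "GenomicRegion")
}

#' @export
print.GenomicRegion <- function(x, ...) {
  cat(sprintf("<GenomicRegion> %s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$end - x$start, big.mark = ",")))
  invisible(x)
}

#' Width of a genomic region in bp
#' @param region A `GenomicRegion`.
#' @return Numeric width `end - start`.
#' @export
region_width <- function(region) {
  stopifnot(inherits(region, "GenomicRegion"))
  region$end - region$start
}

region_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(NULL)
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  if (e <= s) return(NULL)
  genomic_region(a$chrom, s, e)
}

# ---- plain interval tables -------------------------------------------------
# Intervals within a single chromosome are data.frames with numeric columns
# `start`, `end` (0-based half-open). Used for no-call tracts and masks.

empty_intervals <- function() data.frame(start = numeric(0), end = numeric(0))

as_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(empty_intervals())
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  data.frame(start = as.numeric(x$start), end = as.numeric(x$end))
}

merge_intervals <- function(iv) {
  iv <- as_intervals(iv)
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]
  out_e <- iv$end[1]
  k <- 1L
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], iv$end[i])
      } else {
        k <- k + 1L
        out_s[k] <- iv$start[i]
        out_e[k] <- iv$end[i]
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}

intervals_width <- function(iv) {
  iv <- merge_intervals(iv)
  if (nrow(iv) == 0) return(0)
  sum(iv$end - iv$start)
}

clip_intervals <- function(iv, region) {
  iv <- as_intervals(iv)
  if (nrow(iv) == 0) return(iv)
  s <- pmax(iv$start, region$start)
  e <- pmin(iv$end, region$end)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

pos_in_intervals <- function(pos, iv) {
  iv <- as_intervals(iv)
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv)))
    out <- out | (pos >= iv$start[i] & pos < iv$end[i])
  out
}

# Intervals covered by >= min_cover of the interval sets in `ivs` (a list).
coverage_intervals <- function(ivs, min_cover = 2L) {
  ivs <- lapply(ivs, as_intervals)
  all <- do.call(rbind, ivs)
  if (is.null(all) || nrow(all) == 0) return(empty_intervals())
  # sweep line over endpoints
  ev <- rbind(data.frame(x = all$start, d = 1L),
              data.frame(x = all$end, d = -1L))
  ev <- stats::aggregate(d ~ x, data = ev, FUN = sum)
  ev <- ev[order(ev$x), ]
  depth <- cumsum(ev$d)
  on <- depth >= min_cover
  # segment [x_i, x_{i+1}) has depth depth[i]
  seg_s <- ev$x[-nrow(ev)]
  seg_e <- ev$x[-1]
  seg_on <- on[-length(on)]
  merge_intervals(data.frame(start = seg_s[seg_on], end = seg_e[seg_on]))
}
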