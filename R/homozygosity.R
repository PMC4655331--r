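# Window-based zygosity profiling, conserved-stretch calling, a
# runs-of-homozygosity scan, major-allele-frequency profiles and
# cross-platform genotype concordance.

call_classes <- function(calls) {
  is_nocall <- calls$confidence == "nocall"
  is_indel <- is_indel_token(calls$a1) | is_indel_token(calls$a2)
  is_variant <- !is_nocall & !(calls$a1 == calls$ref & calls$a2 == calls$ref)
  is_het <- !is_nocall & calls$a1 != calls$a2
  list(nocall = is_nocall, indel = is_indel, variant = is_variant,
       het = is_het)
}

#' Per-window zygosity profile
#'
#' Tiles the callset's region with fixed-width windows anchored at the
#' region start and counts homozygous and heterozygous variant calls per
#' window. Reference-matching calls are not counted. The zygosity ratio is
#' the fraction of variant calls in the window that are homozygous,
#' `n_hom / (n_hom + n_het)`, `NA` when the window holds no variant call.
#' By default only SNVs enter the ratio; `include_indels = TRUE` counts
#' indel calls as well.
#'
#' @param callset A [diploid_callset()].
#' @param window_size Window width in bp (default 5000).
#' @param include_indels Count indel calls in the hom/het tallies?
#' @return data.frame with one row per window: `chrom`, `start`, `end`,
#'   `n_hom`, `n_het`, `n_snv`, `n_indel`, `zygosity_ratio`. The final
#'   window may be partial.
#' @export
window_zygosity_profile <- function(callset, window_size = 5000,
                                    include_indels = FALSE) {
  stopifnot(inherits(callset, "DiploidCallset"), window_size > 0)
  region <- callset$region
  starts <- seq(region$start, region$end - 1, by = window_size)
  ends <- pmin(starts + window_size, region$end)
  calls <- callset$calls
  cl <- call_classes(calls)
  vr <- cl$variant
  widx <- floor((calls$pos - region$start) / window_size) + 1L
  tally <- function(mask) {
    v <- tabulate(widx[mask], nbins = length(starts))
    v
  }
  in_ratio <- vr & (include_indels | !cl$indel)
  n_hom <- tally(in_ratio & !cl$het)
  n_het <- tally(in_ratio & cl$het)
  n_snv <- tally(vr & !cl$indel)
  n_indel <- tally(vr & cl$indel)
  denom <- n_hom + n_het
  out <- data.frame(chrom = region$chrom, start = starts, end = ends,
                    n_hom = n_hom, n_het = n_het, n_snv = n_snv,
                    n_indel = n_indel,
                    zygosity_ratio = ifelse(denom > 0, n_hom / denom, NA))
  attr(out, "window_size") <- window_size
  out
}

#' Call conserved stretches of homozygosity from a window profile
#'
#' A window fails when its zygosity ratio is defined and below `ratio_min`;
#' windows without variant calls pass (absence of variants is evidence of
#' conservation). A conserved stretch is a maximal run of windows containing
#' no more than `max_fail_run` consecutive failing windows, trimmed so that
#' both boundaries are passing windows. Stretches shorter than `min_length`
#' bp are dropped.
#'
#' @param profiles Output of [window_zygosity_profile()] (contiguous,
#'   ordered windows).
#' @param ratio_min Zygosity-ratio threshold (default 0.95).
#' @param max_fail_run Longest tolerated run of failing windows (default 4).
#' @param min_length Minimum stretch length in bp (default 0).
#' @return data.frame with columns `chrom`, `start`, `end`, `n_windows`,
#'   `n_failing_windows`, `pct_homozygous` (variant-weighted homozygous
#'   fraction across the stretch, 1 when it holds no variants).
#' @export
call_conserved_stretches <- function(profiles, ratio_min = 0.95,
                                     max_fail_run = 4, min_length = 0) {
  stopifnot(is.data.frame(profiles),
            all(c("start", "end", "zygosity_ratio") %in% names(profiles)))
  n <- nrow(profiles)
  if (n == 0) return(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), n_windows = integer(0),
                                n_failing_windows = integer(0),
                                pct_homozygous = numeric(0)))
  if (n > 1 && any(profiles$start[-1] != profiles$end[-n]))
    stop("window profiles must be contiguous and ordered")
  fail <- !is.na(profiles$zygosity_ratio) &
    profiles$zygosity_ratio < ratio_min
  # failing runs longer than max_fail_run split the profile
  r <- rle(fail)
  stops <- r$values & r$lengths > max_fail_run
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  breaks <- cbind(run_start[stops], run_end[stops])
  bounds <- c(0L, as.vector(t(breaks)), n + 1L)
  out <- list()
  for (k in seq(1, length(bounds) - 1, by = 2)) {
    lo <- bounds[k] + 1L
    hi <- bounds[k + 1] - 1L
    if (lo > hi) next
    # trim to outermost passing windows
    while (lo <= hi && fail[lo]) lo <- lo + 1L
    while (hi >= lo && fail[hi]) hi <- hi - 1L
    if (lo > hi) next
    idx <- lo:hi
    s <- profiles$start[lo]
    e <- profiles$end[hi]
    if (e - s < min_length) next
    nh <- sum(profiles$n_hom[idx])
    nt <- nh + sum(profiles$n_het[idx])
    out[[length(out) + 1L]] <- data.frame(
      chrom = profiles$chrom[1], start = s, end = e,
      n_windows = length(idx), n_failing_windows = sum(fail[idx]),
      pct_homozygous = if (nt > 0) nh / nt else 1)
  }
  if (!length(out)) return(data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0),
                                      n_windows = integer(0),
                                      n_failing_windows = integer(0),
                                      pct_homozygous = numeric(0)))
  do.call(rbind, out)
}

#' Runs-of-homozygosity scan over a dense callset
#'
#' Reports maximal segments of consecutive sites in which every sliding
#' sub-window of `window` bp contains at most `max_het_per_window`
#' heterozygous calls and no gap between adjacent sites exceeds `max_gap`
#' bp. Segments shorter than `min_length` bp are dropped. The scan expects
#' dense, array-like callsets that include homozygous-reference sites.
#'
#' @param callset A [diploid_callset()].
#' @param window Sliding window width in bp (default 50 kb).
#' @param max_het_per_window Heterozygous calls allowed per window
#'   (default 3).
#' @param max_gap Maximum distance between adjacent considered sites
#'   (default 50 kb).
#' @param min_length Minimum reported segment length in bp (default 1 Mb).
#' @return data.frame of segments: `chrom`, `start`, `end`, `n_sites`,
#'   `n_het` (0-based half-open, spanning first to last site).
#' @export
roh_scan <- function(callset, window = 50000, max_het_per_window = 3,
                     max_gap = 50000, min_length = 1e6) {
  stopifnot(inherits(callset, "DiploidCallset"))
  calls <- callset$calls
  cl <- call_classes(calls)
  use <- !cl$nocall
  pos <- calls$pos[use]
  het <- cl$het[use]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_sites = integer(0),
                      n_het = integer(0))
  if (length(pos) == 0) return(empty)
  run_id <- cumsum(c(1, as.integer(diff(pos) > max_gap)))
  segs <- list()
  for (rid in unique(run_id)) {
    p <- pos[run_id == rid]
    hloc <- het[run_id == rid]
    h <- which(hloc)
    hp <- p[h]
    m <- length(p)
    k <- max_het_per_window
    # [i..j] valid iff no (k+1)-tuple of hets inside with bp span < window
    left <- 1L
    prev_left <- 1L
    maximal <- list()
    for (j in seq_len(m)) {
      if (hloc[j] && length(hp) > k) {
        # index of this het among hets of the run
        hj <- match(j, h)
        if (!is.na(hj) && hj > k) {
          first <- h[hj - k]      # earliest het of the (k+1)-tuple ending here
          if (p[j] - p[first] < window && first >= left)
            left <- first + 1L    # exclude it
        }
      }
      is_last <- j == m
      # segment [prev_left..j-1] was maximal if left advanced past prev_left
      if (left > prev_left && j > 1) {
        maximal[[length(maximal) + 1L]] <- c(prev_left, j - 1L)
        prev_left <- left
      }
      if (is_last)
        maximal[[length(maximal) + 1L]] <- c(left, m)
    }
    for (seg in maximal) {
      i <- seg[1]; j <- seg[2]
      if (j < i) next
      s <- p[i]; e <- p[j] + 1
      if (e - s < min_length) next
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = callset$region$chrom, start = s, end = e,
        n_sites = j - i + 1L,
        n_het = sum(hloc[i:j]))
    }
  }
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  # drop segments contained in another
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out)))
    for (j in seq_len(nrow(out)))
      if (i != j && out$start[j] <= out$start[i] && out$end[j] >= out$end[i] &&
          (out$start[j] < out$start[i] || out$end[j] > out$end[i]))
        keep[i] <- FALSE
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Per-site major-allele frequency profile of a haplotype panel
#'
#' @param haplotypes Matrix (chromosomes x sites) of allele symbols or 0/1
#'   codes; `NA` entries are ignored per site.
#' @return data.frame with one row per site: `site`, `major_allele`,
#'   `freq` (frequency of the most common allele) and `tie` (`TRUE` when
#'   two alleles tie for most common; biallelic ties report 0.5).
#' @export
major_allele_frequency_profile <- function(haplotypes) {
  if (is.null(dim(haplotypes)) || nrow(haplotypes) == 0)
    stop("haplotype matrix must have at least one row")
  out <- lapply(seq_len(ncol(haplotypes)), function(j) {
    x <- haplotypes[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(site = j, major_allele = NA, freq = NA, tie = NA))
    tab <- sort(table(x), decreasing = TRUE)
    tie <- length(tab) > 1 && tab[1] == tab[2]
    data.frame(site = j, major_allele = names(tab)[1],
               freq = as.numeric(tab[1]) / length(x), tie = tie)
  })
  do.call(rbind, out)
}

#' Genotype concordance between two callsets of the same sample
#'
#' Compares unordered allele pairs at positions called with high confidence
#' in both callsets; positions listed in neither are not compared.
#'
#' @param a,b [diploid_callset()] objects with the same `sample_id`.
#' @return List with `n_compared`, `n_concordant` and `rate`.
#' @export
genotype_concordance <- function(a, b) {
  stopifnot(inherits(a, "DiploidCallset"), inherits(b, "DiploidCallset"))
  if (a$sample_id != b$sample_id)
    stop("callsets are from different samples: ", a$sample_id, " vs ",
         b$sample_id)
  ca <- a$calls[a$calls$confidence == "high", ]
  cb <- b$calls[b$calls$confidence == "high", ]
  common <- intersect(ca$pos, cb$pos)
  ia <- match(common, ca$pos)
  ib <- match(common, cb$pos)
  pair <- function(x, i) paste(pmin(x$a1[i], x$a2[i]), pmax(x$a1[i], x$a2[i]))
  conc <- pair(ca, ia) == pair(cb, ib)
  list(n_compared = length(common), n_concordant = sum(conc),
       rate = if (length(common)) sum(conc) / length(common) else NA_real_)
}
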