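# Shared fixture builders and independent brute-force oracles.

# quick callset builder: pos/ref/a1/a2 vectors, defaults high-confidence
make_callset <- function(pos, ref, a1, a2, confidence = "high",
                         phased = FALSE, sample_id = "S1",
                         region = genomic_region("chr6", 0, 1e6),
                         nocall_regions = NULL) {
  n <- length(pos)
  diploid_callset(sample_id, region,
                  data.frame(pos = pos, ref = ref, a1 = a1, a2 = a2,
                             confidence = rep(confidence, length.out = n),
                             phased = rep(phased, length.out = n)),
                  nocall_regions = nocall_regions)
}

# hand-written 5-record VCF fixture (2 samples) used by the io tests
write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr6>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSA\tSB",
    "chr6\t101\trs1\tA\tG\t50\tPASS\t.\tGT\t0/1\t1|1",
    "chr6\t205\trs2\tC\tT\t50\tLowQual\t.\tGT\t0/0\t0/1",
    "chr6\t300\trs3\tG\tA\t50\tPASS\t.\tGT\t./.\t0/0",
    "chr6\t410\trs4\tAT\tA\t50\tPASS\t.\tGT\t1/1\t0/0",
    "chr6\t500\trs5\tT\tTGC\t50\tPASS\t.\tGT\t0|1\t0/0"),
    path)
  path
}

# brute-force ROH oracle: enumerate every site interval, keep valid and
# maximal segments (same rules as roh_scan)
roh_brute_force <- function(pos, het, window, max_het, max_gap,
                            min_length) {
  n <- length(pos)
  valid <- function(i, j) {
    if (j > i && any(diff(pos[i:j]) > max_gap)) return(FALSE)
    h <- pos[i:j][het[i:j]]
    if (length(h) > max_het) {
      for (m in seq_len(length(h) - max_het))
        if (h[m + max_het] - h[m] < window) return(FALSE)
    }
    TRUE
  }
  segs <- list()
  for (i in 1:n) for (j in i:n) {
    if (!valid(i, j)) next
    # maximal: cannot extend either direction
    if (i > 1 && valid(i - 1, j)) next
    if (j < n && valid(i, j + 1)) next
    if (pos[j] + 1 - pos[i] < min_length) next
    segs[[length(segs) + 1L]] <- c(start = pos[i], end = pos[j] + 1)
  }
  out <- unique(do.call(rbind, segs))
  if (is.null(out)) data.frame(start = numeric(0), end = numeric(0)) else
    as.data.frame(out[order(out[, 1]), , drop = FALSE])
}

# brute-force shared-segment oracle over all index intervals
shared_segment_brute_force <- function(match_ok, k) {
  n <- length(match_ok)
  bad <- function(i, j) sum(!match_ok[i:j]) > k
  segs <- list()
  for (i in 1:n) for (j in i:n) {
    if (bad(i, j)) next
    if (i > 1 && !bad(i - 1, j)) next
    if (j < n && !bad(i, j + 1)) next
    segs[[length(segs) + 1L]] <- c(i, j)
  }
  do.call(rbind, segs)
}

# brute-force LD-block oracle: greedy selection over exhaustively
# enumerated valid intervals (leftmost, then longest)
ld_blocks_brute_force <- function(haps, r2_min) {
  m <- ncol(haps)
  r2 <- suppressWarnings(r2_matrix(haps))
  ok <- function(i, j) {
    for (a in i:(j - 1)) for (b in (a + 1):j) {
      v <- r2[a, b]
      if (is.na(v) || v <= r2_min) return(FALSE)
    }
    TRUE
  }
  valid <- list()
  for (i in 1:(m - 1)) for (j in (i + 1):m)
    if (ok(i, j)) valid[[length(valid) + 1L]] <- c(i, j)
  chosen <- list()
  lo <- 1L
  while (length(valid)) {
    cand <- Filter(function(v) v[1] >= lo, valid)
    if (!length(cand)) break
    starts <- vapply(cand, `[`, 0L, 1)
    cand <- cand[starts == min(starts)]
    lens <- vapply(cand, function(v) v[2] - v[1], 0L)
    pick <- cand[[which.max(lens)]]
    chosen[[length(chosen) + 1L]] <- pick
    lo <- pick[2] + 1L
    valid <- Filter(function(v) v[1] >= lo, valid)
  }
  if (!length(chosen))
    return(data.frame(start = integer(0), end = integer(0)))
  out <- as.data.frame(do.call(rbind, chosen))
  names(out) <- c("start", "end")
  out
}

# independent coding-effect oracle: full-CDS translation via seqinr
annotate_oracle <- function(pos, alt, model, ref_seq, region_start = 0) {
  segs <- model$cds_segments[order(model$cds_segments$start), ]
  get_seq <- function(s, e) substring(ref_seq, s - region_start + 1,
                                      e - region_start)
  cds <- paste(vapply(seq_len(nrow(segs)), function(i)
    get_seq(segs$start[i], segs$end[i]), ""), collapse = "")
  mut <- cds
  # genomic offset of pos within concatenated plus-strand CDS
  off <- 0
  for (i in seq_len(nrow(segs))) {
    if (pos >= segs$start[i] && pos < segs$end[i]) {
      off <- off + pos - segs$start[i]
      break
    }
    off <- off + segs$end[i] - segs$start[i]
  }
  substr(mut, off + 1, off + 1) <- alt
  orient <- function(s) {
    if (model$strand == "-")
      paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    else s
  }
  p_ref <- seqinr::translate(strsplit(tolower(orient(cds)), "")[[1]])
  p_alt <- seqinr::translate(strsplit(tolower(orient(mut)), "")[[1]])
  i <- which(p_ref != p_alt)
  if (length(i) == 0) "coding-synonymous"
  else if (any(p_alt[i] == "*")) "coding-nonsense"
  else "coding-missense"
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
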