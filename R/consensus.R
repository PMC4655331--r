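# Haploid splitting, consensus construction under the 2-of-6 rules, and
# intra-/inter-haplotype variant catalogues plus shared-segment scans.
#
# Sequences are represented sparsely: a sites table over positions where
# any input deviates from the reference, plus no-call tract intervals;
# everything else is reference. Comparable length L always excludes
# positions no-called or ambiguous in any compared sequence.

#' Split a diploid callset into two haploid sequences
#'
#' Homozygous sites put the shared allele on both chromosomes; phased
#' heterozygous sites split by phase; unphased heterozygous sites split by
#' the deterministic convention "first listed allele goes to chromosome 0"
#' and are flagged `phase_arbitrary`. Low-confidence and no-call sites
#' propagate to both haploids.
#'
#' @param callset A [diploid_callset()].
#' @return List of two `HaploidSequence` objects, each a list with
#'   `source_sample`, `chrom_index` (0 or 1), `region`, `sites` (data.frame
#'   `pos`, `ref`, `allele`, `confidence`, `phase_arbitrary`) and
#'   `nocall_regions`.
#' @export
split_haploids <- function(callset) {
  stopifnot(inherits(callset, "DiploidCallset"))
  calls <- callset$calls
  arb <- !calls$phased & calls$a1 != calls$a2 & calls$confidence == "high"
  mk <- function(idx) {
    allele <- if (idx == 0) calls$a1 else calls$a2
    allele[calls$confidence == "nocall"] <- "N"
    structure(list(source_sample = callset$sample_id, chrom_index = idx,
                   region = callset$region,
                   sites = data.frame(pos = calls$pos, ref = calls$ref,
                                      allele = allele,
                                      confidence = calls$confidence,
                                      phase_arbitrary = arb),
                   nocall_regions = callset$nocall_regions),
              class = "HaploidSequence")
  }
  list(mk(0L), mk(1L))
}

# allele of a haploid at pos: list(allele, confidence)
haploid_at <- function(hap, pos) {
  if (pos_in_intervals(pos, hap$nocall_regions))
    return(list(allele = "N", confidence = "nocall"))
  i <- match(pos, hap$sites$pos)
  if (is.na(i)) return(list(allele = NA_character_, confidence = "high"))
  list(allele = hap$sites$allele[i], confidence = hap$sites$confidence[i])
}

# Vectorized view of a haploid set: allele and confidence matrices
# (haploid x position) over the union of listed positions, plus the
# reference allele per position. NA allele = reference call.
haploid_matrices <- function(haploids) {
  all_pos <- sort(unique(unlist(lapply(haploids, function(h) h$sites$pos))))
  n <- length(all_pos)
  allele <- matrix(NA_character_, nrow = length(haploids), ncol = n)
  conf <- matrix("high", nrow = length(haploids), ncol = n)
  ref <- rep(NA_character_, n)
  for (k in seq_along(haploids)) {
    h <- haploids[[k]]
    i <- match(all_pos, h$sites$pos)
    hit <- !is.na(i)
    allele[k, hit] <- h$sites$allele[i[hit]]
    conf[k, hit] <- h$sites$confidence[i[hit]]
    ref[hit & is.na(ref)] <- h$sites$ref[i[hit & is.na(ref)]]
    in_tract <- pos_in_intervals(all_pos, h$nocall_regions)
    allele[k, in_tract] <- "N"
    conf[k, in_tract] <- "nocall"
  }
  list(pos = all_pos, allele = allele, conf = conf, ref = ref)
}

#' Build a consensus haplotype from haploid chromosomes
#'
#' Applies the majority rules used for consensus construction from a small
#' set of haploid chromosomes: a position where two or more inputs are
#' ambiguous or low-confidence is no-called (`N`) in the consensus;
#' otherwise the consensus carries the majority allele among the
#' high-confidence inputs, with an exact tie no-called and flagged
#' ambiguous. An alternate allele shared by at least `min_support` haploids
#' is recorded as a called consensus-level variant against the reference.
#'
#' @param haploids List of `HaploidSequence` objects (>= 2) over the same
#'   region.
#' @param min_support Minimum alternate-carrying haploids for a called
#'   consensus variant (default 2).
#' @param reference Optional [reference_track()] supplying reference bases
#'   at sites absent from some inputs.
#' @param name Haplotype label.
#' @return An object of class `ConsensusHaplotype`: `name`, `region`,
#'   `n_inputs`, `sites` (data.frame `pos`, `ref`, `call`, `support`,
#'   `ambiguous`), `variants` (called and uncalled alternate records) and
#'   `nocall_regions` (tracts masked in >= 2 inputs).
#' @export
build_consensus <- function(haploids, min_support = 2, reference = NULL,
                            name = "consensus") {
  stopifnot(length(haploids) >= 2)
  regions <- lapply(haploids, function(h) h$region)
  r0 <- regions[[1]]
  same <- vapply(regions, function(r)
    r$chrom == r0$chrom && r$start == r0$start && r$end == r0$end, logical(1))
  if (!all(same)) stop("haploids must span the same region")
  n_in <- length(haploids)
  hm <- haploid_matrices(haploids)
  site_rows <- list()
  var_rows <- list()
  for (ip in seq_along(hm$pos)) {
    pos <- hm$pos[ip]
    conf <- hm$conf[, ip]
    allele <- hm$allele[, ip]
    ref <- hm$ref[ip]
    if (is.na(ref) && !is.null(reference)) ref <- ref_base_at(reference, pos)
    allele[is.na(allele)] <- ref   # absent record = reference call
    n_bad <- sum(conf %in% c("low", "nocall"))
    if (n_bad >= 2) {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        pos = pos, ref = ref, call = "N", support = 0L, ambiguous = TRUE)
      next
    }
    good <- conf == "high"
    tab <- sort(table(allele[good]), decreasing = TRUE)
    tie <- length(tab) > 1 && tab[1] == tab[2]
    call <- if (tie) "N" else names(tab)[1]
    support <- if (tie) 0L else as.integer(tab[1])
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      pos = pos, ref = ref, call = call, support = support,
      ambiguous = tie)
    # alternate alleles vs reference
    alts <- setdiff(unique(allele[good]), c(ref, "N"))
    for (alt in alts) {
      sup <- sum(allele[good] == alt)
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        pos = pos, ref = ref, alt = alt,
        vtype = variant_type(alt), support = sup,
        called = sup >= min_support)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(pos = numeric(0), ref = character(0), call = character(0),
               support = integer(0), ambiguous = logical(0))
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(pos = numeric(0), ref = character(0), alt = character(0),
               vtype = character(0), support = integer(0),
               called = logical(0))
  masked <- coverage_intervals(lapply(haploids, function(h) h$nocall_regions),
                               min_cover = 2L)
  structure(list(name = name, region = r0, n_inputs = n_in, sites = sites,
                 variants = variants, nocall_regions = masked),
            class = "ConsensusHaplotype")
}

#' @export
print.ConsensusHaplotype <- function(x, ...) {
  cat(sprintf("<ConsensusHaplotype> %s  %s:%d-%d  %d sites, %d called variants\n",
              x$name, x$region$chrom, x$region$start, x$region$end,
              nrow(x$sites), sum(x$variants$called)))
  invisible(x)
}

variant_type <- function(alt) {
  ifelse(startsWith(alt, "ins:"), "insertion",
         ifelse(startsWith(alt, "del:"), "deletion", "SNV"))
}

#' Intra-CEH variant catalogue
#'
#' Records a variant at every position where more than one distinct allele
#' occurs among the haploid chromosomes of one CEH cohort, restricted to
#' positions at which every haploid is high-confidence; any position with
#' low-confidence or no-call data in any haploid is excluded from the
#' catalogue and from the comparable length `L`. The zygosity form of each
#' record is read from the carrier individuals' diploid genotypes.
#'
#' @param haploids List of `HaploidSequence` objects from >= 2 individuals.
#' @param samples List of the source [diploid_callset()] objects (used for
#'   zygosity forms).
#' @return data.frame of variant records (`pos`, `ref`, `alt`, `vtype`,
#'   `support`, `zygosity_form`) with attribute `comparable_length` = the
#'   region width minus all excluded positions and tracts.
#' @export
intra_ceh_catalog <- function(haploids, samples = NULL) {
  stopifnot(length(haploids) >= 2)
  region <- haploids[[1]]$region
  hm <- haploid_matrices(haploids)
  masked <- coverage_intervals(lapply(haploids, function(h) h$nocall_regions),
                               min_cover = 1L)
  all_high <- colSums(hm$conf != "high") == 0
  # tract-masked positions are already counted via interval widths
  excluded_pos <- sum(!all_high & !pos_in_intervals(hm$pos, masked))
  # fast screen: a position can only be polymorphic if some listed allele
  # differs from another listed allele or a haploid lacks a record
  rows <- list()
  for (ip in which(all_high)) {
    allele <- hm$allele[, ip]
    ref <- hm$ref[ip]
    allele[is.na(allele)] <- ref
    distinct <- unique(allele)
    if (length(distinct) <= 1) next
    pos <- hm$pos[ip]
    modal <- names(sort(table(allele), decreasing = TRUE))[1]
    for (alt in setdiff(distinct, modal)) {
      carriers <- unique(vapply(haploids[allele == alt],
                                function(h) h$source_sample, ""))
      form <- zygosity_form_of(samples, carriers, pos, alt)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos, ref = ref, alt = alt, vtype = variant_type(alt),
        support = sum(allele == alt), zygosity_form = form)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = numeric(0), ref = character(0), alt = character(0),
               vtype = character(0), support = integer(0),
               zygosity_form = character(0))
  attr(out, "comparable_length") <-
    region_width(region) - intervals_width(clip_intervals(masked, region)) -
    excluded_pos
  out
}

zygosity_form_of <- function(samples, carriers, pos, alt) {
  if (is.null(samples) || !length(carriers)) return(NA_character_)
  forms <- character(0)
  for (s in samples) {
    if (!(s$sample_id %in% carriers)) next
    i <- match(pos, s$calls$pos)
    if (is.na(i)) next
    forms <- c(forms, if (s$calls$a1[i] != s$calls$a2[i])
      "heterozygous-within-individual" else "homozygous-within-individual")
  }
  if (!length(forms)) return(NA_character_)
  if (length(unique(forms)) > 1) "mixed" else forms[1]
}

consensus_at <- function(cons, pos) {
  if (pos_in_intervals(pos, cons$nocall_regions)) return("N")
  i <- match(pos, cons$sites$pos)
  if (is.na(i)) return(NA_character_)   # reference call
  cons$sites$call[i]
}

#' Inter-haplotype variant catalogue between two consensus sequences
#'
#' Differences are counted only at positions where both consensuses are
#' non-N; the comparable length `L` is the number of positions both non-N
#' over the common region. Indel differences are collapsed to one record
#' per event.
#'
#' @param a,b [build_consensus()] results on a common coordinate frame.
#' @return List with `catalog` (data.frame `pos`, `a`, `b`, `vtype`) and
#'   `L` (comparable length in bp).
#' @export
inter_haplotype_catalog <- function(a, b) {
  common <- region_overlap(a$region, b$region)
  if (is.null(common)) stop("consensus regions are disjoint")
  pos_all <- sort(unique(c(a$sites$pos, b$sites$pos)))
  pos_all <- pos_all[pos_all >= common$start & pos_all < common$end]
  masked <- coverage_intervals(list(a$nocall_regions, b$nocall_regions),
                               min_cover = 1L)
  # vectorized lookup: positions listed by neither side are identical
  # reference in both and never differ
  ia <- match(pos_all, a$sites$pos)
  ib <- match(pos_all, b$sites$pos)
  ca <- ifelse(is.na(ia), NA_character_, a$sites$call[ia])
  cb <- ifelse(is.na(ib), NA_character_, b$sites$call[ib])
  ref <- ifelse(!is.na(ia), a$sites$ref[ia], b$sites$ref[ib])
  in_mask <- pos_in_intervals(pos_all, masked)
  ca[is.na(ca) & in_mask] <- "N"
  cb[is.na(cb) & in_mask] <- "N"
  ca[is.na(ca)] <- ref[is.na(ca)]
  cb[is.na(cb)] <- ref[is.na(cb)]
  excluded <- ca == "N" | cb == "N"
  n_pos_excluded <- sum(excluded & !in_mask)
  diff <- !excluded & ca != cb
  catalog <- if (any(diff)) {
    vt <- ifelse(startsWith(ca[diff], "ins:") | startsWith(cb[diff], "ins:"),
                 "insertion",
          ifelse(startsWith(ca[diff], "del:") | startsWith(cb[diff], "del:"),
                 "deletion", "SNV"))
    data.frame(pos = pos_all[diff], a = ca[diff], b = cb[diff], vtype = vt)
  } else {
    data.frame(pos = numeric(0), a = character(0), b = character(0),
               vtype = character(0))
  }
  L <- region_width(common) -
    intervals_width(clip_intervals(masked, common)) - n_pos_excluded
  list(catalog = catalog, L = L)
}

#' Scan for shared segments between SNP allele vectors
#'
#' Finds every maximal run of SNP indices in which the query disagrees with
#' the reference profile(s) at no more than `max_mismatch` positions. When
#' `refB` is supplied, a SNP matches only if the query agrees with both
#' references. Maximality is two-sided: no reported segment can be extended
#' in either direction without exceeding the mismatch budget.
#'
#' @param query Character (or 0/1) vector of query alleles.
#' @param refA Reference allele vector of equal length.
#' @param refB Optional second reference vector.
#' @param max_mismatch Mismatch budget per segment (default 2).
#' @param positions Optional bp positions of the SNPs; adds bp spans to the
#'   output.
#' @return data.frame of segments: `start_idx`, `end_idx`, `n_total`,
#'   `n_match` (and `start_pos`, `end_pos`, `span_bp` when `positions`
#'   given).
#' @export
shared_segment_scan <- function(query, refA, refB = NULL, max_mismatch = 2,
                                positions = NULL) {
  n <- length(query)
  if (length(refA) != n || (!is.null(refB) && length(refB) != n))
    stop("query and reference vectors must have equal length")
  if (!is.null(positions) && length(positions) != n)
    stop("positions must match the vector length")
  match_ok <- !is.na(query) & !is.na(refA) & query == refA
  if (!is.null(refB)) match_ok <- match_ok & !is.na(refB) & query == refB
  mm <- which(!match_ok)
  k <- max_mismatch
  segs <- if (length(mm) <= k) {
    data.frame(start_idx = 1L, end_idx = n)
  } else {
    b <- c(0L, mm, n + 1L)   # sentinels
    out <- list()
    for (i in seq_len(length(mm) - k + 1L)) {
      s <- b[i] + 1L                 # just after previous mismatch
      e <- b[i + k + 1L] - 1L        # just before the (k+1)-th mismatch
      if (e >= s) out[[length(out) + 1L]] <- data.frame(start_idx = s,
                                                        end_idx = e)
    }
    unique(do.call(rbind, out))
  }
  segs$n_total <- segs$end_idx - segs$start_idx + 1L
  segs$n_match <- vapply(seq_len(nrow(segs)), function(i)
    sum(match_ok[segs$start_idx[i]:segs$end_idx[i]]), integer(1))
  if (!is.null(positions)) {
    segs$start_pos <- positions[segs$start_idx]
    segs$end_pos <- positions[segs$end_idx]
    segs$span_bp <- segs$end_pos - segs$start_pos + 1
  }
  rownames(segs) <- NULL
  segs
}
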