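# Feature-class annotation of variants (with coding-effect translation),
# window binning of variation, low/high-variation flagging, nucleotide
# diversity and star-genealogy haplotype age.

FEATURE_CLASSES <- c("coding-missense", "coding-nonsense",
                     "coding-synonymous", "coding-frameshift",
                     "coding-nonframeshift", "ncRNA-exonic", "UTR5", "UTR3",
                     "intronic", "promoter", "intergenic")

# precedence when a variant falls under several feature intervals or genes
FEATURE_PRECEDENCE <- c("coding", "UTR5", "UTR3", "ncRNA-exonic",
                        "intronic", "promoter", "intergenic")

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Translate one codon
#' @param codon 3-letter DNA string (coding strand).
#' @return One-letter amino acid, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# CDS coordinate (0-based, in coding orientation) of a genomic position
cds_coordinate <- function(model, pos) {
  segs <- model$cds_segments
  ord <- if (model$strand == "+") order(segs$start) else order(-segs$start)
  offset <- 0
  for (i in ord) {
    s <- segs$start[i]; e <- segs$end[i]
    if (pos >= s && pos < e) {
      within <- if (model$strand == "+") pos - s else (e - 1) - pos
      return(offset + within)
    }
    offset <- offset + (e - s)
  }
  NA_real_
}

# codon sequence (coding strand) containing CDS coordinate cpos
codon_at <- function(model, reference, cpos) {
  segs <- model$cds_segments
  ord <- if (model$strand == "+") order(segs$start) else order(-segs$start)
  cds_seq <- paste(vapply(ord, function(i) {
    s <- ref_seq_substr(reference, segs$start[i], segs$end[i])
    if (model$strand == "-")
      s <- paste(rev(strsplit(complement_base(s), "")[[1]]), collapse = "")
    s
  }, ""), collapse = "")
  ci <- floor(cpos / 3)
  substr(cds_seq, ci * 3 + 1, ci * 3 + 3)
}

classify_in_model <- function(v, model, reference, promoter_bp) {
  pos <- v$pos
  tx <- model$tx
  # promoter: strand-aware window upstream of the TSS
  prom <- if (model$strand == "+")
    c(tx$start - promoter_bp, tx$start) else c(tx$end, tx$end + promoter_bp)
  in_tx <- pos >= tx$start && pos < tx$end
  in_exon <- in_tx && any(pos >= model$exons$start & pos < model$exons$end)
  in_cds <- !model$is_ncRNA && in_exon &&
    any(pos >= model$cds_segments$start & pos < model$cds_segments$end)
  if (in_cds) {
    if (v$vtype != "SNV") {
      len <- if (startsWith(v$alt, "ins:")) nchar(sub("^ins:", "", v$alt))
      else as.integer(sub("^del:", "", v$alt))
      return(if (len %% 3 == 0) "coding-nonframeshift" else
        "coding-frameshift")
    }
    if (is.null(reference) || is.null(reference$seq))
      stop("coding variant at ", pos,
           " requires a reference track with sequence")
    cpos <- cds_coordinate(model, pos)
    codon <- codon_at(model, reference, cpos)
    within <- cpos %% 3
    alt_base <- if (model$strand == "+") v$alt else complement_base(v$alt)
    alt_codon <- codon
    substr(alt_codon, within + 1, within + 1) <- alt_base
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(alt_codon)
    if (is.na(ref_aa) || is.na(alt_aa)) return("coding-missense")
    if (alt_aa == "*" && ref_aa != "*") return("coding-nonsense")
    if (alt_aa == ref_aa) return("coding-synonymous")
    return("coding-missense")
  }
  if (in_exon && model$is_ncRNA) return("ncRNA-exonic")
  if (in_exon) {
    if (any(pos >= model$utr5$start & pos < model$utr5$end)) return("UTR5")
    if (any(pos >= model$utr3$start & pos < model$utr3$end)) return("UTR3")
  }
  if (in_tx) return("intronic")
  if (pos >= prom[1] && pos < prom[2]) return("promoter")
  "intergenic"
}

#' Annotate a variant with its genomic feature class
#'
#' Classifies one variant record against a set of gene models. Coding SNVs
#' are translated on the coding strand: an unchanged amino acid is
#' synonymous, a gained stop is nonsense, any other change missense; coding
#' indels are frameshift when their length is not a multiple of 3. When a
#' variant falls in several genes or overlapping features, the class of
#' highest precedence wins (coding > UTR5 > UTR3 > ncRNA-exonic > intronic >
#' promoter > intergenic). The promoter is the `promoter_bp` window upstream
#' of the transcription start, strand-aware.
#'
#' @param v One-row data.frame (or list) with `pos`, `alt`, `vtype`.
#' @param models List of [gene_model()] objects.
#' @param reference A [reference_track()] with sequence covering the CDS of
#'   any affected coding gene.
#' @param promoter_bp Promoter window size in bp (default 1000).
#' @return A feature-class string.
#' @export
annotate_variant <- function(v, models, reference = NULL,
                             promoter_bp = 1000) {
  classes <- vapply(models, function(m)
    classify_in_model(v, m, reference, promoter_bp), "")
  rank <- vapply(classes, function(cl) {
    base <- if (startsWith(cl, "coding-")) "coding" else cl
    match(base, FEATURE_PRECEDENCE)
  }, integer(1))
  classes[which.min(rank)]
}

#' Annotate a whole catalogue
#'
#' @param catalog data.frame of variant records (`pos`, `alt`, `vtype`).
#' @inheritParams annotate_variant
#' @return `catalog` with a `feature_class` column appended.
#' @export
annotate_catalog <- function(catalog, models, reference = NULL,
                             promoter_bp = 1000) {
  catalog$feature_class <- vapply(seq_len(nrow(catalog)), function(i)
    annotate_variant(catalog[i, ], models, reference, promoter_bp), "")
  catalog
}

#' Flag variants absent from a known-sites list
#'
#' @param catalog Variant catalogue with a `pos` column.
#' @param known_sites Numeric vector (or data.frame with `pos`) of known
#'   variant positions.
#' @return `catalog` with a logical `known` column.
#' @export
flag_known_variants <- function(catalog, known_sites) {
  if (is.data.frame(known_sites)) known_sites <- known_sites$pos
  catalog$known <- catalog$pos %in% known_sites
  catalog
}

#' Bin a variant catalogue into fixed-width windows
#'
#' Counts SNVs and indels per window, builds the frequency histogram of
#' per-window counts, the cumulative share of variants across the 10%
#' quantile intervals of windows ranked by count, and the count range of
#' the top decile.
#'
#' @param catalog Variant catalogue with `pos` (and optionally `vtype`).
#' @param region A [genomic_region()] to tile.
#' @param window Window width (default 5000).
#' @return List with `windows` (per-window counts), `histogram`
#'   (`count`, `n_windows`), `decile_share` and `decile_cumulative`
#'   (length 10: share of all variants carried by each successive 10% of
#'   windows ranked most-variable first, and its running total),
#'   `top_decile_range` (`c(min, max)` count among top-10% windows) and
#'   `mean_per_window`.
#' @export
bin_variation <- function(catalog, region, window = 5000) {
  starts <- seq(region$start, region$end - 1, by = window)
  ends <- pmin(starts + window, region$end)
  widx <- floor((catalog$pos - region$start) / window) + 1L
  widx <- widx[widx >= 1 & widx <= length(starts)]
  counts <- tabulate(widx, nbins = length(starts))
  vt <- if ("vtype" %in% names(catalog)) catalog$vtype else
    rep("SNV", nrow(catalog))
  n_snv <- tabulate(widx[vt != "insertion" & vt != "deletion"],
                    nbins = length(starts))
  n_indel <- counts - n_snv
  windows <- data.frame(chrom = region$chrom, start = starts, end = ends,
                        n_variants = counts, n_snv = n_snv,
                        n_indel = n_indel)
  tab <- table(counts)
  histogram <- data.frame(count = as.integer(names(tab)),
                          n_windows = as.integer(tab))
  ord <- order(counts, decreasing = TRUE)
  n_win <- length(counts)
  decile_id <- ceiling(seq_len(n_win) / n_win * 10)
  total <- sum(counts)
  dec <- vapply(1:10, function(d)
    sum(counts[ord][decile_id == d]), numeric(1))
  decile_share <- if (total > 0) dec / total else rep(0, 10)
  top <- counts[ord][seq_len(max(1L, ceiling(n_win * 0.1)))]
  list(windows = windows, histogram = histogram,
       decile_share = decile_share,
       decile_cumulative = cumsum(decile_share),
       top_decile_range = c(min(top), max(top)),
       mean_per_window = mean(counts))
}

#' Flag low- and high-variation regions
#'
#' Tiles the region with windows and labels those holding fewer than
#' `low_max` variants `LOW` and those holding more than `high_min` `HIGH`
#' (strict inequalities; a window at either bound is unlabeled). Adjacent
#' windows with the same label are merged.
#'
#' @param catalog Variant catalogue with `pos`.
#' @param region A [genomic_region()].
#' @param window Window width (default 30 kb).
#' @param low_max Upper bound (exclusive) for `LOW`.
#' @param high_min Lower bound (exclusive) for `HIGH`.
#' @return data.frame of labeled intervals (`chrom`, `start`, `end`,
#'   `name`), BED-ready.
#' @export
flag_variation_regions <- function(catalog, region, window = 30000,
                                   low_max = 3, high_min = 15) {
  bv <- bin_variation(catalog, region, window)
  w <- bv$windows
  lab <- ifelse(w$n_variants < low_max, "LOW",
                ifelse(w$n_variants > high_min, "HIGH", NA))
  out <- list()
  i <- 1L
  while (i <= nrow(w)) {
    if (is.na(lab[i])) { i <- i + 1L; next }
    j <- i
    while (j < nrow(w) && !is.na(lab[j + 1]) && lab[j + 1] == lab[i])
      j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(chrom = w$chrom[1],
                                          start = w$start[i],
                                          end = w$end[j], name = lab[i])
    i <- j + 1L
  }
  if (!length(out)) return(data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0),
                                      name = character(0)))
  do.call(rbind, out)
}

#' Nucleotide diversity and related summary statistics
#'
#' The diversity statistic pi is defined here as the segregating-SNV count
#' divided by the comparable aligned length, `S / L`; `snv_per_100kb` is
#' `1e5 * pi`. The canonical average-pairwise nucleotide diversity is
#' available separately as [pairwise_nucleotide_diversity()].
#'
#' @param S Segregating SNV count.
#' @param L Comparable length in bp (> 0).
#' @param catalog Optional intra-CEH catalogue; supplies `het_fraction`
#'   (share of records heterozygous within their carrier) and the indel
#'   count.
#' @param n_indel Optional indel count for `indel_per_100kb`.
#' @return An object of class `DiversityStats`: `S`, `L`, `pi`,
#'   `snv_per_100kb`, `indel_per_100kb`, `het_fraction`.
#' @export
diversity_stats <- function(S, L, catalog = NULL, n_indel = NULL) {
  if (L <= 0) stop("comparable length L must be > 0")
  stopifnot(S >= 0)
  het_fraction <- NA_real_
  if (!is.null(catalog) && nrow(catalog)) {
    if (is.null(n_indel))
      n_indel <- sum(catalog$vtype %in% c("insertion", "deletion"))
    zf <- catalog$zygosity_form
    het_fraction <- mean(zf == "heterozygous-within-individual", na.rm = TRUE)
  }
  structure(list(S = S, L = L, pi = S / L, snv_per_100kb = 1e5 * S / L,
                 indel_per_100kb = if (is.null(n_indel)) NA_real_ else
                   1e5 * n_indel / L,
                 het_fraction = het_fraction),
            class = "DiversityStats")
}

#' @export
print.DiversityStats <- function(x, ...) {
  cat(sprintf("<DiversityStats> S = %d over L = %s bp: pi = %s (%s SNVs/100 kb)\n",
              x$S, format(x$L, big.mark = ","), signif(x$pi, 3),
              signif(x$snv_per_100kb, 3)))
  invisible(x)
}

#' Star-genealogy age model constants
#'
#' @param mu Mutation rate per site per generation (default 1.1e-8).
#' @param gen_years Years per generation (default 20).
#' @param n_chrom Haploid chromosomes sampled (default 6).
#' @return An object of class `AgeModel`.
#' @export
age_model <- function(mu = 1.1e-8, gen_years = 20, n_chrom = 6) {
  stopifnot(mu > 0, gen_years > 0, n_chrom >= 1)
  structure(list(mu = mu, gen_years = gen_years, n_chrom = n_chrom),
            class = "AgeModel")
}

#' Estimate haplotype age under a star genealogy
#'
#' Under a star genealogy, `n_chrom` haploid lineages descend independently
#' from the founder for `T` generations, so the expected number of
#' segregating sites is `S = n_chrom * mu * T * L`. Inverting and flooring
#' the generation count gives `T = floor(S / (n_chrom * mu * L))` and the
#' age in years `T * gen_years`.
#'
#' @param S Segregating SNV count (>= 0).
#' @param L Comparable length in bp (> 0).
#' @param model An [age_model()].
#' @return List with `T_gen` (floored generations) and `age_years`.
#' @export
estimate_age <- function(S, L, model = age_model()) {
  stopifnot(inherits(model, "AgeModel"))
  if (L <= 0) stop("comparable length L must be > 0")
  if (S < 0) stop("S must be >= 0")
  T_gen <- floor(S / (model$n_chrom * model$mu * L))
  list(T_gen = T_gen, age_years = T_gen * model$gen_years)
}

#' Average-pairwise nucleotide diversity of a haplotype panel
#'
#' The canonical pi: the mean proportion of differing sites over all
#' distinct pairs of sequences, with pairwise deletion of missing data.
#'
#' @param haplotypes Matrix (sequences x sites) of symbols; `NA` = missing.
#' @param L Optional sequence length to normalize by (defaults to the
#'   pairwise-complete site count per pair).
#' @return Mean pairwise diversity (numeric).
#' @export
pairwise_nucleotide_diversity <- function(haplotypes, L = NULL) {
  n <- nrow(haplotypes)
  if (n < 2) stop("need at least two sequences")
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(haplotypes[i, ]) & !is.na(haplotypes[j, ])
    d <- sum(haplotypes[i, ok] != haplotypes[j, ok])
    denom <- if (is.null(L)) sum(ok) else L
    if (denom > 0) { tot <- tot + d / denom; np <- np + 1 }
  }
  tot / np
}
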