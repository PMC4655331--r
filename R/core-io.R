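# Readers/writers for the standard formats the pipeline touches.
# Site calls live in per-sample DiploidCallset objects; downstream modules
# never re-parse files.

CONFIDENCE_LEVELS <- c("high", "low", "nocall")

#' Construct a diploid callset
#'
#' A `DiploidCallset` holds the position-sorted site calls of one sample over
#' one region. Each row of `calls` is one site: `pos` (0-based bp), `ref`
#' (normalized reference allele string), `a1`/`a2` (allele tokens: a base,
#' `"ins:<seq>"`, `"del:<len>"`, or `"N"`), `confidence` (`"high"`, `"low"`,
#' `"nocall"`) and `phased` (logical). Positions absent from `calls` and not
#' covered by `nocall_regions` are taken to be homozygous-reference,
#' high-confidence -- the usual variant-file convention.
#'
#' @param sample_id Sample name.
#' @param region A [genomic_region()].
#' @param calls data.frame with columns `pos`, `ref`, `a1`, `a2`,
#'   `confidence`, `phased`; positions strictly increasing, all inside
#'   `region`.
#' @param nocall_regions Optional data.frame (`start`, `end`) of no-call
#'   tracts where the sample has no usable data.
#' @return An object of class `DiploidCallset`.
#' @export
diploid_callset <- function(sample_id, region, calls,
                            nocall_regions = NULL) {
  stopifnot(is.character(sample_id), inherits(region, "GenomicRegion"))
  need <- c("pos", "ref", "a1", "a2", "confidence", "phased")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols))
    stop("calls is missing columns: ", paste(missing_cols, collapse = ", "))
  calls <- calls[, need, drop = FALSE]
  calls$pos <- as.numeric(calls$pos)
  if (nrow(calls)) {
    if (any(diff(calls$pos) <= 0))
      stop("call positions must be strictly increasing")
    if (any(calls$pos < region$start | calls$pos >= region$end))
      stop("call positions outside region")
    if (!all(calls$confidence %in% CONFIDENCE_LEVELS))
      stop("confidence must be one of: ", paste(CONFIDENCE_LEVELS, collapse = ", "))
  }
  rownames(calls) <- NULL
  structure(list(sample_id = sample_id, region = region, calls = calls,
                 nocall_regions = clip_intervals(as_intervals(nocall_regions),
                                                 region)),
            class = "DiploidCallset")
}

#' @export
print.DiploidCallset <- function(x, ...) {
  cat(sprintf("<DiploidCallset> %s  %s:%d-%d  %d site calls, %d no-call tracts\n",
              x$sample_id, x$region$chrom, x$region$start, x$region$end,
              nrow(x$calls), nrow(x$nocall_regions)))
  invisible(x)
}

# Minimal (parsimonious) representation of a REF/ALT pair: trim the common
# suffix, then the common prefix, adjusting the position offset.
normalize_alleles <- function(ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # suffix
  while (length(r) > 0 && length(a) > 0 &&
         r[length(r)] == a[length(a)] &&
         !(length(r) == 1 && length(a) == 1)) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  off <- 0L
  while (length(r) > 0 && length(a) > 0 && r[1] == a[1] &&
         !(length(r) == 1 && length(a) == 1)) {
    r <- r[-1]
    a <- a[-1]
    off <- off + 1L
  }
  list(offset = off, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# Token for a normalized alt allele relative to a normalized ref.
allele_token <- function(ref, alt) {
  if (identical(ref, alt)) return(if (nzchar(ref)) ref else ".")
  if (nchar(ref) == nchar(alt)) return(alt)          # SNV or MNP
  if (nchar(alt) > nchar(ref)) {
    ins <- if (nchar(ref) == 0) alt else substring(alt, nchar(ref) + 1L)
    return(paste0("ins:", ins))
  }
  paste0("del:", nchar(ref) - nchar(alt))
}

is_indel_token <- function(x) grepl("^(ins|del):", x)

#' Read a multi-sample VCF subset into diploid callsets
#'
#' Parses a VCF v4.x file (GT genotypes required) and returns one
#' [diploid_callset()] per sample. VCF 1-based positions are converted to the
#' internal 0-based convention; `FILTER` values other than `PASS`/`.` map to
#' confidence `"low"`; missing genotypes (`./.`) map to a no-call site with
#' alleles `(N, N)`; the phased separator `|` sets `phased = TRUE`. Indels
#' are normalized to their minimal representation on read.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param region A [genomic_region()]; records outside it are dropped. A
#'   region with no records yields empty callsets, not an error.
#' @return A named list of `DiploidCallset`, one per sample column.
#' @export
read_vcf_subset <- function(path, region) {
  stopifnot(inherits(region, "GenomicRegion"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) == 0) stop("VCF has no sample columns")
  if (nrow(fix) == 0) {
    out <- lapply(samples, function(s)
      diploid_callset(s, region, data.frame(
        pos = numeric(0), ref = character(0), a1 = character(0),
        a2 = character(0), confidence = character(0), phased = logical(0))))
    names(out) <- samples
    return(out)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(samples),
                                     dimnames = list(NULL, samples))
  pos0 <- as.numeric(fix$POS) - 1
  keep <- fix$CHROM == region$chrom & pos0 >= region$start & pos0 < region$end
  filt <- fix$FILTER
  conf <- ifelse(is.na(filt) | filt %in% c("PASS", "."), "high", "low")

  out <- lapply(samples, function(s) {
    rows <- list()
    for (i in which(keep)) {
      g <- gt[i, s]
      ref <- fix$REF[i]
      alts <- if (is.na(fix$ALT[i]) || fix$ALT[i] == ".") character(0) else
        strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      alleles <- c(ref, alts)
      phased <- !is.na(g) && grepl("|", g, fixed = TRUE)
      idx <- if (is.na(g) || g %in% c(".", "./.", ".|.")) c(NA, NA) else
        suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      if (length(idx) == 1) idx <- c(idx, idx)  # haploid-style GT
      if (any(is.na(idx))) {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos0[i], ref = substr(ref, 1, 1), a1 = "N", a2 = "N",
          confidence = "nocall", phased = FALSE)
        next
      }
      # normalize each allele against REF; anchor position on the SNV core
      toks <- character(2)
      offs <- integer(2)
      for (k in 1:2) {
        al <- alleles[idx[k] + 1L]
        nn <- normalize_alleles(ref, al)
        toks[k] <- allele_token(nn$ref, nn$alt)
        offs[k] <- nn$offset
      }
      nr <- normalize_alleles(ref, if (length(alts)) alleles[max(idx) + 1L] else ref)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos0[i] + nr$offset,
        ref = if (nzchar(nr$ref)) nr$ref else substr(ref, 1, 1),
        a1 = toks[1], a2 = toks[2],
        confidence = conf[i], phased = phased)
    }
    calls <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pos = numeric(0), ref = character(0), a1 = character(0),
                 a2 = character(0), confidence = character(0),
                 phased = logical(0))
    calls <- calls[order(calls$pos), , drop = FALSE]
    calls <- calls[!duplicated(calls$pos), , drop = FALSE]
    diploid_callset(s, region, calls)
  })
  names(out) <- samples
  out
}

#' Write diploid callsets to a minimal VCF
#'
#' Emits a VCF v4.2 subset (CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO,
#' FORMAT=GT) covering the union of called sites across samples. Samples with
#' no record at a site are written as `0/0` (or `./.` inside one of their
#' no-call tracts). Indel REF/ALT columns are reconstructed with the
#' reference anchor base when `reference` is given, else `N`.
#'
#' @param callsets List of [diploid_callset()] over a common region.
#' @param path Output file path.
#' @param reference Optional [reference_track()] supplying anchor bases.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callsets, path, reference = NULL) {
  stopifnot(length(callsets) >= 1)
  region <- callsets[[1]]$region
  all_pos <- sort(unique(unlist(lapply(callsets, function(cs) cs$calls$pos))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", region$chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT",
                       vapply(callsets, function(cs) cs$sample_id, "")),
                     collapse = "\t")), con)
  for (p in all_pos) {
    ref <- NA_character_
    toks <- list()
    conf <- "high"
    for (cs in callsets) {
      r <- cs$calls[cs$calls$pos == p, ]
      if (nrow(r)) {
        if (is.na(ref) && r$confidence != "nocall") ref <- r$ref
        if (r$confidence == "low") conf <- "low"
      }
    }
    if (is.na(ref)) ref <- "N"
    # collect alt tokens
    alt_toks <- character(0)
    for (cs in callsets) {
      r <- cs$calls[cs$calls$pos == p, ]
      if (nrow(r))
        alt_toks <- union(alt_toks,
                          setdiff(c(r$a1, r$a2), c(ref, "N")))
    }
    token_to_refalt <- function(tok) {
      if (is_indel_token(tok)) {
        anchor <- if (!is.null(reference)) ref_base_at(reference, p - 1) else "N"
        if (startsWith(tok, "ins:"))
          list(ref = anchor, alt = paste0(anchor, sub("^ins:", "", tok)))
        else {
          n <- as.integer(sub("^del:", "", tok))
          del <- if (!is.null(reference) && !is.null(reference$seq))
            ref_seq_substr(reference, p, p + n) else
              paste(rep("N", n), collapse = "")
          list(ref = paste0(anchor, del), alt = anchor)
        }
      } else list(ref = ref, alt = tok)
    }
    has_indel <- any(is_indel_token(alt_toks))
    if (has_indel && length(alt_toks) > 1)
      alt_toks <- alt_toks[is_indel_token(alt_toks)][1]  # one event per line
    ra <- if (length(alt_toks)) token_to_refalt(alt_toks[1]) else
      list(ref = ref, alt = ".")
    vcf_pos <- if (has_indel) p else p + 1  # indel lines anchored 1 bp left
    alleles <- c(if (has_indel) ra$ref else ref, alt_toks)
    gts <- vapply(callsets, function(cs) {
      r <- cs$calls[cs$calls$pos == p, ]
      if (!nrow(r)) {
        if (pos_in_intervals(p, cs$nocall_regions)) "./." else "0/0"
      } else if (r$confidence == "nocall") {
        "./."
      } else {
        i1 <- match(r$a1, alleles) - 1L
        i2 <- match(r$a2, alleles) - 1L
        if (is.na(i1)) i1 <- 0L
        if (is.na(i2)) i2 <- 0L
        paste0(i1, if (r$phased) "|" else "/", i2)
      }
    }, "")
    writeLines(paste(c(region$chrom, format(vcf_pos, scientific = FALSE),
                       ".", ra$ref,
                       if (length(alt_toks)) ra$alt else ".",
                       ".", if (conf == "high") "PASS" else "LowQual",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write labeled intervals to a BED file
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` (and `score`, `strand`); 0-based half-open, sorted
#'   within each chromosome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals)) {
    by_chrom <- split(intervals$start, intervals$chrom)
    if (any(vapply(by_chrom, function(s) any(diff(s) < 0), logical(1))))
      stop("intervals must be sorted by start within each chromosome")
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  out <- intervals[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(x) > 3)
    names(x)[4:min(ncol(x), 6)] <- extra[seq_len(min(ncol(x), 6) - 3)]
  x
}

#' Construct a gene model
#'
#' @param gene Gene name.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end Transcript bounds (0-based half-open).
#' @param exons data.frame (`start`, `end`) of exon intervals.
#' @param cds data.frame (`start`, `end`) of CDS intervals; may be empty for
#'   non-coding models.
#' @param is_ncRNA Logical; `TRUE` marks a non-coding model.
#' @return An object of class `GeneModel` with CDS reading-frame offsets
#'   computed from cumulative CDS length on the coding strand. A CDS whose
#'   total length is not divisible by 3 triggers a warning and the model is
#'   marked non-coding for effect annotation.
#' @export
gene_model <- function(gene, chrom, strand, tx_start, tx_end, exons,
                       cds = NULL, is_ncRNA = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as_intervals(exons)
  cds <- as_intervals(cds)
  tx <- genomic_region(chrom, tx_start, tx_end)
  utr5 <- empty_intervals()
  utr3 <- empty_intervals()
  if (nrow(cds) == 0) is_ncRNA <- TRUE
  if (!is_ncRNA) {
    cds <- cds[order(cds$start), , drop = FALSE]
    total <- sum(cds$end - cds$start)
    if (total %% 3 != 0) {
      warning(sprintf("gene %s: CDS length %d not divisible by 3; treated as non-coding",
                      gene, total))
      is_ncRNA <- TRUE
    }
  }
  if (!is_ncRNA) {
    # frame offset of each CDS segment in coding order
    ord <- if (strand == "+") order(cds$start) else order(-cds$start)
    lens <- (cds$end - cds$start)[ord]
    frames <- c(0, cumsum(lens))[seq_along(lens)] %% 3
    cds$frame <- NA_integer_
    cds$frame[ord] <- as.integer(frames)
    cds_lo <- min(cds$start)
    cds_hi <- max(cds$end)
    # UTRs: exonic sequence outside the CDS span, split by strand
    for (i in seq_len(nrow(exons))) {
      s <- exons$start[i]; e <- exons$end[i]
      if (s < cds_lo) {
        piece <- data.frame(start = s, end = min(e, cds_lo))
        if (strand == "+") utr5 <- rbind(utr5, piece) else utr3 <- rbind(utr3, piece)
      }
      if (e > cds_hi) {
        piece <- data.frame(start = max(s, cds_hi), end = e)
        if (strand == "+") utr3 <- rbind(utr3, piece) else utr5 <- rbind(utr5, piece)
      }
    }
  }
  structure(list(gene = gene, strand = strand, tx = tx, exons = exons,
                 cds_segments = cds, utr5 = utr5, utr3 = utr3,
                 is_ncRNA = is_ncRNA),
            class = "GeneModel")
}

#' Read gene models from BED12 or a GFF-lite TSV
#'
#' Two formats are accepted. BED12: standard 12-column BED; the thick region
#' defines the CDS and `thickStart == thickEnd` marks a non-coding model.
#' GFF-lite: a header-bearing TSV with columns `gene`, `chrom`, `strand`,
#' `feature`, `start`, `end` (0-based half-open) where `feature` is one of
#' `transcript`, `exon`, `CDS`; rows are grouped by `gene`.
#'
#' @param path Input path.
#' @param format `"auto"` (default; BED12 when the first line has 12
#'   tab-separated fields and no header), `"bed12"` or `"gff_lite"`.
#' @return A named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gff_lite")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (length(strsplit(first, "\t")[[1]]) == 12 &&
                  !grepl("^gene\t", first)) "bed12" else "gff_lite"
  }
  if (format == "bed12") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    models <- lapply(seq_len(nrow(x)), function(i) {
      r <- x[i, ]
      sizes <- as.numeric(strsplit(as.character(r[[11]]), ",")[[1]])
      starts <- as.numeric(strsplit(as.character(r[[12]]), ",")[[1]])
      exons <- data.frame(start = r[[2]] + starts,
                          end = r[[2]] + starts + sizes)
      thick_s <- r[[7]]; thick_e <- r[[8]]
      ncRNA <- thick_s == thick_e
      cds <- if (ncRNA) empty_intervals() else {
        s <- pmax(exons$start, thick_s)
        e <- pmin(exons$end, thick_e)
        data.frame(start = s[e > s], end = e[e > s])
      }
      gene_model(as.character(r[[4]]), as.character(r[[1]]),
                 as.character(r[[6]]), r[[2]], r[[3]], exons, cds,
                 is_ncRNA = ncRNA)
    })
  } else {
    x <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "strand", "feature", "start", "end")
    if (!all(need %in% names(x)))
      stop("GFF-lite TSV needs columns: ", paste(need, collapse = ", "))
    models <- lapply(split(x, x$gene), function(g) {
      tx <- g[g$feature == "transcript", ]
      exons <- g[g$feature == "exon", c("start", "end")]
      cds <- g[g$feature == "CDS", c("start", "end")]
      if (nrow(tx) == 0)
        tx <- data.frame(start = min(g$start), end = max(g$end))
      if (nrow(exons) == 0) exons <- data.frame(start = tx$start[1], end = tx$end[1])
      gene_model(g$gene[1], g$chrom[1], g$strand[1], tx$start[1], tx$end[1],
                 exons, cds, is_ncRNA = nrow(cds) == 0)
    })
  }
  names(models) <- vapply(models, function(m) m$gene, "")
  models
}

#' Construct a reference allele track
#'
#' The reference track supplies reference bases: either sparsely (a `sites`
#' table of `pos`, `base`, enough for catalogue work) or densely (`seq`, a
#' single string covering `region`, required for coding-effect annotation).
#'
#' @param region A [genomic_region()].
#' @param seq Optional reference sequence string of length
#'   `region_width(region)`.
#' @param sites Optional data.frame (`pos`, `base`).
#' @return An object of class `ReferenceTrack`.
#' @export
reference_track <- function(region, seq = NULL, sites = NULL) {
  stopifnot(inherits(region, "GenomicRegion"))
  if (!is.null(seq)) {
    stopifnot(is.character(seq), length(seq) == 1L)
    if (nchar(seq) != region_width(region))
      stop("seq length must equal region width")
  }
  if (!is.null(sites)) {
    stopifnot(all(c("pos", "base") %in% names(sites)))
    sites <- sites[order(sites$pos), c("pos", "base")]
  }
  structure(list(region = region, seq = seq, sites = sites),
            class = "ReferenceTrack")
}

ref_base_at <- function(track, pos) {
  if (!is.null(track$seq))
    return(substr(track$seq, pos - track$region$start + 1,
                  pos - track$region$start + 1))
  if (!is.null(track$sites)) {
    i <- match(pos, track$sites$pos)
    if (!is.na(i)) return(track$sites$base[i])
  }
  "N"
}

ref_seq_substr <- function(track, start, end) {
  if (is.null(track$seq))
    stop("reference track has no sequence covering ", start, "-", end)
  substr(track$seq, start - track$region$start + 1, end - track$region$start)
}
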