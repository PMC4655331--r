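# Pairwise r2 linkage disequilibrium, LD-block detection, block haplotype
# tables with crossover links, co-segregation screening and delta-Ct
# expression quantification.

#' Pairwise r-squared between two sites of a phased haplotype matrix
#'
#' Computes `D = p_AB - p_A * p_B` and `r2 = D^2 / (p_A q_A p_B q_B)` from
#' pairwise-complete rows. A pair involving a monomorphic site has
#' undefined r2 and is flagged.
#'
#' @param haplotypes Phased 0/1 matrix (chromosomes x sites); `NA` allowed.
#' @param i,j Distinct column indices.
#' @return List with `i`, `j`, `p_a`, `p_b`, `D`, `r2`, `defined`,
#'   `n_complete`.
#' @export
pairwise_r2 <- function(haplotypes, i, j) {
  if (i == j) stop("site indices must differ")
  x <- haplotypes[, i]
  y <- haplotypes[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least two pairwise-complete haplotypes")
  pa <- mean(x)
  pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    return(list(i = i, j = j, p_a = pa, p_b = pb, D = NA_real_,
                r2 = NA_real_, defined = FALSE, n_complete = length(x)))
  pab <- mean(x == 1 & y == 1)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(i = i, j = j, p_a = pa, p_b = pb, D = D, r2 = r2, defined = TRUE,
       n_complete = length(x))
}

#' Full pairwise r-squared matrix
#'
#' @inheritParams pairwise_r2
#' @return Symmetric matrix of r2 values (`NA` where undefined; diagonal
#'   `NA`).
#' @export
r2_matrix <- function(haplotypes) {
  m <- ncol(haplotypes)
  out <- matrix(NA_real_, m, m)
  if (m < 2) return(out)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    r <- pairwise_r2(haplotypes, i, j)
    out[i, j] <- out[j, i] <- if (r$defined) r$r2 else NA_real_
  }
  out
}

#' Detect LD blocks as all-pairs r2 runs
#'
#' An LD block is a maximal contiguous run of SNPs in genomic order in
#' which every pairwise r2 strictly exceeds `r2_min` (an undefined r2 --
#' monomorphic site -- never exceeds the threshold). The search is greedy
#' left-to-right: the leftmost maximal run wins and scanning resumes after
#' it. Singleton sites are not reported as blocks.
#'
#' @param haplotypes Phased 0/1 matrix (chromosomes x sites).
#' @param r2_min Strict lower bound for all within-block pairs
#'   (default 0.8).
#' @return data.frame of blocks: `start`, `end` (column indices,
#'   inclusive), `n_sites`, `min_r2`.
#' @export
find_ld_blocks <- function(haplotypes, r2_min = 0.8) {
  m <- ncol(haplotypes)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_sites = integer(0), min_r2 = numeric(0))
  if (m < 2) return(empty)
  blocks <- list()
  i <- 1L
  while (i < m) {
    j <- i
    min_r2_val <- Inf
    repeat {
      if (j + 1L > m) break
      # extend to j+1 iff every pair (k, j+1), k in i..j, exceeds r2_min
      ok <- TRUE
      new_min <- min_r2_val
      for (k in i:j) {
        r <- pairwise_r2(haplotypes, k, j + 1L)
        if (!r$defined || r$r2 <= r2_min) { ok <- FALSE; break }
        new_min <- min(new_min, r$r2)
      }
      if (!ok) break
      j <- j + 1L
      min_r2_val <- new_min
    }
    if (j > i) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        start = i, end = j, n_sites = j - i + 1L, min_r2 = min_r2_val)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(blocks)) return(empty)
  do.call(rbind, blocks)
}

#' Haplotype table of an LD block, with crossover links
#'
#' Counts the within-block haplotype strings of a phased panel and, when
#' the next block is given, the crossover link weights: the fraction of
#' chromosomes carrying haplotype `h1` in this block and `h2` in the next.
#'
#' @param haplotypes Phased 0/1 matrix; must carry a true `phased`
#'   attribute or contain no `NA`.
#' @param block One row of [find_ld_blocks()] output (or a list with
#'   `start`, `end`).
#' @param next_block Optional following block.
#' @return List with `freqs` (named numeric, sums to 1) and, when
#'   `next_block` is given, `links` (matrix `h1` x `h2` of joint
#'   fractions).
#' @export
block_haplotype_table <- function(haplotypes, block, next_block = NULL) {
  phased <- attr(haplotypes, "phased")
  if (!is.null(phased) && !isTRUE(phased))
    stop("block haplotype analysis requires phased input")
  if (any(is.na(haplotypes)))
    stop("block haplotype analysis requires phased, complete input")
  hap_str <- function(b) apply(haplotypes[, b$start:b$end, drop = FALSE], 1,
                               paste, collapse = "")
  h1 <- hap_str(block)
  freqs <- table(h1) / length(h1)
  freqs <- stats::setNames(as.numeric(freqs), names(freqs))
  out <- list(freqs = freqs[order(-freqs)])
  if (!is.null(next_block)) {
    h2 <- hap_str(next_block)
    links <- table(h1, h2) / length(h1)
    out$links <- unclass(links)
  }
  out
}

#' Screen intra-CEH variants for perfect co-segregation with a phenotype
#'
#' Returns the sites at which the allele observed in every sample of one
#' phenotype class is disjoint from the alleles observed in the other
#' class -- a perfect partition. Sites with any overlap (or missing data)
#' are excluded.
#'
#' @param genotypes Matrix of alleles (sites x samples; rownames are site
#'   labels).
#' @param phenotype Logical or two-level vector, one entry per sample
#'   column.
#' @return Integer vector of candidate site row indices (named when
#'   `genotypes` has rownames).
#' @export
cosegregation_screen <- function(genotypes, phenotype) {
  stopifnot(ncol(genotypes) == length(phenotype))
  cls <- unique(phenotype[!is.na(phenotype)])
  if (length(cls) != 2)
    stop("phenotype must contain exactly two classes")
  g1 <- phenotype == cls[1]
  g2 <- phenotype == cls[2]
  hits <- which(vapply(seq_len(nrow(genotypes)), function(i) {
    a1 <- genotypes[i, g1]
    a2 <- genotypes[i, g2]
    if (anyNA(a1) || anyNA(a2)) return(FALSE)
    length(intersect(unique(a1), unique(a2))) == 0
  }, logical(1)))
  if (!is.null(rownames(genotypes))) names(hits) <- rownames(genotypes)[hits]
  hits
}

#' Relative expression by the delta-Ct method
#'
#' Relative expression is `2^-(mean(ct_target) - mean(ct_ref))`. A target
#' beyond the detection limit, or recorded as the no-amplification sentinel
#' (`NA`), is called not expressed with expression 0.
#'
#' @param ct_target,ct_ref Replicate Ct values (cycles); >= 1 each.
#' @param detect_limit Detection limit in cycles (default 35).
#' @return List with `delta_ct`, `expression` and `expressed`.
#' @export
delta_ct_expression <- function(ct_target, ct_ref, detect_limit = 35) {
  if (length(ct_target) < 1 || length(ct_ref) < 1)
    stop("need at least one replicate of target and reference")
  if (all(is.na(ct_ref))) stop("reference gene did not amplify")
  mt <- mean(ct_target, na.rm = TRUE)
  mr <- mean(ct_ref, na.rm = TRUE)
  if (all(is.na(ct_target)) || mt > detect_limit)
    return(list(delta_ct = NA_real_, expression = 0, expressed = FALSE))
  dct <- mt - mr
  list(delta_ct = dct, expression = 2^(-dct), expressed = TRUE)
}

#' Two-locus haplotype frequencies from unphased genotypes (EM)
#'
#' Utility estimator of the four two-locus haplotype frequencies from
#' unphased biallelic genotype counts (0/1/2 alternate-allele dosage),
#' resolving double heterozygotes by expectation-maximization. Provided for
#' unphased r2; the block caller itself requires phased input.
#'
#' @param g1,g2 Integer vectors of genotype dosages at the two loci.
#' @param max_iter,tol EM controls.
#' @return List with `freqs` (`p00`, `p01`, `p10`, `p11`), `D` and `r2`.
#' @export
em_haplotype_freqs <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  stopifnot(n >= 2, all(g1 %in% 0:2), all(g2 %in% 0:2))
  p1 <- mean(g1) / 2
  p2 <- mean(g2) / 2
  # haplotype freqs: h[ab], a allele at locus 1, b at locus 2 (1 = alt)
  h <- c(p00 = (1 - p1) * (1 - p2), p01 = (1 - p1) * p2,
         p10 = p1 * (1 - p2), p11 = p1 * p2)
  dh <- g1 == 1 & g2 == 1
  n_dh <- sum(dh)
  # fixed contributions from unambiguous genotypes (haplotype counts)
  cnt <- c(p00 = 0, p01 = 0, p10 = 0, p11 = 0)
  add <- function(cnt, a, k) { cnt[a] <- cnt[a] + k; cnt }
  for (i in which(!dh)) {
    a <- g1[i]; b <- g2[i]
    # each individual contributes two haplotypes; for non-double-het the
    # phase is determined
    ha <- c(rep(1, a), rep(0, 2 - a))
    hb <- c(rep(1, b), rep(0, 2 - b))
    # pair max with max (only one het at most, so pairing is unambiguous)
    for (k in 1:2)
      cnt <- add(cnt, paste0("p", ha[k], hb[k]), 1)
  }
  for (it in seq_len(max_iter)) {
    # E-step: split double hets between cis (00/11) and trans (01/10)
    pc <- h["p00"] * h["p11"]
    pt <- h["p01"] * h["p10"]
    w <- if (pc + pt > 0) pc / (pc + pt) else 0.5
    e <- cnt
    e["p00"] <- e["p00"] + n_dh * w
    e["p11"] <- e["p11"] + n_dh * w
    e["p01"] <- e["p01"] + n_dh * (1 - w)
    e["p10"] <- e["p10"] + n_dh * (1 - w)
    h_new <- e / sum(e)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  pa <- h["p10"] + h["p11"]
  pb <- h["p01"] + h["p11"]
  D <- h["p11"] - pa * pb
  r2 <- if (pa > 0 && pa < 1 && pb > 0 && pb < 1)
    as.numeric(D^2 / (pa * (1 - pa) * pb * (1 - pb))) else NA_real_
  list(freqs = h, D = as.numeric(D), r2 = r2)
}
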