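# SNP alignments from genotypes (heterozygous calls become missing data),
# Kimura 2-parameter distances, neighbor-joining trees and bootstrap
# support.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Build a SNP alignment from callsets or consensus haplotypes
#'
#' At each listed site, a homozygous high-confidence diploid call
#' contributes its allele symbol; heterozygous, low-confidence and no-call
#' sites become missing data (`NA`). Consensus inputs contribute their call
#' (`N` maps to missing). Positions absent from an input are filled from
#' the reference track (missing when no reference is available).
#'
#' @param inputs Named list of [diploid_callset()] and/or
#'   `ConsensusHaplotype` objects.
#' @param positions Sorted vector of site positions (0-based bp).
#' @param reference Optional [reference_track()].
#' @return Character matrix (taxa x sites) with `NA` for missing; class
#'   `SnpAlignment` attributes carry the positions.
#' @export
build_snp_alignment <- function(inputs, positions, reference = NULL) {
  stopifnot(length(inputs) >= 1)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- vapply(seq_along(inputs), function(i) {
      x <- inputs[[i]]
      if (inherits(x, "DiploidCallset")) x$sample_id
      else if (inherits(x, "ConsensusHaplotype")) x$name
      else paste0("taxon", i)
    }, "")
  ref_sym <- if (!is.null(reference))
    vapply(positions, function(p) ref_base_at(reference, p), "") else
      rep(NA_character_, length(positions))
  ref_sym[ref_sym == "N"] <- NA_character_
  rows <- lapply(inputs, function(x) {
    if (inherits(x, "DiploidCallset")) {
      i <- match(positions, x$calls$pos)
      sym <- ref_sym
      hit <- !is.na(i)
      a1 <- x$calls$a1[i[hit]]
      a2 <- x$calls$a2[i[hit]]
      conf <- x$calls$confidence[i[hit]]
      s <- ifelse(conf == "high" & a1 == a2 & a1 %in% BASES, a1,
                  NA_character_)
      sym[hit] <- s
      sym[pos_in_intervals(positions, x$nocall_regions)] <- NA_character_
      sym
    } else if (inherits(x, "ConsensusHaplotype")) {
      i <- match(positions, x$sites$pos)
      sym <- ref_sym
      hit <- !is.na(i)
      cal <- x$sites$call[i[hit]]
      sym[hit] <- ifelse(cal %in% BASES, cal, NA_character_)
      sym[pos_in_intervals(positions, x$nocall_regions)] <- NA_character_
      sym
    } else stop("unsupported input type: ", class(x)[1])
  })
  aln <- do.call(rbind, rows)
  rownames(aln) <- names(inputs)
  attr(aln, "positions") <- positions
  class(aln) <- c("SnpAlignment", class(aln))
  aln
}

#' Kimura 2-parameter distance between two symbol vectors
#'
#' Transition (`P`: purine-purine or pyrimidine-pyrimidine change) and
#' transversion (`Q`) proportions are computed over pairwise-complete
#' sites, and the distance is `-1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`. When
#' the log argument is non-positive the distance is saturated: `d = Inf`,
#' flagged.
#'
#' @param a,b Character vectors of A/C/G/T symbols (`NA` = missing).
#' @return List with `P`, `Q`, `n_compared`, `d`, `saturated`.
#' @export
k2p_distance <- function(a, b) {
  ok <- !is.na(a) & !is.na(b) & a %in% BASES & b %in% BASES
  n <- sum(ok)
  if (n < 1) stop("need at least one pairwise-complete site")
  a <- a[ok]; b <- b[ok]
  diffs <- a != b
  transition <- diffs & ((a %in% PURINES & b %in% PURINES) |
                           (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  P <- sum(transition) / n
  Q <- sum(diffs & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(P = P, Q = Q, n_compared = n, d = Inf, saturated = TRUE))
  list(P = P, Q = Q, n_compared = n,
       d = -0.5 * log(w1) - 0.25 * log(w2), saturated = FALSE)
}

#' Kimura 2-parameter distance matrix of an alignment
#'
#' @param aln A [build_snp_alignment()] matrix (taxa x sites).
#' @return Symmetric numeric matrix of K2P distances (`Inf` where
#'   saturated).
#' @export
k2p_matrix <- function(aln) {
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- k2p_distance(aln[i, ], aln[j, ])$d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; negative branch lengths are
#' clamped to zero (the tree carries a `clamped` attribute when any were).
#'
#' @param D Symmetric non-negative distance matrix with taxon dimnames
#'   (>= 3 taxa, all finite).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor-joining needs at least 3 taxa")
  if (any(!is.finite(D))) stop("distance matrix contains non-finite entries")
  if (any(D < 0)) stop("distance matrix contains negative entries")
  tree <- ape::nj(stats::as.dist(D))
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for the K2P/NJ tree of an alignment
#'
#' Resamples alignment columns with replacement (missing data travels with
#' its column), recomputes the K2P distance matrix and NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing the same split. Replicates whose
#' resampled distances are non-finite are skipped and excluded from the
#' denominator.
#'
#' @param aln A [build_snp_alignment()] matrix with >= 4 taxa.
#' @param n_reps Number of bootstrap replicates (default 500; 0 returns an
#'   empty table).
#' @param seed Integer seed.
#' @return List with `tree` (the original NJ tree, support as node
#'   labels), `support` (numeric per internal node, percent) and `n_used`
#'   (replicates evaluated).
#' @export
bootstrap_support <- function(aln, n_reps = 500, seed = NULL) {
  stopifnot(nrow(aln) >= 4)
  base_tree <- nj_tree(k2p_matrix(aln))
  if (n_reps == 0)
    return(list(tree = base_tree, support = numeric(0), n_used = 0L))
  with_seed(seed, {
    m <- ncol(aln)
    trees <- list()
    for (r in seq_len(n_reps)) {
      cols <- sample.int(m, m, replace = TRUE)
      D <- k2p_matrix(aln[, cols, drop = FALSE])
      if (any(!is.finite(D))) next
      trees[[length(trees) + 1L]] <- nj_tree(D)
    }
    n_used <- length(trees)
    if (n_used == 0)
      return(list(tree = base_tree, support = numeric(0), n_used = 0L))
    class(trees) <- "multiPhylo"
    counts <- ape::prop.clades(base_tree, trees, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / n_used
    base_tree$node.label <- formatC(support, format = "f", digits = 1)
    list(tree = base_tree, support = support, n_used = n_used)
  })
}

#' Write a tree to newick
#'
#' Branch lengths are written to 6 decimals; internal node labels (e.g.
#' bootstrap support) are preserved.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
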