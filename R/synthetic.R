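# Synthetic cohorts, population haplotype panels and qPCR plates with the
# statistical structure the analysis assumes, plus full ground truth.
#
# The generators plant structure directly (no coalescent machinery): a
# shared founder haplotype, Poisson-placed singleton variants with an
# optional hyper-variable cluster, dense heterozygous flanks, no-call
# tracts, phased block-haplotype panels and replicate Ct tables.

BASES <- c("A", "C", "G", "T")

# One global seed fans out to per-component child seeds so adding a
# generator never perturbs existing streams.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Parameters for the CEH cohort simulator
#'
#' Defaults emulate the structure of a near-fixed CEH cohort: three
#' MHC-homozygous individuals sharing one founder haplotype, sparse
#' singleton variants (8.6 SNVs / 100 kb, 99% heterozygous within their
#' carrier), an indel:SNV ratio of 52:290, founder-vs-reference divergence
#' of 2.2e-3 homozygous differences per bp, and an optional hyper-variable
#' cluster holding 72% of the variants in a 120-kb window.
#'
#' @param region_length Length of the conserved core (bp).
#' @param n_individuals Number of homozygous individuals (default 3).
#' @param snv_rate Expected intra-CEH SNVs per 100 kb of core.
#' @param het_fraction Fraction of planted variants heterozygous within
#'   their carrier; the rest are homozygous in one carrier.
#' @param indel_ratio Expected indel:SNV count ratio.
#' @param indel_len_range Inclusive range of indel lengths (bp), sampled
#'   uniformly.
#' @param cluster `NULL`, or `list(start, length, fraction)` placing
#'   `fraction` of the planted variants uniformly inside the window
#'   `[start, start+length)` (core-relative coordinates).
#' @param nocall_tracts Optional data.frame (`start`, `end`) of no-call
#'   tracts (region-relative), masked in every sample.
#' @param founder_divergence Homozygous founder-vs-reference differences per
#'   bp (shared by all individuals).
#' @param flank_length Length (bp) of heterozygous flanks added on each side
#'   of the core (0 disables flanks).
#' @param flank_het_rate Heterozygous calls per 100 kb per individual inside
#'   the flanks.
#' @param genotyping_error Per-site, per-individual probability of flipping
#'   an allele to a random other base.
#' @param chrom Chromosome label.
#' @param region_start 0-based start of the simulated region.
#' @param seed Integer seed (`NULL` leaves the RNG stream untouched).
#' @return An object of class `CehSimParams`.
#' @export
ceh_sim_params <- function(region_length = 3e6, n_individuals = 3,
                           snv_rate = 8.6, het_fraction = 0.99,
                           indel_ratio = 52 / 290,
                           indel_len_range = c(1, 10),
                           cluster = NULL, nocall_tracts = NULL,
                           founder_divergence = 2.2e-3,
                           flank_length = 0, flank_het_rate = 100,
                           genotyping_error = 0,
                           chrom = "chr6", region_start = 0, seed = NULL) {
  stopifnot(region_length > 0, n_individuals >= 1, snv_rate >= 0,
            het_fraction >= 0, het_fraction <= 1, indel_ratio >= 0,
            founder_divergence >= 0, flank_length >= 0,
            genotyping_error >= 0, genotyping_error <= 1)
  if (!is.null(cluster)) {
    stopifnot(all(c("start", "length", "fraction") %in% names(cluster)))
    if (cluster$fraction > 1 || cluster$fraction < 0)
      stop("cluster fraction must lie in [0, 1]")
    if (cluster$start < 0 || cluster$start + cluster$length > region_length)
      stop("cluster must lie inside the core region")
  }
  structure(list(region_length = region_length,
                 n_individuals = n_individuals, snv_rate = snv_rate,
                 het_fraction = het_fraction, indel_ratio = indel_ratio,
                 indel_len_range = indel_len_range, cluster = cluster,
                 nocall_tracts = as_intervals(nocall_tracts),
                 founder_divergence = founder_divergence,
                 flank_length = flank_length,
                 flank_het_rate = flank_het_rate,
                 genotyping_error = genotyping_error, chrom = chrom,
                 region_start = region_start, seed = seed),
            class = "CehSimParams")
}

rand_bases <- function(n) sample(BASES, n, replace = TRUE)

rand_other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(BASES, b), 1), "",
         USE.NAMES = FALSE)
}

#' Simulate a near-fixed CEH cohort with ground truth
#'
#' All individuals share one founder haplotype that differs from the
#' reference at Poisson-placed homozygous sites; on top of it, singleton
#' intra-CEH variants (SNVs and short indels) are planted at the requested
#' density, a configurable fraction of them inside a hyper-variable cluster
#' window, each carried by exactly one individual (heterozygous with
#' probability `het_fraction`, else homozygous). Optional dense heterozygous
#' flanks delimit the conserved core, no-call tracts mask all samples, and
#' per-site genotyping errors flip alleles at random.
#'
#' @param params A [ceh_sim_params()] object.
#' @return A list with elements `callsets` (list of [diploid_callset()]),
#'   `reference` (a sparse [reference_track()] over the planted sites) and
#'   `truth` (planted variants, founder sites, conserved-core bounds,
#'   cluster bounds and no-call tracts).
#' @export
simulate_ceh_cohort <- function(params) {
  stopifnot(inherits(params, "CehSimParams"))
  seeds <- derive_seeds(params$seed, 5)
  core_len <- params$region_length
  flank <- params$flank_length
  total_len <- core_len + 2 * flank
  r0 <- params$region_start
  region <- genomic_region(params$chrom, r0, r0 + total_len)
  core_start <- r0 + flank
  core_end <- core_start + core_len
  n_ind <- params$n_individuals
  ids <- sprintf("SIM%02d", seq_len(n_ind))

  # founder-vs-reference homozygous sites (shared by everyone)
  founder <- with_seed(seeds[[1]], {
    n_f <- stats::rpois(1, params$founder_divergence * core_len)
    pos <- sort(sample.int(core_len, min(n_f, core_len))) - 1 + core_start
    data.frame(pos = pos, ref = rand_bases(length(pos)))
  })
  founder$alt <- rand_other_base(founder$ref)

  # intra-CEH singleton variants
  planted <- with_seed(seeds[[2]], {
    lam_snv <- params$snv_rate * core_len / 1e5
    n_snv <- stats::rpois(1, lam_snv)
    n_indel <- stats::rpois(1, lam_snv * params$indel_ratio)
    n_tot <- n_snv + n_indel
    in_cluster <- if (!is.null(params$cluster))
      stats::runif(n_tot) < params$cluster$fraction else rep(FALSE, n_tot)
    pos <- integer(n_tot)
    avoid <- founder$pos
    for (i in seq_len(n_tot)) {
      repeat {
        p <- if (in_cluster[i])
          core_start + params$cluster$start + sample.int(params$cluster$length, 1) - 1
        else core_start + sample.int(core_len, 1) - 1
        if (!(p %in% avoid)) break
      }
      pos[i] <- p
      avoid <- c(avoid, p)
    }
    vtype <- c(rep("SNV", n_snv),
               sample(c("insertion", "deletion"), n_indel, replace = TRUE))
    ref <- rand_bases(n_tot)
    len <- sample(seq(params$indel_len_range[1], params$indel_len_range[2]),
                  n_tot, replace = TRUE)
    alt <- ifelse(vtype == "SNV", rand_other_base(ref),
           ifelse(vtype == "insertion",
                  paste0("ins:", vapply(len, function(l)
                    paste(rand_bases(l), collapse = ""), "")),
                  paste0("del:", len)))
    carrier <- sample(ids, n_tot, replace = TRUE)
    het <- stats::runif(n_tot) < params$het_fraction
    chrom_idx <- sample(0:1, n_tot, replace = TRUE)
    df <- data.frame(pos = pos, ref = ref, alt = alt, vtype = vtype,
                     carrier = carrier, het = het, chrom_idx = chrom_idx,
                     in_cluster = in_cluster)
    df[order(df$pos), , drop = FALSE]
  })
  rownames(planted) <- NULL

  # per-individual heterozygous flank variants
  flanks <- with_seed(seeds[[3]], {
    if (flank == 0) NULL else {
      out <- list()
      for (id in ids) {
        for (fs in c(r0, core_end)) {
          n <- stats::rpois(1, params$flank_het_rate * flank / 1e5)
          pos <- fs + sample.int(flank, min(n, flank)) - 1
          ref <- rand_bases(length(pos))
          out[[length(out) + 1L]] <- data.frame(
            pos = pos, ref = ref, alt = rand_other_base(ref), carrier = id)
        }
      }
      do.call(rbind, out)
    }
  })

  tracts <- clip_intervals(
    data.frame(start = params$nocall_tracts$start + r0,
               end = params$nocall_tracts$end + r0), region)

  # assemble per-individual callsets
  err_seed <- seeds[[4]]
  callsets <- with_seed(err_seed, lapply(ids, function(id) {
    rows <- list()
    if (nrow(founder))
      rows[[1]] <- data.frame(pos = founder$pos, ref = founder$ref,
                              a1 = founder$alt, a2 = founder$alt)
    mine <- planted[planted$carrier == id, , drop = FALSE]
    if (nrow(mine)) {
      a1 <- ifelse(mine$het & mine$chrom_idx == 1, mine$ref, mine$alt)
      a2 <- ifelse(mine$het & mine$chrom_idx == 0, mine$ref, mine$alt)
      rows[[length(rows) + 1L]] <- data.frame(pos = mine$pos, ref = mine$ref,
                                              a1 = a1, a2 = a2)
    }
    if (!is.null(flanks)) {
      fm <- flanks[flanks$carrier == id, , drop = FALSE]
      if (nrow(fm))
        rows[[length(rows) + 1L]] <- data.frame(pos = fm$pos, ref = fm$ref,
                                                a1 = fm$ref, a2 = fm$alt)
    }
    calls <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pos = numeric(0), ref = character(0), a1 = character(0),
                 a2 = character(0))
    calls <- calls[order(calls$pos), , drop = FALSE]
    calls <- calls[!duplicated(calls$pos), , drop = FALSE]
    if (params$genotyping_error > 0 && nrow(calls)) {
      for (col in c("a1", "a2")) {
        flip <- stats::runif(nrow(calls)) < params$genotyping_error
        snv <- flip & !is_indel_token(calls[[col]]) & calls[[col]] %in% BASES
        if (any(snv)) calls[[col]][snv] <- rand_other_base(calls[[col]][snv])
      }
    }
    if (nrow(tracts)) calls <- calls[!pos_in_intervals(calls$pos, tracts), ,
                                     drop = FALSE]
    calls$confidence <- rep("high", nrow(calls))
    calls$phased <- rep(FALSE, nrow(calls))
    diploid_callset(id, region, calls, nocall_regions = tracts)
  }))
  names(callsets) <- ids

  ref_sites <- rbind(founder[, c("pos", "ref")],
                     planted[, c("pos", "ref")],
                     if (!is.null(flanks)) flanks[, c("pos", "ref")])
  names(ref_sites) <- c("pos", "base")
  ref_sites <- ref_sites[!duplicated(ref_sites$pos), ]
  reference <- reference_track(region, sites = ref_sites)

  truth <- list(
    variants = planted[, c("pos", "ref", "alt", "vtype", "carrier", "het",
                           "in_cluster")],
    founder_sites = founder,
    conserved_region = genomic_region(params$chrom, core_start, core_end),
    cluster = if (!is.null(params$cluster))
      genomic_region(params$chrom, core_start + params$cluster$start,
                     core_start + params$cluster$start + params$cluster$length),
    nocall_tracts = tracts,
    params = params)
  list(callsets = callsets, reference = reference, truth = truth)
}

#' Simulate a dense SNP-panel callset with planted heterozygous tracts
#'
#' Emulates SNP-array-like data: evenly spaced sites, homozygous-reference
#' except inside planted heterozygous tracts (and at a low background
#' heterozygosity), the input expected by [roh_scan()]. The truth reports
#' the complement of the het tracts as the planted runs of homozygosity.
#'
#' @param region_length Total span (bp).
#' @param spacing Inter-site spacing (bp).
#' @param het_tracts data.frame (`start`, `end`), region-relative, where
#'   sites are heterozygous with probability `p_het_inside`.
#' @param p_het_inside,p_het_background Per-site heterozygosity inside and
#'   outside the tracts.
#' @param chrom,region_start Coordinates of the simulated region.
#' @param seed Integer seed.
#' @return List with `callset` (a [diploid_callset()]) and `truth`
#'   (`het_tracts`, `roh` = complement intervals, absolute coordinates).
#' @export
simulate_snp_panel <- function(region_length = 3e6, spacing = 1000,
                               het_tracts = NULL, p_het_inside = 0.5,
                               p_het_background = 5e-4, chrom = "chr6",
                               region_start = 0, seed = NULL) {
  region <- genomic_region(chrom, region_start, region_start + region_length)
  tracts <- clip_intervals(
    if (is.null(het_tracts)) empty_intervals() else
      data.frame(start = het_tracts$start + region_start,
                 end = het_tracts$end + region_start), region)
  with_seed(seed, {
    pos <- seq(region_start, region_start + region_length - 1, by = spacing)
    inside <- pos_in_intervals(pos, tracts)
    p <- ifelse(inside, p_het_inside, p_het_background)
    het <- stats::runif(length(pos)) < p
    ref <- rand_bases(length(pos))
    alt <- rand_other_base(ref)
    calls <- data.frame(pos = pos, ref = ref, a1 = ref,
                        a2 = ifelse(het, alt, ref),
                        confidence = "high", phased = FALSE)
    cs <- diploid_callset("PANEL", region, calls)
    # complement of tracts = planted ROH
    roh <- empty_intervals()
    cur <- region_start
    tr <- merge_intervals(tracts)
    for (i in seq_len(nrow(tr))) {
      if (tr$start[i] > cur)
        roh <- rbind(roh, data.frame(start = cur, end = tr$start[i]))
      cur <- tr$end[i]
    }
    if (cur < region$end)
      roh <- rbind(roh, data.frame(start = cur, end = region$end))
    list(callset = cs, truth = list(het_tracts = tracts, roh = roh))
  })
}

#' Perturb a callset with genotyping flips
#'
#' Produces an array-vs-sequencing style replicate: each allele of each SNV
#' call is flipped to a random other base with probability `flip_prob`.
#' Useful for concordance studies.
#'
#' @param callset A [diploid_callset()].
#' @param flip_prob Per-allele flip probability.
#' @param seed Integer seed.
#' @return A perturbed `DiploidCallset` with the same sample id.
#' @export
perturb_callset <- function(callset, flip_prob, seed = NULL) {
  with_seed(seed, {
    calls <- callset$calls
    for (col in c("a1", "a2")) {
      flip <- stats::runif(nrow(calls)) < flip_prob
      snv <- flip & calls[[col]] %in% BASES
      if (any(snv)) calls[[col]][snv] <- rand_other_base(calls[[col]][snv])
    }
    diploid_callset(callset$sample_id, callset$region, calls,
                    callset$nocall_regions)
  })
}

#' Simulate a phased population haplotype panel with planted LD blocks
#'
#' Within each block, every chromosome carries one of the block's listed
#' haplotypes, drawn intact according to the block's frequencies. Adjacent
#' blocks are coupled by a per-chromosome uniform draw (inverse-CDF
#' coupling) that is redrawn with probability `recomb_between` at each block
#' boundary: `recomb_between = 0` gives perfectly linked blocks,
#' `1` gives independent draws (free recombination).
#'
#' @param n_hap Number of chromosomes (rows).
#' @param blocks List of blocks, each `list(haps, freqs)` where `haps` is a
#'   character vector of equal-length `0`/`1` strings and `freqs` sums to 1.
#' @param recomb_between Crossover probability between adjacent blocks.
#' @param seed Integer seed.
#' @return List with `haplotypes` (an `n_hap` x n_sites 0/1 matrix with
#'   `phased` attribute) and `truth` (block index ranges, tables,
#'   `recomb_between`).
#' @export
simulate_population_haplotypes <- function(n_hap, blocks,
                                           recomb_between = 0, seed = NULL) {
  stopifnot(n_hap >= 1, length(blocks) >= 1)
  for (b in blocks) {
    if (length(b$haps) == 0) stop("zero haplotypes in a block")
    if (abs(sum(b$freqs) - 1) > 1e-8)
      stop("block haplotype frequencies must sum to 1")
    if (length(unique(nchar(b$haps))) != 1)
      stop("haplotypes within a block must have equal length")
  }
  with_seed(seed, {
    cols <- list()
    truth_blocks <- list()
    u <- stats::runif(n_hap)
    site0 <- 0L
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (bi > 1) {
        redraw <- stats::runif(n_hap) < recomb_between
        u[redraw] <- stats::runif(sum(redraw))
      }
      cum <- cumsum(b$freqs)
      idx <- findInterval(u, cum, left.open = TRUE) + 1L
      hmat <- do.call(rbind, lapply(strsplit(b$haps, ""), as.integer))
      cols[[bi]] <- hmat[idx, , drop = FALSE]
      truth_blocks[[bi]] <- list(start = site0 + 1L,
                                 end = site0 + ncol(hmat),
                                 haps = b$haps, freqs = b$freqs)
      site0 <- site0 + ncol(hmat)
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- sprintf("hap%05d", seq_len(n_hap))
    attr(mat, "phased") <- TRUE
    list(haplotypes = mat,
         truth = list(blocks = truth_blocks,
                      recomb_between = recomb_between))
  })
}

#' Simulate a qPCR plate around true integer copy numbers
#'
#' Target Ct values follow `ct_ref_mean - log2(copies / 2) + N(0, sd)` per
#' replicate (amplification efficiency 100%); the single-copy-per-chromosome
#' anchor gene `RP1` is emitted with the same noise. Zero copies are
#' recorded as the no-amplification sentinel `NA`.
#'
#' @param true_copies data.frame with a `sample` column and one integer
#'   column per target gene.
#' @param ct_ref_mean Mean anchor Ct (cycles).
#' @param sd Replicate Ct noise (cycles).
#' @param replicates Replicates per well (>= 1).
#' @param seed Integer seed.
#' @return Long-format data.frame (`sample`, `gene`, `replicate`, `ct`).
#' @export
simulate_qpcr_plate <- function(true_copies, ct_ref_mean = 24, sd = 0.1,
                                replicates = 3, seed = NULL) {
  stopifnot(is.data.frame(true_copies), "sample" %in% names(true_copies),
            sd >= 0)
  if (replicates < 1) stop("replicates must be >= 1")
  genes <- setdiff(names(true_copies), "sample")
  if (any(unlist(true_copies[genes]) < 0)) stop("copies must be >= 0")
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(true_copies))) {
      s <- true_copies$sample[i]
      for (g in c(genes, "RP1")) {
        copies <- if (g == "RP1") 2 else true_copies[[g]][i]
        for (r in seq_len(replicates)) {
          ct <- if (copies == 0) NA_real_ else
            ct_ref_mean - log2(copies / 2) + stats::rnorm(1, 0, sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, gene = g, replicate = r, ct = ct)
        }
      }
    }
    do.call(rbind, rows)
  })
}
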