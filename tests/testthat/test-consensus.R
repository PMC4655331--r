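region6 <- genomic_region("chr6", 0, 10000)

test_that("haploid splitting follows phase and the documented convention", {
  cs <- diploid_callset("S1", region6, data.frame(
    pos = c(10, 20, 30, 40),
    ref = c("A", "A", "C", "G"),
    a1 = c("A", "A", "C", "N"),
    a2 = c("A", "G", "T", "N"),
    confidence = c("high", "high", "high", "nocall"),
    phased = c(FALSE, TRUE, FALSE, FALSE)))
  hp <- split_haploids(cs)
  # hom site: both haploids carry the allele
  expect_equal(hp[[1]]$sites$allele[1], "A")
  expect_equal(hp[[2]]$sites$allele[1], "A")
  # phased het: split by phase, no flag
  expect_equal(hp[[1]]$sites$allele[2], "A")
  expect_equal(hp[[2]]$sites$allele[2], "G")
  expect_false(hp[[1]]$sites$phase_arbitrary[2])
  # unphased het: first listed allele to chromosome 0, flagged
  expect_equal(hp[[1]]$sites$allele[3], "C")
  expect_equal(hp[[2]]$sites$allele[3], "T")
  expect_true(hp[[1]]$sites$phase_arbitrary[3])
  # nocall propagates as N on both
  expect_equal(hp[[1]]$sites$allele[4], "N")
})

hap_of <- function(pos, ref, allele, confidence = "high", sample = "S",
                   idx = 0L, region = region6, nocall = NULL) {
  structure(list(source_sample = sample, chrom_index = idx, region = region,
                 sites = data.frame(pos = pos, ref = ref, allele = allele,
                                    confidence = rep(confidence,
                                                     length.out = length(pos)),
                                    phase_arbitrary = FALSE),
                 nocall_regions = cehkit:::as_intervals(nocall)),
            class = "HaploidSequence")
}

six_haploids <- function(alleles, ref = "A", pos = 100,
                         confidence = rep("high", 6)) {
  lapply(1:6, function(i)
    hap_of(pos, ref, alleles[i], confidence = confidence[i],
           sample = paste0("S", ceiling(i / 2)), idx = (i + 1) %% 2))
}

test_that("consensus applies the 2-of-6 support and no-call rules", {
  # 1-of-6 alternate: consensus keeps the majority, variant not called
  cons <- build_consensus(six_haploids(c("A", "A", "A", "A", "A", "G")))
  expect_equal(cons$sites$call, "A")
  expect_equal(cons$variants$support, 1)
  expect_false(cons$variants$called)
  # 2-of-6 alternate: still majority A, but the variant is called
  cons2 <- build_consensus(six_haploids(c("G", "G", "A", "A", "A", "A")))
  expect_equal(cons2$sites$call, "A")
  expect_true(cons2$variants$called)
  expect_equal(cons2$variants$support, 2)
  # two low-confidence inputs: position no-called
  cons3 <- build_consensus(six_haploids(
    rep("A", 6), confidence = c("low", "low", rep("high", 4))))
  expect_equal(cons3$sites$call, "N")
  # 3-3 tie: no-called and flagged ambiguous
  cons4 <- build_consensus(six_haploids(c("A", "A", "A", "G", "G", "G")))
  expect_equal(cons4$sites$call, "N")
  expect_true(cons4$sites$ambiguous)
  # identical inputs reproduce themselves with full support
  cons5 <- build_consensus(six_haploids(rep("G", 6)))
  expect_equal(cons5$sites$call, "G")
  expect_equal(cons5$sites$support, 6)
  expect_error(build_consensus(list(hap_of(1, "A", "A"),
                                    hap_of(1, "A", "A",
                                           region = genomic_region("chr6", 0, 5)))),
               "same region")
})

test_that("intra-CEH catalogue detects singletons and zygosity forms", {
  # one individual het A/G at pos 100; everyone else hom A
  css <- list(
    diploid_callset("S1", region6, data.frame(
      pos = 100, ref = "A", a1 = "A", a2 = "G", confidence = "high",
      phased = FALSE)),
    diploid_callset("S2", region6, data.frame(
      pos = numeric(0), ref = character(0), a1 = character(0),
      a2 = character(0), confidence = character(0), phased = logical(0))),
    diploid_callset("S3", region6, data.frame(
      pos = 200, ref = "C", a1 = "T", a2 = "T", confidence = "high",
      phased = FALSE)))
  haps <- unlist(lapply(css, split_haploids), recursive = FALSE)
  cat <- intra_ceh_catalog(haps, css)
  expect_equal(nrow(cat), 2)
  expect_equal(cat$zygosity_form,
               c("heterozygous-within-individual",
                 "homozygous-within-individual"))
  expect_equal(cat$support, c(1, 2))
  expect_equal(attr(cat, "comparable_length"), region_width(region6))
  # symmetric under sample reordering and chromosome swaps
  cat2 <- intra_ceh_catalog(rev(haps), rev(css))
  expect_equal(cat2[order(cat2$pos), c("pos", "alt", "support")],
               cat[order(cat$pos), c("pos", "alt", "support")],
               ignore_attr = TRUE)
  # identical haploids give an empty catalogue
  same <- unlist(lapply(css[2], split_haploids), recursive = FALSE)
  expect_equal(nrow(intra_ceh_catalog(c(same, same), css[2])), 0)
})

test_that("ambiguous positions leave the catalogue and shrink L", {
  css <- list(
    diploid_callset("S1", region6, data.frame(
      pos = c(100, 300), ref = c("A", "G"), a1 = c("G", "G"),
      a2 = c("G", "A"), confidence = c("low", "high"),
      phased = FALSE)),
    diploid_callset("S2", region6, data.frame(
      pos = numeric(0), ref = character(0), a1 = character(0),
      a2 = character(0), confidence = character(0), phased = logical(0)),
      nocall_regions = data.frame(start = 500, end = 700)))
  haps <- unlist(lapply(css, split_haploids), recursive = FALSE)
  cat <- intra_ceh_catalog(haps, css)
  # the low-confidence site is excluded, the high one kept
  expect_equal(cat$pos, 300)
  # L loses the tract (200 bp) and the one ambiguous listed position
  expect_equal(attr(cat, "comparable_length"),
               region_width(region6) - 200 - 1)
})

test_that("catalogue recovers planted truth exactly on noise-free cohorts", {
  sim <- simulate_ceh_cohort(ceh_sim_params(region_length = 1e6,
                                            seed = 900))
  haps <- unlist(lapply(sim$callsets, split_haploids), recursive = FALSE)
  cat <- intra_ceh_catalog(haps, sim$callsets)
  truth <- sim$truth$variants
  expect_setequal(cat$pos, truth$pos)
  m <- match(cat$pos, truth$pos)
  expect_equal(cat$alt, truth$alt[m])
  expect_equal(cat$zygosity_form == "heterozygous-within-individual",
               truth$het[m])
  # per-type totals match a brute-force recount from the callsets
  n_by_type <- table(cat$vtype)
  expect_equal(as.integer(n_by_type[names(table(truth$vtype))]),
               as.integer(table(truth$vtype)))
})

test_that("inter-haplotype catalogue counts differences over non-N positions", {
  mk_cons <- function(pos, ref, call, nocall = NULL, region = region6) {
    structure(list(name = "c", region = region, n_inputs = 6,
                   sites = data.frame(pos = pos, ref = ref, call = call,
                                      support = 6, ambiguous = FALSE),
                   variants = NULL,
                   nocall_regions = cehkit:::as_intervals(nocall)),
              class = "ConsensusHaplotype")
  }
  a <- mk_cons(c(100, 200, 300), c("A", "C", "G"), c("G", "C", "del:3"))
  b <- mk_cons(c(100, 400), c("A", "T"), c("A", "N"))
  out <- inter_haplotype_catalog(a, b)
  # SNV at 100 (G vs A), deletion at 300 (del vs reference), N at 400 skipped
  expect_equal(out$catalog$pos, c(100, 300))
  expect_equal(out$catalog$vtype, c("SNV", "deletion"))
  expect_equal(out$L, region_width(region6) - 1)
  # identical consensuses: no records, L = full span
  out2 <- inter_haplotype_catalog(a, a)
  expect_equal(nrow(out2$catalog), 0)
  expect_equal(out2$L, region_width(region6))
  # masked tracts shrink L; b's N at 400 falls inside the tract and is
  # not double-counted
  a2 <- mk_cons(100, "A", "G", nocall = data.frame(start = 0, end = 1000))
  out3 <- inter_haplotype_catalog(a2, b)
  expect_equal(out3$L, region_width(region6) - 1000)
  expect_error(inter_haplotype_catalog(
    a, mk_cons(1, "A", "A", region = genomic_region("chr7", 0, 10))),
    "disjoint")
})

test_that("divergence between simulated consensuses lands in the Poisson band", {
  # two independent founders diverged at 2.7e-3 over 1 Mb
  region <- genomic_region("chr6", 0, 1e6)
  set.seed(77)
  n <- rpois(1, 2.7e-3 * 1e6)
  pos <- sort(sample.int(1e6, n)) - 1
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  mk <- function(sites) structure(
    list(name = "x", region = region, n_inputs = 6, sites = sites,
         variants = NULL, nocall_regions = cehkit:::as_intervals(NULL)),
    class = "ConsensusHaplotype")
  a <- mk(data.frame(pos = pos, ref = ref, call = alt, support = 6,
                     ambiguous = FALSE))
  b <- mk(data.frame(pos = numeric(0), ref = character(0),
                     call = character(0), support = integer(0),
                     ambiguous = logical(0)))
  out <- inter_haplotype_catalog(a, b)
  band <- qpois(c(0.005, 0.995), 2700)
  expect_gte(nrow(out$catalog), band[1])
  expect_lte(nrow(out$catalog), band[2])
  expect_equal(nrow(out$catalog) / out$L, 2.7e-3, tolerance = 0.05)
})

test_that("shared-segment scan reproduces worked counts and brute force", {
  # identical vectors: one full segment
  q <- rep("A", 100)
  out <- shared_segment_scan(q, q)
  expect_equal(out$n_match, 100)
  expect_equal(out$n_total, 100)
  # the 1508-SNP configuration with two interior mismatches
  ref <- rep("C", 1508)
  q2 <- ref
  q2[c(400, 900)] <- "T"
  out2 <- shared_segment_scan(q2, ref, max_mismatch = 2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$n_match, 1506)
  expect_equal(out2$n_total, 1508)
  # three mismatches, budget 2: two maximal segments
  q3 <- ref[1:200]
  q3[c(50, 120, 180)] <- "T"
  out3 <- shared_segment_scan(q3, ref[1:200], max_mismatch = 2)
  expect_equal(nrow(out3), 2)
  expect_equal(out3$start_idx, c(1, 51))
  expect_equal(out3$end_idx, c(179, 200))
  # agreement with both references required when refB is present
  refB <- ref[1:100]
  refB[10] <- "G"
  out4 <- shared_segment_scan(rep("C", 100), ref[1:100], refB,
                              max_mismatch = 0)
  expect_equal(out4$start_idx, c(1, 11))
  expect_equal(out4$end_idx, c(9, 100))
  expect_error(shared_segment_scan(q, ref), "equal length")
})

test_that("shared-segment scan equals exhaustive enumeration", {
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 150
    match_ok <- runif(n) > 0.06
    q <- ifelse(match_ok, "A", "G")
    got <- shared_segment_scan(q, rep("A", n), max_mismatch = 2)
    want <- shared_segment_brute_force(match_ok, 2)
    expect_equal(as.matrix(got[, c("start_idx", "end_idx")]),
                 want, ignore_attr = TRUE)
  }
})
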