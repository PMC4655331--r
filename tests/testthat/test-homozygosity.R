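test_that("zygosity windows count and ratio variant calls correctly", {
  region <- genomic_region("chr6", 0, 15000)
  # window 1: 19 hom + 1 het -> ratio 0.95; window 2 empty; window 3 mixed
  pos <- c(seq(100, 2000, by = 100), 10050, 10060)
  n <- length(pos)
  ref <- rep("A", n)
  a1 <- rep("G", n)
  a2 <- rep("G", n)
  a2[20] <- "A"              # one het in window 1
  a1[n - 1] <- "A"           # het in window 3
  a2[n] <- "ins:TT"          # indel call in window 3
  cs <- make_callset(pos, ref, a1, a2, region = region)
  prof <- window_zygosity_profile(cs, window_size = 5000)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$n_hom[1], 19)
  expect_equal(prof$n_het[1], 1)
  expect_equal(prof$zygosity_ratio[1], 0.95)
  # empty window: sentinel NA ratio, zero counts
  expect_equal(prof$n_hom[2] + prof$n_het[2], 0)
  expect_true(is.na(prof$zygosity_ratio[2]))
  # indels excluded from the ratio by default, counted separately
  expect_equal(prof$n_indel[3], 1)
  expect_equal(prof$n_het[3], 1)
  profI <- window_zygosity_profile(cs, window_size = 5000,
                                   include_indels = TRUE)
  expect_equal(profI$n_het[3], 2)
  # conservation: window counts sum to callset totals
  expect_equal(sum(prof$n_snv) + sum(prof$n_indel), n)
})

test_that("hom-reference calls never count as variants", {
  cs <- make_callset(c(10, 20), c("A", "C"), c("A", "G"), c("A", "G"),
                     region = genomic_region("chr6", 0, 5000))
  prof <- window_zygosity_profile(cs)
  expect_equal(prof$n_hom, 1)  # only the C>G site
})

test_that("conserved stretches tolerate short failing runs and split on long ones", {
  mk_prof <- function(ratios) {
    n <- length(ratios)
    data.frame(chrom = "chr6", start = (0:(n - 1)) * 5000,
               end = (1:n) * 5000, n_hom = round(ratios * 20),
               n_het = round((1 - ratios) * 20),
               n_snv = 20, n_indel = 0, zygosity_ratio = ratios)
  }
  # one failure inside: a single spanning stretch
  st <- call_conserved_stretches(mk_prof(c(1, 1, 0.9, 1, 1)))
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start, st$end), c(0, 25000))
  expect_equal(st$n_failing_windows, 1)
  # run of 5 failures: two stretches
  st2 <- call_conserved_stretches(mk_prof(c(1, 1, 0.9, 0.9, 0.9, 0.9, 0.9,
                                            1, 1)))
  expect_equal(nrow(st2), 2)
  expect_equal(st2$start, c(0, 35000))
  expect_equal(st2$end, c(10000, 45000))
  # no-data windows pass
  p <- mk_prof(c(1, 1, 1))
  p$zygosity_ratio <- NA
  p$n_hom <- p$n_het <- p$n_snv <- 0
  expect_equal(nrow(call_conserved_stretches(p)), 1)
  # boundaries are trimmed to passing windows
  st3 <- call_conserved_stretches(mk_prof(c(0.5, 1, 1, 0.5)))
  expect_equal(c(st3$start, st3$end), c(5000, 15000))
  # idempotence under all-passing padding: interior bounds unchanged
  st4 <- call_conserved_stretches(mk_prof(c(1, 1, 0.5, 1, 1, 0.9, 1)))
  padded <- mk_prof(c(1, 1, 1, 1, 0.5, 1, 1, 0.9, 1, 1, 1))
  padded$start <- padded$start - 2 * 5000
  padded$end <- padded$end - 2 * 5000
  st5 <- call_conserved_stretches(padded)
  expect_equal(st5$end - st5$start, (st4$end - st4$start) + 4 * 5000)
  expect_error(call_conserved_stretches(mk_prof(c(1, 1))[c(1, 1), ]),
               "contiguous")
})

test_that("stretch caller recovers a planted conserved core within one window", {
  sim <- simulate_ceh_cohort(ceh_sim_params(
    region_length = 2e6, flank_length = 2e5, cluster = NULL, seed = 17))
  prof <- window_zygosity_profile(sim$callsets[[1]])
  st <- call_conserved_stretches(prof, min_length = 5e5)
  expect_equal(nrow(st), 1)
  core <- sim$truth$conserved_region
  expect_lte(abs(st$start - core$start), 5000)
  expect_lte(abs(st$end - core$end), 5000)
})

test_that("window counts conserve the callset variant totals on simulations", {
  sim <- simulate_ceh_cohort(ceh_sim_params(region_length = 5e5, seed = 23))
  for (cs in sim$callsets) {
    prof <- window_zygosity_profile(cs)
    expect_equal(sum(prof$n_snv) + sum(prof$n_indel), nrow(cs$calls))
  }
})

test_that("ROH scan handles trivial, gap and planted-tract cases", {
  region <- genomic_region("chr6", 0, 3e6)
  # fully homozygous 2 Mb with regular spacing: one segment spanning it
  pos <- seq(0, 2e6, by = 10000)
  cs <- make_callset(pos, rep("A", length(pos)), rep("A", length(pos)),
                     rep("A", length(pos)), region = region)
  seg <- roh_scan(cs)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(0, 2e6 + 1))
  # a 60-kb data gap splits the segment; sub-minimum pieces are dropped
  pos2 <- c(seq(0, 1.2e6, by = 10000), seq(1.26e6, 1.9e6, by = 10000))
  cs2 <- make_callset(pos2, rep("A", length(pos2)), rep("A", length(pos2)),
                      rep("A", length(pos2)), region = region)
  seg2 <- roh_scan(cs2)
  expect_equal(nrow(seg2), 1)   # right piece is 0.64 Mb < 1 Mb
  expect_equal(c(seg2$start, seg2$end), c(0, 1.2e6 + 1))
  seg2b <- roh_scan(cs2, min_length = 5e5)
  expect_equal(nrow(seg2b), 2)
})

test_that("ROH scan recovers a planted segment within 50 kb", {
  panel <- simulate_snp_panel(
    4e6, spacing = 1000,
    het_tracts = data.frame(start = c(0, 2.7e6), end = c(1.2e6, 4e6)),
    seed = 41)
  seg <- roh_scan(panel$callset)
  expect_equal(nrow(seg), 1)
  truth <- panel$truth$roh
  expect_lte(abs(seg$start - truth$start), 5e4)
  expect_lte(abs(seg$end - truth$end), 5e4)
})

test_that("ROH scan equals brute-force enumeration on small instances", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 120
    pos <- sort(sample.int(4e5, n))
    het <- runif(n) < 0.12
    ref <- rep("A", n)
    alt <- ifelse(het, "G", "A")
    cs <- make_callset(pos, ref, ref, alt,
                       region = genomic_region("chr6", 0, 5e5))
    got <- roh_scan(cs, window = 5e4, max_het_per_window = 3,
                    max_gap = 5e4, min_length = 1e5)
    want <- roh_brute_force(pos, het, 5e4, 3, 5e4, 1e5)
    expect_equal(got[, c("start", "end")],
                 as.data.frame(want), ignore_attr = TRUE)
  }
})

test_that("major allele frequency profile reports fixation, dips and ties", {
  h <- matrix("A", nrow = 31, ncol = 5)
  prof <- major_allele_frequency_profile(h)
  expect_true(all(prof$freq == 1))
  h[1:13, 3] <- "G"   # 18/31 A
  prof <- major_allele_frequency_profile(h)
  expect_equal(prof$freq[3], 18 / 31, tolerance = 1e-12)
  expect_equal(round(prof$freq[3], 4), 0.5806)
  h2 <- matrix(c("A", "A", "G", "G"), nrow = 4, ncol = 1)
  prof2 <- major_allele_frequency_profile(h2)
  expect_equal(prof2$freq, 0.5)
  expect_true(prof2$tie)
  expect_error(major_allele_frequency_profile(h[0, , drop = FALSE]), "row")
})

test_that("genotype concordance compares high-confidence unordered pairs", {
  region <- genomic_region("chr6", 0, 1e6)
  pos <- seq(1000, 200000, by = 1000)
  n <- length(pos)
  a <- make_callset(pos, rep("A", n), rep("A", n), rep("G", n),
                    region = region)
  # same genotypes with swapped allele order are concordant
  b <- make_callset(pos, rep("A", n), rep("G", n), rep("A", n),
                    region = region)
  expect_equal(genotype_concordance(a, b)$rate, 1)
  # one discordant site of 200
  calls <- b$calls
  calls$a1[5] <- "A"
  b2 <- diploid_callset("S1", region, calls)
  expect_equal(genotype_concordance(a, b2)$rate, 1 - 1 / n)
  # low-confidence sites are not compared
  calls$confidence[1:10] <- "low"
  b3 <- diploid_callset("S1", region, calls)
  cc <- genotype_concordance(a, b3)
  expect_equal(cc$n_compared, n - 10)
  expect_error(genotype_concordance(a, make_callset(1, "A", "A", "A",
                                                    sample_id = "OTHER")),
               "different samples")
})
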