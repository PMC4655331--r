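# a small plus-strand gene with known codons for the worked examples:
# CDS 30..45 covers codons GCT TGG AAA GCC ATG (Ala Trp Lys Ala Met)
worked_region <- genomic_region("chr6", 0, 2000)
worked_seq <- paste0(paste(rep("T", 30), collapse = ""),
                     "GCTTGGAAAGCCATG",
                     paste(rep("T", 2000 - 45), collapse = ""))
worked_ref <- reference_track(worked_region, seq = worked_seq)
worked_model <- gene_model("W", "chr6", "+", 20, 100,
                           exons = data.frame(start = 20, end = 100),
                           cds = data.frame(start = 30, end = 45))

test_that("coding SNVs classify by translated effect", {
  # GCT -> GCC at the third codon base: Ala -> Ala, synonymous
  expect_equal(annotate_variant(list(pos = 32, alt = "C", vtype = "SNV"),
                                list(worked_model), worked_ref),
               "coding-synonymous")
  # TGG -> TGA: Trp -> stop, nonsense
  expect_equal(annotate_variant(list(pos = 35, alt = "A", vtype = "SNV"),
                                list(worked_model), worked_ref),
               "coding-nonsense")
  # GCT -> GTT: Ala -> Val, missense
  expect_equal(annotate_variant(list(pos = 31, alt = "T", vtype = "SNV"),
                                list(worked_model), worked_ref),
               "coding-missense")
})

test_that("coding indels classify by frame effect", {
  expect_equal(annotate_variant(list(pos = 33, alt = "ins:AT",
                                     vtype = "insertion"),
                                list(worked_model), worked_ref),
               "coding-frameshift")
  expect_equal(annotate_variant(list(pos = 33, alt = "del:3",
                                     vtype = "deletion"),
                                list(worked_model), worked_ref),
               "coding-nonframeshift")
})

test_that("non-coding classes follow interval precedence", {
  av <- function(pos) annotate_variant(list(pos = pos, alt = "A",
                                            vtype = "SNV"),
                                       list(worked_model), worked_ref)
  expect_equal(av(25), "UTR5")       # exonic, before CDS, plus strand
  expect_equal(av(60), "UTR3")       # exonic, after CDS
  expect_equal(av(150), "intergenic")
  # 500 bp upstream of the TSS with a 1-kb promoter window -> promoter
  m2 <- gene_model("P", "chr6", "+", 1500, 1900,
                   exons = data.frame(start = 1500, end = 1900),
                   cds = data.frame(start = 1500, end = 1800))
  expect_equal(annotate_variant(list(pos = 1000, alt = "A", vtype = "SNV"),
                                list(m2), worked_ref), "promoter")
  # minus-strand promoter sits downstream of tx end
  m3 <- gene_model("M", "chr6", "-", 100, 400,
                   exons = data.frame(start = 100, end = 400),
                   cds = NULL, is_ncRNA = TRUE)
  expect_equal(annotate_variant(list(pos = 900, alt = "A", vtype = "SNV"),
                                list(m3), worked_ref), "promoter")
  expect_equal(annotate_variant(list(pos = 200, alt = "A", vtype = "SNV"),
                                list(m3), worked_ref), "ncRNA-exonic")
  # intron of a two-exon gene
  m4 <- gene_model("I", "chr6", "+", 1000, 1410,
                   exons = data.frame(start = c(1000, 1300),
                                      end = c(1099, 1402)),
                   cds = data.frame(start = c(1000, 1300),
                                    end = c(1099, 1402)))
  expect_equal(annotate_variant(list(pos = 1200, alt = "A", vtype = "SNV"),
                                list(m4), worked_ref), "intronic")
  # across genes, the highest-precedence class wins (coding beats promoter)
  expect_equal(annotate_variant(list(pos = 31, alt = "T", vtype = "SNV"),
                                list(worked_model, m3), worked_ref),
               "coding-missense")
})

test_that("random CDS variants agree with the brute-force translator", {
  skip_if_not_installed("seqinr")
  set.seed(202)
  seq <- random_seq(3000)
  region <- genomic_region("chr6", 0, 3000)
  ref <- reference_track(region, seq = seq)
  models <- list(
    gene_model("FWD", "chr6", "+", 100, 1400,
               exons = data.frame(start = c(150, 800), end = c(450, 1100)),
               cds = data.frame(start = c(150, 800), end = c(450, 1100))),
    gene_model("REV", "chr6", "-", 1600, 2900,
               exons = data.frame(start = c(1650, 2300),
                                  end = c(1950, 2600)),
               cds = data.frame(start = c(1650, 2300), end = c(1950, 2600))))
  cds_pos <- c(150:449, 800:1099, 1650:1949, 2300:2599)
  for (i in 1:200) {
    pos <- sample(cds_pos, 1)
    model <- if (pos < 1500) models[[1]] else models[[2]]
    refb <- substring(seq, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    got <- annotate_variant(list(pos = pos, alt = alt, vtype = "SNV"),
                            list(model), ref)
    expect_equal(got, annotate_oracle(pos, alt, model, seq),
                 info = sprintf("pos %d %s>%s (%s)", pos, refb, alt,
                                model$gene))
  }
})

test_that("variation binning conserves totals and ranks windows", {
  region <- genomic_region("chr6", 0, 500000)  # 100 windows of 5 kb
  # 10 variants all in one window
  cat1 <- data.frame(pos = seq(12000, 12900, by = 100), vtype = "SNV")
  bv <- bin_variation(cat1, region)
  expect_equal(sum(bv$windows$n_variants), 10)
  expect_equal(bv$histogram,
               data.frame(count = c(0L, 10L), n_windows = c(99L, 1L)))
  expect_equal(bv$top_decile_range, c(0, 10))
  expect_equal(bv$decile_share[1], 1)
  expect_equal(bv$decile_cumulative[10], 1)
  # uniform one per window: mean 1 and every decile holds 10%
  cat2 <- data.frame(pos = seq(0, 499999, by = 5000) + 100, vtype = "SNV")
  bv2 <- bin_variation(cat2, region)
  expect_equal(bv2$mean_per_window, 1)
  expect_equal(bv2$decile_share, rep(0.1, 10))
  # planted spikes dominate the top decile
  sim_cat <- data.frame(pos = c(sample(0:499999, 50),
                                sample(100000:104999, 200, replace = TRUE)),
                        vtype = "SNV")
  bv3 <- bin_variation(sim_cat, region)
  top_windows <- order(bv3$windows$n_variants, decreasing = TRUE)[1:10]
  expect_true(21 %in% top_windows)  # the spiked window 100-105 kb
})

test_that("low/high variation flags use strict bounds and merge runs", {
  region <- genomic_region("chr6", 0, 150000)  # 5 windows of 30 kb
  at <- function(w, n) rep(w * 30000 + 100, n)  # n variants in window w+1
  cat <- data.frame(pos = c(at(0, 0), at(1, 2), at(2, 15), at(3, 16),
                            at(4, 3)))
  fl <- flag_variation_regions(cat, region)
  # windows 1-2 LOW (0 and 2 < 3), window 3 unlabeled (15), window 4 HIGH
  # (16), window 5 unlabeled (3)
  expect_equal(fl$name, c("LOW", "HIGH"))
  expect_equal(fl$start, c(0, 90000))
  expect_equal(fl$end, c(60000, 120000))
})

test_that("diversity statistics reproduce the worked pi values", {
  d1 <- diversity_stats(238, 2720646)
  expect_equal(signif(d1$pi, 3), 8.75e-5)
  d2 <- diversity_stats(293, 4135945)
  expect_equal(signif(d2$pi, 3), 7.08e-5)
  expect_equal(d1$snv_per_100kb, 1e5 * d1$pi)
  expect_equal(diversity_stats(0, 1000)$pi, 0)
  expect_equal(diversity_stats(100, 1e6)$pi, 1e-4)
  expect_error(diversity_stats(10, 0), "L")
  # het fraction from a catalogue
  cat <- data.frame(vtype = c("SNV", "SNV", "insertion"),
                    zygosity_form = c("heterozygous-within-individual",
                                      "homozygous-within-individual",
                                      "heterozygous-within-individual"))
  expect_equal(diversity_stats(2, 1000, catalog = cat)$het_fraction, 2 / 3)
  expect_equal(diversity_stats(2, 1000, catalog = cat)$indel_per_100kb, 100)
})

test_that("star-genealogy ages reproduce the worked values and bounds", {
  expect_equal(estimate_age(238, 2720646)$age_years, 26500)
  expect_equal(estimate_age(293, 4135945)$age_years, 21460)
  expect_equal(estimate_age(0, 1e6)$age_years, 0)
  # age in years is always a multiple of the generation time
  for (S in c(1, 57, 500))
    expect_equal(estimate_age(S, 2e6)$age_years %% 20, 0)
  # monotone: increasing in S, decreasing in L
  expect_gte(estimate_age(300, 1e6)$T_gen, estimate_age(200, 1e6)$T_gen)
  expect_lte(estimate_age(200, 2e6)$T_gen, estimate_age(200, 1e6)$T_gen)
  expect_error(estimate_age(-1, 1e6), "S")
  expect_error(estimate_age(10, 1e6, age_model(mu = 0)), "mu")
})

test_that("age recovery from simulated cohorts lands in the Poisson band", {
  # plant variants at the density a 1000-generation-old star genealogy
  # implies: rate per 100 kb = n_chrom * mu * T * 1e5
  mu <- 1.1e-8
  T_true <- 1000
  L <- 3e6
  rate <- 6 * mu * T_true * 1e5
  sim <- simulate_ceh_cohort(ceh_sim_params(
    region_length = L, snv_rate = rate, indel_ratio = 0,
    founder_divergence = 0, seed = 321))
  haps <- unlist(lapply(sim$callsets, split_haploids), recursive = FALSE)
  cat <- intra_ceh_catalog(haps, sim$callsets)
  S <- sum(cat$vtype == "SNV")
  est <- estimate_age(S, attr(cat, "comparable_length"))
  band <- qpois(c(0.025, 0.975), 6 * mu * T_true * L)
  T_band <- floor(band / (6 * mu * L))
  expect_gte(est$T_gen, T_band[1])
  expect_lte(est$T_gen, T_band[2])
  # pi equals planted_count / L exactly
  expect_equal(diversity_stats(S, attr(cat, "comparable_length"))$pi,
               S / attr(cat, "comparable_length"))
})

test_that("pairwise nucleotide diversity matches a hand computation", {
  h <- rbind(c("A", "A", "C"), c("A", "G", "C"), c("A", "G", "T"))
  # pairs: 1-2 diff 1/3, 1-3 diff 2/3, 2-3 diff 1/3 -> mean 4/9
  expect_equal(pairwise_nucleotide_diversity(h), 4 / 9)
})
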