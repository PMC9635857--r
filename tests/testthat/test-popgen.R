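test_that("segregating sites use complete deletion", {
  same <- locus_alignment("l", c("ACGT", "ACGT"))
  expect_equal(segregating_sites(same), 0L)
  four <- locus_alignment("l", c("AAAAA", "AAAAT", "ATAAT", "ATCAT"))
  expect_equal(segregating_sites(four), 3L)
  gappy <- locus_alignment("l", c("AA", "AA", "-A", "TA"))
  expect_equal(segregating_sites(gappy), 0L)  # gapped column dropped
})

test_that("pi matches direct pairwise counting", {
  two <- locus_alignment("l", c(
    paste0("AAA", strrep("C", 97)), paste0("TTT", strrep("C", 97))
  ))
  expect_equal(nucleotide_diversity(two), 0.03)
  ident <- locus_alignment("l", rep(strrep("ACGT", 10), 4))
  expect_equal(nucleotide_diversity(ident), 0.0)
  set.seed(21)
  for (i in 1:5) {
    haps <- random_alignment(5, 50)
    aln <- locus_alignment("l", haps)
    expect_equal(nucleotide_diversity(aln), oracle_popgen(haps)$pi)
  }
})

test_that("Watterson's theta follows S / (a1 L)", {
  expect_equal(watterson_theta(3, 2, 100), 0.03)
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(10, 5, 1000), 10 / ((1 + 1/2 + 1/3 + 1/4) * 1000))
})

test_that("Tajima's D matches the brute-force oracle and its signs", {
  # all singletons: one derived allele per haplotype -> negative D
  n <- 10L
  haps <- vapply(seq_len(n), function(i) {
    s <- rep("A", 20)
    s[i] <- "T"
    paste(s, collapse = "")
  }, character(1))
  aln <- locus_alignment("l", haps)
  d_single <- tajima_d(aln)
  expect_lt(d_single, 0)
  expect_equal(d_single, oracle_popgen(haps)$tajima_d)

  # two balanced haplotype groups -> positive D
  bal <- locus_alignment("l", c(rep(strrep("A", 20), 5),
                                rep(paste0(strrep("T", 10), strrep("A", 10)),
                                    5)))
  expect_gt(tajima_d(bal), 0)

  expect_true(is.na(tajima_d(locus_alignment("l", rep("ACGT", 4)))))

  set.seed(31)
  for (i in 1:20) {
    haps <- random_alignment(sample(3:6, 1), sample(10:30, 1))
    aln <- locus_alignment("l", haps)
    orc <- oracle_popgen(haps)
    expect_equal(tajima_d(aln), orc$tajima_d, tolerance = 1e-12)
    expect_equal(segregating_sites(aln), orc$S)
  }
})

test_that("pi equals theta_w for n = 2 and both are order-invariant", {
  set.seed(41)
  for (i in 1:10) {
    haps <- random_alignment(2, 40)
    aln <- locus_alignment("l", haps)
    S <- segregating_sites(aln)
    expect_equal(nucleotide_diversity(aln),
                 watterson_theta(S, 2, 40))
    haps4 <- random_alignment(4, 30)
    a <- locus_alignment("l", haps4)
    b <- locus_alignment("l", rev(haps4))
    expect_equal(nucleotide_diversity(a), nucleotide_diversity(b))
    expect_equal(tajima_d(a), tajima_d(b))
  }
})

test_that("coding-site fractions follow Nei-Gojobori enumeration", {
  ann <- classify_coding_sites("TTT", data.frame(start = 1, end = 3))
  expect_equal(ann$per_position$syn_frac, c(0, 0, 1 / 3))
  expect_equal(ann$per_position$nonsyn_frac, c(1, 1, 2 / 3))

  # every codon's fractional sites sum to 3, against a from-scratch oracle
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  set.seed(51)
  codons <- sample(setdiff(names(gc), c("TAA", "TAG", "TGA")), 12)
  for (cd in codons) {
    ann <- classify_coding_sites(cd, data.frame(start = 1, end = 3))
    oracle_syn <- vapply(1:3, function(k) {
      alts <- setdiff(bases, substr(cd, k, k))
      mean(vapply(alts, function(b) {
        alt <- cd
        substr(alt, k, k) <- b
        gc[[alt]] != "*" && gc[[alt]] == gc[[cd]]
      }, logical(1)))
    }, numeric(1))
    expect_equal(ann$per_position$syn_frac, oracle_syn)
    expect_equal(sum(ann$per_position$syn_frac) +
                   sum(ann$per_position$nonsyn_frac), 3)
  }
  expect_error(classify_coding_sites("TTTT", data.frame(start = 1, end = 4)),
               "divisible by 3")
  expect_warning(classify_coding_sites("TAA", data.frame(start = 1, end = 3)),
                 "stop codon")
})

test_that("variant effects are called from the genetic code", {
  ref <- paste0("NNNNN", "TTAAAA", "NNNNN")
  ref <- gsub("N", "C", ref)
  ann <- classify_coding_sites(ref, data.frame(start = 6, end = 11))
  expect_equal(variant_effect(ann, ref, 8L, "G"), "synonymous")   # TTA->TTG
  expect_equal(variant_effect(ann, ref, 10L, "G"), "nonsynonymous") # AAA->AGA
  expect_equal(variant_effect(ann, ref, 2L, "G"), "noncoding")
})

test_that("class-filtered pi separates synonymous and nonsynonymous", {
  # coding-only locus of two codons; one syn diff and one nonsyn diff
  ref <- "TTAAAA"
  ann <- classify_coding_sites(ref, data.frame(start = 1, end = 6))
  haps <- c("TTAAAA", "TTGAGA")  # TTA->TTG syn, AAA->AGA nonsyn
  aln <- locus_alignment("cds", haps)
  pi_syn <- nucleotide_diversity(aln, ann, "synonymous")
  pi_non <- nucleotide_diversity(aln, ann, "nonsynonymous")
  cw <- sum(ann$per_position$syn_frac)
  expect_equal(as.numeric(pi_syn), 1 / cw)
  expect_equal(as.numeric(pi_non), 1 / (6 - cw))
  # ratio flag logic: here nonsyn density < syn density
  expect_lt(pi_non / pi_syn, 1)

  # silent pools noncoding with synonymous
  ref2 <- paste0("CCCC", ref)
  ann2 <- classify_coding_sites(ref2, data.frame(start = 5, end = 10))
  haps2 <- paste0(c("CCCC", "CACC"), c(ref, ref))
  aln2 <- locus_alignment("mix", haps2)
  pi_sil <- nucleotide_diversity(aln2, ann2, "silent")
  expect_equal(as.numeric(pi_sil), 1 / (4 + sum(ann2$per_position$syn_frac)))
  # empty class reports zero with a flag
  pi_syn0 <- nucleotide_diversity(
    locus_alignment("nc", c("AAAA", "AaTA")),
    classify_coding_sites("AAAA", data.frame(start = integer(),
                                             end = integer())),
    "synonymous"
  )
  expect_equal(as.numeric(pi_syn0), 0)
  expect_true(isTRUE(attr(pi_syn0, "empty_class")))
})

test_that("variant density reproduces bp-per-variant with rounding", {
  v <- data.frame(vtype = c(rep("SNP", 196), rep("indel", 40)))
  dens <- variant_density(v, 31872)
  expect_equal(dens$bp_per_snp, 162.6)
  expect_equal(dens$bp_per_indel, 796.8)
  expect_equal(variant_density(data.frame(vtype = "SNP"), 100)$bp_per_snp,
               100.0)
  no_snp <- variant_density(data.frame(vtype = "indel"), 100)
  expect_true(is.na(no_snp$bp_per_snp))
})

test_that("diversity_stats assembles a consistent per-locus row", {
  set.seed(61)
  haps <- random_alignment(6, 30)
  aln <- locus_alignment("locus1", haps)
  st <- diversity_stats(aln)
  orc <- oracle_popgen(haps)
  expect_equal(st$S, orc$S)
  expect_equal(st$pi_total, orc$pi)
  expect_equal(st$theta_w, orc$theta_w)
  expect_equal(st$tajima_d, orc$tajima_d)
  expect_true(is.na(st$pi_syn))
})
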