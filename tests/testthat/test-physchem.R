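test_that("molecular weight matches residue-mass sums and is additive", {
  expect_equal(molecular_weight("GG"), (2 * 57.0519 + 18.01528) / 1000,
               tolerance = 1e-9)
  expect_equal(molecular_weight("A"), (71.0788 + 18.01528) / 1000,
               tolerance = 1e-9)
  set.seed(4)
  for (i in 1:10) {
    s1 <- paste(sample(c("A", "K", "R", "D", "W", "G"), 8, TRUE),
                collapse = "")
    s2 <- paste(sample(c("E", "S", "T", "Y", "P"), 6, TRUE), collapse = "")
    expect_equal(
      molecular_weight(paste0(s1, s2)),
      molecular_weight(s1) + molecular_weight(s2) - 18.01528 / 1000,
      tolerance = 1e-9
    )
  }
  expect_warning(molecular_weight("AXA"), "X residues")
  expect_error(molecular_weight(""), "empty")
})

test_that("theoretical pI agrees with an independent root-finding oracle", {
  pka <- pka_bjellqvist()
  # oracle: uniroot on a from-scratch charge function
  oracle_pi <- function(s) {
    cnt <- table(factor(strsplit(s, "")[[1]], levels = LETTERS))
    q <- function(ph) {
      1 / (1 + 10^(ph - pka$nterm)) +
        sum(vapply(names(pka$side_pos), function(a) {
          cnt[[a]] / (1 + 10^(ph - pka$side_pos[[a]]))
        }, numeric(1))) -
        1 / (1 + 10^(pka$cterm - ph)) -
        sum(vapply(names(pka$side_neg), function(a) {
          cnt[[a]] / (1 + 10^(pka$side_neg[[a]] - ph))
        }, numeric(1)))
    }
    uniroot(q, c(0, 14), tol = 1e-10)$root
  }
  for (s in c("KKKKKKKKKK", "DDEEKK", "ACDEFGHIKLMNPQRSTVWY", "KRHDE")) {
    expect_equal(theoretical_pi(s, tol = 1e-10), oracle_pi(s),
                 tolerance = 1e-4)
  }
  expect_gt(theoretical_pi("KKKKKKKKKK"), 10)
  # only termini ionize: pI strictly between the terminal pKa values
  pi_ala <- theoretical_pi("AAAA")
  expect_gt(pi_ala, pka$cterm)
  expect_lt(pi_ala, pka$nterm)
})

test_that("pI is composition-only and monotone in acidic residues", {
  set.seed(9)
  for (i in 1:10) {
    s <- paste(sample(c("A", "K", "R", "D", "E", "H", "C", "Y", "G"),
                      20, TRUE), collapse = "")
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(theoretical_pi(s), theoretical_pi(perm), tolerance = 1e-3)
    expect_lte(theoretical_pi(paste0(s, "D")), theoretical_pi(s) + 1e-3)
  }
})

test_that("lysine content reproduces the tabulated percentages", {
  ntd <- paste0(strrep("K", 10), strrep("A", 54))    # 64 aa, 10 K
  gh1 <- paste0(strrep("K", 14), strrep("A", 56))    # 70 aa, 14 K
  ctd <- paste0(strrep("K", 48), strrep("A", 119))   # 167 aa, 48 K
  expect_equal(lysine_content(ntd), 15.6)
  expect_equal(lysine_content(gh1), 20.0)
  expect_equal(lysine_content(ctd), 28.7)
  expect_equal(lysine_content(paste0(ntd, gh1, ctd)), 23.9)
  expect_equal(lysine_content("KKKK"), 100.0)
  expect_equal(lysine_content("AAAA"), 0.0)
  expect_true(is.na(lysine_content("")))
})

test_that("integer net charge counts K/R against D/E only", {
  expect_equal(net_charge("KKRDE"), 1L)
  expect_equal(net_charge("AAAA"), 0L)
  expect_equal(net_charge("HHHH"), 0L)  # His excluded
  # 167-aa tail with 48 K, 10 R, 3 D, 2 E -> +53
  ctd <- paste0(strrep("K", 48), strrep("R", 10), strrep("D", 3),
                strrep("E", 2), strrep("A", 104))
  expect_equal(net_charge(ctd), 53L)
})

test_that("charge profile slides outward from the GH1 boundary", {
  gh1 <- strrep("G", 70)
  mk <- function(ntd, ctd) {
    fx <- make_protein("cp", ntd, gh1, ctd)
    list(part = partition_protein(fx$protein, fx$hits),
         res = fx$protein$residues)
  }
  # whole-region window: single sum equal to the region net charge
  x <- mk("AAAA", strrep("K", 20))
  cp <- charge_profile(x$part, x$res, "CTD")
  expect_equal(cp$sums, 20L)
  expect_equal(cp$frac_positive, 1.0)
  expect_equal(cp$sums[1], net_charge(strrep("K", 20)))

  x <- mk("AAAA", strrep("K", 25))
  expect_length(charge_profile(x$part, x$res, "CTD")$sums, 6L)

  x <- mk("AAAA", paste0(strrep("K", 10), strrep("D", 10), strrep("K", 10)))
  cp <- charge_profile(x$part, x$res, "CTD")
  expect_length(cp$sums, 11L)
  expect_equal(cp$min_sum, 0L)
  expect_equal(cp$sums[6], 0L)  # centered window: 5K 10D 5K

  # NTD orientation: first window must abut the GH1 domain
  x <- mk(paste0(strrep("D", 10), strrep("K", 20)), strrep("K", 30))
  cpn <- charge_profile(x$part, x$res, "NTD")
  expect_equal(cpn$sums[1], 20L)     # boundary window is all K
  expect_equal(cpn$sums[length(cpn$sums)], 0L)  # distal window: 10 D + 10 K
  expect_error(charge_profile(
    partition_protein(list(id = "q", residues = strrep("A", 63)),
                      data.frame(protein_id = "q", domain_name = "GH1",
                                 start = 1L, end = 63L,
                                 evalue = NA_real_)),
    strrep("A", 63), "NTD"
  ), "has no NTD")
})

test_that("profile panel is internally consistent", {
  fx <- make_protein(
    "panel",
    paste0(strrep("K", 10), strrep("A", 54)),
    paste0(strrep("K", 14), strrep("G", 56)),
    paste0(strrep("K", 48), strrep("R", 10), strrep("D", 3),
           strrep("E", 2), strrep("A", 104))
  )
  prof <- physchem_profile(fx$protein, partition_protein(fx$protein, fx$hits))
  expect_equal(prof$length$total, 301L)
  expect_equal(
    prof$net_charge$total,
    prof$net_charge$ntd + sum(prof$net_charge$gh1) + prof$net_charge$ctd
  )
  # length-weighted region lysine percentages reproduce the total within
  # rounding of the printed (1-decimal) values
  w <- c(prof$length$ntd, prof$length$gh1, prof$length$ctd)
  pct <- c(prof$lysine_pct$ntd, prof$lysine_pct$gh1, prof$lysine_pct$ctd)
  expect_equal(sum(w * pct) / sum(w), prof$lysine_pct$total,
               tolerance = 0.1)
  expect_gt(prof$mw_kda, 0)
  expect_true(prof$pi > 0 && prof$pi < 14)
})
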