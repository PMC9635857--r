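planted_inputs <- function() {
  g <- gen_proteome(1L, 1L, 0L, 0L, seed = 42L)
  rep <- classify_proteome(g$records, g$hits, g$gh1_alignment,
                           g$reference_id)
  list(gen = g, report = rep)
}

test_that("verdict logic combines the criteria as specified", {
  x <- planted_inputs()
  expect_equal(x$report$verdict[x$gen$truth$label == "H1"], "H1")
  # Myb architecture has precedence even with perfect binding sites
  arch <- data.frame(protein_id = "m", group = "GH1_Myb", n_gh1 = 1L,
                     has_myb = TRUE, n_at_hooks = 0L)
  prof <- list(protein_id = "m",
               lysine_pct = list(ctd = 30.0), net_charge = list(ctd = 40L))
  charge <- structure(list(protein_id = "m", min_sum = 5L),
                      class = "charge_profile")
  sites <- structure(list(protein_id = "m", conserved_count = 10L),
                     class = "conservation_report")
  call <- classify_h1(arch, prof, charge, sites)
  expect_equal(call$verdict, "GH1_Myb")
  expect_false(call$architecture_ok)

  # clade-III-like values: lysine 10.7%, charge +23, uneven profile
  arch3 <- data.frame(protein_id = "m", group = "typical_H1_candidate",
                      n_gh1 = 1L, has_myb = FALSE, n_at_hooks = 0L)
  prof3 <- list(protein_id = "m",
                lysine_pct = list(ctd = 10.7), net_charge = list(ctd = 23L))
  charge3 <- structure(list(protein_id = "m", min_sum = -3L),
                       class = "charge_profile")
  sites3 <- structure(list(protein_id = "m", conserved_count = 3L),
                      class = "conservation_report")
  call3 <- classify_h1(arch3, prof3, charge3, sites3)
  expect_equal(call3$verdict, "other")
  expect_false(call3$ctd_lysine_ok)
  expect_true(call3$ctd_charge_ok)

  # absent CTD can never be H1
  call_noctd <- classify_h1(arch3, prof3, NULL, sites3)
  expect_false(call_noctd$charge_evenness_ok)
  expect_error(
    classify_h1(arch3, list(protein_id = "other",
                            lysine_pct = list(ctd = 1),
                            net_charge = list(ctd = 1)),
                NULL, sites3),
    "mismatched"
  )
})

test_that("raising any threshold never converts non-H1 into H1", {
  x <- planted_inputs()
  g <- x$gen
  base <- classify_proteome(g$records, g$hits, g$gh1_alignment,
                            g$reference_id)
  stricter <- list(
    h1_criteria(ctd_lys_min_pct = 35),
    h1_criteria(ctd_net_charge_min = 60L),
    h1_criteria(min_window_sum_min = 10L),
    h1_criteria(binding_min = 10L)
  )
  for (crit in stricter) {
    rep2 <- classify_proteome(g$records, g$hits, g$gh1_alignment,
                              g$reference_id, criteria = crit)
    became_h1 <- rep2$verdict == "H1" & base$verdict != "H1"
    expect_false(any(became_h1))
  }
})

test_that("p-distance uses pairwise deletion", {
  aln <- alignment_block(c("a", "b", "c"),
                         c("AAAA", "TTTT", "AAAA"), "nucleotide")
  expect_equal(p_distance(aln, "a", "c"), 0.0)
  expect_equal(p_distance(aln, "a", "b"), 1.0)
  gap <- alignment_block(c("a", "b"), c("A-CD", "AXC-"), "protein")
  expect_equal(p_distance(gap, "a", "b"), 0.0)  # columns 1 and 3 compared
  allgap <- alignment_block(c("a", "b"), c("A--", "-AA"), "protein")
  expect_error(p_distance(allgap, "a", "b"), "no comparable columns")
})

test_that("neighbor joining recovers quartets and small trees exactly", {
  # hand-built additive quartet: ((A,B),(C,D)) with internal edge 3
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 7
  d["A", "D"] <- d["D", "A"] <- 8
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 3
  tr <- nj_tree(d)
  split <- oracle_quartet_split(d)
  splits <- tree_splits(tr)
  expect_true(any(vapply(splits, function(s) {
    identical(s, sort(split[[1]])) || identical(s, sort(split[[2]]))
  }, logical(1))))
  # branch lengths reproduce the additive distances
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]),
               unname(d), tolerance = 1e-9)

  # ultrametric 3-taxon: lengths are half-distances
  d3 <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), c(1, 1, 1))

  # all-zero matrix: star with zero lengths
  d0 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t0 <- nj_tree(d0)
  expect_true(all(t0$edge.length == 0))

  bad <- d
  bad[1, 2] <- 99
  expect_error(nj_tree(bad), "not symmetric")
})

test_that("neighbor joining is exact on random additive 4-6 taxon trees", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.05
    d <- ape::cophenetic.phylo(tr)
    est <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(est, ape::unroot(tr))), 0)
    expect_equal(unname(ape::cophenetic.phylo(est)[rownames(d), colnames(d)]),
                 unname(d), tolerance = 1e-8)
  }
})

test_that("variant assignment picks the nearest labeled group", {
  base <- strrep("ACDEFGHIKL", 10)
  mutate <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(a) {
      sample(setdiff(c("A", "C", "D", "E", "F"), a), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  refs <- c(h12_a = mutate(base, 30, 1), h12_b = mutate(base, 32, 2),
            h13_a = mutate(base, 60, 3), h13_b = mutate(base, 58, 4))
  query_exact <- refs[["h13_a"]]
  query_mut <- mutate(refs[["h12_a"]], 5, 5)  # 5% substitutions
  aln <- alignment_block(
    c(names(refs), "q1", "q2"), c(unname(refs), query_exact, query_mut)
  )
  labels <- c(h12_a = "H1.2", h12_b = "H1.2", h13_a = "H1.3",
              h13_b = "H1.3")
  a1 <- assign_variant(aln, "q1", labels)
  expect_equal(a1$variant, "H1.3")
  expect_gt(a1$margin, 0)
  expect_false(a1$ambiguous)
  a2 <- assign_variant(aln, "q2", labels)
  expect_equal(a2$variant, "H1.2")

  # constructed tie -> ambiguous
  tie <- alignment_block(c("r1", "r2", "q"), c("AAAA", "TTTT", "AATT"))
  at <- assign_variant(tie, "q", c(r1 = "g1", r2 = "g2"))
  expect_true(at$ambiguous)
  expect_equal(at$margin, 0)
  expect_error(assign_variant(tie, "q", character(0)), "no labeled")
})
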