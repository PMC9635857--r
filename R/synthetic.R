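# Synthetic-data generators.  Each is a pure function of its parameters and
# seed (a private RNG stream is used; global RNG state is untouched), and
# every generated object satisfies the invariants of the consuming module.

# background alphabets: no R anywhere (so no spurious R-G-R-P cores) and no
# K/H outside deliberately planted positions where basicity matters
BG_NEUTRAL <- c("A", "S", "T", "V", "L", "I", "P", "G", "Q", "N", "F", "M")
BG_TAIL_NEUTRAL <- c("A", "S", "P", "T", "V")  # no acidic, no basic

# a tail with `frac_k` lysines planted at a fixed stride with jitter, so
# positive charge is spread evenly (every 20-aa window carries several K)
even_lysine_tail <- function(len, frac_k = 0.30) {
  stride <- max(round(1 / frac_k), 2L)
  s <- sample(BG_TAIL_NEUTRAL, len, replace = TRUE)
  pos <- seq(1L, len, by = stride)
  jitter <- sample(c(0L, 0L, 1L), length(pos), replace = TRUE)
  pos <- pmin(pos + jitter, len)
  s[pos] <- "K"
  paste(s, collapse = "")
}

# weakly/negatively charged tail: few lysines, an acidic patch in the middle
acidic_patch_tail <- function(len, frac_k = 0.08) {
  s <- sample(BG_TAIL_NEUTRAL, len, replace = TRUE)
  nk <- max(round(frac_k * len), 1L)
  s[sample.int(len, nk)] <- "K"
  patch_len <- max(10L, round(len / 3))
  from <- max(1L, round(len / 2) - patch_len %/% 2L)
  idx <- from:min(len, from + patch_len - 1L)
  s[idx] <- sample(c("D", "E"), length(idx), replace = TRUE)
  paste(s, collapse = "")
}

# GH1 domain of length 67-71 with basic residues planted at a chosen subset
# of the ten canonical binding-site positions (his at site 1, K/R elsewhere)
gh1_domain <- function(n_basic_sites) {
  len <- sample(67:71, 1L)
  s <- sample(BG_NEUTRAL, len, replace = TRUE)
  sites <- h1_binding_sites()$position
  planted <- sites[seq_len(n_basic_sites)]
  s[sites] <- "N"  # non-basic baseline at every site position
  for (p in planted) {
    s[p] <- if (p == 2L) "H" else sample(c("K", "R"), 1L)
  }
  paste(s, collapse = "")
}

#' Generate a proteome with planted architecture labels
#'
#' Builds a synthetic proteome mimicking the contrasts between true linker
#' histones and the GH1-Myb / GH1-HMGA groups: H1-like proteins get an NTD
#' of 20-70 aa, a GH1 domain with all ten basic binding sites planted, and
#' a CTD of 77-170 aa with ~30% lysine spread evenly (every 20-aa window
#' positive); Myb-like proteins carry an extra Myb hit in a long NTD and a
#' weakly charged CTD with acidic patches and 6/10 sites; HMGA-like
#' proteins carry 3-6 planted `KRPRGRPKK` AT-hooks and mixed weak charge;
#' decoys keep at most 3 basic sites and an uneven tail.  Identical seeds
#' give identical output.
#'
#' @param n_h1,n_myb,n_hmga,n_decoy counts per planted class.
#' @param seed integer seed.
#' @return list of class `proteome_truth`: `records` (a `seq_set`), `hits`
#'   (domain table), `truth` (data.frame `protein_id`, `label`),
#'   `gh1_alignment` (an `alignment_block` of the GH1 domains, `NULL` if
#'   fewer than 2 proteins), `reference_id` (first H1-like protein, else
#'   first protein), `params`.
#' @export
gen_proteome <- function(n_h1 = 5L, n_myb = 4L, n_hmga = 3L, n_decoy = 1L,
                         seed = 1L) {
  total <- n_h1 + n_myb + n_hmga + n_decoy
  check_that(total >= 1L, "need at least one protein")
  with_local_seed(seed, {
    labels <- rep(c("H1", "GH1_Myb", "GH1_HMGA", "decoy"),
                  c(n_h1, n_myb, n_hmga, n_decoy))
    ids <- sprintf("SYN%02dT%04d", seq_along(labels), seq_along(labels) * 37L)
    recs <- vector("list", total)
    hits <- list()
    gh1_seqs <- character(total)
    for (i in seq_along(labels)) {
      lab <- labels[i]
      gh1 <- switch(lab,
        H1 = gh1_domain(10L),
        GH1_Myb = gh1_domain(6L),
        GH1_HMGA = gh1_domain(3L),
        decoy = gh1_domain(sample(2:3, 1L))
      )
      gh1_seqs[i] <- gh1
      ntd <- switch(lab,
        H1 = even_lysine_tail(sample(20:70, 1L), frac_k = 0.18),
        GH1_Myb = paste(sample(BG_NEUTRAL, sample(100:130, 1L),
                               replace = TRUE), collapse = ""),
        GH1_HMGA = paste(sample(BG_TAIL_NEUTRAL, sample(10:30, 1L),
                                replace = TRUE), collapse = ""),
        decoy = paste(sample(BG_NEUTRAL, sample(30:60, 1L),
                             replace = TRUE), collapse = "")
      )
      ctd <- switch(lab,
        H1 = even_lysine_tail(sample(77:170, 1L), frac_k = 0.30),
        GH1_Myb = acidic_patch_tail(sample(90:120, 1L)),
        GH1_HMGA = hmga_tail(sample(3:6, 1L)),
        decoy = acidic_patch_tail(sample(80:120, 1L), frac_k = 0.12)
      )
      seqs <- paste0(ntd, gh1, ctd)
      recs[[i]] <- data.frame(
        id = ids[i], residues = seqs,
        description = sprintf("synthetic %s", lab), stringsAsFactors = FALSE
      )
      g_start <- nchar(ntd) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        protein_id = ids[i], domain_name = "GH1",
        start = g_start, end = g_start + nchar(gh1) - 1L,
        evalue = 1e-20, stringsAsFactors = FALSE
      )
      if (lab == "GH1_Myb") {
        hits[[length(hits) + 1L]] <- data.frame(
          protein_id = ids[i], domain_name = "Myb",
          start = 5L, end = 55L, evalue = 1e-10, stringsAsFactors = FALSE
        )
      }
    }
    records <- do.call(rbind, recs)
    class(records) <- c("seq_set", "data.frame")
    hits <- do.call(rbind, hits)
    aln <- NULL
    if (total >= 2L) {
      w <- max(nchar(gh1_seqs))
      padded <- vapply(gh1_seqs, function(s) {
        paste0(s, strrep("-", w - nchar(s)))
      }, character(1), USE.NAMES = FALSE)
      aln <- alignment_block(ids, padded, "protein")
    }
    structure(
      list(
        records = records, hits = hits,
        truth = data.frame(protein_id = ids, label = labels,
                           stringsAsFactors = FALSE),
        gh1_alignment = aln,
        reference_id = if (n_h1 > 0L) ids[1] else ids[1],
        params = list(n_h1 = n_h1, n_myb = n_myb, n_hmga = n_hmga,
                      n_decoy = n_decoy, seed = seed)
      ),
      class = "proteome_truth"
    )
  })
}

# CTD with `n_hooks` planted AT-hooks separated by neutral/acidic spacers
hmga_tail <- function(n_hooks) {
  hook <- "KRPRGRPKK"
  spacer <- function() {
    paste(sample(c(BG_TAIL_NEUTRAL, "D", "E"), sample(8:16, 1L),
                 replace = TRUE), collapse = "")
  }
  parts <- character(2L * n_hooks + 1L)
  parts[1] <- spacer()
  for (i in seq_len(n_hooks)) {
    parts[2L * i] <- hook
    parts[2L * i + 1L] <- spacer()
  }
  paste(parts, collapse = "")
}

#' Simulate a neutral coalescent haplotype sample (infinite sites)
#'
#' Kingman coalescent: while k lineages remain, an exponential waiting time
#' with rate k(k-1)/2 (units of 2N generations) separates merges of a
#' uniformly chosen pair.  The mutation count is Poisson(theta/2 x total
#' branch length); each mutation falls on a branch with probability
#' proportional to its length and at a fresh position in 1..L (infinite
#' sites mapped into L; positions are drawn without replacement, i.e.
#' collisions are re-drawn).  For n = 2, E\[pairwise differences\] = theta.
#'
#' @param n haplotypes (>= 2).
#' @param L locus length in bp.
#' @param theta per-locus scaled mutation rate (> 0).
#' @param seed integer seed.
#' @return list of class `coalescent_sample`: `alignment` (a
#'   `locus_alignment`), `theta`, `total_branch_length`, `n_mutations`,
#'   `positions`, `seed`.
#' @export
gen_coalescent <- function(n, L, theta, seed = 1L) {
  check_that(n >= 2L, "need n >= 2")
  check_that(L >= 1L, "need L >= 1")
  check_that(theta > 0, "theta must be > 0")
  with_local_seed(seed, {
    # active lineages: leaf sets + birth times
    leafsets <- as.list(seq_len(n))
    birth <- rep(0, n)
    t_now <- 0
    branches <- list()
    blen <- numeric()
    while (length(leafsets) > 1L) {
      k <- length(leafsets)
      t_now <- t_now + stats::rexp(1L, rate = k * (k - 1) / 2)
      pair <- sample.int(k, 2L)
      for (idx in pair) {
        branches[[length(branches) + 1L]] <- leafsets[[idx]]
        blen <- c(blen, t_now - birth[idx])
      }
      merged <- c(leafsets[[pair[1]]], leafsets[[pair[2]]])
      leafsets <- c(leafsets[-pair], list(merged))
      birth <- c(birth[-pair], t_now)
    }
    total_len <- sum(blen)
    n_mut <- stats::rpois(1L, theta / 2 * total_len)
    check_that(n_mut <= L,
      "theta too large: %d mutations cannot occupy %d distinct positions",
      n_mut, L)
    positions <- if (n_mut > 0L) sort(sample.int(L, n_mut)) else integer()
    haps <- matrix("A", nrow = n, ncol = L)
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (j in seq_len(L)) haps[, j] <- ref[j]
    if (n_mut > 0L) {
      mut_branch <- sample.int(length(blen), n_mut, replace = TRUE,
                               prob = blen)
      for (m in seq_len(n_mut)) {
        p <- positions[m]
        carriers <- branches[[mut_branch[m]]]
        derived <- sample(setdiff(c("A", "C", "G", "T"), ref[p]), 1L)
        haps[carriers, p] <- derived
      }
    }
    structure(
      list(
        alignment = locus_alignment(
          sprintf("coalescent_seed%d", seed),
          apply(haps, 1L, paste, collapse = "")
        ),
        theta = theta, total_branch_length = total_len,
        n_mutations = n_mut, positions = positions, seed = seed
      ),
      class = "coalescent_sample"
    )
  })
}

#' Generate Poisson HKA counts with known parameters
#'
#' Draws S_i ~ Poisson(kappa_i theta_i a(n_i)) and
#' D_i ~ Poisson(theta_i (T + 1)), with kappa = k at the focal locus and 1
#' elsewhere -- exactly the model fitted by [hka_fit()].
#'
#' @param theta vector of per-locus theta (> 0).
#' @param T_div divergence time T (> 0), units of 2N generations.
#' @param k_focal selection parameter of the focal locus (> 0; 1 = neutral).
#' @param n vector of sample sizes (recycled).
#' @param seed integer seed.
#' @param focal index of the focal locus (default 1).
#' @return an `hka_data` with attribute `truth` (list of the generating
#'   parameters).
#' @export
gen_hka_counts <- function(theta, T_div, k_focal = 1, n = 20L, seed = 1L,
                           focal = 1L) {
  check_that(all(theta > 0) && T_div > 0 && k_focal > 0,
             "theta, T_div and k_focal must be > 0")
  nloc <- length(theta)
  n <- rep_len(n, nloc)
  with_local_seed(seed, {
    a <- vapply(n, harmonic_a1, numeric(1))
    kappa <- rep(1, nloc)
    kappa[focal] <- k_focal
    S <- stats::rpois(nloc, kappa * theta * a)
    D <- stats::rpois(nloc, theta * (T_div + 1))
    out <- hka_data(
      locus_id = sprintf("locus%02d", seq_len(nloc)),
      S = S, D = D, n = n,
      role = ifelse(seq_len(nloc) == focal, "focal", "neutral")
    )
    attr(out, "truth") <- list(theta = theta, T_div = T_div,
                               k_focal = k_focal, seed = seed)
    out
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a coding-region population sample with planted variant effects
#'
#' Builds a random open reading frame (no internal stops) flanked by
#' noncoding sequence, plants the requested numbers of synonymous and
#' nonsynonymous SNPs in the coding region (verified against the genetic
#' code) and indels in the flanks, and derives a haplotype alignment in
#' which each SNP segregates at a random frequency.  Indels are recorded in
#' the variant table only; the haplotype alignment carries the SNPs.
#'
#' @param L_coding coding length in bp (divisible by 3).
#' @param n haplotypes.
#' @param n_syn,n_nonsyn,n_indel planted variant counts.
#' @param seed integer seed.
#' @param flank length of each noncoding flank.
#' @return list of class `coding_population`: `reference`, `alignment`
#'   (a `locus_alignment`), `variants` (variant table), `annotation`
#'   (a `site_class_annotation`), `coding` (interval data.frame), `truth`
#'   (data.frame of planted positions and effects).
#' @export
gen_coding_population <- function(L_coding, n, n_syn, n_nonsyn, n_indel,
                                  seed = 1L, flank = 150L) {
  check_that(L_coding %% 3L == 0L, "L_coding must be divisible by 3")
  check_that(n >= 2L, "need n >= 2")
  with_local_seed(seed, {
    codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    cds <- paste(sample(codons, L_coding / 3L, replace = TRUE),
                 collapse = "")
    bases <- c("A", "C", "G", "T")
    fl5 <- paste(sample(bases, flank, replace = TRUE), collapse = "")
    fl3 <- paste(sample(bases, flank, replace = TRUE), collapse = "")
    reference <- paste0(fl5, cds, fl3)
    coding <- data.frame(start = flank + 1L, end = flank + L_coding,
                         strand = "+", frame = 0L)
    ann <- classify_coding_sites(reference, coding)
    used <- integer()
    plant <- function(n_want, effect) {
      out <- list()
      tries <- 0L
      while (length(out) < n_want) {
        tries <- tries + 1L
        check_that(tries <= 200L * max(n_want, 1L),
                   "could not place %d %s variants", n_want, effect)
        pos <- sample(seq.int(coding$start, coding$end), 1L)
        if (pos %in% used) next
        ref_b <- substr(reference, pos, pos)
        alts <- setdiff(bases, ref_b)
        ok <- alts[vapply(alts, function(b) {
          variant_effect(ann, reference, pos, b) == effect
        }, logical(1))]
        if (length(ok) == 0L) next
        used <<- c(used, pos)
        out[[length(out) + 1L]] <- data.frame(
          position = pos, ref = ref_b, alt = sample(ok, 1L),
          effect = effect, stringsAsFactors = FALSE
        )
      }
      do.call(rbind, c(out, list(data.frame(
        position = integer(), ref = character(), alt = character(),
        effect = character()
      ))))
    }
    snps <- rbind(plant(n_syn, "synonymous"), plant(n_nonsyn, "nonsynonymous"))
    indels <- list()
    if (n_indel > 0L) {
      flank_pos <- c(seq_len(flank - 4L),
                     seq.int(coding$end + 1L, nchar(reference) - 4L))
      picks <- sample(flank_pos, n_indel)
      for (pos in picks) {
        del_len <- sample(1:3, 1L)
        indels[[length(indels) + 1L]] <- data.frame(
          position = pos,
          ref = substr(reference, pos, pos + del_len),
          alt = substr(reference, pos, pos),
          effect = "indel", stringsAsFactors = FALSE
        )
      }
    }
    truth <- rbind(snps, if (length(indels)) do.call(rbind, indels))
    truth <- truth[order(truth$position), , drop = FALSE]
    rownames(truth) <- NULL
    alt_count <- sample(seq_len(n - 1L), nrow(truth), replace = TRUE)
    variants <- data.frame(
      locus_id = "synthetic_locus", position = truth$position,
      ref = truth$ref, alt = truth$alt,
      vtype = ifelse(truth$effect == "indel", "indel", "SNP"),
      ref_count = n - alt_count, alt_count = alt_count,
      stringsAsFactors = FALSE
    )
    haps <- matrix(strsplit(reference, "")[[1]], nrow = n,
                   ncol = nchar(reference), byrow = TRUE)
    snp_rows <- which(variants$vtype == "SNP")
    for (r in snp_rows) {
      carriers <- sample.int(n, variants$alt_count[r])
      haps[carriers, variants$position[r]] <- variants$alt[r]
    }
    structure(
      list(
        reference = reference,
        alignment = locus_alignment(
          "synthetic_locus", apply(haps, 1L, paste, collapse = "")
        ),
        variants = variants, annotation = ann, coding = coding,
        truth = truth, seed = seed
      ),
      class = "coding_population"
    )
  })
}
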