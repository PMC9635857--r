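# Per-locus diversity statistics: segregating sites, nucleotide diversity by
# site class (Nei-Gojobori fractional site counting), Watterson's theta,
# Tajima's D, and SNP/indel density.  Gap handling is complete deletion:
# a column with a gap in any haplotype is dropped from every statistic.

#' Construct a locus haplotype alignment
#'
#' @param locus_id locus name.
#' @param haplotypes character vector of equal-length nucleotide sequences
#'   (gaps `-` allowed), length >= 2.
#' @return list of class `locus_alignment` with `locus_id`, `haps`
#'   (character matrix, haplotypes x positions), `n`, `L`.
#' @export
locus_alignment <- function(locus_id, haplotypes) {
  check_that(length(haplotypes) >= 2L, "need at least 2 haplotypes")
  L <- unique(nchar(haplotypes))
  check_that(length(L) == 1L && L >= 1L, "haplotypes differ in length")
  m <- do.call(rbind, strsplit(toupper(haplotypes), ""))
  structure(
    list(locus_id = locus_id, haps = m, n = nrow(m), L = ncol(m)),
    class = "locus_alignment"
  )
}

# columns free of gaps in every haplotype
included_columns <- function(aln) {
  which(colSums(aln$haps == "-") == 0L)
}

#' Number of segregating sites
#'
#' Positions with at least two distinct states among the haplotypes, after
#' complete deletion of any column containing a gap.
#'
#' @param aln a `locus_alignment`.
#' @return integer count.
#' @export
segregating_sites <- function(aln) {
  cols <- included_columns(aln)
  if (length(cols) == 0L) return(0L)
  sum(vapply(cols, function(j) {
    length(unique(aln$haps[, j])) >= 2L
  }, logical(1)))
}

# mean number of pairwise differences (count, not per site) over the
# complete-deletion columns
mean_pairwise_differences <- function(aln) {
  cols <- included_columns(aln)
  n <- aln$n
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(aln$haps[i, cols] != aln$haps[j, cols])
    }
  }
  tot / choose(n, 2)
}

#' Nucleotide diversity, optionally restricted to a site class
#'
#' \eqn{\pi} = average pairwise difference per site.  Without an annotation,
#' differences are counted per position and divided by the number of
#' gap-free positions.  With a coding annotation, coding differences are
#' classified synonymous / nonsynonymous codon-by-codon (Nei-Gojobori 1986,
#' equal pathway weighting for multi-hit codons) and site denominators are
#' the fractional class site counts; `"silent"` pools noncoding positions
#' with synonymous sites.  A class with zero sites reports 0 with attribute
#' `empty_class = TRUE`.
#'
#' @param aln a `locus_alignment`.
#' @param annotation a `site_class_annotation` from
#'   [classify_coding_sites()], required for filtered classes.
#' @param class one of `"total"`, `"silent"`, `"synonymous"`,
#'   `"nonsynonymous"`.
#' @return per-site diversity (numeric scalar).
#' @export
nucleotide_diversity <- function(aln, annotation = NULL,
                                 class = c("total", "silent", "synonymous",
                                           "nonsynonymous")) {
  class <- match.arg(class)
  cols <- included_columns(aln)
  if (class == "total") {
    check_that(length(cols) > 0L, "no gap-free columns in %s", aln$locus_id)
    return(mean_pairwise_differences(aln) / length(cols))
  }
  check_that(!is.null(annotation), "class-filtered pi needs an annotation")
  cw <- class_weights(annotation, cols)
  denom <- switch(class,
    silent = cw$noncoding_sites + cw$syn_sites,
    synonymous = cw$syn_sites,
    nonsynonymous = cw$nonsyn_sites
  )
  if (denom <= 0) {
    out <- 0
    attr(out, "empty_class") <- TRUE
    return(out)
  }
  d <- pairwise_class_differences(aln, annotation, cols)
  num <- switch(class,
    silent = d$noncoding + d$syn,
    synonymous = d$syn,
    nonsynonymous = d$nonsyn
  )
  num / (choose(aln$n, 2) * denom)
}

# per-class site denominators over the included columns
class_weights <- function(annotation, cols) {
  pos <- annotation$per_position[cols, , drop = FALSE]
  list(
    noncoding_sites = sum(!pos$is_coding),
    syn_sites = sum(pos$syn_frac[pos$is_coding]),
    nonsyn_sites = sum(pos$nonsyn_frac[pos$is_coding])
  )
}

# total pairwise difference counts by class, summed over all pairs
pairwise_class_differences <- function(aln, annotation, cols) {
  n <- aln$n
  is_coding <- annotation$per_position$is_coding
  noncod_cols <- cols[!is_coding[cols]]
  tot_non <- 0; tot_syn <- 0; tot_nsy <- 0
  codons <- annotation$codons  # list: genomic positions of each codon
  usable <- vapply(codons, function(p) all(p %in% cols), logical(1))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot_non <- tot_non +
        sum(aln$haps[i, noncod_cols] != aln$haps[j, noncod_cols])
      for (ci in which(usable)) {
        p <- codons[[ci]]
        c1 <- paste(aln$haps[i, p], collapse = "")
        c2 <- paste(aln$haps[j, p], collapse = "")
        if (c1 != c2) {
          sd <- codon_pair_differences(c1, c2)
          tot_syn <- tot_syn + sd[["syn"]]
          tot_nsy <- tot_nsy + sd[["nonsyn"]]
        }
      }
    }
  }
  list(noncoding = tot_non, syn = tot_syn, nonsyn = tot_nsy)
}

# Nei-Gojobori difference counting between two codons: average the
# synonymous/nonsynonymous step counts over all orderings of the changes.
codon_pair_differences <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (k == 1L) list(diff_pos) else {
    perms <- if (k == 2L) list(diff_pos, rev(diff_pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) diff_pos[o])
    }
    perms
  }
  syn <- 0; nonsyn <- 0
  for (path in paths) {
    cur <- c1
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (translate_codon(cur) == translate_codon(nxt)) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
  }
  c(syn = syn / length(paths), nonsyn = nonsyn / length(paths))
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (!codon %in% names(gc)) return("X")
  unname(gc[codon])
}

#' Watterson's theta
#'
#' \eqn{\theta_w = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S number of segregating sites.
#' @param n sample size (haplotypes).
#' @param L number of sites.
#' @return per-site estimate.
#' @export
watterson_theta <- function(S, n, L) {
  check_that(n >= 2L, "need n >= 2")
  check_that(L >= 1L, "need L >= 1")
  S / (harmonic_a1(n) * L)
}

harmonic_a1 <- function(n) sum(1 / seq_len(n - 1L))

#' Tajima's D
#'
#' Normalized difference between the mean pairwise difference count and
#' \eqn{S/a_1}, with the standard variance constants computed from the
#' sample size (Tajima 1989).  Undefined (returns `NA`) when there are no
#' segregating sites or the variance term vanishes.
#'
#' @param aln a `locus_alignment`.
#' @return numeric D, or `NA_real_` when undefined.
#' @export
tajima_d <- function(aln) {
  n <- aln$n
  S <- segregating_sites(aln)
  if (S == 0L || n < 3L) return(NA_real_)
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (mean_pairwise_differences(aln) - S / k$a1) / sqrt(v)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Classify sites of a reference sequence into coding site classes
#'
#' Builds a per-position annotation: noncoding positions contribute one
#' silent site each; coding positions carry Nei-Gojobori fractional site
#' counts (a position contributes `f` synonymous sites, where `f` is the
#' fraction of the three possible base changes that preserve the amino
#' acid; changes to a stop codon count as nonsynonymous).  Per codon the
#' synonymous plus nonsynonymous fractions sum to 3.
#'
#' @param reference nucleotide string of the locus.
#' @param coding data.frame with columns `start`, `end` (1-based inclusive)
#'   and optionally `strand` (only `"+"` supported) and `frame`
#'   (0/1/2 leading bases skipped).
#' @return list of class `site_class_annotation`: `length`,
#'   `per_position` (data.frame `is_coding`, `syn_frac`, `nonsyn_frac`),
#'   `codons` (list of genomic position triples), `coding` (input table).
#' @export
classify_coding_sites <- function(reference, coding) {
  L <- nchar(reference)
  check_that(all(coding$start >= 1L & coding$end <= L &
                   coding$start <= coding$end),
             "coding interval outside the reference")
  if (!is.null(coding$strand)) {
    check_that(all(coding$strand == "+"),
               "only forward-strand coding regions are supported")
  }
  coding <- coding[order(coding$start), , drop = FALSE]
  cds_pos <- as.integer(unlist(lapply(seq_len(nrow(coding)), function(i) {
    seq.int(coding$start[i], coding$end[i])
  })))
  check_that(!anyDuplicated(cds_pos), "overlapping coding intervals")
  frame <- if (is.null(coding$frame)) 0L else coding$frame[1]
  if (frame > 0L) cds_pos <- cds_pos[-seq_len(frame)]
  check_that(length(cds_pos) %% 3L == 0L,
             "coding length (%d) not divisible by 3", length(cds_pos))
  ref <- strsplit(toupper(reference), "")[[1]]
  per <- data.frame(
    is_coding = rep(FALSE, L), syn_frac = rep(0, L), nonsyn_frac = rep(0, L)
  )
  per$is_coding[cds_pos] <- TRUE
  codons <- split(cds_pos, rep(seq_len(length(cds_pos) / 3L), each = 3L))
  names(codons) <- NULL
  bases <- c("A", "C", "G", "T")
  for (p3 in codons) {
    codon <- paste(ref[p3], collapse = "")
    aa <- translate_codon(codon)
    if (aa == "*") warning("internal stop codon in the reference CDS")
    for (k in 1:3) {
      alts <- setdiff(bases, ref[p3[k]])
      syn <- vapply(alts, function(b) {
        alt_codon <- codon
        substr(alt_codon, k, k) <- b
        aa2 <- translate_codon(alt_codon)
        aa2 != "*" && aa2 == aa
      }, logical(1))
      per$syn_frac[p3[k]] <- sum(syn) / 3
      per$nonsyn_frac[p3[k]] <- 1 - sum(syn) / 3
    }
  }
  structure(
    list(length = L, per_position = per, codons = codons, coding = coding),
    class = "site_class_annotation"
  )
}

#' Effect of a single-nucleotide variant
#'
#' @param annotation a `site_class_annotation`.
#' @param reference the reference nucleotide string used to build it.
#' @param position 1-based position.
#' @param alt alternate base.
#' @return `"noncoding"`, `"synonymous"` or `"nonsynonymous"`.
#' @export
variant_effect <- function(annotation, reference, position, alt) {
  check_that(position >= 1L && position <= annotation$length,
             "position out of range")
  if (!annotation$per_position$is_coding[position]) return("noncoding")
  codon_pos <- Find(function(p) position %in% p, annotation$codons)
  ref_codon <- substr_positions(reference, codon_pos)
  alt_codon <- ref_codon
  substr(alt_codon, match(position, codon_pos),
         match(position, codon_pos)) <- toupper(alt)
  if (translate_codon(ref_codon) == translate_codon(alt_codon) &&
        translate_codon(alt_codon) != "*") {
    "synonymous"
  } else {
    "nonsynonymous"
  }
}

substr_positions <- function(s, pos) {
  paste(strsplit(s, "")[[1]][pos], collapse = "")
}

#' SNP and indel density
#'
#' Base pairs of sequence per SNP and per indel, rounded half-up to one
#' decimal.  A zero count gives `NA` for that density.
#'
#' @param variants variant data.frame (see [read_variant_table()]).
#' @param total_length total surveyed length in bp.
#' @return list with `bp_per_snp` and `bp_per_indel`.
#' @export
variant_density <- function(variants, total_length) {
  check_that(total_length >= 1, "total_length must be >= 1")
  n_snp <- sum(variants$vtype == "SNP")
  n_indel <- sum(variants$vtype == "indel")
  list(
    bp_per_snp = if (n_snp > 0) round_half_up(total_length / n_snp, 1)
                 else NA_real_,
    bp_per_indel = if (n_indel > 0) round_half_up(total_length / n_indel, 1)
                   else NA_real_
  )
}

#' Per-locus diversity summary
#'
#' One row with S, per-site diversity by class, Watterson's theta and
#' Tajima's D for a locus alignment.  Site-class columns are `NA` when no
#' annotation is given.
#'
#' @param aln a `locus_alignment`.
#' @param annotation optional `site_class_annotation`.
#' @return one-row data.frame: `locus_id`, `n`, `S`, `theta_w`, `pi_total`,
#'   `pi_sil`, `pi_syn`, `pi_nonsyn`, `tajima_d`.
#' @export
diversity_stats <- function(aln, annotation = NULL) {
  S <- segregating_sites(aln)
  L_eff <- length(included_columns(aln))
  data.frame(
    locus_id = aln$locus_id, n = aln$n, S = S,
    theta_w = watterson_theta(S, aln$n, max(L_eff, 1L)),
    pi_total = nucleotide_diversity(aln),
    pi_sil = if (is.null(annotation)) NA_real_ else
      as.numeric(nucleotide_diversity(aln, annotation, "silent")),
    pi_syn = if (is.null(annotation)) NA_real_ else
      as.numeric(nucleotide_diversity(aln, annotation, "synonymous")),
    pi_nonsyn = if (is.null(annotation)) NA_real_ else
      as.numeric(nucleotide_diversity(aln, annotation, "nonsynonymous")),
    tajima_d = tajima_d(aln),
    stringsAsFactors = FALSE
  )
}
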