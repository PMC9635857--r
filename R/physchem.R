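# Physicochemical panel: molecular weight, theoretical pI, lysine content,
# integer net charge, and the 20-aa moving-sum charge profile of the tails.

# Average (isotope-averaged) residue masses, Da.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
MASS_WATER <- 18.01528

#' Bjellqvist pKa table
#'
#' The side-chain and terminal pKa values used by the theoretical-pI
#' calculation.  A single N-terminal pKa is used (rather than the
#' residue-specific variants some tools apply) so that the result is a pure
#' function of amino-acid composition.  Supply a modified copy to
#' [theoretical_pi()] to swap conventions.
#'
#' @return a list with elements `cterm`, `nterm`, `side_pos` and `side_neg`
#'   (named vectors of pKa).
#' @export
pka_bjellqvist <- function() {
  list(
    cterm = 3.55,
    nterm = 7.5,
    side_pos = c(K = 10.00, R = 12.00, H = 5.98),
    side_neg = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  )
}

aa_counts <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  table(factor(ch, levels = c(AA_CANONICAL, "X")))
}

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water, in kilodaltons.  `X`
#' residues carry no mass and trigger a warning.
#'
#' @param residues amino-acid string.
#' @return molecular weight in kDa.
#' @export
molecular_weight <- function(residues) {
  check_that(nchar(residues) >= 1L, "empty sequence")
  cnt <- aa_counts(residues)
  if (cnt[["X"]] > 0L) {
    warning("sequence contains X residues; excluded from the mass sum")
  }
  (sum(AA_AVG_MASS * as.numeric(cnt[names(AA_AVG_MASS)])) + MASS_WATER) / 1000
}

# Modeled net charge of the full titration model at a given pH
# (Henderson-Hasselbalch over side chains plus both termini).
charge_at_ph <- function(residues, ph, pka = pka_bjellqvist()) {
  cnt <- aa_counts(residues)
  pos <- 1 / (1 + 10^(ph - pka$nterm))
  for (aa in names(pka$side_pos)) {
    pos <- pos + cnt[[aa]] / (1 + 10^(ph - pka$side_pos[[aa]]))
  }
  neg <- 1 / (1 + 10^(pka$cterm - ph))
  for (aa in names(pka$side_neg)) {
    neg <- neg + cnt[[aa]] / (1 + 10^(pka$side_neg[[aa]] - ph))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the modeled titration charge is zero, found by bisection on
#' \[0, 14\] to `|charge| < tol`.  The charge model is Henderson-Hasselbalch
#' over the ionizable side chains (D, E, C, Y negative; K, R, H positive)
#' plus both termini, with the Bjellqvist pKa set by default.  The result
#' depends only on amino-acid composition, not residue order.
#'
#' @param residues amino-acid string.
#' @param pka pKa table as produced by [pka_bjellqvist()].
#' @param tol convergence tolerance on the modeled charge.
#' @return pI in pH units.
#' @export
theoretical_pi <- function(residues, pka = pka_bjellqvist(), tol = 1e-4) {
  check_that(nchar(residues) >= 1L, "empty sequence")
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- charge_at_ph(residues, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Lysine content of a region
#'
#' Percentage of lysine residues, rounded half-up to one decimal.  `X`
#' residues are excluded from the denominator.
#'
#' @param residues amino-acid string (may be empty for an absent region).
#' @return percent lysine (1 decimal), or `NA` for an empty region.
#' @export
lysine_content <- function(residues) {
  if (is.null(residues) || nchar(residues) == 0L) return(NA_real_)
  cnt <- aa_counts(residues)
  denom <- nchar(residues) - cnt[["X"]]
  if (denom == 0L) return(NA_real_)
  round_half_up(100 * cnt[["K"]] / denom, 1)
}

#' Integer net charge of a region
#'
#' Counting convention for the tabulated "net charge": K and R count +1,
#' D and E count -1; histidine and the termini are excluded (His is mostly
#' neutral at physiological pH, and the termini belong to the titration
#' model used for pI, not to this integer count).
#'
#' @param residues amino-acid string.
#' @return integer net charge (`NA` for an empty region).
#' @export
net_charge <- function(residues) {
  if (is.null(residues) || nchar(residues) == 0L) return(NA_integer_)
  cnt <- aa_counts(residues)
  as.integer(cnt[["K"]] + cnt[["R"]] - cnt[["D"]] - cnt[["E"]])
}

region_seq <- function(residues, iv) {
  if (is.null(iv)) "" else substr(residues, iv[1], iv[2])
}

#' Moving-sum charge profile of a terminal tail
#'
#' Per-residue charges (+1 for K/R, -1 for D/E, 0 otherwise) summed in a
#' sliding window of `window` residues (20 by default) along the NTD or CTD,
#' starting from the GH1 boundary and sliding outward: for the CTD the first
#' window is the leftmost one, for the NTD the rightmost.  When the whole
#' region is shorter than the window a single truncated window is used; no
#' partial windows are taken at the distal end.
#'
#' @param partition a `region_partition`.
#' @param residues the full protein sequence.
#' @param region `"NTD"` or `"CTD"`.
#' @param window window size in residues.
#' @return list of class `charge_profile` with `protein_id`, `region`,
#'   `window`, `sums` (integer vector, boundary-first order), `min_sum`,
#'   `frac_positive`.
#' @export
charge_profile <- function(partition, residues, region = c("CTD", "NTD"),
                           window = 20L) {
  region <- match.arg(region)
  iv <- if (region == "CTD") partition$ctd else partition$ntd
  check_that(!is.null(iv), "protein %s has no %s", partition$protein_id,
             region)
  seq <- region_seq(residues, iv)
  ch <- strsplit(seq, "")[[1]]
  q <- ifelse(ch %in% c("K", "R"), 1L, ifelse(ch %in% c("D", "E"), -1L, 0L))
  len <- length(q)
  w <- min(window, len)
  n_win <- max(len - w + 1L, 1L)
  starts <- seq_len(n_win)
  sums <- vapply(starts, function(s) sum(q[s:(s + w - 1L)]), integer(1))
  # boundary-first: CTD windows already run boundary -> distal; NTD windows
  # must be reversed so the first window abuts the GH1 domain.
  if (region == "NTD") sums <- rev(sums)
  structure(
    list(
      protein_id = partition$protein_id, region = region, window = w,
      sums = sums, min_sum = min(sums),
      frac_positive = mean(sums > 0)
    ),
    class = "charge_profile"
  )
}

#' Full physicochemical profile of a partitioned protein
#'
#' Assembles the per-protein panel: molecular weight (kDa), theoretical pI,
#' and per-region plus total length, lysine content and integer net charge.
#' Regions of length zero carry `NA` markers.  Linker regions (between GH1
#' domains of multi-domain proteins) contribute to the totals but are not
#' tabulated as a named region.
#'
#' @param protein list/row with `id` and `residues`.
#' @param partition a `region_partition` for the same protein.
#' @return list of class `physchem_profile` with elements `protein_id`,
#'   `mw_kda`, `pi`, `length` / `lysine_pct` / `net_charge` (each a named
#'   list with `total`, `ntd`, `gh1` (vector for multi-GH1), `ctd`).
#' @export
physchem_profile <- function(protein, partition) {
  check_that(identical(protein$id, partition$protein_id),
             "protein/partition id mismatch")
  s <- protein$residues
  ntd <- region_seq(s, partition$ntd)
  ctd <- region_seq(s, partition$ctd)
  gh1 <- vapply(partition$gh1s, function(iv) region_seq(s, iv), character(1))
  structure(
    list(
      protein_id = protein$id,
      mw_kda = round_half_up(molecular_weight(s), 2),
      pi = round_half_up(theoretical_pi(s), 2),
      length = list(
        total = nchar(s), ntd = nchar(ntd),
        gh1 = nchar(gh1), ctd = nchar(ctd)
      ),
      lysine_pct = list(
        total = lysine_content(s), ntd = lysine_content(ntd),
        gh1 = vapply(gh1, lysine_content, numeric(1), USE.NAMES = FALSE),
        ctd = lysine_content(ctd)
      ),
      net_charge = list(
        total = net_charge(s), ntd = net_charge(ntd),
        gh1 = vapply(gh1, net_charge, integer(1), USE.NAMES = FALSE),
        ctd = net_charge(ctd)
      )
    ),
    class = "physchem_profile"
  )
}

#' @export
print.physchem_profile <- function(x, ...) {
  cat(sprintf(
    "<physchem_profile> %s MW %.2f kDa pI %.2f | CTD lysine %s%% net %s\n",
    x$protein_id, x$mw_kda, x$pi,
    format(x$lysine_pct$ctd), format(x$net_charge$ctd)
  ))
  invisible(x)
}
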