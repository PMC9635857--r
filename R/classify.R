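# The H1 verdict: combine architecture, physicochemical and binding-site
# evidence; neighbor-joining trees; distance-based variant nomenclature.

#' Thresholds for the H1 verdict
#'
#' The defaults sit midway between the values observed for true linker
#' histones (CTD lysine ~29-31%, CTD net charge +20 to +53, 10/10 basic
#' binding sites, every 20-aa CTD window positively charged) and those of
#' the GH1-Myb / GH1-HMGA groups (CTD lysine <= ~11%, <= 6 conserved
#' sites).  All are configurable.
#'
#' @param ctd_lys_min_pct minimum CTD lysine content (percent).
#' @param ctd_net_charge_min minimum CTD integer net charge.
#' @param min_window_sum_min minimum of the 20-aa moving charge sums.
#' @param binding_min minimum conserved basic binding sites (of 10).
#' @param require_single_gh1 require exactly one GH1 domain.
#' @return list of class `h1_criteria`.
#' @export
h1_criteria <- function(ctd_lys_min_pct = 20.0, ctd_net_charge_min = 20L,
                        min_window_sum_min = 1L, binding_min = 8L,
                        require_single_gh1 = TRUE) {
  check_that(ctd_lys_min_pct >= 0 && ctd_lys_min_pct <= 100,
             "ctd_lys_min_pct out of range")
  check_that(binding_min >= 0 && binding_min <= 10,
             "binding_min out of range")
  structure(
    list(ctd_lys_min_pct = ctd_lys_min_pct,
         ctd_net_charge_min = ctd_net_charge_min,
         min_window_sum_min = min_window_sum_min,
         binding_min = binding_min,
         require_single_gh1 = require_single_gh1),
    class = "h1_criteria"
  )
}

#' Classify one GH1 protein as H1 / GH1-Myb / GH1-HMGA / other
#'
#' A protein is called H1 only when its architecture is the typical
#' tripartite one (single GH1, no Myb, no AT-hook cluster) AND its CTD is
#' lysine-rich, strongly and evenly positively charged, AND its globular
#' domain retains the basic DNA-binding sites.  Proteins whose architecture
#' is GH1-Myb or GH1-HMGA keep that label regardless of the other criteria
#' (architecture has precedence); everything else failing any criterion is
#' `other`.
#'
#' @param arch one-row architecture call from [classify_architecture()].
#' @param profile a `physchem_profile`.
#' @param charge a `charge_profile` for the CTD, or `NULL` when the protein
#'   has no CTD (then the verdict cannot be H1).
#' @param sites a `conservation_report`.
#' @param criteria an `h1_criteria`.
#' @return list of class `h1_call`: `protein_id`, `verdict`, and the named
#'   booleans `architecture_ok`, `ctd_lysine_ok`, `ctd_charge_ok`,
#'   `charge_evenness_ok`, `binding_sites_ok`.
#' @export
classify_h1 <- function(arch, profile, charge, sites,
                        criteria = h1_criteria()) {
  ids <- c(arch$protein_id, profile$protein_id, sites$protein_id,
           if (!is.null(charge)) charge$protein_id)
  check_that(length(unique(ids)) == 1L,
             "mismatched protein ids: %s", paste(unique(ids), collapse = ", "))
  ok <- list(
    architecture_ok = arch$group == "typical_H1_candidate" &&
      (!criteria$require_single_gh1 || arch$n_gh1 == 1L),
    ctd_lysine_ok = isTRUE(profile$lysine_pct$ctd >= criteria$ctd_lys_min_pct),
    ctd_charge_ok =
      isTRUE(profile$net_charge$ctd >= criteria$ctd_net_charge_min),
    charge_evenness_ok = !is.null(charge) &&
      isTRUE(charge$min_sum >= criteria$min_window_sum_min),
    binding_sites_ok = isTRUE(sites$conserved_count >= criteria$binding_min)
  )
  verdict <- if (arch$group %in% c("GH1_Myb", "GH1_HMGA")) {
    arch$group
  } else if (all(unlist(ok))) {
    "H1"
  } else {
    "other"
  }
  structure(
    c(list(protein_id = arch$protein_id, verdict = verdict), ok),
    class = "h1_call"
  )
}

#' p-distance between two aligned rows
#'
#' Proportion of mismatching sites among columns where neither row has a
#' gap (pairwise deletion).  Zero comparable columns is an error.
#'
#' @param alignment an `alignment_block`.
#' @param id_a,id_b row identifiers.
#' @return numeric in \[0, 1\].
#' @export
p_distance <- function(alignment, id_a, id_b) {
  check_that(id_a %in% alignment$ids, "'%s' not in alignment", id_a)
  check_that(id_b %in% alignment$ids, "'%s' not in alignment", id_b)
  a <- strsplit(alignment$rows[[id_a]], "")[[1]]
  b <- strsplit(alignment$rows[[id_b]], "")[[1]]
  keep <- a != "-" & b != "-"
  check_that(sum(keep) > 0L, "no comparable columns between %s and %s",
             id_a, id_b)
  mean(a[keep] != b[keep])
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param alignment an `alignment_block`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance_matrix <- function(alignment) {
  ids <- alignment$ids
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(alignment, ids[i], ids[j])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: iteratively join the pair minimizing the
#' Q-criterion, with branch lengths from the standard two-point formulas.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling branch (their sum is preserved).  Ties in Q are broken by
#' the lexicographically smallest pair of cluster representatives, so the
#' result is deterministic.  On an additive distance matrix the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param dist symmetric nonnegative matrix with zero diagonal and unique
#'   dimnames, at least 3 taxa.
#' @return an unrooted `phylo` tree (package \pkg{ape}).
#' @export
nj_tree <- function(dist) {
  check_that(is.matrix(dist) && nrow(dist) == ncol(dist) && nrow(dist) >= 3L,
             "need a square matrix with >= 3 taxa")
  check_that(isTRUE(all.equal(dist, t(dist), tolerance = 1e-12)),
             "distance matrix is not symmetric")
  ids <- rownames(dist)
  check_that(!is.null(ids) && !anyDuplicated(ids),
             "distance matrix needs unique dimnames")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  # cluster state: representative label (lexicographic min of members) and
  # newick fragment
  rep_lab <- ids
  frag <- ids
  D <- dist
  active <- seq_along(ids)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    best <- NULL
    best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * Dm[i, j] - r[i] - r[j]
        pair <- sort(c(rep_lab[active[i]], rep_lab[active[j]]))
        if (q < best_q - 1e-12 ||
              (abs(q - best_q) <= 1e-12 && !is.null(best) &&
                 (pair[1] < best$pair[1] ||
                    (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best_q <- min(q, best_q)
          best <- list(i = i, j = j, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    ai <- active[i]; aj <- active[j]
    vi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[ai], fmt(vi), frag[aj], fmt(vj))
    # distances from the new node to every other active cluster
    others <- setdiff(active, c(ai, aj))
    newd <- (D[ai, others] + D[aj, others] - D[ai, aj]) / 2
    # reuse slot ai for the merged cluster
    D[ai, others] <- newd
    D[others, ai] <- newd
    frag[ai] <- new_frag
    rep_lab[ai] <- min(rep_lab[ai], rep_lab[aj])
    active <- setdiff(active, aj)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[a], fmt(la), frag[b], fmt(lb), frag[c3], fmt(lc))
  ape::read.tree(text = newick)
}

#' Assign a variant name by distance to labeled references
#'
#' Deterministic surrogate for placing a query into one of the named H1
#' variant subclades (H1.0-H1.4): the query is assigned to the variant whose
#' labeled reference sequences have the smallest mean p-distance to it.  The
#' margin (runner-up mean minus winning mean) is reported; a margin below
#' `epsilon` flags the assignment as ambiguous.
#'
#' @param alignment an `alignment_block` containing the query and all
#'   references.
#' @param query_id the row to assign.
#' @param labels named character vector: reference id -> variant name.
#' @param epsilon ambiguity threshold on the margin.
#' @return list of class `variant_assignment` with `protein_id`, `variant`,
#'   `mean_distance` (named vector per variant), `margin`, `ambiguous`.
#' @export
assign_variant <- function(alignment, query_id, labels, epsilon = 1e-9) {
  check_that(length(labels) >= 1L, "no labeled references")
  check_that(query_id %in% alignment$ids, "'%s' not in alignment", query_id)
  refs <- names(labels)
  missing <- setdiff(refs, alignment$ids)
  check_that(length(missing) == 0L, "reference(s) not in alignment: %s",
             paste(missing, collapse = ", "))
  d <- vapply(refs, function(r) p_distance(alignment, query_id, r),
              numeric(1))
  means <- tapply(d, labels, mean)
  means <- means[order(names(means))]  # deterministic tie order
  ord <- order(means)
  variant <- names(means)[ord[1]]
  margin <- if (length(means) > 1L) {
    unname(means[ord[2]] - means[ord[1]])
  } else {
    Inf
  }
  structure(
    list(protein_id = query_id, variant = variant,
         mean_distance = means, margin = margin,
         ambiguous = margin < epsilon),
    class = "variant_assignment"
  )
}
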