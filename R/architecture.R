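# Tripartite partition of a GH1 protein, AT-hook detection, and
# domain-architecture grouping.

#' Partition a protein into NTD / GH1 / CTD regions
#'
#' The tripartite model of a linker histone: an N-terminal tail before the
#' first globular (GH1) domain, the GH1 domain(s), and a C-terminal tail
#' after the last one.  Proteins with two or more GH1 domains additionally
#' carry inter-domain linkers, which belong to neither tail.  Region lengths
#' always sum to the protein length.
#'
#' @param protein one row of a `seq_set` (list or data.frame row with `id`
#'   and `residues`).
#' @param hits domain-hit data.frame (see [read_domain_table()]) restricted
#'   to this protein; only rows with `domain_name == "GH1"` are used.
#' @return an object of class `region_partition`: list with `protein_id`,
#'   `length`, and intervals `ntd`, `gh1s` (list), `linkers` (list), `ctd`
#'   (each a length-2 integer vector `c(start, end)` or `NULL` when empty).
#' @export
partition_protein <- function(protein, hits) {
  id <- protein$id
  L <- nchar(protein$residues)
  gh1 <- hits[hits$domain_name == "GH1" &
                hits$protein_id == id, , drop = FALSE]
  check_that(nrow(gh1) >= 1L, "not a GH1 protein: %s", id)
  gh1$start <- as.integer(gh1$start)
  gh1$end <- as.integer(gh1$end)
  check_that(all(gh1$end <= L),
    "GH1 hit exceeds protein length for %s", id)
  gh1 <- gh1[order(gh1$start), , drop = FALSE]
  if (nrow(gh1) > 1L) {
    check_that(all(gh1$start[-1] > gh1$end[-nrow(gh1)]),
      "overlapping GH1 hits on %s", id)
  }
  first <- gh1$start[1]
  last <- gh1$end[nrow(gh1)]
  ntd <- if (first > 1L) c(1L, first - 1L) else NULL
  ctd <- if (last < L) c(last + 1L, L) else NULL
  gh1s <- lapply(seq_len(nrow(gh1)), function(i) {
    c(gh1$start[i], gh1$end[i])
  })
  linkers <- list()
  if (nrow(gh1) > 1L) {
    linkers <- lapply(seq_len(nrow(gh1) - 1L), function(i) {
      c(gh1$end[i] + 1L, gh1$start[i + 1L] - 1L)
    })
    linkers <- Filter(function(iv) iv[2] >= iv[1], linkers)
  }
  out <- structure(
    list(protein_id = id, length = L, ntd = ntd, gh1s = gh1s,
         linkers = linkers, ctd = ctd),
    class = "region_partition"
  )
  stopifnot(sum(region_lengths(out)) == L)
  out
}

interval_len <- function(iv) if (is.null(iv)) 0L else iv[2] - iv[1] + 1L

#' Region lengths of a partition
#'
#' @param partition a `region_partition`.
#' @return named integer vector: `ntd`, one `gh1.*` per domain, `linker.*`
#'   per linker, `ctd` (zero for absent regions).
#' @export
region_lengths <- function(partition) {
  c(
    ntd = interval_len(partition$ntd),
    gh1 = vapply(partition$gh1s, interval_len, integer(1)),
    linker = if (length(partition$linkers)) {
      vapply(partition$linkers, interval_len, integer(1))
    } else {
      NULL
    },
    ctd = interval_len(partition$ctd)
  )
}

#' @export
print.region_partition <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "-" else sprintf("[%d,%d]", iv[1], iv[2])
  cat(sprintf(
    "<region_partition> %s (L=%d) NTD %s | GH1 %s | CTD %s\n",
    x$protein_id, x$length, fmt(x$ntd),
    paste(vapply(x$gh1s, fmt, character(1)), collapse = ","), fmt(x$ctd)
  ))
  invisible(x)
}

# AT-hook: R-G-R-P core with at least `min_flank_basic` additional K/R in the
# up-to-4 residues on either side.  A bare GRP/RGRP with no basic context is
# not a hook.
AT_HOOK_CORE <- "RGRP"

#' Find AT-hook motifs in a protein
#'
#' Scans for the canonical AT-hook core `R-G-R-P` and requires at least two
#' additional basic residues (K/R) within the four residues flanking the
#' core on either side (combined), as in the `KRPRGRPKK` consensus of HMGA
#' proteins.  Occurrences are reported left-to-right, non-overlapping.
#'
#' @param protein list/row with `id` and `residues`.
#' @param min_flank_basic minimum K/R count in the combined flanks
#'   (default 2).
#' @return data.frame with columns `protein_id`, `start` (1-based position
#'   of the core), `matched` (core plus flanks actually present).
#' @export
find_at_hooks <- function(protein, min_flank_basic = 2L) {
  s <- protein$residues
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  k <- nchar(AT_HOOK_CORE)
  hits <- list()
  i <- 1L
  while (i <= n - k + 1L) {
    if (substr(s, i, i + k - 1L) == AT_HOOK_CORE) {
      lo <- max(1L, i - 4L)
      hi <- min(n, i + k - 1L + 4L)
      flank <- c(ch[lo:(i - 1L)][seq_len(max(0L, i - lo))],
                 if (i + k <= hi) ch[(i + k):hi] else character())
      if (sum(flank %in% c("K", "R")) >= min_flank_basic) {
        hits[[length(hits) + 1L]] <- data.frame(
          protein_id = protein$id, start = i,
          matched = substr(s, lo, hi), stringsAsFactors = FALSE
        )
        i <- i + k  # non-overlapping
        next
      }
    }
    i <- i + 1L
  }
  if (length(hits) == 0L) {
    return(data.frame(protein_id = character(), start = integer(),
                      matched = character()))
  }
  do.call(rbind, hits)
}

#' Assign a domain-architecture group
#'
#' Deterministic rule, in precedence order: any Myb hit gives `GH1_Myb`;
#' else two or more AT-hooks give `GH1_HMGA`; else two or more GH1 domains
#' give `multi_GH1`; else a single GH1 gives `typical_H1_candidate`.
#'
#' @param partition a `region_partition`.
#' @param hits domain-hit data.frame for this protein (all domains).
#' @param hooks AT-hook data.frame from [find_at_hooks()].
#' @return data.frame row with `protein_id`, `group`, `n_gh1`, `has_myb`,
#'   `n_at_hooks`.
#' @export
classify_architecture <- function(partition, hits, hooks) {
  id <- partition$protein_id
  n_gh1 <- length(partition$gh1s)
  has_myb <- any(hits$protein_id == id & hits$domain_name == "Myb")
  n_hooks <- sum(hooks$protein_id == id)
  group <- if (has_myb) {
    "GH1_Myb"
  } else if (n_hooks >= 2L) {
    "GH1_HMGA"
  } else if (n_gh1 >= 2L) {
    "multi_GH1"
  } else {
    "typical_H1_candidate"
  }
  data.frame(
    protein_id = id, group = group, n_gh1 = n_gh1,
    has_myb = has_myb, n_at_hooks = n_hooks, stringsAsFactors = FALSE
  )
}
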