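# Shared fixtures and independent oracles, built in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fasta_fixture <- function(ids, seqs, descs = NULL) {
  lines <- unlist(lapply(seq_along(ids), function(i) {
    hdr <- if (!is.null(descs) && nzchar(descs[i])) {
      paste0(">", ids[i], " ", descs[i])
    } else {
      paste0(">", ids[i])
    }
    c(hdr, seqs[i])
  }))
  write_lines_tmp(lines, ".fasta")
}

# a protein with explicit NTD / GH1 / CTD segments plus its GH1 hit row
make_protein <- function(id, ntd, gh1, ctd) {
  residues <- paste0(ntd, gh1, ctd)
  list(
    protein = list(id = id, residues = residues),
    hits = data.frame(
      protein_id = id, domain_name = "GH1",
      start = nchar(ntd) + 1L, end = nchar(ntd) + nchar(gh1),
      evalue = 1e-10, stringsAsFactors = FALSE
    )
  )
}

# brute-force diversity oracle: direct column scans and pairwise loops,
# kept deliberately independent of the package implementation
oracle_popgen <- function(haps) {
  m <- do.call(rbind, strsplit(haps, ""))
  n <- nrow(m)
  keep <- which(colSums(m == "-") == 0L)
  S <- 0L
  for (j in keep) if (length(unique(m[, j])) > 1L) S <- S + 1L
  diffs <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diffs <- c(diffs, sum(m[i, keep] != m[j, keep]))
    }
  }
  k_mean <- mean(diffs)
  a1 <- sum(1 / seq_len(n - 1L))
  D <- NA_real_
  if (S > 0L && n >= 3L) {
    a2 <- sum(1 / seq_len(n - 1L)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    v <- e1 * S + e2 * S * (S - 1)
    if (v > 0) D <- (k_mean - S / a1) / sqrt(v)
  }
  list(
    S = S, L = length(keep),
    pi = if (length(keep)) k_mean / length(keep) else NA_real_,
    theta_w = S / (a1 * max(length(keep), 1L)),
    tajima_d = D
  )
}

random_alignment <- function(n, L, n_mut = NULL, gap_frac = 0) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(base, nrow = n, ncol = L, byrow = TRUE)
  if (is.null(n_mut)) n_mut <- rpois(1, L / 5)
  for (k in seq_len(n_mut)) {
    j <- sample.int(L, 1)
    who <- sample.int(n, sample.int(n - 1L, 1))
    m[who, j] <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
  }
  if (gap_frac > 0) {
    idx <- which(matrix(runif(n * L) < gap_frac, n, L))
    m[idx] <- "-"
  }
  apply(m, 1, paste, collapse = "")
}

# least-squares topology-enumeration oracle for 4-taxon neighbor joining:
# returns the unrooted quartet split supported by the additive matrix
oracle_quartet_split <- function(d) {
  ids <- rownames(d)
  # the true split pairs the two taxa whose sum of distances is minimal
  s12 <- d[1, 2] + d[3, 4]
  s13 <- d[1, 3] + d[2, 4]
  s14 <- d[1, 4] + d[2, 3]
  best <- which.min(c(s12, s13, s14))
  list(
    list(c(ids[1], ids[2]), c(ids[3], ids[4])),
    list(c(ids[1], ids[3]), c(ids[2], ids[4])),
    list(c(ids[1], ids[4]), c(ids[2], ids[3]))
  )[[best]]
}

region_seq_test <- function(s, iv) substr(s, iv[1], iv[2])

included_cols_test <- function(haps) {
  m <- do.call(rbind, strsplit(haps, ""))
  which(colSums(m == "-") == 0L)
}

tree_splits <- function(tree) {
  # leaf bipartitions induced by internal edges
  unroot <- ape::unroot(tree)
  parts <- ape::prop.part(unroot)
  labs <- attr(parts, "labels")
  lapply(parts, function(p) sort(labs[p]))
}
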