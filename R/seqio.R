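# Readers/writers for the external formats the pipeline consumes, and the
# shared sequence/annotation containers.  Coordinates are 1-based inclusive
# throughout the package.

#' Read a FASTA file into a set of sequence records
#'
#' Parses protein or nucleotide FASTA.  Residues are uppercased; the 20
#' canonical amino-acid letters plus `X` are accepted for proteins
#' (`A C G T N` and the gap character for nucleotide alignments).  Duplicate
#' identifiers, empty sequences and illegal characters are errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param allow_gaps logical; accept `-` in the sequence body (for
#'   pre-computed alignments).
#' @return a `data.frame` of class `seq_set` with columns `id`, `residues`,
#'   `description`, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  check_that(file.exists(path), "FASTA file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  check_that(length(x) >= 1L, "empty FASTA: %s", path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers), ""
  )
  dup <- id[duplicated(id)]
  check_that(length(dup) == 0L,
    "duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")
  )
  residues <- toupper(as.character(x))
  names(residues) <- NULL
  empty <- id[nchar(residues) == 0L]
  check_that(length(empty) == 0L,
    "empty sequence for id(s): %s", paste(empty, collapse = ", ")
  )
  legal <- if (alphabet == "protein") c(AA_CANONICAL, "X") else NT_CANONICAL
  if (allow_gaps) legal <- c(legal, "-")
  for (i in seq_along(residues)) {
    ch <- strsplit(residues[[i]], "")[[1]]
    bad <- which(!ch %in% legal)
    check_that(length(bad) == 0L,
      "illegal character '%s' at position %d in sequence '%s'",
      if (length(bad)) ch[bad[1]] else "", if (length(bad)) bad[1] else 0L,
      id[i]
    )
  }
  out <- data.frame(
    id = id, residues = residues, description = description,
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Write sequence records to FASTA
#'
#' @param records a `seq_set` (or data.frame with `id`, `residues`, and
#'   optionally `description`).
#' @param path output path.
#' @param width line-wrap width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records)) records$description[i] else ""
    hdr <- if (nzchar(desc)) {
      paste0(">", records$id[i], " ", desc)
    } else {
      paste0(">", records$id[i])
    }
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", records$residues[i])
    cat(hdr, "\n", body, file = con, sep = "")
  }
  invisible(path)
}

#' Read a gapped multiple alignment from FASTA
#'
#' All rows must have equal (gapped) length and there must be at least two
#' rows.  The gap character is `-`.
#'
#' @inheritParams read_fasta
#' @return an object of class `alignment_block`: a list with `ids`, `rows`
#'   (named character vector of gapped sequences) and `alphabet`.
#' @export
read_alignment <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  recs <- read_fasta(path, alphabet, allow_gaps = TRUE)
  alignment_block(recs$id, recs$residues, alphabet)
}

#' Construct an alignment block
#'
#' @param ids character vector of unique row identifiers.
#' @param rows character vector of equal-length gapped sequences.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return an `alignment_block`.
#' @export
alignment_block <- function(ids, rows, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  check_that(length(ids) == length(rows), "ids and rows differ in length")
  check_that(length(ids) >= 2L, "an alignment needs at least 2 rows")
  check_that(!anyDuplicated(ids), "duplicate ids in alignment")
  w <- unique(nchar(rows))
  check_that(length(w) == 1L, "alignment rows differ in length")
  rows <- toupper(rows)
  names(rows) <- ids
  structure(
    list(ids = as.character(ids), rows = rows, alphabet = alphabet,
         width = w),
    class = "alignment_block"
  )
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf(
    "<alignment_block> %d x %d (%s)\n", length(x$ids), x$width, x$alphabet
  ))
  invisible(x)
}

#' Write an alignment block to gapped FASTA
#'
#' @param aln an `alignment_block`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(
    data.frame(id = aln$ids, residues = unname(aln$rows[aln$ids])),
    path
  )
}

#' Read a domain-annotation table
#'
#' Two dialects are supported: a plain TSV with columns `protein_id`,
#' `domain_name`, `start`, `end` and optionally `evalue`; and HMMER's
#' `domtblout` (whitespace-delimited, `#` comment lines), from which the
#' envelope coordinates are taken.  Coordinates are 1-based inclusive;
#' `start > end` is an error.  E-value filtering is left to the caller.
#'
#' @param path path to the table.
#' @param dialect `"tsv"` or `"hmmer_domtblout"`.
#' @return a `data.frame` with columns `protein_id`, `domain_name`, `start`,
#'   `end`, `evalue` (NA when absent), sorted by `protein_id` then `start`.
#' @export
read_domain_table <- function(path, dialect = c("tsv", "hmmer_domtblout")) {
  dialect <- match.arg(dialect)
  check_that(file.exists(path), "domain table not found: %s", path)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "domain_name", "start", "end")
    miss <- setdiff(need, names(tab))
    check_that(length(miss) == 0L,
      "domain table missing column(s): %s", paste(miss, collapse = ", ")
    )
    if (!"evalue" %in% names(tab)) tab$evalue <- NA_real_
    hits <- tab[, c("protein_id", "domain_name", "start", "end", "evalue")]
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "\\s+")
    # domtblout layout: target name [1], query name [4], i-Evalue [13],
    # env coords [20,21]; description from field 23 onward.
    hits <- do.call(rbind, lapply(fields, function(f) {
      check_that(length(f) >= 22L, "malformed domtblout row: %s",
                 paste(f, collapse = " "))
      data.frame(
        protein_id = f[1], domain_name = f[4],
        start = as.integer(f[20]), end = as.integer(f[21]),
        evalue = as.numeric(f[13]), stringsAsFactors = FALSE
      )
    }))
    if (is.null(hits)) {
      hits <- data.frame(
        protein_id = character(), domain_name = character(),
        start = integer(), end = integer(), evalue = numeric()
      )
    }
  }
  hits$start <- as.integer(hits$start)
  hits$end <- as.integer(hits$end)
  bad <- which(is.na(hits$start) | is.na(hits$end) |
                 hits$start < 1L | hits$start > hits$end)
  check_that(length(bad) == 0L,
    "invalid coordinates (start > end or non-positive) at row %d",
    if (length(bad)) bad[1] else 0L
  )
  check_that(all(is.na(hits$evalue) | hits$evalue >= 0),
             "negative e-value in domain table")
  hits <- hits[order(hits$protein_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read a variant table (VCF subset or TSV)
#'
#' The VCF dialect reads CHROM, POS, REF, ALT and per-sample GT fields (or,
#' failing that, `AC`/`AN` from INFO).  Multi-allelic sites are decomposed
#' into one record per alternate allele.  Missing genotypes (`.`) are counted
#' as absent haplotypes, never as reference.  The TSV dialect has columns
#' `locus_id`, `position`, `ref`, `alt`, `ref_count`, `alt_count`.
#'
#' @param path path to the file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return a `data.frame` with columns `locus_id`, `position`, `ref`, `alt`,
#'   `vtype` (`"SNP"`/`"indel"`), `ref_count`, `alt_count`.
#' @export
read_variant_table <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  check_that(file.exists(path), "variant table not found: %s", path)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("locus_id", "position", "ref", "alt", "ref_count", "alt_count")
    miss <- setdiff(need, names(tab))
    check_that(length(miss) == 0L,
      "variant table missing column(s): %s", paste(miss, collapse = ", ")
    )
    out <- tab[, need]
  } else {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    rows <- lapply(body, parse_vcf_record)
    out <- do.call(rbind, rows)
  }
  check_that(!is.null(out) && nrow(out) > 0L, "no variant records in %s", path)
  out$vtype <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                      "SNP", "indel")
  check_that(all(out$ref_count >= 0 & out$alt_count >= 0),
             "negative allele count")
  check_that(all(out$ref_count + out$alt_count > 0),
             "variant with zero total allele count")
  out <- out[, c("locus_id", "position", "ref", "alt", "vtype",
                 "ref_count", "alt_count")]
  rownames(out) <- NULL
  out
}

# One VCF data line -> decomposed per-alt-allele rows with allele counts.
parse_vcf_record <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  check_that(length(f) >= 8L, "malformed VCF record: %s", line)
  chrom <- f[1]
  pos <- as.integer(f[2])
  ref <- toupper(f[4])
  alts <- strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]
  n_alt <- length(alts)
  if (length(f) >= 10L && grepl("GT", strsplit(f[9], ":")[[1]][1])) {
    gt_idx <- which(strsplit(f[9], ":", fixed = TRUE)[[1]] == "GT")
    calls <- vapply(f[-(1:9)], function(s) {
      strsplit(s, ":", fixed = TRUE)[[1]][gt_idx]
    }, character(1))
    alleles <- unlist(strsplit(calls, "[/|]"))
    alleles <- alleles[alleles != "."]  # missing = absent haplotype
    counts <- tabulate(as.integer(alleles) + 1L, nbins = n_alt + 1L)
    ref_n <- counts[1]
    alt_n <- counts[-1]
  } else {
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, "="), info, value = TRUE)
      if (length(hit) == 0L) return(NULL)
      as.integer(strsplit(sub("^[A-Z]+=", "", hit[1]), ",")[[1]])
    }
    ac <- get_field("AC")
    an <- get_field("AN")
    check_that(!is.null(ac) && !is.null(an),
               "VCF record lacks both GT and AC/AN: %s", line)
    check_that(length(ac) == n_alt, "AC arity mismatch: %s", line)
    check_that(sum(ac) <= an, "AC exceeds AN in record: %s", line)
    ref_n <- an - sum(ac)
    alt_n <- ac
  }
  data.frame(
    locus_id = chrom, position = pos, ref = ref, alt = alts,
    ref_count = ref_n, alt_count = alt_n, stringsAsFactors = FALSE
  )
}

#' Write a variant table as TSV
#'
#' Round-trips with [read_variant_table()] (`dialect = "tsv"`).
#'
#' @param variants data.frame as returned by [read_variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tree in newick format
#'
#' Standard newick with branch lengths, terminated by `;`.  Negative branch
#' lengths (possible in raw neighbor-joining output) are written as-is with
#' a warning.
#'
#' @param tree an object of class `phylo` (see [nj_tree()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  check_that(inherits(tree, "phylo"), "`tree` must be a 'phylo' object")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    warning("tree contains negative branch lengths; writing as-is")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
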