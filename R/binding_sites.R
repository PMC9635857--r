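# Mapping the ten putative basic DNA-binding sites of the globular domain
# through an alignment, and counting how many are conserved per protein.

#' Default GH1 binding-site positions
#'
#' The ten putative basic DNA-binding sites of the plant GH1 domain, in
#' ungapped GH1-domain coordinates: His2 (5' of helix I), Lys17 and
#' Arg/Lys19 (between helices I and II), Lys29 (helix II), Lys43, Lys/Arg44,
#' Lys51, Lys52 (helix III), Lys61 and Lys67 (beta-hairpin).  Users working
#' in the avian GH5 numbering can supply their own positions to
#' [build_site_map()].
#'
#' @return data.frame with columns `label`, `context`, `position`.
#' @export
h1_binding_sites <- function() {
  data.frame(
    label = c("His2", "Lys17", "Arg19", "Lys29", "Lys43", "Lys44",
              "Lys51", "Lys52", "Lys61", "Lys67"),
    context = c("pre_helix_I", "between_I_II", "between_I_II", "helix_II",
                "helix_III", "helix_III", "helix_III", "helix_III",
                "beta_hairpin", "beta_hairpin"),
    position = c(2L, 17L, 19L, 29L, 43L, 44L, 51L, 52L, 61L, 67L),
    stringsAsFactors = FALSE
  )
}

#' Build a reference site map on an alignment
#'
#' Converts unaligned (ungapped) residue positions of a reference sequence
#' into alignment columns, gap-aware.
#'
#' @param alignment an `alignment_block` of GH1 domains.
#' @param reference_id row to use as the coordinate reference.
#' @param sites data.frame with `label`, `context`, `position` (ungapped,
#'   1-based); defaults to [h1_binding_sites()].
#' @return object of class `site_map`: the input data.frame plus a `column`
#'   field (1-based alignment column), attributes `reference_id`.
#' @export
build_site_map <- function(alignment, reference_id,
                           sites = h1_binding_sites()) {
  check_that(reference_id %in% alignment$ids,
             "reference '%s' not in alignment", reference_id)
  ref <- strsplit(alignment$rows[[reference_id]], "")[[1]]
  ungapped_cols <- which(ref != "-")
  bad <- sites$position[sites$position > length(ungapped_cols) |
                          sites$position < 1L]
  check_that(length(bad) == 0L,
    "site position %d outside the reference's ungapped length (%d)",
    if (length(bad)) bad[1] else 0L, length(ungapped_cols)
  )
  out <- sites
  out$column <- ungapped_cols[sites$position]
  check_that(!is.unsorted(out$column, strictly = TRUE),
             "site columns must be strictly increasing")
  attr(out, "reference_id") <- reference_id
  class(out) <- c("site_map", "data.frame")
  out
}

#' Score binding-site conservation for one protein
#'
#' For each mapped site column, records the protein's residue and whether it
#' is basic (K, R or H -- His counts because His2 is itself one of the ten
#' sites).  A gap is never basic.  Conservation is class-based: a site
#' replaced by a chemically similar but non-basic residue counts as not
#' conserved.
#'
#' @param alignment an `alignment_block` containing `protein_id`.
#' @param map a `site_map` from [build_site_map()].
#' @param protein_id row to score.
#' @return list of class `conservation_report` with `protein_id`, `sites`
#'   (data.frame: `label`, `column`, `residue`, `is_basic`) and
#'   `conserved_count` (0-10).
#' @export
score_conservation <- function(alignment, map, protein_id) {
  check_that(protein_id %in% alignment$ids,
             "protein '%s' not in alignment", protein_id)
  row <- strsplit(alignment$rows[[protein_id]], "")[[1]]
  residue <- row[map$column]
  is_basic <- residue %in% c("K", "R", "H")
  structure(
    list(
      protein_id = protein_id,
      sites = data.frame(
        label = map$label, column = map$column,
        residue = residue, is_basic = is_basic, stringsAsFactors = FALSE
      ),
      conserved_count = sum(is_basic)
    ),
    class = "conservation_report"
  )
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %s: %d/%d basic sites\n",
              x$protein_id, x$conserved_count, nrow(x$sites)))
  invisible(x)
}
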