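# Whole-proteome classification pipeline: ties partition, physchem, AT-hook,
# binding-site and threshold logic together into one report.

# Score the ten sites directly on an ungapped GH1 domain sequence (used when
# no cross-protein GH1 alignment is supplied).  Positions beyond the domain
# length count as not conserved.
score_sites_direct <- function(gh1_seq, protein_id,
                               sites = h1_binding_sites()) {
  ch <- strsplit(gh1_seq, "")[[1]]
  residue <- ifelse(sites$position <= length(ch), ch[sites$position], "-")
  is_basic <- residue %in% c("K", "R", "H")
  structure(
    list(
      protein_id = protein_id,
      sites = data.frame(label = sites$label, column = sites$position,
                         residue = residue, is_basic = is_basic,
                         stringsAsFactors = FALSE),
      conserved_count = sum(is_basic)
    ),
    class = "conservation_report"
  )
}

#' Classify every protein of a proteome
#'
#' Runs the full identification pipeline per protein: tripartite partition
#' from the GH1 hits, AT-hook detection, architecture grouping, the
#' physicochemical panel, the CTD moving-charge profile, binding-site
#' conservation, and the final H1 verdict.  Binding sites are scored on a
#' supplied GH1 alignment (gap-aware, via a reference) or, failing that,
#' directly on each protein's own GH1 domain in domain coordinates.
#' Proteins without a GH1 hit are skipped with a warning.
#'
#' @param records a `seq_set` of proteins.
#' @param hits domain table (see [read_domain_table()]).
#' @param gh1_alignment optional `alignment_block` of GH1 domains.
#' @param reference_id reference row of `gh1_alignment` for site mapping.
#' @param sites binding-site table (default [h1_binding_sites()]).
#' @param criteria an `h1_criteria`.
#' @return data.frame, one row per classified protein: verdict, group,
#'   criterion booleans and the underlying metric values.
#' @export
classify_proteome <- function(records, hits, gh1_alignment = NULL,
                              reference_id = NULL,
                              sites = h1_binding_sites(),
                              criteria = h1_criteria()) {
  map <- NULL
  if (!is.null(gh1_alignment)) {
    if (is.null(reference_id)) reference_id <- gh1_alignment$ids[1]
    map <- build_site_map(gh1_alignment, reference_id, sites)
  }
  rows <- list()
  for (i in seq_len(nrow(records))) {
    prot <- records[i, ]
    my_hits <- hits[hits$protein_id == prot$id, , drop = FALSE]
    if (!any(my_hits$domain_name == "GH1")) {
      warning(sprintf("skipping %s: no GH1 hit", prot$id))
      next
    }
    part <- partition_protein(prot, my_hits)
    hooks <- find_at_hooks(prot)
    arch <- classify_architecture(part, my_hits, hooks)
    prof <- physchem_profile(prot, part)
    charge <- if (!is.null(part$ctd)) {
      charge_profile(part, prot$residues, "CTD")
    } else {
      NULL
    }
    cons <- if (!is.null(map) && prot$id %in% gh1_alignment$ids) {
      score_conservation(gh1_alignment, map, prot$id)
    } else {
      score_sites_direct(region_seq(prot$residues, part$gh1s[[1]]),
                         prot$id, sites)
    }
    call <- classify_h1(arch, prof, charge, cons, criteria)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = prot$id, verdict = call$verdict, group = arch$group,
      architecture_ok = call$architecture_ok,
      ctd_lysine_ok = call$ctd_lysine_ok,
      ctd_charge_ok = call$ctd_charge_ok,
      charge_evenness_ok = call$charge_evenness_ok,
      binding_sites_ok = call$binding_sites_ok,
      n_gh1 = arch$n_gh1, has_myb = arch$has_myb,
      n_at_hooks = arch$n_at_hooks,
      length_total = prof$length$total, length_ntd = prof$length$ntd,
      length_gh1 = sum(prof$length$gh1), length_ctd = prof$length$ctd,
      mw_kda = prof$mw_kda, pi = prof$pi,
      lysine_total = prof$lysine_pct$total,
      lysine_ctd = prof$lysine_pct$ctd,
      net_charge_total = prof$net_charge$total,
      net_charge_ctd = prof$net_charge$ctd,
      min_window_sum = if (is.null(charge)) NA_integer_ else charge$min_sum,
      conserved_sites = cons$conserved_count,
      stringsAsFactors = FALSE
    )
  }
  check_that(length(rows) > 0L, "no classifiable proteins")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
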