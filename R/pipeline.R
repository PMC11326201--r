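# End-to-end case orchestration: the five pipeline phases wired together
# over a fixture (or equivalently formatted real) bundle.

#' Preprocess genomic variants into a VUStruct CSV record frame
#'
#' Phase 1: each VCF variant is consequence-called against every transcript
#' model on its chromosome; missense consequences are retained and
#' restricted to the curated (UniProt cross-referenced) transcript subset.
#'
#' @param vcf_path VCF file.
#' @param catalog list of [transcript_model()]s.
#' @return data frame in [parse_vustruct_csv()] layout (one row per
#'   missense consequence on a curated transcript).
#' @export
preprocess_vcf <- function(vcf_path, catalog) {
  gvs <- read_vcf_variants(vcf_path)
  rows <- list()
  for (i in seq_len(nrow(gvs))) {
    gv <- as.list(gvs[i, ])
    for (tm in catalog) {
      if (tm$chrom != gv$chrom) next
      cr <- call_consequence(gv, tm)
      if (cr$consequence != "missense") next
      if (is.na(tm$uniprot_acc)) next       # curated subset only
      rows[[length(rows) + 1L]] <- data.frame(
        gene = tm$gene, transcript = tm$transcript_id,
        unp = tm$uniprot_acc, ref_aa = cr$change$ref_aa,
        pos = cr$change$position, alt_aa = cr$change$alt_aa,
        inheritance = "unknown", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(0), transcript = character(0),
                      unp = character(0), ref_aa = character(0),
                      pos = integer(0), alt_aa = character(0),
                      inheritance = character(0)))
  do.call(rbind, rows)
}

#' Run a full case end-to-end
#'
#' Phases 1-5 over a bundle directory (as produced by [make_case()]):
#' preprocess (VCF -> missense records on curated transcripts), reconcile
#' cross-references (HALT on discrepancy unless `force`), select
#' structures per record, plan and materialize the work tree, execute all
#' jobs through the stub contract, aggregate status, collect metrics,
#' summarize, attach precomputed scores, score digenic pairs, and render
#' the report.
#'
#' @param bundle_dir directory holding `case.vcf`, `transcripts.json`,
#'   `xrefs.tsv`, `structures.json`, `labels_*.tsv` and precomputed score
#'   TSVs.
#' @param out_root output root (the case tree is created under
#'   `<out_root>/VUStruct/<full_id>`; the report under
#'   `<out_root>/report`).
#' @param user_case_id case name.
#' @param guid optional fixed GUID for reproducible paths.
#' @param force proceed despite cross-reference discrepancies.
#' @param calcs structural calculators to plan.
#' @param n_perm,seed PathProx permutation settings.
#' @param digenic_threshold reporting threshold for digenic pairs.
#' @return list: `records`, `reconciliation`, `plan`, `status`,
#'   `metric_rows`, `summary`, `digenic`, `report_dir` (`NULL` past-halt
#'   fields when halted).
#' @export
run_case <- function(bundle_dir, out_root, user_case_id = "case",
                     guid = NULL, force = FALSE,
                     calcs = c("ddg_cartesian", "pathprox"),
                     n_perm = 199, seed = 1, digenic_threshold = 0.5) {
  catalog <- read_transcript_catalog(file.path(bundle_dir, "transcripts.json"))
  xrefs <- read_xref_catalog(file.path(bundle_dir, "xrefs.tsv"))
  records <- preprocess_vcf(file.path(bundle_dir, "case.vcf"), catalog)
  rec <- reconcile_case(records, xrefs, force = force)
  if (rec$halt)
    return(list(records = records, reconciliation = rec, plan = NULL,
                status = NULL, metric_rows = NULL, summary = NULL,
                digenic = NULL, report_dir = NULL))
  runnable <- rec$runnable

  struct_catalog <- read_structure_catalog(file.path(bundle_dir,
                                                     "structures.json"))
  models <- setNames(catalog, vapply(catalog, `[[`, character(1),
                                     "transcript_id"))
  gene_map <- vapply(models, `[[`, character(1), "gene")

  variants <- list()
  for (i in seq_len(nrow(runnable))) {
    r <- runnable[i, ]
    tm <- models[[r$transcript]]
    cands <- struct_catalog[[r$transcript]] %||% list()
    cands <- Filter(Negate(is.null),
                    lapply(cands, ensure_residue_map,
                           transcript_seq = tm$protein_seq))
    sel <- if (length(cands) > 0)
      select_structures(cands, variant_pos = r$pos,
                        transcript_length = nchar(tm$protein_seq),
                        canonical = tm$canonical)
    else structure(list(chosen = list(), scores = numeric(0),
                        rationale = character(0), context_only = FALSE),
                   class = "selection_result")
    # pathprox parameters: map labeled transcript positions and the query
    # onto each chosen structure's residues
    calc_params <- list()
    lab_path <- file.path(bundle_dir, paste0("labels_", r$transcript, ".tsv"))
    if (file.exists(lab_path) && length(sel$chosen) > 0) {
      labels <- read_variant_table(lab_path)
      pp <- lapply(sel$chosen, function(cand) {
        rm <- cand$residue_map
        key_of <- function(pos) {
          hit <- rm[rm$transcript_pos %in% pos, , drop = FALSE]
          paste(hit$chain_id, hit$residue_number, sep = ":")
        }
        p_keys <- key_of(labels$transcript_position[labels$label == "pathogenic"])
        b_keys <- key_of(labels$transcript_position[labels$label == "benign"])
        q_keys <- key_of(r$pos)
        if (length(p_keys) == 0 || length(b_keys) == 0 || length(q_keys) == 0)
          return(NULL)
        list(structure_id = cand$structure_id, query_keys = q_keys,
             p_keys = p_keys, b_keys = b_keys, n_perm = n_perm, seed = seed)
      })
      pp <- Filter(Negate(is.null), pp)
      if (length(pp) > 0) {
        by_structure <- setNames(lapply(pp, function(x) x[-1]),
                                 vapply(pp, `[[`, character(1), "structure_id"))
        calc_params$pathprox <- list(by_structure = by_structure)
      }
    }
    variants[[length(variants) + 1L]] <- list(
      gene = r$gene, transcript_id = r$transcript,
      mutation = paste0(r$ref_aa, r$pos, r$alt_aa),
      selection = sel, calc_params = calc_params)
  }

  case <- new_case_id(user_case_id, guid = guid)
  plan <- plan_case(case, variants, calcs = calcs)
  materialize_case(plan, out_root)
  # pathprox jobs read coordinates relative to the case root; coord paths in
  # the catalog are absolute after read_structure_catalog, keep them usable
  run_all_stubs(plan, out_root)
  status <- aggregate_status(out_root, case$full_id)

  collected <- collect_results(out_root, case$full_id, gene_map = gene_map)
  runnable$variant <- paste0(runnable$gene, ":", runnable$ref_aa,
                             runnable$pos, runnable$alt_aa)
  ranges <- summarize_ranges(collected$rows,
                             variants = unique(runnable$variant))
  summary <- case_summary(runnable, ranges)
  tables <- list()
  for (nm in c("alphamissense_like", "consurf_like", "cosmis_like")) {
    p <- file.path(bundle_dir, paste0(nm, ".tsv"))
    if (file.exists(p)) tables[[nm]] <- read_score_table(p)
  }
  if (length(tables) > 0) summary <- attach_precomputed(summary, tables)
  digenic <- digenic_candidates(unique(runnable$gene),
                                threshold = digenic_threshold)
  flagged_genes <- unique(c(digenic$gene_a, digenic$gene_b))
  summary$digenic_flag <- summary$gene %in% flagged_genes
  summary$recommendation <- ""

  isoforms <- do.call(rbind, lapply(seq_len(nrow(runnable)), function(i) {
    r <- runnable[i, ]
    exp <- expand_isoforms(r, catalog)
    if (length(exp$pairs) == 0) return(NULL)
    data.frame(variant = r$variant,
               transcript = vapply(exp$pairs, function(p)
                 p$transcript$transcript_id, character(1)),
               canonical = vapply(exp$pairs, function(p)
                 p$transcript$canonical, logical(1)),
               unp = vapply(exp$pairs, function(p)
                 p$transcript$uniprot_acc, character(1)),
               stringsAsFactors = FALSE)
  }))
  report_dir <- file.path(out_root, "report")
  render_case(summary, collected$rows, digenic, isoforms, report_dir,
              case_title = paste("Case", user_case_id))
  list(records = records, reconciliation = rec, plan = plan,
       status = status, metric_rows = collected$rows, summary = summary,
       digenic = digenic, report_dir = report_dir, case = case,
       isoforms = isoforms)
}
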