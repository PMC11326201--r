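# Candidate 3D structures: residue mapping, scoring, and greedy selection of
# a non-redundant, technique-diverse representative set.

STRUCTURE_SOURCES <- c("PDB", "SWISSMODEL", "MODBASE", "ALPHAFOLD")
STRUCTURE_METHODS <- c("XRAY", "NMR", "EM", "PREDICTED")

#' Default structure-selection weights
#'
#' Linear score weights: variant coverage dominates (`w_var = 4`); overall
#' coverage, experimental quality, model confidence, multimer status, and
#' experimental (non-predicted) method each contribute with weight 1.
#'
#' @return named numeric vector.
#' @export
default_selection_weights <- function() {
  c(w_cov = 1, w_var = 4, w_qual = 1, w_conf = 1, w_multi = 1, w_exp = 1)
}

# global Needleman-Wunsch with linear gaps; deterministic traceback
# preference: diagonal, then up (gap in b), then left (gap in a).
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  i <- n; j <- m; pi <- integer(0); pj <- integer(0)
  while (i > 0 && j > 0) {
    sc <- S[i + 1, j + 1]
    d <- S[i, j] + (if (av[i] == bv[j]) match else mismatch)
    if (sc == d) {
      pi <- c(i, pi); pj <- c(j, pj); i <- i - 1; j <- j - 1
    } else if (sc == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = S[n + 1, m + 1],
       pairs = data.frame(i = pi, j = pj),
       identical = if (length(pi)) av[pi] == bv[pj] else logical(0))
}

#' Map transcript positions to structure residues
#'
#' If the structure's sequence is an exact substring of the transcript
#' protein, positions map by offset. Otherwise a global pairwise alignment
#' (match +1, mismatch -1, linear gap -2) is computed and only aligned,
#' *identical* positions are mapped. Unresolved residues (absent from the
#' coordinate file) never enter the map. If the fraction of structure
#' residues aligned to an identical transcript residue falls below
#' `min_identity` the candidate is unmappable and an error of class
#' `vustruct_no_map` is signalled.
#'
#' @param transcript_seq transcript protein sequence.
#' @param struct_seq the structure's one-letter sequence (one entry per
#'   residue in the coordinate file's chain, including unresolved ones).
#' @param resolved logical vector parallel to `struct_seq`; `FALSE` marks
#'   residues without coordinates. Default all resolved.
#' @param chain_id chain identifier for the mapped residues.
#' @param residue_numbers author residue numbers parallel to `struct_seq`;
#'   default `1..n`.
#' @param min_identity alignment identity floor in `[0, 1]`.
#' @return a data frame of class `residue_map` with columns
#'   `transcript_pos`, `chain_id`, `residue_number`; the covered set is the
#'   `transcript_pos` column.
#' @export
map_transcript_to_structure <- function(transcript_seq, struct_seq,
                                        resolved = NULL, chain_id = "A",
                                        residue_numbers = NULL,
                                        min_identity = 0.4) {
  if (!nzchar(transcript_seq) || !nzchar(struct_seq))
    vu_stop("vustruct_input_error", "empty sequence")
  ns <- nchar(struct_seq)
  if (is.null(resolved)) resolved <- rep(TRUE, ns)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(ns)
  stopifnot(length(resolved) == ns, length(residue_numbers) == ns)
  off <- regexpr(struct_seq, transcript_seq, fixed = TRUE)
  if (off > 0) {
    keep <- which(resolved)
    rm <- data.frame(transcript_pos = as.integer(off) + keep - 1L,
                     chain_id = rep(chain_id, length(keep)),
                     residue_number = residue_numbers[keep])
  } else {
    al <- align_global(transcript_seq, struct_seq)
    identity <- sum(al$identical) / ns
    if (identity < min_identity)
      vu_stop("vustruct_no_map",
              "alignment identity %.2f below floor %.2f", identity, min_identity)
    keep <- al$identical & resolved[al$pairs$j]
    rm <- data.frame(transcript_pos = al$pairs$i[keep],
                     chain_id = rep(chain_id, sum(keep)),
                     residue_number = residue_numbers[al$pairs$j[keep]])
  }
  if (anyDuplicated(rm$transcript_pos))
    vu_stop("vustruct_input_error", "residue map is not injective")
  class(rm) <- c("residue_map", "data.frame")
  rm
}

#' Construct a structure candidate
#'
#' One candidate 3D structure for a transcript: provenance, method, quality
#' metadata, coordinates, and (optionally precomputed) residue map. When
#' `residue_map` is `NULL` it must be derived later with
#' [map_transcript_to_structure()] from the candidate's `struct_seq`.
#'
#' @param structure_id identifier.
#' @param source one of `PDB`, `SWISSMODEL`, `MODBASE`, `ALPHAFOLD`.
#' @param method one of `XRAY`, `NMR`, `EM`, `PREDICTED`. `ALPHAFOLD`
#'   sources must be `PREDICTED` (with `mean_confidence` present); `PDB`
#'   sources must be experimental.
#' @param coord_path path to a PDB-format coordinate file.
#' @param resolution resolution in Angstrom (experimental entries), or `NA`.
#' @param mean_confidence mean per-residue model confidence 0-100, or `NA`.
#' @param is_multimer does the file contain a multimeric complex?
#' @param chain_ids chains present.
#' @param seq_identity template/target identity percent (models), or `NA`.
#' @param residue_map optional precomputed [map_transcript_to_structure()]
#'   result (takes precedence over alignment).
#' @param struct_seq,resolved,residue_numbers per-residue inputs used to
#'   derive the map when it is not precomputed.
#' @return an object of class `structure_candidate`.
#' @export
structure_candidate <- function(structure_id, source, method, coord_path,
                                resolution = NA, mean_confidence = NA,
                                is_multimer = FALSE, chain_ids = "A",
                                seq_identity = NA, residue_map = NULL,
                                struct_seq = NULL, resolved = NULL,
                                residue_numbers = NULL) {
  source <- match.arg(source, STRUCTURE_SOURCES)
  method <- match.arg(method, STRUCTURE_METHODS)
  if (source == "ALPHAFOLD" && (method != "PREDICTED" || is.na(mean_confidence)))
    vu_stop("vustruct_catalog_error",
            "ALPHAFOLD candidates must be PREDICTED with mean_confidence")
  if (source == "PDB" && method == "PREDICTED")
    vu_stop("vustruct_catalog_error", "PDB candidates must be experimental")
  structure(list(structure_id = structure_id, source = source,
                 method = method, coord_path = coord_path,
                 resolution = as.numeric(resolution),
                 mean_confidence = as.numeric(mean_confidence),
                 is_multimer = isTRUE(is_multimer),
                 chain_ids = chain_ids,
                 seq_identity = as.numeric(seq_identity),
                 residue_map = residue_map,
                 struct_seq = struct_seq, resolved = resolved,
                 residue_numbers = residue_numbers),
            class = "structure_candidate")
}

# ensure the candidate carries a residue map; returns the candidate or NULL
# when it cannot be mapped (identity floor)
ensure_residue_map <- function(cand, transcript_seq, min_identity = 0.4) {
  if (!is.null(cand$residue_map)) return(cand)
  if (is.null(cand$struct_seq))
    vu_stop("vustruct_catalog_error",
            "candidate %s has neither residue_map nor struct_seq", cand$structure_id)
  rm <- tryCatch(
    map_transcript_to_structure(transcript_seq, cand$struct_seq,
                                resolved = cand$resolved,
                                chain_id = cand$chain_ids[1],
                                residue_numbers = cand$residue_numbers,
                                min_identity = min_identity),
    vustruct_no_map = function(e) NULL)
  if (is.null(rm)) return(NULL)
  cand$residue_map <- rm
  cand
}

covered_set <- function(cand) cand$residue_map$transcript_pos

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Score a structure candidate for a variant
#'
#' Linear combination of transcript coverage, variant coverage,
#' experimental quality (`q = clamp((4 - resolution) / 4, 0, 1)` for
#' experimental entries with a resolution, else 0), model confidence,
#' multimer status, and experimental method. Absent fields contribute 0.
#'
#' @param cand a [structure_candidate()] with a residue map.
#' @param variant_pos transcript position of the variant.
#' @param transcript_length protein length of the transcript.
#' @param weights named vector as [default_selection_weights()].
#' @return numeric score.
#' @export
score_candidate <- function(cand, variant_pos, transcript_length,
                            weights = default_selection_weights()) {
  if (any(weights < 0)) vu_stop("vustruct_input_error", "weights must be non-negative")
  cov <- covered_set(cand)
  q <- if (cand$method != "PREDICTED" && !is.na(cand$resolution))
    min(max((4.0 - cand$resolution) / 4.0, 0), 1) else 0
  conf <- if (!is.na(cand$mean_confidence)) cand$mean_confidence / 100 else 0
  unname(
    weights["w_cov"] * (length(cov) / transcript_length) +
    weights["w_var"] * (variant_pos %in% cov) +
    weights["w_qual"] * q +
    weights["w_conf"] * conf +
    weights["w_multi"] * cand$is_multimer +
    weights["w_exp"] * (cand$method != "PREDICTED"))
}

#' Select a representative structure set
#'
#' Greedy selection: (1) candidates not covering the variant are discarded
#' unless nothing covers it, in which case all are kept flagged
#' "context-only"; (2) candidates are sorted by descending score with
#' tie-break (experimental before predicted, lower resolution, lexicographic
#' id); (3) candidates are accepted in order, skipping any whose covered-set
#' Jaccard similarity with an already-accepted candidate of the same method
#' exceeds `jaccard_max`; (4) for canonical transcripts an AlphaFold model,
#' when present among the eligible candidates, is always included.
#'
#' @param cands list of [structure_candidate()]s, all mapped to one
#'   transcript (residue maps present).
#' @param variant_pos transcript position of the variant.
#' @param transcript_length protein length.
#' @param canonical is the transcript the canonical isoform?
#' @param weights selection weights.
#' @param jaccard_max redundancy threshold on covered-set Jaccard
#'   similarity within a method class (default 0.9).
#' @param max_structures optional cap on the number selected (no default cap).
#' @return object of class `selection_result`: `chosen` (ordered candidate
#'   list), `scores` (named, all candidates), `rationale` (per chosen),
#'   `context_only` (flag).
#' @export
select_structures <- function(cands, variant_pos, transcript_length,
                              canonical = FALSE,
                              weights = default_selection_weights(),
                              jaccard_max = 0.9, max_structures = Inf) {
  empty <- structure(list(chosen = list(), scores = numeric(0),
                          rationale = character(0), context_only = FALSE),
                     class = "selection_result")
  if (length(cands) == 0) {
    vu_warn("empty candidate list; nothing selected")
    return(empty)
  }
  covers <- vapply(cands, function(c) variant_pos %in% covered_set(c), logical(1))
  context_only <- !any(covers)
  pool <- if (context_only) cands else cands[covers]
  scores <- vapply(pool, score_candidate, numeric(1),
                   variant_pos = variant_pos,
                   transcript_length = transcript_length, weights = weights)
  ids <- vapply(pool, `[[`, character(1), "structure_id")
  names(scores) <- ids
  resol <- vapply(pool, function(c) if (is.na(c$resolution)) Inf else c$resolution,
                  numeric(1))
  predicted <- vapply(pool, function(c) c$method == "PREDICTED", logical(1))
  ord <- order(-scores, predicted, resol, ids)
  pool <- pool[ord]; scores <- scores[ord]
  chosen <- list(); rationale <- character(0)
  for (k in seq_along(pool)) {
    cand <- pool[[k]]
    redundant <- any(vapply(chosen, function(c)
      c$method == cand$method &&
        jaccard(covered_set(c), covered_set(cand)) > jaccard_max, logical(1)))
    if (redundant) next
    if (length(chosen) >= max_structures) break
    chosen[[length(chosen) + 1L]] <- cand
    rationale <- c(rationale,
                   sprintf("%s (%s/%s) score %.3f", cand$structure_id,
                           cand$source, cand$method, scores[k]))
  }
  if (canonical) {
    have_af <- any(vapply(chosen, function(c) c$source == "ALPHAFOLD", logical(1)))
    af_pool <- which(vapply(pool, function(c) c$source == "ALPHAFOLD", logical(1)))
    if (!have_af && length(af_pool) > 0) {
      best <- af_pool[1]   # pool already score-ordered
      chosen[[length(chosen) + 1L]] <- pool[[best]]
      rationale <- c(rationale,
                     sprintf("%s (ALPHAFOLD) score %.3f, included for canonical transcript",
                             pool[[best]]$structure_id, scores[best]))
    }
  }
  structure(list(chosen = chosen, scores = scores, rationale = rationale,
                 context_only = context_only),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<structure selection> %d of %d candidate(s) chosen%s\n",
              length(x$chosen), length(x$scores),
              if (x$context_only) " (context-only: none covers the variant)" else ""))
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}

#' Read / write a structure catalog (JSON)
#'
#' One object per candidate with the [structure_candidate()] metadata fields
#' plus `coord_path` (relative paths are resolved against the catalog's
#' directory) and per-residue `struct_seq` / `resolved` / `residue_numbers`,
#' plus the `transcript_id` the candidate belongs to.
#'
#' @param cands named list: `transcript_id` -> list of candidates (writer).
#' @param path file path.
#' @return reader: named list mapping transcript_id to candidate lists.
#' @export
write_structure_catalog <- function(cands, path) {
  recs <- list()
  for (txid in names(cands)) {
    for (cand in cands[[txid]]) {
      recs[[length(recs) + 1L]] <- list(
        transcript_id = txid, structure_id = cand$structure_id,
        source = cand$source, method = cand$method,
        coord_path = cand$coord_path, resolution = cand$resolution,
        mean_confidence = cand$mean_confidence,
        is_multimer = cand$is_multimer, chain_ids = cand$chain_ids,
        seq_identity = cand$seq_identity, struct_seq = cand$struct_seq,
        resolved = cand$resolved, residue_numbers = cand$residue_numbers)
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_structure_catalog
#' @export
read_structure_catalog <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  out <- list()
  for (r in recs) {
    cp <- r$coord_path
    if (!grepl("^/", cp)) cp <- file.path(base, cp)
    cand <- structure_candidate(
      structure_id = r$structure_id, source = r$source, method = r$method,
      coord_path = cp, resolution = r$resolution %||% NA,
      mean_confidence = r$mean_confidence %||% NA,
      is_multimer = isTRUE(r$is_multimer),
      chain_ids = unlist(r$chain_ids), seq_identity = r$seq_identity %||% NA,
      struct_seq = r$struct_seq,
      resolved = if (is.null(r$resolved)) NULL else unlist(r$resolved),
      residue_numbers = if (is.null(r$residue_numbers)) NULL else unlist(r$residue_numbers))
    out[[r$transcript_id]] <- c(out[[r$transcript_id]], list(cand))
  }
  out
}
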