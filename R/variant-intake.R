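# Phase 1: case input parsing, SNV consequence calling, missense retention,
# isoform expansion.

VUSTRUCT_COLUMNS <- c("gene", "transcript", "unp", "mutation", "inheritance")
INHERITANCE_LEVELS <- c("maternal", "paternal", "de_novo", "unknown")

#' Parse a VUStruct CSV file
#'
#' The pipeline-ready flat file: comma-delimited with header
#' `gene,transcript,unp,mutation,inheritance`. `mutation` is a protein
#' substitution in 1-letter or HGVS-p 3-letter form; `inheritance` is one of
#' `maternal`, `paternal`, `de_novo`, or blank (recorded as `unknown`).
#'
#' @param path path to the CSV file, or a literal string containing the CSV
#'   text (detected by the presence of a newline).
#' @return a data frame with one row per input row (order preserved) and
#'   columns `gene`, `transcript`, `unp`, `ref_aa`, `pos`, `alt_aa`,
#'   `inheritance`. Blank optional fields are kept as `""`.
#' @export
parse_vustruct_csv <- function(path) {
  con <- if (grepl("\n", path)) textConnection(path) else path
  df <- read.csv(con, colClasses = "character", check.names = FALSE,
                 strip.white = TRUE)
  missing_cols <- setdiff(VUSTRUCT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    vu_stop("vustruct_format_error",
            "VUStruct CSV is missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  n <- nrow(df)
  out <- data.frame(gene = character(n), transcript = character(n),
                    unp = character(n), ref_aa = character(n),
                    pos = integer(n), alt_aa = character(n),
                    inheritance = character(n), stringsAsFactors = FALSE)
  errs <- character(0)
  for (i in seq_len(n)) {
    pc <- tryCatch(parse_protein_change(df$mutation[i]), error = function(e) e)
    if (inherits(pc, "error")) {
      errs <- c(errs, sprintf("row %d: %s", i, conditionMessage(pc)))
      next
    }
    inh <- df$inheritance[i]
    if (is.na(inh) || inh == "") inh <- "unknown"
    if (!inh %in% INHERITANCE_LEVELS) {
      errs <- c(errs, sprintf("row %d: unknown inheritance '%s'", i, inh))
      next
    }
    out[i, ] <- list(df$gene[i], df$transcript[i], df$unp[i],
                     pc$ref_aa, pc$position, pc$alt_aa, inh)
  }
  if (length(errs) > 0)
    vu_stop("vustruct_row_error", "bad VUStruct CSV row(s):\n%s",
            paste(errs, collapse = "\n"))
  out
}

#' Write a VUStruct CSV file
#'
#' Inverse of [parse_vustruct_csv()]: `unknown` inheritance is written as a
#' blank field, so a parse/write cycle is the identity on well-formed rows.
#'
#' @param records data frame as returned by [parse_vustruct_csv()].
#' @param path output path.
#' @export
write_vustruct_csv <- function(records, path) {
  inh <- ifelse(records$inheritance == "unknown", "", records$inheritance)
  df <- data.frame(gene = records$gene, transcript = records$transcript,
                   unp = records$unp,
                   mutation = paste0(records$ref_aa, records$pos, records$alt_aa),
                   inheritance = inh)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read single-nucleotide variants from a VCF file
#'
#' Reads a VCF v4.x file and returns one row per (record, alt allele);
#' multi-allelic rows are split. FILTER and INFO are ignored.
#'
#' @param path path to a VCF file.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call the protein-level consequence of a genomic variant on a transcript
#'
#' A minimal single-nucleotide consequence caller. The variant position is
#' located within the model's CDS exons; the strand-aware 0-based CDS offset
#' is computed (for minus-strand models the offset counts from the 3'-most
#' genomic base of the CDS and alleles are complemented), the affected codon
#' is mutated, and both codons are translated with the standard nuclear
#' code. Positions outside the CDS are `non_coding`; non-1:1 substitutions
#' (indels) are classified `other`.
#'
#' @param gv list with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (forward-strand alleles).
#' @param tm a [transcript_model()].
#' @return a list of class `consequence_record`: `transcript_id`,
#'   `consequence` (one of `missense`, `synonymous`, `stop_gained`,
#'   `stop_lost`, `non_coding`, `other`) and, for the three protein-changing
#'   classes, `change` (a [protein_change()]-like triple).
#' @export
call_consequence <- function(gv, tm) {
  stopifnot(gv$chrom == tm$chrom)
  rec <- function(consequence, change = NULL)
    structure(list(transcript_id = tm$transcript_id,
                   consequence = consequence, change = change),
              class = "consequence_record")
  if (nchar(gv$ref) != 1 || nchar(gv$alt) != 1) return(rec("other"))
  ex <- tm$cds_exons
  hit <- which(gv$pos >= ex$start & gv$pos <= ex$end)
  if (length(hit) == 0) return(rec("non_coding"))
  i <- hit[1]
  # forward-strand reference check against the catalog's exon sequence
  fwd_base <- substr(tm$exon_seqs[i], gv$pos - ex$start[i] + 1,
                     gv$pos - ex$start[i] + 1)
  if (fwd_base != gv$ref)
    vu_stop("vustruct_integrity_error",
            "reference allele %s does not match transcript model %s base %s at %s:%d (stale catalog?)",
            gv$ref, tm$transcript_id, fwd_base, gv$chrom, gv$pos)
  widths <- ex$end - ex$start + 1L
  preceding <- c(0L, cumsum(widths))[i]
  within <- if (tm$strand == "+") gv$pos - ex$start[i] else ex$end[i] - gv$pos
  offset <- preceding + within                   # 0-based CDS offset
  cds <- spliced_cds(tm)
  codon_index <- offset %/% 3L
  frame <- offset %% 3L
  codon <- substr(cds, codon_index * 3L + 1L, codon_index * 3L + 3L)
  alt_base <- if (tm$strand == "+") gv$alt else revcomp(gv$alt)
  mut_codon <- codon
  substr(mut_codon, frame + 1L, frame + 1L) <- alt_base
  ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
  if (ref_aa == alt_aa) return(rec("synonymous"))
  pc <- list(ref_aa = ref_aa, position = codon_index + 1L, alt_aa = alt_aa)
  class(pc) <- "protein_change"
  if (alt_aa == "*") return(rec("stop_gained", pc))
  if (ref_aa == "*") return(rec("stop_lost", pc))
  rec("missense", pc)
}

#' Retain missense consequence records
#'
#' Order-preserving filter; idempotent.
#'
#' @param records list of `consequence_record`s.
#' @return the sub-list with `consequence == "missense"`.
#' @export
filter_missense <- function(records) {
  Filter(function(r) identical(r$consequence, "missense"), records)
}

#' Expand a variant record across a gene's curated isoforms
#'
#' Restricts to transcripts carrying a UniProt cross-reference (the curated
#' subset), lists the canonical isoform first, then "-N" isoforms by
#' suffix. On each isoform the change is re-validated at the same ordinal
#' position: isoforms whose protein is shorter than the position, or whose
#' residue at that position differs from the reference residue, are dropped
#' (with a warning for a mismatch).
#'
#' @param record one row of a [parse_vustruct_csv()] data frame (as a list
#'   or one-row data frame) with at least `gene`, `ref_aa`, `pos`, `alt_aa`.
#' @param catalog list of [transcript_model()]s.
#' @return a list with `pairs` (list of `list(transcript =, change =)`)
#'   and `unresolved` (`TRUE` when the gene is absent from the catalog or
#'   has no curated transcript; such records are surfaced by
#'   [reconcile_case()]).
#' @export
expand_isoforms <- function(record, catalog) {
  record <- as.list(record)
  models <- Filter(function(tm) tm$gene == record$gene, catalog)
  if (length(models) == 0)
    return(list(pairs = list(), unresolved = TRUE))
  curated <- Filter(function(tm) !is.na(tm$uniprot_acc), models)
  if (length(curated) == 0)
    return(list(pairs = list(), unresolved = TRUE))
  ord <- order(!vapply(curated, `[[`, logical(1), "canonical"),
               vapply(curated, function(tm) tm$isoform_suffix %||% 0L, integer(1)),
               vapply(curated, `[[`, character(1), "transcript_id"))
  curated <- curated[ord]
  pairs <- list()
  for (tm in curated) {
    p <- as.integer(record$pos)
    if (p > nchar(tm$protein_seq)) next
    found <- substr(tm$protein_seq, p, p)
    if (found != record$ref_aa) {
      vu_warn("isoform %s: residue %s at position %d does not match reference %s; isoform dropped",
              tm$transcript_id, found, p, record$ref_aa)
      next
    }
    pairs[[length(pairs) + 1L]] <-
      list(transcript = tm,
           change = protein_change(record$ref_aa, p, record$alt_aa))
  }
  list(pairs = pairs, unresolved = FALSE)
}
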