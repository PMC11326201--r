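# Transcript <-> UniProt cross-reference reconciliation. Any variant whose
# transcript record disagrees with its curated protein sequence halts the
# case (overridable), mirroring the manual download-and-patch workflow.

XREF_STATUSES <- c("PERFECT", "SEQ_MISMATCH_SAME_LEN", "LEN_MISMATCH",
                   "MISSING_XREF")

#' Classify one transcript/protein cross-reference
#'
#' The four observed categories: no curated cross-reference at all
#' (`MISSING_XREF`); identical sequences (`PERFECT`); equal lengths but
#' differing sequence (`SEQ_MISMATCH_SAME_LEN`, detail = first differing
#' position); differing lengths (`LEN_MISMATCH`, detail = "lenA/lenB").
#'
#' @param entry list (or one-row data frame) with `transcript_id`,
#'   `ensembl_protein_seq`, `uniprot_acc`, `uniprot_seq` (the latter two may
#'   be `NA`/empty).
#' @return list with `transcript_id`, `status`, `detail` (`""` for PERFECT).
#' @export
classify_xref <- function(entry) {
  entry <- as.list(entry)
  ens <- entry$ensembl_protein_seq
  if (is.null(ens) || is.na(ens) || !nzchar(ens))
    vu_stop("vustruct_input_error", "empty ENSEMBL protein sequence for %s",
            entry$transcript_id %||% "?")
  unp <- entry$uniprot_seq
  res <- function(status, detail = "")
    list(transcript_id = entry$transcript_id, status = status, detail = detail)
  if (is.null(unp) || is.na(unp) || !nzchar(unp))
    return(res("MISSING_XREF", "no curated cross-reference"))
  if (identical(ens, unp)) return(res("PERFECT"))
  if (nchar(ens) == nchar(unp)) {
    a <- strsplit(ens, "")[[1]]; b <- strsplit(unp, "")[[1]]
    first <- which(a != b)[1]
    return(res("SEQ_MISMATCH_SAME_LEN", sprintf("first difference at position %d", first)))
  }
  res("LEN_MISMATCH", sprintf("lengths %d/%d", nchar(ens), nchar(unp)))
}

#' Reconcile a case's variants against the cross-reference catalog
#'
#' Variants whose transcript cross-references `PERFECT`ly are runnable; all
#' others are collected into a discrepancy report. A non-empty report
#' signals case-level HALT (an exit status plus a machine-readable report,
#' not a process abort); `force = TRUE` lets the runnable subset proceed
#' while still emitting the report.
#'
#' @param records data frame from [parse_vustruct_csv()] (must have a
#'   `transcript` column).
#' @param xrefs data frame with columns `transcript_id`,
#'   `ensembl_protein_seq`, `uniprot_acc`, `uniprot_seq`.
#' @param force proceed with the runnable subset despite discrepancies.
#' @return list of class `xref_reconciliation`: `runnable` (data frame
#'   subset of `records`), `report` (data frame with `transcript_id`,
#'   `gene`, `mutation`, `status`, `detail`), `halt` (logical).
#' @export
reconcile_case <- function(records, xrefs, force = FALSE) {
  if (anyDuplicated(xrefs$transcript_id))
    vu_stop("vustruct_catalog_error",
            "duplicate cross-reference entries for transcript(s): %s",
            paste(unique(xrefs$transcript_id[duplicated(xrefs$transcript_id)]),
                  collapse = ", "))
  n <- nrow(records)
  status <- character(n); detail <- character(n)
  for (i in seq_len(n)) {
    j <- which(xrefs$transcript_id == records$transcript[i])
    if (length(j) == 0) {
      status[i] <- "MISSING_XREF"
      detail[i] <- "transcript absent from cross-reference catalog"
    } else {
      cl <- classify_xref(xrefs[j, ])
      status[i] <- cl$status; detail[i] <- cl$detail
    }
  }
  ok <- status == "PERFECT"
  report <- data.frame(
    transcript_id = records$transcript[!ok],
    gene = records$gene[!ok],
    mutation = paste0(records$ref_aa, records$pos, records$alt_aa)[!ok],
    status = status[!ok], detail = detail[!ok], stringsAsFactors = FALSE)
  structure(list(runnable = records[ok, , drop = FALSE],
                 report = report,
                 halt = nrow(report) > 0 && !force),
            class = "xref_reconciliation")
}

#' @export
print.xref_reconciliation <- function(x, ...) {
  cat(sprintf("<xref reconciliation> %d runnable, %d discrepant%s\n",
              nrow(x$runnable), nrow(x$report),
              if (x$halt) " -- HALT" else ""))
  if (nrow(x$report) > 0) print(x$report)
  invisible(x)
}

#' Read / write the cross-reference catalog (TSV)
#'
#' Columns: `transcript_id`, `ensembl_protein_seq`, `uniprot_acc`,
#' `uniprot_seq` (blank for absent).
#'
#' @param path file path.
#' @param xrefs data frame (for the writer).
#' @export
read_xref_catalog <- function(path) {
  df <- read.delim(path, colClasses = "character")
  df$uniprot_acc[df$uniprot_acc == ""] <- NA_character_
  df$uniprot_seq[df$uniprot_seq == ""] <- NA_character_
  df
}

#' @rdname read_xref_catalog
#' @export
write_xref_catalog <- function(xrefs, path) {
  df <- xrefs
  df$uniprot_acc[is.na(df$uniprot_acc)] <- ""
  df$uniprot_seq[is.na(df$uniprot_seq)] <- ""
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the discrepancy report as CSV
#'
#' @param reconciliation an `xref_reconciliation`.
#' @param path output path.
#' @export
write_discrepancy_report <- function(reconciliation, path) {
  write.csv(reconciliation$report, path, row.names = FALSE)
  invisible(path)
}
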