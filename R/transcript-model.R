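# Transcript models: spliced CDS with genomic placement, protein sequence,
# and UniProt cross-reference status.

# reverse complement of a plain character DNA string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# translate a spliced CDS (sense strand) codon-by-codon with the standard
# nuclear code; returns the AA string including any stop as '*'
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0)
    vu_stop("vustruct_catalog_error", "CDS length %d is not divisible by 3", n)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa))
    vu_stop("vustruct_catalog_error", "CDS contains a non-ACGT codon")
  paste0(aa, collapse = "")
}

#' Construct a transcript model
#'
#' A spliced coding model: CDS exons as genomic intervals in *transcript
#' order* (for minus-strand models transcript order runs from high to low
#' genomic coordinates), per-exon forward-strand sequences, and the encoded
#' protein. Construction validates the translation invariant: the spliced
#' CDS (reverse-complemented for minus-strand models) must translate to
#' `protein_seq` followed by a terminal stop.
#'
#' @param transcript_id,gene,chrom identifier strings.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons data frame with integer columns `start`, `end`
#'   (1-based, inclusive, `start <= end`), rows in transcript order.
#' @param exon_seqs character vector of forward-strand exon sequences,
#'   parallel to `cds_exons`.
#' @param protein_seq amino-acid string (no stop).
#' @param uniprot_acc UniProt accession, or `NA` when the transcript has no
#'   curated cross-reference (such transcripts are excluded from analysis).
#' @param canonical is this the canonical isoform?
#' @param isoform_suffix integer "-N" suffix for curated non-canonical
#'   isoforms, `NA` for the canonical.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand, cds_exons,
                             exon_seqs, protein_seq, uniprot_acc = NA,
                             canonical = TRUE, isoform_suffix = NA) {
  if (!strand %in% c("+", "-"))
    vu_stop("vustruct_catalog_error", "strand must be '+' or '-'")
  cds_exons <- as.data.frame(cds_exons)
  if (!all(c("start", "end") %in% names(cds_exons)))
    vu_stop("vustruct_catalog_error", "cds_exons needs columns start, end")
  cds_exons$start <- as.integer(cds_exons$start)
  cds_exons$end <- as.integer(cds_exons$end)
  if (any(cds_exons$end < cds_exons$start))
    vu_stop("vustruct_catalog_error", "exon end before start")
  widths <- cds_exons$end - cds_exons$start + 1L
  if (length(exon_seqs) != nrow(cds_exons))
    vu_stop("vustruct_catalog_error", "exon_seqs length != number of exons")
  if (any(nchar(exon_seqs) != widths))
    vu_stop("vustruct_catalog_error", "exon sequence lengths disagree with intervals")
  tm <- structure(list(
    transcript_id = transcript_id, gene = gene, chrom = chrom,
    strand = strand, cds_exons = cds_exons, exon_seqs = exon_seqs,
    protein_seq = protein_seq,
    uniprot_acc = if (is.null(uniprot_acc)) NA_character_ else uniprot_acc,
    canonical = isTRUE(canonical),
    isoform_suffix = if (is.null(isoform_suffix)) NA_integer_ else as.integer(isoform_suffix)
  ), class = "transcript_model")
  aa <- translate_cds(spliced_cds(tm))
  if (aa != paste0(protein_seq, "*"))
    vu_stop("vustruct_catalog_error",
            "transcript %s: spliced CDS does not translate to protein_seq + stop",
            transcript_id)
  tm
}

# sense-strand spliced CDS of a model (exons in transcript order;
# minus-strand exon sequences are stored forward-strand and flipped here)
spliced_cds <- function(tm) {
  seqs <- tm$exon_seqs
  if (tm$strand == "-") seqs <- vapply(seqs, revcomp, character(1))
  paste0(seqs, collapse = "")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s> gene %s, %s strand %s, %d CDS exon(s), %d aa%s\n",
              x$transcript_id, x$gene, x$chrom, x$strand,
              nrow(x$cds_exons), nchar(x$protein_seq),
              if (!is.na(x$uniprot_acc)) paste0(", UniProt ", x$uniprot_acc) else ""))
  invisible(x)
}

#' Write / read a transcript catalog (JSON)
#'
#' The catalog is a JSON array with one object per transcript model.
#'
#' @param models list of [transcript_model()] objects.
#' @param path file path.
#' @return `read_transcript_catalog` returns a list of `transcript_model`s.
#' @export
write_transcript_catalog <- function(models, path) {
  recs <- lapply(models, function(tm) {
    list(transcript_id = tm$transcript_id, gene = tm$gene, chrom = tm$chrom,
         strand = tm$strand,
         cds_starts = tm$cds_exons$start, cds_ends = tm$cds_exons$end,
         exon_seqs = tm$exon_seqs, protein_seq = tm$protein_seq,
         uniprot_acc = tm$uniprot_acc, canonical = tm$canonical,
         isoform_suffix = tm$isoform_suffix)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_transcript_catalog
#' @export
read_transcript_catalog <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    transcript_model(
      transcript_id = r$transcript_id, gene = r$gene, chrom = r$chrom,
      strand = r$strand,
      cds_exons = data.frame(start = unlist(r$cds_starts),
                             end = unlist(r$cds_ends)),
      exon_seqs = unlist(r$exon_seqs), protein_seq = r$protein_seq,
      uniprot_acc = r$uniprot_acc %||% NA_character_,
      canonical = isTRUE(r$canonical),
      isoform_suffix = r$isoform_suffix %||% NA_integer_)
  })
}
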