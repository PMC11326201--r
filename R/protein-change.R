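# Amino-acid nomenclature and protein-change parsing.

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

# 3-letter -> 1-letter lookup, built from the standard Biostrings table,
# with the stop codon name added.
aa3_to_1 <- local({
  code <- Biostrings::AMINO_ACID_CODE   # names: 1-letter, values: 3-letter
  m <- setNames(names(code), toupper(code))
  m[["TER"]] <- "*"
  m
})

#' Parse a protein-level substitution string
#'
#' Accepts the 1-letter short form (`"F767L"`) or the HGVS-p 3-letter form
#' (`"p.Phe767Leu"`, leading `p.` optional). The reference residue must be
#' one of the 20 standard amino acids; the alternate may additionally be a
#' stop (`*` or `Ter`). Reference and alternate must differ.
#'
#' @param s a single substitution string.
#' @return an object of class `protein_change`: a list with `ref_aa`,
#'   `position` (1-based) and `alt_aa`.
#' @examples
#' parse_protein_change("F767L")
#' parse_protein_change("p.Val469Leu")
#' @export
parse_protein_change <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s))
    vu_stop("vustruct_parse_error", "protein change must be a single string")
  x <- sub("^p\\.", "", trimws(s))
  m1 <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z*])$", x))[[1]]
  m3 <- regmatches(x, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*)$", x))[[1]]
  if (length(m1) == 4) {
    ref <- toupper(m1[2]); pos <- as.integer(m1[3]); alt <- toupper(m1[4])
  } else if (length(m3) == 4) {
    ref <- unname(aa3_to_1[toupper(m3[2])])
    alt <- if (m3[4] == "*") "*" else unname(aa3_to_1[toupper(m3[4])])
    pos <- as.integer(m3[3])
    if (is.na(ref) || is.na(alt))
      vu_stop("vustruct_parse_error", "unknown residue code in '%s'", s)
  } else {
    vu_stop("vustruct_parse_error", "cannot parse protein change '%s'", s)
  }
  protein_change(ref, pos, alt)
}

#' Construct a protein change
#'
#' @param ref_aa,alt_aa 1-letter residue codes (`alt_aa` may be `"*"`).
#' @param position 1-based residue position.
#' @return an object of class `protein_change`.
#' @export
protein_change <- function(ref_aa, position, alt_aa) {
  if (!ref_aa %in% AA1)
    vu_stop("vustruct_parse_error", "unknown reference residue '%s'", ref_aa)
  if (!alt_aa %in% c(AA1, "*"))
    vu_stop("vustruct_parse_error", "unknown alternate residue '%s'", alt_aa)
  if (is.na(position) || position < 1)
    vu_stop("vustruct_parse_error", "non-positive protein position")
  if (ref_aa == alt_aa)
    vu_stop("vustruct_parse_error",
            "reference and alternate residues are identical (%s%d%s)",
            ref_aa, position, alt_aa)
  structure(list(ref_aa = ref_aa, position = as.integer(position),
                 alt_aa = alt_aa),
            class = "protein_change")
}

#' @export
format.protein_change <- function(x, ...) {
  paste0(x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein change>", format(x), "\n")
  invisible(x)
}
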