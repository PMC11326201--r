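# Independent oracles and shared fixture helpers. Oracles deliberately use
# different machinery than the implementation (Biostrings full-sequence
# translation, recursive alignment scoring, exhaustive enumeration).

# --- full-CDS mutate-and-translate consequence oracle ---------------------
# Rebuilds the complete mutated spliced CDS, reverse-complements minus
# strand models with Biostrings, translates both full proteins, and
# classifies from the first differing residue.
oracle_consequence <- function(gv, tm) {
  if (nchar(gv$ref) != 1 || nchar(gv$alt) != 1) return("other")
  ex <- tm$cds_exons
  hit <- which(gv$pos >= ex$start & gv$pos <= ex$end)
  if (length(hit) == 0) return(list(consequence = "non_coding"))
  i <- hit[1]
  seqs <- tm$exon_seqs
  within <- gv$pos - ex$start[i] + 1
  stopifnot(substr(seqs[i], within, within) == gv$ref)
  mut <- seqs
  substr(mut[i], within, within) <- gv$alt
  splice <- function(exseqs) {
    s <- Biostrings::DNAStringSet(exseqs)
    if (tm$strand == "-") s <- Biostrings::reverseComplement(s)
    Biostrings::DNAString(paste0(as.character(s), collapse = ""))
  }
  # no.init.codon: score codon 1 by the plain code table (a mutated start
  # such as ATG->TTG is a substitution, not an alternative initiator)
  aa_ref <- as.character(Biostrings::translate(splice(seqs), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(splice(mut), no.init.codon = TRUE))
  if (aa_ref == aa_alt) return(list(consequence = "synonymous"))
  diffpos <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])[1]
  r <- substr(aa_ref, diffpos, diffpos); a <- substr(aa_alt, diffpos, diffpos)
  cons <- if (a == "*") "stop_gained" else if (r == "*") "stop_lost" else "missense"
  list(consequence = cons, ref_aa = r, position = diffpos, alt_aa = a)
}

# all exonic SNVs never produce errors on generator output; draw random
# exonic and intronic SNVs for a model
random_snvs <- function(tm, genome, n, include_noncoding = TRUE) {
  slice <- genome[[tm$chrom]]
  exonic <- unlist(mapply(seq, tm$cds_exons$start, tm$cds_exons$end,
                          SIMPLIFY = FALSE))
  pool <- if (include_noncoding) seq_len(nchar(slice)) else exonic
  pos <- sample(pool, n, replace = TRUE)
  lapply(pos, function(p) {
    ref <- substr(slice, p, p)
    list(chrom = tm$chrom, pos = p, ref = ref,
         alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1))
  })
}

# mirror-image model: reverse-complement the chromosome slice and flip the
# model to the opposite strand; variant (pos, ref, alt) maps to
# (L + 1 - pos, comp(ref), comp(alt))
mirror_model <- function(tm, genome) {
  slice <- genome[[tm$chrom]]
  L <- nchar(slice)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc_slice <- vustruct:::revcomp(slice)
  ex <- tm$cds_exons
  new_start <- L + 1L - ex$end
  new_end <- L + 1L - ex$start
  new_seqs <- vapply(tm$exon_seqs, vustruct:::revcomp, character(1))
  transcript_model(
    transcript_id = paste0(tm$transcript_id, "m"), gene = tm$gene,
    chrom = tm$chrom, strand = if (tm$strand == "+") "-" else "+",
    cds_exons = data.frame(start = new_start, end = new_end),
    exon_seqs = unname(new_seqs), protein_seq = tm$protein_seq,
    uniprot_acc = tm$uniprot_acc, canonical = tm$canonical,
    isoform_suffix = tm$isoform_suffix)
}

mirror_variant <- function(gv, genome) {
  L <- nchar(genome[[gv$chrom]])
  comp <- function(x) chartr("ACGT", "TGCA", x)
  list(chrom = gv$chrom, pos = L + 1L - gv$pos,
       ref = comp(gv$ref), alt = comp(gv$alt))
}

# --- recursive optimal global alignment score (memoised) ------------------
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) 0
    else if (i == 0) j * gap
    else if (j == 0) i * gap
    else max(rec(i - 1, j - 1) + (if (av[i] == bv[j]) match else mismatch),
             rec(i - 1, j) + gap, rec(i, j - 1) + gap)
    memo[[key]] <- val
    val
  }
  rec(length(av), length(bv))
}

# --- exhaustive-enumeration permutation p-value ---------------------------
exact_pvalue <- function(q, P, B, coords, kernel = "reciprocal") {
  D <- pairwise_distances(coords)
  K <- pathprox_kernel(kernel)
  pool <- c(P, B)
  k <- K(apply(D[q, pool, drop = FALSE], 2, min))
  np <- length(P); n <- length(pool)
  obs <- mean(k[seq_len(np)]) - mean(k[-seq_len(np)])
  subsets <- combn(n, np)
  scores <- apply(subsets, 2, function(idx) mean(k[idx]) - mean(k[-idx]))
  mean(scores >= obs - 1e-9)
}

# --- geometry helpers -----------------------------------------------------
# random rigid-body transform of a residue_coords frame
rigid_transform <- function(coords, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(9), 3)
    Q <- qr.Q(qr(M))                       # random orthogonal matrix
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]      # proper rotation
    t0 <- rnorm(3, sd = 20)
    xyz <- as.matrix(coords[, c("x", "y", "z")]) %*% Q
    coords$x <- xyz[, 1] + t0[1]
    coords$y <- xyz[, 2] + t0[2]
    coords$z <- xyz[, 3] + t0[3]
    coords
  })
}

# toy coordinate set: n residues, chain A, random positions in a box
toy_coords <- function(n, seed = 1, scale = 20) {
  withr::with_seed(seed, {
    df <- data.frame(chain = "A", resno = seq_len(n),
                     x = runif(n, 0, scale), y = runif(n, 0, scale),
                     z = runif(n, 0, scale), stringsAsFactors = FALSE)
    df$key <- paste(df$chain, df$resno, sep = ":")
    class(df) <- c("residue_coords", "data.frame")
    df
  })
}

# quick structure candidate over an in-memory residue map
toy_candidate <- function(id, covered, source = "PDB", method = "XRAY",
                          resolution = 2.0, mean_confidence = NA,
                          is_multimer = FALSE, coord_path = "unused.pdb") {
  rm <- data.frame(transcript_pos = covered,
                   chain_id = rep("A", length(covered)),
                   residue_number = covered)
  class(rm) <- c("residue_map", "data.frame")
  structure_candidate(id, source, method, coord_path,
                      resolution = resolution,
                      mean_confidence = mean_confidence,
                      is_multimer = is_multimer, residue_map = rm)
}
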