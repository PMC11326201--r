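# Deterministic fixture generators: every input dialect the pipeline
# consumes can be produced from a seed, so the whole pipeline runs and is
# tested with no external data.

#' Fixture generator configuration
#'
#' @param seed master seed; all generators are pure functions of their
#'   config.
#' @param n_genes number of genes.
#' @param exons_per_gene inclusive range of CDS exon counts.
#' @param protein_len inclusive range of protein lengths (aa, excluding
#'   stop).
#' @param p_minus probability a gene sits on the minus strand.
#' @param isoform_prob probability a gene with >= 3 exons gets a curated
#'   "-2" isoform (exon-skipping, frame-preserving).
#' @param xref_props named proportions over the four cross-reference
#'   categories (must sum to 1); planted counts are exact (largest-remainder
#'   rounding) over canonical transcripts.
#' @param geometry toy-structure backbone geometry, `"helix"` or `"line"`.
#' @param n_pathogenic,n_benign labeled site counts per variant table.
#' @param clustering_width window width (residues) within which pathogenic
#'   sites are planted; `NA` means the full protein (uniform regime).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1, n_genes = 6, exons_per_gene = c(1, 3),
                           protein_len = c(30, 60), p_minus = 0.5,
                           isoform_prob = 0.5,
                           xref_props = c(PERFECT = 0.7,
                                          SEQ_MISMATCH_SAME_LEN = 0.1,
                                          LEN_MISMATCH = 0.1,
                                          MISSING_XREF = 0.1),
                           geometry = "helix", n_pathogenic = 8,
                           n_benign = 8, clustering_width = NA) {
  if (abs(sum(xref_props) - 1) > 1e-9)
    vu_stop("vustruct_config_error", "xref proportions must sum to 1")
  if (!all(names(xref_props) %in% XREF_STATUSES))
    vu_stop("vustruct_config_error", "unknown xref category name")
  structure(list(seed = seed, n_genes = n_genes,
                 exons_per_gene = exons_per_gene, protein_len = protein_len,
                 p_minus = p_minus, isoform_prob = isoform_prob,
                 xref_props = xref_props, geometry = geometry,
                 n_pathogenic = n_pathogenic, n_benign = n_benign,
                 clustering_width = clustering_width),
            class = "fixture_config")
}

# exact integer counts from proportions (largest remainder)
planted_counts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

random_cds <- function(n_aa) {
  codons <- c("ATG", sample(SENSE_CODONS, n_aa - 1, replace = TRUE),
              sample(STOP_CODONS, 1))
  paste0(codons, collapse = "")
}

#' Generate a toy transcriptome
#'
#' For each gene: a random multi-exon spliced CDS on a random strand,
#' placed on its own chromosome slice with random intronic spacers and
#' flanks, plus the translated protein, an optional frame-preserving
#' exon-skipping "-2" isoform, and a cross-reference entry in one of the
#' four planted discrepancy categories (exact counts over canonical
#' transcripts; isoforms are always PERFECT). `MISSING_XREF` genes carry no
#' UniProt accession and are therefore excluded by the curated-subset
#' restriction.
#'
#' @param cfg a [fixture_config()].
#' @return list: `transcripts` (list of [transcript_model()]),
#'   `xrefs` (data frame), `genome` (named list chrom -> sequence string).
#' @export
make_toy_transcriptome <- function(cfg) {
  withr::with_seed(cfg$seed, {
    counts <- planted_counts(cfg$xref_props, cfg$n_genes)
    categories <- sample(rep(names(cfg$xref_props), counts))
    transcripts <- list(); xref_rows <- list(); genome <- list()
    for (g in seq_len(cfg$n_genes)) {
      gene <- sprintf("GENE%02d", g)
      chrom <- sprintf("chr%02d", g)
      txid <- sprintf("TX%04d", g * 10)
      acc <- sprintf("P%05d", 10000 + g)
      n_aa <- sample(cfg$protein_len[1]:cfg$protein_len[2], 1)
      cds <- random_cds(n_aa)
      n_cds <- nchar(cds)
      strand <- if (runif(1) < cfg$p_minus) "-" else "+"
      k <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
      # codon-aligned exon boundaries so an internal exon can be skipped in
      # frame; fall back to fewer exons for short CDSs
      k <- min(k, n_aa %/% 4 + 1)
      if (k > 1) {
        cuts <- sort(sample(seq_len(n_cds %/% 3 - 1), k - 1)) * 3
        bounds <- c(0, cuts, n_cds)
      } else bounds <- c(0, n_cds)
      chunk_len <- diff(bounds)
      chunks <- substring(cds, bounds[-length(bounds)] + 1, bounds[-1])
      introns <- replicate(k - 1, paste0(
        sample(c("A", "C", "G", "T"), sample(10:30, 1), replace = TRUE),
        collapse = ""))
      flank5 <- paste0(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                       collapse = "")
      flank3 <- paste0(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                       collapse = "")
      # genomic order of exon chunks: transcript order for '+', reversed
      # (and reverse-complemented) for '-'
      genomic_chunks <- if (strand == "+") chunks else
        rev(vapply(chunks, revcomp, character(1)))
      pieces <- character(0)
      starts <- integer(k); ends <- integer(k)
      pos <- nchar(flank5) + 1L
      pieces <- flank5
      for (e in seq_len(k)) {
        starts[e] <- pos
        ends[e] <- pos + nchar(genomic_chunks[e]) - 1L
        pieces <- paste0(pieces, genomic_chunks[e])
        pos <- ends[e] + 1L
        if (e < k) {
          pieces <- paste0(pieces, introns[e])
          pos <- pos + nchar(introns[e])
        }
      }
      pieces <- paste0(pieces, flank3)
      genome[[chrom]] <- pieces
      # intervals back into transcript order
      if (strand == "+") {
        tx_starts <- starts; tx_ends <- ends
      } else {
        tx_starts <- rev(starts); tx_ends <- rev(ends)
      }
      exon_seqs <- substring(pieces, tx_starts, tx_ends)
      protein <- substr(translate_cds(cds), 1, n_aa)
      category <- categories[g]
      tm <- transcript_model(
        transcript_id = txid, gene = gene, chrom = chrom, strand = strand,
        cds_exons = data.frame(start = tx_starts, end = tx_ends),
        exon_seqs = exon_seqs, protein_seq = protein,
        uniprot_acc = if (category == "MISSING_XREF") NA else acc,
        canonical = TRUE, isoform_suffix = NA)
      transcripts[[length(transcripts) + 1L]] <- tm
      unp_seq <- switch(category,
        PERFECT = protein,
        MISSING_XREF = NA_character_,
        LEN_MISMATCH = substr(protein, 1, n_aa - 1),
        SEQ_MISMATCH_SAME_LEN = {
          i <- sample(n_aa, 1)
          s <- protein
          substr(s, i, i) <- sample(setdiff(AA1, substr(s, i, i)), 1)
          s
        })
      xref_rows[[length(xref_rows) + 1L]] <- data.frame(
        transcript_id = txid, ensembl_protein_seq = protein,
        uniprot_acc = if (category == "MISSING_XREF") NA_character_ else acc,
        uniprot_seq = unp_seq, stringsAsFactors = FALSE)
      # frame-preserving exon-skipping isoform (drops exon 2)
      if (k >= 3 && category != "MISSING_XREF" &&
          runif(1) < cfg$isoform_prob) {
        keep <- setdiff(seq_len(k), 2)
        iso_cds <- paste0(chunks[keep], collapse = "")
        iso_protein <- substr(translate_cds(iso_cds), 1,
                              nchar(iso_cds) %/% 3 - 1)
        iso <- transcript_model(
          transcript_id = paste0(txid, "B"), gene = gene, chrom = chrom,
          strand = strand,
          cds_exons = data.frame(start = tx_starts[keep],
                                 end = tx_ends[keep]),
          exon_seqs = exon_seqs[keep], protein_seq = iso_protein,
          uniprot_acc = paste0(acc, "-2"), canonical = FALSE,
          isoform_suffix = 2L)
        transcripts[[length(transcripts) + 1L]] <- iso
        xref_rows[[length(xref_rows) + 1L]] <- data.frame(
          transcript_id = iso$transcript_id,
          ensembl_protein_seq = iso_protein,
          uniprot_acc = iso$uniprot_acc, uniprot_seq = iso_protein,
          stringsAsFactors = FALSE)
      }
    }
    list(transcripts = transcripts, xrefs = do.call(rbind, xref_rows),
         genome = genome)
  })
}

#' Write a toy Cα-trace structure in PDB format
#'
#' `helix` places Cα atoms on an ideal alpha-helix (rise 1.5 A per residue,
#' 100 degree turn, radius 2.3 A); `line` spaces consecutive Cα 3.8 A
#' apart along the x axis. Residues listed in `mask` are left unresolved
#' (no ATOM record).
#'
#' @param seq protein sequence giving residue identities and count.
#' @param geometry `"helix"` or `"line"`.
#' @param path output PDB path.
#' @param mask integer positions to leave unresolved.
#' @param chain chain id.
#' @param n_copies number of identical chains (a homomultimer when > 1);
#'   copies are translated 30 A apart and lettered A, B, ...
#' @return invisible list with the coordinate data frame and `path`.
#' @export
make_toy_structure <- function(seq, geometry = c("helix", "line"), path,
                               mask = integer(0), chain = "A", n_copies = 1) {
  geometry <- match.arg(geometry)
  n <- nchar(seq)
  stopifnot(n >= 2)
  i <- seq_len(n)
  if (geometry == "helix") {
    th <- (i - 1) * 100 * pi / 180
    xyz0 <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1))
  } else {
    xyz0 <- cbind(3.8 * (i - 1), 0, 0)
  }
  keep <- setdiff(i, mask)
  aa3 <- toupper(setNames(Biostrings::AMINO_ACID_CODE[AA1], AA1))
  resid <- aa3[strsplit(seq, "")[[1]]]
  chains <- LETTERS[seq_len(n_copies)]
  rows <- list()
  for (ci in seq_len(n_copies)) {
    xyz <- xyz0
    xyz[, 1] <- xyz[, 1] + 30 * (ci - 1)
    rows[[ci]] <- data.frame(chain = chains[ci], resno = keep,
                             resid = resid[keep],
                             x = xyz[keep, 1], y = xyz[keep, 2],
                             z = xyz[keep, 3])
  }
  df <- do.call(rbind, rows)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]))),
                   resno = df$resno, resid = df$resid, chain = df$chain,
                   elety = rep("CA", nrow(df)))
  invisible(list(coords = df, path = path))
}

#' Generate labeled pathogenic/benign variant tables
#'
#' Pathogenic positions are drawn within a random window of
#' `clustering_width` residues (the clustered regime); with
#' `clustering_width` equal to the protein length (or `NA`) they are
#' uniform. Benign positions are uniform. Both sets are disjoint from each
#' other and from the query position.
#'
#' @param protein_len protein length.
#' @param n_path,n_benign site counts.
#' @param clustering_width window width in residues (`NA` = uniform).
#' @param query_pos the query variant's position (excluded from both sets).
#' @param seed integer seed.
#' @return list of two data frames (`pathogenic`, `benign`) with columns
#'   `transcript_position`, `label`.
#' @export
make_variant_tables <- function(protein_len, n_path, n_benign,
                                clustering_width = NA, query_pos, seed = 1) {
  if (is.na(clustering_width)) clustering_width <- protein_len
  if (n_path + n_benign + 1 > protein_len)
    vu_stop("vustruct_config_error", "more labeled sites than residues")
  withr::with_seed(seed, {
    win_start <- sample(seq_len(protein_len - clustering_width + 1), 1)
    window <- setdiff(seq(win_start, win_start + clustering_width - 1),
                      query_pos)
    if (length(window) < n_path)
      vu_stop("vustruct_config_error", "clustering window too small")
    path_pos <- sort(sample(window, n_path))
    rest <- setdiff(seq_len(protein_len), c(path_pos, query_pos))
    ben_pos <- sort(sample(rest, n_benign))
    list(pathogenic = data.frame(transcript_position = path_pos,
                                 label = "pathogenic"),
         benign = data.frame(transcript_position = ben_pos,
                             label = "benign"))
  })
}

#' Write a labeled variant table (TSV)
#'
#' @param table data frame with `transcript_position`, `label`.
#' @param path output path.
#' @export
write_variant_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# write a minimal VCF v4.2 text file (PASS-only, minimal contig header)
write_minimal_vcf <- function(variants, contig_lengths, path) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     contig_lengths),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", variants$chrom,
                     variants$pos, variants$ref, variants$alt))
  writeLines(lines, path)
  invisible(path)
}

# enumerate SNVs on a transcript until one of each requested consequence
# class is found (used to plant variants in toy cases)
find_snv_of_class <- function(tm, genome, class, skip = character(0)) {
  slice <- genome[[tm$chrom]]
  positions <- unlist(mapply(seq, tm$cds_exons$start, tm$cds_exons$end,
                             SIMPLIFY = FALSE))
  if (class == "non_coding") {
    off <- setdiff(seq_len(nchar(slice)), positions)[1]
    ref <- substr(slice, off, off)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    return(list(chrom = tm$chrom, pos = off, ref = ref, alt = alt))
  }
  for (p in positions) {
    ref <- substr(slice, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      key <- paste(p, alt)
      if (key %in% skip) next
      gv <- list(chrom = tm$chrom, pos = p, ref = ref, alt = alt)
      cr <- call_consequence(gv, tm)
      if (cr$consequence == class) return(gv)
    }
  }
  NULL
}

#' Generate a complete toy case bundle
#'
#' Writes, under `dir`: a minimal VCF, the transcript catalog (JSON), the
#' cross-reference catalog (TSV), a structure catalog (JSON) with toy PDB
#' files per curated transcript (one experimental-style partial structure,
#' one AlphaFold-style full-length model; a homodimer when the gene draw
#' says so), labeled pathogenic/benign variant tables per transcript, and
#' precomputed score tables (AlphaMissense-like per variant,
#' ConSurf-/COSMIS-like per site). Planted variants cover the missense,
#' synonymous, stop-gained and non-coding consequence classes; missense
#' variants are planted on curated `PERFECT` transcripts, plus one on a
#' discrepant transcript when the planted categories include one.
#'
#' @param cfg a [fixture_config()].
#' @param dir output directory (created).
#' @return list describing the bundle (paths plus the generated objects).
#' @export
make_case <- function(cfg, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  tr <- make_toy_transcriptome(cfg)
  write_transcript_catalog(tr$transcripts, file.path(dir, "transcripts.json"))
  write_xref_catalog(tr$xrefs, file.path(dir, "xrefs.tsv"))

  canon <- Filter(function(tm) tm$canonical, tr$transcripts)
  status_of <- vapply(canon, function(tm) {
    classify_xref(tr$xrefs[tr$xrefs$transcript_id == tm$transcript_id, ])$status
  }, character(1))
  perfect <- canon[status_of == "PERFECT"]
  discrepant <- canon[!status_of %in% c("PERFECT", "MISSING_XREF")]
  if (length(perfect) < 2)
    vu_stop("vustruct_config_error",
            "toy case needs at least two PERFECT genes; increase n_genes or the PERFECT proportion")

  variants <- list()
  # one missense per PERFECT gene (first three), one on a discrepant gene
  # when present, plus one synonymous, one stop-gained, one non-coding
  targets <- head(perfect, 3)
  for (tm in targets)
    variants <- c(variants, list(find_snv_of_class(tm, tr$genome, "missense")))
  if (length(discrepant) > 0)
    variants <- c(variants,
                  list(find_snv_of_class(discrepant[[1]], tr$genome, "missense")))
  extras <- list(
    find_snv_of_class(targets[[1]], tr$genome, "synonymous"),
    find_snv_of_class(targets[[1]], tr$genome, "stop_gained"),
    find_snv_of_class(targets[[1]], tr$genome, "non_coding"))
  variants <- c(variants, Filter(Negate(is.null), extras))
  variants <- Filter(Negate(is.null), variants)
  vdf <- do.call(rbind, lapply(variants, as.data.frame))
  write_minimal_vcf(vdf, vapply(tr$genome, nchar, integer(1)),
                    file.path(dir, "case.vcf"))

  # structures + labeled tables + precomputed tables for curated transcripts
  withr::with_seed(cfg$seed + 1L, {
    catalog <- list()
    am_rows <- list(); site_rows <- list()
    for (tm in Filter(function(x) !is.na(x$uniprot_acc), tr$transcripts)) {
      L <- nchar(tm$protein_seq)
      sid_x <- paste0("X", tm$transcript_id)
      sid_af <- paste0("AF", tm$transcript_id)
      multi <- runif(1) < 0.3
      # experimental-style partial structure: central 70% of the chain
      lo <- max(1L, ceiling(L * 0.15)); hi <- min(L, floor(L * 0.85))
      px <- file.path("structures", paste0(sid_x, ".pdb"))
      make_toy_structure(substr(tm$protein_seq, lo, hi), cfg$geometry,
                         file.path(dir, px),
                         n_copies = if (multi) 2 else 1)
      paf <- file.path("structures", paste0(sid_af, ".pdb"))
      make_toy_structure(tm$protein_seq, cfg$geometry, file.path(dir, paf))
      cands <- list(
        structure_candidate(sid_x, "PDB", "XRAY", px,
                            resolution = round(runif(1, 1.5, 3.5), 2),
                            is_multimer = multi,
                            chain_ids = if (multi) c("A", "B") else "A",
                            struct_seq = substr(tm$protein_seq, lo, hi),
                            residue_numbers = seq_len(hi - lo + 1L)),
        structure_candidate(sid_af, "ALPHAFOLD", "PREDICTED", paf,
                            mean_confidence = round(runif(1, 60, 95), 1),
                            struct_seq = tm$protein_seq))
      catalog[[tm$transcript_id]] <- cands
      # labeled variant tables
      qpos <- NA
      for (v in variants) {
        cr <- tryCatch(call_consequence(v, tm), error = function(e) NULL)
        if (!is.null(cr) && cr$consequence == "missense") {
          qpos <- cr$change$position; break
        }
      }
      tabs <- make_variant_tables(L, min(cfg$n_pathogenic, L %/% 4),
                                  min(cfg$n_benign, L %/% 4),
                                  cfg$clustering_width,
                                  query_pos = if (is.na(qpos)) 0 else qpos,
                                  seed = cfg$seed + nchar(tm$transcript_id) +
                                    utf8ToInt(substr(tm$transcript_id, 3, 3)))
      write_variant_table(rbind(tabs$pathogenic, tabs$benign),
                          file.path(dir, paste0("labels_", tm$transcript_id,
                                                ".tsv")))
      # precomputed tables: per-site rows everywhere, per-variant rows for
      # the planted missense change
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        unp = tm$uniprot_acc, pos = seq_len(L),
        value = round(runif(L), 3))
      if (!is.na(qpos)) {
        for (v in variants) {
          cr <- tryCatch(call_consequence(v, tm), error = function(e) NULL)
          if (!is.null(cr) && cr$consequence == "missense")
            am_rows[[length(am_rows) + 1L]] <- data.frame(
              unp = tm$uniprot_acc, pos = cr$change$position,
              alt_aa = cr$change$alt_aa, value = round(runif(1), 3))
        }
      }
    }
    write_structure_catalog(catalog, file.path(dir, "structures.json"))
    if (length(am_rows) > 0) {
      am <- unique(do.call(rbind, am_rows))
      write.table(am, file.path(dir, "alphamissense_like.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
    sites <- do.call(rbind, site_rows)
    write.table(sites, file.path(dir, "consurf_like.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(transform(sites, value = round(value * 2 - 1, 3)),
                file.path(dir, "cosmis_like.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  })
  list(dir = dir, vcf = file.path(dir, "case.vcf"),
       transcripts = file.path(dir, "transcripts.json"),
       xrefs = file.path(dir, "xrefs.tsv"),
       structures = file.path(dir, "structures.json"),
       variants = vdf, transcriptome = tr)
}
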