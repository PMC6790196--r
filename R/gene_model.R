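#' Gene model for a single gene
#'
#' A `gene_model` bundles the genomic sequence of one gene (always stored in
#' gene-strand orientation, so exon 1 comes first) with its ordered exon
#' intervals, the genomic offset of the translation start, and a per-exon
#' domain label. All coordinates are 0-based half-open; GFF3 input/output
#' converts to and from the 1-based inclusive convention of that format.
#'
#' Domain labels follow the butyrophilin convention: the two extracellular
#' immunoglobulin-like domains (`IgV`, `IgC`, usually exons 2 and 3), the
#' transmembrane exon (`TM`), several very short `heptad` exons, and the
#' intracellular `B30.2` exon; `UTR` and `other` are also accepted.
#'
#' @param gene_id single identifier string.
#' @param genomic_seq DNA string (character scalar, alphabet `A,C,G,T,N`) in
#'   gene-strand orientation.
#' @param exons integer matrix with two columns (`start`, `end`), 0-based
#'   half-open, strictly increasing and non-overlapping.
#' @param cds_start 0-based genomic offset of the first base of the start
#'   codon; must fall inside an exon.
#' @param domain_labels character vector, one label per exon, each in
#'   `IgV, IgC, TM, heptad, B30.2, UTR, other`.
#' @param cds_codon_count optional integer: number of codons in the
#'   constitutive CDS up to and including the natural stop. Computed from the
#'   constitutive transcript when `NULL`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, genomic_seq, exons, cds_start,
                       domain_labels = NULL, cds_codon_count = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  genomic_seq <- toupper(as.character(genomic_seq))
  if (!grepl("^[ACGTN]*$", genomic_seq)) {
    stop("genomic_seq contains characters outside {A,C,G,T,N}")
  }
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  n <- nrow(exons)
  if (n < 1L) stop("gene model needs at least one exon")
  if (any(exons[, "end"] <= exons[, "start"])) {
    stop("validation error: exon with non-positive length")
  }
  if (n > 1L && any(exons[-1L, "start"] < exons[-n, "end"])) {
    stop("validation error: exons overlap or are out of order")
  }
  L <- nchar(genomic_seq)
  if (exons[1L, "start"] < 0L || exons[n, "end"] > L) {
    stop("validation error: exon interval outside the genomic sequence")
  }
  cds_start <- as.integer(cds_start)
  in_exon <- any(cds_start >= exons[, "start"] & cds_start < exons[, "end"])
  if (!in_exon) stop("validation error: cds_start does not fall inside an exon")
  if (is.null(domain_labels)) domain_labels <- rep("other", n)
  ok <- c("IgV", "IgC", "TM", "heptad", "B30.2", "UTR", "other")
  if (length(domain_labels) != n || !all(domain_labels %in% ok)) {
    stop("domain_labels must give one known label per exon")
  }
  m <- structure(
    list(gene_id = gene_id, genomic_seq = genomic_seq, exons = exons,
         cds_start = cds_start, domain_labels = domain_labels,
         cds_codon_count = cds_codon_count),
    class = "gene_model"
  )
  if (is.null(cds_codon_count)) {
    pr <- translate_and_scan(constitutive_mrna(m), cds_offset_in_mrna(m))
    m$cds_codon_count <- if (is.na(pr$first_stop_codon_index)) {
      pr$n_codons
    } else {
      pr$first_stop_codon_index
    }
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d bp, %d exons, CDS from %d (%d codons)\n",
              x$gene_id, nchar(x$genomic_seq), nrow(x$exons), x$cds_start,
              x$cds_codon_count))
  invisible(x)
}

exon_lengths <- function(model) model$exons[, "end"] - model$exons[, "start"]

#' Splice exons out of a gene model
#'
#' Concatenates the sequences of the requested exons, in order, from the
#' model's gene-strand genomic sequence. The full exon index set yields the
#' constitutive mRNA; an empty subset yields the empty string.
#'
#' @param model a [gene_model()].
#' @param exon_subset increasing vector of 1-based exon indices
#'   (default: all exons).
#' @return DNA string (character scalar).
#' @export
splice_out <- function(model, exon_subset = seq_len(nrow(model$exons))) {
  if (length(exon_subset) == 0L) return("")
  exon_subset <- as.integer(exon_subset)
  if (any(exon_subset < 1L) || any(exon_subset > nrow(model$exons))) {
    stop("argument error: exon index out of range")
  }
  if (any(diff(exon_subset) <= 0L)) {
    stop("argument error: exon_subset must be strictly increasing")
  }
  paste(substring(model$genomic_seq,
                  model$exons[exon_subset, "start"] + 1L,
                  model$exons[exon_subset, "end"]),
        collapse = "")
}

#' @rdname splice_out
#' @export
constitutive_mrna <- function(model) splice_out(model)

#' Transcript coordinate of a genomic position
#'
#' Maps a 0-based genomic offset to the 0-based position in the constitutive
#' transcript, or `NA` for intronic/flanking positions.
#'
#' @param model a [gene_model()].
#' @param gpos 0-based genomic offsets.
#' @return integer vector of 0-based transcript offsets (NA where intronic).
#' @export
genomic_to_transcript <- function(model, gpos) {
  lens <- exon_lengths(model)
  cum <- cumsum(c(0L, lens))
  out <- rep(NA_integer_, length(gpos))
  for (e in seq_len(nrow(model$exons))) {
    hit <- gpos >= model$exons[e, "start"] & gpos < model$exons[e, "end"]
    out[hit] <- cum[e] + (gpos[hit] - model$exons[e, "start"])
  }
  out
}

#' @rdname genomic_to_transcript
#' @param tpos 0-based transcript offsets.
#' @export
transcript_to_genomic <- function(model, tpos) {
  lens <- exon_lengths(model)
  cum <- cumsum(c(0L, lens))
  out <- rep(NA_integer_, length(tpos))
  for (e in seq_len(nrow(model$exons))) {
    hit <- tpos >= cum[e] & tpos < cum[e + 1L]
    out[hit] <- model$exons[e, "start"] + (tpos[hit] - cum[e])
  }
  out
}

#' 0-based offset of the translation start in the constitutive transcript
#' @param model a [gene_model()].
#' @export
cds_offset_in_mrna <- function(model) genomic_to_transcript(model, model$cds_start)

#' Translate an mRNA and scan for the first in-frame stop
#'
#' Translates with the standard nuclear code from `cds_offset`, ignoring any
#' trailing partial codon. Codons containing `N` are reported as `X` and
#' never inferred to be stops. The returned `premature` flag compares the
#' first stop against `cds_codon_count` (the codon count of the constitutive
#' CDS including its natural stop) when supplied, and against the number of
#' complete codons in the input otherwise.
#'
#' @param mrna DNA string.
#' @param cds_offset 0-based offset of the first codon base.
#' @param cds_codon_count optional reference codon count (see above).
#' @return list of class `protein_result` with `peptide` (residues before the
#'   first stop), `full_translation`, `first_stop_codon_index` (1-based, NA if
#'   none), `n_codons`, `premature`.
#' @export
translate_and_scan <- function(mrna, cds_offset = 0L, cds_codon_count = NULL) {
  mrna <- toupper(as.character(mrna))
  n <- nchar(mrna)
  cds_offset <- as.integer(cds_offset)
  if (cds_offset < 0L || cds_offset >= n) stop("cds_offset outside the sequence")
  cds <- substr(mrna, cds_offset + 1L, n)
  n_codons <- nchar(cds) %/% 3L
  if (n_codons == 0L) {
    return(structure(list(peptide = "", full_translation = "",
                          first_stop_codon_index = NA_integer_,
                          n_codons = 0L, premature = FALSE),
                     class = "protein_result"))
  }
  cds <- substr(cds, 1L, n_codons * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  stops <- which(strsplit(aa, "")[[1]] == "*")
  first_stop <- if (length(stops)) stops[1L] else NA_integer_
  ref <- if (is.null(cds_codon_count)) n_codons else as.integer(cds_codon_count)
  premature <- !is.na(first_stop) && first_stop < ref
  peptide <- if (is.na(first_stop)) aa else substr(aa, 1L, first_stop - 1L)
  structure(list(peptide = peptide, full_translation = aa,
                 first_stop_codon_index = first_stop, n_codons = n_codons,
                 premature = premature),
            class = "protein_result")
}

#' @export
print.protein_result <- function(x, ...) {
  cat(sprintf("<protein_result> %d aa before stop; first stop codon: %s%s\n",
              nchar(x$peptide),
              ifelse(is.na(x$first_stop_codon_index), "none",
                     x$first_stop_codon_index),
              if (isTRUE(x$premature)) " (premature)" else ""))
  invisible(x)
}

#' Exon-local position of a CDS codon
#'
#' Studies of this gene family report stop positions in two conventions: the
#' global codon index from the translation start, and an exon-local "triplet"
#' index whose numbering restarts at the first complete codon whose first
#' base lies in that exon. This helper converts a global codon index into the
#' exon-local convention.
#'
#' @param model a [gene_model()].
#' @param codon_index 1-based codon index counted from the CDS start on the
#'   constitutive transcript.
#' @return list with `exon` (1-based exon index of the codon's first base)
#'   and `local_triplet` (1-based exon-local codon index).
#' @export
codon_exon_position <- function(model, codon_index) {
  codon_index <- as.integer(codon_index)
  off <- cds_offset_in_mrna(model)
  tpos <- off + 3L * (codon_index - 1L)          # first base, transcript coords
  lens <- exon_lengths(model)
  cum <- cumsum(c(0L, lens))
  exon <- findInterval(tpos, cum, rightmost.closed = FALSE)
  if (exon < 1L || tpos >= cum[length(cum)]) {
    stop("codon_index falls outside the constitutive transcript")
  }
  # first complete codon whose first base lies in this exon
  first_in_exon <- as.integer(ceiling((cum[exon] - off) / 3)) + 1L
  first_tpos <- off + 3L * (first_in_exon - 1L)
  if (first_tpos < cum[exon]) first_in_exon <- first_in_exon + 1L
  list(exon = as.integer(exon),
       local_triplet = as.integer(codon_index - first_in_exon + 1L))
}

#' Count allotypes among a set of allele sequences
#'
#' An allotype is a distinct predicted protein: alleles differing only by
#' synonymous substitutions collapse to one allotype. Sequences are
#' translated from `cds_offset` up to (excluding) the first stop.
#'
#' @param seqs character vector of allele mRNA/CDS sequences.
#' @param cds_offset 0-based translation start offset (single value, recycled).
#' @return integer: number of distinct predicted proteins.
#' @export
count_allotypes <- function(seqs, cds_offset = 0L) {
  peptides <- vapply(seqs, function(s) {
    translate_and_scan(s, cds_offset)$peptide
  }, character(1), USE.NAMES = FALSE)
  length(unique(peptides))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read a gene model from GFF3 + FASTA
#'
#' Expects `gene`, `exon` and `CDS` features whose `seqnames` match a record
#' in the FASTA. Minus-strand genes are reverse-complemented at load time and
#' all coordinates remapped, so downstream code always works in gene-strand
#' orientation. Per-exon domain labels are read from a `domain` attribute
#' when present.
#'
#' @param gff3_path path to a GFF3 file.
#' @param fasta_path path to the matching genomic FASTA.
#' @param gene_id optional gene to extract when the GFF3 holds several.
#' @return a [gene_model()] (or a named list of them when `gene_id` is `NULL`
#'   and several genes are annotated).
#' @export
read_gene_model <- function(gff3_path, fasta_path, gene_id = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ids <- unique(as.character(gr$ID[gr$type == "gene"]))
  if (!is.null(gene_id)) ids <- gene_id
  models <- lapply(ids, function(id) .one_gene_model(gr, seqs, id))
  names(models) <- ids
  if (length(models) == 1L) models[[1L]] else models
}

.one_gene_model <- function(gr, seqs, id) {
  parent <- vapply(as.list(gr$Parent), function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, character(1))
  keep <- (!is.na(parent) & parent == id) |
    (gr$type == "gene" & !is.na(gr$ID) & gr$ID == id)
  sub <- gr[keep]
  gene <- sub[sub$type == "gene"]
  exons <- sub[sub$type == "exon"]
  cds <- sub[sub$type == "CDS"]
  if (length(gene) != 1L || length(exons) < 1L) {
    stop(sprintf("format error: gene '%s' needs one gene and >=1 exon feature", id))
  }
  chrom <- as.character(GenomicRanges::seqnames(gene))
  if (!chrom %in% names(seqs)) {
    stop(sprintf("format error: sequence '%s' missing from the FASTA", chrom))
  }
  gseq <- as.character(seqs[[chrom]])
  L <- nchar(gseq)
  st <- GenomicRanges::start(exons) - 1L   # to 0-based half-open
  en <- GenomicRanges::end(exons)
  o <- order(st)
  st <- st[o]; en <- en[o]
  if (length(st) > 1L && any(st[-1L] < en[-length(en)])) {
    stop(sprintf("validation error: overlapping exons in gene '%s'", id))
  }
  labels <- if (!is.null(exons$domain)) as.character(exons$domain)[o] else NULL
  strand <- as.character(GenomicRanges::strand(gene))
  if (length(cds) < 1L) stop(sprintf("format error: gene '%s' has no CDS", id))
  if (strand == "-") {
    gseq <- revcomp(gseq)
    new_st <- L - en
    new_en <- L - st
    o2 <- order(new_st)
    st <- new_st[o2]; en <- new_en[o2]
    if (!is.null(labels)) labels <- rev(labels)
    cds_start <- L - max(GenomicRanges::end(cds))
  } else {
    cds_start <- min(GenomicRanges::start(cds)) - 1L
  }
  gene_model(id, gseq, cbind(st, en), cds_start, domain_labels = labels)
}

#' Write gene models to GFF3 + FASTA
#'
#' Inverse of [read_gene_model()]: emits one FASTA record per gene (the
#' gene-strand genomic sequence, so all features are written on `+`) and
#' gene/exon/CDS features with a `domain` attribute carrying the exon labels.
#'
#' @param models a [gene_model()] or list of them.
#' @param gff3_path,fasta_path output paths.
#' @return invisibly, the paths.
#' @export
write_gene_model <- function(models, gff3_path, fasta_path) {
  if (inherits(models, "gene_model")) models <- list(models)
  grs <- lapply(models, function(m) {
    n <- nrow(m$exons)
    cds_end <- m$exons[n, "end"]       # CDS recorded from start codon to last exon end
    GenomicRanges::GRanges(
      seqnames = m$gene_id,
      ranges = IRanges::IRanges(
        start = c(m$exons[1, "start"], m$exons[, "start"], m$cds_start) + 1L,
        end = c(m$exons[n, "end"], m$exons[, "end"], cds_end)
      ),
      strand = "+",
      type = c("gene", rep("exon", n), "CDS"),
      ID = c(m$gene_id, sprintf("%s.e%d", m$gene_id, seq_len(n)),
             sprintf("%s.cds", m$gene_id)),
      Parent = IRanges::CharacterList(
        c(list(character(0)), rep(list(m$gene_id), n + 1L))),
      phase = c(rep(NA_integer_, n + 1L), 0L),
      domain = c(NA_character_, m$domain_labels, NA_character_)
    )
  })
  gr <- do.call(c, unname(grs))
  rtracklayer::export(gr, gff3_path, format = "gff3")
  seqs <- Biostrings::DNAStringSet(vapply(models, `[[`, character(1), "genomic_seq"))
  names(seqs) <- vapply(models, `[[`, character(1), "gene_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(c(gff3 = gff3_path, fasta = fasta_path))
}

#' Validate a GFF3 + FASTA gene model pair
#'
#' Loads the pair with [read_gene_model()] (which enforces all gene-model
#' invariants) and reports one line per gene.
#'
#' @inheritParams read_gene_model
#' @return invisibly, the models.
#' @export
validate_gene_model_files <- function(gff3_path, fasta_path) {
  models <- read_gene_model(gff3_path, fasta_path)
  if (inherits(models, "gene_model")) models <- list(models)
  for (m in models) {
    message(sprintf("OK %s: %d exons, CDS %d codons", m$gene_id,
                    nrow(m$exons), m$cds_codon_count))
  }
  invisible(models)
}
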