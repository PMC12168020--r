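# Genome/annotation I/O and gene-oriented sequence windows.
#
# Coordinate conventions used everywhere downstream:
#   * genomic coordinates are 1-based inclusive, as in GFF3;
#   * gene-relative positions put 0 on the first base of the annotated start
#     codon, negative positions upstream (-1 is the base immediately 5' of
#     the ATG), read in the gene's orientation.

#' Build an in-memory genome reference
#'
#' @param contigs named character vector or list, contig name -> sequence.
#' @return A \code{genome_ref} object (named list of uppercase sequences).
#' @export
genome_ref <- function(contigs) {
  contigs <- as.list(contigs)
  if (length(contigs) == 0L) stop("genome has no contigs", call. = FALSE)
  nms <- names(contigs)
  if (is.null(nms) || any(!nzchar(nms))) stop("contigs must be named", call. = FALSE)
  if (anyDuplicated(nms)) {
    stop("duplicate contig name: ", nms[duplicated(nms)][1L], call. = FALSE)
  }
  contigs <- lapply(contigs, function(s) {
    s <- toupper(as.character(s))
    if (!nzchar(s)) stop("empty contig sequence", call. = FALSE)
    assert_dna(s, "contig", allow_n = TRUE)
    s
  })
  structure(contigs, class = "genome_ref")
}

#' Load a genome from a FASTA file
#'
#' Sequences are uppercased on load; duplicate headers are an error.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return A \code{genome_ref}.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records",
                             call. = FALSE)
  nms <- sub("\\s.*$", "", names(ss))   # first token of the header
  if (anyDuplicated(nms)) {
    stop("duplicated FASTA header: ", nms[duplicated(nms)][1L], call. = FALSE)
  }
  genome_ref(stats::setNames(as.character(ss), nms))
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", length(x), " contig(s), ",
      sum(vapply(x, nchar, 0L)), " bp total\n", sep = "")
  invisible(x)
}

#' Load gene annotations from GFF3
#'
#' Reads gene + CDS features (\code{ID=} attribute is the gene id, CDS rows
#' are matched by \code{Parent=}).  \code{cds_start} is the 1-based genomic
#' coordinate of the first base of the start codon in gene orientation; for
#' minus-strand genes that is the larger coordinate.
#'
#' @param path GFF3 file.
#' @param genome a \code{genome_ref}; seqids must be present in it.
#' @param gene_ids optional character vector restricting which genes to load.
#' @return data.frame with columns gene_id, contig, strand, cds_start, cds_end.
#' @export
load_annotation <- function(path, genome, gene_ids = NULL) {
  stopifnot(inherits(genome, "genome_ref"))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!is.null(gene_ids)) genes <- genes[genes$ID %in% gene_ids, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features found in ", path, call. = FALSE)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    contig <- as.character(g$seqnames)
    if (!contig %in% names(genome)) {
      stop("seqid '", contig, "' (gene ", g$ID, ") not present in genome",
           call. = FALSE)
    }
    parents <- vapply(cds$Parent, function(p) g$ID %in% unlist(p), logical(1))
    my_cds <- cds[parents, , drop = FALSE]
    if (nrow(my_cds) == 0L) {
      stop("gene without CDS: ", g$ID, call. = FALSE)
    }
    strand <- as.character(g$strand)
    if (!strand %in% c("+", "-")) stop("gene ", g$ID, " has no strand", call. = FALSE)
    lo <- min(my_cds$start); hi <- max(my_cds$end)
    clen <- nchar(genome[[contig]])
    if (lo < 1L || hi > clen) {
      stop("CDS of gene ", g$ID, " exceeds contig bounds", call. = FALSE)
    }
    data.frame(gene_id = g$ID, contig = contig, strand = strand,
               cds_start = if (strand == "+") lo else hi,
               cds_end = if (strand == "+") hi else lo,
               stringsAsFactors = FALSE)
  })
  anns <- do.call(rbind, out)
  rownames(anns) <- NULL
  anns
}

#' Gene-oriented sequence window around a start codon
#'
#' Extracts the window covering gene-relative positions \code{[-u, d - 1]}
#' (position 0 = first base of the start codon).  Minus-strand genes are
#' reverse-complemented so that "upstream" is always 5' of the CDS in the
#' returned sequence.
#'
#' @param genome a \code{genome_ref}.
#' @param ann a single-row annotation (as from [load_annotation()]).
#' @param u upstream extent in bp (positions -u .. -1).
#' @param d downstream extent in bp (positions 0 .. d-1).
#' @return An \code{oriented_locus}: list(gene_id, window_seq, u, d).
#' @export
orient_locus <- function(genome, ann, u, d) {
  stopifnot(inherits(genome, "genome_ref"), u >= 0L, d >= 3L)
  contig <- genome[[ann$contig]]
  if (is.null(contig)) stop("contig '", ann$contig, "' not in genome", call. = FALSE)
  n <- nchar(contig)
  s <- ann$cds_start
  if (ann$strand == "+") {
    from <- s - u; to <- s + d - 1L
    if (from < 1L || to > n) {
      stop("window [-", u, ", ", d, ") for gene ", ann$gene_id,
           " exceeds contig bounds", call. = FALSE)
    }
    win <- substr(contig, from, to)
  } else {
    from <- s - d + 1L; to <- s + u
    if (from < 1L || to > n) {
      stop("window [-", u, ", ", d, ") for gene ", ann$gene_id,
           " exceeds contig bounds", call. = FALSE)
    }
    win <- revcomp(substr(contig, from, to))
  }
  codon <- substr(win, u + 1L, u + 3L)
  if (codon != "ATG") {
    warning("gene ", ann$gene_id, ": annotated start codon is ", codon,
            ", not ATG", call. = FALSE)
  }
  structure(list(gene_id = ann$gene_id, window_seq = win, u = as.integer(u),
                 d = as.integer(d), start_codon = codon),
            class = "oriented_locus")
}

#' Slice an oriented locus by gene-relative positions (inclusive)
#'
#' @param locus an \code{oriented_locus}.
#' @param from,to gene-relative positions, \code{from <= to}.
#' @return nucleotide string.
#' @export
locus_slice <- function(locus, from, to) {
  stopifnot(inherits(locus, "oriented_locus"), from <= to)
  if (from < -locus$u || to > locus$d - 1L) {
    stop("slice [", from, ", ", to, "] outside locus window [-", locus$u, ", ",
         locus$d - 1L, "]", call. = FALSE)
  }
  substr(locus$window_seq, from + locus$u + 1L, to + locus$u + 1L)
}

#' @export
print.oriented_locus <- function(x, ...) {
  cat("<oriented_locus> ", x$gene_id, ": positions [", -x$u, ", ", x$d - 1L,
      "], start codon ", x$start_codon, "\n", sep = "")
  invisible(x)
}
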