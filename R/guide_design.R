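# sgRNA candidate enumeration, scoring, off-target counting and selection
# inside the promoter window.
#
# Geometry: SpCas9 NGG PAM; blunt cut between spacer positions 17 and 18,
# i.e. 3 bp 5' of the PAM on the protospacer strand.  `cut_pos` is reported
# as the gene-strand coordinate of the first base 3' of the cut.

#' Guide-selection configuration
#'
#' Defaults encode the selection policy used for promoter replacement: the
#' cut must fall within 200 bp upstream of the start codon and the
#' efficiency score must exceed 60.
#'
#' @param window_start,window_end gene-relative cut window (inclusive).
#' @param score_threshold strict lower bound on the efficiency score.
#' @param max_mm maximum Hamming mismatches for off-target counting.
#' @param require_cut_in_deletion additionally require the cut (and the whole
#'   protospacer+PAM) to lie inside the promoter interval that the homology
#'   arms delete, so edited alleles cannot be re-cut.
#' @return A \code{guide_config} list.
#' @export
guide_config <- function(window_start = -200L, window_end = -1L,
                         score_threshold = 60, max_mm = 2L,
                         require_cut_in_deletion = TRUE) {
  stopifnot(window_start < window_end, window_end <= 0L)
  structure(list(window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 score_threshold = score_threshold,
                 max_mm = as.integer(max_mm),
                 require_cut_in_deletion = isTRUE(require_cut_in_deletion)),
            class = "guide_config")
}

#' Enumerate all NGG guide candidates whose cut falls in the window
#'
#' Scans both strands of the oriented locus.  Minus-strand candidates report
#' the spacer on their own (protospacer) strand.
#'
#' @param locus an \code{oriented_locus} covering at least
#'   \code{[window_start - 25, window_end + 25]}.
#' @param cfg a [guide_config()].
#' @return data.frame: target_id, spacer, pam, strand_rel_gene,
#'   protospacer_start, cut_pos, distance_to_atg.
#' @export
scan_pams <- function(locus, cfg = guide_config()) {
  stopifnot(inherits(locus, "oriented_locus"))
  lo <- cfg$window_start - 25L; hi <- cfg$window_end + 25L
  if (-locus$u > lo || locus$d - 1L < hi) {
    stop("locus must cover [", lo, ", ", hi, "] for scanning", call. = FALSE)
  }
  region <- locus_slice(locus, lo, hi)
  if (grepl("N", region, fixed = TRUE)) {
    stop("guide window for ", locus$gene_id, " contains N", call. = FALSE)
  }
  s <- locus$window_seq
  rel <- function(i) i - locus$u - 1L   # 1-based window index -> gene-relative
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  rows <- list()
  # + strand: spacer[20] + N + GG ; PAM start index pp, spacer pp-20..pp-1
  gg <- which(chars[-n] == "G" & chars[-1] == "G")      # index of first G
  for (i in gg) {
    pp <- i - 1L                                        # PAM start (N of NGG)
    if (pp - 20L < 1L || pp + 2L > n) next
    cut_pos <- rel(pp - 3L)
    if (cut_pos < cfg$window_start || cut_pos > cfg$window_end) next
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = locus$gene_id,
      spacer = substr(s, pp - 20L, pp - 1L),
      pam = substr(s, pp, pp + 2L),
      strand_rel_gene = "+",
      protospacer_start = rel(pp - 20L),
      cut_pos = cut_pos,
      distance_to_atg = abs(cut_pos),
      stringsAsFactors = FALSE)
  }
  # - strand: CCN on the given strand; protospacer is the reverse complement
  cc <- which(chars[-n] == "C" & chars[-1] == "C")
  for (i in cc) {
    if (i + 22L > n || i < 1L) next
    cut_pos <- rel(i + 6L)
    if (cut_pos < cfg$window_start || cut_pos > cfg$window_end) next
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = locus$gene_id,
      spacer = revcomp(substr(s, i + 3L, i + 22L)),
      pam = revcomp(substr(s, i, i + 2L)),
      strand_rel_gene = "-",
      protospacer_start = rel(i + 22L),
      cut_pos = cut_pos,
      distance_to_atg = abs(cut_pos),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(target_id = character(0), spacer = character(0),
                      pam = character(0), strand_rel_gene = character(0),
                      protospacer_start = integer(0), cut_pos = integer(0),
                      distance_to_atg = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$cut_pos, out$strand_rel_gene), , drop = FALSE]
}

#' Rule-based guide efficiency score
#'
#' A transparent deterministic stand-in for black-box on-target models,
#' calibrated so that the conventional "score > 60" filter keeps guides with
#' benign composition and a unique genomic site: start at 100; -30 if spacer
#' GC fraction lies outside \[0.40, 0.80\]; -40 if the spacer contains
#' "TTTT" (Pol III terminator); -20 per perfect-match genomic site beyond
#' the on-target one; floored at 0.
#'
#' @param spacer 20-nt spacer string.
#' @param perfect_hits genome-wide perfect-match count including the
#'   on-target site (so 1 means unique).
#' @return score in 0..100.
#' @export
score_guide <- function(spacer, perfect_hits = 1L) {
  stopifnot(nchar(spacer) == 20L, perfect_hits >= 1L)
  sc <- 100
  gc <- gc_fraction(spacer)
  if (gc < 0.40 || gc > 0.80) sc <- sc - 30
  if (grepl("TTTT", spacer, fixed = TRUE)) sc <- sc - 40
  sc <- sc - 20 * (perfect_hits - 1L)
  max(sc, 0)
}

#' Genome-wide PAM-adjacent off-target counts at Hamming distance <= max_mm
#'
#' Counts occurrences of the spacer on both strands of every contig that are
#' immediately followed by an NGG PAM, binned by mismatch count.  The
#' on-target site is included (so \code{hits["0"] >= 1} for a genomic
#' spacer).
#'
#' @param spacer 20-nt spacer.
#' @param genome a \code{genome_ref}.
#' @param max_mm maximum mismatches (0..3).
#' @return named integer vector of length \code{max_mm + 1}, names "0".."max_mm".
#' @export
count_offtargets <- function(spacer, genome, max_mm = 2L,
                             index = genome_pam_index(genome)) {
  stopifnot(nchar(spacer) == 20L)
  if (max_mm > 3L) stop("max_mm > 3 is not supported", call. = FALSE)
  hits <- stats::setNames(integer(max_mm + 1L), as.character(0:max_mm))
  if (ncol(index$mat) == 0L) return(hits)
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  mm <- .colSums(index$mat != sp, 20L, ncol(index$mat))
  tab <- tabulate(mm[mm <= max_mm] + 1L, nbins = max_mm + 1L)
  hits[] <- as.integer(tab)
  hits
}

#' Precompute all PAM-adjacent protospacer sites of a genome
#'
#' Enumerates every 20-mer immediately followed by an NGG PAM on either
#' strand of every contig, stored as a 20-row character matrix for
#' vectorized Hamming comparison.  Compute once and reuse when counting
#' off-targets for many spacers against the same genome.
#'
#' @param genome a \code{genome_ref}.
#' @return list with \code{mat} (20 x n_sites character matrix).
#' @export
genome_pam_index <- function(genome) {
  stopifnot(inherits(genome, "genome_ref"))
  cols <- list()
  for (contig in unlist(genome, use.names = FALSE)) {
    fwd <- Biostrings::DNAString(contig)
    for (subj in list(fwd, Biostrings::reverseComplement(fwd))) {
      s <- as.character(subj)
      n <- nchar(s)
      if (n < 23L) next
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      # spacer start i has PAM at i+20..i+22 with GG at i+21..i+22
      gg <- which(ch == "G")
      gg <- gg[gg >= 22L & gg <= n - 1L]
      gg <- gg[ch[gg + 1L] == "G"]
      starts <- gg - 21L
      starts <- starts[starts >= 1L]
      if (length(starts) == 0L) next
      idx <- outer(0:19, starts, `+`)
      cols[[length(cols) + 1L]] <- matrix(ch[idx], nrow = 20L)
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(character(0), nrow = 20L)
  list(mat = mat)
}

#' Score candidates and attach off-target hit counts
#'
#' Candidates whose composition score (GC/TTTT penalties alone) already
#' fails the threshold are not off-target-searched (hit penalties can only
#' lower the score); their hits columns are NA and score is the composition
#' score.
#'
#' @param cands candidate data.frame from [scan_pams()].
#' @param genome a \code{genome_ref}.
#' @param cfg a [guide_config()].
#' @return \code{cands} with added columns hits0, hits1, hits2 (as available)
#'   and score.
#' @export
score_guides <- function(cands, genome, cfg = guide_config()) {
  nmm <- cfg$max_mm
  hitcols <- paste0("hits", 0:nmm)
  for (hc in hitcols) cands[[hc]] <- NA_integer_
  cands$score <- NA_real_
  if (nrow(cands) == 0L) return(cands)
  index <- genome_pam_index(genome)
  for (i in seq_len(nrow(cands))) {
    comp <- score_guide(cands$spacer[i], perfect_hits = 1L)
    if (comp <= cfg$score_threshold) {
      cands$score[i] <- comp
      next
    }
    h <- count_offtargets(cands$spacer[i], genome, max_mm = nmm,
                          index = index)
    cands[i, hitcols] <- as.list(h)
    cands$score[i] <- score_guide(cands$spacer[i], perfect_hits = max(h[["0"]], 1L))
  }
  cands
}

#' Select the single best guide for a target
#'
#' Filters candidates to score strictly above the threshold with the cut in
#' the configured window (and, when \code{require_cut_in_deletion} is set
#' and a deleted interval is supplied, cut plus the whole protospacer+PAM
#' inside that interval), then ranks by fewest extra perfect hits, fewest
#' 1-mismatch hits, highest score, smallest distance to the ATG, and
#' lexicographic spacer as the final deterministic tie-break.
#'
#' @param cands scored candidates (from [score_guides()]).
#' @param cfg a [guide_config()].
#' @param deleted_interval optional gene-relative inclusive interval
#'   \code{c(start, end)} replaced by the promoter (from [extract_arms()]).
#' @return the selected candidate (one-row data.frame).
#' @export
select_guide <- function(cands, cfg = guide_config(), deleted_interval = NULL) {
  if (nrow(cands) == 0L) {
    stop("no guide candidates supplied", call. = FALSE)
  }
  target <- cands$target_id[1]
  keep <- !is.na(cands$score) & cands$score > cfg$score_threshold &
    cands$cut_pos >= cfg$window_start & cands$cut_pos <= cfg$window_end &
    !is.na(cands$hits0)
  if (cfg$require_cut_in_deletion && !is.null(deleted_interval)) {
    proto_lo <- ifelse(cands$strand_rel_gene == "+",
                       cands$protospacer_start,
                       cands$protospacer_start - 22L)
    proto_hi <- proto_lo + 22L
    keep <- keep &
      cands$cut_pos >= deleted_interval[1] & cands$cut_pos <= deleted_interval[2] &
      proto_lo >= deleted_interval[1] & proto_hi <= deleted_interval[2]
  }
  surv <- cands[keep, , drop = FALSE]
  if (nrow(surv) == 0L) {
    stop("no guide passes the filters for target ", target, call. = FALSE)
  }
  extra0 <- pmax(surv$hits0 - 1L, 0L)
  h1 <- if ("hits1" %in% names(surv)) surv$hits1 else 0L
  ord <- order(extra0, h1, -surv$score, surv$distance_to_atg, surv$spacer)
  surv[ord[1L], , drop = FALSE]
}

#' Design one guide per gene
#'
#' Convenience pipeline: orient each gene, enumerate candidates, score them
#' against the genome, and select the best guide.
#'
#' @param genome a \code{genome_ref}.
#' @param annotations data.frame from [load_annotation()].
#' @param cfg a [guide_config()].
#' @param deleted_interval optional interval forwarded to [select_guide()]
#'   (same for all genes, e.g. from the default arm placement).
#' @return data.frame of selected guides, one row per gene; genes for which
#'   no guide passes are reported in attribute \code{"failed"}.
#' @export
design_guides <- function(genome, annotations, cfg = guide_config(),
                          deleted_interval = NULL) {
  u <- -cfg$window_start + 30L
  d <- cfg$window_end + 30L + 3L
  picks <- list(); failed <- character(0)
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, , drop = FALSE]
    res <- tryCatch({
      locus <- orient_locus(genome, ann, u = u, d = max(d, 25L))
      cands <- scan_pams(locus, cfg)
      cands <- score_guides(cands, genome, cfg)
      select_guide(cands, cfg, deleted_interval)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, ann$gene_id)
    } else {
      picks[[length(picks) + 1L]] <- res
    }
  }
  out <- if (length(picks)) do.call(rbind, picks) else
    data.frame(target_id = character(0))
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}
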