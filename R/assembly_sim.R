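# In silico SapI (GCTCTTC, 1/4) digestion, single-pot Golden Gate ligation
# of the pooled basic plasmids with promoter parts, Gibson-overlap checks,
# and reconstruction of the edited genomic locus.
#
# Fragment model: a linear fragment stores the TOP-strand sequence between
# two consecutive top-strand cuts; each cut's 3-nt 5' overhang is written as
# the top-strand fusion site and belongs to the fragment to its right
# (its `left_ov`), while the fragment to the left records the same string as
# `right_ov`.  Two ends ligate iff their fusion-site strings are equal --
# equality of top-strand fusion sites is exactly Watson-Crick annealing of
# the two complementary protruding single strands.  Ligation concatenates
# the top strands without duplicating the overhang.

#' Construct a plasmid object
#'
#' @param id identifier.
#' @param sequence top-strand nucleotide string.
#' @param circular logical; circular plasmids are rotation-invariant for
#'   site scanning.
#' @param meta optional named list of metadata (target, arms, ...).
#' @return A \code{plasmid}.
#' @export
plasmid <- function(id, sequence, circular = TRUE, meta = list()) {
  sequence <- toupper(sequence)
  assert_dna(sequence, "plasmid sequence")
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 meta = meta), class = "plasmid")
}

new_fragment <- function(seq, left_ov = "", right_ov = "", circular = FALSE) {
  structure(list(sequence = seq, left_ov = left_ov, right_ov = right_ov,
                 circular = isTRUE(circular)), class = "gg_fragment")
}

# All SapI cut events on a sequence.  Returns data.frame(site_start, orient,
# cut, overhang): `cut` is the 0-based top-strand index at which the
# right-hand fragment begins (its first three bases are the overhang).
sapi_cuts <- function(seq, circular) {
  n <- nchar(seq)
  sites <- sapi_sites(seq, circular = circular)
  if (nrow(sites) == 0L) {
    return(data.frame(site_start = integer(0), orient = character(0),
                      cut = integer(0), overhang = character(0)))
  }
  # overlapping recognition heptamers cannot both be cut
  if (nrow(sites) > 1L) {
    st <- sort(sites$start)
    if (any(diff(st) < 7L)) stop("overlapping SapI recognition sites",
                                 call. = FALSE)
  }
  ext <- paste0(seq, seq)   # for wrap-around slicing on circles
  slice <- function(i0, len) {        # i0 0-based on the circle/line
    if (circular) i0 <- ((i0 %% n) + n) %% n
    if (!circular && (i0 < 0L || i0 + len > n)) {
      stop("SapI cut site truncated at a linear sequence end", call. = FALSE)
    }
    substr(ext, i0 + 1L, i0 + len)
  }
  cut0 <- ifelse(sites$orient == "+", sites$start - 1L + 8L,
                 sites$start - 1L - 4L)
  ov <- vapply(cut0, slice, character(1), len = 3L)
  if (circular) cut0 <- ((cut0 %% n) + n) %% n
  data.frame(site_start = sites$start, orient = sites$orient, cut = cut0,
             overhang = ov, stringsAsFactors = FALSE)
}

#' Digest a plasmid (or linear fragment) with SapI
#'
#' Implements the GCTCTTC(1/4) geometry: top-strand cut 1 nt 3' of the
#' recognition site, bottom-strand cut 4 nt, leaving 3-nt 5' overhangs;
#' both site orientations are recognized.  A circular input with k sites
#' yields k fragments; a linear input yields k + 1 (blunt outer ends).
#' A circular plasmid with no site is returned unchanged as one circular
#' fragment.
#'
#' @param p a [plasmid()].
#' @return list of \code{gg_fragment}s.
#' @export
sapi_digest <- function(p) {
  stopifnot(inherits(p, "plasmid"))
  n <- nchar(p$sequence)
  cuts <- sapi_cuts(p$sequence, circular = p$circular)
  if (nrow(cuts) == 0L) {
    return(list(new_fragment(p$sequence, circular = p$circular)))
  }
  cuts <- cuts[order(cuts$cut), , drop = FALSE]
  ext <- paste0(p$sequence, p$sequence)
  frags <- list()
  if (p$circular) {
    k <- nrow(cuts)
    for (i in seq_len(k)) {
      a <- cuts$cut[i]
      b <- if (i < k) cuts$cut[i + 1L] else cuts$cut[1L] + n
      frags[[i]] <- new_fragment(substr(ext, a + 1L, b),
                                 left_ov = cuts$overhang[i],
                                 right_ov = cuts$overhang[if (i < k) i + 1L else 1L])
    }
  } else {
    bounds <- c(0L, cuts$cut, n)
    ovs <- c("", cuts$overhang, "")
    for (i in seq_len(length(bounds) - 1L)) {
      frags[[i]] <- new_fragment(substr(p$sequence, bounds[i] + 1L, bounds[i + 1L]),
                                 left_ov = ovs[i], right_ov = ovs[i + 1L])
    }
  }
  frags
}

#' Build a promoter part with SapI flanks for the scarless slot
#'
#' Flanks the (SapI-free) promoter core so that digestion releases exactly
#' one insert fragment with upstream fusion site \code{o_up} and downstream
#' fusion site "ATG".  An empty core gives the promoter-deletion part, whose
#' insert joins \code{o_up} directly to the ATG.
#'
#' @param id part identifier (e.g. promoter name, or "DELETION").
#' @param core_seq promoter sequence; may be "" for the deletion part.
#' @param o_up 3-nt upstream fusion site (must match the cassette's; not "ATG").
#' @return A \code{promoter_part}: list(id, core_seq, o_up, flanked_seq).
#' @export
make_part <- function(id, core_seq, o_up = "AAT") {
  core_seq <- toupper(core_seq)
  if (nzchar(core_seq)) assert_dna(core_seq, "promoter core")
  stopifnot(nchar(o_up) == 3L)
  if (o_up == "ATG") {
    stop("o_up must not be 'ATG' (ambiguous circular self-insertion)",
         call. = FALSE)
  }
  if (has_sapi(core_seq)) {
    stop("promoter core '", id, "' contains a SapI recognition site",
         call. = FALSE)
  }
  flanked <- paste0("T", SAPI_SITE, "A", o_up, core_seq, "ATG", "C",
                    SAPI_SITE_RC, "T")
  frags <- sapi_digest(plasmid(id, flanked, circular = FALSE))
  ins <- Filter(function(f) f$left_ov == o_up && f$right_ov == "ATG", frags)
  if (length(ins) != 1L) {
    stop("part '", id, "' does not digest to a unique (o_up, ATG) insert",
         call. = FALSE)
  }
  structure(list(id = id, core_seq = core_seq, o_up = o_up,
                 flanked_seq = flanked, insert = ins[[1L]]),
            class = "promoter_part")
}

#' Gibson-overlap validation of an element against a backbone
#'
#' Checks that the element's terminal 20-mers exactly match the backbone
#' junction 20-mers: the element's first 20 nt must equal the backbone's
#' last 20 nt (left junction) and the element's last 20 nt the backbone's
#' first 20 nt (right junction).  On mismatch the longest exact terminal
#' overlap is reported.
#'
#' @param element a \code{synthetic_element} or bare sequence.
#' @param backbone_left sequence ending at the element's left junction.
#' @param backbone_right sequence starting at the element's right junction
#'   (for a single circular backbone pass the same sequence twice).
#' @param overlap_len expected overlap (20).
#' @return list(pass, left_overlap, right_overlap, reason).
#' @export
gibson_check <- function(element, backbone_left, backbone_right,
                         overlap_len = 20L) {
  eseq <- if (inherits(element, "synthetic_element")) element$sequence else element
  if (nchar(eseq) < 2L * overlap_len) {
    return(list(pass = FALSE, left_overlap = 0L, right_overlap = 0L,
                reason = "too short"))
  }
  # align the two 20-mers at the junction; report the longest contiguous
  # run of positionwise matches anchored at either end of the overlap
  aligned_overlap <- function(a, b) {
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    eq <- av == bv
    if (all(eq)) return(length(eq))
    run_from <- function(v) { r <- 0L; for (x in v) { if (!x) break; r <- r + 1L }; r }
    max(run_from(eq), run_from(rev(eq)))
  }
  left <- aligned_overlap(
    substr(backbone_left, nchar(backbone_left) - overlap_len + 1L,
           nchar(backbone_left)),
    substr(eseq, 1L, overlap_len))
  right <- aligned_overlap(
    substr(eseq, nchar(eseq) - overlap_len + 1L, nchar(eseq)),
    substr(backbone_right, 1L, overlap_len))
  pass <- left == overlap_len && right == overlap_len
  list(pass = pass, left_overlap = left, right_overlap = right,
       reason = if (pass) NA_character_ else "terminal overlap mismatch")
}

#' Clone an element into a linear backbone by Gibson assembly
#'
#' The backbone's first 20 nt must equal the element's last 20 nt and its
#' last 20 nt the element's first 20 nt; the circular product carries each
#' overlap once.
#'
#' @param element a \code{synthetic_element}.
#' @param backbone linear backbone sequence.
#' @return A circular [plasmid()] ("basic plasmid") carrying design metadata.
#' @export
assemble_basic_plasmid <- function(element, backbone) {
  chk <- gibson_check(element, backbone_left = backbone,
                      backbone_right = backbone)
  if (!chk$pass) {
    stop("Gibson overlap check failed for ", element$target_id, " (overlaps ",
         chk$left_overlap, "/", chk$right_overlap, "): ", chk$reason,
         call. = FALSE)
  }
  seq <- paste0(element$sequence, substr(backbone, 21L, nchar(backbone) - 20L))
  plasmid(paste0("p", element$target_id), seq, circular = TRUE,
          meta = list(target_id = element$target_id, element = element))
}

# rotate a circular sequence so it starts at 1-based position i
rotate_seq <- function(seq, i) {
  if (i == 1L) return(seq)
  paste0(substr(seq, i, nchar(seq)), substr(seq, 1L, i - 1L))
}

#' Single-pot Golden Gate of pooled basic plasmids with promoter parts
#'
#' Each basic plasmid must digest into exactly one backbone fragment whose
#' fusion sites are (ATG, o_up); every part insert with matching fusion
#' sites is ligated in, enumerating the full target x promoter-state
#' library.  Products are validated SapI-free (assembly is irreversible).
#'
#' @param basic list of basic [plasmid()]s.
#' @param parts list of [make_part()] promoter parts.
#' @param include_deletion also enumerate the promoter-deletion variant
#'   (an empty-core part) for every target.
#' @return A \code{library_pool}: list(products, diversity, failed_targets,
#'   incompatible_parts).
#' @export
golden_gate <- function(basic, parts, include_deletion = TRUE) {
  stopifnot(length(basic) > 0L)
  products <- list()
  failed <- character(0)
  part_used <- stats::setNames(logical(length(parts)),
                               vapply(parts, `[[`, "", "id"))
  for (p in basic) {
    frags <- sapi_digest(p)
    bb <- Filter(function(f) !f$circular && f$left_ov == "ATG" &&
                   nchar(f$sequence) > 50L, frags)
    if (length(frags) != 2L || length(bb) != 1L) {
      failed <- c(failed, p$id)
      next
    }
    bb <- bb[[1L]]
    target <- if (!is.null(p$meta$target_id)) p$meta$target_id else p$id
    use_parts <- parts
    if (include_deletion) {
      use_parts <- c(use_parts, list(make_part("DELETION", "", o_up = bb$right_ov)))
    }
    for (part in use_parts) {
      ins <- part$insert
      if (!(bb$right_ov == ins$left_ov && ins$right_ov == bb$left_ov)) next
      if (part$id %in% names(part_used)) part_used[part$id] <- TRUE
      seq <- paste0(bb$sequence, ins$sequence)
      # rotate the circular product so its linear representation starts at
      # the element's Gibson-left arm, keeping the promoter slot internal
      el <- p$meta$element
      if (!is.null(el)) {
        tail_len <- el$layout$gibson_len + el$layout$spacer_len +
          el$layout$linker_len + el$arms$arm_len
        seq <- rotate_seq(seq, nchar(bb$sequence) - tail_len + 1L)
      }
      if (has_sapi(seq, circular = TRUE)) {
        stop("assembly product ", target, " x ", part$id,
             " retains a SapI site", call. = FALSE)
      }
      products[[length(products) + 1L]] <- structure(list(
        id = paste0(target, ".", part$id),
        target_id = target, promoter_id = part$id,
        core_seq = part$core_seq, o_up = part$o_up,
        sequence = seq, circular = TRUE,
        meta = p$meta), class = "assembly_product")
    }
  }
  unused <- names(part_used)[!part_used]
  if (length(unused)) {
    warning("part(s) incompatible with every backbone: ",
            paste(unused, collapse = ", "), call. = FALSE)
  }
  keys <- vapply(products, function(x) paste(x$target_id, x$promoter_id),
                 character(1))
  structure(list(products = products,
                 diversity = length(unique(keys)),
                 failed_targets = failed,
                 incompatible_parts = unused),
            class = "library_pool")
}

#' @export
print.library_pool <- function(x, ...) {
  cat("<library_pool> ", length(x$products), " products, diversity ",
      x$diversity, if (length(x$failed_targets))
        paste0(", ", length(x$failed_targets), " assembly-failed") else "",
      "\n", sep = "")
  invisible(x)
}

#' Predict the post-recombination (edited) genomic locus
#'
#' Reconstructs the genomic sequence expected after homologous
#' recombination with an assembly product: upstream context, upstream arm,
#' upstream fusion site, promoter core, then the CDS from its original ATG
#' onward.  Asserts that the arms match the locus and that the CDS start is
#' intact.
#'
#' @param product an \code{assembly_product} from [golden_gate()].
#' @param locus the \code{oriented_locus} the design was derived from.
#' @return list(sequence, atg_offset): the edited window and the 1-based
#'   position of the (unchanged) start codon within it.
#' @export
reconstruct_edited_locus <- function(product, locus) {
  stopifnot(inherits(product, "assembly_product"),
            inherits(locus, "oriented_locus"))
  el <- product$meta$element
  if (is.null(el)) stop("product carries no element metadata", call. = FALSE)
  arms <- el$arms
  up_iv <- arms$up_interval
  if (locus_slice(locus, up_iv[1], up_iv[2]) != arms$up_arm ||
      locus_slice(locus, 0L, arms$arm_len - 1L) != arms$down_arm) {
    stop("junction mismatch: arms do not match the supplied locus",
         call. = FALSE)
  }
  upstream_ctx <- if (up_iv[1] > -locus$u) {
    locus_slice(locus, -locus$u, up_iv[1] - 1L)
  } else ""
  cds_on <- locus_slice(locus, 0L, locus$d - 1L)
  seq <- paste0(upstream_ctx, arms$up_arm, product$o_up, product$core_seq,
                cds_on)
  atg_offset <- nchar(upstream_ctx) + nchar(arms$up_arm) + 3L +
    nchar(product$core_seq) + 1L
  if (substr(seq, atg_offset, atg_offset + 2L) != substr(cds_on, 1L, 3L)) {
    stop("junction mismatch: CDS start not intact after reconstruction",
         call. = FALSE)
  }
  list(sequence = seq, atg_offset = atg_offset)
}

#' Write a pool manifest TSV
#'
#' @param pool a \code{library_pool}.
#' @param path output TSV (product_id, target_id, promoter_id, length).
#' @return invisibly, the manifest data.frame.
#' @export
write_pool_manifest <- function(pool, path) {
  man <- data.frame(
    product_id = vapply(pool$products, `[[`, "", "id"),
    target_id = vapply(pool$products, `[[`, "", "target_id"),
    promoter_id = vapply(pool$products, `[[`, "", "promoter_id"),
    length = vapply(pool$products, function(x) nchar(x$sequence), 0L),
    stringsAsFactors = FALSE)
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
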