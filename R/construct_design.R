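# Homology-arm extraction and assembly of the fixed-layout synthetic gene
# block:  gibson_left | spacer | linker | up_arm | SapI cassette | down_arm
# | gibson_right.  The fixed (non-arm) budget is 2*20 + 20 + 80 + 36 =
# 176 bp, so the whole element is 2*arm_len + 176: 300 bp with 62-bp arms,
# 500 bp with 162-bp arms.

# shipped fixed-region defaults (SapI-free by construction, asserted below)
DEFAULT_GIBSON_LEFT  <- "GGCACAGCTTGGGAGACTTT"
DEFAULT_GIBSON_RIGHT <- "CTTGATGACATTGGCACCGT"
DEFAULT_LINKER <- paste0(
  "ACCAGCACTATCCATTTCGGCTTATGGTATCCCAACACTGGCGGACGGGC",
  "AGATTAAGCCCAAACGTGCCGTCTTTATTT")
DEFAULT_CASSETTE_FILLER <- "TGGTGGAATCGTCCCGC"

#' SapI stuffer cassette with programmable upstream overhang
#'
#' Builds the 36-bp double-SapI cassette placed between the homology arms.
#' The two recognition sites point outward so that digestion of the cloned
#' plasmid excises the entire cassette and leaves 3-nt 5' overhangs: the
#' configurable \code{o_up} on the upstream-arm side and the downstream
#' arm's own ATG on the CDS side (GCTCTTC(1/4) geometry) -- the basis of the
#' scarless promoter slot.
#'
#' @param o_up 3-nt upstream fusion site; must not be "ATG".
#' @param filler 17-nt stuffer interior.
#' @return cassette string (36 bp).
#' @export
sapi_cassette <- function(o_up = "AAT", filler = DEFAULT_CASSETTE_FILLER) {
  stopifnot(nchar(o_up) == 3L, nchar(filler) == 17L)
  assert_dna(o_up, "o_up"); assert_dna(filler, "filler")
  if (o_up == "ATG") stop("o_up must differ from the downstream ATG overhang",
                          call. = FALSE)
  cass <- paste0(o_up, "C", SAPI_SITE_RC, filler, SAPI_SITE, "A")
  if (nrow(sapi_sites(cass)) != 2L) {
    stop("cassette must contain exactly two SapI recognition sites", call. = FALSE)
  }
  cass
}

#' Fixed layout of the synthetic element
#'
#' @param arm_len homology-arm length in bp (62 or 162 in the shipped
#'   designs; any positive length is accepted).
#' @param o_up upstream 3-nt fusion site for the promoter slot.
#' @param gibson_left_seq,gibson_right_seq 20-bp Gibson overlap sequences.
#' @param linker_seq 80-bp fixed region between spacer slot and upstream arm
#'   (stands for the sgRNA scaffold/terminator region).
#' @param cassette 36-bp double-SapI cassette, see [sapi_cassette()].
#' @param spacer_len spacer slot width (20).
#' @return An \code{element_layout} list.
#' @export
element_layout <- function(arm_len = 162L, o_up = "AAT",
                           gibson_left_seq = DEFAULT_GIBSON_LEFT,
                           gibson_right_seq = DEFAULT_GIBSON_RIGHT,
                           linker_seq = DEFAULT_LINKER,
                           cassette = sapi_cassette(o_up),
                           spacer_len = 20L) {
  stopifnot(arm_len > 0L)
  for (s in c(gibson_left_seq, gibson_right_seq, linker_seq)) {
    assert_dna(s, "layout sequence")
    if (has_sapi(s)) stop("layout fixed sequence contains a SapI site",
                          call. = FALSE)
  }
  gibson_len <- nchar(gibson_left_seq)
  budget <- 2L * gibson_len + spacer_len + nchar(linker_seq) + nchar(cassette)
  if (nchar(gibson_right_seq) != gibson_len) {
    stop("gibson arms must have equal length", call. = FALSE)
  }
  if (budget != 176L) {
    stop("fixed-region budget must be 176 bp (got ", budget, ")", call. = FALSE)
  }
  structure(list(arm_len = as.integer(arm_len), o_up = o_up,
                 gibson_len = gibson_len, spacer_len = as.integer(spacer_len),
                 linker_len = nchar(linker_seq), cassette_len = nchar(cassette),
                 gibson_left_seq = gibson_left_seq,
                 gibson_right_seq = gibson_right_seq,
                 linker_seq = linker_seq, cassette = cassette),
            class = "element_layout")
}

#' Extract SapI-free homology arms around the start codon
#'
#' The downstream arm is fixed at gene-relative \code{[0, arm_len - 1]}
#' (it must begin with the ATG); the upstream arm starts at the distal end
#' of the window, \code{[-window, -window + arm_len - 1]}, and slides 1 bp
#' toward the ATG past any SapI recognition site until clean, as long as
#' the deleted promoter interval between the arms stays non-empty.
#'
#' @param locus an \code{oriented_locus} covering \code{[-window, arm_len - 1]}.
#' @param arm_len arm length in bp.
#' @param window upstream design window in bp (default 500).
#' @return An \code{arm_pair}: up_arm/down_arm sequences with their
#'   gene-relative inclusive intervals, arm_len, and the deleted interval.
#' @export
extract_arms <- function(locus, arm_len = 162L, window = 500L) {
  stopifnot(inherits(locus, "oriented_locus"), arm_len > 0L,
            window > arm_len)
  if (locus$u < window || locus$d < arm_len) {
    stop("locus must cover [-", window, ", ", arm_len - 1L, "]", call. = FALSE)
  }
  region <- locus_slice(locus, -window, arm_len - 1L)
  if (grepl("N", region, fixed = TRUE)) {
    stop("design window for ", locus$gene_id, " contains N", call. = FALSE)
  }
  down <- locus_slice(locus, 0L, arm_len - 1L)
  if (substr(down, 1L, 3L) != "ATG") {
    stop("design-failed for ", locus$gene_id,
         ": downstream arm does not start with ATG", call. = FALSE)
  }
  if (has_sapi(down)) {
    stop("design-failed for ", locus$gene_id,
         ": downstream arm contains a SapI site and cannot move", call. = FALSE)
  }
  up_start <- -window
  repeat {
    up <- locus_slice(locus, up_start, up_start + arm_len - 1L)
    if (!has_sapi(up)) break
    up_start <- up_start + 1L
    if (up_start + arm_len - 1L >= -1L) {
      stop("design-failed for ", locus$gene_id,
           ": no SapI-free upstream-arm placement leaves a deleted interval",
           call. = FALSE)
    }
  }
  structure(list(
    up_arm = up, up_interval = c(up_start, up_start + arm_len - 1L),
    down_arm = down, down_interval = c(0L, arm_len - 1L),
    arm_len = as.integer(arm_len),
    deleted_interval = c(up_start + arm_len, -1L),
    gene_id = locus$gene_id), class = "arm_pair")
}

#' Assemble the full synthetic element
#'
#' Concatenates gibson_left + spacer + linker + up_arm + cassette +
#' down_arm + gibson_right and validates the element invariants: total
#' length \code{2*arm_len + 176}; exactly two SapI recognition sites
#' (counting both strands), both inside the cassette; gap-free feature
#' tiling.
#'
#' @param guide one-row guide data.frame (needs \code{spacer}) or a bare
#'   20-nt spacer string.
#' @param arms an \code{arm_pair} from [extract_arms()].
#' @param layout an [element_layout()].
#' @return A \code{synthetic_element}: list(target_id, sequence, features,
#'   spacer, arms, layout).
#' @export
build_element <- function(guide, arms, layout = element_layout(arms$arm_len)) {
  spacer <- if (is.character(guide)) guide else guide$spacer
  stopifnot(inherits(arms, "arm_pair"), inherits(layout, "element_layout"))
  if (nchar(spacer) != layout$spacer_len) {
    stop("spacer must be ", layout$spacer_len, " nt", call. = FALSE)
  }
  if (arms$arm_len != layout$arm_len) {
    stop("arm length ", arms$arm_len, " does not match layout arm_len ",
         layout$arm_len, call. = FALSE)
  }
  parts <- list(gibson_left = layout$gibson_left_seq, spacer = spacer,
                linker = layout$linker_seq, up_arm = arms$up_arm,
                sapi_cassette = layout$cassette, down_arm = arms$down_arm,
                gibson_right = layout$gibson_right_seq)
  lens <- vapply(parts, nchar, 0L)
  ends <- cumsum(lens)
  feats <- data.frame(name = names(parts), start = c(1L, utils::head(ends, -1) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  seq <- paste(unlist(parts), collapse = "")
  expected <- 2L * arms$arm_len + 176L
  if (nchar(seq) != expected) {
    stop("element length ", nchar(seq), " != 2*arm_len + 176 = ", expected,
         call. = FALSE)
  }
  sites <- sapi_sites(seq)
  cass <- feats[feats$name == "sapi_cassette", ]
  inside <- sites$start >= cass$start & (sites$start + 6L) <= cass$end
  if (nrow(sites) != 2L || !all(inside)) {
    bad <- sites[!inside, , drop = FALSE]
    offender <- vapply(bad$start, function(p) {
      feats$name[p >= feats$start & p <= feats$end][1]
    }, character(1))
    stop("extra SapI site(s) outside the cassette, in feature(s): ",
         paste(unique(offender), collapse = ", "), call. = FALSE)
  }
  structure(list(target_id = arms$gene_id, sequence = seq, features = feats,
                 spacer = spacer, arms = arms, layout = layout),
            class = "synthetic_element")
}

#' @export
print.synthetic_element <- function(x, ...) {
  cat("<synthetic_element> ", x$target_id, ": ", nchar(x$sequence), " bp, ",
      x$arms$arm_len, "-bp arms\n", sep = "")
  invisible(x)
}

#' Write elements to FASTA plus a feature-table TSV
#'
#' @param elements list of \code{synthetic_element}s.
#' @param fasta_path output FASTA (one record per element, id = target_id).
#' @param tsv_path output feature TSV (target_id, name, start, end).
#' @return invisibly, the feature table.
#' @export
write_elements <- function(elements, fasta_path, tsv_path) {
  ids <- vapply(elements, function(e) e$target_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate target_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(
    vapply(elements, function(e) e$sequence, character(1)))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, fasta_path)
  feats <- if (length(elements)) {
    do.call(rbind, lapply(elements, function(e) {
      cbind(target_id = e$target_id, e$features)
    }))
  } else {
    data.frame(target_id = character(0), name = character(0),
               start = integer(0), end = integer(0))
  }
  utils::write.table(feats, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(feats)
}
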