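# End-to-end design pipeline: genome + annotation -> selected guides ->
# homology arms -> synthetic elements -> basic plasmids.

#' Design promoter-replacement constructs for a set of genes
#'
#' For every annotated gene: orient the locus, extract SapI-free homology
#' arms, enumerate/score/select an sgRNA (requiring the cut inside the
#' deleted promoter interval), and build the synthetic element.  Genes
#' whose design fails (SapI in the fixed downstream arm, no passing guide,
#' ...) are collected in \code{failed} with the reason, mirroring how
#' individual constructs can drop out of a synthesized library.
#'
#' @param genome a \code{genome_ref}.
#' @param annotations data.frame from [load_annotation()] (or
#'   [make_toy_genome()]).
#' @param arm_len homology-arm length (62 or 162).
#' @param window upstream design window (500).
#' @param cfg a [guide_config()].
#' @param layout an [element_layout()]; defaults to the standard layout at
#'   \code{arm_len}.
#' @return A \code{design_set}: list(elements, guides, loci, failed).
#' @export
design_constructs <- function(genome, annotations, arm_len = 162L,
                              window = 500L, cfg = guide_config(),
                              layout = element_layout(arm_len)) {
  elements <- list(); loci <- list(); guides <- list()
  failed <- data.frame(gene_id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  u <- max(window, -cfg$window_start + 30L) + 20L
  d <- max(arm_len, cfg$window_end + 33L, 25L)
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, , drop = FALSE]
    res <- tryCatch({
      locus <- orient_locus(genome, ann, u = u, d = d)
      arms <- extract_arms(locus, arm_len = arm_len, window = window)
      cands <- scan_pams(locus, cfg)
      cands <- score_guides(cands, genome, cfg)
      guide <- select_guide(cands, cfg, deleted_interval = arms$deleted_interval)
      list(locus = locus, guide = guide,
           element = build_element(guide, arms, layout))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- rbind(failed, data.frame(gene_id = ann$gene_id,
                                         reason = conditionMessage(res),
                                         stringsAsFactors = FALSE))
    } else {
      elements[[ann$gene_id]] <- res$element
      loci[[ann$gene_id]] <- res$locus
      guides[[length(guides) + 1L]] <- res$guide
    }
  }
  structure(list(elements = elements,
                 guides = if (length(guides)) do.call(rbind, guides) else NULL,
                 loci = loci, failed = failed),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat("<design_set> ", length(x$elements), " elements designed, ",
      nrow(x$failed), " failed\n", sep = "")
  invisible(x)
}

#' Build basic plasmids and run the single-pot Golden Gate library
#'
#' Clones every designed element into the backbone by Gibson assembly and
#' enumerates the promoter-insertion library.
#'
#' @param design a \code{design_set} from [design_constructs()].
#' @param promoters named character vector of promoter core sequences.
#' @param backbone linear backbone sequence (see [toy_backbone()]).
#' @param o_up upstream fusion site, matching the element layout.
#' @param include_deletion enumerate the promoter-deletion variant.
#' @param exclude optional gene ids to drop (e.g. cloning failures).
#' @return A \code{library_pool}.
#' @export
assemble_library <- function(design, promoters, backbone, o_up = "AAT",
                             include_deletion = TRUE, exclude = character(0)) {
  els <- design$elements[setdiff(names(design$elements), exclude)]
  basic <- lapply(els, assemble_basic_plasmid, backbone = backbone)
  parts <- lapply(names(promoters), function(nm) {
    make_part(nm, promoters[[nm]], o_up = o_up)
  })
  golden_gate(basic, parts, include_deletion = include_deletion)
}
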