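# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the package's scanning code paths.

rc <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Brute-force PAM scan: slide a 23-nt frame over both strands of the locus
# window and keep frames ending in NGG whose cut (between protospacer
# positions 17 and 18) falls inside [ws, we].  Returns a sorted key set
# "spacer|strand|cut" for comparison with scan_pams().
naive_pam_keys <- function(window_seq, u, ws, we) {
  keys <- character(0)
  n <- nchar(window_seq)
  # top strand: window index i is gene-relative i - u - 1
  for (i in seq_len(n - 22L)) {
    frame <- substr(window_seq, i, i + 22L)
    if (substr(frame, 22L, 23L) == "GG") {
      cut <- (i + 17L) - u - 1L          # first base 3' of the cut
      if (cut >= ws && cut <= we) {
        keys <- c(keys, paste(substr(frame, 1L, 20L), "+", cut, sep = "|"))
      }
    }
  }
  # bottom strand: scan the reverse complement explicitly
  rcs <- rc(window_seq)
  for (j in seq_len(n - 22L)) {
    frame <- substr(rcs, j, j + 22L)
    if (substr(frame, 22L, 23L) == "GG") {
      # rc index j corresponds to top index n - j + 1; protospacer occupies
      # rc j..j+19, i.e. top (n-j-18)..(n-j+1); cut between protospacer 17/18
      # maps to top first-base-3'-of-cut at rc position j+17 -> top n-j-16+1
      cut_top_index <- n - (j + 17L) + 1L + 1L
      cut <- cut_top_index - u - 1L
      if (cut >= ws && cut <= we) {
        keys <- c(keys, paste(substr(frame, 1L, 20L), "-", cut, sep = "|"))
      }
    }
  }
  sort(keys)
}

# Naive genome-wide PAM-adjacent Hamming-neighbourhood counter.
naive_offtargets <- function(spacer, contigs, max_mm) {
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  hits <- setNames(integer(max_mm + 1L), as.character(0:max_mm))
  for (contig in contigs) {
    for (s in c(contig, rc(contig))) {
      n <- nchar(s)
      if (n < 23L) next
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (i in seq_len(n - 22L)) {
        if (ch[i + 21L] != "G" || ch[i + 22L] != "G") next
        d <- sum(ch[i:(i + 19L)] != sp)
        if (d <= max_mm) hits[as.character(d)] <- hits[as.character(d)] + 1L
      }
    }
  }
  hits
}

# Directly build an oriented_locus from upstream + CDS-side sequence
# (position 0 = first base of cds_side).
synthetic_locus <- function(upstream, cds_side, gene_id = "gX") {
  structure(list(gene_id = gene_id,
                 window_seq = paste0(upstream, cds_side),
                 u = nchar(upstream), d = nchar(cds_side),
                 start_codon = substr(cds_side, 1L, 3L)),
            class = "oriented_locus")
}

# rotation-invariant equality of circular sequences
rot_eq <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

# deterministic random DNA for fixtures
rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# shared small designed pool, built once per test run
.shared <- new.env(parent = emptyenv())
shared_design <- function() {
  if (is.null(.shared$design)) {
    tg <- make_toy_genome(toy_genome_spec(n_genes = 6L, seed = 42L))
    .shared$toy <- tg
    .shared$design <- design_constructs(tg$genome, tg$annotations,
                                        arm_len = 162L)
  }
  list(toy = .shared$toy, design = .shared$design)
}
shared_pool <- function() {
  if (is.null(.shared$pool)) {
    d <- shared_design()
    .shared$pool <- assemble_library(d$design, toy_promoters(),
                                     toy_backbone())
  }
  .shared$pool
}
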