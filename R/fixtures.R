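# Deterministic toy-data generators: a toy genome with promoter-swappable
# genes, a SapI-free backbone and promoter set, simulated long reads over a
# library pool, and plate-reader tables.  Every generator is a pure
# function of (spec, seed); each uses its own seeded RNG stream and
# restores the caller's RNG state.

#' Specification for a toy genome
#'
#' @param n_genes number of genes; placed on alternating strands.
#' @param contig_length single-contig length (>= 810 * n_genes).
#' @param seed RNG seed.
#' @param guaranteed_pam implant one unique, high-scoring 20-nt protospacer
#'   with a TGG PAM at gene-relative \[-80, -58\] of every gene, so each
#'   promoter window has at least one selectable guide.
#' @param implant_sapi optional data.frame(gene_index, rel_pos): write a
#'   SapI recognition site at the given gene-relative position (for
#'   negative tests).
#' @return A \code{toy_genome_spec}.
#' @export
toy_genome_spec <- function(n_genes = 56L, contig_length = 1000L * n_genes,
                            seed = 1L, guaranteed_pam = TRUE,
                            implant_sapi = NULL) {
  stopifnot(n_genes >= 1L)
  block <- contig_length %/% n_genes
  if (block < 810L) {
    stop("contig too short: need >= 810 bp per gene, got ", block, call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 contig_length = as.integer(contig_length),
                 seed = as.integer(seed),
                 guaranteed_pam = isTRUE(guaranteed_pam),
                 implant_sapi = implant_sapi),
            class = "toy_genome_spec")
}

# write `piece` at gene-relative position `rel` of gene i (oriented);
# returns the modified contig string
write_rel <- function(contig, cds_start, strand, rel, piece) {
  if (strand == "+") {
    at <- cds_start + rel
    substr(contig, at, at + nchar(piece) - 1L) <- piece
  } else {
    rcp <- revcomp(piece)
    hi <- cds_start - rel            # genomic coord of piece's first base
    lo <- hi - nchar(piece) + 1L
    substr(contig, lo, hi) <- rcp
  }
  contig
}

read_rel <- function(contig, cds_start, strand, rel, len) {
  if (strand == "+") {
    substr(contig, cds_start + rel, cds_start + rel + len - 1L)
  } else {
    revcomp(substr(contig, cds_start - rel - len + 1L, cds_start - rel))
  }
}

#' Generate a deterministic toy genome with annotation
#'
#' Genes sit on alternating strands, one per \code{contig_length/n_genes}
#' block, each with >= 540 bp of upstream sequence and a 240-bp CDS
#' beginning ATG.  SapI recognition sites are scrubbed from every gene's
#' design window \[-520, +239\] (unless \code{implant_sapi} plants one), so
#' that clean designs exist by construction.  Files are written when
#' \code{dir} is given.
#'
#' @param spec a [toy_genome_spec()].
#' @param dir optional output directory for \code{genome.fa} and
#'   \code{genes.gff3}.
#' @return list(genome, annotations, fasta, gff) -- paths are NULL when no
#'   dir was given.
#' @export
make_toy_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  n <- spec$n_genes
  block <- spec$contig_length %/% n
  cds_len <- 240L
  with_seed(spec$seed, {
    contig <- random_dna(spec$contig_length)
    anns <- data.frame(gene_id = sprintf("tf%02d", seq_len(n)),
                       contig = "chrT", strand = rep(c("+", "-"), length.out = n),
                       cds_start = NA_integer_, cds_end = NA_integer_,
                       stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      off <- (i - 1L) * block
      if (anns$strand[i] == "+") {
        s <- off + 561L
        anns$cds_start[i] <- s; anns$cds_end[i] <- s + cds_len - 1L
      } else {
        s <- off + block - 560L
        anns$cds_start[i] <- s; anns$cds_end[i] <- s - cds_len + 1L
      }
      contig <- write_rel(contig, s, anns$strand[i], 0L, "ATG")
      # scrub SapI sites from the design window (both strands)
      guard <- 0L
      repeat {
        win <- read_rel(contig, s, anns$strand[i], -520L, 520L + cds_len)
        sites <- sapi_sites(win)
        if (nrow(sites) == 0L || guard > 50L) break
        rel0 <- sites$start[1L] - 521L        # window index -> gene-relative
        old <- read_rel(contig, s, anns$strand[i], rel0 + 3L, 1L)
        contig <- write_rel(contig, s, anns$strand[i], rel0 + 3L,
                            if (old == "A") "G" else "A")
        guard <- guard + 1L
      }
      if (spec$guaranteed_pam) {
        # unique benign spacer (GC ~ 0.5, no TTTT, SapI-free with flanks);
        # a recognition site straddling the fixed implant bases and the
        # genomic context cannot be avoided by redrawing the spacer, so
        # those context bases are scrubbed instead
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 200L) {
            stop("could not implant a clean protospacer for gene ",
                 anns$gene_id[i], call. = FALSE)
          }
          sp <- random_dna(20L)
          gc <- gc_fraction(sp)
          if (gc < 0.45 || gc > 0.70) next
          if (grepl("TTTT", sp, fixed = TRUE)) next
          cand <- paste0(sp, "TGG")
          probe <- write_rel(contig, s, anns$strand[i], -80L, cand)
          win <- read_rel(probe, s, anns$strand[i], -520L, 520L + cds_len)
          sites <- sapi_sites(win)
          if (nrow(sites) == 0L) {
            contig <- probe
            break
          }
          rel0 <- sites$start[1L] - 521L
          outside <- setdiff(rel0:(rel0 + 6L), -80L:-58L)
          if (length(outside) > 0L) {
            old <- read_rel(contig, s, anns$strand[i], outside[1L], 1L)
            contig <- write_rel(contig, s, anns$strand[i], outside[1L],
                                if (old == "A") "G" else "A")
          }
        }
      }
    }
    if (!is.null(spec$implant_sapi)) {
      for (j in seq_len(nrow(spec$implant_sapi))) {
        gi <- spec$implant_sapi$gene_index[j]
        contig <- write_rel(contig, anns$cds_start[gi], anns$strand[gi],
                            spec$implant_sapi$rel_pos[j], SAPI_SITE)
      }
    }
    genome <- genome_ref(list(chrT = contig))
    fasta <- gff <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fasta <- file.path(dir, "genome.fa")
      gff <- file.path(dir, "genes.gff3")
      ss <- Biostrings::DNAStringSet(contig); names(ss) <- "chrT"
      Biostrings::writeXStringSet(ss, fasta, width = 80L)
      lines <- c("##gff-version 3",
                 sprintf("# toy genome, seed=%d", spec$seed))
      for (i in seq_len(nrow(anns))) {
        lo <- min(anns$cds_start[i], anns$cds_end[i])
        hi <- max(anns$cds_start[i], anns$cds_end[i])
        lines <- c(lines,
          sprintf("chrT\tpromotune\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  lo, hi, anns$strand[i], anns$gene_id[i]),
          sprintf("chrT\tpromotune\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                  lo, hi, anns$strand[i], anns$gene_id[i], anns$gene_id[i]))
      }
      writeLines(lines, gff)
    }
    list(genome = genome, annotations = anns, fasta = fasta, gff = gff)
  })
}

#' Deterministic SapI-free toy promoter set
#'
#' @param n number of promoters.
#' @param lengths promoter lengths in bp (recycled).
#' @param seed RNG seed.
#' @return named character vector of promoter core sequences.
#' @export
toy_promoters <- function(n = 6L, lengths = c(120L, 110L, 100L, 130L, 90L, 140L),
                          seed = 2L) {
  lengths <- rep_len(lengths, n)
  with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      repeat {
        s <- random_dna(lengths[i])
        if (!has_sapi(s)) { out[i] <- s; break }
      }
    }
    stats::setNames(out, sprintf("prom%02d", seq_len(n)))
  })
}

#' Deterministic toy plasmid backbone for Gibson cloning
#'
#' A SapI-free linear backbone whose first 20 nt equal the default
#' element's terminal Gibson arm and whose last 20 nt equal the element's
#' leading Gibson arm, so every element produced under the default layout
#' clones into it.
#'
#' @param core_len interior length in bp.
#' @param seed RNG seed.
#' @param layout an [element_layout()] supplying the Gibson arm sequences.
#' @return backbone sequence string.
#' @export
toy_backbone <- function(core_len = 520L, seed = 3L, layout = element_layout()) {
  with_seed(seed, {
    repeat {
      core <- random_dna(core_len)
      bb <- paste0(layout$gibson_right_seq, core, layout$gibson_left_seq)
      if (!has_sapi(bb)) return(bb)
    }
  })
}

#' Read-simulation configuration
#'
#' @param n_reads number of reads.
#' @param abundance named non-negative weights per construct id (default:
#'   uniform over the pool).
#' @param read_model "full" (full-length reads) or "truncated" (length
#'   uniform in \[0.5, 1\] of the construct, uniform start).
#' @param substitution_rate i.i.d. per-base substitution probability.
#' @param seed RNG seed.
#' @return A \code{read_sim_config}.
#' @export
read_sim_config <- function(n_reads, abundance = NULL,
                            read_model = c("full", "truncated"),
                            substitution_rate = 0, seed = 4L) {
  if (n_reads <= 0L) stop("n_reads must be positive", call. = FALSE)
  if (!is.null(abundance)) {
    stopifnot(all(abundance >= 0), any(abundance > 0), !is.null(names(abundance)))
  }
  structure(list(n_reads = as.integer(n_reads), abundance = abundance,
                 read_model = match.arg(read_model),
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate long reads from a library pool
#'
#' Reads are drawn from the (linearized) construct sequences proportionally
#' to the abundance weights, emitted in forward or reverse-complement
#' orientation with probability 1/2, with i.i.d. substitution errors and
#' constant Q20 qualities.  The simulation is substitution-only (no
#' indels).
#'
#' @param pool a \code{library_pool}.
#' @param cfg a [read_sim_config()].
#' @param fastq_path output FASTQ path.
#' @return invisibly, a data.frame of per-read truth (read_id,
#'   construct_id, orientation, length).
#' @export
simulate_reads <- function(pool, cfg, fastq_path) {
  stopifnot(inherits(pool, "library_pool"), inherits(cfg, "read_sim_config"))
  prods <- pool$products
  if (length(prods) == 0L) stop("pool is empty", call. = FALSE)
  ids <- vapply(prods, `[[`, "", "id")
  w <- if (is.null(cfg$abundance)) stats::setNames(rep(1, length(ids)), ids) else
    cfg$abundance
  if (!all(names(w) %in% ids)) {
    stop("abundance names not all present in the pool", call. = FALSE)
  }
  seqs <- stats::setNames(vapply(prods, `[[`, "", "sequence"), ids)
  alphabet <- c("A", "C", "G", "T")
  with_seed(cfg$seed, {
    pick <- sample(names(w), cfg$n_reads, replace = TRUE, prob = w / sum(w))
    out_seq <- character(cfg$n_reads)
    orient <- sample(c("+", "-"), cfg$n_reads, replace = TRUE)
    for (i in seq_len(cfg$n_reads)) {
      s <- seqs[[pick[i]]]
      if (cfg$read_model == "truncated") {
        L <- nchar(s)
        len <- max(31L, as.integer(round(stats::runif(1, 0.5, 1) * L)))
        start <- sample.int(L - len + 1L, 1L)
        s <- substr(s, start, start + len - 1L)
      }
      if (cfg$substitution_rate > 0) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(ch)) < cfg$substitution_rate)
        for (j in hit) ch[j] <- sample(setdiff(alphabet, ch[j]), 1L)
        s <- paste(ch, collapse = "")
      }
      if (orient[i] == "-") s <- revcomp(s)
      out_seq[i] <- s
    }
    rid <- sprintf("sim_%06d", seq_len(cfg$n_reads))
    con <- file(fastq_path, "w")
    writeLines(paste0("@", rid, "\n", out_seq, "\n+\n",
                      vapply(nchar(out_seq),
                             function(k) strrep("5", k), character(1))),
               con)
    close(con)
    invisible(data.frame(read_id = rid, construct_id = pick,
                         orientation = orient, length = nchar(out_seq),
                         stringsAsFactors = FALSE))
  })
}

#' Simulate plate-reader tables from known strain truths
#'
#' Generates (well, strain, od600, a535) measurements and OD growth curves
#' consistent with the supplied per-strain truth plus multiplicative
#' Gaussian noise.  Growth curves are pure exponentials
#' \code{od0 * exp(mu * t)} over \code{times} (no lag or saturation phase).
#'
#' @param truth data.frame with columns strain_id, nab, mu.
#' @param noise multiplicative noise SD (e.g. 0.02 for 2\%).
#' @param seed RNG seed.
#' @param od600 baseline culture density for the endpoint wells.
#' @param times growth-curve sampling times in hours.
#' @param od0 inoculation OD for the curves.
#' @return list(wells, curves): endpoint table and long-format curve table
#'   (strain_id, time_h, od600).
#' @export
simulate_plate <- function(truth, noise = 0.02, seed = 5L, od600 = 2,
                           times = 0:10, od0 = 0.1) {
  stopifnot(all(c("strain_id", "nab", "mu") %in% names(truth)))
  with_seed(seed, {
    n <- nrow(truth)
    odw <- od600 * (1 + noise * stats::rnorm(n))
    wells <- data.frame(
      well_id = sprintf("%s%02d", LETTERS[(seq_len(n) - 1L) %/% 12L + 1L],
                        (seq_len(n) - 1L) %% 12L + 1L),
      strain_id = truth$strain_id,
      od600 = odw,
      a535 = truth$nab * odw * (1 + noise * stats::rnorm(n)),
      blank_corrected = TRUE, stringsAsFactors = FALSE)
    curves <- do.call(rbind, lapply(seq_len(n), function(i) {
      od <- od0 * exp(truth$mu[i] * times) *
        (1 + noise * stats::rnorm(length(times)))
      data.frame(strain_id = truth$strain_id[i], time_h = times, od600 = od,
                 stringsAsFactors = FALSE)
    }))
    list(wells = wells, curves = curves)
  })
}
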