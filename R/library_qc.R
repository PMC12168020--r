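# Long-read library QC: reads are assigned to (target, promoter-state)
# constructs through diagnostic exact-match tags -- the target-specific
# 20-nt spacer, promoter-specific 31-mers, and target-specific junction
# 31-mers spanning the scarless o_up/ATG joint of the promoter-deletion
# variants.  Abundance is defined as the assigned-read fraction (stated in
# report headers).  Tags are indexed in both orientations, so scanning a
# read forward covers reverse-strand reads too.

#' Build the diagnostic tag index for a library pool
#'
#' Spacer 20-mers (and reverse complements) identify the target; promoter
#' k-mers identify the promoter state; junction k-mers crossing the
#' up-arm/o_up/ATG joint of deletion products identify the deletion state.
#' k-mers shared between two promoters (or two targets) are dropped from
#' both sets with a warning; a tag present in a product of another identity
#' is likewise dropped.
#'
#' @param pool a \code{library_pool} from [golden_gate()].
#' @param k promoter/junction tag length (default 31).
#' @return A \code{tag_index}.
#' @export
build_tag_index <- function(pool, k = 31L) {
  stopifnot(inherits(pool, "library_pool"))
  prods <- pool$products
  if (length(prods) == 0L) stop("empty pool", call. = FALSE)
  seqs <- vapply(prods, `[[`, "", "sequence")
  if (anyDuplicated(seqs)) {
    stop("two constructs have identical sequence: ",
         prods[[which(duplicated(seqs))[1L]]]$id, call. = FALSE)
  }
  both <- function(x) unique(c(x, vapply(x, revcomp, character(1),
                                         USE.NAMES = FALSE)))
  drop_shared <- function(sets, what) {
    tally <- table(unlist(sets, use.names = FALSE))
    shared <- names(tally)[tally > 1L]
    if (length(shared)) {
      warning(length(shared), " ", what,
              " tag k-mer(s) shared between identities; dropped", call. = FALSE)
      sets <- lapply(sets, setdiff, y = shared)
    }
    sets
  }
  # spacer tags per target (identical across promoter states of a target)
  spacer_by_target <- list()
  for (p in prods) {
    sp <- p$meta$element$spacer
    if (is.null(sp)) stop("product ", p$id, " carries no spacer metadata",
                          call. = FALSE)
    spacer_by_target[[p$target_id]] <- both(sp)
  }
  spacer_by_target <- drop_shared(spacer_by_target, "spacer")
  # promoter tags per (non-deletion) promoter
  prom_ids <- unique(vapply(prods, `[[`, "", "promoter_id"))
  prom_ids <- setdiff(prom_ids, "DELETION")
  prom_sets <- list()
  for (pid in prom_ids) {
    core <- prods[[which(vapply(prods, `[[`, "", "promoter_id") == pid)[1L]]]$core_seq
    prom_sets[[pid]] <- both(kmers_of(core, k))
  }
  prom_sets <- drop_shared(prom_sets, "promoter")
  # deletion junction tags per target: k-mers crossing the o_up joint
  del_sets <- list()
  nondel_kmers <- unique(unlist(lapply(prods, function(p) {
    if (p$promoter_id == "DELETION") return(character(0))
    both(kmers_of(rotate_seq(p$sequence, 1L), k))   # linear scan is enough
  }), use.names = FALSE))
  for (p in prods) {
    if (p$promoter_id != "DELETION") next
    el <- p$meta$element
    junction <- paste0(substr(el$arms$up_arm,
                              nchar(el$arms$up_arm) - (k - 2L),
                              nchar(el$arms$up_arm)),
                       p$o_up,
                       substr(el$arms$down_arm, 1L, k - 2L))
    tags <- setdiff(both(kmers_of(junction, k)), nondel_kmers)
    del_sets[[p$target_id]] <- tags
  }
  del_sets <- drop_shared(del_sets, "deletion-junction")
  env_from <- function(sets) {
    e <- new.env(hash = TRUE, parent = emptyenv())
    for (idn in names(sets)) for (km in sets[[idn]]) assign(km, idn, envir = e)
    e
  }
  structure(list(spacer_env = env_from(spacer_by_target),
                 prom_env = env_from(prom_sets),
                 del_env = env_from(del_sets),
                 k = as.integer(k),
                 spacer_by_target = spacer_by_target,
                 prom_sets = prom_sets, del_sets = del_sets),
            class = "tag_index")
}

read_fastq_checked <- function(path) {
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      # locate the offending record for a useful message
      n <- length(readLines(path, warn = FALSE))
      stop("malformed FASTQ '", path, "' (around record ",
           ceiling(n / 4), "): ", conditionMessage(e), call. = FALSE)
    })
  res
}

#' Assign long reads to library constructs by tag matching
#'
#' A read is assigned to a target iff exactly one spacer tag matches; its
#' promoter state requires a strict-majority promoter-tag vote, or -- with
#' no promoter tag at all -- a deletion-junction tag of the same target.
#' Otherwise the read is unassigned with a reason code.  Both orientations
#' are covered because the index stores each tag and its reverse
#' complement.
#'
#' @param reads FASTQ path (Phred+33) or a named character vector of read
#'   sequences.
#' @param index a [build_tag_index()].
#' @return data.frame (one row per read): read_id, target_id,
#'   promoter_state, n_spacer_hits, n_promoter_hits, read_length, reason.
#' @export
assign_reads <- function(reads, index) {
  stopifnot(inherits(index, "tag_index"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    ss <- read_fastq_checked(reads)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(reads))) names(reads) else
      paste0("read", seq_along(seqs))
  }
  k <- index$k
  n <- length(seqs)
  target <- character(n); prom <- character(n); reason <- rep(NA_character_, n)
  nsp <- integer(n); npr <- integer(n)
  for (i in seq_len(n)) {
    s <- seqs[i]
    km20 <- unique(kmers_of(s, 20L))
    sp_hits <- unlist(mget(km20, envir = index$spacer_env,
                           ifnotfound = NA_character_), use.names = FALSE)
    sp_targets <- unique(sp_hits[!is.na(sp_hits)])
    nsp[i] <- length(sp_targets)
    if (length(sp_targets) == 0L) {
      target[i] <- NA_character_; prom[i] <- NA_character_
      reason[i] <- "no-target-tag"; next
    }
    if (length(sp_targets) > 1L) {
      target[i] <- NA_character_; prom[i] <- NA_character_
      reason[i] <- "ambiguous-target"; next
    }
    target[i] <- sp_targets
    kmk <- unique(kmers_of(s, k))
    pr_hits <- unlist(mget(kmk, envir = index$prom_env,
                           ifnotfound = NA_character_), use.names = FALSE)
    pr_hits <- pr_hits[!is.na(pr_hits)]
    npr[i] <- length(pr_hits)
    if (length(pr_hits) > 0L) {
      votes <- sort(table(pr_hits), decreasing = TRUE)
      if (length(votes) > 1L && votes[1L] == votes[2L]) {
        target[i] <- NA_character_; prom[i] <- NA_character_
        reason[i] <- "ambiguous-promoter"; next
      }
      prom[i] <- names(votes)[1L]
    } else {
      dl_hits <- unlist(mget(kmk, envir = index$del_env,
                             ifnotfound = NA_character_), use.names = FALSE)
      dl_targets <- unique(dl_hits[!is.na(dl_hits)])
      if (length(dl_targets) == 1L && dl_targets == target[i]) {
        prom[i] <- "DELETION"
      } else {
        target[i] <- NA_character_; prom[i] <- NA_character_
        reason[i] <- if (length(dl_targets) == 0L) "no-promoter-tag" else
          "ambiguous-promoter"
      }
    }
  }
  data.frame(read_id = ids, target_id = target, promoter_state = prom,
             n_spacer_hits = nsp, n_promoter_hits = npr,
             read_length = nchar(seqs), read_seq = seqs,
             reason = reason, stringsAsFactors = FALSE)
}

#' Per-construct coverage, coverage rate and abundance
#'
#' Depth model: each assigned read covers \code{min(read length, construct
#' length)} positions of its construct, placed by anchoring the read's
#' first spacer-tag match to that tag's position in the construct (both
#' orientations), clipped to the construct.  Coverage rate is the percent
#' of positions covered at least once; abundance is the assigned-read
#' fraction.
#'
#' @param assignments from [assign_reads()].
#' @param pool the \code{library_pool} the reads were drawn from.
#' @return A \code{coverage_report}: list(per_construct data.frame,
#'   overall_mean_depth, overall_coverage_rate, abundance_cv,
#'   n_assigned, n_unassigned).
#' @export
coverage_report <- function(assignments, pool) {
  stopifnot(inherits(pool, "library_pool"))
  prods <- pool$products
  keys <- vapply(prods, function(p) paste(p$target_id, p$promoter_id),
                 character(1))
  names(prods) <- keys
  cov <- lapply(prods, function(p) integer(nchar(p$sequence)))
  nreads <- stats::setNames(integer(length(prods)), keys)
  asg <- assignments[!is.na(assignments$target_id), , drop = FALSE]
  for (i in seq_len(nrow(asg))) {
    key <- paste(asg$target_id[i], asg$promoter_state[i])
    p <- prods[[key]]
    if (is.null(p)) next
    cseq <- p$sequence
    L <- nchar(cseq)
    rl <- asg$read_length[i]
    rs <- asg$read_seq[i]
    spacer <- p$meta$element$spacer
    # anchor: first occurrence of the spacer tag in read (either orientation)
    rpos <- regexpr(spacer, rs, fixed = TRUE)
    orient <- 1L
    if (rpos == -1L) {
      rpos <- regexpr(revcomp(spacer), rs, fixed = TRUE)
      orient <- -1L
    }
    cpos <- regexpr(spacer, paste0(cseq, substr(cseq, 1L, 19L)), fixed = TRUE)
    if (rpos == -1L || cpos == -1L) {     # assigned via rc-tag edge case
      span <- c(1L, min(rl, L))
    } else if (orient == 1L) {
      off <- as.integer(cpos) - as.integer(rpos)
      span <- c(1L + off, rl + off)
    } else {
      hi <- as.integer(cpos) + 19L + (as.integer(rpos) - 1L)
      span <- c(hi - rl + 1L, hi)
    }
    lo <- max(1L, span[1]); hi <- min(L, span[2])
    if (hi >= lo) cov[[key]][lo:hi] <- cov[[key]][lo:hi] + 1L
    nreads[key] <- nreads[key] + 1L
  }
  total_assigned <- sum(nreads)
  per <- do.call(rbind, lapply(keys, function(key) {
    p <- prods[[key]]
    v <- cov[[key]]
    data.frame(construct_id = p$id, target_id = p$target_id,
               promoter_state = p$promoter_id,
               length = length(v),
               mean_depth = sum(v) / length(v),
               coverage_rate_pct = 100 * mean(v > 0L),
               read_count = nreads[[key]],
               abundance = if (total_assigned > 0L)
                 nreads[[key]] / total_assigned else 0,
               flagged = nreads[[key]] == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  allv <- unlist(cov, use.names = FALSE)
  ab <- per$abundance
  structure(list(
    per_construct = per,
    overall_mean_depth = sum(allv) / length(allv),
    overall_coverage_rate = 100 * mean(allv > 0L),
    abundance_cv = if (mean(ab) > 0) stats::sd(ab) / mean(ab) else NA_real_,
    n_assigned = total_assigned,
    n_unassigned = nrow(assignments) - nrow(asg),
    abundance_definition = "assigned-read fraction"),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> ", nrow(x$per_construct), " constructs; overall depth ",
      round(x$overall_mean_depth, 2), "x, coverage rate ",
      round(x$overall_coverage_rate, 2), "%, abundance CV ",
      round(x$abundance_cv, 3),
      " (abundance = ", x$abundance_definition, ")\n", sep = "")
  invisible(x)
}

#' Write the per-construct QC report as TSV
#'
#' @param report a [coverage_report()].
#' @param path output TSV.
#' @return invisibly, the per-construct table.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# per-construct library QC",
    "# abundance = assigned-read fraction; depth model: each read covers",
    "# min(read length, construct length) positions anchored at its first spacer-tag match",
    sprintf("# overall_mean_depth=%g overall_coverage_rate=%g abundance_cv=%g",
            report$overall_mean_depth, report$overall_coverage_rate,
            report$abundance_cv)), con)
  utils::write.table(
    report$per_construct[, c("construct_id", "mean_depth",
                             "coverage_rate_pct", "read_count", "abundance")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report$per_construct)
}
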