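# Low-level nucleotide-string helpers shared by all modules. Sequences are
# plain uppercase character scalars throughout the package; Biostrings is
# used at the I/O and pattern-matching boundaries.

SAPI_SITE <- "GCTCTTC"
SAPI_SITE_RC <- "GAAGAGC"

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return The reverse complement, same case.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# all 1-based start positions of `pattern` in `subject` (exact, overlapping)
str_find_all <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (hit == -1L) break
    out <- c(out, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)  # allow overlaps
  }
  out
}

#' Locate SapI recognition sites on both strands
#'
#' Reports the 1-based start (on the given/top strand) of every GCTCTTC
#' (orientation \code{"+"}) and GAAGAGC (orientation \code{"-"}, i.e. the
#' recognition heptamer lies on the bottom strand) occurrence.
#'
#' @param seq nucleotide string.
#' @param circular scan across the origin of a circular sequence.
#' @return data.frame with columns \code{start}, \code{orient}.
#' @export
sapi_sites <- function(seq, circular = FALSE) {
  n <- nchar(seq)
  subject <- if (circular && n >= 7L) paste0(seq, substr(seq, 1L, 6L)) else seq
  fwd <- str_find_all(SAPI_SITE, subject)
  rev <- str_find_all(SAPI_SITE_RC, subject)
  keep <- function(p) p[p <= n]   # de-duplicate wrapped hits
  fwd <- keep(fwd); rev <- keep(rev)
  out <- data.frame(
    start = c(fwd, rev),
    orient = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

has_sapi <- function(seq, circular = FALSE) nrow(sapi_sites(seq, circular)) > 0L

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}

assert_dna <- function(seq, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, seq)) {
    stop(what, " contains characters outside ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}", call. = FALSE)
  }
  invisible(seq)
}

# run code under a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# overlapping k-mers of a string, 1-based starts
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}
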