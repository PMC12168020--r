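test_that("scan_pams finds a single implanted protospacer-PAM", {
  # GG/CC-free background so only the implant can produce candidates
  bg <- function(n) paste(rep_len(c("A", "C", "T", "G"), n), collapse = "")
  spacer <- "ATCGATCGATCGATCGATCG"
  up <- paste0(bg(180), spacer, "TGG", bg(42))   # implant ends 42 bp 5' of ATG
  loc <- synthetic_locus(up, paste0("ATG", bg(37)))
  cands <- scan_pams(loc, guide_config())
  expect_equal(nrow(cands), 1L)
  expect_identical(cands$spacer, spacer)
  expect_match(cands$pam, "GG$")
  expect_equal(nchar(cands$spacer) + nchar(cands$pam), 23L)
  # protospacer starts at -(42 + 23) = -65; cut 3 bp 5' of the PAM
  expect_equal(cands$protospacer_start, -65L)
  expect_equal(cands$cut_pos, -48L)
  expect_equal(cands$distance_to_atg, 48L)

  none <- synthetic_locus(bg(240), paste0("ATG", bg(37)))
  expect_equal(nrow(scan_pams(none, guide_config())), 0L)
})

test_that("scan_pams matches the brute-force 23-mer oracle on random windows", {
  for (seed in c(101, 202, 303)) {
    up <- rand_dna(500, seed)
    loc <- synthetic_locus(up, paste0("ATG", rand_dna(47, seed + 1L)))
    cfg <- guide_config()
    got <- scan_pams(loc, cfg)
    keys <- sort(paste(got$spacer, got$strand_rel_gene, got$cut_pos, sep = "|"))
    expect_identical(keys, naive_pam_keys(loc$window_seq, loc$u,
                                          cfg$window_start, cfg$window_end))
  }
})

test_that("scan_pams is strand-symmetric under coordinate reflection", {
  up <- rand_dna(400, 77)
  cds <- paste0("ATG", rand_dna(47, 78))
  loc <- synthetic_locus(up, cds)
  # the same physical DNA presented from the opposite strand, oriented for
  # a mirror-image gene, yields candidates that reflect onto each other
  mirror <- synthetic_locus(rc(cds), rc(up))
  a <- scan_pams(loc, guide_config(window_start = -200L, window_end = -1L))
  # the cut between gene-relative c-1 and c sits between mirror positions
  # -c-1 and -c, so a cut at c reflects to -c with the strand flipped
  b_keys <- naive_pam_keys(mirror$window_seq, mirror$u, 1L, 200L)
  reflect <- vapply(strsplit(b_keys, "|", fixed = TRUE), function(p) {
    paste(p[1], ifelse(p[2] == "+", "-", "+"), -as.integer(p[3]), sep = "|")
  }, character(1))
  a_keys <- paste(a$spacer, a$strand_rel_gene, a$cut_pos, sep = "|")
  expect_setequal(a_keys, reflect)
})

test_that("rule-based score applies the stated penalties", {
  expect_equal(score_guide("ATCGATCGATCGATCGATCG", 1L), 100)   # GC 0.50
  expect_equal(score_guide("ATTTTCGGCGATCGATCGAT", 1L), 60)    # TTTT
  expect_equal(score_guide(strrep("GC", 10), 2L), 50)          # GC 1.0 + extra hit
  expect_equal(score_guide(strrep("GC", 10), 9L), 0)           # floored
})

test_that("count_offtargets matches the naive Hamming oracle", {
  spacer <- "GATTACAGATTACAGGATCC"
  bg <- rand_dna(10000, 500)
  # scrub chance occurrences of GG-adjacent near-matches is unnecessary:
  # the oracle sees exactly the same genome
  contig <- paste0(substr(bg, 1, 4000), spacer, "TGG",
                   substr(bg, 4001, 7000), spacer, "AGG",
                   substr(bg, 7001, 10000))
  g <- genome_ref(list(c1 = contig))
  h <- count_offtargets(spacer, g, max_mm = 2L)
  expect_equal(h[["0"]], 2L)   # TGG and AGG copies both count
  expect_identical(h, naive_offtargets(spacer, list(contig), 2L))

  one <- genome_ref(list(c1 = paste0(substr(bg, 1, 2000), spacer, "TGG",
                                     substr(bg, 2001, 4000))))
  expect_equal(count_offtargets(spacer, one, 2L)[["0"]], 1L)

  # random spacers drawn from the genome itself
  for (at in c(1500L, 5200L)) {
    sp <- substr(contig, at, at + 19L)
    expect_identical(count_offtargets(sp, g, 2L),
                     naive_offtargets(sp, list(contig), 2L))
  }
  expect_error(count_offtargets(spacer, g, max_mm = 4L), "max_mm")
})

test_that("select_guide filters strictly and breaks ties deterministically", {
  base <- data.frame(
    target_id = "t", spacer = c("AAAACCCCGGGGTTTAGCTA", "CCCCGGGGAAAATTTAGCTA"),
    pam = "TGG", strand_rel_gene = "+", protospacer_start = c(-120L, -80L),
    cut_pos = c(-103L, -63L), distance_to_atg = c(103L, 63L),
    hits0 = 1L, hits1 = 0L, hits2 = 0L, score = c(90, 70),
    stringsAsFactors = FALSE)
  expect_equal(select_guide(base, guide_config())$score, 90)

  tie <- base; tie$score <- 80
  tie$distance_to_atg <- c(150L, 50L); tie$cut_pos <- c(-150L, -50L)
  expect_equal(select_guide(tie, guide_config())$distance_to_atg, 50L)

  # fewest extra perfect hits beats a higher score
  hitty <- base; hitty$hits0 <- c(2L, 1L)
  expect_equal(select_guide(hitty, guide_config())$spacer, base$spacer[2])

  low <- base; low$score <- c(60, 55)     # threshold is strict >
  expect_error(select_guide(low, guide_config()), "no guide")

  # require_cut_in_deletion: protospacer must sit inside the deleted interval
  expect_equal(
    select_guide(base, guide_config(),
                 deleted_interval = c(-90L, -1L))$cut_pos, -63L)
})

test_that("selected guides obey the design-window invariants", {
  d <- shared_design()
  gd <- d$design$guides
  expect_gt(nrow(gd), 0L)
  expect_true(all(nchar(gd$spacer) == 20L))
  expect_true(all(nchar(gd$pam) == 3L))
  expect_true(all(substr(gd$pam, 2L, 3L) == "GG"))
  expect_true(all(gd$cut_pos >= -200L & gd$cut_pos <= -1L))
  expect_true(all(gd$score > 60))
  expect_true(all(gd$hits0 >= 1L))
})
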