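# a hand-built 200-nt circular test plasmid: 50-nt prefix, the 36-nt
# cassette, then "ATG" + filler to 200 nt.  All cut coordinates below are
# computed by hand from the GCTCTTC(1/4) geometry.
toy_cassette_plasmid <- function() {
  cass <- sapi_cassette("AAT")
  pre <- rand_dna(50, 600)
  post <- paste0("ATG", rand_dna(111, 601))
  while (grepl("GCTCTTC|GAAGAGC", paste0(pre, "x", post))) {
    pre <- rand_dna(50, 602); post <- paste0("ATG", rand_dna(111, 603))
  }
  list(p = plasmid("toy", paste0(pre, cass, post)), pre = pre, cass = cass,
       post = post)
}

test_that("SapI digestion implements the (1/4) geometry on both orientations", {
  tp <- toy_cassette_plasmid()
  frags <- sapi_digest(tp$p)
  expect_length(frags, 2L)
  lens <- vapply(frags, function(f) nchar(f$sequence), 0L)
  stuffer <- frags[[which.min(lens)]]
  backbone <- frags[[which.max(lens)]]
  # reverse-orientation site GAAGAGC starts at 55 (1-based): bottom cut 1 nt,
  # top cut 4 nt to its 5' side -> stuffer begins at position 51 and its
  # first three bases are the AAT fusion site
  expect_identical(stuffer$sequence, tp$cass)
  expect_equal(nchar(stuffer$sequence), 36L)
  expect_identical(stuffer$left_ov, "AAT")
  # forward site GCTCTTC at 79..85, 1-nt spacer, cut leaves the ATG of the
  # downstream sequence as the 5' overhang
  expect_identical(stuffer$right_ov, "ATG")
  expect_identical(backbone$left_ov, "ATG")
  expect_identical(backbone$right_ov, "AAT")
  expect_identical(substr(backbone$sequence, 1, 3), "ATG")
  expect_true(all(nchar(c(stuffer$left_ov, stuffer$right_ov)) == 3L))

  # no site: circular plasmid comes back unchanged
  noc <- plasmid("flat", rand_dna(120, 604), circular = TRUE)
  expect_false(grepl("GCTCTTC|GAAGAGC", noc$sequence))
  f0 <- sapi_digest(noc)
  expect_length(f0, 1L)
  expect_true(f0[[1]]$circular)
  expect_identical(f0[[1]]$sequence, noc$sequence)
})

test_that("digest/ligate round trip regenerates the plasmid exactly", {
  tp <- toy_cassette_plasmid()
  frags <- sapi_digest(tp$p)
  lens <- vapply(frags, function(f) nchar(f$sequence), 0L)
  bb <- frags[[which.max(lens)]]; st <- frags[[which.min(lens)]]
  expect_identical(bb$right_ov, st$left_ov)
  expect_identical(st$right_ov, bb$left_ov)
  religated <- paste0(bb$sequence, st$sequence)
  expect_true(rot_eq(religated, tp$p$sequence))
})

test_that("promoter parts digest to a unique (o_up, ATG) insert", {
  core <- rand_dna(120, 610)
  expect_false(grepl("GCTCTTC|GAAGAGC", core))
  part <- make_part("prX", core, o_up = "AAT")
  frags <- sapi_digest(plasmid("prX", part$flanked_seq, circular = FALSE))
  expect_length(frags, 3L)
  mid <- frags[[2]]
  expect_identical(mid$left_ov, "AAT")
  expect_identical(mid$right_ov, "ATG")
  expect_identical(mid$sequence, paste0("AAT", core))

  expect_error(make_part("bad", paste0("ACGT", "GAAGAGC", core), "AAT"),
               "SapI")
  expect_error(make_part("selfy", core, o_up = "ATG"), "ATG")
  del <- make_part("DELETION", "", o_up = "AAT")
  expect_identical(del$insert$sequence, "AAT")
  expect_identical(del$insert$right_ov, "ATG")
})

test_that("golden gate enumerates target x promoter-state diversity", {
  d <- shared_design()
  bb <- toy_backbone()
  proms <- toy_promoters()
  basic <- lapply(d$design$elements, assemble_basic_plasmid, backbone = bb)

  pool1 <- golden_gate(basic[1], lapply("prom01", function(i)
    make_part(i, proms[[i]])), include_deletion = FALSE)
  expect_equal(pool1$diversity, 1L)

  pool <- golden_gate(basic, lapply(names(proms), function(i)
    make_part(i, proms[[i]])), include_deletion = TRUE)
  expect_equal(pool$diversity, length(basic) * (length(proms) + 1L))

  # a part flanked for a different fusion site is excluded with a warning
  odd <- make_part("odd", proms[[1]], o_up = "GGG")
  expect_warning(
    pool_odd <- golden_gate(basic, c(lapply(names(proms), function(i)
      make_part(i, proms[[i]])), list(odd)), include_deletion = TRUE),
    "odd")
  expect_equal(pool_odd$diversity, pool$diversity)
})

test_that("assembly is irreversible: products carry no SapI site", {
  pool <- shared_pool()
  for (p in pool$products[seq(1, length(pool$products), by = 5L)]) {
    expect_equal(nrow(sapi_sites(p$sequence, circular = TRUE)), 0L)
    redig <- sapi_digest(plasmid(p$id, p$sequence, circular = TRUE))
    expect_length(redig, 1L)
    expect_identical(redig[[1]]$sequence, p$sequence)
  }
})

test_that("site counting on circular plasmids is rotation invariant", {
  tp <- toy_cassette_plasmid()
  n <- nchar(tp$p$sequence)
  for (shift in c(1L, 17L, 60L, 151L, n)) {
    rot <- paste0(substr(tp$p$sequence, shift, n),
                  substr(tp$p$sequence, 1, shift - 1L))
    expect_equal(nrow(sapi_sites(rot, circular = TRUE)), 2L)
    expect_length(sapi_digest(plasmid("r", rot)), 2L)
  }
})

test_that("gibson overlap check reports junction overlap lengths", {
  d <- shared_design()
  el <- d$design$elements[[1]]
  bb <- toy_backbone()
  ok <- gibson_check(el, backbone_left = bb, backbone_right = bb)
  expect_true(ok$pass)
  expect_equal(c(ok$left_overlap, ok$right_overlap), c(20L, 20L))

  mut <- el$sequence
  substr(mut, 1, 1) <- if (substr(mut, 1, 1) == "A") "C" else "A"
  bad <- gibson_check(mut, bb, bb)
  expect_false(bad$pass)
  expect_equal(bad$left_overlap, 19L)
  expect_equal(bad$right_overlap, 20L)

  short <- gibson_check("ACGTACGT", bb, bb)
  expect_false(short$pass)
  expect_match(short$reason, "too short")
})

test_that("edited-locus reconstruction keeps the CDS start scarless", {
  d <- shared_design()
  pool <- shared_pool()
  del <- Filter(function(p) p$promoter_id == "DELETION", pool$products)[[1]]
  prom <- Filter(function(p) p$target_id == del$target_id &&
                   p$promoter_id != "DELETION", pool$products)[[1]]
  loc <- d$design$loci[[del$target_id]]
  arms <- del$meta$element$arms

  rec_del <- reconstruct_edited_locus(del, loc)
  expect_identical(substr(rec_del$sequence, rec_del$atg_offset,
                          rec_del$atg_offset + 2L), "ATG")
  # deletion variant: ...up_arm . o_up . ATG...
  junction <- paste0(arms$up_arm, "AAT", "ATG")
  expect_true(grepl(junction, rec_del$sequence, fixed = TRUE))

  rec_prom <- reconstruct_edited_locus(prom, loc)
  expect_identical(substr(rec_prom$sequence, rec_prom$atg_offset,
                          rec_prom$atg_offset + 2L), "ATG")
  # length bookkeeping: swap changes length by promoter length minus the
  # deleted native interval
  native_len <- nchar(loc$window_seq)
  deleted_len <- arms$deleted_interval[2] - arms$deleted_interval[1] + 1L
  expect_equal(nchar(rec_prom$sequence),
               native_len - deleted_len + 3L + nchar(prom$core_seq))
  expect_equal(nchar(rec_del$sequence), native_len - deleted_len + 3L)
})
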