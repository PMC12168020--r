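test_that("tag index has one spacer set per target and one k-mer set per promoter", {
  pool <- shared_pool()
  idx <- build_tag_index(pool, k = 31L)
  n_targets <- length(unique(vapply(pool$products, `[[`, "", "target_id")))
  expect_length(idx$spacer_by_target, n_targets)
  expect_length(idx$prom_sets, 6L)
  expect_length(idx$del_sets, n_targets)
  # no tag maps to two identities (environments are last-write-wins, so
  # verify at the set level)
  all_prom <- unlist(idx$prom_sets, use.names = FALSE)
  expect_false(anyDuplicated(all_prom) > 0L)
  all_spacer <- unlist(idx$spacer_by_target, use.names = FALSE)
  expect_false(anyDuplicated(all_spacer) > 0L)

  expect_error(build_tag_index(structure(list(products = list()),
                                         class = "library_pool")), "empty")
})

test_that("a 31-mer shared between two promoters is dropped from both sets", {
  d <- shared_design()
  shared31 <- rand_dna(31, 700)
  proms <- toy_promoters()
  proms[["prom01"]] <- paste0(substr(proms[["prom01"]], 1, 40), shared31,
                              substr(proms[["prom01"]], 72, 120))
  proms[["prom02"]] <- paste0(substr(proms[["prom02"]], 1, 30), shared31,
                              substr(proms[["prom02"]], 62, 110))
  stopifnot(!grepl("GCTCTTC|GAAGAGC", proms[["prom01"]]),
            !grepl("GCTCTTC|GAAGAGC", proms[["prom02"]]))
  pool <- assemble_library(d$design, proms, toy_backbone())
  expect_warning(idx <- build_tag_index(pool, k = 31L), "promoter")
  expect_false(shared31 %in% idx$prom_sets$prom01)
  expect_false(shared31 %in% idx$prom_sets$prom02)
})

test_that("error-free full-length reads are all assigned to their construct", {
  pool <- shared_pool()
  idx <- build_tag_index(pool)
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- simulate_reads(pool, read_sim_config(n_reads = 200, seed = 21), fq)
  asg <- assign_reads(fq, idx)
  expect_equal(nrow(asg), 200L)
  expect_true(all(is.na(asg$reason)))
  expect_identical(paste0(asg$target_id, ".", asg$promoter_state),
                   truth$construct_id)
})

test_that("a chimeric read carrying two spacer tags is unassigned", {
  pool <- shared_pool()
  idx <- build_tag_index(pool)
  p1 <- pool$products[[1]]; p2 <- pool$products[[10]]
  stopifnot(p1$target_id != p2$target_id)
  chimera <- paste0(substr(p1$sequence, 1, 300), substr(p2$sequence, 1, 300))
  asg <- assign_reads(c(chi = chimera), idx)
  expect_identical(asg$reason, "ambiguous-target")
  expect_true(is.na(asg$target_id))
})

test_that("assignment is orientation invariant and conserves reads", {
  pool <- shared_pool()
  idx <- build_tag_index(pool)
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(pool, read_sim_config(n_reads = 60, seed = 31,
                                       substitution_rate = 0.02), fq)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  a <- assign_reads(stats::setNames(reads, paste0("r", seq_along(reads))), idx)
  b <- assign_reads(stats::setNames(vapply(reads, rc, "", USE.NAMES = FALSE),
                                    paste0("r", seq_along(reads))), idx)
  expect_identical(a$target_id, b$target_id)
  expect_identical(a$promoter_state, b$promoter_state)
  expect_equal(sum(is.na(a$reason)) + sum(!is.na(a$reason)), length(reads))
})

test_that("noisy reads lose assignments but never cross-assign", {
  pool <- shared_pool()
  idx <- build_tag_index(pool)
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- simulate_reads(pool, read_sim_config(n_reads = 300, seed = 41,
                                                substitution_rate = 0.02), fq)
  asg <- assign_reads(fq, idx)
  ok <- is.na(asg$reason)
  expect_lt(mean(ok), 1)                       # 2% errors knock some reads out
  expect_gt(mean(ok), 0.3)
  expect_identical(paste0(asg$target_id[ok], ".", asg$promoter_state[ok]),
                   truth$construct_id[ok])     # zero cross-assignments
})

test_that("uniform error-free coverage: 100% rate and zero abundance CV", {
  pool <- shared_pool()
  idx <- build_tag_index(pool)
  # exactly 10 full-length reads per construct, built deterministically
  reads <- unlist(lapply(pool$products, function(p) rep(p$sequence, 10L)))
  names(reads) <- paste0("r", seq_along(reads))
  asg <- assign_reads(reads, idx)
  expect_true(all(is.na(asg$reason)))
  rep_ <- coverage_report(asg, pool)
  expect_true(all(rep_$per_construct$coverage_rate_pct == 100))
  expect_true(all(rep_$per_construct$read_count == 10L))
  expect_equal(rep_$abundance_cv, 0)
  expect_equal(sum(rep_$per_construct$abundance), 1, tolerance = 1e-9)
  expect_equal(rep_$overall_coverage_rate, 100)
})

test_that("skewed abundances are recovered within binomial sampling error", {
  pool <- shared_pool()
  ids <- vapply(pool$products, `[[`, "", "id")
  two <- structure(list(products = pool$products[1:2], diversity = 2L,
                        failed_targets = character(0)),
                   class = "library_pool")
  idx <- build_tag_index(two)
  w <- stats::setNames(c(9, 1), ids[1:2])
  fq <- withr::local_tempfile(fileext = ".fastq")
  n <- 2000L
  simulate_reads(two, read_sim_config(n_reads = n, abundance = w, seed = 51), fq)
  asg <- assign_reads(fq, idx)
  rep_ <- coverage_report(asg, two)
  p <- 0.9
  sigma <- sqrt(p * (1 - p) / n)
  est <- rep_$per_construct$abundance[rep_$per_construct$construct_id == ids[1]]
  expect_lt(abs(est - p), 3 * sigma)
})

test_that("abundance estimates converge to truth with read depth", {
  pool <- shared_pool()
  keep <- pool$products[1:4]
  sub <- structure(list(products = keep, diversity = 4L,
                        failed_targets = character(0)), class = "library_pool")
  idx <- build_tag_index(sub)
  ids <- vapply(keep, `[[`, "", "id")
  w <- stats::setNames(c(4, 3, 2, 1), ids)
  truth_frac <- w / sum(w)
  l1 <- vapply(c(200L, 2000L), function(n) {
    fq <- withr::local_tempfile(fileext = ".fastq")
    simulate_reads(sub, read_sim_config(n_reads = n, abundance = w, seed = 61), fq)
    rep_ <- coverage_report(assign_reads(fq, idx), sub)
    est <- stats::setNames(rep_$per_construct$abundance,
                           rep_$per_construct$construct_id)
    sum(abs(est[ids] - truth_frac))
  }, numeric(1))
  expect_lt(l1[2], l1[1])
  expect_lt(l1[2], 0.05)
})

test_that("a construct with zero reads is flagged with zero depth", {
  pool <- shared_pool()
  two <- structure(list(products = pool$products[1:2], diversity = 2L,
                        failed_targets = character(0)), class = "library_pool")
  idx <- build_tag_index(two)
  reads <- rep(two$products[[1]]$sequence, 5L)
  names(reads) <- paste0("r", 1:5)
  rep_ <- coverage_report(assign_reads(reads, idx), two)
  starved <- rep_$per_construct[rep_$per_construct$read_count == 0L, ]
  expect_equal(nrow(starved), 1L)
  expect_equal(starved$mean_depth, 0)
  expect_equal(starved$coverage_rate_pct, 0)
  expect_true(starved$flagged)
})
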