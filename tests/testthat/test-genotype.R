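test_that("reference construction enumerates the slot product", {
  refs <- fix_refs()
  expect_equal(nrow(refs$constructs), 20)  # 4 promoters x 5 RBSs x 1 x 1
  single <- build_references(sim_part_library(1, 1, seed = 5))
  expect_equal(nrow(single$constructs), 1)
  lib <- fix_lib()
  dup <- lib
  dup$parts$part_id[dup$parts$slot == "promoter"][2] <- "P01"
  expect_error(build_references(dup), "duplicate")
  empty <- lib
  empty$parts <- empty$parts[empty$parts$slot != "rbs", ]
  expect_error(build_references(empty), "empty")
})

test_that("an exact construct read is called with full query coverage", {
  refs <- fix_refs()
  reads <- tibble::tibble(read_id = c("exact", "exact_rc"),
                          sequence = c(refs$constructs$sequence[7],
                                       revcomp(refs$constructs$sequence[7])))
  calls <- call_reads(reads, refs, top_k = 0)
  expect_equal(calls$construct, rep(refs$constructs$construct[7], 2))
  expect_equal(calls$coverage, c(1, 1))
  expect_true(all(calls$passed))
  expect_equal(calls$strand, c("+", "-"))
})

test_that("query coverage is read-relative: truncated reads still pass", {
  refs <- fix_refs()
  full <- refs$constructs$sequence[3]
  trunc <- substr(full, 1, floor(0.9 * nchar(full)))
  calls <- call_reads(tibble::tibble(read_id = "t", sequence = trunc),
                      refs, top_k = 0)
  expect_equal(calls$construct, refs$constructs$construct[3])
  expect_gt(calls$coverage, 0.99)
  expect_true(calls$passed)
})

test_that("random DNA fails the coverage filter", {
  refs <- fix_refs()
  rnd <- random_dna(5, nchar(refs$constructs$sequence[1]), seed = 9)
  calls <- call_reads(tibble::tibble(read_id = paste0("r", 1:5),
                                     sequence = rnd), refs)
  expect_true(all(calls$coverage < 0.95))
  expect_false(any(calls$passed))
  expect_error(call_reads(tibble::tibble(read_id = "e", sequence = ""), refs),
               "empty")
})

test_that("quality scores implement the purity definitions exactly", {
  qc <- qc_scores(40, 24, 6)
  expect_equal(qc$score1, 0.6)
  expect_equal(qc$score2, 0.75)
  expect_true(qc$qc_pass)
  # low depth fails regardless of purity
  expect_false(qc_scores(10, 10, 0)$qc_pass)
  expect_false(qc_scores(15, 15, 0)$qc_pass)  # threshold is strict (> 15)
  expect_true(qc_scores(16, 16, 0)$qc_pass)
  pure <- qc_scores(30, 30, 0)
  expect_equal(pure$score1, 1)
  expect_equal(pure$score2, 1)
})

test_that("scores stay in [0,1] and score2 decreases with the runner-up", {
  primary <- 20
  seconds <- 0:20
  qc <- qc_scores(rep(50, 21), rep(primary, 21), seconds)
  expect_true(all(qc$score1 >= 0 & qc$score1 <= 1))
  expect_true(all(qc$score2 >= 0 & qc$score2 <= 1))
  expect_true(all(diff(qc$score2) < 0))
})

test_that("bins are genotyped from their passing reads with QC verdicts", {
  lib <- fix_lib()
  tg <- fix_tags()
  cols <- dplyr::bind_cols(tg$pairs[1:6, ],
                           simulate_assembly(lib, 6, seed = 71)[, -1])
  reads <- simulate_tagged_reads(
    cols, lib, read_sim_config(reads_per_colony = 25, seed = 72))
  dm <- demultiplex(reads, tg$pairs, binding_fwd = lib$binding_fwd,
                    binding_rev = lib$binding_rev)
  calls <- call_reads(tibble::tibble(read_id = dm$assigned$read_id,
                                     sequence = dm$assigned$insert),
                      fix_refs())
  gt <- genotype_bins(dm, calls)
  expect_true(all(gt$passed_reads <= gt$total_reads))
  expect_true(all(gt$primary_count >= gt$second_count))
  truth <- setNames(true_construct(cols), cols$colony_index)
  ok <- gt$qc_pass
  expect_gt(sum(ok), 0)
  expect_true(all(gt$genotype[ok] == truth[as.character(gt$colony_index[ok])]))
})

test_that("pure error-free bins give perfect scores and zero wrong calls", {
  lib <- fix_lib()
  tg <- fix_tags()
  cols <- dplyr::bind_cols(tg$pairs[1:5, ],
                           simulate_assembly(lib, 5, seed = 73)[, -1])
  reads <- simulate_tagged_reads(
    cols, lib, read_sim_config(0, 0, 0, reads_per_colony = 20, seed = 74))
  dm <- demultiplex(reads, tg$pairs, binding_fwd = lib$binding_fwd,
                    binding_rev = lib$binding_rev)
  calls <- call_reads(tibble::tibble(read_id = dm$assigned$read_id,
                                     sequence = dm$assigned$insert),
                      fix_refs())
  gt <- genotype_bins(dm, calls)
  expect_true(all(gt$qc_pass))
  expect_true(all(gt$score1 == 1))
  expect_true(all(gt$score2 == 1))
  truth <- setNames(true_construct(cols), cols$colony_index)
  expect_true(all(gt$genotype == truth[as.character(gt$colony_index)]))
})

test_that("library profiles recover combination and marginal ratios", {
  lib <- fix_lib()
  asm <- simulate_assembly(lib, 2000, seed = 75)
  asm$colony_index <- seq_len(nrow(asm))
  reads <- simulate_tagged_reads(asm, lib,
                                 read_sim_config(0, 0, 0,
                                                 reads_per_colony = 1,
                                                 seed = 76),
                                 tagless = TRUE)
  calls <- call_reads(reads, fix_refs())
  prof <- profile_library(calls)
  expect_equal(sum(prof$combinations$ratio), 1)
  marg <- prof$marginals
  expect_equal(sum(marg$ratio[marg$slot == "promoter"]), 1)
  p <- 1 / 20
  se <- sqrt(p * (1 - p) / 2000)
  expect_true(all(abs(prof$combinations$ratio - p) <= 3.5 * se))
  # degenerate: a single-combination library
  one <- calls[calls$construct == calls$construct[1], ]
  p1 <- profile_library(one)
  expect_equal(p1$combinations$ratio, 1)
  expect_error(profile_library(calls[calls$passed == FALSE, ]), "no coverage")
})
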