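test_that("designed tag sets satisfy length, distance and composition rules", {
  tags <- design_tags(20, length = 7, min_dist = 3, seed = 1)
  expect_equal(nrow(tags), 20)
  expect_true(all(nchar(tags$sequence) == 7))
  d <- adist(tags$sequence)
  expect_true(all(d[upper.tri(d)] >= 3))
  expect_false(any(grepl("AAAA|CCCC|GGGG|TTTT", tags$sequence)))
  expect_identical(design_tags(20, seed = 1), design_tags(20, seed = 1))
  single <- design_tags(1, seed = 2)
  expect_equal(nrow(single), 1)
})

test_that("infeasible tag requests fail with the packing bound", {
  expect_error(design_tags(5000, length = 7, min_dist = 3, seed = 1),
               "sphere-packing")
})

test_that("tag pair enumeration is the cartesian product in row-major order", {
  tg <- fix_tags()
  expect_equal(nrow(tg$pairs), 96)  # 8 forward x 12 reverse
  expect_equal(tg$pairs$colony_index, 1:96)
  expect_equal(tg$pairs$fwd_id[1:12], rep("F01", 12))
  expect_equal(tg$pairs$rev_id[1:12], sprintf("R%02d", 1:12))
  one <- enumerate_pairs(tg$fwd[1, ], tg$rev[1, ])
  expect_equal(nrow(one), 1)
  dup <- tg$fwd
  dup$sequence[2] <- dup$sequence[1]
  expect_error(enumerate_pairs(dup, tg$rev), "duplicate")
})

test_that("error-free reads demultiplex perfectly", {
  lib <- fix_lib()
  tg <- fix_tags()
  cols <- dplyr::bind_cols(tg$pairs[seq(1, 96, by = 7), ],
                           simulate_assembly(lib, 14, seed = 51)[, -1])
  reads <- simulate_tagged_reads(
    cols, lib, read_sim_config(0, 0, 0, reads_per_colony = 10, seed = 52))
  dm <- demultiplex(reads, tg$pairs, binding_fwd = lib$binding_fwd,
                    binding_rev = lib$binding_rev)
  expect_equal(nrow(dm$assigned), nrow(reads))
  truth <- parse_read_truth(dm$assigned$read_id)
  expect_true(all(truth$colony_index == dm$assigned$colony_index))
  # trimmed insert = binding + amplicon + binding, exactly
  expect_true(all(nchar(dm$assigned$insert) ==
                    nchar(reads$sequence[match(dm$assigned$read_id,
                                               reads$read_id)]) - 14))
})

test_that("demultiplexing partitions reads and reports unassignment reasons", {
  lib <- fix_lib()
  tg <- fix_tags()
  nr <- fix_noisy_reads()
  dm <- demultiplex(nr$reads, tg$pairs, binding_fwd = lib$binding_fwd,
                    binding_rev = lib$binding_rev)
  expect_equal(nrow(dm$assigned) + nrow(dm$unassigned), nrow(nr$reads))
  expect_equal(anyDuplicated(c(dm$assigned$read_id, dm$unassigned$read_id)), 0)
  expect_true(all(dm$unassigned$reason %in%
                    c("no-fwd", "no-rev", "ambiguous", "unknown-pair")))
})

test_that("bin assignment is invariant to reverse-complementing every read", {
  lib <- fix_lib()
  tg <- fix_tags()
  nr <- fix_noisy_reads()
  dm1 <- demultiplex(nr$reads, tg$pairs, binding_fwd = lib$binding_fwd,
                     binding_rev = lib$binding_rev)
  flipped <- dplyr::mutate(nr$reads, sequence = revcomp(sequence))
  dm2 <- demultiplex(flipped, tg$pairs, binding_fwd = lib$binding_fwd,
                     binding_rev = lib$binding_rev)
  a1 <- dm1$assigned[order(dm1$assigned$read_id),
                     c("read_id", "colony_index")]
  a2 <- dm2$assigned[order(dm2$assigned$read_id),
                     c("read_id", "colony_index")]
  expect_identical(a1, a2)
})

test_that("a tag equidistant to two candidates is ambiguous, not guessed", {
  fwd <- tibble::tibble(tag_id = c("F01", "F02"), orientation = "forward",
                        sequence = c("ACGTACG", "ACGTACC"))
  rev <- tibble::tibble(tag_id = "R01", orientation = "reverse",
                        sequence = "TTGGCCA")
  pairs <- enumerate_pairs(fwd, rev)
  insert <- strrep("AC", 30)
  read <- tibble::tibble(
    read_id = "r1",
    sequence = paste0("ACGTACT", insert, revcomp("TTGGCCA")))
  dm <- demultiplex(read, pairs, max_edit = 1)
  expect_equal(nrow(dm$assigned), 0)
  expect_equal(dm$unassigned$reason, "ambiguous")
})

test_that("one tag error can never cause misassignment at max_edit 1", {
  # exhaustive single-edit mutations of the forward tag
  tags <- design_tags(8, min_dist = 3, seed = 31)
  rev <- design_tags(4, orientation = "reverse", min_dist = 3, seed = 32)
  pairs <- enumerate_pairs(tags, rev)
  tag <- tags$sequence[3]
  insert <- strrep("GATC", 15)
  tail_seq <- paste0(insert, revcomp(rev$sequence[2]))
  truth_index <- pairs$colony_index[pairs$fwd_id == "F03" &
                                      pairs$rev_id == "R02"]
  bases <- c("A", "C", "G", "T")
  mutants <- character(0)
  for (i in 1:7) {
    for (b in bases) {
      sub <- tag
      substr(sub, i, i) <- b
      mutants <- c(mutants, sub,
                   paste0(substr(tag, 1, i - 1), substr(tag, i + 1, 7)),
                   paste0(substr(tag, 1, i), b, substr(tag, i + 1, 7)))
    }
  }
  reads <- tibble::tibble(read_id = paste0("m", seq_along(mutants)),
                          sequence = paste0(mutants, tail_seq))
  dm <- demultiplex(reads, pairs, max_edit = 1)
  expect_true(all(dm$assigned$colony_index == truth_index))
})

test_that("read count report covers every pair and conserves totals", {
  lib <- fix_lib()
  tg <- fix_tags()
  nr <- fix_noisy_reads()
  dm <- demultiplex(nr$reads, tg$pairs, binding_fwd = lib$binding_fwd,
                    binding_rev = lib$binding_rev)
  rc <- read_count_report(dm)
  expect_equal(nrow(rc), 96)
  expect_equal(sum(rc$n_reads), nrow(dm$assigned))
  empty <- demultiplex(nr$reads[0, ], tg$pairs)
  rc0 <- read_count_report(empty)
  expect_true(all(rc0$n_reads == 0))
})
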