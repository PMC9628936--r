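# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_lib <- function() {
  fixture("lib", function() sim_part_library(4, 5, seed = 101))
}

fix_refs <- function() {
  fixture("refs", function() build_references(fix_lib()))
}

fix_tags <- function() {
  fixture("tags", function() {
    fwd <- design_tags(8, min_dist = 4, orientation = "forward", seed = 11)
    rev <- design_tags(12, min_dist = 4, orientation = "reverse", seed = 12)
    list(fwd = fwd, rev = rev, pairs = enumerate_pairs(fwd, rev))
  })
}

# 10 colonies x 20 reads at nanopore-like error rates, with truth
fix_noisy_reads <- function() {
  fixture("noisy_reads", function() {
    lib <- fix_lib()
    tg <- fix_tags()
    cols <- dplyr::bind_cols(tg$pairs[1:10, ],
                             simulate_assembly(lib, 10, seed = 21)[, -1])
    reads <- simulate_tagged_reads(
      cols, lib, read_sim_config(reads_per_colony = 20, seed = 22))
    list(colonies = cols, reads = reads)
  })
}

# greedy 1:1 matching of detections to truth within a pixel tolerance;
# returns counts for recall/precision
match_truth <- function(truth, detected, tol = 3) {
  if (nrow(detected) == 0) {
    return(list(tp = 0, fn = nrow(truth), fp = 0, max_err = Inf))
  }
  d <- sqrt(outer(truth$x, detected$x, "-")^2 +
              outer(truth$y, detected$y, "-")^2)
  cand <- which(d <= tol, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_t <- logical(nrow(truth)); used_d <- logical(nrow(detected))
  err <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- TRUE; used_d[j] <- TRUE
      err <- c(err, d[i, j])
    }
  }
  list(tp = sum(used_t), fn = sum(!used_t), fp = sum(!used_d),
       max_err = if (length(err)) max(err) else Inf)
}

true_construct <- function(truth_tbl) {
  paste(truth_tbl$promoter_id, truth_tbl$rbs_id, sep = "|")
}
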