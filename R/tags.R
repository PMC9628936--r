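#' Design a minimum-distance barcode tag set
#'
#' Greedy distance-filtered sampling over the 4^length candidate space:
#' candidates are shuffled and accepted when their pairwise Levenshtein
#' (default) or Hamming distance to every accepted tag is at least
#' `min_dist`, they contain no homopolymer run longer than 3 and are not
#' self-complementary. Levenshtein is the default metric because nanopore
#' errors are indel-rich.
#'
#' @param n_tags Number of tags requested.
#' @param length Tag length in bp (default 7).
#' @param min_dist Minimum pairwise distance (default 3, tolerating one
#'   edit per tag end without ambiguity).
#' @param orientation "forward" or "reverse"; sets the id prefix.
#' @param metric "levenshtein" or "hamming".
#' @param seed Integer seed; the set is deterministic given the seed.
#' @return Tibble with columns `tag_id`, `orientation`, `sequence`.
#' @examples
#' design_tags(8, seed = 1)
#' @export
design_tags <- function(n_tags, length = 7, min_dist = 3,
                        orientation = c("forward", "reverse"),
                        metric = c("levenshtein", "hamming"), seed = 1) {
  orientation <- match.arg(orientation)
  metric <- match.arg(metric)
  stopifnot(n_tags >= 1, length >= 2, min_dist >= 1)

  # Hamming sphere-packing upper bound; Levenshtein distance between
  # equal-length strings never exceeds Hamming distance, so any set at
  # Levenshtein >= d is also a Hamming-d code and the bound applies.
  e <- floor((min_dist - 1) / 2)
  vol <- sum(choose(length, 0:e) * 3^(0:e))
  bound <- floor(4^length / vol)
  if (n_tags > bound) {
    abort(sprintf(
      "cannot design %d tags of length %d at min_dist %d: sphere-packing bound is %d",
      n_tags, length, min_dist, bound))
  }

  candidates <- if (4^length <= 65536) {
    do.call(paste0, expand.grid(rep(list(DNA_BASES), length),
                                stringsAsFactors = FALSE))
  } else {
    unique(random_dna(200000, length))
  }
  with_seed(seed, {
    candidates <- sample(candidates)
    candidates <- candidates[!grepl("AAAA|CCCC|GGGG|TTTT", candidates)]
    candidates <- candidates[candidates != revcomp(candidates)]
    accepted <- character(0)
    for (cand in candidates) {
      if (length(accepted) == n_tags) break
      d <- if (metric == "levenshtein") {
        adist(cand, accepted)
      } else {
        adist(cand, accepted, costs = list(ins = 99, del = 99, sub = 1))
      }
      if (length(accepted) == 0 || all(d >= min_dist)) {
        accepted <- c(accepted, cand)
      }
    }
    if (length(accepted) < n_tags) {
      abort(sprintf(
        "only %d tags of length %d achievable at min_dist %d (requested %d)",
        length(accepted), length, min_dist, n_tags))
    }
    prefix <- if (orientation == "forward") "F" else "R"
    tibble::tibble(tag_id = sprintf("%s%02d", prefix, seq_len(n_tags)),
                   orientation = orientation, sequence = accepted)
  })
}

#' Enumerate forward x reverse tag combinations
#'
#' The multiplexing arithmetic of dual tagging: every forward tag combined
#' with every reverse tag addresses one colony, so 8 forward and 12
#' reverse primers address up to 96 colonies, and 24 additional device
#' barcodes multiply the capacity to 2304.
#'
#' @param fwd_tags,rev_tags Tibbles from [design_tags()] (columns `tag_id`,
#'   `sequence`).
#' @return Tibble with one row per combination, `colony_index` assigned in
#'   row-major order (forward-major): `colony_index`, `fwd_id`, `fwd_seq`,
#'   `rev_id`, `rev_seq`.
#' @examples
#' nrow(enumerate_pairs(design_tags(8, seed = 1),
#'                      design_tags(12, orientation = "reverse", seed = 2)))
#' @export
enumerate_pairs <- function(fwd_tags, rev_tags) {
  if (nrow(fwd_tags) == 0 || nrow(rev_tags) == 0) abort("empty tag list")
  if (anyDuplicated(fwd_tags$sequence)) abort("duplicate forward tag sequences")
  if (anyDuplicated(rev_tags$sequence)) abort("duplicate reverse tag sequences")
  grid <- tidyr::expand_grid(
    fwd = seq_len(nrow(fwd_tags)),
    rev = seq_len(nrow(rev_tags))
  )
  tibble::tibble(
    colony_index = seq_len(nrow(grid)),
    fwd_id = fwd_tags$tag_id[grid$fwd],
    fwd_seq = fwd_tags$sequence[grid$fwd],
    rev_id = rev_tags$tag_id[grid$rev],
    rev_seq = rev_tags$sequence[grid$rev]
  )
}

# Best tag match per read window: distance and match end, via the
# semi-global scanner; returns list(best, second, which, end).
scan_best <- function(windows, tag_seqs) {
  res <- edit_scan_cpp(windows, tag_seqs)
  d <- res$dist
  which_best <- max.col(-d, ties.method = "first")
  n <- nrow(d)
  best <- d[cbind(seq_len(n), which_best)]
  if (ncol(d) == 1) {
    second <- rep(Inf, n)
  } else {
    d2 <- d
    d2[cbind(seq_len(n), which_best)] <- NA_integer_
    second <- apply(d2, 1, min, na.rm = TRUE)
  }
  list(best = best, second = second, which = which_best,
       end = res$end[cbind(seq_len(n), which_best)])
}

#' Demultiplex tagged reads into per-colony bins
#'
#' Searches the forward tag within the first `search_window` bases and the
#' (reverse-complemented) reverse tag within the last `search_window`
#' bases of each read, in both read orientations, by semi-global edit
#' distance. A read is assigned if and only if exactly one declared tag
#' pair matches within the edit budget on both ends, strictly better than
#' any other tag; any ambiguity (a tie at either end, or two orientations
#' implying different pairs) leaves the read unassigned rather than
#' best-guessed. Assigned reads are trimmed to the insert between the tags
#' (binding sites retained) and re-oriented tag-forward.
#'
#' When the primer binding site sequences are supplied, each tag is
#' matched together with its constant binding-site context (the full tag
#' primer), which separates "tag damaged beyond the budget" from "wrong
#' tag": errors landing in the shared context shift every candidate
#' equally, so the true tag keeps its margin. The edit budget is then
#' `max_edit` (the tag-region budget) plus the 97.5% binomial quantile of
#' context errors at `context_error_rate`.
#'
#' @param reads Tibble with `read_id`, `sequence` (see [read_fastq()]).
#' @param pairs Declared tag combinations from [enumerate_pairs()].
#' @param max_edit Maximum edit distance attributed to the tag region
#'   (default 1). Must satisfy `max_edit <= floor((min_dist - 1) / 2)` of
#'   the tag set for assignment to be provably unambiguous.
#' @param min_margin Required edit-distance margin between the best and
#'   second-best tag at each end (default 1: any strict winner). Raising
#'   it trades assignment rate for lower misassignment; with a
#'   min_dist-4 tag set, margin 2 cuts misassignment by an order of
#'   magnitude at roughly 20 points of assignment.
#' @param search_window Bases searched at each read end; defaults to the
#'   matched pattern length + the edit budget + 3, anchoring the search to
#'   the read terminus where the tag primer was attached.
#' @param binding_fwd,binding_rev Primer binding site sequences flanking
#'   the amplicon ("" = match the bare tags only).
#' @param context_error_rate Assumed worst-case per-base read error rate
#'   used to budget edits in the binding-site context.
#' @return A list of class `partchar_demux`: `assigned` (tibble: `read_id`,
#'   `colony_index`, `fwd_id`, `rev_id`, `orientation`, `fwd_dist`,
#'   `rev_dist`, `insert`), `unassigned` (tibble: `read_id`, `reason` in
#'   no-fwd / no-rev / ambiguous / unknown-pair), and `pairs`.
#' @export
demultiplex <- function(reads, pairs, max_edit = 1, min_margin = 1,
                        search_window = NULL,
                        binding_fwd = "", binding_rev = "",
                        context_error_rate = 0.1) {
  fwd_tags <- unique(pairs[, c("fwd_id", "fwd_seq")])
  rev_tags <- unique(pairs[, c("rev_id", "rev_seq")])
  pat_f <- paste0(fwd_tags$fwd_seq, binding_fwd)
  pat_r <- paste0(binding_rev, revcomp(rev_tags$rev_seq))
  budget <- function(context) {
    max_edit + if (nchar(context) > 0) {
      stats::qbinom(0.975, nchar(context), context_error_rate)
    } else 0
  }
  max_edit_f <- budget(binding_fwd)
  max_edit_r <- budget(binding_rev)
  search_window <- search_window %||%
    (max(nchar(c(pat_f, pat_r))) + max(max_edit_f, max_edit_r) + 3)

  n <- nrow(reads)
  seq_fwd <- reads$sequence
  seq_rev <- revcomp(seq_fwd)
  prefix <- function(s) substr(s, 1, pmin(nchar(s), search_window))
  suffix <- function(s) substr(s, pmax(1, nchar(s) - search_window + 1), nchar(s))

  # one orientation: fwd tag pattern in prefix, rev pattern in suffix
  scan_orient <- function(s) {
    list(f = scan_best(prefix(s), pat_f),
         r = scan_best(suffix(s), pat_r))
  }
  plus <- scan_orient(seq_fwd)
  minus <- scan_orient(seq_rev)

  end_ok <- function(sc, lim) {
    sc$best <= lim & (sc$second - sc$best) >= min_margin
  }
  resolve <- function(o) {
    ok_f <- end_ok(o$f, max_edit_f); ok_r <- end_ok(o$r, max_edit_r)
    list(valid = ok_f & ok_r,
         total = ifelse(ok_f & ok_r, o$f$best + o$r$best, NA_integer_),
         no_f = !ok_f & o$f$best > max_edit_f,
         amb_f = !ok_f & o$f$best <= max_edit_f,
         no_r = !ok_r & o$r$best > max_edit_r,
         amb_r = !ok_r & o$r$best <= max_edit_r)
  }
  rp <- resolve(plus); rm_ <- resolve(minus)

  use_plus <- rp$valid & (!rm_$valid | rp$total <= rm_$total)
  use_minus <- rm_$valid & !use_plus
  both_differ <- rp$valid & rm_$valid & rp$total == rm_$total &
    (fwd_tags$fwd_id[plus$f$which] != fwd_tags$fwd_id[minus$f$which] |
       rev_tags$rev_id[plus$r$which] != rev_tags$rev_id[minus$r$which])
  use_plus[both_differ] <- FALSE
  use_minus[both_differ] <- FALSE

  orientation <- ifelse(use_plus, "+", ifelse(use_minus, "-", NA))
  pick <- function(field_p, field_m) ifelse(use_plus, field_p,
                                            ifelse(use_minus, field_m, NA))
  fwd_id <- pick(fwd_tags$fwd_id[plus$f$which], fwd_tags$fwd_id[minus$f$which])
  rev_id <- pick(rev_tags$rev_id[plus$r$which], rev_tags$rev_id[minus$r$which])
  fwd_dist <- pick(plus$f$best, minus$f$best)
  rev_dist <- pick(plus$r$best, minus$r$best)

  key <- paste(fwd_id, rev_id)
  idx <- match(key, paste(pairs$fwd_id, pairs$rev_id))
  matched <- !is.na(orientation)
  known <- matched & !is.na(idx)

  # reason for the unassigned, in priority order
  reason <- rep(NA_character_, n)
  amb <- both_differ | (rp$amb_f & rm_$amb_f) | (rp$amb_r & rm_$amb_r) |
    (rp$amb_f & rm_$no_f) | (rp$no_f & rm_$amb_f) |
    (rp$amb_r & rm_$no_r) | (rp$no_r & rm_$amb_r)
  no_f <- rp$no_f & rm_$no_f
  no_r <- rp$no_r & rm_$no_r
  reason[!matched] <- "ambiguous"
  reason[!matched & no_r] <- "no-rev"
  reason[!matched & no_f] <- "no-fwd"
  reason[!matched & amb] <- "ambiguous"
  reason[matched & !known] <- "unknown-pair"

  # trim to the insert between the tags (binding sites retained), read
  # re-oriented tag-forward
  oriented <- ifelse(use_plus, seq_fwd, seq_rev)
  f_end <- pick(plus$f$end, minus$f$end)
  r_end <- pick(plus$r$end, minus$r$end)  # end within the suffix window
  len <- nchar(oriented)
  suffix_off <- pmax(0, len - search_window)
  rev_len <- nchar(rev_tags$rev_seq[1])
  f_cut <- f_end - nchar(binding_fwd)  # end of the fwd tag itself
  r_cut <- suffix_off + r_end - rev_len  # base before revcomp(rev tag)
  insert <- ifelse(known, substr(oriented, f_cut + 1, pmax(f_cut, r_cut)),
                   NA_character_)

  assigned <- tibble::tibble(
    read_id = reads$read_id[known],
    colony_index = pairs$colony_index[idx[known]],
    fwd_id = fwd_id[known], rev_id = rev_id[known],
    orientation = orientation[known],
    fwd_dist = as.integer(fwd_dist[known]),
    rev_dist = as.integer(rev_dist[known]),
    insert = insert[known]
  )
  unassigned <- tibble::tibble(read_id = reads$read_id[!known],
                               reason = reason[!known])
  structure(list(assigned = assigned, unassigned = unassigned, pairs = pairs),
            class = "partchar_demux")
}

#' @export
print.partchar_demux <- function(x, ...) {
  n <- nrow(x$assigned) + nrow(x$unassigned)
  cat(sprintf("<partchar_demux> %d reads: %d assigned (%.1f%%), %d unassigned\n",
              n, nrow(x$assigned), 100 * nrow(x$assigned) / max(n, 1),
              nrow(x$unassigned)))
  if (nrow(x$unassigned)) print(dplyr::count(x$unassigned, .data$reason))
  invisible(x)
}

#' @method tidy partchar_demux
#' @export
tidy.partchar_demux <- function(x, ...) x$assigned

#' @method glance partchar_demux
#' @export
glance.partchar_demux <- function(x, ...) {
  n <- nrow(x$assigned) + nrow(x$unassigned)
  tibble::tibble(
    n_reads = n,
    n_assigned = nrow(x$assigned),
    assignment_rate = nrow(x$assigned) / max(n, 1),
    n_bins_used = dplyr::n_distinct(x$assigned$colony_index)
  )
}

#' Per-pair read count report
#'
#' Read counts for every declared forward x reverse tag combination
#' (zeros included), the grid a demultiplexing run is judged by.
#'
#' @param demux A [demultiplex()] result.
#' @return Tibble of class `partchar_readcounts`: `colony_index`, `fwd_id`,
#'   `rev_id`, `n_reads`.
#' @export
read_count_report <- function(demux) {
  counts <- dplyr::count(demux$assigned, .data$colony_index, name = "n_reads")
  out <- dplyr::left_join(
    demux$pairs[, c("colony_index", "fwd_id", "rev_id")],
    counts, by = "colony_index")
  out$n_reads[is.na(out$n_reads)] <- 0L
  class(out) <- c("partchar_readcounts", class(out))
  out
}
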