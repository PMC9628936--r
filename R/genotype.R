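#' Build the multi-reference construct set
#'
#' Enumerates every slot combination in circuit order
#' (promoter - RBS - CDS - terminator), flanked by the tag-primer binding
#' sites, yielding one reference sequence per possible assembled
#' construct. Reads are later aligned against all of them; the best-scoring
#' construct is the read's genotype.
#'
#' @param library A `partchar_parts` object ([sim_part_library()] /
#'   [read_part_fasta()]).
#' @return A list of class `partchar_refs`: `constructs` (tibble:
#'   `construct`, `promoter_id`, `rbs_id`, `cds_id`, `terminator_id`,
#'   `sequence`) and `parts`.
#' @examples
#' refs <- build_references(sim_part_library(4, 5, seed = 1))
#' nrow(refs$constructs)  # 4 x 5 x 1 x 1 = 20
#' @export
build_references <- function(library) {
  parts <- library$parts
  by_slot <- split(parts, parts$slot)
  for (sl in c("promoter", "rbs", "cds", "terminator")) {
    if (is.null(by_slot[[sl]]) || nrow(by_slot[[sl]]) == 0) {
      abort(sprintf("empty part slot '%s'", sl))
    }
    if (anyDuplicated(by_slot[[sl]]$part_id)) {
      abort(sprintf("duplicate part id in slot '%s'", sl))
    }
  }
  grid <- tidyr::expand_grid(
    promoter_id = by_slot$promoter$part_id,
    rbs_id = by_slot$rbs$part_id,
    cds_id = by_slot$cds$part_id,
    terminator_id = by_slot$terminator$part_id
  )
  seq_of <- function(slot, ids) {
    tbl <- by_slot[[slot]]
    tbl$sequence[match(ids, tbl$part_id)]
  }
  constructs <- dplyr::mutate(
    grid,
    construct = paste(.data$promoter_id, .data$rbs_id, sep = "|"),
    sequence = paste0(library$binding_fwd,
                      seq_of("promoter", .data$promoter_id),
                      seq_of("rbs", .data$rbs_id),
                      seq_of("cds", .data$cds_id),
                      seq_of("terminator", .data$terminator_id),
                      library$binding_rev),
    .before = 1
  )
  structure(list(constructs = constructs, parts = parts),
            class = "partchar_refs")
}

#' @export
print.partchar_refs <- function(x, ...) {
  cat(sprintf("<partchar_refs> %d constructs, median length %d bp\n",
              nrow(x$constructs),
              as.integer(stats::median(nchar(x$constructs$sequence)))))
  invisible(x)
}

#' Call the genotype of each read against all constructs
#'
#' Local alignment (affine gaps, both strands) of every read against every
#' construct reference. A shared-k-mer prescreen ranks candidate
#' (strand, construct) pairs and only the most promising are aligned in
#' full; set `top_k = 0` to force exhaustive alignment. A read passes when
#' the query coverage of its best alignment (aligned read bases / read
#' length) reaches `min_query_cov`.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param refs A [build_references()] object.
#' @param min_query_cov Query coverage threshold (default 0.95).
#' @param match,mismatch,gap_open,gap_ext Alignment scores (positive
#'   penalties); defaults +2 / -3 / -5 / -2.
#' @param top_k Candidate constructs aligned per read after the k-mer
#'   prescreen (0 = all constructs on both strands).
#' @param band Alignment band half-width in bp (0 = unbanded); the default
#'   scales with read length and tolerates ~10% indels plus tag overhangs.
#' @param kmer Prescreen k-mer size.
#' @param circular Treat constructs as circular plasmids (references are
#'   doubled so reads spanning the origin still align contiguously).
#' @return Tibble of class `partchar_calls`: `read_id`, `construct`,
#'   `promoter_id`, `rbs_id`, `strand`, `score`, `coverage`, `passed`,
#'   `ambiguous`.
#' @export
call_reads <- function(reads, refs, min_query_cov = 0.95,
                       match = 2, mismatch = 3, gap_open = 5, gap_ext = 2,
                       top_k = 5, band = NULL, kmer = 11, circular = FALSE) {
  if (nrow(reads) == 0) abort("no reads to call")
  if (any(!nzchar(reads$sequence))) abort("empty read sequence")
  ref_seq <- refs$constructs$sequence
  if (circular) ref_seq <- paste0(ref_seq, ref_seq)
  band <- band %||% as.integer(0.2 * max(nchar(reads$sequence)) + 30)
  res <- sw_call_batch_cpp(reads$sequence, ref_seq,
                           as.integer(match), as.integer(mismatch),
                           as.integer(gap_open), as.integer(gap_ext),
                           as.integer(kmer), as.integer(top_k),
                           as.integer(band))
  cons <- refs$constructs[res$ref, ]
  out <- tibble::tibble(
    read_id = reads$read_id,
    construct = cons$construct,
    promoter_id = cons$promoter_id,
    rbs_id = cons$rbs_id,
    strand = ifelse(res$strand > 0, "+", "-"),
    score = res$score,
    coverage = res$coverage,
    passed = res$coverage >= min_query_cov,
    ambiguous = res$tie
  )
  class(out) <- c("partchar_calls", class(out))
  out
}

#' Quality scores and QC verdict for a genotyped sample bin
#'
#' Bin-purity statistics of a demultiplexed, genotyped colony:
#' `score1 = primary / total` (primary mapped reference read count over
#' the total read count of the bin) and
#' `score2 = (primary - second) / primary` (margin of the primary over the
#' second-most-supported reference). A bin passes QC when
#' `total > min_reads`, `score1 > min_score1` and `score2 > min_score2`
#' (defaults 15 / 0.4 / 0.65, the empirical criteria).
#'
#' @param total_reads,primary_count,second_count Integer vectors.
#' @param min_reads,min_score1,min_score2 QC thresholds.
#' @return Tibble with `score1`, `score2`, `qc_pass`.
#' @examples
#' qc_scores(40, 24, 6)  # score1 0.6, score2 0.75, pass
#' @export
qc_scores <- function(total_reads, primary_count, second_count,
                      min_reads = 15, min_score1 = 0.4, min_score2 = 0.65) {
  score1 <- ifelse(total_reads > 0, primary_count / total_reads, 0)
  score2 <- ifelse(primary_count > 0,
                   (primary_count - second_count) / primary_count, 0)
  tibble::tibble(
    score1 = score1, score2 = score2,
    qc_pass = total_reads > min_reads & score1 > min_score1 &
      score2 > min_score2
  )
}

#' Genotype every demultiplexed colony bin
#'
#' Tallies coverage-passing read calls per bin: the construct with the
#' most reads is the primary reference and the colony's genotype call, the
#' runner-up count feeds `score2`, and the QC verdict gates downstream
#' use. The `score1` denominator counts every read assigned to the bin,
#' including coverage-failed ones, so it reflects mapping success as well
#' as purity.
#'
#' @param demux A [demultiplex()] result.
#' @param calls A [call_reads()] result on the demultiplexed inserts.
#' @param min_reads,min_score1,min_score2 QC thresholds (defaults
#'   15 / 0.4 / 0.65).
#' @return Tibble of class `partchar_genotypes`, one row per non-empty
#'   bin: `colony_index`, `genotype`, `promoter_id`, `rbs_id`,
#'   `total_reads`, `passed_reads`, `primary_count`, `second_count`,
#'   `score1`, `score2`, `qc_pass`. Bins with zero passing reads carry an
#'   `NA` genotype and fail QC.
#' @export
genotype_bins <- function(demux, calls, min_reads = 15, min_score1 = 0.4,
                          min_score2 = 0.65) {
  joined <- dplyr::left_join(demux$assigned[, c("read_id", "colony_index")],
                             calls, by = "read_id")
  per_bin <- dplyr::group_by(joined, .data$colony_index)
  tally <- dplyr::summarise(
    per_bin,
    total_reads = dplyr::n(),
    passed_reads = sum(.data$passed, na.rm = TRUE),
    top = list({
      ok <- .data$passed %in% TRUE
      if (any(ok)) sort(table(.data$construct[ok]), decreasing = TRUE)
      else table(character(0))
    }),
    .groups = "drop"
  )
  tally <- dplyr::mutate(
    tally,
    genotype = purrr::map_chr(.data$top, ~ if (length(.x)) names(.x)[1] else NA_character_),
    primary_count = purrr::map_int(.data$top, ~ if (length(.x)) as.integer(.x[1]) else 0L),
    second_count = purrr::map_int(.data$top, ~ if (length(.x) > 1) as.integer(.x[2]) else 0L),
    top = NULL
  )
  qc <- qc_scores(tally$total_reads, tally$primary_count, tally$second_count,
                  min_reads, min_score1, min_score2)
  out <- dplyr::bind_cols(tally, qc)
  out <- tidyr::separate(out, "genotype",
                         into = c("promoter_id", "rbs_id"), sep = "\\|",
                         remove = FALSE, fill = "right")
  out <- out[, c("colony_index", "genotype", "promoter_id", "rbs_id",
                 "total_reads", "passed_reads", "primary_count",
                 "second_count", "score1", "score2", "qc_pass")]
  class(out) <- c("partchar_genotypes", class(out))
  out
}

#' Profile a combinatorial library from pooled read calls
#'
#' Counts coverage-passing reads per part combination and derives
#' combination ratios and per-slot marginal part ratios, optionally
#' compared against the input molar ratios of the assembly reaction with
#' a Spearman rank-correlation statistic.
#'
#' @param calls A [call_reads()] result.
#' @param input_ratios Optional named list of per-slot input molar ratios
#'   (as in [simulate_assembly()]); combination-level expectations are the
#'   products of the normalized slot ratios.
#' @return A list of class `partchar_profile`: `combinations` (tibble:
#'   `construct`, `promoter_id`, `rbs_id`, `n`, `ratio`, and `input_ratio`
#'   when supplied), `marginals` (tibble: `slot`, `part_id`, `ratio`),
#'   `spearman` (NA without input ratios), `n_reads`.
#' @export
profile_library <- function(calls, input_ratios = NULL) {
  ok <- calls[calls$passed, ]
  if (nrow(ok) == 0) abort("no coverage-passing calls to profile")
  comb <- dplyr::count(ok, .data$construct, .data$promoter_id, .data$rbs_id,
                       name = "n")
  comb$ratio <- comb$n / sum(comb$n)
  marg <- dplyr::bind_rows(
    dplyr::summarise(dplyr::group_by(ok, part_id = .data$promoter_id),
                     slot = "promoter", n = dplyr::n(), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(ok, part_id = .data$rbs_id),
                     slot = "rbs", n = dplyr::n(), .groups = "drop")
  )
  marg <- dplyr::mutate(dplyr::group_by(marg, .data$slot),
                        ratio = .data$n / sum(.data$n))
  marg <- dplyr::ungroup(marg)[, c("slot", "part_id", "n", "ratio")]

  spearman <- NA_real_
  if (!is.null(input_ratios)) {
    norm <- function(x) x / sum(x)
    pr <- norm(input_ratios$promoter)
    rr <- norm(input_ratios$rbs)
    comb$input_ratio <- as.numeric(pr[comb$promoter_id] * rr[comb$rbs_id])
    spearman <- stats::cor(comb$input_ratio, comb$ratio, method = "spearman")
  }
  structure(list(combinations = comb, marginals = marg,
                 spearman = spearman, n_reads = nrow(ok)),
            class = "partchar_profile")
}

#' @export
print.partchar_profile <- function(x, ...) {
  cat(sprintf("<partchar_profile> %d passing reads, %d combinations\n",
              x$n_reads, nrow(x$combinations)))
  if (!is.na(x$spearman)) {
    cat(sprintf("  Spearman (input molar ratio vs measured): %.3f\n", x$spearman))
  }
  invisible(x)
}

#' @method tidy partchar_profile
#' @export
tidy.partchar_profile <- function(x, ...) x$combinations

#' @method glance partchar_profile
#' @export
glance.partchar_profile <- function(x, ...) {
  tibble::tibble(n_reads = x$n_reads,
                 n_combinations = nrow(x$combinations),
                 spearman = x$spearman)
}
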