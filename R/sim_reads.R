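#' Error model and depth for simulated tagged long reads
#'
#' Per-base error rates emulating nanopore basecalls. The defaults (5%
#' substitutions plus 3% indels, split evenly) are a realistic setting for
#' an R9-generation flow cell; all rates are exposed here because reported
#' error rates vary between chemistries and basecallers.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-base rates in
#'   `[0, 1)`; their sum must be < 1.
#' @param reads_per_colony Reads emitted per colony.
#' @param seed Integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(substitution_rate = 0.05,
                            insertion_rate = 0.015,
                            deletion_rate = 0.015,
                            reads_per_colony = 30,
                            seed = 1) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1) {
    abort("error rates must lie in [0, 1) and sum to less than 1")
  }
  if (reads_per_colony < 1) abort("reads_per_colony must be a positive integer")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 reads_per_colony = as.integer(reads_per_colony),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

# Corrupt DNA strings with iid per-base substitutions, deletions and
# insertions (random base inserted after the affected position).
mutate_sequences <- function(seqs, sub_rate, ins_rate, del_rate) {
  if (sub_rate + ins_rate + del_rate == 0) return(seqs)
  vapply(strsplit(seqs, ""), function(b) {
    n <- length(b)
    u <- runif(n)
    sub <- u < sub_rate
    del <- u >= sub_rate & u < sub_rate + del_rate
    ins <- u >= sub_rate + del_rate & u < sub_rate + del_rate + ins_rate
    if (any(sub)) {
      # substitute with a uniformly chosen *different* base
      b[sub] <- vapply(b[sub], function(x) sample(setdiff(DNA_BASES, x), 1),
                       character(1))
    }
    if (any(ins)) {
      b[ins] <- paste0(b[ins], sample(DNA_BASES, sum(ins), replace = TRUE))
    }
    if (any(del)) b <- b[!del]
    paste(b, collapse = "")
  }, character(1))
}

#' Simulate barcode-tagged amplicon long reads with known ground truth
#'
#' Emits error-corrupted reads of the structure
#' `fwd_tag + fwd binding site + promoter + RBS + CDS + terminator +
#' rev binding site + revcomp(rev_tag)`, emulating pooled colony-PCR
#' amplicons of the GFP module sequenced on a long-read device. About half
#' the reads are emitted reverse-complemented (library strands are
#' unordered). Each read id encodes its ground truth
#' (`colony`, `fwd`, `rev`, `promoter`, `rbs`, `strand`) and can be parsed
#' back with [parse_read_truth()].
#'
#' @param colonies Tibble with one row per colony: `colony_index`,
#'   `promoter_id`, `rbs_id`, and (unless `tagless`) `fwd_id`, `fwd_seq`,
#'   `rev_id`, `rev_seq` as produced by [enumerate_pairs()]. Optional
#'   `cds_id`, `terminator_id` columns override the library's single
#'   defaults.
#' @param library A [sim_part_library()] object providing part and binding
#'   site sequences.
#' @param config A [read_sim_config()].
#' @param tagless If `TRUE`, reads carry no tags (a pooled plasmid-library
#'   sequencing run profiled before tagging).
#' @return Tibble with columns `read_id`, `sequence`.
#' @export
simulate_tagged_reads <- function(colonies, library,
                                  config = read_sim_config(),
                                  tagless = FALSE) {
  parts <- library$parts
  cds_default <- parts$part_id[parts$slot == "cds"][1]
  term_default <- parts$part_id[parts$slot == "terminator"][1]
  if (!tagless) {
    need <- c("colony_index", "promoter_id", "rbs_id", "fwd_id", "fwd_seq",
              "rev_id", "rev_seq")
  } else {
    need <- c("colony_index", "promoter_id", "rbs_id")
  }
  missing_cols <- setdiff(need, names(colonies))
  if (length(missing_cols)) {
    abort(paste0("colonies is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  seq_of <- function(slot, ids) {
    sub <- parts[parts$slot == slot, ]
    s <- sub$sequence[match(ids, sub$part_id)]
    if (anyNA(s)) {
      abort(sprintf("unknown %s part id '%s'", slot, ids[which(is.na(s))[1]]))
    }
    s
  }
  cds_ids <- colonies[["cds_id"]] %||% cds_default
  term_ids <- colonies[["terminator_id"]] %||% term_default
  templates <- paste0(
    library$binding_fwd,
    seq_of("promoter", colonies$promoter_id),
    seq_of("rbs", colonies$rbs_id),
    seq_of("cds", cds_ids),
    seq_of("terminator", term_ids),
    library$binding_rev
  )
  if (!tagless) {
    templates <- paste0(colonies$fwd_seq, templates, revcomp(colonies$rev_seq))
  }
  assert_dna(templates, "read template")

  with_seed(config$seed, {
    n_per <- config$reads_per_colony
    idx <- rep(seq_len(nrow(colonies)), each = n_per)
    seqs <- mutate_sequences(templates[idx], config$substitution_rate,
                             config$insertion_rate, config$deletion_rate)
    flip <- runif(length(seqs)) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    tibble::tibble(
      read_id = sprintf(
        "r%06d|colony=%s|fwd=%s|rev=%s|promoter=%s|rbs=%s|strand=%s",
        seq_along(seqs), colonies$colony_index[idx],
        if (tagless) "NA" else colonies$fwd_id[idx],
        if (tagless) "NA" else colonies$rev_id[idx],
        colonies$promoter_id[idx], colonies$rbs_id[idx],
        ifelse(flip, "-", "+")),
      sequence = seqs
    )
  })
}

#' Parse ground truth back out of simulated read ids
#'
#' @param read_ids Character vector of ids from [simulate_tagged_reads()].
#' @return Tibble with columns `read_id`, `colony_index`, `fwd_id`,
#'   `rev_id`, `promoter_id`, `rbs_id`, `strand`.
#' @export
parse_read_truth <- function(read_ids) {
  fields <- strsplit(read_ids, "|", fixed = TRUE)
  get <- function(i, prefix) {
    v <- vapply(fields, `[`, character(1), i)
    sub(paste0("^", prefix, "="), "", v)
  }
  tibble::tibble(
    read_id = read_ids,
    colony_index = as.integer(get(2, "colony")),
    fwd_id = get(3, "fwd"),
    rev_id = get(4, "rev"),
    promoter_id = get(5, "promoter"),
    rbs_id = get(6, "rbs"),
    strand = get(7, "strand")
  )
}
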