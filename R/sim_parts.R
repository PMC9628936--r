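#' Generate a synthetic DNA part library with programmed strengths
#'
#' Builds a reference set of synthetic promoter, RBS, terminator and CDS
#' sequences for simulation and testing. Each promoter and RBS carries a
#' programmed relative strength; the first part of each type is the
#' standard (strength exactly 1), playing the role of the J23119 promoter
#' and B0030 RBS of a standard characterization circuit. Colony GFP output
#' is modeled as proportional to promoter strength times RBS strength.
#'
#' Sequence lengths default to small values so that simulated amplicons
#' stay short and alignment-based genotyping of tens of thousands of reads
#' remains fast; the genotyper does not depend on part lengths.
#'
#' @param n_promoters,n_rbs Number of promoters / RBSs (>= 1 each).
#' @param promoter_len,rbs_len,cds_len,terminator_len,binding_len Sequence
#'   lengths in bp. `binding_len` is the tag-primer binding site flanking
#'   the amplicon (17-20 bp in a typical design).
#' @param strength_range Log10 range of programmed strengths relative to
#'   the standard part; strengths are drawn log-uniformly within it.
#' @param seed Integer seed; the library is deterministic given the seed.
#' @return A list of class `partchar_parts`:
#'   \describe{
#'     \item{parts}{tibble: `slot`, `part_id`, `sequence`, `strength`
#'       (NA for CDS/terminator).}
#'     \item{binding_fwd,binding_rev}{tag-primer binding site sequences.}
#'     \item{standard_promoter_id,standard_rbs_id}{ids of the standards.}
#'   }
#' @examples
#' lib <- sim_part_library(n_promoters = 4, n_rbs = 5, seed = 1)
#' dplyr::count(lib$parts, slot)
#' @export
sim_part_library <- function(n_promoters = 4, n_rbs = 5,
                             promoter_len = 40, rbs_len = 15,
                             cds_len = 150, terminator_len = 50,
                             binding_len = 18,
                             strength_range = c(-1, 1),
                             seed = 1) {
  stopifnot(n_promoters >= 1, n_rbs >= 1)
  with_seed(seed, {
    prom_ids <- sprintf("P%02d", seq_len(n_promoters))
    rbs_ids <- sprintf("B%02d", seq_len(n_rbs))
    strengths <- function(n) {
      s <- 10^runif(n, strength_range[1], strength_range[2])
      s[1] <- 1  # the standard part anchors the relative scale
      s
    }
    parts <- dplyr::bind_rows(
      tibble::tibble(slot = "promoter", part_id = prom_ids,
                     sequence = random_dna(n_promoters, promoter_len),
                     strength = strengths(n_promoters)),
      tibble::tibble(slot = "rbs", part_id = rbs_ids,
                     sequence = random_dna(n_rbs, rbs_len),
                     strength = strengths(n_rbs)),
      tibble::tibble(slot = "cds", part_id = "sfGFP",
                     sequence = random_dna(1, cds_len), strength = NA_real_),
      tibble::tibble(slot = "terminator", part_id = "T01",
                     sequence = random_dna(1, terminator_len),
                     strength = NA_real_)
    )
    structure(list(
      parts = parts,
      binding_fwd = random_dna(1, binding_len),
      binding_rev = random_dna(1, binding_len),
      standard_promoter_id = prom_ids[1],
      standard_rbs_id = rbs_ids[1]
    ), class = "partchar_parts")
  })
}

#' @export
print.partchar_parts <- function(x, ...) {
  n <- table(x$parts$slot)
  cat("<partchar_parts> ", paste(sprintf("%s: %d", names(n), n), collapse = ", "),
      "\n  standards: ", x$standard_promoter_id, " / ", x$standard_rbs_id, "\n",
      sep = "")
  invisible(x)
}

part_sequence <- function(parts_tbl, slot, part_id) {
  i <- which(parts_tbl$slot == slot & parts_tbl$part_id == part_id)
  if (length(i) != 1) {
    abort(sprintf("unknown %s part id '%s'", slot, part_id))
  }
  parts_tbl$sequence[i]
}

#' Write a part library as per-slot FASTA files
#'
#' @param library A `partchar_parts` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of written file paths.
#' @export
write_part_fasta <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(library$parts$slot), function(sl) {
    sub <- library$parts[library$parts$slot == sl, ]
    set <- Biostrings::DNAStringSet(sub$sequence)
    names(set) <- sub$part_id
    p <- file.path(dir, paste0(sl, ".fasta"))
    Biostrings::writeXStringSet(set, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a part library from per-slot FASTA files
#'
#' @param paths Named character vector (names = slots: promoter, rbs, cds,
#'   terminator) of FASTA paths.
#' @param binding_fwd,binding_rev Tag-primer binding site sequences.
#' @return A `partchar_parts` object (strengths unknown, set to NA).
#' @export
read_part_fasta <- function(paths, binding_fwd = "", binding_rev = "") {
  parts <- purrr::map2_dfr(paths, names(paths), function(p, sl) {
    set <- Biostrings::readDNAStringSet(p)
    tibble::tibble(slot = sl, part_id = names(set),
                   sequence = as.character(set), strength = NA_real_)
  })
  structure(list(
    parts = parts,
    binding_fwd = binding_fwd, binding_rev = binding_rev,
    standard_promoter_id = parts$part_id[parts$slot == "promoter"][1],
    standard_rbs_id = parts$part_id[parts$slot == "rbs"][1]
  ), class = "partchar_parts")
}
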