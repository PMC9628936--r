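#' Simulate a combinatorial Golden Gate assembly
#'
#' Draws `n_constructs` part combinations with each slot sampled
#' independently in proportion to its input molar ratio, the behaviour a
#' one-pot combinatorial assembly approaches when ligation is unbiased:
#' the frequency of each part combination tracks the molar ratio of the
#' parts supplied to the reaction.
#'
#' @param library A [sim_part_library()] object (or compatible `parts`
#'   tibble wrapper).
#' @param n_constructs Number of assembled constructs to draw.
#' @param ratios Optional named list of per-slot molar ratios, e.g.
#'   `list(promoter = c(P01 = 0.7, P02 = 0.1, ...))`. Ratios must be
#'   positive; they are normalized internally. Slots omitted from the list
#'   use equal ratios. Parts omitted from a supplied slot get ratio 0.
#' @param seed Integer seed.
#' @return A tibble with one row per construct: `construct_id`,
#'   `promoter_id`, `rbs_id`, `cds_id`, `terminator_id`.
#' @examples
#' lib <- sim_part_library(seed = 1)
#' asm <- simulate_assembly(lib, 1000, seed = 2)
#' dplyr::count(asm, promoter_id)
#' @export
simulate_assembly <- function(library, n_constructs, ratios = NULL, seed = 1) {
  parts <- library$parts
  slot_ids <- split(parts$part_id, parts$slot)
  for (sl in c("promoter", "rbs", "cds", "terminator")) {
    if (length(slot_ids[[sl]]) == 0) {
      abort(sprintf("part set for slot '%s' is empty", sl))
    }
  }
  draw <- function(sl) {
    ids <- slot_ids[[sl]]
    p <- rep(1, length(ids))
    names(p) <- ids
    if (!is.null(ratios[[sl]])) {
      r <- ratios[[sl]]
      if (any(r <= 0)) abort("molar ratios must be positive")
      unknown <- setdiff(names(r), ids)
      if (length(unknown)) {
        abort(sprintf("ratio given for unknown %s part '%s'", sl, unknown[1]))
      }
      p[] <- 0
      p[names(r)] <- r
    }
    sample(ids, n_constructs, replace = TRUE, prob = p / sum(p))
  }
  with_seed(seed, tibble::tibble(
    construct_id = seq_len(n_constructs),
    promoter_id = draw("promoter"),
    rbs_id = draw("rbs"),
    cds_id = draw("cds"),
    terminator_id = draw("terminator")
  ))
}
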