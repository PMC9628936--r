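#' Assign picked-colony indices to detected colonies by position
#'
#' Colonies are picked for tagged colony PCR at known plate positions; the
#' pick list (colony_index, x, y) is the key that later joins phenotypes
#' to genotypes. This matches each pick to its nearest detected colony
#' (greedy, closest first, one colony per pick) within a tolerance.
#'
#' @param matched A [match_colonies()] result.
#' @param picks Tibble with `colony_index`, `x`, `y`.
#' @param max_dist_px Maximum pick-to-centroid distance.
#' @return `matched` with its `colony_index` replaced by the pick indices;
#'   detections not picked are dropped, picks without a detection are
#'   reported in the `unpicked` attribute.
#' @export
assign_colony_index <- function(matched, picks, max_dist_px = 10) {
  if (anyDuplicated(picks$colony_index)) abort("duplicate pick colony_index")
  d <- sqrt(outer(picks$x, matched$x, "-")^2 + outer(picks$y, matched$y, "-")^2)
  cand <- which(d <= max_dist_px, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_p <- logical(nrow(picks)); used_m <- logical(nrow(matched))
  map <- rep(NA_integer_, nrow(matched))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_p[i] && !used_m[j]) {
      used_p[i] <- TRUE; used_m[j] <- TRUE
      map[j] <- picks$colony_index[i]
    }
  }
  out <- matched[!is.na(map), ]
  out$colony_index <- map[!is.na(map)]
  attr(out, "unpicked") <- picks[!used_p, ]
  class(out) <- class(matched)
  out
}

#' Join colony phenotypes to genotypes by colony index
#'
#' Inner join of matched-colony intensities and QC-passing genotype calls
#' on the shared colony index. Saturation-flagged phenotypes and QC-failed
#' genotypes are excluded; orphans on both sides are reported as
#' attributes (`orphan_phenotypes`, `orphan_genotypes`).
#'
#' @param phenotypes A [match_colonies()] /[assign_colony_index()] result.
#' @param genotypes A [genotype_bins()] result.
#' @param strain Optional strain label attached to every row.
#' @return Tibble: `colony_index`, `strain`, `colony_intensity`,
#'   `promoter_id`, `rbs_id`, `genotype` plus phenotype detail columns.
#' @export
join_colonies <- function(phenotypes, genotypes, strain = "strain1") {
  if (anyDuplicated(phenotypes$colony_index)) {
    abort("duplicate colony_index among phenotypes")
  }
  if (anyDuplicated(genotypes$colony_index)) {
    abort("duplicate colony_index among genotypes")
  }
  ph <- phenotypes[!phenotypes$flag_saturated, ]
  gt <- genotypes[genotypes$qc_pass, ]
  joined <- dplyr::inner_join(
    ph[, c("colony_index", "colony_intensity", "size_gfp", "size_rfp",
           "total_gfp", "total_rfp")],
    gt[, c("colony_index", "genotype", "promoter_id", "rbs_id", "score1",
           "score2")],
    by = "colony_index")
  joined <- dplyr::mutate(joined, strain = strain, .after = "colony_index")
  attr(joined, "orphan_phenotypes") <-
    phenotypes[!phenotypes$colony_index %in% joined$colony_index, ]
  attr(joined, "orphan_genotypes") <-
    genotypes[!genotypes$colony_index %in% joined$colony_index, ]
  joined
}

#' Standard circuit reference intensity
#'
#' The mean colony intensity of the standard characterization circuit
#' (standard promoter + standard RBS), the denominator of the relative
#' part unit. Requires at least `min_colonies` QC-passing colonies.
#'
#' @param joined A [join_colonies()] result.
#' @param standard_promoter_id,standard_rbs_id Ids of the standard parts.
#' @param min_colonies Minimum colonies of the standard circuit.
#' @return A list of class `partchar_standard`: ids, `standard_intensity`,
#'   `n_colonies`, `strain`.
#' @export
standard_reference <- function(joined, standard_promoter_id,
                               standard_rbs_id, min_colonies = 3) {
  std <- joined[joined$promoter_id == standard_promoter_id &
                  joined$rbs_id == standard_rbs_id, ]
  if (nrow(std) < min_colonies) {
    abort(sprintf(
      "standard circuit %s|%s has %d QC-passing colonies; need >= %d",
      standard_promoter_id, standard_rbs_id, nrow(std), min_colonies))
  }
  structure(list(standard_promoter_id = standard_promoter_id,
                 standard_rbs_id = standard_rbs_id,
                 standard_intensity = mean(std$colony_intensity),
                 n_colonies = nrow(std),
                 strain = unique(joined$strain)),
            class = "partchar_standard")
}

#' @export
print.partchar_standard <- function(x, ...) {
  cat(sprintf("<partchar_standard> %s|%s: intensity %.4f (n = %d)\n",
              x$standard_promoter_id, x$standard_rbs_id,
              x$standard_intensity, x$n_colonies))
  invisible(x)
}

#' Relative promoter / RBS unit
#'
#' Expresses a part's mean colony fluorescence relative to the standard
#' circuit's: `RPU (or RRU) = mean intensity / standard intensity`, so the
#' standard part itself scores exactly 1. The `"typeset"` convention
#' divides by (standard - mean) instead and is provided only for
#' auditability; it is singular at the standard circuit and not used
#' anywhere in the package.
#'
#' @param mean_intensity Numeric vector of part mean colony intensities.
#' @param standard A [standard_reference()] (or a positive number).
#' @param convention "ratio" (default) or "typeset".
#' @return Numeric vector of relative units.
#' @examples
#' relative_unit(c(1, 2, 0), 1)
#' @export
relative_unit <- function(mean_intensity, standard,
                          convention = c("ratio", "typeset")) {
  convention <- match.arg(convention)
  s <- if (inherits(standard, "partchar_standard")) {
    standard$standard_intensity
  } else {
    standard
  }
  if (!is.numeric(s) || s <= 0) abort("standard intensity must be positive")
  switch(convention,
         ratio = mean_intensity / s,
         typeset = mean_intensity / (s - mean_intensity))
}

#' Aggregate per-part strengths from joined colonies
#'
#' Characterization circuits vary one slot at a time: a colony whose RBS
#' is the standard measures its promoter, and vice versa; the standard
#' circuit itself contributes to both standards. Per part (and strain) the
#' mean and SD of the colony intensity give the part strength (RFU), and
#' dividing by the standard circuit's mean intensity gives the relative
#' unit (RPU for promoters, RRU for RBSs). Groups with fewer than
#' `min_colonies` colonies are dropped (reported in the `dropped`
#' attribute); groups larger than `max_colonies` keep the first
#' `max_colonies` colonies by colony index.
#'
#' @param joined A [join_colonies()] result.
#' @param standard A [standard_reference()], or `NULL` to compute it from
#'   `joined` using the id defaults below.
#' @param standard_promoter_id,standard_rbs_id Standard part ids (used
#'   when `standard` is NULL and to classify circuits).
#' @param min_colonies,max_colonies Colony count window per part
#'   (defaults 3 and 20).
#' @return Tibble of class `partchar_strengths`: `part_id`, `part_type`,
#'   `strain`, `n_colonies`, `mean_intensity`, `sd_intensity`,
#'   `relative_unit`.
#' @export
part_strength <- function(joined, standard = NULL,
                          standard_promoter_id = NULL,
                          standard_rbs_id = NULL,
                          min_colonies = 3, max_colonies = 20) {
  if (nrow(joined) == 0) abort("no joined colonies to aggregate")
  if (is.null(standard)) {
    if (is.null(standard_promoter_id) || is.null(standard_rbs_id)) {
      abort("supply a standard_reference() or the standard part ids")
    }
    standard <- standard_reference(joined, standard_promoter_id,
                                   standard_rbs_id, min_colonies)
  } else {
    standard_promoter_id <- standard$standard_promoter_id
    standard_rbs_id <- standard$standard_rbs_id
  }

  # a circuit measures the slot that differs from the standard
  meas_prom <- joined[joined$rbs_id == standard_rbs_id, ]
  meas_rbs <- joined[joined$promoter_id == standard_promoter_id, ]
  long <- dplyr::bind_rows(
    dplyr::mutate(meas_prom, part_id = .data$promoter_id,
                  part_type = "promoter"),
    dplyr::mutate(meas_rbs, part_id = .data$rbs_id, part_type = "RBS")
  )
  long <- dplyr::arrange(long, .data$colony_index)
  grouped <- dplyr::group_by(long, .data$part_id, .data$part_type,
                             .data$strain)
  grouped <- dplyr::slice_head(grouped, n = max_colonies)
  agg <- dplyr::summarise(
    grouped,
    n_colonies = dplyr::n(),
    mean_intensity = mean(.data$colony_intensity),
    sd_intensity = sd(.data$colony_intensity),
    .groups = "drop"
  )
  dropped <- agg[agg$n_colonies < min_colonies, ]
  agg <- agg[agg$n_colonies >= min_colonies, ]
  agg$relative_unit <- relative_unit(agg$mean_intensity, standard)
  attr(agg, "dropped") <- dropped
  attr(agg, "standard") <- standard
  class(agg) <- c("partchar_strengths", class(agg))
  agg
}

#' Compare part strengths across strains
#'
#' Part-by-strain matrix of relative units plus the pairwise Spearman
#' rank correlation between strains over their shared parts.
#'
#' @param strengths A [part_strength()] result covering >= 2 strains (rows
#'   from several strains can be combined with [dplyr::bind_rows()]).
#' @param min_shared Minimum number of parts shared by a strain pair.
#' @return A list of class `partchar_straincmp`: `matrix` (tibble, one row
#'   per part, one column per strain) and `correlations` (tibble:
#'   `strain_a`, `strain_b`, `n_shared`, `spearman`).
#' @export
strain_comparison <- function(strengths, min_shared = 3) {
  strains <- unique(strengths$strain)
  if (length(strains) < 2) abort("need >= 2 strains to compare")
  wide <- tidyr::pivot_wider(
    strengths[, c("part_id", "part_type", "strain", "relative_unit")],
    names_from = "strain", values_from = "relative_unit")
  pairs <- utils::combn(strains, 2, simplify = FALSE)
  cors <- purrr::map_dfr(pairs, function(p) {
    a <- wide[[p[1]]]; b <- wide[[p[2]]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_shared) {
      abort(sprintf("strains %s and %s share only %d parts (need >= %d)",
                    p[1], p[2], sum(ok), min_shared))
    }
    tibble::tibble(strain_a = p[1], strain_b = p[2], n_shared = sum(ok),
                   spearman = cor(a[ok], b[ok], method = "spearman"))
  })
  structure(list(matrix = wide, correlations = cors),
            class = "partchar_straincmp")
}

#' @export
print.partchar_straincmp <- function(x, ...) {
  cat(sprintf("<partchar_straincmp> %d parts x %d strains\n",
              nrow(x$matrix), ncol(x$matrix) - 2))
  print(x$correlations)
  invisible(x)
}

#' @method tidy partchar_straincmp
#' @export
tidy.partchar_straincmp <- function(x, ...) x$correlations

#' @method glance partchar_straincmp
#' @export
glance.partchar_straincmp <- function(x, ...) {
  tibble::tibble(n_parts = nrow(x$matrix),
                 n_strains = ncol(x$matrix) - 2,
                 min_spearman = min(x$correlations$spearman),
                 mean_spearman = mean(x$correlations$spearman))
}
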