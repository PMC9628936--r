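#' Build a pipeline run configuration
#'
#' Collects the file paths and stage parameters of one characterization
#' run. Defaults equal the pipeline's standard operating thresholds: QC at
#' total reads > 15, score1 > 0.4, score2 > 0.65; query coverage >= 0.95;
#' demultiplexing at edit distance <= 1; parts aggregated over 3-20
#' colonies.
#'
#' @param gfp_image,rfp_image Plate photographs (PNG/TIFF).
#' @param picks TSV of picked colonies (`colony_index`, `x`, `y`).
#' @param reads FASTQ of pooled tagged reads.
#' @param parts_dir Directory of per-slot part FASTAs
#'   (promoter/rbs/cds/terminator.fasta) plus `binding_sites.tsv`.
#' @param fwd_tags,rev_tags Tag TSVs (`tag_id`, `orientation`, `sequence`).
#' @param out_dir Output directory for stage TSVs and the run log.
#' @param strain Strain label.
#' @param standard_promoter_id,standard_rbs_id Standard part ids; default
#'   to the first part of each FASTA.
#' @param max_edit Demultiplexing tag-region edit budget.
#' @param min_query_cov,min_reads,min_score1,min_score2 Genotyping /
#'   QC parameters.
#' @param min_colonies Minimum colonies per part.
#' @param max_dist_px Colony matching / pick assignment tolerance.
#' @param detect A [detect_params()] list.
#' @param seed Integer seed (stages are deterministic; kept for the log).
#' @return A list of class `partchar_config`.
#' @export
run_config <- function(gfp_image, rfp_image, picks, reads, parts_dir,
                       fwd_tags, rev_tags, out_dir,
                       strain = "strain1",
                       standard_promoter_id = NULL, standard_rbs_id = NULL,
                       max_edit = 1,
                       min_query_cov = 0.95, min_reads = 15,
                       min_score1 = 0.4, min_score2 = 0.65,
                       min_colonies = 3, max_dist_px = 10,
                       detect = detect_params(), seed = 1) {
  structure(list(
    paths = list(gfp_image = gfp_image, rfp_image = rfp_image, picks = picks,
                 reads = reads, parts_dir = parts_dir, fwd_tags = fwd_tags,
                 rev_tags = rev_tags, out_dir = out_dir),
    strain = strain,
    standard_promoter_id = standard_promoter_id,
    standard_rbs_id = standard_rbs_id,
    max_edit = max_edit,
    min_query_cov = min_query_cov, min_reads = min_reads,
    min_score1 = min_score1, min_score2 = min_score2,
    min_colonies = min_colonies, max_dist_px = max_dist_px,
    detect = detect, seed = as.integer(seed)
  ), class = "partchar_config")
}

#' Write / read a run configuration as YAML
#' @param config A `partchar_config`.
#' @param path YAML file path.
#' @return `read_run_config()` returns a `partchar_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "partchar_config")
}

validate_config <- function(config) {
  inputs <- config$paths[setdiff(names(config$paths), "out_dir")]
  missing <- inputs[!vapply(unlist(inputs), file.exists, logical(1))]
  if (length(missing)) {
    abort(sprintf("missing input path(s): %s",
                  paste(unlist(missing), collapse = ", ")),
          class = "partchar_validation_error")
  }
  thr <- c(config$min_query_cov, config$min_score1, config$min_score2)
  if (any(thr < 0 | thr > 1)) {
    abort("score/coverage thresholds must lie in [0, 1]",
          class = "partchar_validation_error")
  }
  invisible(config)
}

read_tag_tsv <- function(path) {
  tags <- read_tsv_file(path)
  assert_dna(tags$sequence, "tag")
  tags
}

#' Run the full characterization pipeline
#'
#' Executes phenotype (detect + match + pick assignment), demultiplex,
#' genotype (multi-reference calling + QC) and quantify (join + part
#' strengths) in order. Every stage writes a TSV under the configured
#' output directory and the run closes with a machine-readable YAML log of
#' parameters and per-stage counts.
#'
#' @param config A [run_config()] (or path to its YAML).
#' @param quiet Suppress per-stage messages.
#' @return A list of class `partchar_run`: `phenotypes`, `demux`,
#'   `genotypes`, `joined`, `strengths`, `standard`, `log`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- phenotype ------------------------------------------------------
  matched <- phenotype_plate(config$paths$gfp_image, config$paths$rfp_image,
                             params = config$detect,
                             max_dist_px = config$max_dist_px)
  picks <- read_tsv_file(config$paths$picks)
  pheno <- assign_colony_index(matched, picks, config$max_dist_px)
  write_tsv_file(pheno, file.path(out_dir, "phenotypes.tsv"))
  say("phenotype: %d detected pairs, %d assigned to picks",
      nrow(matched), nrow(pheno))

  # -- demultiplex ----------------------------------------------------
  slots <- c("promoter", "rbs", "cds", "terminator")
  fasta <- stats::setNames(
    file.path(config$paths$parts_dir, paste0(slots, ".fasta")), slots)
  binding <- read_tsv_file(file.path(config$paths$parts_dir,
                                     "binding_sites.tsv"))
  library <- read_part_fasta(fasta,
                             binding_fwd = binding$sequence[binding$side == "fwd"],
                             binding_rev = binding$sequence[binding$side == "rev"])
  reads <- read_fastq(config$paths$reads)
  pairs <- enumerate_pairs(read_tag_tsv(config$paths$fwd_tags),
                           read_tag_tsv(config$paths$rev_tags))
  demux <- demultiplex(reads, pairs, max_edit = config$max_edit,
                       binding_fwd = library$binding_fwd,
                       binding_rev = library$binding_rev)
  write_tsv_file(demux$assigned[, setdiff(names(demux$assigned), "insert")],
                 file.path(out_dir, "demux_assignments.tsv"))
  say("demux: %d/%d reads assigned across %d bins", nrow(demux$assigned),
      nrow(reads), dplyr::n_distinct(demux$assigned$colony_index))

  # -- genotype -------------------------------------------------------
  refs <- build_references(library)
  inserts <- tibble::tibble(read_id = demux$assigned$read_id,
                            sequence = demux$assigned$insert)
  calls <- call_reads(inserts, refs, min_query_cov = config$min_query_cov)
  genotypes <- genotype_bins(demux, calls, min_reads = config$min_reads,
                             min_score1 = config$min_score1,
                             min_score2 = config$min_score2)
  write_tsv_file(genotypes, file.path(out_dir, "genotypes.tsv"))
  say("genotype: %d bins, %d passing QC", nrow(genotypes),
      sum(genotypes$qc_pass))

  # -- quantify -------------------------------------------------------
  std_prom <- config$standard_promoter_id %||% library$standard_promoter_id
  std_rbs <- config$standard_rbs_id %||% library$standard_rbs_id
  joined <- join_colonies(pheno, genotypes, strain = config$strain)
  standard <- standard_reference(joined, std_prom, std_rbs,
                                 config$min_colonies)
  strengths <- part_strength(joined, standard,
                             min_colonies = config$min_colonies)
  write_tsv_file(strengths, file.path(out_dir, "part_strengths.tsv"))
  say("quantify: %d parts (standard intensity %.4f from %d colonies)",
      nrow(strengths), standard$standard_intensity, standard$n_colonies)

  log <- list(
    package_version = as.character(utils::packageVersion("partchar")),
    config = unclass(config),
    counts = list(
      colonies_matched = nrow(matched),
      colonies_assigned = nrow(pheno),
      reads_total = nrow(reads),
      reads_assigned = nrow(demux$assigned),
      reads_coverage_passed = sum(calls$passed),
      bins_genotyped = nrow(genotypes),
      bins_qc_passed = sum(genotypes$qc_pass),
      colonies_joined = nrow(joined),
      parts_quantified = nrow(strengths)
    )
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  structure(list(phenotypes = pheno, demux = demux, genotypes = genotypes,
                 joined = joined, strengths = strengths, standard = standard,
                 log = log),
            class = "partchar_run")
}

#' @export
print.partchar_run <- function(x, ...) {
  cat("<partchar_run>\n")
  utils::str(x$log$counts, give.head = FALSE)
  invisible(x)
}

#' Generate a coherent synthetic demo dataset on disk
#'
#' Writes everything [run_pipeline()] needs: a dual-channel plate image
#' pair with truth table, a pick list, per-slot part FASTAs with binding
#' sites, tag TSVs, a tagged-read FASTQ and a ready-to-run YAML config.
#' Colonies carry one-slot-varied characterization circuits (each
#' non-standard part measured against the standard background), so
#' programmed part strengths are recoverable end to end.
#'
#' @param outdir Output directory.
#' @param seed Integer seed controlling every random choice.
#' @param n_colonies Colonies on the plate (one tag pair each).
#' @param n_promoters,n_rbs Parts per slot (first of each is the standard).
#' @param reads_per_colony Simulated sequencing depth per colony.
#' @param image_size Plate image size `c(height, width)` px.
#' @param base_gfp Mean GFP level of the standard circuit (8-bit units).
#' @param colony_cv Log-normal colony-to-colony expression CV.
#' @param read_config A [read_sim_config()]; its seed is overridden.
#' @return Invisibly, a list with the config path, the config, and the
#'   ground truth (`colonies`, `library`).
#' @export
make_demo <- function(outdir, seed = 1, n_colonies = 24, n_promoters = 4,
                      n_rbs = 3, reads_per_colony = 30,
                      image_size = c(640, 640), base_gfp = 50,
                      colony_cv = 0.06,
                      read_config = read_sim_config()) {
  if (!dir.create(outdir, showWarnings = FALSE, recursive = TRUE) &&
      !dir.exists(outdir)) {
    abort(sprintf("cannot create demo directory '%s'", outdir))
  }
  library <- sim_part_library(n_promoters, n_rbs,
                              strength_range = c(-0.5, 0.5), seed = seed)
  fwd <- design_tags(8, min_dist = 4, orientation = "forward", seed = seed + 1)
  rev <- design_tags(12, min_dist = 4, orientation = "reverse", seed = seed + 2)
  pairs <- enumerate_pairs(fwd, rev)
  if (n_colonies > nrow(pairs)) {
    abort(sprintf("at most %d colonies addressable with this tag set",
                  nrow(pairs)))
  }

  # one-slot-varied circuits, cycled so every part gets colonies
  parts <- library$parts
  circuits <- dplyr::bind_rows(
    tibble::tibble(promoter_id = parts$part_id[parts$slot == "promoter"],
                   rbs_id = library$standard_rbs_id),
    tibble::tibble(promoter_id = library$standard_promoter_id,
                   rbs_id = parts$part_id[parts$slot == "rbs"])
  )
  circuits <- dplyr::distinct(circuits)
  idx <- rep(seq_len(nrow(circuits)), length.out = n_colonies)
  colonies <- with_seed(seed + 3, {
    colonies <- dplyr::bind_cols(
      tibble::tibble(colony_index = pairs$colony_index[seq_len(n_colonies)]),
      circuits[sample(idx), ]
    )
    strength <- function(slot, ids) {
      parts$strength[match(ids, parts$part_id)]
    }
    colonies$true_gfp <- base_gfp *
      strength("promoter", colonies$promoter_id) *
      strength("rbs", colonies$rbs_id) *
      rlnorm(n_colonies, 0, colony_cv)
    colonies$true_rfp <- 100 * rlnorm(n_colonies, 0, colony_cv)
    colonies
  })

  plate <- simulate_plate(n_colonies, image_size = image_size,
                          gfp_levels = colonies$true_gfp,
                          rfp_levels = colonies$true_rfp,
                          seed = seed + 4)
  paths <- write_plate(plate, outdir, "plate")
  picks <- dplyr::bind_cols(colonies[, "colony_index"],
                            plate$truth[, c("x", "y")])
  write_tsv_file(picks, file.path(outdir, "picks.tsv"))
  write_tsv_file(colonies, file.path(outdir, "colony_truth.tsv"))

  write_part_fasta(library, outdir)
  write_tsv_file(tibble::tibble(side = c("fwd", "rev"),
                                sequence = c(library$binding_fwd,
                                             library$binding_rev)),
                 file.path(outdir, "binding_sites.tsv"))
  write_tsv_file(fwd, file.path(outdir, "fwd_tags.tsv"))
  write_tsv_file(rev, file.path(outdir, "rev_tags.tsv"))

  read_config$reads_per_colony <- as.integer(reads_per_colony)
  read_config$seed <- as.integer(seed + 5)
  sim_cols <- dplyr::inner_join(colonies, pairs, by = "colony_index")
  reads <- simulate_tagged_reads(sim_cols, library, read_config)
  write_fastq(reads, file.path(outdir, "reads.fastq"))

  config <- run_config(
    gfp_image = paths[["gfp"]], rfp_image = paths[["rfp"]],
    picks = file.path(outdir, "picks.tsv"),
    reads = file.path(outdir, "reads.fastq"),
    parts_dir = outdir,
    fwd_tags = file.path(outdir, "fwd_tags.tsv"),
    rev_tags = file.path(outdir, "rev_tags.tsv"),
    out_dir = file.path(outdir, "results"),
    standard_promoter_id = library$standard_promoter_id,
    standard_rbs_id = library$standard_rbs_id,
    seed = seed
  )
  config_path <- file.path(outdir, "config.yaml")
  write_run_config(config, config_path)
  invisible(list(config_path = config_path, config = config,
                 colonies = colonies, library = library))
}
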