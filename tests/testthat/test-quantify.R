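make_pheno <- function(idx, intensity, saturated = FALSE) {
  tibble::tibble(colony_index = idx, x = 0, y = 0, dist_px = 0,
                 size_gfp = 100L, size_rfp = 100L, mean_g = 50, mean_r = 50,
                 total_gfp = intensity * 5000, total_rfp = 5000,
                 flag_saturated = saturated, colony_intensity = intensity)
}

make_geno <- function(idx, promoter, rbs, qc = TRUE) {
  tibble::tibble(colony_index = idx, genotype = paste(promoter, rbs, sep = "|"),
                 promoter_id = promoter, rbs_id = rbs,
                 total_reads = 30L, passed_reads = 30L, primary_count = 30L,
                 second_count = 0L, score1 = 1, score2 = 1, qc_pass = qc)
}

test_that("phenotype-genotype joins keep QC-passing colonies and report orphans", {
  ph <- make_pheno(1:5, c(1, 2, 3, 4, 5))
  gt <- make_geno(1:5, "P01", "B01", qc = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  j <- join_colonies(ph, gt)
  expect_equal(j$colony_index, c(1, 2, 4, 5))
  expect_equal(attr(j, "orphan_genotypes")$colony_index, 3)
  # disjoint index sets: empty join, everything orphaned
  j2 <- join_colonies(make_pheno(1:3, 1), make_geno(4:6, "P01", "B01"))
  expect_equal(nrow(j2), 0)
  expect_equal(nrow(attr(j2, "orphan_phenotypes")), 3)
  expect_error(join_colonies(make_pheno(c(1, 1), 1),
                             make_geno(1, "P01", "B01")),
               "duplicate")
})

test_that("saturation-flagged phenotypes are excluded from the join", {
  ph <- make_pheno(1:4, 1, saturated = c(FALSE, TRUE, FALSE, FALSE))
  gt <- make_geno(1:4, "P01", "B01")
  j <- join_colonies(ph, gt)
  expect_equal(j$colony_index, c(1, 3, 4))
})

test_that("part strengths aggregate per part with colony-count limits", {
  # standard circuit (P01|B01) x5 at intensity 1; P02 promoter circuit x5
  # at intensity 2; one under-replicated part with 2 colonies
  ph <- make_pheno(1:12, c(rep(1, 5), rep(2, 5), 7, 7))
  gt <- dplyr::bind_rows(
    make_geno(1:5, "P01", "B01"),
    make_geno(6:10, "P02", "B01"),
    make_geno(11:12, "P01", "B04")
  )
  j <- join_colonies(ph, gt)
  st <- part_strength(j, standard_promoter_id = "P01",
                      standard_rbs_id = "B01")
  expect_setequal(st$part_id, c("P01", "P02", "B01"))
  expect_equal(attr(st, "dropped")$part_id, "B04")
  p02 <- st[st$part_id == "P02", ]
  expect_equal(p02$n_colonies, 5L)
  expect_equal(p02$mean_intensity, 2)
  expect_equal(p02$sd_intensity, 0)
  expect_equal(p02$relative_unit, 2)
  # the standard part itself anchors at exactly 1
  expect_equal(st$relative_unit[st$part_id == "P01"], 1)
})

test_that("relative units follow the ratio convention", {
  expect_equal(relative_unit(2, 1), 2)
  expect_equal(relative_unit(1, 1), 1)
  expect_equal(relative_unit(0, 1), 0)
  expect_equal(relative_unit(1, 2, convention = "typeset"), 1)
  expect_error(relative_unit(1, -1), "positive")
})

test_that("relative units are invariant to a common fluorescence scale", {
  ph <- make_pheno(1:10, rep(c(1, 3), each = 5))
  gt <- dplyr::bind_rows(make_geno(1:5, "P01", "B01"),
                         make_geno(6:10, "P03", "B01"))
  j1 <- join_colonies(ph, gt)
  ph2 <- dplyr::mutate(ph, colony_intensity = colony_intensity * 7,
                       total_gfp = total_gfp * 7)
  j2 <- join_colonies(ph2, gt)
  s1 <- part_strength(j1, standard_promoter_id = "P01", standard_rbs_id = "B01")
  s2 <- part_strength(j2, standard_promoter_id = "P01", standard_rbs_id = "B01")
  expect_equal(s1$relative_unit, s2$relative_unit)
})

test_that("strain comparison is rank-based and scale-free", {
  st <- function(strain, units) {
    tibble::tibble(part_id = sprintf("P%02d", seq_along(units)),
                   part_type = "promoter", strain = strain,
                   n_colonies = 5L, mean_intensity = units,
                   sd_intensity = 0.1, relative_unit = units)
  }
  u <- c(0.2, 0.5, 1, 2, 5)
  cmp <- strain_comparison(dplyr::bind_rows(st("A", u), st("B", u * 3.7)))
  expect_equal(cmp$correlations$spearman, 1)
  expect_equal(nrow(cmp$matrix), 5)
  # independently shuffled strengths decorrelate
  set.seed(202)
  u20 <- exp(rnorm(20))
  cmp2 <- strain_comparison(dplyr::bind_rows(st("A", u20),
                                             st("B", sample(u20))))
  expect_lt(abs(cmp2$correlations$spearman), 0.5)
  expect_error(strain_comparison(st("A", u)), "2 strains")
  expect_error(
    strain_comparison(dplyr::bind_rows(st("A", u[1:2]), st("B", u[1:2]))),
    "share")
})

test_that("the standard reference requires enough QC-passing colonies", {
  ph <- make_pheno(1:2, 1)
  gt <- make_geno(1:2, "P01", "B01")
  j <- join_colonies(ph, gt)
  expect_error(standard_reference(j, "P01", "B01"), "need >= 3")
})
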