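test_that("library-size normalization centers samples and is scale-invariant", {
  dm <- tibble::tibble(
    sample_id = rep(c("R1", "R2"), each = 4),
    gene = "G", exon_index = rep(1:4, 2),
    depth = c(rep(100, 4), rep(200, 4)),
    role = "reference_normal"
  )
  nm <- normalize_depth_matrix(dm)
  expect_equal(nm$norm, rep(1, 8)) # uniform depth -> all 1.0

  set.seed(9)
  dm2 <- make_depth_matrix(n_ref = 5, seed = 9)
  n1 <- normalize_depth_matrix(dm2)
  dm3 <- dm2 |> dplyr::mutate(depth = ifelse(sample_id == "N01", depth * 7, depth))
  n2 <- normalize_depth_matrix(dm3)
  expect_equal(n1$norm, n2$norm, tolerance = 1e-12)

  # hand-rolled per-sample mean division
  manual <- dm2 |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(expected = depth / mean(depth)) |>
    dplyr::ungroup()
  expect_equal(n1$norm, manual$expected)

  dm_zero <- dm |> dplyr::mutate(depth = ifelse(sample_id == "R1", 0, depth))
  expect_error(normalize_depth_matrix(dm_zero), "zero total depth")
})

test_that("exon ratios are null at the reference mean and ~ -2 for het loss", {
  # a large unspiked background keeps library-size normalization unbiased,
  # as on a real multi-gene panel
  dm <- make_depth_matrix(n_ref = 20, cv = 0.02, seed = 101,
                          n_exons_per_gene = c(A = 8, B = 120),
                          test_spikes = data.frame(gene = "A", first_exon = 1,
                                                   last_exon = 8, copy_ratio = 0.5))
  r <- exon_ratios(dm, "TEST")
  lossy <- r |> dplyr::filter(gene == "A")
  clean <- r |> dplyr::filter(gene == "B")
  expect_true(all(abs(lossy$fold_change + 2) < 0.25))
  expect_true(all(lossy$p_value < 0.05))
  expect_true(all(abs(clean$ratio - 1) < 0.15))
  # exact-null construction: test equals the reference mean
  dm_null <- tibble::tibble(
    sample_id = rep(c("R1", "R2", "R3", "T"), each = 2),
    gene = "G", exon_index = rep(1:2, 4),
    depth = c(90, 110, 100, 100, 110, 90, 100, 100),
    role = rep(c("reference_normal", "reference_normal", "reference_normal",
                 "test"), each = 2)
  )
  rn <- suppressWarnings(exon_ratios(dm_null, "T"))
  expect_equal(rn$ratio, c(1, 1), tolerance = 1e-12)
  expect_equal(rn$fold_change, c(1, 1), tolerance = 1e-12)
  expect_true(all(rn$p_value > 0.5))
})

test_that("z-based p-values agree with a Monte-Carlo location-test oracle", {
  set.seed(202)
  dm <- make_depth_matrix(n_ref = 20, cv = 0.10, seed = 202,
                          n_exons_per_gene = c(A = 15, B = 15),
                          test_spikes = data.frame(gene = "A", first_exon = 3,
                                                   last_exon = 6, copy_ratio = 1.5))
  nm <- normalize_depth_matrix(dm)
  r <- exon_ratios(nm, "TEST")
  refs <- nm |> dplyr::filter(role == "reference_normal")
  n_mc <- 10000
  idx <- sample(nrow(r), 12)
  for (i in idx) {
    rv <- refs$norm[refs$gene == r$gene[i] & refs$exon_index == r$exon_index[i]]
    tv <- nm$norm[nm$sample_id == "TEST" & nm$gene == r$gene[i] &
                    nm$exon_index == r$exon_index[i]]
    mu <- mean(log2(rv)); s <- max(sd(log2(rv)), 0.05)
    draws <- rnorm(n_mc, mu, s)
    p_mc <- mean(abs(draws - mu) >= abs(log2(tv) - mu))
    se <- sqrt(max(p_mc * (1 - p_mc), 1e-6) / n_mc)
    expect_lt(abs(r$p_value[i] - p_mc), max(4 * se, 0.02))
  }
})

test_that("segments reproduce whole-gene loss and intragenic gain patterns", {
  # MSH2-like whole-gene deletion at ratio ~0.5
  dm <- make_depth_matrix(n_ref = 20, cv = 0.03, seed = 303,
                          n_exons_per_gene = c(MSH2 = 16, CTRL = 150),
                          test_spikes = data.frame(gene = "MSH2", first_exon = 1,
                                                   last_exon = 16, copy_ratio = 0.5))
  seg <- call_segments(exon_ratios(dm, "TEST"))
  msh2 <- seg |> dplyr::filter(gene == "MSH2")
  expect_equal(nrow(msh2), 1L)
  expect_equal(msh2$direction, "loss")
  expect_equal(msh2$scope, "whole_gene")
  expect_equal(c(msh2$first_exon, msh2$last_exon), c(1L, 16L))
  expect_equal(nrow(seg |> dplyr::filter(gene == "CTRL")), 0L)

  # BRCA2-like intragenic duplication of exons 5-11 at ratio ~1.5
  dm2 <- make_depth_matrix(n_ref = 20, cv = 0.03, seed = 304,
                           n_exons_per_gene = c(BRCA2 = 20, CTRL = 150),
                           test_spikes = data.frame(gene = "BRCA2", first_exon = 5,
                                                    last_exon = 11, copy_ratio = 1.5))
  seg2 <- call_segments(exon_ratios(dm2, "TEST"))
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$direction, "gain")
  expect_equal(seg2$scope, "intragenic")
  expect_equal(c(seg2$first_exon, seg2$last_exon), c(5L, 11L))
})

test_that("sub-threshold fold changes are never called however significant", {
  r <- tibble::tibble(gene = "G", exon_index = 1L, ratio = 1 / 1.6,
                      log2_ratio = log2(1 / 1.6), fold_change = -1.6,
                      p_value = 0.001)
  expect_equal(nrow(call_segments(r)), 0L)
  r2 <- r |> dplyr::mutate(fold_change = -1.8, p_value = 0.2)
  expect_equal(nrow(call_segments(r2)), 0L)
  r3 <- r |> dplyr::mutate(fold_change = -1.8, p_value = 0.01)
  expect_equal(call_segments(r3)$direction, "loss")
})

test_that("a non-significant exon splits runs into separate segments", {
  r <- tibble::tibble(
    gene = "G", exon_index = 1:5,
    ratio = c(0.5, 0.5, 1.0, 0.5, 0.5),
    log2_ratio = log2(ratio),
    fold_change = ifelse(ratio >= 1, ratio, -1 / ratio),
    p_value = c(0.001, 0.001, 0.9, 0.001, 0.001)
  )
  seg <- call_segments(r)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$first_exon, c(1L, 4L))
  expect_equal(seg$last_exon, c(2L, 5L))
  expect_true(all(seg$scope == "intragenic"))
})

test_that("signed fold change is antisymmetric under ratio inversion", {
  fc <- function(r) ifelse(r >= 1, r, -1 / r)
  grid <- c(seq(0.1, 0.99, by = 0.01), seq(1.01, 10, by = 0.01))
  expect_equal(fc(grid), -fc(1 / grid), tolerance = 1e-9)
  # computed through exon_ratios: a ratio r and its reciprocal mirror signs
  expect_equal(fc(1), 1)
})

test_that("null cohorts produce per-exon false calls at most at alpha", {
  set.seed(404)
  n_draws <- 0
  n_false <- 0
  for (rep in 1:5) {
    dm <- make_depth_matrix(n_ref = 20, cv = 0.10, seed = 404 + rep,
                            n_exons_per_gene = c(A = 100, B = 100, C = 100, D = 100))
    r <- exon_ratios(dm, "TEST")
    sig <- (r$fold_change > 1.3 | r$fold_change < -1.7) & r$p_value < 0.05
    n_draws <- n_draws + nrow(r)
    n_false <- n_false + sum(sig)
  }
  expect_gte(n_draws, 2000)
  expect_lte(n_false / n_draws, 0.05)
})

test_that("CNV calls are invariant to scaling one sample's raw depths", {
  dm <- make_depth_matrix(n_ref = 12, cv = 0.08, seed = 505,
                          test_spikes = data.frame(gene = "B", first_exon = 2,
                                                   last_exon = 4, copy_ratio = 1.5))
  cnv1 <- call_cnv(dm, "TEST")
  dm_scaled <- dm |> dplyr::mutate(depth = ifelse(sample_id == "TEST",
                                                  depth * 13, depth))
  cnv2 <- call_cnv(dm_scaled, "TEST")
  expect_equal(cnv1$segments, cnv2$segments, tolerance = 1e-12)
})

test_that("depth matrix TSV round-trips and tidy/glance methods work", {
  dm <- make_depth_matrix(n_ref = 3, seed = 606)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_matrix(dm, path)
  back <- read_depth_matrix(path)
  expect_equal(
    back |> dplyr::arrange(sample_id, gene, exon_index) |> as.data.frame(),
    dm |> dplyr::mutate(depth = as.numeric(depth)) |>
      dplyr::arrange(sample_id, gene, exon_index) |> as.data.frame()
  )
  cnv <- suppressWarnings(call_cnv(dm, "TEST"))
  td <- tidy(cnv)
  expect_true(all(c("sample_id", "gene", "direction") %in% names(td)))
  gl <- glance(cnv)
  expect_equal(gl$n_segments, nrow(cnv$segments))
  expect_s3_class(autoplot(cnv), "ggplot")
})
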