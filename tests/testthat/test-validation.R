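test_that("binomial power matches exhaustive enumeration at 17X heterozygous", {
  # exhaustive enumeration of the binomial tail at depth 17, threshold 20%:
  # detection needs >= ceil(0.2*17) = 4 alt reads
  exact <- 1 - sum(choose(17, 0:3)) / 2^17
  expect_equal(detection_power(17, 0.5, 0.20), exact, tolerance = 1e-12)
  expect_gte(detection_power(17, 0.5, 0.20), 0.99)
  expect_equal(detection_power(10, 1.0, 0.5), 1.0)
  expect_equal(detection_power(5, 0.5, 0), 1.0)
  expect_warning(p0 <- detection_power(10, 0.5, 1.5), "sensitivity is 0")
  expect_equal(p0, 0)
})

test_that("power agrees with a seeded Monte-Carlo oracle over a threshold grid", {
  set.seed(123)
  n_mc <- 1e6
  x <- rbinom(n_mc, 10, 0.5)
  for (t in c(0.1, 0.2, 0.35, 0.5, 0.8)) {
    p_hat <- mean(x >= ceiling(t * 10))
    p <- detection_power(10, 0.5, t)
    se <- sqrt(p * (1 - p) / n_mc)
    expect_lt(abs(p - p_hat), 3 * se + 1e-9)
  }
})

test_that("power is monotone in the true allele fraction", {
  vfs <- seq(0.05, 1, by = 0.05)
  p <- detection_power(30, vfs, 0.20)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("17X is the smallest depth with stable 99% heterozygous sensitivity", {
  expect_equal(min_depth_for_power(0.5, 0.20, 0.99), 17L)
  # the guard the stability reading rests on: no dips from 17 up
  expect_true(all(detection_power(17:500, 0.5, 0.20) >= 0.99))
  expect_lt(detection_power(16, 0.5, 0.20), 0.99)
  expect_equal(min_depth_for_power(1.0, 0.5, 0.99), 1L)
  # brute-force scan oracle for another parameter set
  d <- min_depth_for_power(0.5, 0.25, 0.99)
  pows <- detection_power(1:5000, 0.5, 0.25)
  expect_true(all(pows[d:5000] >= 0.99))
  expect_lt(pows[d - 1], 0.99)
  expect_error(min_depth_for_power(0.2, 0.25), "must exceed")
})

test_that("power_table reproduces a sensitivity grid", {
  tab <- power_table(c(10, 17, 50), c(0.25, 0.5), 0.20)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$sensitivity[tab$depth == 17 & tab$true_vf == 0.5],
               detection_power(17, 0.5, 0.2))
})

noise_calls <- function(df) {
  tibble::tibble(control_id = df$control, replicate_id = df$rep, key = df$key,
                 DP = df$DP, VF = df$VF, region_class = df$class)
}

test_that("noise planted below thresholds is fully filtered; above survives", {
  # reproducible true call in all replicates + sub-threshold noise in some
  below <- noise_calls(data.frame(
    control = "C1", rep = c(1, 2, 3, 1, 2),
    key = c("t", "t", "t", "n1", "n2"),
    DP = c(200, 210, 190, 40, 80),
    VF = c(0.5, 0.49, 0.51, 0.30, 0.15),
    class = "exonic"
  ))
  np <- characterize_noise(below)
  expect_true(np$thresholds_ok)
  expect_equal(np$surviving$n_surviving[1], 0L)
  expect_equal(sum(!np$calls$reproducible), 2L)

  above <- dplyr::bind_rows(below, noise_calls(data.frame(
    control = "C1", rep = 1, key = "loud", DP = 60, VF = 0.30, class = "exonic"
  )))
  np2 <- characterize_noise(above)
  expect_false(np2$thresholds_ok)
  expect_equal(np2$surviving$n_surviving[1], 1L)
})

test_that("surviving noise counts match a brute-force filter-and-count", {
  set.seed(88)
  tab <- noise_calls(data.frame(
    control = sample(paste0("C", 1:4), 200, replace = TRUE),
    rep = sample(1:3, 200, replace = TRUE),
    key = sample(paste0("v", 1:60), 200, replace = TRUE),
    DP = sample(10:200, 200, replace = TRUE),
    VF = runif(200),
    class = sample(c("exonic", "noncoding_flank"), 200, replace = TRUE)
  )) |> dplyr::distinct(control_id, replicate_id, key, .keep_all = TRUE)
  grid <- tibble::tibble(dp_min = c(50, 80), vf_exonic = c(0.2, 0.3),
                         vf_noncoding = c(0.25, 0.35))
  np <- characterize_noise(tab, threshold_grid = grid)
  # brute force
  nreps <- tapply(tab$replicate_id, tab$control_id,
                  function(r) length(unique(r)))
  seen <- aggregate(replicate_id ~ control_id + key, tab,
                    function(r) length(unique(r)))
  seen$repro <- seen$replicate_id == nreps[seen$control_id]
  for (i in seq_len(nrow(np$surviving))) {
    g <- np$surviving[i, ]
    surv <- 0
    for (j in seq_len(nrow(seen))) {
      if (seen$repro[j]) next
      occ <- tab[tab$control_id == seen$control_id[j] & tab$key == seen$key[j], ]
      thr <- ifelse(occ$region_class == "exonic", g$vf_exonic, g$vf_noncoding)
      if (any(occ$DP >= g$dp_min & occ$VF >= thr)) surv <- surv + 1
    }
    expect_equal(np$surviving$n_surviving[i], surv)
  }
  # tightening either threshold never increases survivors
  np_rows <- characterize_noise(tab, threshold_grid = tibble::tibble(
    dp_min = c(50, 60, 70), vf_exonic = 0.2, vf_noncoding = 0.25
  ))
  surv_by_dp <- np_rows$surviving$n_surviving[order(np_rows$surviving$dp_min)]
  expect_true(all(diff(surv_by_dp) <= 0))
})

test_that("single-replicate controls are excluded with a warning", {
  tab <- noise_calls(data.frame(
    control = c("C1", "C1", "C2"), rep = c(1, 2, 1),
    key = c("a", "a", "b"), DP = 100, VF = 0.5, class = "exonic"
  ))
  expect_warning(np <- characterize_noise(tab), "single replicate")
  expect_false("C2" %in% np$calls$control_id)
})

conc_calls <- function(df) {
  tibble::tibble(replicate_id = df$rep, key = df$key, region_class = df$class,
                 borderline = df$borderline)
}

test_that("identical replicate call sets give Jaccard 1 everywhere", {
  one <- data.frame(key = c("a", "b", "c"),
                    class = c("exonic", "exonic", "noncoding_flank"),
                    borderline = FALSE)
  tab <- conc_calls(dplyr::bind_rows(
    dplyr::mutate(one, rep = 1), dplyr::mutate(one, rep = 2),
    dplyr::mutate(one, rep = 3)
  ))
  cc <- replicate_concordance(tab)
  expect_true(all(cc$jaccard$jaccard == 1))
  expect_true(cc$all_identical_exonic)
  expect_true(is.na(cc$borderline_explained))
})

test_that("a single borderline noncoding discordance is fully explained", {
  base <- data.frame(key = c("a", "b"), class = c("exonic", "noncoding_flank"),
                     borderline = FALSE)
  extra <- data.frame(key = "c", class = "noncoding_flank", borderline = TRUE)
  tab <- conc_calls(dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(base, extra), rep = 1),
    dplyr::mutate(base, rep = 2),
    dplyr::mutate(base, rep = 3)
  ))
  cc <- replicate_concordance(tab)
  jc <- cc$jaccard
  expect_true(all(jc$jaccard[jc$region_class == "exonic"] == 1))
  expect_true(any(jc$jaccard[jc$region_class == "noncoding_flank"] < 1))
  expect_true(cc$all_identical_exonic)
  expect_equal(cc$borderline_explained, 1.0)
  gl <- glance(cc)
  expect_equal(gl$mean_jaccard_exonic, 1)
})

test_that("pairwise Jaccard equals brute-force set arithmetic", {
  set.seed(99)
  for (trial in 1:5) {
    keys <- paste0("v", 1:30)
    tab <- dplyr::bind_rows(lapply(1:3, function(r) {
      k <- sample(keys, sample(10:25, 1))
      conc_calls(data.frame(rep = r, key = k,
                            class = sample(c("exonic", "noncoding_flank"),
                                           length(k), replace = TRUE),
                            borderline = FALSE))
    }))
    # region class must be consistent per key across replicates
    cls <- setNames(sample(c("exonic", "noncoding_flank"), 30, TRUE), keys)
    tab$region_class <- cls[tab$key]
    cc <- replicate_concordance(tab)
    for (i in seq_len(nrow(cc$jaccard))) {
      row <- cc$jaccard[i, ]
      a <- tab$key[tab$replicate_id == row$rep_a & tab$region_class == row$region_class]
      b <- tab$key[tab$replicate_id == row$rep_b & tab$region_class == row$region_class]
      expect_equal(row$jaccard, jaccard_oracle(a, b))
    }
  }
})
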