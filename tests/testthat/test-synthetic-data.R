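test_that("configuration validates the recovery ordering and ranges", {
  expect_error(simulation_config(recovery_fractions = c(0.8, 0.5), seed = 1))
  expect_error(simulation_config(recovery_fractions = c(0.5, 1.0), seed = 1))
  expect_error(simulation_config(deficit_scale = 0, seed = 1))
  expect_error(simulation_config(seed = 1, coupling_strength = 1.2))
  expect_error(simulation_config())
  cfg <- simulation_config(seed = 1)
  expect_equal(cfg$n_patients, 21)
  expect_equal(cfg$n_controls, 17)
  expect_equal(cfg$n_nodes, 90)
})

test_that("substrate generator: exact edge count, determinism, small-world sigma", {
  net <- generate_base_connectome(60, 0.12, seed = 5)
  n_pairs <- 60 * 59 / 2
  expect_equal(sum(upper_tri_vector(net$weights) > 0), floor(0.12 * n_pairs + 0.5))
  net2 <- generate_base_connectome(60, 0.12, seed = 5)
  expect_identical(net$weights, net2$weights)
  expect_false(identical(net$weights,
                         generate_base_connectome(60, 0.12, seed = 6)$weights))

  sw <- small_world_indices(net, n_nulls = 15, seed = 2)
  expect_gt(sw$sigma, 1)
  expect_error(generate_base_connectome(10, 0.001, seed = 1))
})

test_that("subject matrices: determinism, invariants, coupling construction", {
  cfg <- simulation_config(n_nodes = 30, n_patients = 3, n_controls = 3,
                           seed = 9, affected_nodes = c(2, 7, 11))
  base <- generate_base_connectome(30, 0.15, seed = 99)
  m1 <- generate_subject_matrices(base, cfg, 1, "pat01", "patient", 2)
  m2 <- generate_subject_matrices(base, cfg, 1, "pat01", "patient", 2)
  expect_identical(m1$sc$weights, m2$sc$weights)
  expect_identical(m1$fc$weights, m2$fc$weights)
  expect_true(all(m1$sc$weights >= 0))
  expect_true(all(abs(m1$fc$weights) <= 1))
  expect_equal(m1$sc$weights, t(m1$sc$weights))

  # full coupling: FC at structural edges is an exact linear image of the
  # rank-Gaussianised SC, so the coupling correlation is exactly 1
  cfg1 <- simulation_config(n_nodes = 30, n_patients = 3, n_controls = 3,
                            seed = 9, coupling_strength = 1)
  mc <- generate_subject_matrices(base, cfg1, 2, "pat02", "patient", 1)
  expect_equal(compute_coupling(mc$sc, mc$fc)$r, 1)
})

test_that("zero coupling strength gives null-centred coupling scores", {
  base <- generate_base_connectome(40, 0.15, seed = 3)
  cfg0 <- simulation_config(n_nodes = 40, n_patients = 2, n_controls = 2,
                            seed = 21, coupling_strength = 0)
  rs <- purrr::map_dbl(1:40, function(i) {
    m <- generate_subject_matrices(base, cfg0, i, sprintf("c%02d", i),
                                   "control", 1)
    compute_coupling(m$sc, m$fc)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("realized coupling increases monotonically with coupling strength", {
  base <- generate_base_connectome(40, 0.15, seed = 13)
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mean_r <- purrr::map_dbl(grid, function(cs) {
    cfg <- simulation_config(n_nodes = 40, n_patients = 2, n_controls = 2,
                             seed = 77, coupling_strength = cs)
    mean(purrr::map_dbl(1:25, function(i) {
      m <- generate_subject_matrices(base, cfg, i, sprintf("c%02d", i),
                                     "control", 1)
      compute_coupling(m$sc, m$fc)$r
    }))
  })
  expect_gte(cor(mean_r, grid, method = "spearman"), 0.9)
})

test_that("full study: size arithmetic, determinism, complete design", {
  cfg <- simulation_config(seed = 11)
  st <- generate_study(cfg)
  expect_length(st$matrices, 38 * 3 * 2)  # subjects x timepoints x modalities
  expect_equal(nrow(st$subjects), 38)
  expect_equal(nrow(st$clinical), 38 * 3)
  expect_equal(nrow(st$manifest), 228)
  expect_length(st$ground_truth$affected_nodes, 5)

  st2 <- generate_study(simulation_config(seed = 11))
  expect_identical(purrr::map(st$matrices, "weights"),
                   purrr::map(st2$matrices, "weights"))
  expect_identical(st$clinical, st2$clinical)
})

test_that("patients recover monotonically but incompletely at affected nodes", {
  cfg <- simulation_config(n_nodes = 50, n_patients = 12, n_controls = 12,
                           seed = 19)
  st <- generate_study(cfg)
  aff <- st$ground_truth$affected_nodes
  si <- purrr::map_dfr(st$matrices[grepl("structural", names(st$matrices))],
                       function(m) tibble::tibble(
                         group = m$group, timepoint = m$timepoint,
                         si_aff = mean(rowSums(m$weights)[aff])))
  means <- si |>
    dplyr::group_by(group, timepoint) |>
    dplyr::summarise(m = mean(si_aff), .groups = "drop")
  pat <- means$m[means$group == "patient"][match(cfg$timepoints,
    means$timepoint[means$group == "patient"])]
  ctl <- mean(means$m[means$group == "control"])
  expect_true(pat[1] < pat[2] && pat[2] < pat[3] && pat[3] < ctl)
})

test_that("hemoglobin-like covariate rises over follow-up in patients only", {
  st <- generate_study(simulation_config(n_nodes = 20, n_patients = 10,
                                         n_controls = 10, seed = 4))
  hb <- st$clinical |>
    dplyr::group_by(group, timepoint) |>
    dplyr::summarise(m = mean(hemoglobin), .groups = "drop")
  pat <- hb$m[hb$group == "patient"]
  names(pat) <- hb$timepoint[hb$group == "patient"]
  expect_true(pat["baseline"] < pat["1-month"] &&
                pat["1-month"] < pat["6-month"])
  ctl <- hb$m[hb$group == "control"]
  expect_lt(max(ctl) - min(ctl), 10)
})

test_that("no systematic affected/unaffected degree gap in controls across draws", {
  # the affected-node set carries no deficit in controls; averaged over
  # generator draws (fresh substrates), its mean strength matches the rest
  ratios <- purrr::map_dbl(1:6, function(k) {
    cfg <- simulation_config(n_nodes = 60, n_patients = 2, n_controls = 6,
                             seed = 500 + k)
    st <- generate_study(cfg)
    aff <- st$ground_truth$affected_nodes
    keys <- grepl("^ctl.*structural$", names(st$matrices))
    si <- sapply(st$matrices[keys], function(m) rowSums(m$weights))
    mean(si[aff, ]) / mean(si[-aff, ])
  })
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)
})

test_that("null studies produce near-nominal nodal false-positive rates", {
  # deficit_scale = 1 plants nothing; the fraction of nodes whose group
  # effect crosses the 1/N family threshold should sit near that alpha
  alpha <- false_positive_adjust(90)
  hits <- purrr::map_int(1:2, function(k) {
    cfg <- simulation_config(n_nodes = 90, n_patients = 10, n_controls = 10,
                             deficit_scale = 1, seed = 900 + k)
    st <- generate_study(cfg)
    si <- purrr::map_dfr(st$matrices[grepl("structural", names(st$matrices))],
                         function(m) tibble::tibble(
                           subject_id = m$subject_id, group = m$group,
                           timepoint = m$timepoint,
                           node = seq_len(90), si = rowSums(m$weights)))
    ps <- si |>
      dplyr::group_by(node) |>
      dplyr::group_modify(function(d, key) {
        fit <- rm_anova(d, si, subject_id, group, timepoint)
        tibble::tibble(p = tidy(fit)$p.value[1])
      }) |>
      dplyr::ungroup()
    sum(ps$p < alpha)
  })
  expect_lte(sum(hits), ceiling(0.03 * 180))
})
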