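test_that("the same seed reproduces simulated data bit-identically", {
  tr1 <- preset_panel_truth(seed = 13)
  tr2 <- preset_panel_truth(seed = 13)
  expect_identical(simulate_panel(tr1)$run$counts,
                   simulate_panel(tr2)$run$counts)
  et1 <- preset_expression_truth(seed = 13)
  expect_identical(simulate_expression_matrix(et1)$expr$values,
                   simulate_expression_matrix(et1)$expr$values)
  # a different seed changes the data
  tr3 <- preset_panel_truth(seed = 14)
  expect_false(identical(simulate_panel(tr1)$run$counts,
                         simulate_panel(tr3)$run$counts))
})

test_that("truth validation rejects inconsistent ground truths", {
  des <- sim_design()
  mu <- c(A = 100, B = 50)
  delta <- matrix(0, 2, 3, dimnames = list(c("A", "B"),
                                           unique(des$cell_line)))
  cls <- c(A = "stable", B = "variable")
  expect_error(simulation_truth(des, c(A = -1, B = 50), cls, delta),
               "positive")
  d2 <- delta; d2["A", 1] <- 1
  expect_error(simulation_truth(des, mu, cls, d2), "stable genes")
  expect_error(simulation_truth(des, mu, cls, delta, contamination = 1),
               "contamination")
  expect_error(sim_design(replicates = 0), "invalid design")
})

test_that("simulated counts are unbiased at the planted base means", {
  des <- do.call(rbind, replicate(200, sim_design(
    cell_lines = "L1", conditions = "untreated", replicates = 1),
    simplify = FALSE))
  des$sample_id <- paste0("s", seq_len(nrow(des)))
  genes <- sprintf("G%02d", 1:20)
  mu <- setNames(exp(seq(log(20), log(5000), length.out = 20)), genes)
  delta <- matrix(0, 20, 1, dimnames = list(genes, "L1"))
  tr <- simulation_truth(des, mu, setNames(rep("stable", 20), genes),
                         delta, background = 0, seed = 101)
  run <- simulate_panel(tr)$run
  obs <- rowMeans(run$counts[genes, ])
  se <- sqrt((mu + tr$dispersion * mu ^ 2) / 200)
  within3 <- abs(obs - mu) <= 3 * se
  expect_gte(mean(within3), 0.95)
  # negatives with zero rate are all zero
  expect_true(all(run$counts[run$probe_class == "negative", ] == 0))
})

test_that("planted lane factors of (1, 4) are recovered as shifts", {
  des <- sim_design(cell_lines = "L1", conditions = "untreated")
  des <- rbind(des, des)
  des$sample_id <- c("s1", "s2")
  genes <- sprintf("HK%03d", 1:200)
  mu <- setNames(rep(800, 200), genes)
  delta <- matrix(0, 200, 1, dimnames = list(genes, "L1"))
  cls <- setNames(c("endogenous", rep("housekeeping", 199)), genes)
  tr <- simulation_truth(des, mu, setNames(rep("stable", 200), genes),
                         delta, probe_class = cls,
                         lane_factor = c(1, 4), background = 0,
                         dispersion = 0.01, seed = 55)
  run <- simulate_panel(tr)$run
  norm <- normalize_counts(run, genes[-1])
  # d = (-1, +1) up to a common constant
  expect_lt(abs(diff(norm$sample_shift) - 2), 0.05 * 2)
  expect_equal(sum(norm$sample_shift), 0, tolerance = 1e-9)
})

test_that("contaminated samples exceed the background threshold in expectation", {
  tr <- preset_panel_truth(contaminate = "Me275_CTL_coculture_1",
                           pi = 0.05, seed = 17)
  j <- "Me275_CTL_coculture_1"
  expected_cd3d <- tr$lane_factor[j] *
    (tr$mu["CD3D"] * (1 - 0.05) + 0.05 * tr$marker_signature["CD3D"])
  # analytic threshold from the Poisson background: mean + 2 SD
  B_expect <- tr$background[j] + 2 * sqrt(tr$background[j])
  expect_gt(unname(expected_cd3d) - tr$background[j], B_expect)
  # clean samples stay at trace level
  clean <- setdiff(names(tr$contamination), j)
  expect_true(all(tr$mu["CD3D"] * tr$lane_factor[clean] < B_expect))
})

test_that("the expression simulator hits its planted noise model", {
  des <- sim_design(conditions = c("untreated", "CTL_coculture"),
                    replicates = 2)
  genes <- c(S = "stable", V = "variable")
  mu <- c(S = 2 ^ 8, V = 2 ^ 8)
  delta <- matrix(0, 2, 3, dimnames = list(names(genes),
                                           unique(des$cell_line)))
  tr <- simulation_truth(des, mu, genes, delta, seed = 77)
  sim <- simulate_expression_matrix(tr)
  # zero treatment effect: values center on log2 mu
  expect_lt(abs(mean(sim$expr$values["S", ]) - 8), 0.1)
  expect_equal(unname(sim$sigma["S"]), 0.05)
  expect_gt(unname(sim$sigma["V"]), 0.25)

  # noise-free limit: logFC equals delta exactly per cell line
  tr0 <- simulation_truth(des, mu, c(S = "stable", V = "variable"),
                          matrix(c(0, 0, 0, 2, 1, -1), 2, 3, byrow = TRUE,
                                 dimnames = list(names(genes),
                                                 unique(des$cell_line))),
                          sigma_stable = 0, seed = 78)
  tr0$sigma_variable_meanlog <- -Inf   # degenerate: sigma 0
  sim0 <- simulate_expression_matrix(tr0)
  fc0 <- condition_logfc(2 ^ sim0$expr$values, "CTL_coculture",
                         "untreated", pseudocount = 1e-9,
                         conditions = sim0$expr$sample_condition,
                         cell_lines = sim0$expr$cell_line)
  expect_equal(fc0$logfc["V", colnames(tr0$delta)],
               tr0$delta["V", ], tolerance = 1e-6)
})

test_that("missing entries are injected at the requested rate", {
  tr <- preset_expression_truth(missing_rate = 0.1, seed = 19)
  sim <- simulate_expression_matrix(tr)
  frac <- mean(is.na(sim$expr$values))
  expect_lt(abs(frac - 0.1), 0.02)
})

test_that("the simulation truth round-trips through YAML", {
  tr <- preset_panel_truth(contaminate = "Me275_CTL_coculture_1", seed = 23)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth(tr, f)
  back <- read_truth(f)
  expect_identical(back$design, tr$design)
  expect_identical(names(back$mu), names(tr$mu))
  expect_equal(back$mu, tr$mu, tolerance = 1e-9)
  expect_identical(back$stability_class, tr$stability_class)
  expect_identical(back$probe_class, tr$probe_class)
  expect_equal(back$delta, tr$delta, tolerance = 1e-9)
  expect_equal(back$lane_factor, tr$lane_factor, tolerance = 1e-9)
  expect_equal(back$contamination, tr$contamination)
  expect_identical(back$seed, tr$seed)
  # and the round-tripped truth regenerates identical data
  expect_identical(simulate_panel(back)$run$counts,
                   simulate_panel(tr)$run$counts)
})

test_that("end-to-end pipeline recovers planted truth", {
  des <- sim_design(conditions = c("untreated", "CTL_coculture"),
                    replicates = 3)
  # effects planted clear of the fourfold decision boundary
  tr <- preset_panel_truth(des, n_de = 40, de_delta = 3, seed = 47,
                           contaminate = "T1185B_CTL_coculture_2")
  sim <- simulate_panel(tr)
  norm <- normalize_counts(sim$run, hk5)
  scr <- expression_screen(hk8, norm)
  expect_setequal_sorted(scr$usable, hk5)
  fc <- condition_logfc(norm, "CTL_coculture", "untreated")
  cons <- consensus_fourfold(fc, 4)
  # recall assessed on well-expressed planted genes: below ~50 counts the
  # pseudocount deliberately shrinks fold-changes toward zero
  planted_up <- rownames(tr$delta)[tr$delta[, 1] > 0 &
                                     tr$probe_class == "endogenous" &
                                     tr$mu >= 50]
  planted_up <- setdiff(planted_up, CTL_MARKERS)
  recall <- mean(planted_up %in% cons$up)
  expect_gte(recall, 0.9)
  null_genes <- rownames(tr$delta)[rowSums(tr$delta != 0) == 0]
  expect_length(intersect(cons$up, null_genes), 0)
  qc <- contamination_check(norm, sim$run)
  expect_identical(names(attr(qc, "flagged")), "T1185B_CTL_coculture_2")
})
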