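test_that("stability screen computes pooled n-1 SDs with a strict cutoff", {
  vals <- rbind(flat = rep(7.3, 6),
                wobbly = rep(c(6, 7), 3),
                # {4.75, 5, 5.25} has sample SD exactly 0.25 (all three
                # values, their mean and the square root are exact binary
                # fractions), probing the strict cutoff
                edge = c(4.75, 5, 5.25, NA, NA, NA))
  colnames(vals) <- paste0("s", 1:6)
  expr <- expression_matrix(vals, rep(c("untreated", "treated"), 3))
  st <- stability_screen(expr, threshold = 0.25)

  expect_equal(st$sd[st$gene == "flat"], 0)
  expect_true(st$stable[st$gene == "flat"])
  expect_equal(st$sd[st$gene == "wobbly"], sd(rep(c(6, 7), 3)))
  expect_equal(st$sd[st$gene == "wobbly"], 0.5477, tolerance = 1e-4)
  expect_false(st$stable[st$gene == "wobbly"])
  # strict inequality at the boundary: sd exactly 0.25 is NOT stable
  expect_identical(st$sd[st$gene == "edge"], 0.25)
  expect_false(st$stable[st$gene == "edge"])
  # sorted ascending by SD
  expect_identical(st$gene, c("flat", "edge", "wobbly"))
})

test_that("stability screen excludes under-observed genes with a reason", {
  vals <- rbind(ok = c(5, 5.1, 5.2, 5), sparse = c(6, NA, NA, NA),
                holey = c(7, 7.1, NA, NA))
  colnames(vals) <- paste0("s", 1:4)
  expr <- expression_matrix(vals, rep("u", 4))
  st <- stability_screen(expr, max_missing = 0.4)
  excl <- attr(st, "excluded")
  expect_setequal_sorted(excl$gene, c("sparse", "holey"))
  expect_match(excl$reason[excl$gene == "sparse"], "fewer than 2")
  expect_match(excl$reason[excl$gene == "holey"], "missing fraction")
  expect_identical(st$gene, "ok")
})

test_that("stability reports are invariant under sample permutation", {
  set.seed(11)
  tr <- preset_expression_truth(n_stable = 20, n_variable = 80, seed = 11)
  expr <- simulate_expression_matrix(tr)$expr
  st1 <- stability_screen(expr)
  perm <- sample(ncol(expr$values))
  expr2 <- expression_matrix(expr$values[, perm],
                             expr$sample_condition[perm],
                             expr$cell_line[perm])
  st2 <- stability_screen(expr2)
  expect_equal(st1$gene, st2$gene)
  expect_equal(st1$sd, st2$sd)
  expect_equal(st1$stable, st2$stable)
})

test_that("expression screen flags low and unmeasurable candidates", {
  run <- make_small_run(3)
  norm <- normalize_counts(run, c("RPLP0", "ALG12"))
  scr <- expression_screen(c("RPLP0", "ALG12"), norm, floor = 20)
  expect_setequal_sorted(scr$usable, c("RPLP0", "ALG12"))
  expect_equal(scr$median_counts[["RPLP0"]] >= 20, TRUE)

  # default floor is twice the pooled negative-control mean
  scr2 <- expression_screen("RPLP0", norm)
  expect_equal(scr2$floor, 2 * mean(norm$background))

  expect_error(expression_screen("NOPE", norm), "NOPE")

  # monotone in floor: raising the floor never rescues a gene
  floors <- c(1, 10, 100, 1000, 1e5)
  usable_sets <- lapply(floors, function(f)
    expression_screen(c("RPLP0", "ALG12"), norm, floor = f)$usable)
  for (i in seq_len(length(floors) - 1))
    expect_true(all(usable_sets[[i + 1]] %in% usable_sets[[i]]))
})

test_that("candidates planted at background level are caught", {
  tr <- preset_panel_truth(seed = 5)
  sim <- simulate_panel(tr)
  norm <- normalize_counts(sim$run, hk5)
  scr <- expression_screen(hk8, norm)
  expect_setequal_sorted(scr$too_low, c("DIRC1", "SLC26A3", "PHKG1"))
  expect_setequal_sorted(scr$usable, hk5)
})

test_that("panel design fills strata and picks flat normalization genes", {
  set.seed(3)
  tr <- preset_expression_truth(n_stable = 100, n_variable = 900, seed = 3)
  sim <- simulate_expression_matrix(tr)
  fc <- condition_logfc(2 ^ sim$expr$values, "CTL_coculture", "untreated",
                        conditions = sim$expr$sample_condition,
                        cell_lines = sim$expr$cell_line)
  des <- design_panel(sim$expr, fc, n_targets = 185, n_norm = 8)
  expect_equal(sum(des$role == "target"), 185)
  expect_equal(sum(des$role == "normalization"), 8)
  expect_false(anyDuplicated(des$gene) > 0)
  # normalization genes are flat
  expect_true(all(abs(des$mean_logfc[des$role == "normalization"]) < 0.25))
  # every occupied stratum is represented by at least one target;
  # bin occupancy recomputed independently with equal-width 5x5 cuts
  genes <- intersect(rownames(sim$expr$values), names(fc$mean_logfc))
  me <- rowMeans(sim$expr$values[genes, ], na.rm = TRUE)
  mf <- fc$mean_logfc[genes]
  eb <- cut(me, seq(min(me), max(me), length.out = 6),
            include.lowest = TRUE, labels = FALSE)
  fb <- cut(mf, seq(min(mf), max(mf), length.out = 6),
            include.lowest = TRUE, labels = FALSE)
  stratum <- paste(eb, fb)
  names(stratum) <- genes
  pool <- setdiff(genes, des$gene[des$role == "normalization"])
  occupied <- unique(stratum[pool])
  target_strata <- unique(stratum[des$gene[des$role == "target"]])
  expect_setequal_sorted(occupied, target_strata)
})

test_that("panel design degenerate and error cases", {
  vals <- matrix(rep(c(5, 8, 11, 14, 17), each = 4), 5, 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expr <- expression_matrix(vals, rep(c("u", "t"), 2))
  fc <- condition_logfc(2 ^ vals, "t", "u",
                        conditions = rep(c("u", "t"), 2))
  # exactly 5 stable flat genes, n_norm = 5: all are selected
  des <- suppressWarnings(design_panel(expr, fc, n_targets = 0, n_norm = 5))
  expect_setequal_sorted(des$gene[des$role == "normalization"],
                         paste0("g", 1:5))
  expect_error(design_panel(expr, fc, n_targets = 100, n_norm = 5),
               "only")
  # shortfall warns and returns a partial design
  vals2 <- vals + matrix(rnorm(20, 0, 2), 5, 4)
  expr2 <- expression_matrix(vals2, rep(c("u", "t"), 2))
  expect_warning(design_panel(expr2, fc, n_targets = 0, n_norm = 5),
                 "shortfall")
})

test_that("stable-gene recovery meets precision and recall on the preset", {
  tr <- preset_expression_truth(seed = 17)
  sim <- simulate_expression_matrix(tr)
  st <- stability_screen(sim$expr, threshold = 0.25)
  truth_stable <- names(tr$stability_class)[tr$stability_class == "stable"]
  called <- st$gene[st$stable]
  precision <- mean(called %in% truth_stable)
  recall <- mean(truth_stable %in% called)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})
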