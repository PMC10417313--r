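# Subject-level splitting, stage assembly and SMOTE.

# Lightweight cohort stub: split_cohort only consults subject ids.
stub_cohort <- function(n) {
  structure(list(subjects = lapply(seq_len(n), function(i)
    list(id = sprintf("S%03d", i), condition = "control", grids = list())),
    axis = ppm_axis(), config = NULL), class = "mrsi_cohort")
}

test_that("cohort splitting is by subject with round-to-nearest counts", {
  plan <- split_cohort(stub_cohort(28), 0.25, seed = 4)
  expect_length(plan$train_subjects, 21)
  expect_length(plan$test_subjects, 7)
  expect_length(intersect(plan$train_subjects, plan$test_subjects), 0)
  expect_setequal(c(plan$train_subjects, plan$test_subjects),
                  subject_ids(stub_cohort(28)))
  p2 <- split_cohort(stub_cohort(2), 0.5, seed = 1)
  expect_length(p2$train_subjects, 1)
  expect_length(p2$test_subjects, 1)
  expect_identical(split_cohort(stub_cohort(28), 0.25, seed = 4), plan)
  expect_error(split_cohort(stub_cohort(2), 0.25, seed = 1))
  # leakage property across seeds
  for (s in 1:10) {
    p <- split_cohort(stub_cohort(9), 0.3, seed = s)
    expect_length(intersect(p$train_subjects, p$test_subjects), 0)
  }
})

test_that("stage datasets carry the right classes, provenance and no leakage", {
  coh <- generate_cohort(2, 2, 1, 3, phantom_config(), seed = 41)
  # hold out the longitudinal subject so both stages see both classes
  ids <- subject_ids(coh)
  plan <- structure(list(train_subjects = ids[1:4], test_subjects = ids[5],
                         seed = 1L), class = "split_plan")
  for (stage in c("N_vs_RT", "R_vs_T")) {
    ds <- assemble_stage(coh, plan, stage)
    for (side in ds) {
      expect_false(any(side$provenance$label == "unknown"))
      expect_equal(sqrt(rowSums(side$x^2)), rep(1, nrow(side$x)),
                   tolerance = 1e-9)  # UL2 applied
      if (stage == "N_vs_RT") {
        expect_true(all(side$provenance$label[side$y == 1] %in% c("R", "T")))
        expect_true(all(side$provenance$label[side$y == 0] == "N"))
      } else {
        expect_true(all(side$provenance$label %in% c("R", "T")))
        expect_true(all(side$provenance$label[side$y == 1] == "R"))
      }
    }
    expect_length(intersect(unique(ds$train$provenance$subject),
                            unique(ds$test$provenance$subject)), 0)
  }
  # voxel counts are conserved: every labelled voxel appears exactly once
  ds <- assemble_stage(coh, plan, "N_vs_RT")
  n_labelled <- sum(unlist(lapply(coh$subjects, function(s)
    lapply(s$grids, function(g) sum(g$labels != "unknown")))))
  expect_equal(nrow(ds$train$x) + nrow(ds$test$x), n_labelled)
  # a cohort without R voxels cannot feed the response stage
  ctrl <- generate_cohort(2, 0, 0, 0, phantom_config(), seed = 5)
  plan2 <- split_cohort(ctrl, 0.5, seed = 1)
  expect_error(assemble_stage(ctrl, plan2, "R_vs_T"),
               class = "mrsinet_class_error")
})

test_that("SMOTE balances counts by convex minority interpolation", {
  set.seed(6)
  x <- ul2_normalize(matrix(runif(140 * 30, 0.1, 1), 140, 30))
  y <- rep(c(0L, 1L), c(100, 40))
  prov <- data.frame(subject = "S1", grid = 1L, row = 0L,
                     col = seq_len(140) - 1L,
                     label = ifelse(y == 1, "T", "N"))
  ds <- mrsinet:::new_stage_dataset(x, y, prov, "N_vs_RT")
  bal <- smote_balance(ds, k_neighbors = 5, seed = 1)
  expect_equal(sum(bal$y == 0), 100)
  expect_equal(sum(bal$y == 1), 100)          # 60 synthetic rows added
  expect_equal(sum(bal$provenance$subject == "synthetic"), 60)
  # majority rows pass through unchanged, in place
  expect_identical(bal$x[seq_len(140), ], ds$x)
  # default output keeps the unit-norm invariant
  expect_equal(sqrt(rowSums(bal$x^2)), rep(1, 200), tolerance = 1e-9)

  # raw synthetic rows lie in the componentwise envelope of their parents
  raw <- smote_balance(ds, k_neighbors = 5, seed = 1, renormalize = FALSE)
  minority <- ds$x[ds$y == 1L, ]
  lo <- apply(minority, 2, min); hi <- apply(minority, 2, max)
  synth <- raw$x[141:200, ]
  expect_true(all(synth >= matrix(lo, 60, 30, byrow = TRUE) - 1e-12))
  expect_true(all(synth <= matrix(hi, 60, 30, byrow = TRUE) + 1e-12))

  # already balanced data is returned unchanged
  even <- mrsinet:::new_stage_dataset(x[1:80, ], rep(c(0L, 1L), 40),
                                      prov[1:80, ], "N_vs_RT")
  expect_identical(smote_balance(even, 5, 1), even)
  # minority too small for k suggests a smaller k
  small <- mrsinet:::new_stage_dataset(x[1:24, ], rep(c(0L, 1L), c(20, 4)),
                                       prov[1:24, ], "N_vs_RT")
  expect_error(smote_balance(small, 5, 1), "smaller k")
})

test_that("synthetic rows interpolate a parent and one of its k nearest neighbours", {
  # with k = 1 each synthetic row must lie on the segment between a
  # minority point and its single nearest neighbour — verifiable exactly
  x <- matrix(c(0, 0,  1, 0,  10, 10, 10.5, 10,  5, 5), ncol = 2, byrow = TRUE)
  y <- c(1L, 1L, 1L, 1L, 0L)
  xall <- rbind(x, matrix(runif(12 * 2, 20, 30), 12, 2))
  yall <- c(y, rep(0L, 12))
  prov <- data.frame(subject = "S1", grid = 1, row = 0,
                     col = seq_along(yall), label = "T")
  ds <- mrsinet:::new_stage_dataset(xall, yall, prov, "R_vs_T")
  bal <- smote_balance(ds, k_neighbors = 1, seed = 3, renormalize = FALSE)
  synth <- bal$x[(length(yall) + 1):nrow(bal$x), , drop = FALSE]
  pairs <- list(c(1, 2), c(2, 1), c(3, 4), c(4, 3))
  on_segment <- function(p) any(vapply(pairs, function(pr) {
    a <- x[pr[1], ]; b <- x[pr[2], ]
    d <- b - a
    t_ <- if (abs(d[1]) > 1e-12) (p[1] - a[1]) / d[1] else (p[2] - a[2]) / d[2]
    t_ >= 0 && t_ < 1 && max(abs(a + t_ * d - p)) < 1e-9
  }, logical(1)))
  expect_true(all(apply(synth, 1, on_segment)))
})
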