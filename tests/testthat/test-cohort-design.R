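test_that("clustering separates well-separated blobs and is reproducible", {
  X <- withr::with_seed(1, rbind(
    matrix(rnorm(40 * 2, mean = 0), ncol = 2),
    matrix(rnorm(40 * 2, mean = 8), ncol = 2)))
  df <- as.data.frame(X)
  truth <- rep(1:2, each = 40)
  cl <- cluster_subjects(df, k_range = 2:4, seed = 3)
  expect_equal(length(unique(cl)), 2)
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_equal(agree, 1)
  expect_identical(cl, cluster_subjects(df, k_range = 2:4, seed = 3))
  expect_warning(one <- cluster_subjects(as.data.frame(matrix(1, 10, 3))),
                 "identical")
  expect_true(all(one == 1L))
  expect_error(cluster_subjects(df[1:3, ]), "at least 4")
})

test_that("a 5/5 cohort at 20% test yields 8 train / 2 test balanced by
           diagnosis", {
  subjects <- data.frame(id = sprintf("P%02d", 1:10),
                         group = rep(c("AS", "control"), each = 5))
  sp <- split_cohort(subjects, rep(1L, 10), test_frac = 0.2, seed = 4)
  expect_length(sp$train_ids, 8)
  expect_length(sp$test_ids, 2)
  test_groups <- subjects$group[subjects$id %in% sp$test_ids]
  expect_setequal(test_groups, c("AS", "control"))
  sp2 <- split_cohort(subjects, rep(1L, 10), test_frac = 0.2, seed = 4)
  expect_identical(sp2$test_ids, sp$test_ids)
})

test_that("split invariants hold across random cohorts", {
  for (i in 1:30) {
    n <- withr::with_seed(i, sample(20:60, 1))
    subjects <- withr::with_seed(i, data.frame(
      id = sprintf("P%03d", 1:n),
      group = sample(c("AS", "MR", "control"), n, replace = TRUE)))
    labels <- withr::with_seed(i + 100, sample(1:3, n, replace = TRUE))
    sp <- suppressWarnings(split_cohort(subjects, labels, 0.25, seed = i))
    expect_setequal(c(sp$train_ids, sp$test_ids), subjects$id)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    # per-stratum proportional balance within one subject
    for (cl in unique(labels)) for (g in unique(subjects$group)) {
      ids <- subjects$id[labels == cl & subjects$group == g]
      if (!length(ids)) next
      n_test <- length(intersect(ids, sp$test_ids))
      expect_lte(abs(n_test - 0.25 * length(ids)), 1)
    }
    sp <- add_tuning_set(sp, 0.8, seed = i)
    expect_true(all(sp$tuning_ids %in% sp$train_ids))
  }
})

test_that("tuning-set sizes follow the ceiling rule at study scales", {
  for (case in list(c(196, 157), c(193, 155), c(195, 156))) {
    ids <- sprintf("P%03d", seq_len(case[1]))
    strata <- withr::with_seed(case[1], sample(c("AS", "MR", "SHD", "CTRL"),
                                               case[1], replace = TRUE))
    ts <- tuning_split(ids, tuning_frac = 0.8, seed = 1, strata = strata)
    expect_length(ts$tuning_ids, case[2])
    expect_setequal(c(ts$tuning_ids, ts$holdout_ids), ids)
  }
  expect_error(tuning_split(character(0), 0.8, 1), "empty")
})

test_that("KS screen matches a brute-force ECDF sweep", {
  a <- data.frame(f = c(1, 2, 3, 4))
  b <- data.frame(f = c(1.5, 2.5, 3.5))
  res <- ks_screen(a, b)
  expect_equal(res$D, brute_ks(a$f, b$f))
  same <- data.frame(f = c(1, 2, 3, 4, 5))
  expect_equal(ks_screen(same, same)$D, 0)
  lo <- data.frame(f = 1:5)
  hi <- data.frame(f = 101:105)
  expect_equal(ks_screen(lo, hi)$D, 1)
  expect_warning(res_const <- ks_screen(data.frame(f = rep(1, 5)),
                                        data.frame(f = rep(1, 4))),
                 "constant")
  expect_equal(res_const$D, 0)
  expect_equal(res_const$p, 1)
})

test_that("KS D is translation invariant and bounded", {
  a <- withr::with_seed(1, rnorm(30))
  b <- withr::with_seed(2, rnorm(25, mean = 1))
  d0 <- ks_screen(data.frame(f = a), data.frame(f = b))$D
  d1 <- ks_screen(data.frame(f = a + 5), data.frame(f = b + 5))$D
  expect_equal(d0, d1)
  expect_gte(d0, 0)
  expect_lte(d0, 1)
})

test_that("paired NMI is 1 for identical or monotone-equivalent sources and
           small for independent ones", {
  a <- withr::with_seed(3, rnorm(1000))
  expect_equal(nmi_paired(a, a)$aggregate, 1)
  expect_equal(nmi_paired(a, a^3)$aggregate, 1)
  b <- withr::with_seed(4, rnorm(1000))
  expect_lte(nmi_paired(a, b)$aggregate, 0.1)
  expect_equal(nmi_paired(a, b)$aggregate, nmi_paired(b, a)$aggregate)
  expect_warning(nmi_paired(rnorm(5), rnorm(5)), "fewer subjects")
})

test_that("sample-size arithmetic follows the events-per-variable plan", {
  expect_identical(effective_df(2.5), 5L)
  expect_identical(effective_df(1.0), 2L)
  expect_identical(effective_df(2.2), 5L)
  expect_identical(peduzzi_min_events(5, 10), 50L)
  expect_identical(peduzzi_min_events(1, 10), 10L)
  expect_identical(peduzzi_min_events(3, 10), 30L)
  plan <- enrollment_target(50, 15, 4)
  expect_identical(plan$enrollment_target, 260L)
  expect_identical(plan$per_condition_total, 65L)
  expect_identical(plan$min_events_train,
                   peduzzi_min_events(plan$effective_df, plan$epv))
  expect_identical(enrollment_target(50, 15, 1)$enrollment_target, 65L)
  expect_identical(enrollment_target(10, 0, 1)$enrollment_target, 10L)
})
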