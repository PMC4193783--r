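# hand-built trace with full control over records
fake_trace <- function(mcs, ncl, cx = NULL, cy = NULL, cells0 = NULL,
                       cadence = 100) {
  n <- length(mcs)
  if (is.null(cx)) cx <- matrix(0, n, 2)
  if (is.null(cy)) cy <- matrix(0, n, 2)
  if (is.null(cells0))
    cells0 <- tibble::tibble(cell = seq_len(ncol(cx)),
                             type = rep(1L, ncol(cx)),
                             misspecified = rep(FALSE, ncol(cx)))
  structure(list(summary = tibble::tibble(mcs = mcs, n_clusters = ncl),
                 area = matrix(49, n, ncol(cx)), cx = cx, cy = cy,
                 cells0 = cells0, cadence = cadence, n_mcs = max(mcs),
                 t_end = max(mcs), accept_rate = NA_real_,
                 crossing_mcs = NA_integer_, schedule = NULL, system = NULL),
            class = "potts_trace")
}

test_that("cluster counting matches hand-checkable configurations", {
  expect_equal(count_clusters(make_fixture("french_flag")), 4)
  sys <- make_fixture("french_flag")
  sys$cells$type <- rep(2L, 100)
  expect_equal(count_clusters(sys), 1)
  # one off-type cell inside band 2 becomes its own extra cluster
  sys2 <- make_fixture("french_flag")
  sys2$cells$type[48] <- 1L # cell at tile (col 8, row 3), inside band 2
  expect_equal(count_clusters(sys2), 5)
})

test_that("cluster counter agrees with a site-level flood-fill oracle", {
  set.seed(14)
  for (i in 1:100) {
    sys <- make_fixture("random100")
    expect_equal(count_clusters(sys), flood_fill_clusters(sys))
  }
})

test_that("run classification finds correctness, stability and t_s", {
  # constant at the sorted state from the start
  cl <- classify_run(fake_trace(seq(0, 1000, 100), rep(4L, 11)))
  expect_true(cl$correct && cl$stable)
  expect_equal(cl$t_s, 100) # first record after the gate at t = 0

  # sorts late, then dissociates: correct but unstable
  ncl <- c(40, 10, 6, 4, 5, 5)
  cl <- classify_run(fake_trace(seq(0, 500, 100), ncl))
  expect_true(cl$correct)
  expect_false(cl$stable)
  expect_equal(cl$t_s, 300)

  # never reaches four clusters
  cl <- classify_run(fake_trace(seq(0, 500, 100), rep(6L, 6)))
  expect_false(cl$correct)
  expect_true(is.na(cl$t_s))

  # gated classification ignores pre-onset coincidences
  ncl <- c(4, 4, 6, 5, 4, 4)
  cl <- classify_run(fake_trace(seq(0, 500, 100), ncl), t_gate = 500 - 200)
  expect_true(cl$correct)
  expect_equal(cl$t_s, 400)
  empty <- suppressWarnings(fake_trace(integer(), integer()))
  expect_error(classify_run(empty), "empty")
})

test_that("ensemble summaries compute F_C and F_S with the 0-correct guard", {
  runs <- tibble::tibble(correct = rep(TRUE, 10),
                         stable = rep(c(TRUE, FALSE), c(2, 8)),
                         t_s = rep(5000, 10))
  s <- summarize_ensemble(runs)
  expect_equal(s$f_correct, 1)
  expect_equal(s$f_stable, 0.2)

  s0 <- summarize_ensemble(tibble::tibble(correct = rep(FALSE, 30),
                                          stable = FALSE, t_s = NA_real_))
  expect_equal(s0$f_correct, 0)
  expect_true(is.na(s0$f_stable) && !s0$f_stable_defined)

  s1 <- summarize_ensemble(tibble::tibble(correct = TRUE, stable = TRUE,
                                          t_s = 100))
  expect_equal(s1$f_correct, 1)
  expect_equal(s1$f_stable, 1)
})

test_that("size variation reduces to direct arithmetic on type means", {
  cells <- tibble::tibble(type = 1:4, area = c(40, 45, 53, 58))
  m <- c(40, 45, 53, 58)
  byhand <- sqrt(sum((m - mean(m))^2) / 4) / mean(m)
  expect_equal(size_variation(cells), byhand)
  expect_equal(size_variation(tibble::tibble(type = 1:4, area = rep(49, 4))),
               0)
  expect_warning(sv <- size_variation(tibble::tibble(type = c(1, 2, 3),
                                                     area = 49)), "types")
  expect_true(is.na(sv))
})

test_that("cell speeds recover programmed centroid motion", {
  n <- 11
  cx <- cbind(rep(5, n), 5 + (0:10)) # cell 2 moves 1 site per record
  tr <- fake_trace(seq(0, 1000, 100), rep(4L, n), cx = cx)
  sp <- cell_speeds(tr, window = 100)
  expect_equal(sp$speed, c(0, 1))
  # window coarser than cadence averages displacement per window
  sp2 <- cell_speeds(tr, window = 500)
  expect_equal(sp2$speed, c(0, 5))
  expect_error(cell_speeds(tr, window = 150), "multiple")
})

test_that("cluster lifetimes delimit maximal sorted intervals", {
  tr <- fake_trace(seq(0, 1000, 100), c(9L, 4L, 4L, 5L, 4L, 5L, 4L, 4L,
                                        4L, 5L, 6L))
  lt <- cluster_lifetimes(tr)
  expect_equal(lt$lifetime, c(200, 100, 300))
  # stable run: a single interval from t_s to the end
  tr2 <- fake_trace(seq(0, 500, 100), c(9L, rep(4L, 5)))
  lt2 <- cluster_lifetimes(tr2)
  expect_equal(nrow(lt2), 1)
  expect_equal(c(lt2$start, lt2$end), c(100, 500))
  # alternating visits each last one cadence
  tr3 <- fake_trace(seq(0, 500, 100), rep(c(4L, 5L), 3))
  expect_true(all(cluster_lifetimes(tr3)$lifetime == 100))
})

test_that("a marked cell starting past the line crosses at time zero", {
  sys <- make_fixture("merge16", j = 1)
  tr <- run_mcs(sys, 0, monitor = list(cell = attr(sys, "marked_cell"),
                                       x = 5))
  expect_equal(tr$crossing_mcs, 0L)
})

test_that("merging integration is faster at stronger adhesion", {
  set.seed(61)
  m_weak <- merging_time(0.25, n_runs = 25, horizon = 5000)
  m_strong <- merging_time(4, n_runs = 25, horizon = 5000)
  expect_gte(m_weak$n_crossed, 15)
  expect_equal(m_strong$n_crossed, 25)
  expect_gt(m_weak$mean_crossing, m_strong$mean_crossing)
})

test_that("initial-cluster statistics honour their group-size gates", {
  runs <- tibble::tibble(
    mu0 = 0.75, j = 0.25,
    initial_n_clusters = c(50, 52, 54, 50, 52, 54),
    correct = rep(c(TRUE, FALSE), each = 3),
    t_s = c(1000, 2000, 3000, NA, NA, NA))
  st <- initial_cluster_stats(runs)
  expect_true(st$t_testable)
  expect_equal(st$t_p, 1) # identical groups: no mean difference
  expect_true(st$spearman_testable)
  expect_equal(st$spearman_rho, 1) # t_s perfectly ranked with cluster count
  # too few runs in a group: flagged untestable
  st2 <- initial_cluster_stats(runs[c(1, 4, 5, 6), ])
  expect_false(st2$t_testable)
  expect_false(st2$spearman_testable)
  expect_true(is.na(st2$t_p))
})
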