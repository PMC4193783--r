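test_that("fixtures have their defining structure", {
  ff <- make_fixture("french_flag")
  expect_equal(count_clusters(ff), 4)
  expect_equal(count_misspecified(ff$cells), 0)

  m16 <- make_fixture("merge16", j = 1)
  expect_equal(nrow(m16$cells), 16)
  expect_equal(as.integer(table(m16$cells$type)), c(7L, 9L))
  marked <- attr(m16, "marked_cell")
  expect_equal(m16$cells$type[marked], 2L)
  # marked cell sits left of the interface, touching it
  expect_lt(m16$cells$x[marked], attr(m16, "boundary_x"))
  expect_equal(m16$cells$col[marked], 2L)

  tc <- make_fixture("two_cell")
  expect_equal(sum(tc$cells$area),
               tc$grid$interior_width * tc$grid$interior_height)
  expect_error(make_fixture("no_such_kind"))
})

test_that("scenario presets encode the experiment designs", {
  s1 <- scenario("chemotaxis", "full")
  expect_equal(s1$mu0, c(0.25, 0.5, 0.75, 1, 1.5))
  expect_equal(s1$j, 0)
  expect_equal(s1$r, 1)
  expect_equal(s1$n_runs, 10)
  expect_equal(s1$n_mcs, 100000)

  s2 <- scenario("adhesion", "full")
  expect_lt(s2$r, 0.05)
  expect_equal(s2$mu0, 0)
  expect_equal(s2$n_runs, 30)
  expect_equal(s2$n_mcs, 200000)

  sd <- scenario("delayed", "full")
  expect_equal(sd$t_gate, 500)
  expect_equal(sd$n_mcs, 2000)
  sched <- sd$schedule_fun()
  expect_equal(sched$mcs, 500)
  expect_equal(sched$j, 1.5)

  expect_equal(scenario("chemotaxis_large")$grid$n_cells, 210)
  expect_equal(scenario("adhesion_uniform")$j_mode, "uniform")
  expect_error(scenario("nope"))
})

test_that("scenario runs are reproducible and resumable", {
  scn <- scenario("merging", "smoke")
  scn$n_runs <- 3
  scn$j <- c(1, 4)
  a <- run_scenario(scn, seed_base = 5)
  b <- run_scenario(scn, seed_base = 5)
  expect_identical(a$runs$crossing_mcs, b$runs$crossing_mcs)
  expect_equal(nrow(a$runs), 6)
  expect_true(all(c("j", "seed", "crossing_mcs") %in% names(a$runs)))
  expect_equal(nrow(a$summary), 2)

  dir <- tempfile("ens")
  c1 <- run_scenario(scn, seed_base = 5, out_dir = dir)
  expect_true(file.exists(file.path(dir, "runs.csv")))
  c2 <- run_scenario(scn, seed_base = 5, out_dir = dir) # resumes, no re-run
  expect_equal(c2$runs$crossing_mcs, c1$runs$crossing_mcs)
})

test_that("sorting scenarios classify runs and tidy into tables", {
  scn <- scenario("chemotaxis", "smoke")
  scn$mu0 <- 1.5; scn$n_runs <- 2; scn$n_mcs <- 300
  ens <- run_scenario(scn, seed_base = 2)
  expect_s3_class(tidy(ens), "tbl_df")
  expect_equal(nrow(tidy(ens)), 2)
  g <- glance(ens)
  expect_true(all(c("f_correct", "f_stable", "mean_t_s") %in% names(g)))
  expect_true(all(ens$runs$initial_n_clusters > 4))
})

test_that("trace tidiers expose per-cell and per-run views", {
  set.seed(9)
  sys <- init_cells(grid_spec(4, 2), potts_params(mu0 = 0.75), r = 1)
  tr <- run_mcs(sys, 200, cadence = 100)
  td <- tidy(tr)
  expect_equal(nrow(td), 3 * 8)
  expect_true(all(c("mcs", "cell", "type", "area", "x", "y") %in% names(td)))
  expect_equal(sum(td$area[td$mcs == 0]), 8 * 49)
  gl <- glance(tr)
  expect_equal(gl$n_records, 3)
  expect_true(gl$accept_rate > 0 && gl$accept_rate < 1)
})

test_that("plots build without evaluation errors", {
  sys <- make_fixture("french_flag")
  p1 <- autoplot(sys)
  expect_s3_class(p1, "ggplot")
  set.seed(10)
  tr <- run_mcs(sys, 100, cadence = 50)
  expect_s3_class(autoplot(tr), "ggplot")
  scn <- scenario("merging", "smoke"); scn$n_runs <- 2; scn$j <- c(1, 4)
  expect_s3_class(autoplot(run_scenario(scn, 1)), "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
})
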