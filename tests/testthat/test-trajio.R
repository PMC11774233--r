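# Trajectory discovery, XYZ parsing, property tables, ensemble assembly.

test_that("trajectory discovery parses TRAJ<k> ids and ignores the rest", {
  root <- tempfile("root")
  for (d in c("TRAJ1", "TRAJ2", "TRAJ9", "RESULTS", "TRAJx"))
    dir.create(file.path(root, d), recursive = TRUE)
  for (k in c(1, 2, 9))
    file.create(file.path(root, paste0("TRAJ", k), "dyn.xyz"))
  expect_equal(suppressMessages(discover_trajectories(root)), c(1L, 2L, 9L))

  empty <- tempfile("empty"); dir.create(empty)
  expect_equal(discover_trajectories(empty), integer(0))
  expect_error(discover_trajectories(tempfile("nope")), "does not exist")
  # TRAJ directory without a geometry series is skipped
  dir.create(file.path(root, "TRAJ5"))
  expect_equal(suppressMessages(discover_trajectories(root)), c(1L, 2L, 9L))
})

test_that("concatenated XYZ parsing reads frames, times and labels", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("3", "time = 0.0 fs",
               "O 0.0 0.0 0.0", "H 0.96 0.0 0.0", "H -0.24 0.93 0.0",
               "3", "time = 0.1 fs",
               "O 0.0 0.0 0.1", "H 0.96 0.0 0.1", "H -0.24 0.93 0.1"), f)
  tr <- read_xyz_trajectory(f)
  expect_length(tr$geometries, 2)
  expect_equal(tr$times, c(0, 0.1))
  expect_equal(tr$geometries[[1]]$labels, c("O", "H", "H"))
  expect_equal(tr$geometries[[2]]$coords[3, ], c(-0.24, 0.93, 0.1))
})

test_that("XYZ parser rejects malformed and inconsistent blocks", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("3", "time = 0.0 fs", "C 0 0 0", "C 1 0 0", "C 0 1 0",
               "4", "time = 0.1 fs", "C 0 0 0", "C 1 0 0", "C 0 1 0",
               "C 1 1 0"), f)
  expect_error(read_xyz_trajectory(f), "frame 2.*atom count")
  writeLines(c("x", "comment", "C 0 0 0"), f)
  expect_error(read_xyz_trajectory(f), "malformed atom count")
  writeLines(c("1", "time = 0.0 fs", "C 0 zz 0"), f)
  expect_error(read_xyz_trajectory(f), "frame 1")
})

test_that("XYZ write/read round trip reproduces coordinates", {
  set.seed(42)
  geoms <- lapply(1:3, function(i) random_geometry(5))
  f <- tempfile(fileext = ".xyz")
  write_xyz_trajectory(f, c(0, 0.1, 0.2), geoms)
  back <- read_xyz_trajectory(f)
  expect_equal(back$times, c(0, 0.1, 0.2))
  for (i in 1:3)
    expect_equal(back$geometries[[i]]$coords, geoms[[i]]$coords,
                 tolerance = 1e-8)
})

test_that("property tables enforce schema, hop flags and populations", {
  tdir <- tempfile("traj"); dir.create(tdir)
  df <- data.frame(traj = 1, time = c(0, 10, 20), State = c(2, 1, 1),
                   Total_Energy = -229.8, S1 = -230, S2 = -229.9,
                   DE21 = c(3, 0.5, 2), Hops_S21 = c(0, 1, 0),
                   Hops_S12 = 0, Pop1 = c(0, 0.5, 0.9),
                   Pop2 = c(1, 0.5, 0.1))
  utils::write.csv(df, file.path(tdir, "properties.csv"), row.names = FALSE)
  p <- read_properties(tdir)
  expect_equal(p$Hops_S21, c(0, 1, 0))
  expect_equal(p$time[p$Hops_S21 == 1], 10)

  bad <- df; bad$State <- NULL
  utils::write.csv(bad, file.path(tdir, "properties.csv"), row.names = FALSE)
  expect_error(read_properties(tdir), "State")
  bad <- df; bad$Hops_S21 <- c(0, 2, 0)
  utils::write.csv(bad, file.path(tdir, "properties.csv"), row.names = FALSE)
  expect_error(read_properties(tdir), "0/1")
  bad <- df; bad$Pop1 <- c(0, 1.7, 0)
  utils::write.csv(bad, file.path(tdir, "properties.csv"), row.names = FALSE)
  expect_error(read_properties(tdir), "outside")
})

test_that("ensemble assembly inner-joins on (traj, time) with tolerance", {
  set.seed(7)
  geoms <- list("1" = list(times = seq(0, 9.9, 0.1) * 1,
                           geometries = replicate(100, random_geometry(3),
                                                  simplify = FALSE)))
  props <- list("1" = data.frame(time = seq(0, 9.9, 0.1) + 1e-8, State = 2,
                                 Total_Energy = 0, S1 = -1,
                                 Hops_S21 = 0, Hops_S12 = 0))
  ens <- assemble_ensemble(geoms, props)
  expect_equal(ens$n_frames, 100)
  # drop one property row -> 99 surviving frames, with a message
  props$"1" <- props$"1"[-50, ]
  expect_message(ens2 <- assemble_ensemble(geoms, props), "dropped")
  expect_equal(ens2$n_frames, 99)
  # nothing matches -> empty-ensemble error
  props$"1"$time <- props$"1"$time + 500
  expect_error(suppressMessages(assemble_ensemble(geoms, props)), "empty")
})

test_that("frame selection honours the time tolerance and reports misses", {
  dir <- make_synth_dir(n_trajs = 2, n_steps = 11, jitter = 0)
  ens <- load_ensemble(dir)
  g <- select_frame(ens, 1, 0.5)
  expect_s3_class(g, "geometry")
  expect_identical(select_frame(ens, 1, 0.5 + 4e-7)$coords, g$coords)
  expect_error(select_frame(ens, 1, 999), "nearest available time")
  expect_error(select_frame(ens, 77, 0.5), "no trajectory")
})

test_that("ingestion is order-independent and counts add up", {
  dir <- make_synth_dir(n_trajs = 3, n_steps = 21)
  ids <- discover_trajectories(dir)
  read_all <- function(order) {
    geoms <- list(); props <- list()
    for (id in order) {
      tdir <- file.path(dir, paste0("TRAJ", id))
      geoms[[as.character(id)]] <- read_xyz_trajectory(file.path(tdir, "dyn.xyz"))
      props[[as.character(id)]] <- read_properties(tdir)
    }
    assemble_ensemble(geoms, props)
  }
  a <- read_all(ids)
  b <- read_all(rev(ids))
  expect_identical(a$index, b$index)
  expect_identical(lapply(a$geometries, `[[`, "coords"),
                   lapply(b$geometries, `[[`, "coords"))
  expect_equal(a$n_frames, 3 * 21)
})

test_that("dataset CSV round trip is the identity to 1e-6", {
  set.seed(9)
  tab <- as_ftable(matrix(rnorm(60), 10, 6))
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(tab, f)
  back <- read_dataset_csv(f)
  expect_equal(names(back), names(tab))
  expect_equal(as.matrix(back), as.matrix(tab), tolerance = 2e-6)
  # header-only file for an empty table
  write_dataset_csv(tab[0, ], f)
  expect_equal(nrow(read_dataset_csv(f)), 0)
  expect_error(write_dataset_csv(tab[, -1], f), "index")
})
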