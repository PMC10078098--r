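test_that("perceive_features finds the four feature classes at the right points", {
  # benzene ring in a plane: one aromatic feature at the centroid
  b <- parse_smiles("c1ccccc1", "benzene")
  ang <- 2 * pi * (0:5) / 6
  b$coords <- cbind(1.39 * cos(ang) + 2, 1.39 * sin(ang) - 1, 0.5)
  f <- perceive_features(b)
  ar <- f[f$ftype == "aromatic", ]
  expect_equal(nrow(ar), 1)
  expect_equal(c(ar$x, ar$y, ar$z), c(2, -1, 0.5), tolerance = 1e-9)

  # methanol: its O is both donor and acceptor at the O position
  m <- parse_smiles("CO", "methanol")
  m$coords <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  fm <- perceive_features(m)
  expect_equal(sort(fm$ftype[abs(fm$x - 1.4) < 1e-9]), c("acceptor", "donor"))

  # n-hexane: one hydrophobic feature at the carbon centroid
  h <- parse_smiles("CCCCCC", "hexane")
  h$coords <- cbind(seq(0, 7.5, by = 1.5), 0, 0)
  fh <- perceive_features(h)
  expect_equal(fh$ftype, "hydrophobic")
  expect_equal(fh$x, mean(seq(0, 7.5, by = 1.5)))

  # missing coordinates is an error
  expect_error(perceive_features(parse_smiles("CCO", "flat")), "coordinates")
})

test_that("min_reference_count implements the ceiling prevalence rule", {
  expect_equal(min_reference_count(20, 0.70), 14L)
  expect_equal(min_reference_count(10, 0.70), 7L)
  expect_equal(min_reference_count(20, 1.0), 20L)
  expect_equal(min_reference_count(3, 0.70), 3L)   # ceiling(2.1)
})

test_that("build_pharmacophore keeps exactly the planted features above threshold", {
  plan <- default_feature_plan()
  plan$prevalence <- c(0.9, 0.75, 0.5, 1.0, 0.8, 0.6)
  ps <- generate_pose_set(plan, n_poses = 20, seed = 21)
  model <- build_pharmacophore(ps$poses, prevalence_threshold = 0.70)
  keep <- plan[plan$prevalence >= 0.70, ]
  expect_equal(nrow(model$features), nrow(keep))
  # each kept planted feature is recovered within the merge radius, with the
  # planted prevalence, and nothing below threshold leaks in
  for (i in seq_len(nrow(keep))) {
    d <- sqrt((model$features$x - keep$x[i])^2 +
              (model$features$y - keep$y[i])^2 +
              (model$features$z - keep$z[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 1.5)
    expect_identical(model$features$ftype[j], keep$ftype[i])
    expect_equal(model$features$prevalence[j], keep$prevalence[i],
                 tolerance = 1e-9)
  }
})

test_that("a feature in 13 of 20 poses is excluded at the 70% threshold", {
  plan <- data.frame(ftype = c("donor", "acceptor"),
                     x = c(0, 10), y = 0, z = 0,
                     prevalence = c(13 / 20, 14 / 20))
  ps <- generate_pose_set(plan, n_poses = 20, seed = 5)
  model <- build_pharmacophore(ps$poses, prevalence_threshold = 0.70)
  expect_equal(nrow(model$features), 1)
  expect_identical(model$features$ftype, "acceptor")
  expect_equal(model$features$prevalence, 0.70)
})

test_that("identical poses give prevalence 1 for every perceived feature", {
  plan <- default_feature_plan()
  plan$prevalence <- rep(1, 6)
  ps <- generate_pose_set(plan, n_poses = 20, seed = 9)
  model <- build_pharmacophore(ps$poses)
  expect_equal(nrow(model$features), 6)
  expect_true(all(model$features$prevalence == 1))
})

test_that("model feature count is non-increasing in the prevalence threshold", {
  ps <- generate_pose_set(seed = 31)
  counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(thr)
    nrow(build_pharmacophore(ps$poses, prevalence_threshold = thr)$features),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("build_pharmacophore is invariant to pose order", {
  ps <- generate_pose_set(seed = 17)
  m1 <- build_pharmacophore(ps$poses)
  m2 <- build_pharmacophore(rev(ps$poses))
  expect_equal(m1$features[order(m1$features$ftype, m1$features$x), ],
               m2$features[order(m2$features$ftype, m2$features$x), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(build_pharmacophore(ps$poses[1]), ">= 2")
})

test_that("match_pharmacophore applies the five-of-six rule", {
  plan <- default_feature_plan()
  ps <- generate_pose_set(plan, n_poses = 20, seed = 2)
  model <- build_pharmacophore(ps$poses)
  expect_equal(nrow(model$features), 6)

  make_candidate <- function(rows) {
    frs <- lapply(rows, function(f) consensusVS:::feature_fragment(
      plan$ftype[f], c(plan$x[f], plan$y[f], plan$z[f]), jitter = 0.05))
    consensusVS:::assemble_pose("cand", frs)
  }
  set.seed(1)
  expect_true(match_pharmacophore(make_candidate(1:6), model)$pass)
  expect_equal(match_pharmacophore(make_candidate(1:6), model)$n_matched, 6L)
  m5 <- match_pharmacophore(make_candidate(1:5), model)
  expect_equal(m5$n_matched, 5L); expect_true(m5$pass)
  m4 <- match_pharmacophore(make_candidate(1:4), model)
  expect_equal(m4$n_matched, 4L); expect_false(m4$pass)
})

test_that("match count is invariant under joint rigid transform of pose and model", {
  plan <- default_feature_plan()
  ps <- generate_pose_set(plan, n_poses = 20, seed = 23)
  model <- build_pharmacophore(ps$poses)
  set.seed(4)
  pose <- ps$poses[[1]]
  base <- match_pharmacophore(pose, model)$n_matched
  for (seed in 1:10) {
    tr <- random_rigid_transform(seed)
    pose_t <- pose
    pose_t$coords <- apply_rigid(pose$coords, tr)
    model_t <- model
    xyz <- apply_rigid(as.matrix(model$features[, c("x", "y", "z")]), tr)
    model_t$features$x <- xyz[, 1]
    model_t$features$y <- xyz[, 2]
    model_t$features$z <- xyz[, 3]
    expect_equal(match_pharmacophore(pose_t, model_t)$n_matched, base)
  }
})

test_that("pharmacophore JSON serialization round-trips", {
  model <- build_pharmacophore(generate_pose_set(seed = 3)$poses)
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(model, path)
  back <- read_pharmacophore(path)
  expect_equal(back$n_references, model$n_references)
  expect_equal(back$min_match, model$min_match)
  expect_equal(back$features, model$features, tolerance = 1e-12)
})
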