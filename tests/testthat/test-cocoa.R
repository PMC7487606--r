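small_sim <- function(...) {
  default_planted_fixture(n_samples = 30, n_background_loci = 2000,
                          n_planted_regions = 60, n_decoy_sets = 6,
                          decoy_regions_per_set = 60, genome_length = 2e6,
                          seed = 17, ...)
}

test_that("the fitted object recovers the planted set end to end", {
  sim <- small_sim()
  fit <- cocoa(sim$signal, sim$targets, sim$db, min_covered_regions = 1,
               n_perm = 60, seed = 2)
  expect_s3_class(fit, "cocoa")
  top <- fit$results[fit$results$rank == 1, ]
  expect_equal(top$region_set, "planted")
  expect_lt(top$q_value, 0.05)
  expect_true(all(fit$results$p_value >= 0 & fit$results$p_value <= 1))
  expect_true(all(fit$results$q_value >= fit$results$p_value))
  expect_equal(fit$metric, "covariance")   # auto for nucleotide signal

  # methods
  expect_output(print(fit), "covariance")
  s <- summary(fit)
  expect_equal(s$top$region_set[1], "planted")
  cf <- coef(fit)
  expect_equal(dim(cf), c(7L, 1L))
  expect_equal(unname(cf["planted", 1]), top$score)
})

test_that("fixed seeds make the whole inference byte-identical", {
  sim <- small_sim()
  f1 <- cocoa(sim$signal, sim$targets, sim$db, min_covered_regions = 1,
              n_perm = 25, seed = 9)
  f2 <- cocoa(sim$signal, sim$targets, sim$db, min_covered_regions = 1,
              n_perm = 25, seed = 9)
  expect_identical(f1$results, f2$results)
  expect_identical(f1$null$scores, f2$null$scores)
})

test_that("precomputed FCS reproduces the two-step ranking", {
  sim <- small_sim()
  fit <- cocoa(sim$signal, sim$targets, sim$db, min_covered_regions = 1,
               n_perm = 0)
  fcs <- compute_fcs(sim$signal, sim$targets, "covariance")
  fit2 <- suppressMessages(
    cocoa(NULL, region_db = sim$db, fcs = fcs, min_covered_regions = 1))
  expect_equal(fit2$results$region_set, fit$results$region_set)
  expect_equal(fit2$results$score, fit$results$score)
  expect_equal(fit2$results$rank, fit$results$rank)
  expect_true(all(is.na(fit2$results$p_value)))
})

test_that("unsupervised runs derive PCA targets internally", {
  sim <- small_sim()
  fit <- cocoa(sim$signal, targets = NULL, region_db = sim$db,
               min_covered_regions = 1, n_perm = 0, n_pcs = 2)
  expect_equal(sort(unique(fit$results$target)), c("PC1", "PC2"))
  # the planted factor dominates variance, so PC1 should find the planted set
  pc1 <- fit$results[fit$results$target == "PC1", ]
  expect_equal(pc1$region_set[pc1$rank == 1], "planted")
})

test_that("mean and median scoring rank heterogeneous sets concordantly", {
  # sets whose true scores genuinely differ: mixture sets holding 0..20
  # planted regions topped up with random regions (among statistically
  # identical sets, ranks are exchangeable noise and no scoring statistic
  # could order them consistently)
  sim <- small_sim()
  fcs <- compute_fcs(sim$signal, sim$targets, "covariance")
  set.seed(64)
  pr <- sim$planted_set$regions
  sets <- lapply(0:20, function(k) {
    idx <- if (k > 0) sample.int(nrow(pr), k) else integer()
    s <- sample.int(2e6 - 500, 20 - k)
    region_set(sprintf("mix_%02d", k),
               rbind(pr[idx, ],
                     data.frame(chrom = rep("chr1", 20 - k), start = s,
                                end = s + 500)))
  })
  db <- region_set_db(sets)
  r_mean <- run_cocoa(fcs, db, stat = "mean", min_covered_regions = 1)
  r_med <- run_cocoa(fcs, db, stat = "median", min_covered_regions = 1)
  m <- merge(r_mean[c("region_set", "score")],
             r_med[c("region_set", "score")], by = "region_set")
  expect_gt(cor(m$score.x, m$score.y, method = "spearman"), 0.9)
})

test_that("sample-id mismatches are rejected with offenders named", {
  sim <- small_sim()
  bad <- sim$targets
  rownames(bad$values)[1] <- "SOMEONE_ELSE"
  expect_error(cocoa(sim$signal, bad, sim$db), "SOMEONE_ELSE")
})

test_that("the file pipeline runs from a simulated directory and logs provenance", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  out <- file.path(dir, "out")
  fit <- cocoa_pipeline(
    signal_path = file.path(dir, "signal.tsv"),
    regiondb_dir = file.path(dir, "regiondb"),
    out_dir = out,
    targets_path = file.path(dir, "targets.tsv"),
    min_covered_regions = 1, n_perm = 20, seed = 5)
  expect_true(all(file.exists(file.path(out, c("results.tsv", "nulls.tsv",
                                               "run.log",
                                               "resolved_config.tsv")))))
  tab <- read.delim(file.path(out, "results.tsv"))
  expect_equal(tab$region_set[tab$rank == 1], "planted")
  expect_equal(nrow(tab), 7L)
  expect_true(all(c("p_value", "q_value", "p_source", "rank") %in% names(tab)))
  nulls <- read.delim(file.path(out, "nulls.tsv"))
  expect_equal(sort(names(nulls)),
               sort(c("region_set", "target", "shape", "scale", "p_source")))
  # FCS pass-through route gives the identical ranking
  fcs_path <- file.path(dir, "fcs.tsv")
  fcs <- compute_fcs(sim$signal, sim$targets, "covariance")
  write_signal_matrix(
    signal_matrix(fcs$coords,
                  matrix(fcs$values, ncol = 1,
                         dimnames = list(NULL, "latent_factor"))),
    fcs_path)
  out2 <- file.path(dir, "out2")
  cocoa_pipeline(signal_path = NULL, fcs_path = fcs_path,
                 regiondb_dir = file.path(dir, "regiondb"), out_dir = out2,
                 min_covered_regions = 1, n_perm = 0)
  tab2 <- read.delim(file.path(out2, "results.tsv"))
  expect_equal(tab2$region_set, tab$region_set)
  expect_equal(tab2$score, tab$score, tolerance = 1e-10)
})
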