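test_that("nucleotide scorer nests the stat over loci then regions", {
  # region A holds FCS {0.2, 0.4}, region B holds {0.6}
  coords <- point_loci(c(10, 15, 105))
  fcs <- make_fcs(coords, c(0.2, 0.4, 0.6))
  rs <- region_set("x", data.frame(chrom = "chr1", start = c(0, 100),
                                   end = c(50, 150)))
  got <- score_region_set(fcs, rs, stat = "mean")
  expect_equal(got$score, 0.45)
  expect_equal(got$n_regions_covered, 2L)
  expect_equal(got$n_features, 3L)

  # absolute values are taken before any averaging
  fcs2 <- make_fcs(coords, c(-0.2, 0.4, 0.6))
  expect_equal(score_region_set(fcs2, rs, use_abs = TRUE)$score, 0.45)
  expect_equal(score_region_set(fcs2, rs, use_abs = FALSE)$score, 0.35)

  # uncovered set -> missing score, not an error
  far <- region_set("far", data.frame(chrom = "chr9", start = 0, end = 10))
  got <- suppressWarnings(score_region_set(fcs, far))
  expect_true(is.na(got$score))
  expect_equal(got$n_regions_covered, 0L)
})

test_that("weighted scorer applies overlap-proportion weights", {
  # FCS 0.5 covers 100% of r1; FCS 1.0 covers 50% of r2 -> 2/3
  coords <- data.frame(chrom = "chr1", start = c(0, 100), end = c(10, 105))
  fcs <- make_fcs(coords, c(0.5, 1.0), resolution = "region")
  rs <- region_set("r", data.frame(chrom = "chr1", start = c(0, 100),
                                   end = c(10, 110)))
  expect_equal(score_region_set(fcs, rs)$score, 2 / 3)

  # one data region exactly equal to one set region -> its own FCS
  fcs1 <- make_fcs(data.frame(chrom = "chr1", start = 20, end = 40), 0.8,
                   resolution = "region")
  rs1 <- region_set("r1", data.frame(chrom = "chr1", start = 20, end = 40))
  expect_equal(score_region_set(fcs1, rs1)$score, 0.8)
})

test_that("both scorers match quadratic-scan oracles on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n_loci <- sample(5:40, 1)
    n_reg <- sample(2:10, 1)
    pos <- sample.int(900, n_loci)
    coords_nt <- point_loci(pos)
    fvec <- rnorm(n_loci)
    fvec[sample.int(n_loci, n_loci %/% 8)] <- NA
    regions <- random_regions(n_reg)
    rs <- region_set("r", regions)
    for (stat in c("mean", "median")) {
      got <- score_region_set(make_fcs(coords_nt, fvec), rs, stat = stat)
      expect_equal(got$score,
                   oracle_score_nucleotide(coords_nt, fvec, regions, stat),
                   tolerance = 1e-12)
    }
    coords_rg <- random_regions(n_loci)
    gotw <- score_region_set(make_fcs(coords_rg, fvec, resolution = "region"),
                             rs)
    expect_equal(gotw$score, oracle_score_weighted(coords_rg, fvec, regions),
                 tolerance = 1e-12)
  }
})

test_that("scorers are convex combinations and order-invariant", {
  set.seed(55)
  pos <- sample.int(500, 30)
  fvec <- rnorm(30)
  regions <- random_regions(6)
  rs <- region_set("r", regions)
  fcs <- make_fcs(point_loci(pos), fvec)
  sc <- score_region_set(fcs, rs)$score
  idx <- oracle_overlaps(point_loci(pos), regions)
  contributing <- abs(fvec[unique(idx$query)])
  expect_gte(sc, min(contributing))
  expect_lte(sc, max(contributing))

  # permuting locus storage order changes nothing
  ord <- sample.int(30)
  expect_equal(score_region_set(make_fcs(point_loci(pos[ord]), fvec[ord]),
                                rs)$score, sc)
  # permuting region order changes nothing
  rs2 <- region_set("r", regions[sample.int(6), ])
  expect_equal(score_region_set(fcs, rs2)$score, sc)
})

test_that("degenerate reductions recover the plain stat", {
  set.seed(77)
  pos <- (1:10) * 100
  fvec <- rnorm(10)
  # every region contains exactly one locus -> plain stat of |FCS|
  rs <- region_set("one", data.frame(chrom = "chr1", start = pos - 2,
                                     end = pos + 2))
  fcs <- make_fcs(point_loci(pos), fvec)
  expect_equal(score_region_set(fcs, rs, stat = "mean")$score,
               mean(abs(fvec)))
  expect_equal(score_region_set(fcs, rs, stat = "median")$score,
               median(abs(fvec)))
  # weighted scorer with all weights equal -> plain mean
  dreg <- data.frame(chrom = "chr1", start = pos, end = pos + 10)
  rsw <- region_set("w", data.frame(chrom = "chr1", start = pos,
                                    end = pos + 20))
  fcsw <- make_fcs(dreg, fvec, resolution = "region")
  expect_equal(score_region_set(fcsw, rsw)$score, mean(abs(fvec)))
})

test_that("run_cocoa filters by coverage and ranks deterministically", {
  coords <- point_loci((1:20) * 10)
  fvec <- rep(0.3, 20)
  fcs <- make_fcs(coords, fvec)
  sets <- list(
    region_set("a", data.frame(chrom = "chr1", start = c(0, 100),
                               end = c(50, 150))),
    region_set("b", data.frame(chrom = "chr1", start = 0, end = 200)),
    region_set("empty", data.frame(chrom = "chr5", start = 0, end = 99))
  )
  db <- region_set_db(sets)
  res <- suppressMessages(suppressWarnings(run_cocoa(fcs, db, min_covered_regions = 1)))
  expect_equal(sort(unique(res$region_set)), c("a", "b"))
  # constant FCS field: every surviving set scores exactly the constant
  expect_equal(res$score, rep(0.3, nrow(res)))
  # equal scores -> name-ascending tie-break
  expect_equal(res$region_set[res$rank == 1], "a")
  suppressWarnings(expect_warning(
    out <- suppressMessages(run_cocoa(fcs, db, min_covered_regions = 1000)),
    "filtered"))
  expect_equal(nrow(out), 0L)
})

test_that("per-sample region-set signal average weights regions equally", {
  # one region, loci {0.2, 0.6} -> 0.4
  coords <- point_loci(c(5, 8))
  vals <- matrix(c(0.2, 0.6), 2, 1, dimnames = list(NULL, "s"))
  sm <- signal_matrix(coords, vals)
  rs <- region_set("r", data.frame(chrom = "chr1", start = 0, end = 10))
  expect_equal(unname(region_set_signal_average(sm, rs)), 0.4)

  # region with 10 loci and region with 1 locus weigh equally
  coords2 <- point_loci(c(1:10, 100))
  vals2 <- matrix(c(rep(0.4, 10), 0.8), 11, 1, dimnames = list(NULL, "s"))
  sm2 <- signal_matrix(coords2, vals2)
  rs2 <- region_set("r", data.frame(chrom = "chr1", start = c(0, 95),
                                    end = c(50, 105)))
  expect_equal(unname(region_set_signal_average(sm2, rs2)), 0.6)

  set.seed(31)
  coords3 <- point_loci(sample.int(800, 40))
  vals3 <- matrix(runif(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  vals3[cbind(sample.int(40, 5), sample(1:3, 5, TRUE))] <- NA
  sm3 <- signal_matrix(coords3, vals3)
  regions3 <- random_regions(7)
  expect_equal(unname(region_set_signal_average(sm3, region_set("r", regions3))),
               oracle_signal_average(coords3, vals3, regions3),
               tolerance = 1e-12)

  none <- region_set("n", data.frame(chrom = "chrX", start = 0, end = 5))
  expect_true(all(is.na(suppressWarnings(region_set_signal_average(sm3, none)))))
})
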