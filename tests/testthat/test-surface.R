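test_that("an isolated atom's ASA equals the analytic expanded-sphere area", {
  asa <- shrake_rupley_asa(matrix(0, 1, 3), radii = 1.7)
  expect_equal(asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  # probe-radius dependence
  asa0 <- shrake_rupley_asa(matrix(0, 1, 3), radii = 1.7, probe_radius = 0)
  expect_equal(asa0, 4 * pi * 1.7^2, tolerance = 1e-12)
})

test_that("far-apart atoms are mutually unoccluded; their ASAs are exactly additive", {
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0))
  r <- c(1.7, 1.52, 1.8)
  asa <- shrake_rupley_asa(xyz, r)
  expect_equal(asa, 4 * pi * (r + 1.4)^2, tolerance = 1e-12)
})

test_that("two-sphere overlap matches the spherical-cap closed form and a dense oracle", {
  r <- 1.7; probe <- 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    asa <- shrake_rupley_asa(xyz, c(r, r), probe)
    analytic <- two_sphere_asa_analytic(r, probe, d)
    expect_equal(asa[1], analytic, tolerance = 0.01)
    expect_equal(asa[2], analytic, tolerance = 0.01)
    mc <- asa_montecarlo(xyz, c(r, r), probe)
    expect_equal(asa[1], mc[1], tolerance = 0.01)
  }
})

test_that("ASA converges with point density and is rigid-motion invariant", {
  set.seed(51)
  xyz <- matrix(rnorm(15, sd = 2), ncol = 3)
  r <- runif(5, 1.5, 1.8)
  a1 <- sum(shrake_rupley_asa(xyz, r, n_points = 960L))
  a2 <- sum(shrake_rupley_asa(xyz, r, n_points = 1920L))
  expect_lt(abs(a1 - a2) / a2, 0.005)

  # translation + rotation
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(xyz %*% rot, 2, c(5, -3, 11), "+")
  b1 <- shrake_rupley_asa(xyz, r)
  b2 <- shrake_rupley_asa(moved, r)
  expect_equal(b1, b2, tolerance = 1e-6)

  expect_error(shrake_rupley_asa(rbind(c(0, 0, 0), c(0, 0, 0)), c(1.7, 1.7)),
               "coincident")
})

test_that("tyrosine subset ASA is monotone in subset size and errors on bad input", {
  st <- simulate_structure(2, buried_fraction = 0, seed = 7)
  a_oh <- tyrosine_subset_asa(st$atoms, 1, "OH_ONLY")
  a_ipso <- tyrosine_subset_asa(st$atoms, 1, "OH_IPSO_ORTHO")
  a_ring <- tyrosine_subset_asa(st$atoms, 1, "FULL_RING")
  expect_lte(a_oh, a_ipso)
  expect_lte(a_ipso, a_ring)
  expect_gt(a_oh, 5)

  expect_error(tyrosine_subset_asa(st$atoms, 99, "OH_ONLY"), "no residue")
  broken <- st$atoms[!(st$atoms$resno == 1 & st$atoms$elety == "OH"), ]
  expect_error(tyrosine_subset_asa(broken, 1, "OH_ONLY"), "missing atom")
})

test_that("PDB round-trip preserves structure well enough for identical ASA calls", {
  st <- simulate_structure(2, buried_fraction = 0.5, seed = 8)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_structure_pdb(st$atoms, tmp)
  back <- read_structure_pdb(tmp)
  expect_equal(nrow(back), nrow(st$atoms))
  for (p in st$ground_truth$position) {
    expect_equal(tyrosine_subset_asa(back, p, "OH_ONLY"),
                 tyrosine_subset_asa(st$atoms, p, "OH_ONLY"),
                 tolerance = 1e-3)
  }
})

test_that("max aggregation over structures keeps the largest exposure and tracks unresolved sites", {
  per <- list(s1 = c(Y10 = 3.0, Y20 = 1.0),
              s2 = c(Y10 = 7.5, Y30 = 2.0),
              s3 = c(Y10 = 0.0))
  agg <- aggregate_max_asa(per)
  expect_equal(agg$asa[["Y10"]], 7.5)
  expect_equal(agg$asa[["Y20"]], 1.0)
  expect_length(agg$unresolved, 0L)

  one <- aggregate_max_asa(per["s1"])
  expect_equal(one$asa, per$s1)

  agg2 <- aggregate_max_asa(per, all_sites = c("Y10", "Y20", "Y30", "Y40"))
  expect_equal(agg2$unresolved, "Y40")
})

test_that("composite false-positive scoring reproduces the worked rules", {
  # four tagged below 5, two tagged above 5 but below the smallest untagged
  asa <- c(Y1 = 2, Y2 = 3, Y3 = 1, Y4 = 4, Y5 = 8, Y6 = 9, Y7 = 60)
  sc <- score_exposure(c("Y1", "Y2", "Y3", "Y4", "Y5", "Y6"), asa)
  expect_equal(sc$fp_score, 42L)
  expect_true(sc$is_false_positive)
  expect_equal(sc$n_below_threshold, 4L)
  expect_equal(sc$n_below_min_untagged, 2L)

  # all tagged well-exposed and above the smallest untagged: score 0
  asa2 <- c(Y1 = 30, Y2 = 40, Y3 = 10)
  sc2 <- score_exposure(c("Y1", "Y2"), asa2)
  expect_equal(sc2$fp_score, 0L)
  expect_false(sc2$is_false_positive)

  # one buried tagged residue scores 10 (not also +1) and flags the FN
  asa3 <- c(Y1 = 4.9, Y2 = 50)
  sc3 <- score_exposure("Y1", asa3)
  expect_equal(sc3$fp_score, 10L)
  expect_false(sc3$is_false_positive)  # final set needs score > 10
  expect_equal(sc3$fn_flags, "Y2")

  # no untagged tyrosines: the +1 clause is skipped
  sc4 <- score_exposure(c("Y1", "Y2"), c(Y1 = 6, Y2 = 2))
  expect_equal(sc4$fp_score, 10L)
  expect_length(sc4$fn_flags, 0L)

  expect_error(score_exposure("Y9", asa3), "absent")
})

test_that("fp_score equals a naive per-residue recount on random fixtures", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    asa <- setNames(runif(n, 0, 30), paste0("Y", seq_len(n)))
    tagged <- names(asa)[runif(n) < 0.5]
    if (length(tagged) == 0) tagged <- names(asa)[1]
    sc <- score_exposure(tagged, asa, threshold = 5)
    untagged <- setdiff(names(asa), tagged)
    naive <- 0L
    for (t in tagged) {
      if (asa[[t]] < 5) naive <- naive + 10L
      else if (length(untagged) > 0 && asa[[t]] < min(asa[untagged]))
        naive <- naive + 1L
    }
    expect_equal(sc$fp_score, naive)
  }
})
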