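test_that("PC errors count opposing homozygotes, symmetrically", {
  expect_equal(pc_errors(c(2L), c(0L)), 1)      # BB child, AA parent
  expect_equal(pc_errors(c(0L, 1L, 2L, NA), c(2L, 0L, 2L, 0L)), 1)
  x <- sample(c(0:2, NA), 50, TRUE)
  expect_equal(pc_errors(x, x), 0)
  y <- sample(c(0:2, NA), 50, TRUE)
  expect_equal(pc_errors(x, y), pc_errors(y, x))
})

test_that("random-pair PC error count matches the closed form", {
  # two unrelated HWE individuals, B-allele frequency q: opposing
  # homozygotes occur at rate 2 p^2 q^2 per marker
  q <- 0.3; p <- 1 - q; n <- 1000
  expected <- 2 * p^2 * q^2 * n
  set.seed(12)
  draws <- replicate(200, {
    a <- rbinom(n, 2, q); b <- rbinom(n, 2, q)
    pc_errors(a, b)
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("PPC feasibility equals brute-force transmission enumeration", {
  for (gm_ in 0:2) for (gf_ in 0:2) for (gc_ in 0:2) {
    impl <- ppc_errors(gc_, gm_, gf_)
    expect_equal(impl, as.integer(!oracle_trio_ok(gm_, gf_, gc_)),
                 info = paste(gm_, gf_, gc_))
  }
  # named examples
  expect_equal(ppc_errors(1L, 0L, 0L), 1)   # AA x AA -> AB
  expect_equal(pc_errors(1L, 0L), 0)
  expect_equal(ppc_errors(0L, 0L, 2L), 1)   # AA x BB -> AA
  for (gc_ in 0:2) expect_equal(ppc_errors(gc_, 1L, 1L), 0)  # AB x AB
})

test_that("ppc >= max(pc) over all 27 single-marker triplets", {
  for (gm_ in 0:2) for (gf_ in 0:2) for (gc_ in 0:2)
    expect_gte(ppc_errors(gc_, gm_, gf_),
               max(pc_errors(gc_, gm_), pc_errors(gc_, gf_)))
})

test_that("PC threshold calibration separates true pairs from random pairs", {
  sim <- simulate_population(sim_config(seed = 14, markers_per_lg = 400,
                                        random_miscall = 0.01))
  cal <- calibrate_pc_threshold(sim$gm, sim$ped, seed = 3)
  # known duos sit below, random pairs above; the only leakage allowed
  # is the close-relative tail of the random set (the pedigree is
  # inbred, so "random non-PC" includes full sibs and grandparents)
  expect_gte(mean(cal$pc_counts < cal$threshold), 0.99)
  expect_gte(mean(cal$random_counts >= cal$threshold), 0.99)
  expect_lt(median(cal$pc_counts), median(cal$random_counts) / 4)
  # determinism under a fixed seed
  cal2 <- calibrate_pc_threshold(sim$gm, sim$ped, seed = 3)
  expect_identical(cal$threshold, cal2$threshold)
  expect_identical(cal$random_counts, cal2$random_counts)
})

test_that("error-free data give an all-zero PC distribution and threshold >= 1", {
  sim <- simulate_population(sim_config(seed = 15, missing_rate = 0))
  cal <- calibrate_pc_threshold(sim$gm, sim$ped, seed = 2)
  expect_true(all(cal$pc_counts == 0))
  expect_gte(cal$threshold, 1)
})

test_that("PPC threshold is 110% of the observed maximum, rounded up", {
  expect_equal(calibrate_ppc_threshold(c(3, 10, 7)), 11)
  expect_equal(calibrate_ppc_threshold(0), 0)
  expect_equal(calibrate_ppc_threshold(19), 21)
  expect_error(calibrate_ppc_threshold(integer(0)), "no confirmed")
})

test_that("parent search ranks the hidden true parent first", {
  sim <- simulate_population(sim_config(seed = 16, random_miscall = 0.005))
  cal <- calibrate_pc_threshold(sim$gm, sim$ped, seed = 4)
  kid <- "G2_1_1"
  true_mother <- sim$ped$mother[match(kid, sim$ped$id)]
  out <- search_parents(sim$gm, kid, individuals(sim$gm), cal$threshold,
                        ped = sim$ped,
                        generation = pedigree_generation(sim$ped))
  expect_equal(out$candidate[1], true_mother)
  expect_lt(out$error_count[1], cal$threshold)
  # full sibs can pass the PC screen and must be flagged, not confirmed
  if (any(out$possible_full_sib))
    expect_false(out$candidate[1] %in% out$candidate[out$possible_full_sib])
  # no candidate passes -> empty frame
  none <- search_parents(sim$gm, kid, individuals(sim$gm), 0, ped = sim$ped)
  expect_equal(nrow(none), 0)
})

test_that("grandparent AB+AA-AA test counts missing obligate alleles", {
  # child AB, known parent AA, grandparents AA & AA -> obligate B absent
  expect_equal(grandparent_test(1L, 0L, 0L, 0L), 1)
  expect_equal(grandparent_test(1L, 0L, 1L, 0L), 0)   # B available in gp1
  # child homozygous: the obligate allele is fixed regardless of parent
  expect_equal(grandparent_test(0L, 1L, 2L, 2L), 1)   # A absent from both
  # simulated true grandparent pair scores below random pairs
  sim <- simulate_population(sim_config(seed = 17))
  ped <- sim$ped; dos <- sim$gm$calls
  kid <- "G2_1_1"
  mo <- ped$mother[match(kid, ped$id)]
  fa <- ped$father[match(kid, ped$id)]
  gp <- c(ped$mother[match(mo, ped$id)], ped$father[match(mo, ped$id)])
  true_cnt <- grandparent_test(dos[, kid], dos[, fa], dos[, gp[1]],
                               dos[, gp[2]])
  set.seed(18)
  founders <- ped$id[is.na(ped$mother)]
  rnd <- replicate(50, {
    pr <- sample(founders, 2)
    grandparent_test(dos[, kid], dos[, fa], dos[, pr[1]], dos[, pr[2]])
  })
  expect_lte(true_cnt, min(rnd))
})

test_that("verify_parentage issues verdicts against calibrated thresholds", {
  sim <- simulate_population(default_scenario(seed = 42))
  reg <- sim$truth$registry
  excl <- reg$individual[reg$type %in% c("triploid", "bad_quality")]
  gm <- drop_from_matrix(sim$gm, individuals = excl)
  cal <- calibrate_pc_threshold(gm, sim$ped, seed = 5)
  ver <- verify_parentage(gm, sim$ped, cal$threshold)
  wrong <- reg$individual[reg$type == "wrong_parent"]
  pc <- ver$verdicts[ver$verdicts$relation != "PPC", ]
  expect_true(all(wrong %in% pc$child[pc$verdict == "rejected"]))
  # wrong records reject decisively (error counts far above threshold);
  # at most a rare borderline true duo may land just over the line
  rej <- pc[pc$verdict == "rejected", ]
  expect_true(all(rej$error_count[rej$child %in% wrong] >
                    3 * cal$threshold))
  other <- rej[!(rej$child %in% wrong), ]
  expect_lte(nrow(other), ceiling(0.01 * nrow(pc)))
  if (nrow(other)) expect_true(all(other$error_count < 1.5 * cal$threshold))
  # ungenotyped parties untestable
  ped2 <- sim$ped
  ped2$mother[match("G1_1_1", ped2$id)] <- "GHOST"
  ped2 <- pedigree(ped2$id, ped2$mother, ped2$father, ped2$selected)
  ver2 <- verify_parentage(gm, ped2, cal$threshold)
  v <- ver2$verdicts
  expect_equal(v$verdict[v$child == "G1_1_1" & v$relation == "PC_mother"],
               "untestable")
})
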