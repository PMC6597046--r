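test_that("trio logic forces slots from homozygous configurations", {
  fam <- make_family(4, rep("m", 40), seed = 41)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  # mother het / father hom-AA everywhere: every paternal slot is A
  kids <- paste0("K", 1:4)
  expect_true(all(hm$pat[, kids] == "A"))
  # maternal slots equal the simulated maternal gamete at every marker
  for (j in seq_along(kids)) {
    truth <- ifelse(fam$truth$hap_m[, j] == 1L, "B", "A")
    expect_equal(unname(hm$mat[, kids[j]]), unname(truth))
  }
})

test_that("fully informative families phase to generator truth everywhere", {
  set.seed(43)
  pattern <- sample(c("m", "f", "b"), 120, TRUE)
  fam <- make_family(6, pattern, seed = 44)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  kids <- paste0("K", 1:6)
  pm <- (hm$mat[, kids] == "B") + 0L
  pp <- (hm$pat[, kids] == "B") + 0L
  expect_false(anyNA(pm)); expect_false(anyNA(pp))
  expect_equal(unname(pm), unname(fam$truth$hap_m), ignore_attr = TRUE)
  expect_equal(unname(pp), unname(fam$truth$hap_p), ignore_attr = TRUE)
})

test_that("uninformative double-het sites yield unknowns, never wrong calls", {
  set.seed(45)
  pattern <- sample(c("m", "f", "b", "u"), 150, TRUE,
                    prob = c(.27, .27, .26, .20))
  fam <- make_family(6, pattern, seed = 46)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  kids <- paste0("K", 1:6)
  pm <- (hm$mat[, kids] == "B") + 0L
  ok <- !is.na(pm)
  expect_equal(sum(pm[ok] != fam$truth$hap_m[ok]), 0)
  pp <- (hm$pat[, kids] == "B") + 0L
  okp <- !is.na(pp)
  expect_equal(sum(pp[okp] != fam$truth$hap_p[okp]), 0)
  # unknowns are confined to double-het configurations
  amb <- which(is.na(pm), arr.ind = TRUE)
  if (nrow(amb)) expect_true(all(pattern[amb[, 1]] == "u"))
})

test_that("recombination events bracket true crossovers; none invented", {
  fam <- make_family(8, rep("m", 200), seed = 47)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  ev <- detect_recombinations(hm)
  ev <- ev[ev$side == "mat", ]
  for (i in seq_len(nrow(ev))) {
    tr <- fam$truth$meioses[[paste(ev$child[i], "mat")]][["LG1"]]
    expect_true(any(tr$pos >= ev$cm_left[i] & tr$pos <= ev$cm_right[i]))
  }
  # per-meiosis count never exceeds truth; no-crossover meioses empty
  for (k in paste0("K", 1:8)) {
    tr <- fam$truth$meioses[[paste(k, "mat")]][["LG1"]]
    expect_lte(sum(ev$child == k), length(tr$pos))
    if (length(tr$pos) == 0) expect_equal(sum(ev$child == k), 0)
  }
})

test_that("double recombinations respect the window and singleton rule", {
  ev <- data.frame(parent = "P", child = "C", side = "mat",
                   linkage_group = "LG1",
                   left_marker = c("M10", "M14"), right_marker = c("M11", "M15"),
                   cm_left = c(10, 15), cm_right = c(11, 16),
                   from_origin = c(1L, 2L), to_origin = c(2L, 1L),
                   inf_left = c(10, 14), inf_right = c(11, 15))
  dr <- detect_double_recomb(ev, window_cm = 10)   # deviant span 4 cM
  expect_equal(nrow(dr), 1)
  expect_equal(dr$span_cm, 4)
  expect_equal(dr$n_markers, 4)   # informative markers M11..M14
  expect_false(dr$is_singleton)
  ev2 <- ev; ev2$cm_left[2] <- 26; ev2$cm_right[2] <- 27
  expect_equal(nrow(detect_double_recomb(ev2, 10)), 0)  # 15 cM apart
  ev3 <- ev; ev3[2, c("left_marker", "right_marker")] <- c("M11", "M12")
  ev3$cm_left[2] <- 11; ev3$cm_right[2] <- 12
  ev3$inf_left[2] <- 11; ev3$inf_right[2] <- 12
  dr3 <- detect_double_recomb(ev3, 10)
  expect_true(dr3$is_singleton)
  expect_equal(dr3$marker, "M11")
})

test_that("an injected single-marker miscall appears as a singleton there", {
  fam <- make_family(8, rep("m", 120), seed = 48)
  # flip one child's heterozygous call to the opposite homozygote-free
  # het pattern: make child K1 hom at a mid marker where it was het
  k <- 60
  mk <- markers(fam$gm)[k]
  old <- fam$gm$calls[mk, "K1"]
  gm2 <- edit_calls(fam$gm, mk, "K1", 1L - old, reason = "inject")
  hm <- phase_pedigree(gm2, fam$ped, fam$map)
  drs <- detect_double_recomb(detect_recombinations(hm), 10)
  hit <- drs[drs$child == "K1" & drs$is_singleton, ]
  expect_true(mk %in% hit$marker)
})

test_that("cause classification separates clustering, map and isolated", {
  sim <- simulate_population(default_scenario(seed = 31))
  qc <- sample_qc(sim$baf, sim$map)
  gm <- drop_from_matrix(sim$gm, individuals = qc$individual[qc$exclude])
  reg <- sim$truth$registry
  hm <- phase_pedigree(gm, sim$ped, sim$map)
  drs <- detect_double_recomb(detect_recombinations(hm), 10)
  causes <- classify_dr_causes(drs, gm, sim$ped, anomalies = hm$anomalies)
  shift <- reg$marker[reg$type == "cluster_shift"]
  called <- causes$marker[causes$cause == "clustering"]
  expect_gte(mean(shift %in% called), 0.75)  # the rest are caught upstream
  # the worklist leads with shared causes
  expect_true(all(which(causes$cause != "isolated") <
                    min(which(causes$cause == "isolated"))))
})

test_that("a marker stored at the wrong position is a map suspect", {
  sim <- simulate_population(sim_config(seed = 32, missing_rate = 0,
                                        n_linkage_groups = 2,
                                        markers_per_lg = 100))
  map2 <- sim$map
  victim <- map2$marker[match("LG1", map2$linkage_group) + 50]
  i <- match(victim, map2$marker)
  true_cm <- map2$cm[i]
  map2$cm[i] <- true_cm + 40
  map2 <- genetic_map(map2$marker, map2$linkage_group, map2$cm, map2$bp)
  hm <- phase_pedigree(sim$gm, sim$ped, map2)
  drs <- detect_double_recomb(detect_recombinations(hm), 10)
  causes <- classify_dr_causes(drs, sim$gm, sim$ped,
                               anomalies = hm$anomalies)
  expect_equal(causes$cause[causes$marker == victim], "map")
  ## moving it back is accepted; keeping it in place is not
  mv <- evaluate_map_move(sim$gm, sim$ped, map2, victim, true_cm)
  expect_true(mv$accept)
  expect_lt(mv$dr_after, mv$dr_before)
  stay <- evaluate_map_move(sim$gm, sim$ped, map2, victim, true_cm + 40)
  expect_false(stay$accept)
  expect_error(evaluate_map_move(sim$gm, sim$ped, map2, victim, 1e4),
               "off linkage group")
})

test_that("family-wide phase conflicts blank the recombinant sibs only", {
  # fabricated diagnostic state: parent P, six informative sibs, five
  # sharing a singleton at the pivot, one (K6) carrying the genuine
  # recombination
  kids <- paste0("K", 1:6)
  ped <- pedigree(c("P", "Q", kids), mother = c(NA, NA, rep("P", 6)),
                  father = c(NA, NA, rep("Q", 6)))
  mk <- paste0("M", 1:5)
  dos <- matrix(1L, 5, 8, dimnames = list(mk, c("P", "Q", kids)))
  gm <- dosage_gm(dos)
  origin <- matrix(NA_integer_, 5, 8, dimnames = list(mk, c("P", "Q", kids)))
  origin[, kids[1:5]] <- 1L
  origin["M3", kids[1:5]] <- 2L            # shared singleton at the pivot
  origin[, "K6"] <- 1L                     # informative, no singleton
  hm <- structure(list(mat = matrix(NA_character_, 5, 8,
                                    dimnames = dimnames(origin)),
                       pat = matrix(NA_character_, 5, 8,
                                    dimnames = dimnames(origin)),
                       origin_mat = origin,
                       origin_pat = origin * NA_integer_,
                       anomalies = data.frame(), ped = ped,
                       map = simple_map(mk)),
                  class = "homolog_matrix")
  drs <- data.frame(parent = "P", child = kids[1:5], side = "mat",
                    linkage_group = "LG1", marker_first = "M3",
                    marker_last = "M3", span_cm = 0, n_markers = 1L,
                    is_singleton = TRUE, marker = "M3")
  out <- resolve_phase_conflict(gm, hm, drs)
  expect_equal(out$edits$individual, "K6")
  expect_equal(out$edits$marker, "M3")
  expect_true(is.na(out$gm$calls["M3", "K6"]))
  expect_equal(out$gm$edit_log$reason, "phase_fix")
  # no family-wide pattern (two sibs only) -> no edits
  out2 <- resolve_phase_conflict(gm, hm, drs[1:2, ])
  expect_equal(nrow(out2$edits), 0)
})

test_that("blanking a genotype never increases Mendelian inconsistencies", {
  sim <- simulate_population(sim_config(seed = 34, random_miscall = 0.005,
                                        generations = 2,
                                        markers_per_lg = 60))
  ped <- normalize_pedigree(sim$ped)
  before <- nrow(find_inconsistencies(ped, sim$gm)$flags)
  set.seed(35)
  gm2 <- sim$gm
  cells_m <- sample(markers(gm2), 20, replace = TRUE)
  cells_i <- sample(individuals(gm2), 20, replace = TRUE)
  gm2 <- edit_calls(gm2, cells_m, cells_i, NA_integer_, reason = "blank")
  after <- nrow(find_inconsistencies(ped, gm2)$flags)
  expect_lte(after, before)
})

test_that("graphical genotypes export the origin matrix for a family", {
  fam <- make_family(5, rep("m", 60), seed = 49)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  gg <- graphical_genotypes(hm, "MUM")
  expect_setequal(rownames(gg), paste0("K", 1:5))
  expect_equal(ncol(gg), 60)
  # every row is blocks of constant origin with as many boundaries as
  # detected events
  ev <- detect_recombinations(hm)
  for (k in rownames(gg)) {
    o <- gg[k, ]; o <- o[!is.na(o)]
    expect_equal(sum(o[-1] != o[-length(o)]), sum(ev$child == k))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  graphical_genotypes(hm, "MUM", path = path)
  expect_true(file.exists(path))
})
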