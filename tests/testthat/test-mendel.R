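test_that("trio elimination finds the classic AA x AA -> AB conflict", {
  ped <- pedigree(c("M", "F", "C"), mother = c(NA, NA, "M"),
                  father = c(NA, NA, "F"))
  obs <- c(M = 1L, F = 1L, C = 2L)            # genotype index = dosage + 1
  sets <- eliminate_genotypes(ped, obs)
  expect_false(attr(sets, "consistent"))
  ok <- eliminate_genotypes(ped, c(M = 1L, F = 1L, C = 1L))
  expect_true(attr(ok, "consistent"))
})

test_that("conflicts are found through an ungenotyped generation", {
  # grandparent AA, parent ungenotyped, co-parent AA, grandchild BB:
  # the parent can carry at most one B, the co-parent none, so BB is
  # impossible; brute force over the parent's genotypes agrees
  ped <- pedigree(c("GP1", "GP2", "P", "S", "C"),
                  mother = c(NA, NA, "GP1", NA, "P"),
                  father = c(NA, NA, "GP2", NA, "S"))
  obs <- c(GP1 = 1L, GP2 = 1L, P = NA, S = 2L, C = 3L)
  sets <- eliminate_genotypes(ped, obs)
  expect_false(attr(sets, "consistent"))
  expect_false(oracle_pedigree_consistent(ped, obs - 1L))
  # with a het grandparent the same configuration is fine
  obs2 <- c(GP1 = 2L, GP2 = 1L, P = NA, S = 2L, C = 3L)
  expect_true(attr(eliminate_genotypes(ped, obs2), "consistent"))
  expect_true(oracle_pedigree_consistent(ped, obs2 - 1L))
})

test_that("an ungenotyped parent's set is constrained by spouse and children", {
  kids <- paste0("K", 1:10)
  ped <- pedigree(c("P", "S", kids), mother = c(NA, NA, rep("P", 10)),
                  father = c(NA, NA, rep("S", 10)))
  # spouse AA, children AA and AB: parent must carry B iff some child AB
  obs <- c(P = NA, S = 1L, setNames(c(rep(1L, 5), rep(2L, 5)), kids))
  sets <- eliminate_genotypes(ped, obs)
  expect_false(sets["P", 1])                 # pure AA cannot give AB kids
  obs2 <- c(P = NA, S = 1L, setNames(rep(1L, 10), kids))
  sets2 <- eliminate_genotypes(ped, obs2)
  expect_true(sets2["P", 1])
})

test_that("elimination verdict equals exhaustive enumeration on random pedigrees", {
  set.seed(33)
  for (rep in 1:120) {
    n <- sample(4:8, 1)
    ids <- paste0("I", seq_len(n))
    mother <- father <- rep(NA_character_, n)
    for (i in 3:n) {
      if (runif(1) < 0.7 && i >= 3) {
        pars <- sample(seq_len(i - 1), 2)
        mother[i] <- ids[pars[1]]; father[i] <- ids[pars[2]]
      }
    }
    ped <- pedigree(ids, mother, father)
    obs <- sample(c(1:3, NA), n, TRUE)
    names(obs) <- ids
    fast <- attr(eliminate_genotypes(ped, obs), "consistent")
    slow <- oracle_pedigree_consistent(ped, obs - 1L)
    expect_equal(fast, slow, info = paste("rep", rep))
  }
})

test_that("a single injected miscall is localized to its trio", {
  sim <- simulate_population(sim_config(seed = 19, missing_rate = 0,
                                        generations = 2))
  ped <- normalize_pedigree(sim$ped)
  base <- find_inconsistencies(ped, sim$gm)
  expect_equal(nrow(base$flags), 0)          # error-free -> zero flags
  # inject one opposing-homozygote miscall into a child
  kid <- "G1_1_1"
  mo <- sim$ped$mother[match(kid, sim$ped$id)]
  m <- rownames(sim$gm$calls)[which(sim$gm$calls[, mo] == 0L &
                                      sim$gm$calls[, kid] == 0L)[1]]
  gm2 <- edit_calls(sim$gm, m, kid, 2L, reason = "inject")
  rep2 <- find_inconsistencies(ped, gm2)
  expect_true(all(rep2$flags$marker == m))
  expect_true(kid %in% rep2$flags$individual)
  fam <- c(kid, mo, sim$ped$father[match(kid, sim$ped$id)])
  expect_true(all(rep2$flags$individual %in% fam))
})

test_that("injected errors are recalled at >= 95% (0.5% error rate)", {
  sim <- simulate_population(sim_config(seed = 20, markers_per_lg = 400,
                                        random_miscall = 0.005))
  ped <- normalize_pedigree(sim$ped)
  rep <- find_inconsistencies(ped, sim$gm)
  reg <- sim$truth$registry
  mis <- reg[reg$type == "miscall", ]
  # which injected miscalls are detectable at all: those violating
  # transmission somewhere; measure recall on flagged markers
  flagged_mk <- unique(rep$flags$marker)
  # a miscalled cell is recalled if its marker x individual cell (or a
  # cell of the same conflict edge) is flagged
  key_flag <- paste(rep$flags$marker, rep$flags$individual)
  hit <- paste(mis$marker, mis$individual) %in% key_flag
  # a miscall is detectable when it is singly culpable: the marker is
  # inconsistent with the cell present and consistent once the cell is
  # blanked (errors only visible jointly with other errors are excluded)
  dos <- sim$gm$calls
  ids <- ped$id
  have <- intersect(ids, colnames(dos))
  detectable <- vapply(seq_len(nrow(mis)), function(i) {
    obs <- setNames(rep(NA_integer_, length(ids)), ids)
    obs[have] <- dos[mis$marker[i], have] + 1L
    if (attr(eliminate_genotypes(ped, obs), "consistent")) return(FALSE)
    obs[mis$individual[i]] <- NA_integer_
    attr(eliminate_genotypes(ped, obs), "consistent")
  }, TRUE)
  expect_gte(mean(hit[detectable]), 0.95)
})

test_that("forced imputation fills singletons correctly and creates no conflicts", {
  sim <- simulate_population(sim_config(seed = 22, generations = 3,
                                        missing_rate = 0))
  ped <- normalize_pedigree(sim$ped)
  # withhold one mid-generation parent entirely
  victim <- "G1_1_1"
  truth <- sim$gm$calls[, victim]
  gm2 <- sim$gm
  gm2$calls[, victim] <- NA_integer_
  imp <- impute_forced(ped, gm2)
  filled <- which(!is.na(imp$calls[, victim]))
  expect_gt(length(filled), 0)
  expect_gte(mean(imp$calls[filled, victim] == truth[filled]), 0.99)
  expect_true(all(imp$edit_log$reason == "mendel_impute"))
  before <- find_inconsistencies(ped, gm2)
  after <- find_inconsistencies(ped, imp)
  expect_equal(after$flags, before$flags)
  # nothing missing -> no imputations
  expect_equal(nrow(impute_forced(ped, sim$gm)$edit_log), 0)
})

test_that("blanking flagged calls reaches a consistent fixpoint", {
  sim <- simulate_population(sim_config(seed = 23, random_miscall = 0.01))
  ped <- normalize_pedigree(sim$ped)
  res <- resolve_inconsistencies(ped, sim$gm)
  expect_true(res$clean)
  expect_gt(res$n_blanked, 0)
  final <- find_inconsistencies(ped, res$gm)
  expect_equal(nrow(final$flags), 0)
})
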