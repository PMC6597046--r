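ev_row <- function(lm, rm, cl, cr, child = "C1", lg = "LG1")
  data.frame(parent = "P", child = child, side = "mat", linkage_group = lg,
             left_marker = lm, right_marker = rm, cm_left = cl, cm_right = cr,
             from_origin = 1L, to_origin = 2L, inf_left = 1L, inf_right = 2L)

test_that("borders fall at interval midpoints, snapped between markers", {
  map <- genetic_map(paste0("M", 1:5), "LG1", c(0, 10, 14, 20, 30))
  hbs <- define_borders(ev_row("M2", "M3", 10, 14), map)
  expect_equal(nrow(hbs$blocks), 2)
  expect_equal(hbs$markers[[1]], c("M1", "M2"))   # border at 12 cM
  expect_equal(hbs$markers[[2]], c("M3", "M4", "M5"))
})

test_that("one border can cut two overlapping events", {
  map <- genetic_map(paste0("M", 1:6), "LG1", c(0, 10, 14, 20, 30, 40))
  # first event's midpoint (15 cM) falls in the gap both events share
  ev <- rbind(ev_row("M2", "M4", 10, 20, "C1"),
              ev_row("M3", "M5", 14, 30, "C2"))
  hbs <- define_borders(ev, map)
  expect_equal(nrow(hbs$blocks), 2)   # the shared gap suffices
  expect_equal(hbs$markers[[1]], paste0("M", 1:3))
})

test_that("selected-material events never fall inside a block", {
  set.seed(51)
  for (rep in 1:25) {
    n <- 40
    map <- genetic_map(paste0("M", 1:n), "LG1", sort(runif(n, 0, 100)))
    k <- sample(3:12, 1)
    li <- sort(sample(1:(n - 1), k))
    ri <- pmin(li + sample(1:4, k, TRUE), n)
    keep <- ri > li
    ev <- do.call(rbind, lapply(which(keep), function(i)
      ev_row(map$marker[li[i]], map$marker[ri[i]], map$cm[li[i]],
             map$cm[ri[i]], child = paste0("C", i))))
    hbs <- define_borders(ev, map)
    # partition invariant
    expect_equal(unlist(hbs$markers, use.names = FALSE), map$marker)
    # no event interval strictly inside one block
    blk_of <- rep(hbs$blocks$block, lengths(hbs$markers))
    names(blk_of) <- unlist(hbs$markers, use.names = FALSE)
    expect_true(all(blk_of[ev$left_marker] != blk_of[ev$right_marker]))
  }
})

test_that("selected flags filter the events used for borders", {
  map <- genetic_map(paste0("M", 1:4), "LG1", c(0, 10, 20, 30))
  ped <- pedigree(c("P", "Q", "SEL", "SDL"),
                  mother = c(NA, NA, "P", "P"), father = c(NA, NA, "Q", "Q"),
                  selected = c(TRUE, TRUE, TRUE, FALSE))
  ev <- rbind(ev_row("M1", "M2", 0, 10, "SEL"),
              ev_row("M3", "M4", 20, 30, "SDL"))
  hbs <- define_borders(ev, map, ped = ped)
  expect_equal(nrow(hbs$blocks), 2)   # only the selected child's event cuts
})

test_that("split_block divides markers and leaves other blocks alone", {
  map <- genetic_map(paste0("M", 1:10), "LG1", seq(0, 90, 10))
  hbs <- define_borders(ev_row("M6", "M7", 50, 60), map)
  b1 <- hbs$blocks$block[1]
  out <- split_block(hbs, b1, "M3")
  expect_equal(nrow(out$blocks), 3)
  expect_equal(out$markers[[paste0(b1, "a")]], paste0("M", 1:3))
  expect_equal(out$markers[[paste0(b1, "b")]], paste0("M", 4:6))
  expect_equal(out$markers[[hbs$blocks$block[2]]], hbs$markers[[2]])
  expect_error(split_block(hbs, b1, "M6"), "not inside")
  expect_error(split_block(hbs, "nope", "M3"), "unknown block")
})

test_that("haplotype codes are deterministic and shared for equal strings", {
  fam <- make_family(6, rep(c("m", "f", "b"), 20), seed = 52)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  hbs <- define_borders(detect_recombinations(hm), fam$map)
  ht <- assign_haplotypes(hm, hbs)
  b <- ht$blocks$blocks$block[1]
  same <- which(ht$strings_mat[b, ] == ht$strings_mat[b, 1])
  expect_true(all(ht$codes_mat[b, same] == ht$codes_mat[b, 1]))
  ht2 <- assign_haplotypes(hm, hbs)
  expect_identical(ht$codes_mat, ht2$codes_mat)
  expect_identical(ht$dictionary, ht2$dictionary)
})

test_that("error-free inheritance: child codes come from parents per block", {
  fam <- make_family(8, rep(c("m", "f", "b"), 40), seed = 53)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  ev <- detect_recombinations(hm)
  hbs <- define_borders(ev, fam$map)   # all events cut -> blocks crossover-free
  ht <- assign_haplotypes(hm, hbs)
  for (b in ht$blocks$blocks$block) {
    mo <- c(ht$codes_mat[b, "MUM"], ht$codes_pat[b, "MUM"])
    for (k in paste0("K", 1:8)) {
      cc <- ht$codes_mat[b, k]
      if (!is.na(cc) && !anyNA(mo)) expect_true(cc %in% mo)
    }
  }
})

test_that("haplotypes convert back to the phased alleles they encode", {
  fam <- make_family(5, rep(c("m", "f"), 30), seed = 54)
  hm <- phase_pedigree(fam$gm, fam$ped, fam$map)
  hbs <- define_borders(detect_recombinations(hm), fam$map)
  ht <- assign_haplotypes(hm, hbs)
  back <- haplotypes_to_phased(ht)
  mk <- rownames(hm$mat)
  ok <- !is.na(back$mat[mk, ])
  expect_equal(back$mat[mk, ][ok], hm$mat[ok])
  okp <- !is.na(back$pat[mk, ])
  expect_equal(back$pat[mk, ][okp], hm$pat[okp])
})

test_that("missing-position haplotypes resolve through the parents", {
  # worked pattern: child maternal string A?BA, mother carries AABA only
  ped <- pedigree(c("P", "Q", "C"), mother = c(NA, NA, "P"),
                  father = c(NA, NA, "Q"))
  mk <- paste0("M", 1:4)
  hbs <- structure(list(
    blocks = data.frame(block = "LG1_1", linkage_group = "LG1",
                        cm_start = 0, cm_end = 30, n_markers = 4),
    markers = list(LG1_1 = mk), map = simple_map(mk)),
    class = "haploblock_set")
  mat <- cbind(P = c("A", "A", "B", "A"), Q = c("B", "B", "B", "B"),
               C = c("A", NA, "B", "A"))
  pat <- cbind(P = c("A", "B", "A", "A"), Q = c("B", "A", "A", "B"),
               C = c("B", "B", "B", "B"))
  rownames(mat) <- rownames(pat) <- mk
  hm <- structure(list(mat = mat, pat = pat,
                       origin_mat = matrix(NA_integer_, 4, 3,
                                           dimnames = dimnames(mat)),
                       origin_pat = matrix(NA_integer_, 4, 3,
                                           dimnames = dimnames(mat)),
                       anomalies = data.frame(), ped = ped,
                       map = simple_map(mk)), class = "homolog_matrix")
  ht <- assign_haplotypes(hm, hbs)
  res <- resolve_missing_haplotype(ht, "C", "LG1_1", "mat", ped)
  expect_true(res$resolved)
  expect_equal(res$string, "AABA")
  # no parental match -> unresolved
  mat2 <- mat; mat2[, "P"] <- c("B", "A", "A", "B")
  pat2 <- pat; pat2[, "P"] <- c("B", "A", "A", "A")
  hm2 <- hm; hm2$mat <- mat2; hm2$pat <- pat2
  ht2 <- assign_haplotypes(hm2, hbs)
  res2 <- resolve_missing_haplotype(ht2, "C", "LG1_1", "mat", ped)
  expect_false(res2$resolved)
})

test_that("ambiguous parental matches are decided by flanking blocks", {
  ped <- pedigree(c("P", "Q", "C"), mother = c(NA, NA, "P"),
                  father = c(NA, NA, "Q"))
  mk <- paste0("M", 1:6)
  hbs <- structure(list(
    blocks = data.frame(block = c("LG1_1", "LG1_2"), linkage_group = "LG1",
                        cm_start = c(0, 40), cm_end = c(30, 90),
                        n_markers = c(2, 4)),
    markers = list(LG1_1 = mk[1:2], LG1_2 = mk[3:6]),
    map = simple_map(mk)), class = "haploblock_set")
  # mother's homolog 1 = AA|AABA, homolog 2 = BB|ABBA; child's maternal
  # flanking block matches homolog 1, target string A?BA matches both
  # AABA and ABBA at known positions
  mat <- cbind(P = c("A", "A", "A", "A", "B", "A"),
               Q = c("B", "B", "B", "B", "B", "B"),
               C = c("A", "A", "A", NA, "B", "A"))
  pat <- cbind(P = c("B", "B", "A", "B", "B", "A"),
               Q = c("B", "B", "A", "A", "A", "B"),
               C = c("B", "B", "B", "B", "B", "B"))
  rownames(mat) <- rownames(pat) <- mk
  hm <- structure(list(mat = mat, pat = pat,
                       origin_mat = matrix(NA_integer_, 6, 3,
                                           dimnames = dimnames(mat)),
                       origin_pat = matrix(NA_integer_, 6, 3,
                                           dimnames = dimnames(mat)),
                       anomalies = data.frame(), ped = ped,
                       map = simple_map(mk)), class = "homolog_matrix")
  ht <- assign_haplotypes(hm, hbs)
  res <- resolve_missing_haplotype(ht, "C", "LG1_2", "mat", ped)
  expect_true(res$resolved)
  expect_equal(res$string, "AABA")   # homolog-1 candidate wins
})

test_that("haploblock Mendel check flags unexplained codes and traces SNPs", {
  # child code pair {1,3} from parents {1,2} and {4,5}
  ped <- pedigree(c("Mo", "Fa", "C"), mother = c(NA, NA, "Mo"),
                  father = c(NA, NA, "Fa"))
  mk <- paste0("M", 1:3)
  # father carries BAB / ABA: the child's BBB is neither inherited
  # whole nor a single-crossover recombinant of the pair
  strings <- c("AAA", "ABA", "BBB", "BAB", "ABA")
  mat <- cbind(Mo = strsplit(strings[1], "")[[1]],
               Fa = strsplit(strings[4], "")[[1]],
               C = strsplit(strings[1], "")[[1]])
  pat <- cbind(Mo = strsplit(strings[2], "")[[1]],
               Fa = strsplit(strings[5], "")[[1]],
               C = strsplit(strings[3], "")[[1]])
  rownames(mat) <- rownames(pat) <- mk
  hbs <- structure(list(
    blocks = data.frame(block = "LG1_1", linkage_group = "LG1",
                        cm_start = 0, cm_end = 100, n_markers = 3),
    markers = list(LG1_1 = mk), map = simple_map(mk)),
    class = "haploblock_set")
  hm <- structure(list(mat = mat, pat = pat,
                       origin_mat = matrix(NA_integer_, 3, 3),
                       origin_pat = matrix(NA_integer_, 3, 3),
                       anomalies = data.frame(), ped = ped,
                       map = simple_map(mk)), class = "homolog_matrix")
  ht <- assign_haplotypes(hm, hbs)
  chk <- haplo_mendel_check(ped, ht)
  expect_equal(chk$inconsistent_blocks, "LG1_1")
  expect_true("C" %in% chk$flags$individual)
  # error-free family checks clean, and an injected SNP miscall is
  # traced back to its marker through the cross-check
  fam <- make_family(6, rep(c("m", "f", "b"), 20), seed = 55)
  hm2 <- phase_pedigree(fam$gm, fam$ped, fam$map)
  hbs2 <- define_borders(detect_recombinations(hm2), fam$map)
  ht2 <- assign_haplotypes(hm2, hbs2)
  clean <- haplo_mendel_check(fam$ped, ht2, gm = fam$gm)
  expect_equal(nrow(clean$flags), 0)
  expect_equal(nrow(clean$snp_conflicts), 0)
  # corrupt one phased cell's underlying call
  mkx <- rownames(hm2$mat)[10]
  gm3 <- edit_calls(fam$gm, mkx, "K2",
                    (fam$gm$calls[mkx, "K2"] + 1L) %% 3L, reason = "inject")
  chk3 <- haplo_mendel_check(fam$ped, ht2, gm = gm3)
  expect_true(mkx %in% chk3$snp_conflicts$marker)
  expect_true("K2" %in% chk3$snp_conflicts$individual)
})
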