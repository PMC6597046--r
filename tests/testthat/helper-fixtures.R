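# shared fixture builders

# genotype_matrix from a character matrix given as rows of strings
make_gm <- function(..., individuals) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- individuals
  genotype_matrix(m)
}

# genotype_matrix from a dosage matrix with auto names
dosage_gm <- function(dos, markers = NULL, individuals = NULL) {
  if (is.null(rownames(dos)))
    rownames(dos) <- markers %||% paste0("M", seq_len(nrow(dos)))
  if (is.null(colnames(dos)))
    colnames(dos) <- individuals %||% paste0("I", seq_len(ncol(dos)))
  storage.mode(dos) <- "integer"
  genotype_matrix(dos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evenly spaced single-linkage-group map over the markers of a matrix
simple_map <- function(markers, lg = "LG1", length_cm = 100) {
  genetic_map(markers, lg, seq(0, length_cm, length.out = length(markers)))
}

# independent transmission oracle: is child dosage feasible for the
# parent pair, by enumerating one transmitted allele per parent?
oracle_trio_ok <- function(gm_, gf_, gc_) {
  gam <- function(g) if (g == 0) 0L else if (g == 2) 1L else 0:1
  gc_ %in% unique(outer(gam(gm_), gam(gf_), `+`))
}

# exhaustive pedigree consistency oracle over all genotype assignments
# of the unobserved individuals (dosages 0:2); independent of the
# elimination path
oracle_pedigree_consistent <- function(ped, obs) {
  ids <- ped$id
  free <- which(is.na(obs))
  grids <- rep(list(0:2), length(free))
  grid <- if (length(free)) as.matrix(expand.grid(grids)) else
    matrix(nrow = 1, ncol = 0)
  mi <- match(ped$mother, ids); fi <- match(ped$father, ids)
  trios <- which(!is.na(mi) & !is.na(fi))
  for (r in seq_len(nrow(grid))) {
    g <- obs
    g[free] <- grid[r, ]
    ok <- TRUE
    for (i in trios) {
      if (!oracle_trio_ok(g[mi[i]], g[fi[i]], g[i])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# a two-founder family with designed phased parents; markers get an
# informativeness pattern: "m" mother het / father hom, "f" father het,
# "b" both hom, "u" both het (uninformative)
make_family <- function(n_children, pattern, seed = 1, length_cm = 100) {
  set.seed(seed)
  n <- length(pattern)
  mk <- paste0("M", seq_len(n))
  map <- genetic_map(mk, "LG1", seq(0, length_cm, length.out = n))
  h <- function(x) matrix(x, n, 2)
  mum <- matrix(0L, n, 2); dad <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    if (pattern[i] == "m") { mum[i, ] <- c(0L, 1L); dad[i, ] <- 0L }
    else if (pattern[i] == "f") { dad[i, ] <- c(0L, 1L); mum[i, ] <- 0L }
    else if (pattern[i] == "u") { mum[i, ] <- c(0L, 1L); dad[i, ] <- c(0L, 1L) }
    else { mum[i, ] <- sample(0:1, 1); dad[i, ] <- sample(0:1, 1) }
  }
  kids <- paste0("K", seq_len(n_children))
  hap_m <- matrix(NA_integer_, n, n_children, dimnames = list(mk, kids))
  hap_p <- hap_m
  meio <- list()
  for (j in seq_len(n_children)) {
    gm_ <- simulate_meiosis(mum[, 1], mum[, 2], map)
    gp_ <- simulate_meiosis(dad[, 1], dad[, 2], map)
    hap_m[, j] <- gm_$gamete; hap_p[, j] <- gp_$gamete
    meio[[paste(kids[j], "mat")]] <- gm_$events
    meio[[paste(kids[j], "pat")]] <- gp_$events
  }
  dos <- cbind(MUM = mum[, 1] + mum[, 2], DAD = dad[, 1] + dad[, 2],
               hap_m + hap_p)
  rownames(dos) <- mk
  ped <- pedigree(c("MUM", "DAD", kids),
                  mother = c(NA, NA, rep("MUM", n_children)),
                  father = c(NA, NA, rep("DAD", n_children)),
                  selected = c(TRUE, TRUE, rep(FALSE, n_children)))
  list(gm = dosage_gm(dos), ped = ped, map = map,
       truth = list(mum = mum, dad = dad, hap_m = hap_m, hap_p = hap_p,
                    meioses = meio))
}
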