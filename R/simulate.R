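#' Simulation configuration
#'
#' Defaults describe a breeding-germplasm study design: a few founders,
#' three generations of full-sib families with parent reuse (creating
#' half-sib structure), five linkage groups of 100 cM carrying 200
#' markers each, founder B-allele frequencies uniform on [0.1, 0.5] so
#' that markers are informative. Error rates default to zero; see
#' \code{\link{default_scenario}} for the standard injected-error
#' scenario.
#'
#' @param seed integer seed (mandatory; full reproducibility).
#' @param n_founders,generations,families_per_generation,family_size
#'   pedigree shape (generations counts all layers including founders).
#' @param n_linkage_groups,markers_per_lg,lg_length_cm map shape.
#' @param founder_maf range of founder B-allele frequencies.
#' @param missing_rate,random_miscall per-cell rates.
#' @param cluster_shift_fraction fraction of markers given a systematic
#'   cluster-calling shift (a whole homozygote class relabelled AB).
#' @param null_allele_fraction fraction of markers segregating a null
#'   allele (frequency \code{null_freq} among founder haplotypes).
#' @param null_freq null-allele frequency at null markers.
#' @param n_duplicates,n_wrong_parents,n_triploids,n_bad_samples,n_segmental
#'   anomaly counts.
#' @param duplicate_miscall miscall rate applied independently to each
#'   member of a duplicate pair.
#' @param bad_missing_rate,bad_miscall extra corruption of bad-quality
#'   samples.
#' @param baf_noise_sd named vector: BAF noise s.d. for good and bad
#'   quality samples.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_founders = 12, generations = 3,
                       families_per_generation = 8, family_size = 12,
                       n_linkage_groups = 5, markers_per_lg = 200,
                       lg_length_cm = 100, founder_maf = c(0.1, 0.5),
                       missing_rate = 0.005, random_miscall = 0,
                       cluster_shift_fraction = 0,
                       null_allele_fraction = 0, null_freq = 0.2,
                       n_duplicates = 0, n_wrong_parents = 0,
                       n_triploids = 0, n_bad_samples = 0, n_segmental = 0,
                       duplicate_miscall = 0.01,
                       bad_missing_rate = 0.10, bad_miscall = 0.05,
                       baf_noise_sd = c(good = 0.02, bad = 0.12)) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(missing_rate, random_miscall, cluster_shift_fraction,
             null_allele_fraction, null_freq, duplicate_miscall,
             bad_missing_rate, bad_miscall)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' The standard injected-error scenario
#'
#' Three generations, about 200 individuals, 5 linkage groups x 200
#' markers, 1\% random miscalls, 2\% cluster-shifted markers, two wrong
#' parent records, one duplicate pair, one triploid and two bad-quality
#' samples.
#' @param seed integer seed.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
default_scenario <- function(seed, ...) {
  sim_config(seed = seed, random_miscall = 0.01,
             cluster_shift_fraction = 0.02, n_wrong_parents = 2,
             n_duplicates = 1, n_triploids = 1, n_bad_samples = 2, ...)
}

#' Simulate a multi-generation outbred pedigree
#'
#' Founders are unrelated; each later generation is built from
#' \code{families_per_generation} full-sib families whose parent pairs
#' are sampled (with reuse, giving half-sib families) from the previous
#' generation. Founders and all individuals used as parents are selected
#' material; remaining seedlings are unselected.
#'
#' @param config a \code{sim_config}. The caller controls the RNG state
#'   (\code{\link{simulate_population}} seeds once for the whole run).
#' @return a \code{pedigree}.
#' @export
simulate_pedigree <- function(config) {
  ids <- paste0("F", seq_len(config$n_founders))
  ped <- data.frame(id = ids, mother = NA_character_, father = NA_character_,
                    selected = TRUE, stringsAsFactors = FALSE)
  prev <- ids
  if (config$generations > 1) for (g in seq_len(config$generations - 1)) {
    if (length(prev) < 2) stop("infeasible pedigree: fewer than 2 parents")
    kids <- character(0)
    for (fam in seq_len(config$families_per_generation)) {
      pair <- sample(prev, 2, replace = FALSE)
      kid_ids <- paste0("G", g, "_", fam, "_", seq_len(config$family_size))
      ped <- rbind(ped, data.frame(id = kid_ids, mother = pair[1],
                                   father = pair[2], selected = FALSE,
                                   stringsAsFactors = FALSE))
      kids <- c(kids, kid_ids)
    }
    prev <- kids
  }
  ped$selected <- ped$selected | ped$id %in% c(ped$mother, ped$father)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate one meiosis under the Haldane model
#'
#' Crossover count per linkage group is Poisson(length_cM / 100),
#' positions uniform in cM, no interference; the gamete starts on a
#' random homolog and switches at each crossover.
#'
#' @param hap1,hap2 integer allele vectors (the parent's two homologs)
#'   aligned to \code{map}.
#' @param map a \code{genetic_map}.
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used).
#' @return list: \code{gamete} (integer vector), \code{events} (per
#'   linkage group: \code{start} homolog and crossover \code{pos} in cM).
#' @export
simulate_meiosis <- function(hap1, hap2, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gamete <- integer(nrow(map))
  events <- list()
  for (lg in unique(map$linkage_group)) {
    kk <- which(map$linkage_group == lg)
    len <- max(map$cm[kk])
    n_co <- stats::rpois(1, len / 100)
    pos <- sort(stats::runif(n_co, 0, len))
    start <- sample(1:2, 1)
    origin <- 1L + (start - 1L + findInterval(map$cm[kk], pos)) %% 2L
    gamete[kk] <- ifelse(origin == 1L, hap1[kk], hap2[kk])
    events[[lg]] <- list(start = start, pos = pos)
  }
  list(gamete = gamete, events = events)
}

# origin (1/2) of each marker for a stored meiosis event list
meiosis_origins <- function(events, map) {
  origin <- integer(nrow(map))
  for (lg in names(events)) {
    kk <- which(map$linkage_group == lg)
    e <- events[[lg]]
    origin[kk] <- 1L + (e$start - 1L + findInterval(map$cm[kk], e$pos)) %% 2L
  }
  origin
}

#' Simulate a genotyped cohort with a truth ledger
#'
#' Generates the pedigree, map, founder haplotypes and all meioses, then
#' injects the configured error types, recording every injected error in
#' a truth ledger so pipeline recovery can be scored exactly. With all
#' rates and counts zero the corrupted data equal the clean data.
#'
#' @param config a \code{sim_config}.
#' @return list of class \code{simulation}: \code{ped} (recorded
#'   pedigree, including injected record errors), \code{map}, \code{gm}
#'   (corrupted \code{genotype_matrix}), \code{baf} (BAF matrix), and
#'   \code{truth} — a list with the true pedigree, phased haplotypes
#'   (\code{hap_mat}, \code{hap_pat}, 0 = A / 1 = B), per-meiosis
#'   crossover records, clean calls, per-individual ploidy and quality,
#'   and the injected-error \code{registry}.
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  ped <- simulate_pedigree(config)
  n_mk <- config$n_linkage_groups * config$markers_per_lg
  lg <- rep(paste0("LG", seq_len(config$n_linkage_groups)),
            each = config$markers_per_lg)
  cm <- as.vector(apply(matrix(stats::runif(n_mk, 0, config$lg_length_cm),
                               nrow = config$markers_per_lg), 2, sort))
  mk <- paste0("M", seq_len(n_mk))
  map <- genetic_map(mk, lg, cm)
  mk <- map$marker  # map order
  freq <- stats::runif(n_mk, config$founder_maf[1], config$founder_maf[2])
  names(freq) <- mk

  ids <- ped$id
  hap_mat <- matrix(NA_integer_, n_mk, length(ids), dimnames = list(mk, ids))
  hap_pat <- hap_mat
  founders <- ids[is.na(ped$mother)]
  for (f in founders) {
    hap_mat[, f] <- stats::rbinom(n_mk, 1, freq)
    hap_pat[, f] <- stats::rbinom(n_mk, 1, freq)
  }
  meioses <- list()
  gen <- pedigree_generation(ped)
  for (id in ids[order(gen[ids])]) {
    i <- match(id, ped$id)
    if (is.na(ped$mother[i])) next
    for (side in c("mat", "pat")) {
      p <- if (side == "mat") ped$mother[i] else ped$father[i]
      g <- simulate_meiosis(hap_mat[, p], hap_pat[, p], map)
      if (side == "mat") hap_mat[, id] <- g$gamete else hap_pat[, id] <- g$gamete
      meioses[[paste(id, side)]] <- g$events
    }
  }
  clean <- hap_mat + hap_pat
  registry <- data.frame(type = character(), marker = character(),
                         individual = character(), detail = character(),
                         stringsAsFactors = FALSE)
  reg <- function(type, marker = NA, individual = NA, detail = "") {
    registry <<- rbind(registry, data.frame(
      type = type, marker = as.character(marker),
      individual = as.character(individual), detail = detail,
      stringsAsFactors = FALSE))
  }
  ploidy <- stats::setNames(rep(2L, length(ids)), ids)
  quality <- stats::setNames(rep("good", length(ids)), ids)
  calls <- clean
  b_frac <- clean / 2           # true B-signal fraction driving BAF

  seedlings <- ids[!is.na(ped$mother) & !ped$selected]
  pick <- function(n) {
    avail <- setdiff(seedlings, registry$individual)
    if (n > length(avail)) stop("not enough seedlings for anomalies")
    if (n == 0) character(0) else sample(avail, n)
  }

  ## triploids: one parent contributes an unreduced, crossover-bearing
  ## diploid gamete (both meiotic products of one meiosis)
  for (id in pick(config$n_triploids)) {
    fa <- ped$father[match(id, ped$id)]
    g1 <- simulate_meiosis(hap_mat[, fa], hap_pat[, fa], map)
    g2 <- simulate_meiosis(hap_mat[, fa], hap_pat[, fa], map)
    dos3 <- hap_mat[, id] + g1$gamete + g2$gamete
    calls[, id] <- ifelse(dos3 == 0L, 0L, ifelse(dos3 == 3L, 2L, 1L))
    b_frac[, id] <- dos3 / 3
    ploidy[id] <- 3L
    reg("triploid", individual = id, detail = paste("via", fa))
  }

  ## segmental deletions: one parental homolog lost over a 20 cM segment
  for (id in pick(config$n_segmental)) {
    lg_i <- sample(unique(map$linkage_group), 1)
    kk <- which(map$linkage_group == lg_i)
    st <- stats::runif(1, 0, max(map$cm[kk]) - 20)
    seg <- kk[map$cm[kk] >= st & map$cm[kk] <= st + 20]
    keep <- hap_pat[seg, id]   # maternal copy deleted
    calls[seg, id] <- 2L * keep
    b_frac[seg, id] <- keep
    reg("segmental_deletion", individual = id,
        detail = paste0(lg_i, ":", round(st, 2), "-", round(st + 20, 2)))
  }

  ## bad-quality samples: elevated missingness + miscalls + BAF noise
  for (id in pick(config$n_bad_samples)) {
    quality[id] <- "bad"
    reg("bad_quality", individual = id)
  }

  ## duplicates: copy of an existing seedling column
  dup_src <- pick(config$n_duplicates)
  for (src in dup_src) {
    dup <- paste0("DUP_", src)
    i <- match(src, ped$id)
    ped <- rbind(ped, data.frame(id = dup, mother = ped$mother[i],
                                 father = ped$father[i], selected = FALSE,
                                 stringsAsFactors = FALSE))
    calls <- cbind(calls, stats::setNames(data.frame(calls[, src]), dup)[[1]])
    colnames(calls)[ncol(calls)] <- dup
    b_frac <- cbind(b_frac, b_frac[, src])
    colnames(b_frac)[ncol(b_frac)] <- dup
    ploidy[dup] <- 2L; quality[dup] <- "good"
    reg("duplicate", individual = dup, detail = paste("copy of", src))
    reg("duplicate_source", individual = src, detail = paste("copied as", dup))
  }
  class(ped) <- c("pedigree", "data.frame")
  true_ped <- ped

  ## wrong pedigree records: recorded parent swapped to a non-parent
  for (id in pick(config$n_wrong_parents)) {
    i <- match(id, ped$id)
    elders <- ped$id[gen[ped$id] < gen[id] &
                       !(ped$id %in% c(ped$mother[i], ped$father[i]))]
    elders <- elders[!is.na(elders)]
    wrong <- sample(elders, 1)
    reg("wrong_parent", individual = id,
        detail = paste("mother", ped$mother[i], "->", wrong))
    ped$mother[i] <- wrong
  }

  ## null-allele markers: silent allele among founder haplotypes,
  ## propagated through the stored meioses
  n_null <- round(config$null_allele_fraction * n_mk)
  if (n_null > 0) {
    null_mk <- sample(mk, n_null)
    null_mat <- matrix(FALSE, n_mk, length(true_ped$id),
                       dimnames = list(mk, true_ped$id))
    for (f in founders) {
      # null status of the two homologs at null markers
      null_mat[null_mk, f] <- stats::rbinom(n_null, 1, config$null_freq) == 1
    }
    null_pat <- null_mat
    for (f in founders)
      null_pat[null_mk, f] <- stats::rbinom(n_null, 1, config$null_freq) == 1
    for (id in true_ped$id[order(gen[true_ped$id])]) {
      i <- match(id, true_ped$id)
      if (is.na(true_ped$mother[i]) || !paste(id, "mat") %in% names(meioses))
        next
      om <- meiosis_origins(meioses[[paste(id, "mat")]], map)
      op <- meiosis_origins(meioses[[paste(id, "pat")]], map)
      mo <- true_ped$mother[i]; fa <- true_ped$father[i]
      null_mat[, id] <- ifelse(om == 1L, null_mat[, mo], null_pat[, mo])
      null_pat[, id] <- ifelse(op == 1L, null_mat[, fa], null_pat[, fa])
    }
    for (id in colnames(calls)) {
      src <- if (id %in% true_ped$id) id else sub("^DUP_", "", id)
      nm <- null_mat[null_mk, src]; np <- null_pat[null_mk, src]
      one_null <- xor(nm, np)
      both <- nm & np
      vis <- ifelse(nm, hap_pat[null_mk, src], hap_mat[null_mk, src])
      calls[null_mk, id][one_null] <- 2L * vis[one_null]
      calls[null_mk, id][both] <- NA_integer_
    }
    for (m in null_mk) reg("null_allele", marker = m)
  }

  ## cluster shifts: one homozygote class relabelled AB at the marker
  n_shift <- round(config$cluster_shift_fraction * n_mk)
  if (n_shift > 0) {
    shift_mk <- sample(setdiff(mk, registry$marker), n_shift)
    for (m in shift_mk) {
      # the misplaced cluster is the major homozygote class: a cluster
      # position drawn onto the heterozygote band relabels that whole
      # class AB (with B the minor allele this is the AA cluster)
      from <- if (sum(calls[m, ] == 0L, na.rm = TRUE) >=
                    sum(calls[m, ] == 2L, na.rm = TRUE)) 0L else 2L
      hit <- !is.na(calls[m, ]) & calls[m, ] == from
      calls[m, hit] <- 1L
      reg("cluster_shift", marker = m,
          detail = paste(GENO_STR[from + 1], "->AB"))
    }
  }

  ## random miscalls (uniform over the two wrong calls), extra for bad
  ## samples, then missingness
  miscall <- function(cols, rate) {
    if (rate <= 0) return()
    sub <- calls[, cols, drop = FALSE]
    hit <- which(!is.na(sub) & matrix(stats::runif(length(sub)) < rate,
                                      nrow(sub)))
    if (!length(hit)) return()
    wrong <- (sub[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
    sub[hit] <- wrong
    calls[, cols] <<- sub
    cells <- arrayInd(hit, dim(sub))
    for (r in seq_len(nrow(cells)))
      reg("miscall", marker = rownames(sub)[cells[r, 1]],
          individual = cols[cells[r, 2]])
  }
  good_cols <- colnames(calls)[quality[colnames(calls)] != "bad"]
  bad_cols <- setdiff(colnames(calls), good_cols)
  dup_ids <- paste0("DUP_", dup_src)
  miscall(setdiff(good_cols, dup_ids), config$random_miscall)
  miscall(intersect(good_cols, dup_ids), config$duplicate_miscall)
  miscall(bad_cols, config$bad_miscall)
  drop_rate <- ifelse(colnames(calls) %in% bad_cols,
                      config$bad_missing_rate, config$missing_rate)
  nas <- matrix(stats::runif(length(calls)), nrow(calls)) <
    rep(drop_rate, each = nrow(calls))
  calls[nas] <- NA_integer_

  ## BAF from the true B-signal fraction
  sdv <- ifelse(colnames(b_frac) %in% bad_cols,
                config$baf_noise_sd[["bad"]], config$baf_noise_sd[["good"]])
  baf <- b_frac + matrix(stats::rnorm(length(b_frac), 0,
                                      rep(sdv, each = nrow(b_frac))),
                         nrow(b_frac))
  baf <- pmin(pmax(baf, 0), 1)
  dimnames(baf) <- dimnames(b_frac)

  storage.mode(calls) <- "integer"
  gm <- genotype_matrix(calls)
  structure(list(
    ped = ped, map = map, gm = gm, baf = baf,
    truth = list(ped = true_ped, hap_mat = hap_mat, hap_pat = hap_pat,
                 meioses = meioses, clean_calls = clean, freq = freq,
                 ploidy = ploidy, quality = quality, registry = registry)),
    class = "simulation")
}

#' Simulate B-allele frequencies for given genotypes
#'
#' BAF = b_copies / ploidy plus Gaussian noise, truncated to [0, 1].
#' @param b_copies integer matrix of B-allele copy numbers.
#' @param ploidy integer (scalar or per-column vector).
#' @param noise_sd Gaussian noise s.d. (scalar or per-column).
#' @return numeric matrix of BAF values.
#' @export
simulate_baf <- function(b_copies, ploidy = 2, noise_sd = 0.02) {
  mu <- sweep(b_copies, 2, rep_len(ploidy, ncol(b_copies)), `/`)
  sdv <- rep_len(noise_sd, ncol(b_copies))
  baf <- mu + matrix(stats::rnorm(length(mu), 0, rep(sdv, each = nrow(mu))),
                     nrow(mu))
  baf <- pmin(pmax(baf, 0), 1)
  dimnames(baf) <- dimnames(b_copies)
  baf
}

#' True grandparental origins of a simulated meiosis
#'
#' Looks up the stored crossover record and returns the origin (1 =
#' parent's first homolog) per marker — the generator truth against
#' which phased origins are scored.
#' @param sim a \code{simulation}.
#' @param child child id.
#' @param side \code{"mat"} or \code{"pat"}.
#' @return integer vector aligned to the simulation's map.
#' @export
true_origins <- function(sim, child, side) {
  ev <- sim$truth$meioses[[paste(child, side)]]
  if (is.null(ev)) stop("no stored meiosis for ", child, " ", side)
  meiosis_origins(ev, sim$map)
}

#' Write a simulated cohort to a directory
#'
#' Emits the genotype TSV, pedigree CSV, map CSV and BAF TSV in the
#' formats the readers accept.
#' @param sim a \code{simulation}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_table(sim$gm, file.path(dir, "genotypes.tsv"))
  write_pedigree(sim$ped, file.path(dir, "pedigree.csv"))
  write_genetic_map(sim$map, file.path(dir, "map.csv"))
  baf <- data.frame(marker = rownames(sim$baf), sim$baf, check.names = FALSE)
  utils::write.table(baf, file.path(dir, "baf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
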