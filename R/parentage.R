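#' Parent-child (PC) Mendelian-inconsistent error count
#'
#' Counts co-called markers at which the child and the putative parent
#' are opposing homozygotes (AA vs BB) — for biallelic codominant calls
#' this is exactly the condition that the offspring carries no allele
#' present in the parent. Symmetric in its arguments.
#'
#' @param child,parent integer dosage vectors (0/1/2/NA) over the same
#'   markers, e.g. columns of a \code{genotype_matrix}'s \code{calls}.
#' @return integer error count.
#' @export
pc_errors <- function(child, parent) {
  sum((child == 0L & parent == 2L) | (child == 2L & parent == 0L),
      na.rm = TRUE)
}

# Feasibility of a child genotype given both parents' genotypes, for one
# biallelic marker: feasible iff one allele can be transmitted by each
# parent to assemble the child. Encoded as a 3x3x3 lookup
# [mother+1, father+1, child+1] over dosages.
ppc_feasible_table <- function() {
  feas <- array(FALSE, dim = c(3, 3, 3))
  gametes <- list(`0` = 0L, `1` = 0:1, `2` = 1L)   # B-allele count per gamete
  for (gm in 0:2) for (gf in 0:2) {
    kids <- unique(outer(gametes[[gm + 1]], gametes[[gf + 1]], `+`))
    feas[gm + 1, gf + 1, kids + 1] <- TRUE
  }
  feas
}

.ppc_feas <- ppc_feasible_table()

#' Parent-parent-child (PPC) Mendelian-inconsistent error count
#'
#' Counts co-called markers at which no assignment of one transmitted
#' allele per recorded parent can produce the child's genotype. This is
#' the full transmission-feasibility test: it counts AA x AA -> AB
#' (neither parent can donate B), and also AA x BB -> AA (each parent is
#' compatible alone, but jointly the child must be AB), which a
#' per-parent check misses.
#'
#' @param child,mother,father integer dosage vectors over the same
#'   markers.
#' @return integer error count.
#' @export
ppc_errors <- function(child, mother, father) {
  ok <- !is.na(child) & !is.na(mother) & !is.na(father)
  if (!any(ok)) return(0L)
  sum(!.ppc_feas[cbind(mother[ok] + 1L, father[ok] + 1L, child[ok] + 1L)])
}

#' Calibrate the PC rejection threshold
#'
#' PC error counts are computed for all known parent-child pairs and for
#' \code{n_random} random pairs with no recorded PC relation. The two
#' distributions separate (random pairs accumulate opposing homozygotes
#' in proportion to allele frequencies; true pairs only through
#' genotyping error); the threshold is the rounded midpoint between the
#' upper percentile of the known-PC distribution and the lower
#' percentile of the random distribution. Counts at or above the
#' threshold reject the parentage.
#'
#' @param gm a \code{genotype_matrix}.
#' @param ped a \code{pedigree} (supplies known PC pairs and the no-PC
#'   constraint for random pairs).
#' @param n_random number of random non-PC pairs, default 1000.
#' @param percentiles upper percentile of the PC distribution and lower
#'   percentile of the random distribution, default c(0.99, 0.01).
#' @param seed integer seed for the random-pair draw.
#' @return list: \code{threshold} (integer, at least 1 so that
#'   error-free data confirm rather than reject), \code{pc_counts},
#'   \code{random_counts}, \code{overlap} (TRUE, with a warning, when
#'   the chosen percentiles overlap).
#' @export
calibrate_pc_threshold <- function(gm, ped, n_random = 1000,
                                   percentiles = c(0.99, 0.01), seed = 1) {
  ids <- intersect(ped$id, individuals(gm))
  dos <- gm$calls
  duos <- rbind(
    data.frame(child = ped$id, parent = ped$mother),
    data.frame(child = ped$id, parent = ped$father))
  duos <- duos[!is.na(duos$parent) & duos$child %in% ids &
                 duos$parent %in% ids, ]
  if (nrow(duos) < 20)
    stop("need at least 20 genotyped known PC pairs to calibrate")
  pc_counts <- mapply(function(c, p) pc_errors(dos[, c], dos[, p]),
                      duos$child, duos$parent)
  is_pc <- new.env(hash = TRUE)
  for (i in seq_len(nrow(duos))) {
    assign(paste(duos$child[i], duos$parent[i]), TRUE, envir = is_pc)
    assign(paste(duos$parent[i], duos$child[i]), TRUE, envir = is_pc)
  }
  set.seed(seed)
  random_counts <- numeric(0)
  guard <- 0
  while (length(random_counts) < n_random && guard < 50 * n_random) {
    a <- sample(ids, 1); b <- sample(ids, 1)
    guard <- guard + 1
    if (a == b || !is.null(is_pc[[paste(a, b)]])) next
    random_counts <- c(random_counts, pc_errors(dos[, a], dos[, b]))
  }
  hi_pc <- stats::quantile(pc_counts, percentiles[1], names = FALSE, type = 1)
  lo_rand <- stats::quantile(random_counts, percentiles[2], names = FALSE, type = 1)
  overlap <- lo_rand <= hi_pc
  if (overlap)
    warning("PC and random error-count distributions overlap at the ",
            "chosen percentiles; threshold unreliable")
  list(threshold = max(1L, as.integer(round((hi_pc + lo_rand) / 2))),
       pc_counts = unname(pc_counts), random_counts = random_counts,
       overlap = overlap)
}

#' Calibrate the PPC rejection threshold
#'
#' 110\% of the highest PPC error count observed among confirmed trios,
#' rounded up. Counts above the threshold reject the parent pair.
#'
#' @param ppc_counts integer vector of PPC error counts for confirmed
#'   trios.
#' @return integer threshold.
#' @export
calibrate_ppc_threshold <- function(ppc_counts) {
  if (!length(ppc_counts)) stop("no confirmed trios to calibrate from")
  as.integer(ceiling(1.10 * max(ppc_counts)))
}

#' Verify recorded pedigree relationships
#'
#' Counts PC errors for every genotyped child-parent duo and PPC errors
#' for every trio whose two PC relations are confirmed, and issues
#' verdicts against the calibrated thresholds: a PC relation is rejected
#' when its count reaches \code{pc_threshold}; a PPC trio is rejected
#' when its count exceeds \code{ppc_threshold} (derived from the
#' confirmed trios themselves when not supplied). Relations involving an
#' ungenotyped party are untestable.
#'
#' @param gm a \code{genotype_matrix}.
#' @param ped a \code{pedigree}.
#' @param pc_threshold integer from \code{\link{calibrate_pc_threshold}}.
#' @param ppc_threshold optional integer; when NULL it is calibrated as
#'   110\% of the maximum PPC count among trios with both PC relations
#'   confirmed.
#' @return list: \code{verdicts} (data frame child, relation,
#'   counterpart, error_count, threshold, verdict) and
#'   \code{ppc_threshold}.
#' @export
verify_parentage <- function(gm, ped, pc_threshold, ppc_threshold = NULL) {
  dos <- gm$calls
  gt <- function(id) !is.na(id) & id %in% colnames(dos)
  rows <- list()
  conf <- function(cnt, thr) if (cnt < thr) "confirmed" else "rejected"
  pc_ok <- new.env(hash = TRUE)
  for (rel in c("PC_mother", "PC_father")) {
    par <- if (rel == "PC_mother") ped$mother else ped$father
    for (i in seq_len(nrow(ped))) {
      if (is.na(par[i])) next
      if (!gt(ped$id[i]) || !gt(par[i])) {
        rows[[length(rows) + 1]] <- data.frame(
          child = ped$id[i], relation = rel, counterpart = par[i],
          error_count = NA_integer_, threshold = pc_threshold,
          verdict = "untestable")
        next
      }
      cnt <- pc_errors(dos[, ped$id[i]], dos[, par[i]])
      v <- conf(cnt, pc_threshold)
      if (v == "confirmed")
        assign(paste(ped$id[i], rel), TRUE, envir = pc_ok)
      rows[[length(rows) + 1]] <- data.frame(
        child = ped$id[i], relation = rel, counterpart = par[i],
        error_count = cnt, threshold = pc_threshold, verdict = v)
    }
  }
  trio <- ped[!is.na(ped$mother) & !is.na(ped$father), , drop = FALSE]
  trio <- trio[gt(trio$id) & gt(trio$mother) & gt(trio$father), , drop = FALSE]
  both_ok <- vapply(trio$id, function(id)
    !is.null(pc_ok[[paste(id, "PC_mother")]]) &&
    !is.null(pc_ok[[paste(id, "PC_father")]]), TRUE)
  ppc_cnt <- mapply(function(c, m, f)
    ppc_errors(dos[, c], dos[, m], dos[, f]),
    trio$id, trio$mother, trio$father)
  if (is.null(ppc_threshold)) {
    if (any(both_ok)) ppc_threshold <- calibrate_ppc_threshold(ppc_cnt[both_ok])
    else ppc_threshold <- NA_integer_
  }
  for (i in seq_len(nrow(trio))) {
    v <- if (!both_ok[i]) "rejected"
    else if (is.na(ppc_threshold)) "untestable"
    else if (ppc_cnt[i] <= ppc_threshold) "confirmed" else "rejected"
    rows[[length(rows) + 1]] <- data.frame(
      child = trio$id[i], relation = "PPC",
      counterpart = paste(trio$mother[i], trio$father[i], sep = "+"),
      error_count = as.integer(ppc_cnt[i]), threshold = ppc_threshold,
      verdict = v)
  }
  verdicts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(child = character(), relation = character(),
               counterpart = character(), error_count = integer(),
               threshold = integer(), verdict = character())
  rownames(verdicts) <- NULL
  list(verdicts = verdicts, ppc_threshold = ppc_threshold)
}

#' Search candidate parents for an individual
#'
#' Ranks all candidates whose PC error count against the child falls
#' below the rejection threshold, ascending by error count (ties broken
#' by id). Full siblings of the child can pass the PC screen (they share
#' both parental genomes); candidates recorded with the same parents as
#' the child are therefore flagged, never auto-confirmed. Candidates
#' known to be younger than the child (via \code{generation}) are
#' excluded.
#'
#' @param gm a \code{genotype_matrix}.
#' @param child child id.
#' @param candidates character vector of candidate ids.
#' @param pc_threshold rejection threshold.
#' @param ped optional \code{pedigree} used to flag possible full sibs.
#' @param generation optional named integer vector (e.g. from
#'   \code{\link{pedigree_generation}}); candidates with a strictly
#'   larger generation index than the child are excluded.
#' @return data frame: candidate, error_count, possible_full_sib,
#'   ranked ascending; zero rows when nothing passes.
#' @export
search_parents <- function(gm, child, candidates, pc_threshold, ped = NULL,
                           generation = NULL) {
  dos <- gm$calls
  candidates <- setdiff(intersect(candidates, colnames(dos)), child)
  if (!is.null(generation) && child %in% names(generation)) {
    keep <- is.na(generation[candidates]) |
      generation[candidates] <= generation[[child]]
    candidates <- candidates[keep %in% TRUE | is.na(keep)]
  }
  if (!length(candidates))
    return(data.frame(candidate = character(), error_count = integer(),
                      possible_full_sib = logical()))
  cnt <- vapply(candidates, function(p) pc_errors(dos[, child], dos[, p]), 0L)
  pass <- cnt < pc_threshold
  candidates <- candidates[pass]; cnt <- cnt[pass]
  sib <- rep(FALSE, length(candidates))
  if (!is.null(ped)) {
    ci <- match(child, ped$id); ki <- match(candidates, ped$id)
    sib <- !is.na(ki) & !is.na(ci) &
      !is.na(ped$mother[ci]) & !is.na(ped$father[ci]) &
      ped$mother[ki] %in% ped$mother[ci] & ped$father[ki] %in% ped$father[ci]
  }
  o <- order(cnt, candidates)
  data.frame(candidate = candidates[o], error_count = cnt[o],
             possible_full_sib = sib[o], row.names = NULL)
}

#' Grandparent-pair test through an ungenotyped parent
#'
#' When a parent is ungenotyped but its own parents (the child's
#' grandparents) are genotyped, each marker where the child's allele
#' received from the ungenotyped parent is determinable (child
#' homozygous; or child heterozygous with the known parent homozygous)
#' is checked against the candidate grandparent pair: if neither
#' grandparent carries the obligate allele, the marker counts one error.
#' The eponymous configuration is an AB child with an AA known parent
#' and AA + AA candidate grandparents (obligate B absent from both).
#'
#' @param child,known_parent,gp1,gp2 dosage vectors over the same
#'   markers.
#' @return integer error count.
#' @export
grandparent_test <- function(child, known_parent, gp1, gp2) {
  ok <- !is.na(child) & !is.na(gp1) & !is.na(gp2)
  # obligate allele from the ungenotyped parent: dosage of B it must carry
  obl <- rep(NA_integer_, length(child))    # 0 = obligate A, 1 = obligate B
  obl[ok & child == 0L] <- 0L
  obl[ok & child == 2L] <- 1L
  het <- ok & child == 1L & !is.na(known_parent)
  obl[het & known_parent == 0L] <- 1L       # known parent gave A, so B obligate
  obl[het & known_parent == 2L] <- 0L
  # allele absent from a grandparent iff it is homozygous for the other
  missing_a <- gp1 == 2L & gp2 == 2L
  missing_b <- gp1 == 0L & gp2 == 0L
  sum((obl == 0L & missing_a) | (obl == 1L & missing_b), na.rm = TRUE)
}
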