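# Genotype space for k codominant alleles: unordered pairs (a <= b),
# indexed 1..k(k+1)/2. For SNPs (k = 2, alleles A/B) the genotype index
# minus one equals the B dosage.
genotype_space <- function(k) {
  pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("a1", "a2")
  pairs
}

# feas[gm, gf, gc]: child genotype gc feasible from parents gm x gf
# (one allele transmitted by each parent).
feasibility_array <- function(k) {
  gs <- genotype_space(k)
  G <- nrow(gs)
  feas <- array(FALSE, dim = c(G, G, G))
  for (gm in seq_len(G)) for (gf in seq_len(G)) {
    am <- unique(gs[gm, ]); af <- unique(gs[gf, ])
    for (x in am) for (y in af) {
      gc <- which(gs[, 1] == min(x, y) & gs[, 2] == max(x, y))
      feas[gm, gf, gc] <- TRUE
    }
  }
  feas
}

.snp_feas <- feasibility_array(2)
# bitmask version for the SNP fast path: bit g set iff child genotype g
# is feasible from the (gm, gf) parent pair
.snp_feas_mask <- {
  m <- matrix(0L, 3, 3)
  for (a in 1:3) for (b in 1:3)
    m[a, b] <- sum(bitwShiftL(1L, which(.snp_feas[a, b, ]) - 1L))
  m
}

# family index cache shared by repeated eliminations on one pedigree
family_index <- function(ped) {
  fams <- nuclear_families(ped)
  list(m = match(fams$mother, ped$id), f = match(fams$father, ped$id),
       kids = lapply(fams$children, match, ped$id), n_fam = nrow(fams),
       fams = fams)
}

# SNP-specialized elimination on bitsets (genotype g <-> bit 2^(g-1));
# returns integer bitset vector, 0 = empty (inconsistent individual)
eliminate_bits <- function(fi, obs_bits, n) {
  sets <- obs_bits
  if (fi$n_fam == 0) return(sets)
  bit <- c(1L, 2L, 4L)
  for (sweep in seq_len(3L * n + 3L)) {
    changed <- FALSE
    for (k in seq_len(fi$n_fam)) {
      mi <- fi$m[k]; fj <- fi$f[k]; kids <- fi$kids[[k]]
      Sm <- sets[mi]; Sf <- sets[fj]
      if (Sm == 0L || Sf == 0L) next
      ck <- sets[kids]
      keep_m <- 0L; keep_f <- 0L
      keep_c <- integer(length(kids))
      for (a in 1:3) {
        if (!bitwAnd(Sm, bit[a])) next
        for (b in 1:3) {
          if (!bitwAnd(Sf, bit[b])) next
          comp <- bitwAnd(ck, .snp_feas_mask[a, b])
          if (all(comp > 0L)) {
            keep_m <- bitwOr(keep_m, bit[a])
            keep_f <- bitwOr(keep_f, bit[b])
            keep_c <- bitwOr(keep_c, comp)
          }
        }
      }
      nm <- bitwAnd(Sm, keep_m); nf <- bitwAnd(Sf, keep_f)
      if (nm != Sm) { sets[mi] <- nm; changed <- TRUE }
      if (nf != Sf) { sets[fj] <- nf; changed <- TRUE }
      upd <- keep_c != ck
      if (any(upd)) { sets[kids[upd]] <- keep_c[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  sets
}

#' Genotype elimination over a pedigree (one locus)
#'
#' Constraint propagation in the style of the Lange-Goradia algorithm:
#' each individual starts with its observed genotype (or all genotypes
#' if missing); nuclear families are swept repeatedly, keeping a parent
#' genotype only if some genotype pair with its mate leaves every child
#' a feasible genotype, and keeping a child genotype only if some
#' retained parental pair can produce it. Sets shrink monotonically to a
#' fixpoint. Because constraints propagate across families, errors are
#' detected over multiple generations even when intermediate individuals
#' are ungenotyped; inbreeding loops need no special handling. An empty
#' set signals a Mendelian inconsistency at this locus.
#'
#' @param ped a normalized \code{pedigree}.
#' @param obs integer vector of observed genotype indices (for SNPs:
#'   dosage + 1), NA = missing, named by individual id or aligned to
#'   \code{ped$id}.
#' @param n_genotypes number of genotype states (3 for SNPs).
#' @param feas optional precomputed feasibility array (for multi-allelic
#'   loci).
#' @return logical matrix individuals x genotypes of feasible sets, with
#'   attribute \code{consistent} (FALSE iff any row is empty).
#' @export
eliminate_genotypes <- function(ped, obs, n_genotypes = 3, feas = NULL) {
  n <- nrow(ped)
  if (!is.null(names(obs))) obs <- obs[ped$id]
  fi <- family_index(ped)
  if (n_genotypes == 3 && is.null(feas)) {
    obs_bits <- ifelse(is.na(obs), 7L, bitwShiftL(1L, as.integer(obs) - 1L))
    bits <- eliminate_bits(fi, obs_bits, n)
    sets <- cbind(bitwAnd(bits, 1L) > 0, bitwAnd(bits, 2L) > 0,
                  bitwAnd(bits, 4L) > 0)
    rownames(sets) <- ped$id
    return(structure(sets, consistent = all(bits > 0L)))
  }
  if (is.null(feas))
    feas <- feasibility_array((sqrt(8 * n_genotypes + 1) - 1) / 2)
  sets <- matrix(TRUE, n, n_genotypes, dimnames = list(ped$id, NULL))
  has_obs <- !is.na(obs)
  sets[has_obs, ] <- FALSE
  sets[cbind(which(has_obs), obs[has_obs])] <- TRUE
  if (fi$n_fam == 0)
    return(structure(sets, consistent = !any(rowSums(sets) == 0)))
  for (sweep in seq_len(3L * n + 3L)) {
    changed <- FALSE
    for (k in seq_len(fi$n_fam)) {
      mi <- fi$m[k]; fj <- fi$f[k]; kids <- fi$kids[[k]]
      Sm <- sets[mi, ]; Sf <- sets[fj, ]
      if (!any(Sm) || !any(Sf)) next
      keep_m <- rep(FALSE, n_genotypes)
      keep_f <- rep(FALSE, n_genotypes)
      keep_c <- matrix(FALSE, length(kids), n_genotypes)
      for (a in which(Sm)) for (b in which(Sf)) {
        okall <- TRUE
        for (ci in seq_along(kids)) {
          if (!any(sets[kids[ci], ] & feas[a, b, ])) { okall <- FALSE; break }
        }
        if (okall) {
          keep_m[a] <- TRUE; keep_f[b] <- TRUE
          for (ci in seq_along(kids))
            keep_c[ci, ] <- keep_c[ci, ] | (sets[kids[ci], ] & feas[a, b, ])
        }
      }
      new_m <- Sm & keep_m; new_f <- Sf & keep_f
      if (any(new_m != Sm)) { sets[mi, ] <- new_m; changed <- TRUE }
      if (any(new_f != Sf)) { sets[fj, ] <- new_f; changed <- TRUE }
      for (ci in seq_along(kids)) {
        nc <- sets[kids[ci], ] & keep_c[ci, ]
        if (any(nc != sets[kids[ci], ])) { sets[kids[ci], ] <- nc; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  structure(sets, consistent = !any(rowSums(sets) == 0))
}

#' Pedigree-wide Mendelian-inconsistency report
#'
#' Runs genotype elimination at every marker. Where a fixpoint contains
#' an empty feasible set, the conflict is localized by leave-one-out
#' re-elimination over the observed members of the affected nuclear
#' families: every member whose single removal restores consistency is
#' flagged (the inconsistency is a property of a relationship, not of
#' one individual; the whole minimal conflicting set is reported, rather
#' than attributing the error to one party by convention). If no single
#' removal restores consistency (multiple independent errors at the
#' marker), the empty-set individuals themselves are flagged.
#'
#' @param ped a normalized \code{pedigree}.
#' @param gm a \code{genotype_matrix} (pedigree members without genotype
#'   columns are treated as ungenotyped).
#' @param markers optional subset of marker ids to check.
#' @return list of class \code{consistency_report}: \code{flags} (data
#'   frame marker, individual), \code{per_marker} and
#'   \code{per_individual} error-count tables,
#'   \code{inconsistent_markers}.
#' @export
find_inconsistencies <- function(ped, gm, markers = NULL) {
  dos <- gm$calls
  if (!is.null(markers)) dos <- dos[intersect(markers, rownames(dos)), ,
                                    drop = FALSE]
  ids <- ped$id
  n <- length(ids)
  have <- ids %in% colnames(dos)
  col_of <- match(ids, colnames(dos))
  fi <- family_index(ped)
  fams <- fi$fams
  mkv <- rownames(dos)
  flags <- list()
  add_flags <- function(k_idx, members) {
    for (m in members)
      flags[[length(flags) + 1]] <<- data.frame(
        marker = mkv[k_idx], individual = m, stringsAsFactors = FALSE)
  }
  getcol <- function(id) {
    j <- col_of[match(id, ids)]
    if (is.na(j)) rep(NA_integer_, nrow(dos)) else dos[, j]
  }

  ## pass A: vectorized local screen within nuclear families; a trio
  ## violation is attributed to the duo edge when it is an opposing
  ## homozygote, to the full trio otherwise (e.g. AA x AA -> AB)
  local_work <- matrix(FALSE, nrow(dos), n,
                       dimnames = list(mkv, ids))  # cells to mask in pass B
  for (f in seq_len(nrow(fams))) {
    mo <- fams$mother[f]; fa <- fams$father[f]
    gmo <- getcol(mo); gfa <- getcol(fa)
    for (ch in fams$children[[f]]) {
      gch <- getcol(ch)
      trio <- !is.na(gch) & !is.na(gmo) & !is.na(gfa)
      bad3 <- trio & !.snp_feas[cbind(gmo + 1L, gfa + 1L, gch + 1L)]
      opp_m <- !is.na(gch) & !is.na(gmo) & abs(gch - gmo) == 2L
      opp_f <- !is.na(gch) & !is.na(gfa) & abs(gch - gfa) == 2L
      w <- which(bad3 %in% TRUE | opp_m %in% TRUE | opp_f %in% TRUE)
      for (k in w) {
        members <- if (opp_m[k] %in% TRUE && opp_f[k] %in% TRUE)
          c(ch, mo, fa)
        else if (opp_m[k] %in% TRUE) c(ch, mo)
        else if (opp_f[k] %in% TRUE) c(ch, fa)
        else c(ch, mo, fa)
        add_flags(k, members)
        local_work[k, match(members, ids)] <- TRUE
      }
    }
  }

  ## pass B: elimination with locally-flagged cells masked, catching
  ## conflicts that only emerge across generations; leave-one-out (then
  ## greedy) localization on the residue
  inconsistent <- character(0)
  for (k in seq_len(nrow(dos))) {
    obs_bits <- rep(7L, n)
    v <- dos[k, col_of[have]]
    obs_bits[have] <- ifelse(is.na(v), 7L, bitwShiftL(1L, v))
    had_local <- any(local_work[k, ])
    obs_bits[local_work[k, ]] <- 7L
    bits <- eliminate_bits(fi, obs_bits, n)
    if (all(bits > 0L)) {
      if (had_local) inconsistent <- c(inconsistent, mkv[k])
      next
    }
    inconsistent <- c(inconsistent, mkv[k])
    for (iter in 1:5) {
      empty <- ids[bits == 0L]
      aff <- vapply(seq_len(nrow(fams)), function(i)
        any(c(fams$mother[i], fams$father[i], fams$children[[i]]) %in% empty),
        TRUE)
      members <- unique(unlist(c(fams$mother[aff], fams$father[aff],
                                 fams$children[aff])))
      members <- members[obs_bits[match(members, ids)] != 7L]
      if (!length(members)) { add_flags(k, empty); break }
      n_empty <- vapply(members, function(m) {
        ob2 <- obs_bits; ob2[match(m, ids)] <- 7L
        sum(eliminate_bits(fi, ob2, n) == 0L)
      }, 0L)
      fixers <- members[n_empty == 0L]
      if (length(fixers)) { add_flags(k, fixers); break }
      best <- members[which.min(n_empty)]   # greedy: multiple errors
      add_flags(k, best)
      obs_bits[match(best, ids)] <- 7L
      bits <- eliminate_bits(fi, obs_bits, n)
      if (all(bits > 0L)) break
    }
  }
  if (length(flags)) {
    raw <- do.call(rbind, flags)
    agg <- stats::aggregate(list(n_edges = rep(1L, nrow(raw))),
                            by = raw[c("marker", "individual")], FUN = sum)
    flags <- agg[order(agg$marker, agg$individual), , drop = FALSE]
    rownames(flags) <- NULL
  } else {
    flags <- data.frame(marker = character(), individual = character(),
                        n_edges = integer())
  }
  per_marker <- table(factor(flags$marker, levels = rownames(dos)))
  per_individual <- table(factor(flags$individual, levels = ids))
  structure(list(flags = flags, per_marker = per_marker,
                 per_individual = per_individual,
                 inconsistent_markers = inconsistent),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("consistency_report: ", nrow(x$flags), " flags over ",
      length(x$inconsistent_markers), " inconsistent marker(s)\n", sep = "")
  invisible(x)
}

#' Impute genotypes forced by the pedigree
#'
#' After elimination at a consistent marker, any missing call whose
#' feasible set is a singleton is forced by the relatives' genotypes and
#' is filled in, with provenance recorded in the edit log (reason
#' \code{"mendel_impute"}). Ambiguous cells stay missing. Imputation
#' never creates a new inconsistency: the filled genotype was in every
#' relative's surviving combination.
#'
#' @param ped a normalized \code{pedigree}.
#' @param gm a \code{genotype_matrix}.
#' @return the updated \code{genotype_matrix}.
#' @export
impute_forced <- function(ped, gm) {
  dos <- gm$calls
  ids <- ped$id
  n <- length(ids)
  have <- ids %in% colnames(dos)
  col_of <- match(ids, colnames(dos))
  fi <- family_index(ped)
  for (k in seq_len(nrow(dos))) {
    obs_bits <- rep(7L, n)
    v <- dos[k, col_of[have]]
    obs_bits[have] <- ifelse(is.na(v), 7L, bitwShiftL(1L, v))
    if (!any(obs_bits[have] == 7L)) next
    bits <- eliminate_bits(fi, obs_bits, n)
    if (any(bits == 0L)) next
    forced <- have & obs_bits == 7L & bits %in% c(1L, 2L, 4L)
    if (any(forced)) {
      vals <- match(bits[forced], c(1L, 2L, 4L)) - 1L
      gm <- edit_calls(gm, rownames(dos)[k], ids[forced], vals,
                       reason = "mendel_impute")
    }
  }
  gm
}

#' Blank Mendelian-inconsistent calls until none remain
#'
#' Iterates \code{\link{find_inconsistencies}} and sets every flagged
#' call to missing (edit reason \code{"mendel_fix"}) until the data set
#' is consistent or \code{max_iter} is reached; after the first pass
#' only the previously inconsistent markers are re-checked. Blanking a
#' member of each minimal conflicting set removes that conflict, so the
#' loop terminates quickly in practice.
#'
#' @param ped a normalized \code{pedigree}.
#' @param gm a \code{genotype_matrix}.
#' @param max_iter iteration cap, default 10.
#' @return list: \code{gm} (edited matrix), \code{report} (first-pass
#'   consistency report), \code{iterations}, \code{n_blanked},
#'   \code{clean} (TRUE iff no inconsistency remains).
#' @export
resolve_inconsistencies <- function(ped, gm, max_iter = 10) {
  n_blanked <- 0L
  first <- NULL
  subset <- NULL
  for (it in seq_len(max_iter)) {
    rep <- find_inconsistencies(ped, gm, markers = subset)
    if (is.null(first)) first <- rep
    if (nrow(rep$flags) == 0)
      return(list(gm = gm, report = first, iterations = it - 1L,
                  n_blanked = n_blanked, clean = TRUE))
    keep <- rep$flags$individual %in% individuals(gm)
    fl <- rep$flags[keep, , drop = FALSE]
    # greedy repair: where one individual sits on several conflict
    # edges at a marker (a miscalled parent opposing many children),
    # blank that individual alone; the next sweep verifies
    pick <- do.call(rbind, lapply(split(fl, fl$marker), function(d) {
      if (max(d$n_edges) >= 2L) d[d$n_edges == max(d$n_edges), , drop = FALSE]
      else d
    }))
    gm <- edit_calls(gm, pick$marker, pick$individual, NA_integer_,
                     reason = "mendel_fix")
    n_blanked <- n_blanked + nrow(pick)
    subset <- rep$inconsistent_markers
  }
  last <- find_inconsistencies(ped, gm, markers = subset)
  list(gm = gm, report = first, iterations = max_iter,
       n_blanked = n_blanked, clean = nrow(last$flags) == 0)
}
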