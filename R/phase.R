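# forward / backward last-observation fill for integer vectors
na_ffill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- rep(NA_integer_, length(x))
  out[idx > 0] <- x[idx[idx > 0]]
  out
}
na_bfill <- function(x) rev(na_ffill(rev(x)))

other_allele <- function(a) ifelse(is.na(a), NA_character_,
                                   ifelse(a == "A", "B", "A"))

#' Phase a pedigree deterministically
#'
#' Produces a per-individual pair of allele sequences (maternal slot,
#' paternal slot) over the mapped markers, plus per-meiosis grandparental
#' origins, in three deterministic passes:
#' \enumerate{
#' \item Trio logic: wherever genotype configurations force the
#'   transmitted alleles (child homozygous, or child heterozygous with a
#'   homozygous parent), slots are assigned.
#' \item Parent het-site phasing from progeny: for each parent, het
#'   markers with unknown phase are oriented by a strict-majority vote of
#'   its children, each child voting for the orientation that avoids a
#'   crossover since the nearest phased informative marker (forward then
#'   backward sweep). Founders with no anchor get the convention "first
#'   informative het marker's A goes to homolog 1".
#' \item Double-heterozygote resolution: a child marker left ambiguous
#'   (child and both parents heterozygous) is assigned only when the
#'   flanking informative origins on a parental meiosis agree on both
#'   sides, implying the transmitted allele; when the two parents' implied
#'   alleles are both A or both B the genotype cannot be heterozygous and
#'   the cell is recorded as a phase anomaly and left unknown. Ambiguity
#'   is never guessed.
#' }
#'
#' @param gm a \code{genotype_matrix}.
#' @param ped a \code{pedigree}.
#' @param map a \code{genetic_map}; only mapped markers are phased.
#' @return object of class \code{homolog_matrix}: list with character
#'   matrices \code{mat}, \code{pat} (markers x individuals, values
#'   "A"/"B"/NA), integer origin matrices \code{origin_mat},
#'   \code{origin_pat} (1/2/NA: which parental homolog was transmitted),
#'   \code{anomalies} (data frame marker, individual, type), plus the
#'   \code{map} (restricted, in order) and \code{ped} used.
#' @export
phase_pedigree <- function(gm, ped, map) {
  mk <- map$marker[map$marker %in% markers(gm)]
  map <- map[match(mk, map$marker), , drop = FALSE]
  ids <- individuals(gm)[individuals(gm) %in% ped$id]
  dos <- gm$calls[mk, ids, drop = FALSE]
  nmk <- length(mk); nid <- length(ids)
  mat <- matrix(NA_character_, nmk, nid, dimnames = list(mk, ids))
  pat <- mat
  pi <- match(ids, ped$id)
  mother <- ped$mother[pi]; father <- ped$father[pi]
  has_m <- !is.na(mother) & mother %in% ids
  has_f <- !is.na(father) & father %in% ids

  ## pass 1: trio logic
  for (j in seq_len(nid)) {
    c <- dos[, j]
    mat[c == 0L & !is.na(c), j] <- "A"; pat[c == 0L & !is.na(c), j] <- "A"
    mat[c == 2L & !is.na(c), j] <- "B"; pat[c == 2L & !is.na(c), j] <- "B"
    het <- !is.na(c) & c == 1L
    if (has_m[j]) {
      gmo <- dos[, mother[j]]
      mat[het & gmo %in% 0L, j] <- "A"; pat[het & gmo %in% 0L, j] <- "B"
      mat[het & gmo %in% 2L, j] <- "B"; pat[het & gmo %in% 2L, j] <- "A"
    }
    if (has_f[j]) {
      gfa <- dos[, father[j]]
      amb <- het & is.na(mat[, j])
      pat[amb & gfa %in% 0L, j] <- "A"; mat[amb & gfa %in% 0L, j] <- "B"
      pat[amb & gfa %in% 2L, j] <- "B"; mat[amb & gfa %in% 2L, j] <- "A"
    }
  }

  lg_index <- split(seq_len(nmk), map$linkage_group)

  kids_mat <- split(which(has_m), mother[has_m])  # children grouped by mother
  kids_pat <- split(which(has_f), father[has_f])  # children grouped by father

  received <- function(p_id, kid_cols) {
    # markers x children matrix of alleles received from parent p
    sapply(kid_cols, function(j)
      if (identical(mother[j], p_id)) mat[, j] else pat[, j])
  }

  ## pass 2: phase parents' unknown het sites from progeny votes. The
  ## vote chain is run forward and backward independently; after
  ## aligning the two solutions (homolog labels are arbitrary for
  ## founders) only sites on which both directions agree are kept, so a
  ## chain flip must fool both directions to survive.
  chain_pass <- function(base_col, ord, rec, phet, allow_anchor) {
    col <- base_col
    last_origin <- rep(NA_integer_, ncol(rec))
    anchored <- FALSE
    for (k in ord) {
      if (!phet[k]) next
      if (is.na(col[k])) {
        votes_A1 <- 0L; votes_B1 <- 0L
        for (ci in seq_len(ncol(rec))) {
          r <- rec[k, ci]
          if (is.na(r) || is.na(last_origin[ci])) next
          want_mat <- if (last_origin[ci] == 1L) r else other_allele(r)
          if (want_mat == "A") votes_A1 <- votes_A1 + 1L
          else votes_B1 <- votes_B1 + 1L
        }
        # strict margin guards against flips from sparse votes
        if (votes_A1 >= votes_B1 + 2L) col[k] <- "A"
        else if (votes_B1 >= votes_A1 + 2L) col[k] <- "B"
        else if (!anchored && allow_anchor &&
                 votes_A1 == 0L && votes_B1 == 0L) col[k] <- "A"
      }
      if (!is.na(col[k])) {
        anchored <- TRUE
        for (ci in seq_len(ncol(rec))) {
          r <- rec[k, ci]
          if (!is.na(r)) last_origin[ci] <- if (r == col[k]) 1L else 2L
        }
      }
    }
    col
  }
  parent_ids <- union(names(kids_mat), names(kids_pat))
  parent_ids <- parent_ids[order(match(parent_ids, ids))]
  for (p in parent_ids) {
    pj <- match(p, ids)
    kid_cols <- c(kids_mat[[p]], kids_pat[[p]])
    rec <- received(p, kid_cols)
    if (is.null(dim(rec))) rec <- matrix(rec, ncol = length(kid_cols))
    phet <- !is.na(dos[, pj]) & dos[, pj] == 1L
    for (lg in names(lg_index)) {
      kk <- lg_index[[lg]]
      base <- mat[, pj]
      # founder-style convention ("first informative het site's A goes
      # to homolog 1") applies only when no het site in the linkage
      # group was phased through the parent's own parents
      allow_anchor <- !any(!is.na(base[kk]) & phet[kk])
      fwd <- chain_pass(base, kk, rec, phet, allow_anchor)
      bwd <- chain_pass(base, rev(kk), rec, phet, allow_anchor)
      both <- kk[!is.na(fwd[kk]) & !is.na(bwd[kk])]
      if (length(both) && mean(fwd[both] == bwd[both]) < 0.5)
        bwd[kk] <- other_allele(bwd[kk])   # label flip between runs
      res <- ifelse(is.na(fwd[kk]), bwd[kk],
                    ifelse(is.na(bwd[kk]), fwd[kk],
                           ifelse(fwd[kk] == bwd[kk], fwd[kk], NA)))
      new_na <- is.na(base[kk]) & !is.na(res) & phet[kk]
      mat[kk[new_na], pj] <- res[new_na]
      pat[kk[new_na], pj] <- other_allele(res[new_na])
    }
  }

  origin_one <- function(p_col, kid_col, side) {
    # origin of each marker's transmitted allele in meiosis p -> kid
    r <- if (side == "mat") mat[, kid_col] else pat[, kid_col]
    p_het <- !is.na(dos[, p_col]) & dos[, p_col] == 1L
    o <- rep(NA_integer_, nmk)
    okk <- p_het & !is.na(mat[, p_col]) & !is.na(r)
    o[okk] <- ifelse(r[okk] == mat[okk, p_col], 1L, 2L)
    o
  }

  compute_origins <- function() {
    om <- matrix(NA_integer_, nmk, nid, dimnames = list(mk, ids))
    op <- om
    for (j in which(has_m)) om[, j] <- origin_one(match(mother[j], ids), j, "mat")
    for (j in which(has_f)) op[, j] <- origin_one(match(father[j], ids), j, "pat")
    list(om = om, op = op)
  }
  ori <- compute_origins()

  ## pass 3: conservative double-het resolution from flanking origins
  anomalies <- list()
  for (j in seq_len(nid)) {
    amb <- which(!is.na(dos[, j]) & dos[, j] == 1L & is.na(mat[, j]))
    if (!length(amb)) next
    for (lg in names(lg_index)) {
      kk <- lg_index[[lg]]
      a_here <- intersect(amb, kk)
      if (!length(a_here)) next
      imp_m <- rep(NA_character_, nmk); imp_f <- imp_m
      if (has_m[j]) {
        mo <- match(mother[j], ids)
        o <- ori$om[kk, j]
        stable <- ifelse(!is.na(na_ffill(o)) & !is.na(na_bfill(o)) &
                           na_ffill(o) == na_bfill(o), na_ffill(o), NA_integer_)
        hom <- ifelse(is.na(stable), NA_character_,
                      ifelse(stable == 1L, mat[kk, mo], pat[kk, mo]))
        imp_m[kk] <- hom
      }
      if (has_f[j]) {
        fa <- match(father[j], ids)
        o <- ori$op[kk, j]
        stable <- ifelse(!is.na(na_ffill(o)) & !is.na(na_bfill(o)) &
                           na_ffill(o) == na_bfill(o), na_ffill(o), NA_integer_)
        hom <- ifelse(is.na(stable), NA_character_,
                      ifelse(stable == 1L, mat[kk, fa], pat[kk, fa]))
        imp_f[kk] <- hom
      }
      for (k in a_here) {
        a <- imp_m[k]; b <- imp_f[k]
        if (!is.na(a) && !is.na(b)) {
          if (a == b) {
            anomalies[[length(anomalies) + 1]] <- data.frame(
              marker = mk[k], individual = ids[j],
              type = "implied_hom_conflict", stringsAsFactors = FALSE)
          } else { mat[k, j] <- a; pat[k, j] <- b }
        } else if (!is.na(a)) { mat[k, j] <- a; pat[k, j] <- other_allele(a) }
        else if (!is.na(b)) { pat[k, j] <- b; mat[k, j] <- other_allele(b) }
      }
    }
  }
  ori <- compute_origins()
  anomalies <- if (length(anomalies)) do.call(rbind, anomalies) else
    data.frame(marker = character(), individual = character(),
               type = character())
  structure(list(mat = mat, pat = pat, origin_mat = ori$om,
                 origin_pat = ori$op, anomalies = anomalies, map = map,
                 ped = ped),
            class = "homolog_matrix")
}

#' @export
print.homolog_matrix <- function(x, ...) {
  cat("homolog_matrix: ", nrow(x$mat), " markers x ", ncol(x$mat),
      " individuals; ", round(100 * mean(!is.na(x$mat)), 1),
      "% maternal slots phased\n", sep = "")
  invisible(x)
}

#' Detect recombination events from phased origins
#'
#' For each meiosis (parent -> child) and linkage group, a switch of
#' grandparental origin between two consecutive informative markers is
#' one recombination event, reported with its flanking-marker interval.
#' A switch before the first informative marker of a chromosome is
#' undetectable by definition and yields no event.
#'
#' @param hm a \code{homolog_matrix}.
#' @return data frame of events: parent, child, side (mat/pat),
#'   linkage_group, left_marker, right_marker, cm_left, cm_right,
#'   from_origin, to_origin, inf_left, inf_right (indices of the flanks
#'   in the meiosis' informative-marker sequence).
#' @export
detect_recombinations <- function(hm) {
  map <- hm$map
  ids <- colnames(hm$mat)
  pi <- match(ids, hm$ped$id)
  out <- list()
  scan <- function(origin_col, parent, child, side) {
    for (lg in unique(map$linkage_group)) {
      kk <- which(map$linkage_group == lg)
      o <- origin_col[kk]
      inf <- which(!is.na(o))
      if (length(inf) < 2) next
      ov <- o[inf]
      sw <- which(ov[-1] != ov[-length(ov)])
      for (s in sw) {
        out[[length(out) + 1]] <<- data.frame(
          parent = parent, child = child, side = side, linkage_group = lg,
          left_marker = map$marker[kk[inf[s]]],
          right_marker = map$marker[kk[inf[s + 1]]],
          cm_left = map$cm[kk[inf[s]]], cm_right = map$cm[kk[inf[s + 1]]],
          from_origin = ov[s], to_origin = ov[s + 1],
          inf_left = s, inf_right = s + 1, stringsAsFactors = FALSE)
      }
    }
  }
  for (j in seq_along(ids)) {
    mo <- hm$ped$mother[pi[j]]; fa <- hm$ped$father[pi[j]]
    if (!is.na(mo) && mo %in% ids && any(!is.na(hm$origin_mat[, j])))
      scan(hm$origin_mat[, j], mo, ids[j], "mat")
    if (!is.na(fa) && fa %in% ids && any(!is.na(hm$origin_pat[, j])))
      scan(hm$origin_pat[, j], fa, ids[j], "pat")
  }
  if (!length(out))
    return(data.frame(parent = character(), child = character(),
                      side = character(), linkage_group = character(),
                      left_marker = character(), right_marker = character(),
                      cm_left = numeric(), cm_right = numeric(),
                      from_origin = integer(), to_origin = integer(),
                      inf_left = integer(), inf_right = integer()))
  do.call(rbind, out)
}

#' Detect double recombinations within a short window
#'
#' Two consecutive recombination events in one meiosis that bracket a
#' deviant segment shorter than \code{window_cm} form a double
#' recombination; when the deviant segment is a single informative
#' marker the case is a singleton (one marker whose phased allele
#' implies two flanking crossovers — the signature of a
#' Mendelian-consistent call error).
#'
#' @param events event data frame from \code{\link{detect_recombinations}}.
#' @param window_cm maximum deviant-segment span in cM, default 10.
#' @return data frame: parent, child, side, linkage_group, marker_first,
#'   marker_last, span_cm, n_markers (informative markers in the deviant
#'   segment), is_singleton, marker (= marker_first when singleton).
#' @export
detect_double_recomb <- function(events, window_cm = 10) {
  empty <- data.frame(parent = character(), child = character(),
                      side = character(), linkage_group = character(),
                      marker_first = character(), marker_last = character(),
                      span_cm = numeric(), n_markers = integer(),
                      is_singleton = logical(), marker = character())
  if (!nrow(events)) return(empty)
  key <- paste(events$parent, events$child, events$side,
               events$linkage_group, sep = "\r")
  out <- list()
  for (grp in split(seq_len(nrow(events)), key)) {
    e <- events[grp[order(events$cm_left[grp])], , drop = FALSE]
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1)) {
      span <- e$cm_left[i + 1] - e$cm_right[i]
      if (span < window_cm) {
        n_mark <- e$inf_left[i + 1] - e$inf_right[i] + 1L
        out[[length(out) + 1]] <- data.frame(
          parent = e$parent[i], child = e$child[i], side = e$side[i],
          linkage_group = e$linkage_group[i],
          marker_first = e$right_marker[i], marker_last = e$left_marker[i + 1],
          span_cm = span, n_markers = n_mark,
          is_singleton = n_mark == 1L,
          marker = if (n_mark == 1L) e$right_marker[i] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Classify probable causes of double recombinations
#'
#' Groups singleton double recombinations (and phase anomalies recorded
#' during phasing) by marker and ranks a curation worklist. A shared
#' marker with a clear excess of heterozygous calls over the
#' Hardy-Weinberg expectation carries the relabelled-cluster signature
#' (a systematically miscalled homozygote class turns into spurious
#' heterozygotes, which also depletes opposing-homozygote counts); a
#' shared marker without it points at a wrong map position (a
#' mispositioned marker shows origin switches in exactly the meioses
#' that recombine between its stored and true location). Markers whose
#' heterozygote excess is extreme enter the worklist as cluster
#' suspects even without recombination signals — a fully relabelled
#' cluster can leave no informative meiosis at all. Remaining markers
#' below \code{min_individuals} are isolated — a single call error or a
#' genuine double crossover — and are ranked last, ancestors before
#' seedlings, mirroring the rule that shared-region double
#' recombinations must be resolved first.
#'
#' @param drs double-recombination data frame from
#'   \code{\link{detect_double_recomb}}.
#' @param gm the \code{genotype_matrix} (for the signal individuals'
#'   calls).
#' @param ped the \code{pedigree} (selected flags order the isolated
#'   tail of the worklist).
#' @param anomalies optional phase-anomaly data frame (from
#'   \code{homolog_matrix$anomalies}); anomaly cells count as signals.
#' @param min_individuals signal individuals needed for a shared cause,
#'   default 3.
#' @param extreme_het_excess heterozygote excess above which a marker
#'   is a cluster suspect regardless of recombination signals, default
#'   0.2.
#' @return data frame (the worklist, in priority order): marker, cause
#'   ("clustering", "map", "isolated"), n_individuals, n_families,
#'   priority rank.
#' @export
classify_dr_causes <- function(drs, gm, ped, anomalies = NULL,
                               min_individuals = 3,
                               extreme_het_excess = 0.2) {
  sig <- data.frame(marker = character(), individual = character(),
                    parent = character())
  if (nrow(drs)) {
    s <- drs[drs$is_singleton, , drop = FALSE]
    if (nrow(s))
      sig <- rbind(sig, data.frame(marker = s$marker, individual = s$child,
                                   parent = s$parent))
  }
  if (!is.null(anomalies) && nrow(anomalies))
    sig <- rbind(sig, data.frame(marker = anomalies$marker,
                                 individual = anomalies$individual,
                                 parent = NA_character_))
  ## a relabelled major homozygote cluster can leave too few
  ## informative meioses for any recombination signal: the whole marker
  ## is heterozygous. Such markers show an extreme excess of
  ## heterozygotes over the Hardy-Weinberg expectation (equivalently,
  ## suspiciously few opposing homozygotes) and enter the worklist
  ## directly.
  dos <- gm$calls
  qhat <- rowMeans(dos, na.rm = TRUE) / 2
  hexc <- rowMeans(dos == 1L, na.rm = TRUE) - 2 * qhat * (1 - qhat)
  hexc[is.na(hexc)] <- 0
  extreme <- rownames(dos)[hexc > extreme_het_excess]
  if (!nrow(sig) && !length(extreme))
    return(data.frame(marker = character(), cause = character(),
                      n_individuals = integer(), n_families = integer(),
                      priority = integer()))
  sig <- unique(sig[, c("marker", "individual")])
  fam_of <- function(id) {
    i <- match(id, ped$id)
    ifelse(is.na(i), NA, paste(ped$mother[i], ped$father[i]))
  }
  rows <- lapply(split(sig$individual, sig$marker), unique)
  out <- data.frame(marker = names(rows),
                    n_individuals = lengths(rows),
                    n_families = vapply(rows, function(v)
                      length(unique(stats::na.omit(fam_of(v)))), 0L),
                    stringsAsFactors = FALSE)
  missing_extreme <- setdiff(extreme, out$marker)
  if (length(missing_extreme))
    out <- rbind(out, data.frame(marker = missing_extreme,
                                 n_individuals = 0L, n_families = 0L,
                                 stringsAsFactors = FALSE))
  out$cause <- "isolated"
  shared <- out$n_individuals >= min_individuals | out$marker %in% extreme
  # shared markers with a clear heterozygote excess carry the
  # relabelled-cluster signature; shared markers without it point at a
  # wrong map position (origin switches in recombining meioses only)
  out$cause[shared] <- ifelse(hexc[out$marker[shared]] > 0.1,
                              "clustering", "map")
  sel <- vapply(rows, function(v)
    any(ped$selected[match(v, ped$id)] %in% TRUE), TRUE)
  out$.sel <- sel[out$marker]
  out <- out[order(out$cause == "isolated", -out$n_individuals,
                   !out$.sel, out$marker), ]
  out$.sel <- NULL
  out$priority <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("marker", "cause", "n_individuals", "n_families", "priority")]
}

#' Evaluate a candidate map move for a marker
#'
#' Re-runs phasing and double-recombination detection with the marker
#' placed at the candidate position, and accepts the move only if the
#' total double-recombination count strictly decreases and no meiosis
#' gains a double recombination it did not have before. Markers whose
#' excess double recombinations no single move can resolve are flagged
#' for removal.
#'
#' @param gm a \code{genotype_matrix}.
#' @param ped a \code{pedigree}.
#' @param map a \code{genetic_map} containing the marker.
#' @param marker marker id to move.
#' @param candidate_cm candidate cM position on the marker's linkage
#'   group.
#' @param window_cm double-recombination window, default 10.
#' @return list: accept (logical), dr_before, dr_after, delta,
#'   gained_meioses (character vector of meioses that would gain).
#' @export
evaluate_map_move <- function(gm, ped, map, marker, candidate_cm,
                              window_cm = 10) {
  i <- match(marker, map$marker)
  if (is.na(i)) stop("marker not on the map")
  lg <- map$linkage_group[i]
  rng <- range(map$cm[map$linkage_group == lg])
  if (candidate_cm < rng[1] - 20 || candidate_cm > rng[2] + 20)
    stop("candidate position falls off linkage group ", lg)
  dr_of <- function(m) {
    hm <- phase_pedigree(gm, ped, m)
    detect_double_recomb(detect_recombinations(hm), window_cm)
  }
  key <- function(d) if (nrow(d)) paste(d$parent, d$child, d$side) else character(0)
  before <- dr_of(map)
  map2 <- map
  map2$cm[i] <- candidate_cm
  map2 <- genetic_map(map2$marker, map2$linkage_group, map2$cm, map2$bp)
  after <- dr_of(map2)
  tb <- table(key(before)); ta <- table(key(after))
  meioses <- union(names(tb), names(ta))
  gained <- meioses[ifelse(is.na(ta[meioses]), 0, ta[meioses]) >
                      ifelse(is.na(tb[meioses]), 0, tb[meioses])]
  list(accept = nrow(after) < nrow(before) && length(gained) == 0,
       dr_before = nrow(before), dr_after = nrow(after),
       delta = nrow(after) - nrow(before), gained_meioses = gained)
}

#' Resolve a family-wide phase conflict at a marker
#'
#' When most progeny of one parent show a singleton double recombination
#' at the same marker while one or two sibs do not (because those sibs
#' carry a genuine recombination whose placement at this marker corrupted
#' the parent's inferred phase), the genuine-recombination individuals
#' have their genotype at the pivot marker set to missing (edit reason
#' \code{"phase_fix"}); re-phasing then orients the parent from the
#' unaffected sibs and the false double recombinations disappear. If the
#' pattern is not matched no edit is made and the case stays on the
#' manual worklist.
#'
#' @param gm a \code{genotype_matrix}.
#' @param hm the current \code{homolog_matrix}.
#' @param drs double-recombination data frame.
#' @param min_sibs minimum number of sibs sharing the singleton, default 3.
#' @return list: \code{gm} (possibly edited), \code{edits} (data frame
#'   marker, individual of blanked cells).
#' @export
resolve_phase_conflict <- function(gm, hm, drs, min_sibs = 3) {
  edits <- data.frame(marker = character(), individual = character())
  s <- drs[drs$is_singleton, , drop = FALSE]
  if (!nrow(s)) return(list(gm = gm, edits = edits))
  key <- paste(s$parent, s$marker)
  for (grp in split(seq_len(nrow(s)), key)) {
    parent <- s$parent[grp[1]]; marker <- s$marker[grp[1]]
    affected <- unique(s$child[grp])
    if (length(affected) < min_sibs) next
    # informative sibs: children of this parent with an origin call at
    # the pivot marker
    ids <- colnames(hm$mat)
    pi <- match(ids, hm$ped$id)
    is_kid_m <- hm$ped$mother[pi] %in% parent
    is_kid_f <- hm$ped$father[pi] %in% parent
    k <- match(marker, rownames(hm$mat))
    inf <- ids[(is_kid_m & !is.na(hm$origin_mat[k, ])) |
               (is_kid_f & !is.na(hm$origin_pat[k, ]))]
    others <- setdiff(inf, affected)
    if (length(others) >= 1 && length(others) <= 2 &&
        length(affected) >= length(inf) - 2) {
      gm <- edit_calls(gm, marker, others, NA_integer_, reason = "phase_fix")
      edits <- rbind(edits, data.frame(marker = marker, individual = others))
    }
  }
  list(gm = gm, edits = edits)
}

#' Graphical genotypes of a family
#'
#' The grandparental-origin state of each child at each marker for one
#' parent's meioses — the matrix behind graphical-genotyping plots used
#' to spot map-order and call errors (a mispositioned marker shows as an
#' isolated discordant column, a crossover as a single block boundary
#' per child).
#'
#' @param hm a \code{homolog_matrix}.
#' @param parent parent id whose meioses to export.
#' @param path optional CSV path to write the matrix to.
#' @return integer matrix children x markers with values 1, 2, NA.
#' @export
graphical_genotypes <- function(hm, parent, path = NULL) {
  ids <- colnames(hm$mat)
  pi <- match(ids, hm$ped$id)
  km <- ids[hm$ped$mother[pi] %in% parent]
  kf <- ids[hm$ped$father[pi] %in% parent]
  rows <- rbind(if (length(km)) t(hm$origin_mat[, km, drop = FALSE]),
                if (length(kf)) t(hm$origin_pat[, kf, drop = FALSE]))
  if (is.null(rows)) rows <- matrix(NA_integer_, 0, nrow(hm$mat),
                                    dimnames = list(NULL, rownames(hm$mat)))
  rownames(rows) <- c(km, kf)
  if (!is.null(path))
    utils::write.csv(rows, path, row.names = TRUE)
  rows
}
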