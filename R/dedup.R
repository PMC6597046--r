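#' Pairwise genotype identity between two individuals
#'
#' Identity-by-state fraction: the proportion of markers called in both
#' individuals at which the two genotype calls are identical. Clones,
#' sports and resampled duplicates sit near 1; with the duplicate
#' threshold calibrated so that all known duplicates exceed it, the IBS
#' fraction preserves the behaviour of an IBD-proportion screen for
#' near-identical material.
#'
#' @param gm a \code{genotype_matrix}.
#' @param a,b individual ids.
#' @param min_shared minimum number of co-called markers, default 500.
#' @return fraction in [0, 1], or NA (with a warning) when fewer than
#'   \code{min_shared} markers are co-called.
#' @export
pairwise_identity <- function(gm, a, b, min_shared = 500) {
  x <- gm$calls[, a]; y <- gm$calls[, b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_shared) {
    warning("only ", sum(ok), " co-called markers for (", a, ", ", b,
            "); identity undefined")
    return(NA_real_)
  }
  mean(x[ok] == y[ok])
}

# All-pairs IBS identity matrix (NA below min_shared).
identity_matrix <- function(gm, min_shared = 500) {
  dos <- gm$calls
  n <- ncol(dos)
  ids <- colnames(dos)
  obs <- !is.na(dos)
  co <- crossprod(obs)                       # co-called counts
  same <- matrix(0, n, n)
  for (g in 0:2) {
    gk <- dos == g & obs
    same <- same + crossprod(gk)
  }
  idm <- same / co
  idm[co < min_shared] <- NA
  dimnames(idm) <- list(ids, ids)
  idm
}

#' Find groups of duplicate individuals
#'
#' All pairs with identity above \code{threshold} (default 0.97, the
#' calibrated duplicate cut-off) are linked; groups are the transitive
#' closure (union-find) of the linked pairs.
#'
#' @param gm a \code{genotype_matrix}.
#' @param threshold identity threshold, default 0.97.
#' @param min_shared minimum co-called markers per pair.
#' @return list of character vectors (each a group of >= 2 ids), sorted
#'   for determinism.
#' @export
find_duplicate_groups <- function(gm, threshold = 0.97, min_shared = 500) {
  idm <- identity_matrix(gm, min_shared)
  ids <- colnames(idm)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  hits <- which(upper.tri(idm) & !is.na(idm) & idm > threshold, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    ri <- find(hits[k, 1]); ci <- find(hits[k, 2])
    if (ri != ci) parent[max(ri, ci)] <- min(ri, ci)
  }
  roots <- vapply(seq_along(ids), find, 1L)
  grp <- split(ids, roots)
  grp <- grp[lengths(grp) >= 2]
  grp <- lapply(grp, sort)
  unname(grp[order(vapply(grp, `[`, "", 1))])
}

#' Decide which member of each duplicate group to keep
#'
#' If the group members' pedigree records agree, the first id in sort
#' order is kept. If records differ, the member whose recorded parents
#' pass verification (per the supplied parentage verdicts) is the
#' true-to-type one and is kept. When two unselected seedlings of the
#' same family are duplicates it cannot be decided which is true-to-type
#' and both are targeted for re-sampling; undecidable cases likewise.
#'
#' @param groups list of duplicate groups (from
#'   \code{\link{find_duplicate_groups}}).
#' @param ped a \code{pedigree}.
#' @param verdicts optional parentage verdict data frame (from
#'   \code{\link{verify_parentage}}) with columns \code{child},
#'   \code{verdict}; a member "passes" if it has no rejected relation.
#' @return data frame: group, member, decision (keep/drop/resample).
#' @export
resolve_duplicates <- function(groups, ped, verdicts = NULL) {
  out <- list()
  for (g in seq_along(groups)) {
    members <- sort(groups[[g]])
    i <- match(members, ped$id)
    rec <- paste(ped$mother[i], ped$father[i])
    same_family <- length(unique(rec)) == 1 && !anyNA(ped$mother[i])
    unselected <- !ped$selected[i] %in% TRUE
    decision <- rep("drop", length(members))
    if (same_family && all(unselected) && length(members) == 2) {
      decision[] <- "resample"
    } else if (length(unique(rec)) == 1) {
      decision[1] <- "keep"
    } else {
      passes <- rep(NA, length(members))
      if (!is.null(verdicts) && nrow(verdicts)) {
        passes <- vapply(members, function(m) {
          v <- verdicts$verdict[verdicts$child == m]
          length(v) > 0 && !any(v == "rejected")
        }, TRUE)
      }
      if (sum(passes, na.rm = TRUE) == 1) {
        decision[which(passes)] <- "keep"
        decision[-which(passes)] <- "resample"
      } else {
        decision[] <- "resample"
      }
    }
    out[[g]] <- data.frame(group = g, member = members, decision = decision,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group = integer(), member = character(),
                      decision = character()))
  do.call(rbind, out)
}
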