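#' Define haploblock borders from recombinations in selected material
#'
#' Haploblocks are map segments in which no recombination is observed in
#' selected material (cultivars, selections, parents). Recombination
#' events are processed smallest interval first; an event whose interval
#' is already cut by an existing border is skipped (one border can
#' account for several overlapping events), otherwise a border is placed
#' at the cM midpoint of its interval, snapped to the boundary between
#' the two markers flanking the midpoint (ties toward the lower-cM
#' side). The resulting cut set partitions each linkage group's markers
#' into blocks; no border is removable without leaving some event uncut.
#'
#' @param events recombination events (from
#'   \code{\link{detect_recombinations}}); when \code{ped} is given only
#'   events whose child is selected material are used, otherwise all
#'   supplied events are.
#' @param map a \code{genetic_map}.
#' @param ped optional \code{pedigree} supplying the selected flags.
#' @return object of class \code{haploblock_set}: list with
#'   \code{blocks} (data frame: block, linkage_group, cm_start, cm_end,
#'   n_markers), \code{markers} (list of marker-id vectors per block)
#'   and the \code{map}.
#' @export
define_borders <- function(events, map, ped = NULL) {
  if (!is.null(ped) && nrow(events)) {
    sel <- ped$id[ped$selected %in% TRUE]
    events <- events[events$child %in% sel, , drop = FALSE]
  }
  lgs <- unique(map$linkage_group)
  cuts <- stats::setNames(vector("list", length(lgs)), lgs)
  if (nrow(events)) {
    events$len <- events$cm_right - events$cm_left
    o <- order(events$len, events$linkage_group, events$cm_left,
               events$child)
    for (i in o) {
      lg <- events$linkage_group[i]
      kk <- which(map$linkage_group == lg)
      gi <- match(events$left_marker[i], map$marker[kk])
      gj <- match(events$right_marker[i], map$marker[kk])
      if (is.na(gi) || is.na(gj) || gj <= gi) next
      gaps <- gi:(gj - 1)                       # gap g = between kk[g], kk[g+1]
      if (any(gaps %in% cuts[[lg]])) next
      m <- (events$cm_left[i] + events$cm_right[i]) / 2
      below <- gaps[map$cm[kk[gaps]] < m]
      g <- if (length(below)) max(below) else gaps[1]
      cuts[[lg]] <- c(cuts[[lg]], g)
    }
  }
  blocks <- list(); mlist <- list(); bid <- 0L
  for (lg in lgs) {
    kk <- which(map$linkage_group == lg)
    bounds <- sort(unique(cuts[[lg]]))
    starts <- c(1, bounds + 1)
    ends <- c(bounds, length(kk))
    for (b in seq_along(starts)) {
      bid <- bid + 1L
      idx <- kk[starts[b]:ends[b]]
      blocks[[bid]] <- data.frame(
        block = paste0(lg, "_", b), linkage_group = lg,
        cm_start = map$cm[idx[1]], cm_end = map$cm[idx[length(idx)]],
        n_markers = length(idx), stringsAsFactors = FALSE)
      mlist[[bid]] <- map$marker[idx]
    }
  }
  blocks <- do.call(rbind, blocks)
  names(mlist) <- blocks$block
  structure(list(blocks = blocks, markers = mlist, map = map),
            class = "haploblock_set")
}

#' @export
print.haploblock_set <- function(x, ...) {
  cat("haploblock_set: ", nrow(x$blocks), " blocks over ",
      length(unique(x$blocks$linkage_group)), " linkage group(s)\n", sep = "")
  invisible(x)
}

#' Split a haploblock at a recombination site
#'
#' Replaces one block by two, cutting after \code{after_marker} — used
#' when a recombination inside a block is discovered in (possibly
#' ungenotyped-progenitor) selected material. Haplotype codes for the
#' two new blocks must be re-derived (\code{\link{assign_haplotypes}});
#' codes of all other blocks are untouched by construction.
#'
#' @param hbs a \code{haploblock_set}.
#' @param block block id to split.
#' @param after_marker marker id within the block after which to cut.
#' @return the updated \code{haploblock_set}.
#' @export
split_block <- function(hbs, block, after_marker) {
  i <- match(block, hbs$blocks$block)
  if (is.na(i)) stop("unknown block ", block)
  mk <- hbs$markers[[block]]
  at <- match(after_marker, mk)
  if (is.na(at) || at >= length(mk))
    stop("split point not inside block ", block)
  cm <- hbs$map$cm[match(mk, hbs$map$marker)]
  new_rows <- data.frame(
    block = paste0(block, c("a", "b")),
    linkage_group = hbs$blocks$linkage_group[i],
    cm_start = c(cm[1], cm[at + 1]),
    cm_end = c(cm[at], cm[length(cm)]),
    n_markers = c(at, length(mk) - at), stringsAsFactors = FALSE)
  before <- seq_len(i - 1)
  after <- setdiff(seq_len(nrow(hbs$blocks)), c(before, i))
  hbs$blocks <- rbind(hbs$blocks[before, ], new_rows, hbs$blocks[after, ])
  rownames(hbs$blocks) <- NULL
  ml <- hbs$markers
  ml <- append(ml[names(ml) != block],
               stats::setNames(list(mk[1:at], mk[(at + 1):length(mk)]),
                               new_rows$block),
               after = i - 1)
  hbs$markers <- ml[hbs$blocks$block]
  hbs
}

#' Assign integer-coded haplotypes per block
#'
#' Each individual's two phased allele strings over a block's markers
#' are mapped to integer codes through a per-block dictionary. Codes are
#' assigned in order of first appearance, scanning individuals in input
#' order (maternal slot before paternal), so the coding is deterministic
#' for a fixed individual order. Strings containing unknown alleles get
#' no code yet (the string is kept, pending
#' \code{\link{resolve_missing_haplotype}}).
#'
#' @param hm a \code{homolog_matrix}.
#' @param hbs a \code{haploblock_set}.
#' @return object of class \code{haplotype_matrix}: list with integer
#'   matrices \code{codes_mat}, \code{codes_pat} (blocks x individuals),
#'   character matrices \code{strings_mat}, \code{strings_pat} (allele
#'   strings, "?" for unknown), \code{dictionary} (per block, code ->
#'   string), and \code{blocks} (the \code{haploblock_set}).
#' @export
assign_haplotypes <- function(hm, hbs) {
  ids <- colnames(hm$mat)
  bn <- hbs$blocks$block
  str_of <- function(slot, mk) {
    s <- slot[mk, , drop = FALSE]
    s[is.na(s)] <- "?"
    apply(s, 2, paste, collapse = "")
  }
  codes_mat <- matrix(NA_integer_, length(bn), length(ids),
                      dimnames = list(bn, ids))
  codes_pat <- codes_mat
  strings_mat <- matrix(NA_character_, length(bn), length(ids),
                        dimnames = list(bn, ids))
  strings_pat <- strings_mat
  dict <- stats::setNames(vector("list", length(bn)), bn)
  for (b in bn) {
    mk <- hbs$markers[[b]]
    sm <- str_of(hm$mat, mk); sp <- str_of(hm$pat, mk)
    strings_mat[b, ] <- sm; strings_pat[b, ] <- sp
    seen <- character(0)
    for (i in seq_along(ids)) for (s in c(sm[i], sp[i]))
      if (!grepl("?", s, fixed = TRUE) && !(s %in% seen))
        seen <- c(seen, s)
    dict[[b]] <- stats::setNames(seen, seq_along(seen))
    code_of <- stats::setNames(seq_along(seen), seen)
    known_m <- !grepl("?", sm, fixed = TRUE)
    known_p <- !grepl("?", sp, fixed = TRUE)
    codes_mat[b, known_m] <- code_of[sm[known_m]]
    codes_pat[b, known_p] <- code_of[sp[known_p]]
  }
  structure(list(codes_mat = codes_mat, codes_pat = codes_pat,
                 strings_mat = strings_mat, strings_pat = strings_pat,
                 dictionary = dict, blocks = hbs),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix: ", nrow(x$codes_mat), " blocks x ",
      ncol(x$codes_mat), " individuals; ",
      sum(is.na(x$codes_mat)) + sum(is.na(x$codes_pat)),
      " unresolved slot(s)\n", sep = "")
  invisible(x)
}

# nearest resolved flanking origin (which parental homolog the
# individual carries) on the same linkage group, searching away from
# block index bi; returns 1, 2 or NA
flanking_origin <- function(ht, id, parent, bi, side_codes) {
  blocks <- ht$blocks$blocks
  lg <- blocks$linkage_group[bi]
  same_lg <- which(blocks$linkage_group == lg)
  ord <- same_lg[order(abs(same_lg - bi))]
  for (fb in setdiff(ord, bi)) {
    my <- side_codes[fb, id]
    if (is.na(my)) next
    p1 <- ht$codes_mat[fb, parent]; p2 <- ht$codes_pat[fb, parent]
    if (is.na(p1) || is.na(p2) || p1 == p2) next
    if (my == p1) return(1L)
    if (my == p2) return(2L)
  }
  NA_integer_
}

#' Resolve a haplotype containing missing SNP alleles
#'
#' A haplotype string with unknown positions (e.g. \code{"A?BA"}) is
#' matched against the transmitting parent's two haplotypes at the
#' block: if exactly one parental haplotype agrees at every known
#' position it is adopted. If both agree, the nearest flanking blocks
#' where the individual's inherited parental homolog is identifiable are
#' consulted and the candidate on that same homolog is chosen
#' (minimizing recombination); if still ambiguous the slot stays
#' unresolved.
#'
#' @param ht a \code{haplotype_matrix}.
#' @param individual individual id.
#' @param block block id.
#' @param side \code{"mat"} (candidate haplotypes come from the mother)
#'   or \code{"pat"} (from the father).
#' @param ped the \code{pedigree}.
#' @return list: \code{resolved} (logical), \code{code}, \code{string}.
#' @export
resolve_missing_haplotype <- function(ht, individual, block, side, ped) {
  bi <- match(block, ht$blocks$blocks$block)
  strings <- if (side == "mat") ht$strings_mat else ht$strings_pat
  codes <- if (side == "mat") ht$codes_mat else ht$codes_pat
  s <- strings[bi, individual]
  unresolved <- list(resolved = FALSE, code = NA_integer_, string = s)
  if (!grepl("?", s, fixed = TRUE))
    return(list(resolved = TRUE, code = codes[bi, individual], string = s))
  p <- if (side == "mat") ped$mother[match(individual, ped$id)]
       else ped$father[match(individual, ped$id)]
  if (is.na(p) || !(p %in% colnames(strings))) return(unresolved)
  cand_codes <- c(ht$codes_mat[bi, p], ht$codes_pat[bi, p])
  cand_codes <- cand_codes[!is.na(cand_codes)]
  if (!length(cand_codes)) return(unresolved)
  dict <- ht$dictionary[[block]]
  pattern <- paste0("^", gsub("?", ".", s, fixed = TRUE), "$")
  matches <- unique(cand_codes[grepl(pattern, dict[as.character(cand_codes)])])
  if (length(matches) == 1)
    return(list(resolved = TRUE, code = matches,
                string = unname(dict[as.character(matches)])))
  if (length(matches) == 2) {
    o <- flanking_origin(ht, individual, p, bi, codes)
    if (!is.na(o)) {
      pick <- c(ht$codes_mat[bi, p], ht$codes_pat[bi, p])[o]
      if (!is.na(pick) && pick %in% matches)
        return(list(resolved = TRUE, code = pick,
                    string = unname(dict[as.character(pick)])))
    }
  }
  unresolved
}

#' Resolve all unresolved haplotype slots
#'
#' Applies \code{\link{resolve_missing_haplotype}} to every slot whose
#' string contains unknowns, writing resolved codes and strings back.
#' @param ht a \code{haplotype_matrix}.
#' @param ped the \code{pedigree}.
#' @return the updated \code{haplotype_matrix} with an attribute
#'   \code{n_resolved}.
#' @export
resolve_all_missing <- function(ht, ped) {
  n <- 0L
  for (side in c("mat", "pat")) {
    strings <- if (side == "mat") ht$strings_mat else ht$strings_pat
    open <- which(is.na(if (side == "mat") ht$codes_mat else ht$codes_pat) &
                    grepl("?", strings, fixed = TRUE), arr.ind = TRUE)
    for (r in seq_len(nrow(open))) {
      b <- rownames(strings)[open[r, 1]]
      id <- colnames(strings)[open[r, 2]]
      if (!(id %in% ped$id)) next
      res <- resolve_missing_haplotype(ht, id, b, side, ped)
      if (res$resolved) {
        n <- n + 1L
        if (side == "mat") {
          ht$codes_mat[b, id] <- res$code
          ht$strings_mat[b, id] <- res$string
        } else {
          ht$codes_pat[b, id] <- res$code
          ht$strings_pat[b, id] <- res$string
        }
      }
    }
  }
  attr(ht, "n_resolved") <- n
  ht
}

#' Convert coded haplotypes back to phased SNP alleles
#'
#' @param ht a \code{haplotype_matrix}.
#' @return list of character matrices \code{mat}, \code{pat}
#'   (markers x individuals) with alleles at all resolved positions.
#' @export
haplotypes_to_phased <- function(ht) {
  hbs <- ht$blocks
  mk <- unlist(hbs$markers, use.names = FALSE)
  ids <- colnames(ht$codes_mat)
  out_m <- matrix(NA_character_, length(mk), length(ids),
                  dimnames = list(mk, ids))
  out_p <- out_m
  for (b in hbs$blocks$block) {
    bm <- hbs$markers[[b]]
    for (side in c("mat", "pat")) {
      strings <- if (side == "mat") ht$strings_mat else ht$strings_pat
      sp <- strsplit(strings[b, ], "")
      al <- do.call(cbind, sp)
      al[al == "?"] <- NA_character_
      if (side == "mat") out_m[bm, ] <- al else out_p[bm, ] <- al
    }
  }
  list(mat = out_m, pat = out_p)
}

#' Mendelian-consistency check at the haploblock level
#'
#' Generalizes genotype elimination to the multi-allelic haplotype codes
#' of each block: a child's code pair must be assemblable from one code
#' of each parent. Conflicts are localized as at the SNP level. As a
#' cross-check, blocks whose resolved codes contradict the underlying
#' SNP calls (expanded haplotype dosages differing from observed
#' genotypes) are also reported — haplotype curation catching residual
#' SNP errors.
#'
#' @param ped a normalized \code{pedigree}.
#' @param ht a \code{haplotype_matrix}.
#' @param gm optional \code{genotype_matrix} for the SNP cross-check.
#' @param max_alleles_elim haplotype-code count above which the
#'   cross-generation elimination is skipped for a block (the genotype
#'   space grows quadratically in the allele count); the local trio
#'   screen always runs.
#' @return list: \code{flags} (data frame block, individual),
#'   \code{inconsistent_blocks}, \code{snp_conflicts} (data frame block,
#'   marker, individual, or zero rows).
#' @export
haplo_mendel_check <- function(ped, ht, gm = NULL, max_alleles_elim = 8) {
  flags <- list()
  inconsistent <- character(0)
  fams <- nuclear_families(ped)
  code_pair <- function(b, id) {
    if (!(id %in% colnames(ht$codes_mat))) return(c(NA_integer_, NA_integer_))
    c(ht$codes_mat[b, id], ht$codes_pat[b, id])
  }
  # is string s a single-crossover recombinant of strings p1, p2?
  recombinant_of <- function(s, p1, p2) {
    L <- nchar(s)
    if (L < 2) return(FALSE)
    sv <- strsplit(s, "")[[1]]
    v1 <- strsplit(p1, "")[[1]]; v2 <- strsplit(p2, "")[[1]]
    for (cut in 1:(L - 1)) {
      if (all(sv[1:cut] == v1[1:cut]) && all(sv[(cut + 1):L] == v2[(cut + 1):L]))
        return(TRUE)
      if (all(sv[1:cut] == v2[1:cut]) && all(sv[(cut + 1):L] == v1[(cut + 1):L]))
        return(TRUE)
    }
    FALSE
  }
  feas_cache <- new.env()
  for (b in ht$blocks$blocks$block) {
    dict <- ht$dictionary[[b]]
    k <- length(dict)
    if (k < 2) next
    ids <- ped$id
    ## local screen: each fully-coded trio must be assemblable from one
    ## code of each parent; a code absent from a parent is tolerated if
    ## it is a single-crossover recombinant of that parent's two
    ## haplotypes (blocks are recombination-free for selected material
    ## only — unselected seedlings may legitimately recombine inside)
    blk_flags <- character(0)
    recombinants <- character(0)
    from_parent <- function(code, par) {
      if (code %in% par) return(TRUE)
      if (anyNA(par)) return(FALSE)
      recombinant_of(dict[[as.character(code)]],
                     dict[[as.character(par[1])]],
                     dict[[as.character(par[2])]])
    }
    for (f in seq_len(nrow(fams))) {
      mo <- code_pair(b, fams$mother[f]); fa <- code_pair(b, fams$father[f])
      for (ch in fams$children[[f]]) {
        cc <- code_pair(b, ch)
        if (anyNA(cc) || anyNA(mo) || anyNA(fa)) next
        plain <- (cc[1] %in% mo && cc[2] %in% fa) ||
                 (cc[2] %in% mo && cc[1] %in% fa)
        if (plain) next
        ok <- (from_parent(cc[1], mo) && from_parent(cc[2], fa)) ||
              (from_parent(cc[2], mo) && from_parent(cc[1], fa))
        if (ok) recombinants <- c(recombinants, ch)
        else blk_flags <- union(blk_flags,
                                c(ch, fams$mother[f], fams$father[f]))
      }
    }
    ## cross-generation elimination for tractable allele counts;
    ## recombinant carriers are uninformative for atomic transmission
    if (k <= max_alleles_elim && !length(blk_flags)) {
      key <- as.character(k)
      if (is.null(feas_cache[[key]])) feas_cache[[key]] <- feasibility_array(k)
      feas <- feas_cache[[key]]
      gs <- genotype_space(k)
      G <- nrow(gs)
      PI <- matrix(NA_integer_, k, k)
      for (i in seq_len(G)) {
        PI[gs[i, 1], gs[i, 2]] <- i
        PI[gs[i, 2], gs[i, 1]] <- i
      }
      obs <- rep(NA_integer_, length(ids)); names(obs) <- ids
      for (id in setdiff(intersect(ids, colnames(ht$codes_mat)),
                         recombinants)) {
        cc <- code_pair(b, id)
        if (!anyNA(cc)) obs[id] <- PI[cc[1], cc[2]]
      }
      sets <- eliminate_genotypes(ped, obs, n_genotypes = G, feas = feas)
      if (!attr(sets, "consistent")) {
        empty <- ids[rowSums(sets) == 0]
        aff <- fams[vapply(seq_len(nrow(fams)), function(i)
          any(c(fams$mother[i], fams$father[i], fams$children[[i]]) %in%
                empty), TRUE), , drop = FALSE]
        members <- unique(unlist(c(aff$mother, aff$father, aff$children)))
        members <- members[!is.na(obs[members])]
        fixers <- character(0)
        for (m in members) {
          obs2 <- obs; obs2[m] <- NA_integer_
          if (attr(eliminate_genotypes(ped, obs2, G, feas), "consistent"))
            fixers <- c(fixers, m)
        }
        if (!length(fixers)) fixers <- intersect(empty, ids[!is.na(obs)])
        blk_flags <- union(blk_flags, fixers)
      }
    }
    if (length(blk_flags)) {
      inconsistent <- c(inconsistent, b)
      for (m in blk_flags)
        flags[[length(flags) + 1]] <- data.frame(block = b, individual = m,
                                                 stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(block = character(), individual = character())
  snp_conflicts <- data.frame(block = character(), marker = character(),
                              individual = character())
  if (!is.null(gm)) {
    phased <- haplotypes_to_phased(ht)
    mk <- intersect(rownames(phased$mat), markers(gm))
    ids <- intersect(colnames(phased$mat), individuals(gm))
    dosage <- (phased$mat[mk, ids, drop = FALSE] == "B") +
      (phased$pat[mk, ids, drop = FALSE] == "B")
    obs <- gm$calls[mk, ids, drop = FALSE]
    bad <- which(!is.na(dosage) & !is.na(obs) & dosage != obs, arr.ind = TRUE)
    if (nrow(bad)) {
      block_of <- rep(ht$blocks$blocks$block,
                      lengths(ht$blocks$markers))
      names(block_of) <- unlist(ht$blocks$markers, use.names = FALSE)
      snp_conflicts <- data.frame(
        block = unname(block_of[mk[bad[, 1]]]),
        marker = mk[bad[, 1]], individual = ids[bad[, 2]],
        stringsAsFactors = FALSE)
    }
  }
  list(flags = flags, inconsistent_blocks = inconsistent,
       snp_conflicts = snp_conflicts)
}
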