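#' Categorize SNPs by call statistics
#'
#' Reproduces the five-category regrouping used to pick a reliable SNP
#' subset after sample exclusion: \emph{robust} (no-call rate < 5\%, all
#' three genotype clusters present), \emph{two_cluster} (< 5\% no-call,
#' AB present but one homozygote class absent), \emph{monomorphic}
#' (exactly one genotype class observed), \emph{failed} (> 50\% no-call;
#' the undefined 5--50\% band is also failed, conservatively), and
#' \emph{null_suspect} (assigned by \code{\link{detect_null_suspects}},
#' overriding robust/two_cluster). Retained = robust + two_cluster.
#'
#' @param gm a \code{genotype_matrix} (post sample-QC individuals only).
#' @param no_call_max no-call threshold for retention, default 0.05.
#' @param null_suspects optional character vector of marker ids to
#'   override as \code{null_suspect}.
#' @return data frame: marker, category, call_rate, n_classes, retained.
#' @export
categorize_snps <- function(gm, no_call_max = 0.05, null_suspects = NULL) {
  cr <- call_rate(gm, "marker")
  dos <- gm$calls
  nAA <- rowSums(dos == 0L, na.rm = TRUE)
  nAB <- rowSums(dos == 1L, na.rm = TRUE)
  nBB <- rowSums(dos == 2L, na.rm = TRUE)
  n_classes <- (nAA > 0) + (nAB > 0) + (nBB > 0)
  nc_rate <- 1 - cr
  category <- rep("failed", nrow(dos))
  # monomorphic = one allele, i.e. a single homozygote class; a marker
  # whose only observed class is AB is impossible biology (a relabelled
  # cluster) and stays failed
  category[n_classes == 1 & nAB == 0 & nc_rate <= 0.5] <- "monomorphic"
  ok <- nc_rate < no_call_max
  category[ok & n_classes == 3] <- "robust"
  category[ok & n_classes == 2 & nAB > 0] <- "two_cluster"
  category[n_classes == 0] <- "failed"
  out <- data.frame(marker = rownames(dos), category = category,
                    call_rate = unname(cr), n_classes = as.integer(n_classes),
                    stringsAsFactors = FALSE)
  if (length(null_suspects)) {
    hit <- out$marker %in% null_suspects &
      out$category %in% c("robust", "two_cluster")
    out$category[hit] <- "null_suspect"
  }
  out$retained <- out$category %in% c("robust", "two_cluster")
  out
}

#' Detect SNPs with a probable null allele
#'
#' A null allele produces no assay signal, so a true A/null heterozygote
#' is called AA and a null homozygote is missing. The classic pedigree
#' signature is recurring opposing-homozygote contradictions between
#' verified parent-child duos (an apparently AA parent with a BB child,
#' or vice versa) at one marker. Markers accumulating such
#' contradictions over more than \code{min_duos} distinct duos are
#' flagged; a single sporadic contradiction is more likely a random
#' miscall and is not.
#'
#' @param gm a \code{genotype_matrix}.
#' @param duos data frame with columns \code{parent}, \code{child}: the
#'   verified parent-child pairs to scan.
#' @param min_duos minimum number of \emph{independent} contradicting
#'   duos, default 3. Duos are grouped into independent events by a
#'   greedy cover over individuals: one miscalled homozygous parent
#'   contradicts every opposite-homozygote child at once but counts as
#'   a single event, while a segregating null produces contradictions
#'   through several unrelated carriers.
#' @param check_missingness additionally require the marker's no-call
#'   rate to exceed twice the data set's median by at least 1 percent;
#'   null homozygotes give no signal, so a real segregating null
#'   inflates missingness. Default TRUE.
#' @return character vector of suspect marker ids.
#' @export
detect_null_suspects <- function(gm, duos, min_duos = 3,
                                 check_missingness = TRUE) {
  if (is.null(duos) || nrow(duos) == 0) {
    warning("no verified duos available; no null-allele scan performed")
    return(character(0))
  }
  dos <- gm$calls
  pairs <- list()   # per marker row index: list of c(parent, child)
  edge_m <- integer(0); edge_p <- character(0); edge_c <- character(0)
  for (i in seq_len(nrow(duos))) {
    p <- duos$parent[i]; c <- duos$child[i]
    if (!(p %in% colnames(dos)) || !(c %in% colnames(dos))) next
    gp <- dos[, p]; gc <- dos[, c]
    opp <- which(((gp == 0L & gc == 2L) | (gp == 2L & gc == 0L)) %in% TRUE)
    if (length(opp)) {
      edge_m <- c(edge_m, opp)
      edge_p <- c(edge_p, rep(p, length(opp)))
      edge_c <- c(edge_c, rep(c, length(opp)))
    }
  }
  if (!length(edge_m)) return(character(0))
  n_events <- vapply(split(seq_along(edge_m), edge_m), function(ix) {
    pp <- edge_p[ix]; cc <- edge_c[ix]
    events <- 0L
    while (length(pp)) {
      events <- events + 1L
      tab <- table(c(pp, cc))
      hub <- names(tab)[which.max(tab)]  # individual covering most duos
      keep <- pp != hub & cc != hub
      pp <- pp[keep]; cc <- cc[keep]
    }
    events
  }, 0L)
  hit <- as.integer(names(n_events))[n_events >= min_duos]
  if (check_missingness) {
    miss <- 1 - rowMeans(!is.na(dos))
    hit <- hit[miss[hit] > 2 * stats::median(miss) + 0.01]
  }
  rownames(dos)[hit]
}
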