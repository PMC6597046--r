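#' Off-band fraction of a sample's B-allele frequencies
#'
#' Fraction of SNPs whose B-allele frequency (BAF) falls in the off-band
#' intervals [0.125, 0.375] or [0.625, 0.875] — between the three
#' clusters a clean diploid shows at 0, 0.5 and 1. The symmetric upper
#' band mirrors the lower one.
#'
#' @param baf numeric vector of BAF values in [0, 1] (NAs ignored).
#' @return fraction in [0, 1].
#' @export
baf_offband_fraction <- function(baf) {
  baf <- baf[!is.na(baf)]
  if (!length(baf)) return(NA_real_)
  mean((baf >= 0.125 & baf <= 0.375) | (baf >= 0.625 & baf <= 0.875))
}

#' Classify sample genotyping quality from B-allele frequencies
#'
#' A diploid sample is of good quality when less than 0.3\% of its SNPs
#' have off-band BAF, intermediate between 0.3\% and 3\%, and bad above
#' 3\%. Boundary fractions go to the less severe class (the defining
#' inequalities are strict).
#'
#' @param baf numeric vector of one sample's BAF values.
#' @param thresholds two fractions (good/intermediate, intermediate/bad).
#' @param min_n minimum number of non-missing BAFs required.
#' @return one of \code{"good"}, \code{"intermediate"}, \code{"bad"},
#'   or \code{"unknown"} (with a warning) below \code{min_n}.
#' @export
classify_quality <- function(baf, thresholds = c(0.003, 0.03), min_n = 100) {
  baf <- baf[!is.na(baf)]
  if (length(baf) < min_n) {
    warning("fewer than ", min_n, " BAF values; quality unknown")
    return("unknown")
  }
  f <- baf_offband_fraction(baf)
  if (f <= thresholds[1]) "good"
  else if (f <= thresholds[2]) "intermediate"
  else "bad"
}

#' Expected B-allele frequency for a given ploidy and B copy number
#'
#' For a locus with \code{b_copies} copies of the B allele among
#' \code{ploidy} chromosome copies the expected BAF is
#' \code{b_copies / ploidy}: 0, 1/3, 2/3, 1 for triploids and 0, 1/4,
#' 1/2, 3/4, 1 for tetraploids.
#'
#' @param ploidy integer >= 1.
#' @param b_copies integer in [0, ploidy].
#' @return expected BAF in [0, 1].
#' @export
expected_baf <- function(ploidy, b_copies) {
  if (ploidy < 1) stop("ploidy must be >= 1")
  if (any(b_copies < 0) || any(b_copies > ploidy))
    stop("b_copies must be between 0 and ploidy")
  b_copies / ploidy
}

# Histogram peak finder: counts in fixed-width bins, 3-bin smoothing,
# local maxima above a minimum mass fraction; adjacent maxima merged.
baf_peaks <- function(baf, binwidth = 0.02, min_fraction = 0.01) {
  baf <- baf[!is.na(baf)]
  breaks <- seq(0, 1, by = binwidth)
  cnt <- tabulate(pmin(findInterval(baf, breaks, rightmost.closed = TRUE),
                       length(breaks) - 1), nbins = length(breaks) - 1)
  sm <- as.numeric(stats::filter(cnt, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- cnt[is.na(sm)]
  mids <- breaks[-length(breaks)] + binwidth / 2
  n <- length(sm)
  left <- c(-Inf, sm[-n]); right <- c(sm[-1], -Inf)
  is_peak <- sm >= left & sm >= right & cnt >= min_fraction * length(baf) & cnt > 0
  pk <- mids[is_peak]
  if (!length(pk)) return(numeric(0))
  # merge runs of adjacent peak bins (plateaus) into one peak
  grp <- cumsum(c(1, diff(which(is_peak)) > 1))
  w <- sm[is_peak]
  as.numeric(tapply(pk * w, grp, sum) / tapply(w, grp, sum))
}

match_template <- function(peaks, template, tol = 0.05) {
  length(peaks) == length(template) &&
    all(abs(sort(peaks) - sort(template)) <= tol)
}

# Per-chromosome heterozygous-band pattern. Trisomic chromosomes put
# their heterozygous BAFs at 1/3 and 2/3 instead of 1/2; monosomic
# (haploid-like) chromosomes have essentially no heterozygous band.
chromosome_pattern <- function(baf, tol = 0.1, min_het_frac = 0.02) {
  baf <- baf[!is.na(baf)]
  if (!length(baf)) return("unknown")
  het <- baf[baf > 0.15 & baf < 0.85]
  if (length(het) < min_het_frac * length(baf)) return("haploid_like")
  f_mid <- mean(abs(het - 0.5) < tol)
  f_third <- mean(pmin(abs(het - 1 / 3), abs(het - 2 / 3)) < tol)
  if (f_third > f_mid) "polyploid_like" else "diploid_like"
}

#' Classify sample ploidy from B-allele frequencies
#'
#' Locates peaks in the sample's BAF histogram. More than three peaks
#' means polyploid: a peak set near \{0, 1/3, 2/3, 1\} (within
#' \code{tol}) is called triploid and one near \{0, 1/4, 1/2, 3/4, 1\}
#' tetraploid (or a sample mixture, which gives the same pattern); a
#' mixed set near \{0, 1/3, 1/2, 2/3, 1\} — a diploid heterozygous band
#' with shoulders at the trisomic positions — marks a putative
#' aneuploid. A globally diploid (or putative-aneuploid) histogram is
#' additionally scanned per chromosome
#' when a map is supplied: a chromosome whose heterozygous BAFs sit at
#' 1/3 and 2/3 (or that lacks a heterozygous band) while the rest sit at
#' 1/2 marks the sample aneuploid.
#'
#' @param baf numeric vector of one sample's BAFs, named by marker or in
#'   map order when \code{map} is given.
#' @param map optional \code{genetic_map} (enables the per-chromosome
#'   scan; without it only the global call is made and the result is
#'   flagged \code{chromosome_scan = FALSE}).
#' @param tol peak-to-template matching tolerance in BAF units.
#' @return list with \code{ploidy_call} (\code{"diploid"},
#'   \code{"triploid"}, \code{"tetraploid_or_mixture"},
#'   \code{"aneuploid"}), \code{peaks}, \code{per_chromosome} (named
#'   pattern vector or NULL) and \code{chromosome_scan}.
#' @export
classify_ploidy <- function(baf, map = NULL, tol = 0.05) {
  pk <- baf_peaks(baf)
  call <- if (match_template(pk, c(0, 1 / 3, 2 / 3, 1), tol)) "triploid"
  else if (match_template(pk, c(0, 0.25, 0.5, 0.75, 1), tol)) "tetraploid_or_mixture"
  else if (match_template(pk, c(0, 1 / 3, 1 / 2, 2 / 3, 1), tol)) "aneuploid"
  else if (length(pk) > 3) "polyploid"
  else "diploid"
  per_chrom <- NULL
  if (!is.null(map) && call %in% c("diploid", "aneuploid")) {
    if (is.null(names(baf))) names(baf) <- map$marker[seq_along(baf)]
    idx <- split(map$marker, map$linkage_group)
    per_chrom <- vapply(idx, function(mk) chromosome_pattern(baf[mk]), "")
    # only the trisomic (1/3, 2/3) het band is conclusive: a chromosome
    # with no het band at all may simply be autozygous in inbred
    # material, so haploid_like alone does not trigger the call
    tri <- per_chrom == "polyploid_like"
    if (any(tri) && !all(tri)) call <- "aneuploid"
  }
  list(ploidy_call = call, peaks = pk, per_chromosome = per_chrom,
       chromosome_scan = !is.null(map))
}

#' Run sample QC over a BAF matrix
#'
#' @param baf matrix of BAF values, markers x individuals.
#' @param map optional \code{genetic_map} for the per-chromosome scan.
#' @param thresholds,min_n passed to \code{\link{classify_quality}}.
#' @return data frame (one row per individual): \code{individual},
#'   \code{fraction_offband}, \code{quality}, \code{ploidy_call},
#'   \code{flagged_chromosomes}, \code{exclude} (bad quality or
#'   non-diploid). Ploidy is only assessed for samples whose quality is
#'   not bad (a noisy sample fakes extra peaks).
#' @export
sample_qc <- function(baf, map = NULL, thresholds = c(0.003, 0.03),
                      min_n = 100) {
  res <- lapply(colnames(baf), function(id) {
    v <- baf[, id]
    q <- classify_quality(v, thresholds, min_n)
    pl <- classify_ploidy(stats::setNames(v, rownames(baf)), map)
    # a sharp polyploid peak template is conclusive even though the
    # off-band fraction is necessarily high for such samples; a noisy
    # histogram without a template match is just a bad sample
    call <- if (pl$ploidy_call %in% c("triploid", "tetraploid_or_mixture"))
      pl$ploidy_call
    else if (q %in% c("bad", "unknown")) "unknown"
    else pl$ploidy_call
    flagged <- if (call != "unknown" && !is.null(pl$per_chromosome))
      paste(names(pl$per_chromosome)[pl$per_chromosome == "polyploid_like"],
            collapse = ";") else ""
    list(individual = id, fraction_offband = baf_offband_fraction(v),
         quality = q, ploidy_call = call, flagged_chromosomes = flagged)
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  out$exclude <- out$quality %in% c("bad") |
    !(out$ploidy_call %in% c("diploid", "unknown")) |
    (out$quality == "unknown")
  out
}

#' Scan for candidate segmental aneuploid regions
#'
#' A segmental aneuploid (one parental chromosome segment missing or
#' duplicated) shows a localized excess of parent-child Mendelian
#' errors and double recombinations on just that segment. Counts both
#' signal types in sliding windows along the map and reports windows
#' whose count exceeds a multiple of the individual's genome-wide rate.
#'
#' @param signals data frame with columns \code{individual},
#'   \code{linkage_group}, \code{cm} — one row per PC error or double
#'   recombination attributed to a position.
#' @param map a \code{genetic_map} (defines chromosome extents).
#' @param window_cm sliding window width, default 20.
#' @param step_cm window step, default half the window.
#' @param multiple flag windows with count > multiple x expected count
#'   under a uniform genome-wide rate; default 5.
#' @param min_count additional absolute floor on the window count.
#' @return data frame of candidate segments: individual, linkage_group,
#'   cm_start, cm_end, count, expected.
#' @export
segmental_scan <- function(signals, map, window_cm = 20,
                           step_cm = window_cm / 2, multiple = 5,
                           min_count = 5) {
  spans <- tapply(map$cm, map$linkage_group, max)
  genome_cm <- sum(spans)
  out <- list()
  for (id in unique(signals$individual)) {
    s <- signals[signals$individual == id, , drop = FALSE]
    rate <- nrow(s) / genome_cm
    expected <- rate * window_cm
    for (lg in names(spans)) {
      pos <- s$cm[s$linkage_group == lg]
      starts <- seq(0, max(0, spans[[lg]] - window_cm), by = step_cm)
      for (st in starts) {
        cnt <- sum(pos >= st & pos < st + window_cm)
        if (cnt >= min_count && cnt > multiple * expected)
          out[[length(out) + 1]] <- data.frame(
            individual = id, linkage_group = lg, cm_start = st,
            cm_end = st + window_cm, count = cnt, expected = expected)
      }
    }
  }
  if (!length(out))
    return(data.frame(individual = character(), linkage_group = character(),
                      cm_start = numeric(), cm_end = numeric(),
                      count = integer(), expected = numeric()))
  res <- do.call(rbind, out)
  # merge overlapping flagged windows per individual x linkage group
  res <- res[order(res$individual, res$linkage_group, res$cm_start), ]
  merged <- list()
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    n <- length(merged)
    if (n && merged[[n]]$individual == r$individual &&
        merged[[n]]$linkage_group == r$linkage_group &&
        r$cm_start <= merged[[n]]$cm_end) {
      merged[[n]]$cm_end <- max(merged[[n]]$cm_end, r$cm_end)
      merged[[n]]$count <- max(merged[[n]]$count, r$count)
    } else merged[[n + 1]] <- r
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}
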