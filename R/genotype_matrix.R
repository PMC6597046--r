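#' Genotype call matrix
#'
#' Container for diploid biallelic SNP calls on a markers-by-individuals
#' grid. Calls are stored internally as the B-allele dosage (0 = AA,
#' 1 = AB, 2 = BB, NA = missing); the printed/on-disk representation uses
#' the array convention \code{"AA"}, \code{"AB"}, \code{"BB"} and a
#' configurable missing token. Every in-place edit made by curation
#' functions is recorded in an edit log (marker, individual, original
#' call, current call, reason tag), so the provenance of the final data
#' set can be audited and summarised.
#'
#' @param calls character or integer matrix, markers in rows (rownames =
#'   marker ids), individuals in columns (colnames = individual ids).
#'   Character matrices may use \code{"AA"}, \code{"AB"}, \code{"BB"} and
#'   any of \code{missing_codes}; integer matrices use dosages 0/1/2.
#' @param missing_codes character vector of tokens treated as missing.
#' @return An object of class \code{genotype_matrix}: a list with
#'   elements \code{calls} (integer dosage matrix) and \code{edit_log}
#'   (data frame of recorded edits).
#' @export
genotype_matrix <- function(calls, missing_codes = c("--", "NN", "NC", "")) {
  if (nrow(calls) > 0 && is.null(rownames(calls)))
    stop("calls must have marker rownames")
  if (ncol(calls) > 0 && is.null(colnames(calls)))
    stop("calls must have individual colnames")
  if (is.null(rownames(calls))) rownames(calls) <- character(0)
  if (is.null(colnames(calls))) colnames(calls) <- character(0)
  dup_m <- unique(rownames(calls)[duplicated(rownames(calls))])
  dup_i <- unique(colnames(calls)[duplicated(colnames(calls))])
  if (length(dup_m))
    stop("duplicated marker ids: ", paste(dup_m, collapse = ", "))
  if (length(dup_i))
    stop("duplicated individual ids: ", paste(dup_i, collapse = ", "))
  if (is.character(calls)) {
    dos <- calls_to_dosage(calls, missing_codes)
    n_unknown <- attr(dos, "n_unknown") %||% 0L
    attr(dos, "n_unknown") <- NULL
  } else {
    dos <- calls
    storage.mode(dos) <- "integer"
    if (any(!is.na(dos) & !(dos %in% 0:2)))
      stop("integer calls must be dosages in 0:2 or NA")
    n_unknown <- 0L
  }
  structure(
    list(calls = dos, edit_log = empty_edit_log(),
         n_unknown_tokens = n_unknown),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

GENO_STR <- c("AA", "AB", "BB")

empty_edit_log <- function() {
  data.frame(marker = character(), individual = character(),
             original = character(), current = character(),
             reason = character(), stringsAsFactors = FALSE)
}

calls_to_dosage <- function(chr, missing_codes) {
  dos <- match(chr, GENO_STR) - 1L
  unknown <- !is.na(chr) & is.na(dos) & !(chr %in% missing_codes)
  n_unknown <- sum(unknown)
  if (n_unknown > 0)
    warning(n_unknown, " unknown genotype token(s) mapped to missing")
  out <- matrix(as.integer(dos), nrow = nrow(chr), dimnames = dimnames(chr))
  attr(out, "n_unknown") <- n_unknown
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$calls), " markers x ", ncol(x$calls),
      " individuals; ", nrow(x$edit_log), " logged edits\n", sep = "")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a \code{genotype_matrix}.
#' @export
markers <- function(gm) rownames(gm$calls)

#' @rdname genotype_matrix
#' @export
individuals <- function(gm) colnames(gm$calls)

#' Dosage calls as "AA"/"AB"/"BB" strings
#' @param gm a \code{genotype_matrix}.
#' @param missing_token token written for missing calls.
#' @return character matrix with the same dimnames as the dosage matrix.
#' @export
calls_chr <- function(gm, missing_token = "--") {
  chr <- array(GENO_STR[gm$calls + 1L], dim = dim(gm$calls),
               dimnames = dimnames(gm$calls))
  chr[is.na(chr)] <- missing_token
  chr
}

#' Edit genotype calls with provenance
#'
#' Sets calls at the given (marker, individual) cells and appends one edit
#' log row per changed cell. \code{value} may be a single dosage (recycled)
#' or a vector matched to the cells.
#'
#' @param gm a \code{genotype_matrix}.
#' @param marker,individual character vectors (recycled to equal length)
#'   naming the cells to edit.
#' @param value new dosage(s) in 0:2, or NA to blank the call.
#' @param reason short tag recorded in the edit log.
#' @return the modified \code{genotype_matrix}.
#' @export
edit_calls <- function(gm, marker, individual, value, reason) {
  n <- max(length(marker), length(individual))
  marker <- rep_len(marker, n); individual <- rep_len(individual, n)
  value <- rep_len(as.integer(value), n)
  mi <- match(marker, rownames(gm$calls))
  ii <- match(individual, colnames(gm$calls))
  if (anyNA(mi) || anyNA(ii))
    stop("unknown marker or individual id in edit_calls")
  idx <- cbind(mi, ii)
  old <- gm$calls[idx]
  changed <- !(is.na(old) & is.na(value)) & (is.na(old) | is.na(value) | old != value)
  if (any(changed)) {
    gm$calls[idx[changed, , drop = FALSE]] <- value[changed]
    tok <- function(v) ifelse(is.na(v), "--", GENO_STR[v + 1L])
    gm$edit_log <- rbind(gm$edit_log, data.frame(
      marker = marker[changed], individual = individual[changed],
      original = tok(old[changed]), current = tok(value[changed]),
      reason = reason, stringsAsFactors = FALSE))
  }
  gm
}

#' Remove markers or individuals from a genotype matrix
#'
#' @param gm a \code{genotype_matrix}.
#' @param markers,individuals ids to drop (either may be NULL).
#' @param reason tag recorded once per dropped row/column in the edit log
#'   (with current call \code{"removed"}).
#' @return the reduced \code{genotype_matrix}; the edit log is retained.
#' @export
drop_from_matrix <- function(gm, markers = NULL, individuals = NULL,
                             reason = "removed") {
  if (length(markers)) {
    keep <- !(rownames(gm$calls) %in% markers)
    gm$edit_log <- rbind(gm$edit_log, data.frame(
      marker = intersect(markers, rownames(gm$calls)), individual = "*",
      original = "*", current = "removed", reason = reason,
      stringsAsFactors = FALSE))
    gm$calls <- gm$calls[keep, , drop = FALSE]
  }
  if (length(individuals)) {
    keep <- !(colnames(gm$calls) %in% individuals)
    gm$edit_log <- rbind(gm$edit_log, data.frame(
      marker = "*", individual = intersect(individuals, colnames(gm$calls)),
      original = "*", current = "removed", reason = reason,
      stringsAsFactors = FALSE))
    gm$calls <- gm$calls[, keep, drop = FALSE]
  }
  gm
}

#' Call rates
#'
#' Fraction of non-missing calls per marker or per individual.
#' @param gm a \code{genotype_matrix}.
#' @param by \code{"marker"} or \code{"individual"}.
#' @return named numeric vector of call rates in [0, 1].
#' @export
call_rate <- function(gm, by = c("marker", "individual")) {
  by <- match.arg(by)
  ok <- !is.na(gm$calls)
  if (by == "marker") rowMeans(ok) else colMeans(ok)
}

#' Read a genotype table
#'
#' Reads genotype calls from a tab-separated table (header = individual
#' ids, first column = marker id, cells AA/AB/BB/missing) or from a PLINK
#' PED/MAP pair with alleles coded A/B (or via \code{allele_map} for
#' nucleotide codings).
#'
#' @param path file path; for \code{dialect = "plink"} the \code{.ped}
#'   file (the \code{.map} file is found by extension substitution unless
#'   \code{map_path} is given).
#' @param dialect \code{"tsv"} or \code{"plink"}.
#' @param missing_codes tokens treated as missing in TSV cells.
#' @param map_path optional explicit PLINK .map path.
#' @param allele_map optional named character vector translating PED
#'   allele symbols to \code{"A"}/\code{"B"} (e.g.
#'   \code{c(A = "A", C = "B")} per marker is not supported; the map is
#'   global, suited to arrays exported with A/B coding).
#' @return a \code{genotype_matrix} with an empty edit log.
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "plink"),
                                missing_codes = c("--", "NN", "NC", ""),
                                map_path = NULL, allele_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             comment.char = "")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    return(genotype_matrix(m, missing_codes = missing_codes))
  }
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  marker_ids <- map[[2]]
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (ncol(al) != 2 * length(marker_ids))
    stop("PED allele columns do not match 2 x markers in MAP")
  if (!is.null(allele_map)) {
    known <- al %in% c(names(allele_map), "0")
    al[al %in% names(allele_map)] <- allele_map[al[al %in% names(allele_map)]]
    al[!known] <- "0"
  }
  a1 <- al[, seq(1, ncol(al), by = 2), drop = FALSE]
  a2 <- al[, seq(2, ncol(al), by = 2), drop = FALSE]
  dos <- (a1 == "B") + (a2 == "B")
  dos[a1 == "0" | a2 == "0"] <- NA
  dos <- t(dos)
  dimnames(dos) <- list(marker_ids, ids)
  storage.mode(dos) <- "integer"
  genotype_matrix(dos)
}

#' Write a genotype table
#'
#' Writes calls as TSV (deterministic row/column order: as stored) or as a
#' PLINK PED/MAP pair with A/B allele coding. If the edit log is
#' non-empty a sidecar CSV \code{<path>.edits.csv} is written with one row
#' per logged edit.
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output path (for plink: the .ped path).
#' @param dialect \code{"tsv"} or \code{"plink"}.
#' @param map optional \code{genetic_map} used to fill the PLINK .map
#'   columns; markers absent from it get chromosome 0 / position 0.
#' @return invisibly, \code{path}.
#' @export
write_genotype_table <- function(gm, path, dialect = c("tsv", "plink"),
                                 map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    chr <- calls_chr(gm)
    df <- data.frame(marker = rownames(chr), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dos <- gm$calls
    a1 <- ifelse(is.na(dos), "0", ifelse(dos >= 1, "B", "A"))
    a2 <- ifelse(is.na(dos), "0", ifelse(dos == 2, "B", "A"))
    n <- ncol(dos)
    ped_alleles <- matrix("", nrow = n, ncol = 2 * nrow(dos))
    ped_alleles[, seq(1, ncol(ped_alleles), 2)] <- t(a1)
    ped_alleles[, seq(2, ncol(ped_alleles), 2)] <- t(a2)
    ped <- cbind("FAM", colnames(dos), "0", "0", "0", "-9", ped_alleles)
    utils::write.table(ped, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    mp <- data.frame(chr = "0", marker = rownames(dos), cm = 0, bp = 0)
    if (!is.null(map)) {
      i <- match(rownames(dos), map$marker)
      mp$chr <- ifelse(is.na(i), "0", map$linkage_group[i])
      mp$cm <- ifelse(is.na(i), 0, map$cm[i])
      mp$bp <- ifelse(is.na(i) | is.na(map$bp[i]), 0, map$bp[i])
    }
    utils::write.table(mp, sub("\\.ped$", ".map", path), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (nrow(gm$edit_log) > 0)
    utils::write.csv(gm$edit_log, paste0(path, ".edits.csv"), row.names = FALSE)
  invisible(path)
}
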