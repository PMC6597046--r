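#' Classify SNPs into curation types 1-7
#'
#' One type per marker, by precedence 7 > 6 > 5 > 4 > 3 > 2 > 1:
#' \describe{
#' \item{7}{failed calling, or removed during curation because calls
#'   could not be resolved;}
#' \item{6}{monomorphic;}
#' \item{5}{genetic/physical position could not be determined
#'   (unmappable);}
#' \item{4}{null allele;}
#' \item{3}{additional genotype clusters from differential intensity;}
#' \item{2}{a whole genotype cluster was mis-identified and recalled (or
#'   at least 5\% of calls were edited);}
#' \item{1}{fewer than 5\% of calls edited and no cluster-level
#'   evidence.}
#' }
#' Whether a marker was retained is recorded separately from its type: a
#' type describes the cluster phenomenon, retention the decision (null
#' markers, for instance, may be retained in one crop and excluded in
#' another).
#'
#' @param ledger data frame with one row per marker: \code{marker} plus
#'   logical columns \code{failed}, \code{monomorphic},
#'   \code{unmappable}, \code{null_allele}, \code{extra_cluster},
#'   \code{cluster_shift}, numeric \code{edit_fraction}, logical
#'   \code{retained}. Build it with \code{\link{build_snp_ledger}}.
#' @return data frame: marker, type (integer 1-7), edit_fraction,
#'   retained, evidence (semicolon-joined tags).
#' @export
classify_snps <- function(ledger) {
  need <- c("marker", "failed", "monomorphic", "unmappable", "null_allele",
            "extra_cluster", "cluster_shift", "edit_fraction", "retained")
  miss <- setdiff(need, names(ledger))
  if (length(miss)) stop("ledger lacks columns: ", paste(miss, collapse = ", "))
  type <- with(ledger, ifelse(failed, 7L,
               ifelse(monomorphic, 6L,
               ifelse(unmappable, 5L,
               ifelse(null_allele, 4L,
               ifelse(extra_cluster, 3L,
               ifelse(cluster_shift | edit_fraction >= 0.05, 2L, 1L)))))))
  tags <- apply(ledger[, c("failed", "monomorphic", "unmappable",
                           "null_allele", "extra_cluster", "cluster_shift")],
                1, function(r) paste(names(r)[r %in% TRUE], collapse = ";"))
  data.frame(marker = ledger$marker, type = type,
             edit_fraction = ledger$edit_fraction,
             retained = ledger$retained, evidence = tags,
             stringsAsFactors = FALSE)
}

#' Build the per-SNP curation ledger from stage outputs
#'
#' @param all_markers character vector of the initial marker ids.
#' @param categories SNP category data frame (from
#'   \code{\link{categorize_snps}}).
#' @param gm the final \code{genotype_matrix} (its edit log gives the
#'   edit fractions; \code{n_individuals} cells per marker).
#' @param unmappable markers that could not be placed on the map.
#' @param cluster_shift markers flagged as cluster-calling suspects.
#' @param removed markers removed during curation for unresolvable calls.
#' @return ledger data frame for \code{\link{classify_snps}}.
#' @export
build_snp_ledger <- function(all_markers, categories, gm,
                             unmappable = character(0),
                             cluster_shift = character(0),
                             removed = character(0)) {
  i <- match(all_markers, categories$marker)
  cat_of <- ifelse(is.na(i), "failed", categories$category[i])
  el <- gm$edit_log
  el <- el[el$individual != "*" & el$marker %in% all_markers, , drop = FALSE]
  n_edit <- table(factor(el$marker, levels = all_markers))
  n_ind <- max(1L, ncol(gm$calls))
  final_markers <- rownames(gm$calls)
  data.frame(
    marker = all_markers,
    failed = cat_of == "failed" | all_markers %in% removed,
    monomorphic = cat_of == "monomorphic",
    unmappable = all_markers %in% unmappable,
    null_allele = cat_of == "null_suspect",
    extra_cluster = FALSE,
    cluster_shift = all_markers %in% cluster_shift,
    edit_fraction = as.numeric(n_edit) / n_ind,
    retained = all_markers %in% final_markers,
    stringsAsFactors = FALSE)
}

#' Emit the final curated data bundle
#'
#' Writes the curated genotype TSV, the phased two-line-per-individual
#' TSV, the haplotype table, all stage reports, and a JSON run manifest
#' recording configuration, seed, the stage order executed and the
#' marker/individual counts after each stage (a telescoping
#' retained/discarded ledger).
#'
#' @param dir output directory.
#' @param gm curated \code{genotype_matrix}.
#' @param classifications data frame from \code{\link{classify_snps}}.
#' @param hm optional \code{homolog_matrix}.
#' @param ht optional \code{haplotype_matrix}.
#' @param reports named list of data frames to write as CSVs.
#' @param manifest named list serialized as JSON.
#' @return invisibly, the manifest list.
#' @export
emit_final_dataset <- function(dir, gm, classifications, hm = NULL,
                               ht = NULL, reports = list(),
                               manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_table(gm, file.path(dir, "curated_genotypes.tsv"))
  utils::write.csv(classifications, file.path(dir, "snp_classification.csv"),
                   row.names = FALSE)
  if (!is.null(hm)) {
    two_line <- rbind(
      data.frame(individual = colnames(hm$mat), homolog = "mat",
                 t(ifelse(is.na(hm$mat), "-", hm$mat)), check.names = FALSE),
      data.frame(individual = colnames(hm$pat), homolog = "pat",
                 t(ifelse(is.na(hm$pat), "-", hm$pat)), check.names = FALSE))
    two_line <- two_line[order(two_line$individual, two_line$homolog), ]
    utils::write.table(two_line, file.path(dir, "phased_genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ht)) {
    hap <- data.frame(individual = colnames(ht$codes_mat),
                      t(matrix(paste0(ht$codes_mat, "|", ht$codes_pat),
                               nrow(ht$codes_mat),
                               dimnames = dimnames(ht$codes_mat))),
                      check.names = FALSE)
    utils::write.table(hap, file.path(dir, "haplotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dict <- do.call(rbind, lapply(names(ht$dictionary), function(b)
      if (length(ht$dictionary[[b]]))
        data.frame(block = b, code = names(ht$dictionary[[b]]),
                   haplotype = unname(ht$dictionary[[b]]))))
    if (!is.null(dict))
      utils::write.csv(dict, file.path(dir, "code_dictionary.csv"),
                       row.names = FALSE)
    utils::write.csv(ht$blocks$blocks, file.path(dir, "haploblocks.csv"),
                     row.names = FALSE)
  }
  for (nm in names(reports))
    utils::write.csv(reports[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
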