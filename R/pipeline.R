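#' Curation workflow stages, in mandated order
#'
#' The stage order encodes the core claim of the workflow: inheritance
#' principles can only be applied once non-diploid and low-quality
#' samples, unreliable markers, duplicates and wrong pedigree records
#' are dealt with; marker-level Mendelian-inconsistent errors must be
#' resolved before phased (Mendelian-consistent) diagnostics; and all
#' SNP-level issues before haploblock analysis.
#' @export
CURATION_STAGES <- c("sample_qc", "snp_filter", "dedup", "parentage",
                     "mendel", "phase_recomb", "haploblock", "classify")

#' Start a curation run
#'
#' @param gm a \code{genotype_matrix}.
#' @param ped a \code{pedigree}.
#' @param map a \code{genetic_map}.
#' @param baf optional BAF matrix (markers x individuals); without it
#'   the sample_qc stage passes everything through.
#' @param seed integer seed used by stages that randomize (threshold
#'   calibration).
#' @param config named list of stage-parameter overrides (e.g.
#'   \code{dedup_min_shared}, \code{dr_window_cm},
#'   \code{null_min_duos}).
#' @return a \code{curation_state}.
#' @export
new_curation <- function(gm, ped, map, baf = NULL, seed = 1,
                         config = list()) {
  structure(list(gm = gm, ped = ped, map = map, baf = baf, seed = seed,
                 config = config, initial_markers = markers(gm),
                 initial_individuals = individuals(gm),
                 results = list(), counts = list(), stages_done = character(0)),
            class = "curation_state")
}

#' @export
print.curation_state <- function(x, ...) {
  cat("curation_state: stages done [", paste(x$stages_done, collapse = ", "),
      "]; ", nrow(x$gm$calls), " markers x ", ncol(x$gm$calls),
      " individuals remain\n", sep = "")
  invisible(x)
}

cfg <- function(state, name, default) state$config[[name]] %||% default

#' Run one curation stage
#'
#' Stages must run in the order of \code{\link{CURATION_STAGES}};
#' invoking a stage before its prerequisites errors, naming the missing
#' stage (use \code{force = TRUE} to depart from the mandated order
#' deliberately). Re-running a stage on unchanged inputs is idempotent.
#'
#' @param state a \code{curation_state}.
#' @param stage one of \code{\link{CURATION_STAGES}}.
#' @param force skip the prerequisite check.
#' @return the updated \code{curation_state}; stage outputs are in
#'   \code{state$results[[stage]]}, marker/individual counts in
#'   \code{state$counts}.
#' @export
run_stage <- function(state, stage, force = FALSE) {
  stage <- match.arg(stage, CURATION_STAGES)
  pre <- CURATION_STAGES[seq_len(match(stage, CURATION_STAGES) - 1)]
  missing_pre <- setdiff(pre, state$stages_done)
  if (length(missing_pre) && !force)
    stop("stage '", stage, "' requires prerequisite stage '",
         missing_pre[1], "' to have run first")
  before <- c(markers = nrow(state$gm$calls), individuals = ncol(state$gm$calls))
  state <- switch(stage,
    sample_qc = stage_sample_qc(state),
    snp_filter = stage_snp_filter(state),
    dedup = stage_dedup(state),
    parentage = stage_parentage(state),
    mendel = stage_mendel(state),
    phase_recomb = stage_phase_recomb(state),
    haploblock = stage_haploblock(state),
    classify = stage_classify(state))
  state$counts[[stage]] <- list(
    markers_in = unname(before["markers"]),
    markers_out = nrow(state$gm$calls),
    individuals_in = unname(before["individuals"]),
    individuals_out = ncol(state$gm$calls))
  state$stages_done <- union(state$stages_done, stage)
  state
}

stage_sample_qc <- function(state) {
  if (is.null(state$baf)) {
    state$results$sample_qc <- list(table = NULL, excluded = character(0))
    return(state)
  }
  qc <- sample_qc(state$baf, state$map,
                  min_n = cfg(state, "qc_min_n", 100))
  excl <- qc$individual[qc$exclude]
  excl <- intersect(excl, individuals(state$gm))
  if (length(excl))
    state$gm <- drop_from_matrix(state$gm, individuals = excl,
                                 reason = "sample_qc")
  state$results$sample_qc <- list(table = qc, excluded = excl)
  state
}

stage_snp_filter <- function(state) {
  cats <- categorize_snps(state$gm,
                          no_call_max = cfg(state, "no_call_max", 0.05))
  # markers flooded with heterozygotes far beyond the Hardy-Weinberg
  # expectation carry the relabelled-homozygote-cluster signature and
  # are pulled here, before they can distort downstream diagnostics
  dos <- state$gm$calls
  qhat <- rowMeans(dos, na.rm = TRUE) / 2
  hexc <- rowMeans(dos == 1L, na.rm = TRUE) - 2 * qhat * (1 - qhat)
  hexc[is.na(hexc)] <- 0
  suspects <- rownames(dos)[hexc > cfg(state, "extreme_het_excess", 0.2)]
  drop <- setdiff(cats$marker[!cats$retained], suspects)
  if (length(drop))
    state$gm <- drop_from_matrix(state$gm, markers = drop,
                                 reason = "snp_filter")
  if (length(suspects))
    state$gm <- drop_from_matrix(state$gm, markers = suspects,
                                 reason = "cluster_suspect")
  state$results$snp_filter <- list(categories = cats, dropped = drop,
                                   cluster_suspects = suspects)
  state
}

stage_dedup <- function(state) {
  min_shared <- cfg(state, "dedup_min_shared",
                    min(500L, max(50L, floor(nrow(state$gm$calls) / 2))))
  groups <- find_duplicate_groups(state$gm,
                                  threshold = cfg(state, "dedup_threshold", 0.97),
                                  min_shared = min_shared)
  decisions <- resolve_duplicates(groups, state$ped)
  drop <- decisions$member[decisions$decision != "keep"]
  if (length(drop))
    state$gm <- drop_from_matrix(state$gm, individuals = drop,
                                 reason = "duplicate")
  state$results$dedup <- list(groups = groups, decisions = decisions,
                              dropped = drop)
  state
}

stage_parentage <- function(state) {
  ped <- state$ped
  ped <- ped[ped$id %in% c(individuals(state$gm),
                           unlist(ped[, c("mother", "father")])) |
               ped$selected, , drop = FALSE]
  class(ped) <- c("pedigree", "data.frame")
  cal <- calibrate_pc_threshold(state$gm, ped,
                                n_random = cfg(state, "n_random_pairs", 1000),
                                seed = state$seed)
  ver <- verify_parentage(state$gm, ped, cal$threshold)
  gen <- pedigree_generation(ped)
  rejected <- ver$verdicts[ver$verdicts$relation != "PPC" &
                             ver$verdicts$verdict == "rejected", ,
                           drop = FALSE]
  searches <- list()
  for (i in seq_len(nrow(rejected))) {
    child <- rejected$child[i]
    slot <- if (rejected$relation[i] == "PC_mother") "mother" else "father"
    cand <- search_parents(state$gm, child, individuals(state$gm),
                           cal$threshold, ped = ped, generation = gen)
    cand <- cand[!cand$possible_full_sib, , drop = FALSE]
    other <- if (slot == "mother") ped$father[match(child, ped$id)]
             else ped$mother[match(child, ped$id)]
    cand <- cand[!(cand$candidate %in% other), , drop = FALSE]
    # joint test with the confirmed co-parent separates the true parent
    # from close relatives (e.g. a shared grandparent) tied on PC errors
    if (nrow(cand) && !is.na(other) && other %in% individuals(state$gm)) {
      dos <- state$gm$calls
      cand$ppc <- vapply(cand$candidate, function(p)
        ppc_errors(dos[, child], dos[, p], dos[, other]), 0L)
      cand <- cand[order(cand$ppc, cand$error_count, cand$candidate), ,
                   drop = FALSE]
    }
    searches[[child]] <- cand
    ped[[slot]][match(child, ped$id)] <-
      if (nrow(cand)) cand$candidate[1] else NA_character_
  }
  ped <- normalize_pedigree(ped)
  ver2 <- verify_parentage(state$gm, ped, cal$threshold)
  conf_duo <- ver2$verdicts[ver2$verdicts$relation != "PPC" &
                              ver2$verdicts$verdict == "confirmed", ,
                            drop = FALSE]
  nulls <- detect_null_suspects(
    state$gm, data.frame(parent = conf_duo$counterpart,
                         child = conf_duo$child),
    min_duos = cfg(state, "null_min_duos", 3))
  if (length(nulls))
    state$gm <- drop_from_matrix(state$gm, markers = nulls,
                                 reason = "null_suspect")
  state$ped <- ped
  state$results$parentage <- list(
    calibration = cal, verdicts = ver2$verdicts,
    ppc_threshold = ver2$ppc_threshold, rejected = rejected,
    searches = searches, null_suspects = nulls)
  state
}

stage_mendel <- function(state) {
  ped <- normalize_pedigree(state$ped)
  res <- resolve_inconsistencies(ped, state$gm,
                                 max_iter = cfg(state, "mendel_max_iter", 10))
  gm <- impute_forced(ped, res$gm)
  state$gm <- gm
  state$ped <- ped
  state$results$mendel <- list(report = res$report,
                               n_blanked = res$n_blanked,
                               iterations = res$iterations,
                               clean = res$clean)
  state
}

stage_phase_recomb <- function(state) {
  window <- cfg(state, "dr_window_cm", 10)
  hm <- phase_pedigree(state$gm, state$ped, state$map)
  events <- detect_recombinations(hm)
  drs <- detect_double_recomb(events, window)
  causes <- classify_dr_causes(drs, state$gm, state$ped,
                               anomalies = hm$anomalies)
  suspects <- causes$marker[causes$cause == "clustering"]
  if (length(suspects))
    state$gm <- drop_from_matrix(state$gm, markers = suspects,
                                 reason = "cluster_suspect")
  if (length(suspects)) {
    hm <- phase_pedigree(state$gm, state$ped, state$map)
    events <- detect_recombinations(hm)
    drs <- detect_double_recomb(events, window)
  }
  state$results$phase_recomb <- list(hm = hm, events = events, drs = drs,
                                     causes = causes,
                                     cluster_suspects = suspects)
  state
}

stage_haploblock <- function(state) {
  pr <- state$results$phase_recomb
  map <- state$map[state$map$marker %in% markers(state$gm), , drop = FALSE]
  hbs <- define_borders(pr$events, map, ped = state$ped)
  ht <- assign_haplotypes(pr$hm, hbs)
  ht <- resolve_all_missing(ht, state$ped)
  check <- haplo_mendel_check(state$ped, ht, gm = state$gm)
  state$results$haploblock <- list(blocks = hbs, haplotypes = ht,
                                   check = check)
  state
}

stage_classify <- function(state) {
  cats <- state$results$snp_filter$categories
  cluster_shift <- union(
    state$results$snp_filter$cluster_suspects %||% character(0),
    state$results$phase_recomb$cluster_suspects %||% character(0))
  el <- state$gm$edit_log
  removed <- unique(el$marker[el$reason %in%
                                c("cluster_suspect", "map_unresolved") &
                                el$individual == "*"])
  ledger <- build_snp_ledger(state$initial_markers, cats, state$gm,
                             unmappable = setdiff(markers(state$gm),
                                                  state$map$marker),
                             cluster_shift = cluster_shift,
                             removed = removed)
  # a cluster-shift suspect is a wrongly-called cluster (type 2), not a
  # probe failure: clear its 'removed' flag so precedence lands on 2
  ledger$failed[ledger$marker %in% cluster_shift &
                  !(ledger$marker %in%
                      cats$marker[cats$category == "failed"])] <- FALSE
  cls <- classify_snps(ledger)
  state$results$classify <- list(ledger = ledger, classification = cls,
                                 cluster_suspects = cluster_shift)
  state
}

#' Run the full curation pipeline
#'
#' Executes every stage in the mandated order and optionally writes the
#' final bundle (curated genotypes, phased data, haplotypes, reports and
#' a JSON manifest with per-stage retained/discarded counts).
#'
#' @param gm,ped,map,baf,seed,config as in \code{\link{new_curation}}.
#' @param out_dir optional output directory for
#'   \code{\link{emit_final_dataset}}.
#' @return the completed \code{curation_state}.
#' @export
run_pipeline <- function(gm, ped, map, baf = NULL, seed = 1,
                         config = list(), out_dir = NULL) {
  state <- new_curation(gm, ped, map, baf, seed, config)
  for (stage in CURATION_STAGES) state <- run_stage(state, stage)
  if (!is.null(out_dir)) {
    manifest <- list(seed = seed, stage_order = CURATION_STAGES,
                     counts = state$counts,
                     config = if (length(state$config)) state$config else NULL)
    reports <- list(
      sample_qc = state$results$sample_qc$table,
      snp_categories = state$results$snp_filter$categories,
      duplicates = state$results$dedup$decisions,
      parentage_report = state$results$parentage$verdicts,
      mendel_flags = state$results$mendel$report$flags,
      double_recombinations = state$results$phase_recomb$drs,
      dr_causes = state$results$phase_recomb$causes)
    reports <- reports[!vapply(reports, is.null, TRUE)]
    emit_final_dataset(out_dir, state$gm,
                       state$results$classify$classification,
                       hm = state$results$phase_recomb$hm,
                       ht = state$results$haploblock$haplotypes,
                       reports = reports, manifest = manifest)
  }
  state
}
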