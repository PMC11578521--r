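#' Percentage rounded to one decimal
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @return `100 * n / total`, rounded to 1 decimal (the precision headline
#'   conservation percentages are reported at).
#' @export
percent_of <- function(n, total) {
  stopifnot(total > 0)
  round(100 * n / total, 1)
}

#' Inclusion-exclusion union count
#'
#' @param n_a,n_b Set sizes.
#' @param n_overlap Size of the intersection.
#' @return `n_a + n_b - n_overlap`.
#' @export
union_count <- function(n_a, n_b, n_overlap) {
  stopifnot(n_overlap <= min(n_a, n_b))
  n_a + n_b - n_overlap
}

#' Headline counts from per-evidence totals
#'
#' Recomputes the paper-shaped headline quantities from their inputs:
#' total constructs across the two evidence sources, total retained
#' constructs, the retained-uORF union by inclusion-exclusion, and the
#' fully-conserved percentage.
#'
#' @param n_constructs_exp,n_constructs_pred Constructs per evidence source.
#' @param n_retained_exp,n_retained_pred Retained constructs per source.
#' @param n_uorfs_exp,n_uorfs_pred Distinct retained uORFs per source.
#' @param n_uorf_overlap uORFs retained under both sources.
#' @param n_conserved_all,n_uorfs_total Fully-conserved and catalogue
#'   counts.
#' @return List: `n_constructs_total`, `n_retained_total`, `n_uorf_union`,
#'   `pct_conserved_all`.
#' @export
summarize_headline_counts <- function(n_constructs_exp, n_constructs_pred,
                                      n_retained_exp, n_retained_pred,
                                      n_uorfs_exp, n_uorfs_pred,
                                      n_uorf_overlap,
                                      n_conserved_all, n_uorfs_total) {
  list(
    n_constructs_total = n_constructs_exp + n_constructs_pred,
    n_retained_total = n_retained_exp + n_retained_pred,
    n_uorf_union = union_count(n_uorfs_exp, n_uorfs_pred, n_uorf_overlap),
    pct_conserved_all = percent_of(n_conserved_all, n_uorfs_total)
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates the four stages with the gating used throughout:
#' conservation is assessed for every uORF in every target genome;
#' transcript construction runs on the *full* catalogue (even uORFs that
#' failed conservation); structure evaluation runs on validated
#' constructs; and the final uORF list intersects retained constructs with
#' the conserved-in-all-targets set (curated scores). Deterministic for a
#' fixed cohort.
#'
#' @param cohort A [generate_cohort()] result (or a compatible list).
#' @param weights A [conservation_weights()].
#' @param score_threshold Splice-score threshold for predicted junctions.
#' @param min_cds_fraction Minimum CDS length fraction.
#' @param plddt_limit Protein length cutoff for structure evaluation.
#' @param max_mismatch Hamming budget for near-exact alignment.
#' @param outdir Optional directory for the stage tables (TSV).
#' @return List of class `uorf_pipeline_result`: `assessments`,
#'   `conservation_summary`, `conserved_all` (uORF ids), `constructs`,
#'   `comparisons`, `partition`, `summary` (the run summary), `audit`.
#' @export
run_pipeline <- function(cohort, weights = conservation_weights(),
                         score_threshold = 0.9, min_cds_fraction = 0.9,
                         plddt_limit = 2000L, max_mismatch = 3L,
                         outdir = NULL) {
  assessments <- run_conservation(cohort$uorfs, cohort$targets, weights,
                                  max_mismatch)
  cons_summary <- summarize_conservation(assessments, weights)
  n_targets <- length(unique(assessments$target_genome))
  cons_by_uorf <- tapply(assessments$conserved, assessments$uorf_id, sum)
  conserved_all <- names(cons_by_uorf)[cons_by_uorf == n_targets]

  constructs <- build_constructs(cohort$uorfs, cohort$reference$genome,
                                 cohort$reference$annotation,
                                 cohort$junctions,
                                 score_threshold = score_threshold,
                                 min_cds_fraction = min_cds_fraction)
  refs <- reference_transcripts(cohort$reference$annotation,
                                cohort$reference$genome)
  comparisons <- evaluate_structures(constructs, refs, cohort$plddt_backend,
                                     limit = plddt_limit)
  partition <- partition_by_evidence(comparisons)

  retained_ids <- comparisons$construct_id[
    comparisons$retention_class %in% c("higher", "similar")]
  retained <- constructs[constructs$construct_id %in% retained_ids, ,
                         drop = FALSE]
  final_uorfs <- intersect(unique(retained$uorf_id), conserved_all)
  final <- retained[retained$uorf_id %in% conserved_all, , drop = FALSE]

  valid <- constructs[constructs$valid, , drop = FALSE]
  summary <- list(
    n_uorfs_total = length(cohort$uorfs),
    n_conserved_all = length(conserved_all),
    pct_conserved_all = percent_of(length(conserved_all),
                                   length(cohort$uorfs)),
    n_constructs_by_evidence = c(
      experimental = sum(valid$evidence == "experimental"),
      predicted = sum(valid$evidence == "predicted")),
    n_retained_by_evidence = c(
      experimental = sum(retained$evidence == "experimental"),
      predicted = sum(retained$evidence == "predicted")),
    n_retained_uorfs_by_evidence = c(
      experimental = length(unique(retained$uorf_id[
        retained$evidence == "experimental"])),
      predicted = length(unique(retained$uorf_id[
        retained$evidence == "predicted"]))),
    n_uorf_overlap = partition$uorf_overlap,
    n_uorf_union = partition$uorf_union,
    n_non_aug = sum(valid$start_codon_class == "non_AUG"),
    n_reference_duplicates = sum(valid$duplicate_of_reference),
    n_final_uorfs = length(final_uorfs),
    final_uorf_ids = sort(final_uorfs),
    mean_coverage_retained = partition$mean_coverage_retained,
    mean_coverage_all = partition$mean_coverage_all
  )

  result <- structure(list(
    assessments = assessments, conservation_summary = cons_summary,
    conserved_all = conserved_all, constructs = constructs,
    comparisons = comparisons, partition = partition,
    retained = retained, final = final, summary = summary,
    audit = NULL
  ), class = "uorf_pipeline_result")
  result$audit <- audit_counts(result)
  if (!is.null(outdir)) write_pipeline_tables(result, outdir)
  result
}

#' Audit the internal count arithmetic of a pipeline run
#'
#' Verifies the inclusion-exclusion and containment identities the run
#' summary claims: the retained-uORF union, the retained/constructed
#' totals, retained constructs being a subset of validated constructs,
#' constructed uORFs being a subset of the catalogue, the final list being
#' inside both the conserved-in-all set and the retained set, and the
#' conserved percentage recomputation. Any failure names the violated
#' identity.
#'
#' @param result A `uorf_pipeline_result` (or a list with the same
#'   fields).
#' @return List with `pass` (logical) and `checks` (data.frame `identity`,
#'   `lhs`, `rhs`, `pass`).
#' @export
audit_counts <- function(result) {
  s <- result$summary
  checks <- list()
  add <- function(identity, lhs, rhs) {
    checks[[length(checks) + 1L]] <<- data.frame(
      identity = identity, lhs = lhs, rhs = rhs, pass = isTRUE(lhs == rhs),
      stringsAsFactors = FALSE)
  }
  add("uorf_union == |exp| + |pred| - |overlap|",
      s$n_uorf_union,
      union_count(s$n_retained_uorfs_by_evidence[["experimental"]],
                  s$n_retained_uorfs_by_evidence[["predicted"]],
                  s$n_uorf_overlap))
  add("retained_total == retained_exp + retained_pred",
      sum(s$n_retained_by_evidence),
      nrow(result$retained))
  add("retained subset of validated constructs",
      sum(result$retained$valid), nrow(result$retained))
  add("constructed uORFs subset of catalogue",
      length(setdiff(unique(result$constructs$uorf_id),
                     result$assessments$uorf_id)), 0L)
  add("final uORFs inside conserved-in-all set",
      length(setdiff(unique(result$final$uorf_id), result$conserved_all)),
      0L)
  add("final constructs inside retained set",
      length(setdiff(result$final$construct_id,
                     result$retained$construct_id)), 0L)
  add("pct_conserved_all recomputes",
      s$pct_conserved_all,
      percent_of(s$n_conserved_all, s$n_uorfs_total))
  checks <- do.call(rbind, checks)
  list(pass = all(checks$pass), checks = checks)
}

#' Check pipeline output against the cohort's planted truth
#'
#' Four recoveries, each scored as matched records over total records:
#' conservation levels and verdicts per (uORF, genome); linking-junction
#' detection per uORF (a uORF yields at least one construct iff evidence
#' was planted); ORF-validation verdicts per uORF; and the structure delta
#' class per uORF (`skipped` when no validated construct or the protein
#' exceeded the folding length cutoff).
#'
#' @param result A `uorf_pipeline_result`.
#' @param cohort The [generate_cohort()] cohort that produced it.
#' @return data.frame with `field`, `n`, `n_match`, `pct_match`.
#' @export
check_truth_recovery <- function(result, cohort) {
  tc <- cohort$truth$conservation
  key <- paste(result$assessments$uorf_id, result$assessments$target_genome)
  idx <- match(paste(tc$uorf_id, tc$target_genome), key)
  cons_match <- result$assessments$score[idx] == tc$expected_level &
    result$assessments$conserved[idx] == tc$expected_conserved

  tu <- cohort$truth$uorf
  has_construct <- tu$uorf_id %in% result$constructs$uorf_id
  link_match <- has_construct == tu$has_linking_junction

  valid_by_uorf <- tapply(result$constructs$valid, result$constructs$uorf_id,
                          any)
  observed_valid <- tu$uorf_id %in%
    names(valid_by_uorf)[vapply(valid_by_uorf, isTRUE, logical(1))]
  valid_match <- observed_valid == tu$expected_valid_orf

  class_by_uorf <- tapply(result$comparisons$retention_class,
                          result$comparisons$uorf_id,
                          function(x) unique(x)[1])
  observed_class <- ifelse(tu$uorf_id %in% names(class_by_uorf),
                           unlist(class_by_uorf)[tu$uorf_id], "skipped")
  delta_match <- observed_class == tu$expected_delta_class

  data.frame(
    field = c("conservation", "linking_junction", "orf_validation",
              "delta_class"),
    n = c(length(cons_match), length(link_match), length(valid_match),
          length(delta_match)),
    n_match = c(sum(cons_match), sum(link_match), sum(valid_match),
                sum(delta_match)),
    pct_match = c(percent_of(sum(cons_match), length(cons_match)),
                  percent_of(sum(link_match), length(link_match)),
                  percent_of(sum(valid_match), length(valid_match)),
                  percent_of(sum(delta_match), length(delta_match))),
    stringsAsFactors = FALSE
  )
}
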