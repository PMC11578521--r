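#' Per-residue structure-confidence profile
#'
#' Container for AlphaFold-style per-residue confidence (pLDDT, 0-100).
#' A skipped profile (e.g. protein too long to fold) carries no per-residue
#' values and no mean.
#'
#' @param protein_id Identifier.
#' @param per_residue Numeric vector of per-residue values in `[0, 100]`.
#' @param skipped Logical; `TRUE` for profiles that were never computed.
#' @param reason Skip reason, when `skipped`.
#' @return A list of class `confidence_profile` with fields `protein_id`,
#'   `per_residue`, `mean`, `skipped`, `reason`.
#' @export
confidence_profile <- function(protein_id, per_residue = numeric(0),
                               skipped = FALSE, reason = NA_character_) {
  if (skipped) {
    per_residue <- numeric(0)
    m <- NA_real_
  } else {
    if (length(per_residue) == 0L) {
      stop("a non-skipped confidence profile needs per-residue values")
    }
    stopifnot(all(per_residue >= 0), all(per_residue <= 100))
    m <- mean(per_residue)
  }
  structure(list(protein_id = protein_id, per_residue = per_residue,
                 mean = m, skipped = skipped, reason = reason),
            class = "confidence_profile")
}

#' Mean per-residue confidence
#'
#' @param x A [confidence_profile()] or a numeric per-residue vector.
#' @return Arithmetic mean of the per-residue values.
#' @export
mean_plddt <- function(x) {
  v <- if (inherits(x, "confidence_profile")) x$per_residue else x
  if (length(v) == 0L) stop("cannot take the mean of an empty profile")
  mean(v)
}

#' Length cutoff for structure prediction
#'
#' Proteins longer than `limit` residues are not folded; their profiles are
#' marked skipped and any comparison involving them classifies as
#' `"skipped"`. The boundary is strict: a protein of exactly `limit`
#' residues is still folded.
#'
#' @param protein Amino-acid sequence.
#' @param limit Cutoff in residues (default 2000).
#' @param protein_id Identifier recorded on a skipped profile.
#' @return A skipped [confidence_profile()] when the protein exceeds the
#'   limit, otherwise `NULL`.
#' @export
apply_length_skip <- function(protein, limit = 2000L, protein_id = "protein") {
  if (nchar(protein) > limit) {
    confidence_profile(protein_id, skipped = TRUE,
                       reason = paste0("length ", nchar(protein), " > ",
                                       limit, " residues"))
  } else {
    NULL
  }
}

#' Classify a mean-confidence difference
#'
#' delta > 1 is `"higher"`, -1 <= delta <= 1 is `"similar"` (both boundary
#' values inclusive), delta < -1 is `"lower"`. Retained constructs are the
#' union of `"higher"` and `"similar"`.
#'
#' @param delta Novel mean minus reference mean.
#' @return One of `"higher"`, `"similar"`, `"lower"`.
#' @export
classify_delta <- function(delta) {
  stopifnot(is.finite(delta))
  if (delta > 1) "higher" else if (delta >= -1) "similar" else "lower"
}

#' Compare a novel protein's confidence against its reference(s)
#'
#' Computes the mean-confidence difference (delta) of the novel protein
#' against every non-skipped reference and reports the pair with maximal
#' delta: the construct is retained if it is at least similar to *one* of
#' the references. Means are rounded to 2 decimals before differencing, the
#' precision at which deltas are reported, so classification at the
#' published +-1 boundary is not epsilon-sensitive. Invariant to the order
#' of `references`.
#'
#' @param novel A [confidence_profile()] for the novel protein.
#' @param references A [confidence_profile()] or list of them.
#' @return A one-row data.frame: `protein_id`, `reference_id`, `novel_mean`,
#'   `reference_mean`, `delta`, `retention_class`. When the novel profile or
#'   all references are skipped, means/delta are `NA` and the class is
#'   `"skipped"`.
#' @export
compare_structures <- function(novel, references) {
  if (inherits(references, "confidence_profile")) references <- list(references)
  stopifnot(length(references) >= 1L)
  refs <- Filter(function(r) !r$skipped, references)
  if (novel$skipped || length(refs) == 0L) {
    return(data.frame(protein_id = novel$protein_id,
                      reference_id = NA_character_,
                      novel_mean = NA_real_, reference_mean = NA_real_,
                      delta = NA_real_, retention_class = "skipped",
                      stringsAsFactors = FALSE))
  }
  nm <- round(novel$mean, 2)
  deltas <- vapply(refs, function(r) nm - round(r$mean, 2), numeric(1))
  best <- which.max(deltas)
  data.frame(protein_id = novel$protein_id,
             reference_id = refs[[best]]$protein_id,
             novel_mean = nm, reference_mean = round(refs[[best]]$mean, 2),
             delta = round(deltas[best], 2),
             retention_class = classify_delta(deltas[best]),
             stringsAsFactors = FALSE)
}

#' Fold and compare every validated construct against its reference
#'
#' Runs the structure backend on each validated construct's protein and on
#' each distinct reference protein (skipping those beyond `limit` residues),
#' then classifies each construct by its best delta across the references
#' at its locus.
#'
#' @param constructs Construct table from [build_constructs()]; only rows
#'   with `valid == TRUE` are evaluated.
#' @param references List of `reference_transcript` objects (see
#'   [reference_transcripts()]).
#' @param backend Function `(protein_id, protein) -> confidence_profile`,
#'   e.g. from [mock_plddt_backend()].
#' @param limit Length cutoff in residues passed to [apply_length_skip()].
#' @return data.frame with one row per validated construct: `construct_id`,
#'   `uorf_id`, `evidence`, `support`, `reference_id`, `novel_mean`,
#'   `reference_mean`, `delta`, `retention_class`.
#' @export
evaluate_structures <- function(constructs, references, backend,
                                limit = 2000L) {
  keep <- constructs[constructs$valid, , drop = FALSE]
  ref_by_gene <- split(references,
                       vapply(references, `[[`, "", "gene_name"))
  ref_profiles <- new.env(parent = emptyenv())
  get_ref_profile <- function(ref) {
    if (is.null(ref_profiles[[ref$transcript_id]])) {
      prof <- apply_length_skip(ref$protein, limit, ref$transcript_id)
      if (is.null(prof)) prof <- backend(ref$transcript_id, ref$protein)
      ref_profiles[[ref$transcript_id]] <- prof
    }
    ref_profiles[[ref$transcript_id]]
  }
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    cns <- keep[i, ]
    novel <- apply_length_skip(cns$protein, limit, cns$uorf_id)
    if (is.null(novel)) novel <- backend(cns$uorf_id, cns$protein)
    refs <- ref_by_gene[[cns$gene_name]]
    cmp <- compare_structures(novel, lapply(refs, get_ref_profile))
    data.frame(construct_id = cns$construct_id, uorf_id = cns$uorf_id,
               evidence = cns$evidence, support = cns$support,
               reference_id = cmp$reference_id, novel_mean = cmp$novel_mean,
               reference_mean = cmp$reference_mean, delta = cmp$delta,
               retention_class = cmp$retention_class,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(construct_id = character(0), uorf_id = character(0),
                      evidence = character(0), support = numeric(0),
                      reference_id = character(0), novel_mean = numeric(0),
                      reference_mean = numeric(0), delta = numeric(0),
                      retention_class = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Retention counts split by junction evidence source
#'
#' Summarises structure comparisons the way the headline counts are
#' reported: retained constructs (`higher` or `similar`), strictly-higher
#' constructs, and distinct contributing uORFs per evidence source, with
#' the overlap and inclusion-exclusion union across sources. Also reports
#' the mean junction read coverage of retained experimental-evidence
#' constructs against the mean over all experimental constructs.
#'
#' @param comparisons Output of [evaluate_structures()].
#' @return A list: `by_evidence` (data.frame with `evidence`, `n_constructs`,
#'   `n_retained`, `n_higher`, `n_uorfs_retained`), `n_retained_total`,
#'   `n_higher_total`, `uorf_overlap`, `uorf_union`,
#'   `mean_coverage_retained`, `mean_coverage_all` (experimental evidence
#'   only; `NaN` when absent).
#' @export
partition_by_evidence <- function(comparisons) {
  retained <- comparisons$retention_class %in% c("higher", "similar")
  higher <- comparisons$retention_class == "higher"
  ev_levels <- c("experimental", "predicted")
  by_ev <- do.call(rbind, lapply(ev_levels, function(ev) {
    sel <- comparisons$evidence == ev
    data.frame(evidence = ev,
               n_constructs = sum(sel),
               n_retained = sum(sel & retained),
               n_higher = sum(sel & higher),
               n_uorfs_retained = length(unique(comparisons$uorf_id[sel & retained])),
               stringsAsFactors = FALSE)
  }))
  u_exp <- unique(comparisons$uorf_id[retained & comparisons$evidence == "experimental"])
  u_pred <- unique(comparisons$uorf_id[retained & comparisons$evidence == "predicted"])
  exp_sel <- comparisons$evidence == "experimental"
  list(
    by_evidence = by_ev,
    n_retained_total = sum(retained),
    n_higher_total = sum(higher),
    uorf_overlap = length(intersect(u_exp, u_pred)),
    uorf_union = length(union(u_exp, u_pred)),
    mean_coverage_retained = mean(comparisons$support[exp_sel & retained]),
    mean_coverage_all = mean(comparisons$support[exp_sel])
  )
}

#' Structural-change category vocabulary
#'
#' Fixed labels for operator-assigned structural-change categories of
#' strictly-improved constructs. Category calls are made by visual
#' inspection of predicted structures and recorded here only as bookkeeping;
#' the package never infers them.
#'
#' @return data.frame with `code` (0-6) and `label`.
#' @export
change_categories <- function() {
  data.frame(
    code = 0:6,
    label = c("undefined", "end_truncation", "helix_deletion_truncation",
              "helix_elongation", "straightening", "tightening",
              "structural_addition"),
    stringsAsFactors = FALSE
  )
}
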