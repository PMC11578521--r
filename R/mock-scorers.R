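#' Deterministic mock splice-site scorer
#'
#' Stands in for a learned splice-site model behind the pluggable scorer
#' interface used by [pair_and_score()]. The score is a pure function of the
#' two context sequences, keyed on planted 8-mer signatures: a donor context
#' beginning with the strong-donor signature scores 0.96, a bare canonical
#' GT scores 0.35, anything else 0.02; acceptor contexts ending with the
#' strong-acceptor signature score 0.96, a bare AG 0.35, otherwise 0.02.
#' The synthetic-data generator plants these signatures on demand, so test
#' loci can carry guaranteed high-scoring (>= 0.95) or low-scoring (<= 0.5)
#' sites.
#'
#' @param donor_context First `window` intronic bases at the donor site,
#'   read 5'->3' on the transcript strand.
#' @param acceptor_context Last `window` intronic bases at the acceptor
#'   site, read 5'->3' on the transcript strand.
#' @param window Context width both arguments must reach (default 8).
#' @return Named numeric vector `c(donor =, acceptor =)`, both in `[0, 1]`.
#' @export
mock_splice_scorer <- function(donor_context, acceptor_context, window = 8L) {
  if (nchar(donor_context) < window || nchar(acceptor_context) < window) {
    stop("splice-site context shorter than the configured window (",
         window, " bases)")
  }
  donor_context <- substr(donor_context, 1L, window)
  acceptor_context <- substr(acceptor_context,
                             nchar(acceptor_context) - window + 1L,
                             nchar(acceptor_context))
  donor <- if (startsWith(donor_context, DONOR_SIGNATURE)) 0.96
           else if (startsWith(donor_context, "GT")) 0.35
           else 0.02
  acceptor <- if (endsWith(acceptor_context, ACCEPTOR_SIGNATURE)) 0.96
              else if (endsWith(acceptor_context, "AG")) 0.35
              else 0.02
  c(donor = donor, acceptor = acceptor)
}

## van der Corput base-2 low-discrepancy sequence: deterministic,
## reproducible without touching the RNG state.
van_der_corput <- function(n) {
  vapply(seq_len(n), function(i) {
    v <- 0
    f <- 0.5
    while (i > 0L) {
      v <- v + f * (i %% 2L)
      i <- i %/% 2L
      f <- f / 2
    }
    v
  }, numeric(1))
}

#' Deterministic mock per-residue confidence profile
#'
#' Stands in for a structure-prediction backend: produces a per-residue
#' confidence (pLDDT-style, 0-100) vector of the protein's length whose
#' arithmetic mean equals `target_mean` to within 1e-9. Per-residue values
#' are a low-discrepancy sequence rescaled around the target, so profiles
#' are reproducible without a random-state dependency.
#'
#' @param protein Amino-acid sequence (non-empty, no stop symbol).
#' @param target_mean Desired mean confidence in `[0, 100]`.
#' @param protein_id Identifier recorded on the profile.
#' @return A [confidence_profile()].
#' @export
mock_plddt_profile <- function(protein, target_mean, protein_id = "protein") {
  n <- nchar(protein)
  if (n == 0L) stop("cannot build a confidence profile for an empty protein")
  stopifnot(target_mean >= 0, target_mean <= 100)
  spread <- min(8, target_mean, 100 - target_mean)
  v <- van_der_corput(n)
  values <- target_mean + spread * (v - mean(v))
  confidence_profile(protein_id, values)
}

#' Mock structure-confidence backend over planted target means
#'
#' Returns a backend function `(protein_id, protein) -> confidence_profile`
#' that looks up the planted target mean for `protein_id` and delegates to
#' [mock_plddt_profile()]. Proteins longer than `limit` residues are skipped
#' (no per-residue values, no mean), mirroring how very long CDSs are
#' excluded from structure prediction.
#'
#' @param targets data.frame with columns `protein_id`, `target_mean`.
#' @param default_mean Mean used for identifiers absent from `targets`.
#' @param limit Length cutoff in residues (default 2000).
#' @return A function usable as the `backend` of [evaluate_structures()].
#' @export
mock_plddt_backend <- function(targets, default_mean = 70, limit = 2000L) {
  stopifnot(is.data.frame(targets),
            all(c("protein_id", "target_mean") %in% names(targets)))
  lut <- stats::setNames(targets$target_mean, targets$protein_id)
  function(protein_id, protein) {
    skipped <- apply_length_skip(protein, limit = limit,
                                 protein_id = protein_id)
    if (!is.null(skipped)) return(skipped)
    mean <- if (protein_id %in% names(lut)) lut[[protein_id]] else default_mean
    mock_plddt_profile(protein, mean, protein_id)
  }
}
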