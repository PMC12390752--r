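# Key objects and key <-> carrier matching.
#
# The admin key is a polymerase: it recognises primer-bound regions
# nonspecifically, so one admin key opens every carrier (one-to-many).
# A user key is a DNA strand set — competing strands that pair the gap
# regions plus invading strands that enter at the overhang toeholds — and is
# sequence-matched to exactly one carrier (one-to-one). New user keys are
# minted by moving the scaffold breakpoint, which relocates every gap and
# overhang region; candidate keys are screened for cross-hybridization.

#' Scaffold model
#'
#' A circular single-stranded scaffold. When no sequence is supplied, a
#' seeded pseudorandom sequence of the requested length is generated as a
#' synthetic stand-in for M13mp18 (7,249 nt), so nothing has to be
#' downloaded; a real sequence (e.g. from [read_scaffold_fasta()]) is used
#' verbatim when provided.
#'
#' @param scaffold_id identifier.
#' @param length_nt circular length; default the M13mp18 length 7,249.
#' @param sequence optional explicit sequence (ACGT string of `length_nt`).
#' @param seed seed for the synthetic sequence (ignored when `sequence` given).
#' @return object of class `scaffold_model`.
#' @export
scaffold_model <- function(scaffold_id = "synM13-1", length_nt = 7249L,
                           sequence = NULL, seed = 7249L) {
  length_nt <- as.integer(length_nt)
  if (is.null(sequence)) {
    chars <- with_seed(seed, sample(c("A", "C", "G", "T"), length_nt, replace = TRUE))
  } else {
    chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
    if (length(chars) != length_nt) {
      ddc_error("sequence length must equal length_nt", "ddc_design_error")
    }
  }
  structure(list(scaffold_id = scaffold_id,
                 length_nt = length_nt,
                 chars = chars),
            class = "scaffold_model")
}

#' Circular subsequence of a scaffold
#' @param scaffold a [scaffold_model()].
#' @param start0 0-based start position (wraps around the circle).
#' @param len subsequence length.
#' @return character string of length `len`.
#' @export
scaffold_subseq <- function(scaffold, start0, len) {
  idx <- ((as.integer(start0) + seq_len(len) - 1L) %% scaffold$length_nt) + 1L
  paste(scaffold$chars[idx], collapse = "")
}

#' Administrator key
#'
#' The polymerase trigger. Parameters are informational (dose and incubation
#' descriptors); what matters to the model is that the admin key matches every
#' well-formed carrier.
#'
#' @param label free-text label.
#' @param params informational dose descriptor.
#' @return object of class `admin_key`.
#' @export
admin_key <- function(label = "Klenow",
                      params = list(dose_kU_per_l = 8, incubation_h = 4)) {
  structure(list(label = label, params = params),
            class = c("admin_key", "ddc_key"))
}

#' User key
#'
#' A trigger-strand set. In `"abstract"` mode the key simply names its target
#' design (so simulation and statistics can run without any sequences); in
#' `"sequence"` mode it carries the competing strands (exact complements of
#' the target's gap regions) and invading strands (complements of the edge
#' overhang domains).
#'
#' @param target_design_id design the key unlocks.
#' @param competing_strands,invading_strands sequence-mode strand sets.
#' @param mode `"abstract"` or `"sequence"`.
#' @return object of class `user_key`.
#' @export
user_key <- function(target_design_id,
                     competing_strands = NULL, invading_strands = NULL,
                     mode = c("abstract", "sequence")) {
  mode <- match.arg(mode)
  if (mode == "sequence" &&
      (is.null(competing_strands) || is.null(invading_strands))) {
    ddc_error("sequence mode requires competing and invading strands",
              "ddc_mode_error")
  }
  structure(list(target_design_id = target_design_id,
                 competing_strands = competing_strands,
                 invading_strands = invading_strands,
                 mode = mode),
            class = c("user_key", "ddc_key"))
}

#' Does a key unlock a carrier?
#'
#' Admin keys match every well-formed design (one-to-many). A user key
#' matches in abstract mode iff it names the design, and in sequence mode iff
#' every competing strand is the reverse complement of the corresponding gap
#' region and every invading strand the reverse complement of an overhang
#' domain (one-to-one).
#'
#' @param key an [admin_key()] or [user_key()].
#' @param design a [carrier_design()].
#' @return logical.
#' @export
matches <- function(key, design) UseMethod("matches")

#' @export
matches.admin_key <- function(key, design) TRUE

#' @export
matches.user_key <- function(key, design) {
  if (key$mode == "abstract") {
    return(identical(key$target_design_id, design$design_id))
  }
  if (is.null(design$gap_region_seqs) || is.null(design$domain_seqs)) {
    ddc_error("sequence-mode key against a sequence-free design", "ddc_mode_error")
  }
  if (length(key$competing_strands) != length(design$gap_region_seqs) ||
      length(key$invading_strands) != length(design$domain_seqs)) {
    return(FALSE)
  }
  all(revcomp(key$competing_strands) == design$gap_region_seqs) &&
    all(revcomp(key$invading_strands) == unname(design$domain_seqs))
}

#' Derive the user key of a carrier
#'
#' Builds the unique sequence-mode key unlocking `design`: competing strands
#' are reverse complements of the gap regions, invading strands reverse
#' complements of the overhang domains. `matches(derive_user_key(D), D)` is
#' true by construction.
#'
#' @param design a sequence-resolved [carrier_design()].
#' @param scaffold optional [scaffold_model()]; used to resolve sequences when
#'   the design does not carry them (same breakpoint layout as
#'   [carrier_from_breakpoint()]).
#' @return a sequence-mode [user_key()].
#' @export
derive_user_key <- function(design, scaffold = NULL) {
  if (is.null(design$gap_region_seqs) || is.null(design$domain_seqs)) {
    if (is.null(scaffold)) {
      ddc_error("design has no sequences and no scaffold was supplied",
                "ddc_derivation_error")
    }
    design <- carrier_from_breakpoint(scaffold, design$breakpoint,
                                      design_id = design$design_id)
  }
  user_key(target_design_id = design$design_id,
           competing_strands = unname(revcomp(design$gap_region_seqs)),
           invading_strands = unname(revcomp(unname(design$domain_seqs))),
           mode = "sequence")
}

#' Cross-hybridization score between two user keys
#'
#' Length of the longest substring of any strand of key `a` whose reverse
#' complement occurs in a region targeted by key `b`. Because each trigger
#' strand is the exact reverse complement of its target region, this equals
#' the longest common substring between the two keys' raw strands — it is
#' symmetric, and a key against itself scores the full strand length
#' (maximally non-orthogonal). Two keys are called orthogonal under a k-mer
#' policy iff the score is `< k`.
#'
#' @param a,b sequence-mode [user_key()] objects.
#' @return integer, the maximal shared complementary k-mer length.
#' @export
cross_hybridization <- function(a, b) {
  if (!inherits(a, "user_key") || !inherits(b, "user_key") ||
      a$mode != "sequence" || b$mode != "sequence") {
    ddc_error("cross_hybridization requires two sequence-mode user keys",
              "ddc_mode_error")
  }
  sa <- c(a$competing_strands, a$invading_strands)
  sb <- c(b$competing_strands, b$invading_strands)
  best <- 0L
  for (x in sa) {
    for (y in sb) {
      best <- max(best, lcs_length(x, y))
    }
  }
  best
}

# longest common substring length, O(nm) dynamic programme
lcs_length <- function(x, y) {
  a <- utf8ToInt(x); b <- utf8ToInt(y)
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m)
  best <- 0L
  for (i in seq_len(n)) {
    cur <- integer(m)
    hit <- which(b == a[i])
    if (length(hit)) {
      cur[hit] <- ifelse(hit == 1L, 1L, prev[pmax(hit - 1L, 1L)] + 1L)
      best <- max(best, max(cur[hit]))
    }
    prev <- cur
  }
  as.integer(best)
}

#' k-mer orthogonality policy
#' @param k two keys are orthogonal iff they share no complementary k-mer of
#'   this length (default 8, a standard strand-displacement screening
#'   threshold).
#' @return object of class `orthogonality_policy`.
#' @export
orthogonality_policy <- function(k = 8L) {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k)), class = "orthogonality_policy")
}

#' Enumerate the breakpoint key space
#'
#' Candidate user keys are generated by shifting the scaffold breakpoint in
#' steps of `min_shift_nt` around the circle: `floor(length_nt / min_shift_nt)`
#' candidates. At the M13mp18 length (7,249 nt) and 1-nt shifts this exceeds
#' 7,000 keys. Under an [orthogonality_policy()] the candidates are screened
#' by a greedy scan in breakpoint order, keeping a candidate only if its
#' trigger set is orthogonal to every key already kept.
#'
#' @param scaffold a [scaffold_model()].
#' @param min_shift_nt minimum breakpoint shift between candidates (>= 1).
#' @param orthogonality `NULL` (no screen) or an [orthogonality_policy()].
#' @return list with `count`, `breakpoints`, and (when screened) `keys`.
#' @export
enumerate_breakpoint_keys <- function(scaffold, min_shift_nt = 1L,
                                      orthogonality = NULL) {
  min_shift_nt <- as.integer(min_shift_nt)
  if (min_shift_nt < 1L) {
    ddc_error("min_shift_nt must be >= 1", "ddc_parameter_error")
  }
  n_cand <- scaffold$length_nt %/% min_shift_nt
  bps <- min_shift_nt * (seq_len(n_cand) - 1L)
  if (is.null(orthogonality)) {
    return(list(count = n_cand, breakpoints = bps, keys = NULL))
  }
  k <- orthogonality$k
  kept_bps <- integer(0)
  kept_keys <- list()
  for (bp in bps) {
    cand <- derive_user_key(
      carrier_from_breakpoint(scaffold, bp, design_id = sprintf("bp%d", bp)))
    ok <- all(vapply(kept_keys, function(kk) cross_hybridization(cand, kk) < k,
                     logical(1)))
    if (ok) {
      kept_bps <- c(kept_bps, bp)
      kept_keys <- c(kept_keys, list(cand))
    }
  }
  list(count = length(kept_bps), breakpoints = kept_bps, keys = kept_keys)
}
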