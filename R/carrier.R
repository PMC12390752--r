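# Geometric / structural model of one DNA domino-array data carrier (DDC).
#
# The carrier is a rectangular origami whose label lattice sits at one pitch
# in the locked (OFF) conformation and stretches along one axis in the
# unlocked (ON) conformation. Thirteen displaceable edge staples carry 3'
# overhangs (7 orthogonal domains, cycled); single-stranded scaffold gap
# regions on the short sides hold the primers that the admin (polymerase)
# route extends and the user (strand set) route displaces. Two always-biotin
# marker sites report the conformation by their separation.

#' Construct a carrier design
#'
#' @param design_id identifier, e.g. `"DDC-1"`.
#' @param grid_rows,grid_cols,address_rows label-lattice shape
#'   (default 5 x 5 message + 1 x 5 address = 30 addressable sites).
#' @param n_edge_staples number of displaceable edge staples (default 13).
#' @param overhang_domain_ids domain identifier per edge staple; by default
#'   the 13 staples cycle through 7 orthogonal domain ids. Any surjective
#'   assignment of length `n_edge_staples` is accepted.
#' @param domain_seqs named character vector of overhang (toehold + primer)
#'   sequences per domain id, or `NULL` for an abstract (sequence-free) design.
#' @param gap_region_seqs character vector of short-side scaffold gap
#'   sequences, or `NULL`.
#' @param n_gaps number of gap regions when sequences are absent.
#' @param scaffold_id,breakpoint scaffold identity and the position (0-based,
#'   on the circular scaffold) where its register is opened.
#' @param pitch_off,pitch_on label pitch `(dx, dy)` in nm for the OFF and ON
#'   conformations. Only the ratio matters to the algorithms; defaults stretch
#'   the row axis from 6 to 12 nm.
#' @param marker_sites list of two `(row, col)` lattice indices for the
#'   conformation-marker pair; defaults sit in a dedicated column left of the
#'   data array, separated along the stretching axis.
#' @return an object of class `carrier_design`.
#' @export
carrier_design <- function(design_id = "DDC-1",
                           grid_rows = 5L, grid_cols = 5L, address_rows = 1L,
                           n_edge_staples = 13L,
                           overhang_domain_ids = NULL,
                           domain_seqs = NULL,
                           gap_region_seqs = NULL,
                           n_gaps = 2L,
                           scaffold_id = "synM13-1", breakpoint = 0L,
                           pitch_off = c(6, 6), pitch_on = c(6, 12),
                           marker_sites = list(c(0L, -2L), c(2L, -2L))) {
  if (is.null(overhang_domain_ids)) {
    overhang_domain_ids <- paste0("dom", ((seq_len(n_edge_staples) - 1L) %% 7L) + 1L)
  }
  if (length(overhang_domain_ids) != n_edge_staples) {
    ddc_error("need one overhang domain id per edge staple", "ddc_design_error")
  }
  if (any(pitch_off <= 0) || any(pitch_on <= 0)) {
    ddc_error("pitches must be positive", "ddc_design_error")
  }
  if (!is.null(gap_region_seqs)) n_gaps <- length(gap_region_seqs)
  d <- structure(list(design_id = design_id,
                      grid_rows = as.integer(grid_rows),
                      grid_cols = as.integer(grid_cols),
                      address_rows = as.integer(address_rows),
                      n_edge_staples = as.integer(n_edge_staples),
                      overhang_domain_ids = overhang_domain_ids,
                      domain_seqs = domain_seqs,
                      gap_region_seqs = gap_region_seqs,
                      n_gaps = as.integer(n_gaps),
                      scaffold_id = scaffold_id,
                      breakpoint = as.integer(breakpoint),
                      pitch_off = as.numeric(pitch_off),
                      pitch_on = as.numeric(pitch_on),
                      marker_sites = lapply(marker_sites, as.integer)),
                 class = "carrier_design")
  if (identical(d$marker_sites[[1]], d$marker_sites[[2]])) {
    ddc_error("marker sites must be distinct", "ddc_design_error")
  }
  if (marker_distance(d, "ON") <= marker_distance(d, "OFF")) {
    ddc_error("marker distance must increase OFF -> ON", "ddc_design_error")
  }
  d
}

#' @export
print.carrier_design <- function(x, ...) {
  cat(sprintf("<carrier_design %s: %dx%d + %d address row(s), %d edge staples, scaffold %s @%d>\n",
              x$design_id, x$grid_rows, x$grid_cols, x$address_rows,
              x$n_edge_staples, x$scaffold_id, x$breakpoint))
  invisible(x)
}

#' Number of addressable label sites on a carrier
#'
#' Message plus address lattice positions (30 for the default design);
#' conformation-marker sites are not addressable data sites.
#' @param design a [carrier_design()].
#' @return integer count.
#' @export
n_label_sites <- function(design) {
  (design$grid_rows + design$address_rows) * design$grid_cols
}

pitch_for <- function(design, conf) {
  switch(conf,
         OFF = design$pitch_off,
         ON  = design$pitch_on,
         IC  = (design$pitch_off + design$pitch_on) / 2,
         ddc_error(sprintf("unknown conformation '%s'", conf), "ddc_design_error"))
}

# no bounds check; used for marker sites outside the data lattice
site_xy_raw <- function(design, row, col, conf) {
  p <- pitch_for(design, conf)
  c(x = col * p[1], y = row * p[2])
}

#' Physical position of a lattice site
#'
#' Deterministic coordinates `(col * dx, row * dy)` under the given
#' conformation's pitch. Rows are 0-based from the top message row; the
#' address row is row `-1` (above row 0).
#'
#' @param design a [carrier_design()].
#' @param row integer in `[-address_rows, grid_rows - 1]`.
#' @param col integer in `[0, grid_cols - 1]`.
#' @param conf `"OFF"` or `"ON"`.
#' @return named numeric `(x, y)` in nm.
#' @export
site_xy <- function(design, row, col, conf = c("OFF", "ON")) {
  conf <- match.arg(conf)
  if (row < -design$address_rows || row >= design$grid_rows ||
      col < 0 || col >= design$grid_cols) {
    ddc_error(sprintf("site (%d, %d) outside lattice", row, col), "ddc_bounds_error")
  }
  site_xy_raw(design, row, col, conf)
}

#' Separation of the conformation-marker pair
#'
#' Euclidean distance between the two marker sites under a conformation.
#' A short separation reports the locked OFF state, a long one the unlocked
#' ON state; every valid design satisfies `marker_distance(ON) > marker_distance(OFF)`.
#'
#' @param design a [carrier_design()].
#' @param conf `"OFF"`, `"ON"` or `"IC"`.
#' @return distance in nm.
#' @export
marker_distance <- function(design, conf = c("OFF", "ON", "IC")) {
  conf <- match.arg(conf)
  a <- site_xy_raw(design, design$marker_sites[[1]][1], design$marker_sites[[1]][2], conf)
  b <- site_xy_raw(design, design$marker_sites[[2]][1], design$marker_sites[[2]][2], conf)
  sqrt(sum((a - b)^2))
}

#' Conformation category from edge / gap state
#'
#' The carrier is OFF while no edge staple has been displaced and no gap has
#' been resolved, ON once all edges are displaced and all gaps resolved
#' (filled by polymerase or paired by competing strands), and intermediate
#' (IC) in every other state. The transformation itself is modelled as a
#' single event per structure; per-junction cascade dynamics are abstracted.
#'
#' @param design a [carrier_design()].
#' @param edges_displaced logical vector, one flag per edge staple.
#' @param gaps_filled logical vector, one flag per gap region.
#' @return object of class `conformation_state` with `$category` in
#'   `{"OFF", "ON", "IC"}`.
#' @export
derive_state <- function(design, edges_displaced, gaps_filled) {
  if (length(edges_displaced) != design$n_edge_staples ||
      length(gaps_filled) != design$n_gaps) {
    ddc_error("flag vectors must match the design's edge/gap counts",
              "ddc_design_error")
  }
  category <- if (!any(edges_displaced) && !any(gaps_filled)) "OFF"
  else if (all(edges_displaced) && all(gaps_filled)) "ON"
  else "IC"
  structure(list(category = category,
                 edges_displaced = as.logical(edges_displaced),
                 gaps_filled = as.logical(gaps_filled)),
            class = "conformation_state")
}

# --- sequence-resolved designs ----------------------------------------------

# Deterministic layout of sequence regions relative to the scaffold
# breakpoint: two 16-nt gap regions (at the breakpoint and half-way around),
# then 7 x 16-nt overhang domains in 20-nt steps. Shifting the breakpoint
# shifts every region, which is what generates a distinct user key.
GAP_LEN <- 16L
DOMAIN_LEN <- 16L
DOMAIN_STEP <- 20L

#' Build a sequence-resolved carrier from a scaffold breakpoint
#'
#' Resolves the gap-region and overhang-domain sequences of a design from a
#' circular scaffold opened at `breakpoint`. Moving the breakpoint changes the
#' local sequences and hence the trigger-strand set that unlocks the carrier.
#'
#' @param scaffold a [scaffold_model()].
#' @param breakpoint 0-based position on the circular scaffold.
#' @param design_id identifier for the new design.
#' @param ... passed through to [carrier_design()].
#' @return a sequence-resolved [carrier_design()].
#' @export
carrier_from_breakpoint <- function(scaffold, breakpoint, design_id = "DDC-1", ...) {
  breakpoint <- as.integer(breakpoint) %% scaffold$length_nt
  gaps <- c(scaffold_subseq(scaffold, breakpoint, GAP_LEN),
            scaffold_subseq(scaffold, breakpoint + scaffold$length_nt %/% 2L, GAP_LEN))
  dom_starts <- breakpoint + 2L * GAP_LEN + DOMAIN_STEP * (0:6)
  doms <- vapply(dom_starts, function(s) scaffold_subseq(scaffold, s, DOMAIN_LEN),
                 character(1))
  names(doms) <- paste0("dom", 1:7)
  carrier_design(design_id = design_id,
                 domain_seqs = doms,
                 gap_region_seqs = gaps,
                 scaffold_id = scaffold$scaffold_id,
                 breakpoint = breakpoint, ...)
}
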