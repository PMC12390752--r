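# Stochastic readout simulator / synthetic-fixture generator.
#
# Emulates the AFM observation of streptavidin-labelled carriers: a
# key-conditioned Bernoulli transformation per structure, independent
# per-site biotin -> STV binding, optional false spots on "0" sites, and
# isotropic Gaussian localization noise on spot positions. It emulates spot
# patterns only — no tip convolution, drift or instrument file formats.

#' Readout simulation parameters
#'
#' Defaults trace the quantified transformation behaviour: the strand-set
#' (user) trigger converts 89% of structures and the polymerase (admin)
#' trigger 76%, while 86% of untriggered structures stay locked
#' (`p_spont = 0.14`); STV binds each biotin site independently with
#' probability ~0.95. The intermediate-conformation stall rate, false-spot
#' rate and localization noise are free parameters (no quantified rates to
#' trace) with conservative defaults.
#'
#' @param p_user transformation probability under a matched user key.
#' @param p_admin transformation probability under the admin key.
#' @param p_spont trigger-free (or mismatched-key) transformation probability.
#' @param p_ic conditional probability that a structure which fails to reach
#'   the ON conformation stalls intermediate rather than staying locked.
#' @param q per-site biotin -> STV binding probability.
#' @param fp_rate per-"0"-site false-spot probability.
#' @param loc_sigma_nm isotropic localization noise s.d. in nm.
#' @return object of class `readout_params`.
#' @export
readout_params <- function(p_user = 0.89, p_admin = 0.76, p_spont = 0.14,
                           p_ic = 0.05, q = 0.95, fp_rate = 0,
                           loc_sigma_nm = 0.6) {
  probs <- c(p_user = p_user, p_admin = p_admin, p_spont = p_spont,
             p_ic = p_ic, q = q, fp_rate = fp_rate)
  if (any(probs < 0 | probs > 1)) {
    ddc_error("probabilities must lie in [0, 1]", "ddc_parameter_error")
  }
  if (loc_sigma_nm < 0) ddc_error("loc_sigma_nm must be >= 0", "ddc_parameter_error")
  structure(as.list(c(probs, loc_sigma_nm = loc_sigma_nm)),
            class = "readout_params")
}

# Transformation probability of a key against a design. A mismatched user
# key leaves only the spontaneous rate (no partial cross-talk).
key_transform_prob <- function(key, design, params) {
  if (is.null(key)) return(params$p_spont)
  if (inherits(key, "admin_key")) return(params$p_admin)
  if (inherits(key, "user_key")) {
    return(if (matches(key, design)) params$p_user else params$p_spont)
  }
  ddc_error("key must be NULL, an admin_key or a user_key", "ddc_parameter_error")
}

# Precomputed site layout for one design + grid: site coordinates per
# conformation, biotin flags, marker positions. Row -1 is the address row.
site_layout <- function(design, grid) {
  if (nrow(grid$bits) != design$grid_rows || ncol(grid$bits) != design$grid_cols ||
      nrow(grid$address) != design$address_rows) {
    ddc_error("grid shape does not match the design lattice", "ddc_design_error")
  }
  rows <- c(-(seq_len(design$address_rows)), seq_len(design$grid_rows) - 1L)
  sites <- expand.grid(row = rows, col = seq_len(design$grid_cols) - 1L,
                       KEEP.OUT.ATTRS = FALSE)
  sites <- sites[order(sites$row, sites$col), ]
  bit_of <- function(r, c) {
    if (r < 0) grid$address[-r, c + 1L] else grid$bits[r + 1L, c + 1L]
  }
  sites$bit <- mapply(bit_of, sites$row, sites$col)
  mk <- do.call(rbind, design$marker_sites)
  xy <- function(conf) {
    p <- pitch_for(design, conf)
    list(site = cbind(x = sites$col * p[1], y = sites$row * p[2]),
         marker = cbind(x = mk[, 2] * p[1], y = mk[, 1] * p[2]))
  }
  list(design = design, grid = grid, sites = sites,
       coords = list(OFF = xy("OFF"), ON = xy("ON"), IC = xy("IC")))
}

# One stochastic draw from a prepared layout. Returns a spot_field.
#
# p_key is the probability of reaching the ON conformation — the quantity
# the transformation-yield measurements estimate — so P(ON) = p_key exactly
# and the theoretical CorrInfo yield p * q^n is the analytic expectation.
# Structures that fail to reach ON stall intermediate with probability p_ic.
sim_draw <- function(layout, params, p_key) {
  category <- if (stats::runif(1) < p_key) "ON"
  else if (stats::runif(1) < params$p_ic) "IC"
  else "OFF"
  co <- layout$coords[[category]]
  is_biotin <- layout$sites$bit == 1L
  bound <- stats::runif(sum(is_biotin)) < params$q
  fp <- if (params$fp_rate > 0) {
    stats::runif(sum(!is_biotin)) < params$fp_rate
  } else rep(FALSE, sum(!is_biotin))
  marker_bound <- stats::runif(nrow(co$marker)) < params$q
  emit <- rbind(co$site[is_biotin, , drop = FALSE][bound, , drop = FALSE],
                co$site[!is_biotin, , drop = FALSE][fp, , drop = FALSE],
                co$marker[marker_bound, , drop = FALSE])
  if (params$loc_sigma_nm > 0 && nrow(emit) > 0) {
    emit <- emit + matrix(stats::rnorm(2 * nrow(emit), 0, params$loc_sigma_nm),
                          ncol = 2)
  }
  corrinfo <- category == "ON" && all(bound) && !any(fp)
  structure(list(
    spots = data.frame(x_nm = emit[, 1], y_nm = emit[, 2]),
    truth = list(category = category,
                 bound = bound,
                 marker_bound = marker_bound,
                 n_false_spots = sum(fp),
                 corrinfo = corrinfo,
                 grid = layout$grid)),
    class = "spot_field")
}

#' Simulate the readout of one carrier
#'
#' Draws a transformation outcome (Bernoulli with the key-conditioned
#' probability, stalling intermediate with probability `p_ic`), then emits a
#' spot for each biotin site independently with probability `q` (and for each
#' "0" site with probability `fp_rate`) at the site position under the
#' realized conformation plus isotropic Gaussian noise. The two marker sites
#' are always biotinylated and emit with probability `q`.
#'
#' @param design a [carrier_design()].
#' @param grid the physical (typically scrambled) [message_grid][encode_text]
#'   on the carrier.
#' @param key `NULL` (no trigger), an [admin_key()] or a [user_key()].
#' @param params a [readout_params()].
#' @param seed optional seed for this draw.
#' @return a `spot_field`: `$spots` (data frame of x_nm, y_nm) and `$truth`
#'   (category, per-site binding outcomes, false-spot count, CorrInfo flag,
#'   source grid).
#' @export
simulate_structure <- function(design, grid, key = NULL,
                               params = readout_params(), seed = NULL) {
  layout <- site_layout(design, grid)
  p_key <- key_transform_prob(key, design, params)
  if (!is.null(seed)) set.seed(seed)
  sim_draw(layout, params, p_key)
}

#' Simulate an ensemble of carriers
#'
#' Independent draws of [simulate_structure()] under one condition, with a
#' tally of true conformation categories and CorrInfo events (structure ON,
#' every biotin site in the data + address array bound, no false spots —
#' marker sites are tallied separately). Per-structure child seeds are drawn
#' from the root seed and recorded.
#'
#' @inheritParams simulate_structure
#' @param n_structures number of structures (>= 1).
#' @param seed root seed.
#' @param keep_fields keep the individual spot fields (set `FALSE` for large
#'   tally-only runs).
#' @return list with `fields` (or `NULL`), `tally` (one-row data frame of
#'   counts), `categories`, `corrinfo` (logical vector), `child_seeds`.
#' @export
simulate_ensemble <- function(design, grid, key = NULL,
                              params = readout_params(),
                              n_structures = 1000L, seed = NULL,
                              keep_fields = TRUE) {
  stopifnot(n_structures >= 1)
  layout <- site_layout(design, grid)
  p_key <- key_transform_prob(key, design, params)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_structures)
  fields <- vector("list", n_structures)
  categories <- character(n_structures)
  corrinfo <- logical(n_structures)
  for (i in seq_len(n_structures)) {
    set.seed(child_seeds[i])
    f <- sim_draw(layout, params, p_key)
    categories[i] <- f$truth$category
    corrinfo[i] <- f$truth$corrinfo
    if (keep_fields) fields[[i]] <- f
  }
  tally <- data.frame(n = n_structures,
                      OFF = sum(categories == "OFF"),
                      ON = sum(categories == "ON"),
                      IC = sum(categories == "IC"),
                      CorrInfo = sum(corrinfo))
  list(fields = if (keep_fields) fields else NULL,
       tally = tally, categories = categories, corrinfo = corrinfo,
       child_seeds = child_seeds)
}

#' Render a spot field as a synthetic AFM-like raster
#'
#' Sums isotropic Gaussians centred on the spots over a canvas padded around
#' the design bounding box. Deterministic given the field; an empty field
#' yields a blank canvas.
#'
#' @param field a `spot_field`.
#' @param pixel_nm pixel size (> 0).
#' @param psf_sigma_nm Gaussian point-spread s.d.
#' @param bbox optional canvas bounds `c(xmin, xmax, ymin, ymax)`; defaults to
#'   the spot bounding box padded by `3 * psf_sigma_nm` (or a unit box when
#'   the field is empty).
#' @return matrix of intensities (rows = y, increasing; columns = x) with
#'   attributes `x_nm`, `y_nm` giving pixel-centre coordinates.
#' @export
render_raster <- function(field, pixel_nm = 1, psf_sigma_nm = 2, bbox = NULL) {
  if (pixel_nm <= 0) ddc_error("pixel_nm must be > 0", "ddc_parameter_error")
  sp <- field$spots
  if (is.null(bbox)) {
    pad <- 3 * psf_sigma_nm
    bbox <- if (nrow(sp) == 0) c(0, 1, 0, 1)
    else c(min(sp$x_nm) - pad, max(sp$x_nm) + pad,
           min(sp$y_nm) - pad, max(sp$y_nm) + pad)
  }
  xs <- seq(bbox[1], bbox[2], by = pixel_nm)
  ys <- seq(bbox[3], bbox[4], by = pixel_nm)
  img <- matrix(0, nrow = length(ys), ncol = length(xs))
  if (nrow(sp) > 0) {
    gx <- exp(-outer(xs, sp$x_nm, "-")^2 / (2 * psf_sigma_nm^2))
    gy <- exp(-outer(ys, sp$y_nm, "-")^2 / (2 * psf_sigma_nm^2))
    img <- gy %*% t(gx)
  }
  attr(img, "x_nm") <- xs
  attr(img, "y_nm") <- ys
  img
}
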