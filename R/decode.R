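# Observation-side pipeline: conformation classification, lattice
# registration, bit calling, and plaintext recovery from a spot field.

# Template = all lattice sites (address row included) plus the marker pair
# under one conformation's pitch. Cached per design/category (the decoder
# builds the same three templates for every field of an ensemble).
.template_cache <- new.env(parent = emptyenv())

template_sites <- function(design, category, swap_axes = FALSE) {
  key <- paste(design$design_id, design$grid_rows, design$grid_cols,
               design$address_rows, category, swap_axes,
               paste(design$pitch_off, collapse = ","),
               paste(design$pitch_on, collapse = ","),
               paste(unlist(design$marker_sites), collapse = ","),
               sep = "|")
  hit <- .template_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- template_sites_build(design, category, swap_axes)
  .template_cache[[key]] <- out
  out
}

template_sites_build <- function(design, category, swap_axes = FALSE) {
  p <- pitch_for(design, category)
  if (swap_axes) p <- rev(p)
  rows <- c(-(seq_len(design$address_rows)), seq_len(design$grid_rows) - 1L)
  g <- expand.grid(row = rows, col = seq_len(design$grid_cols) - 1L,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$row, g$col), ]
  mk <- do.call(rbind, design$marker_sites)
  data.frame(row = c(g$row, mk[, 1]),
             col = c(g$col, mk[, 2]),
             x = c(g$col, mk[, 2]) * p[1],
             y = c(g$row, mk[, 1]) * p[2],
             marker = c(rep(FALSE, nrow(g)), rep(TRUE, nrow(mk))))
}

# Translation-only registration of spots onto a template by iterated
# nearest-site correspondence. The zero shift is tried first (fields in
# design coordinates register there directly); if that fit is not clean, an
# anchor search seeds the iteration with every translation that maps the
# first spot onto a template site, which recovers arbitrary rigid
# translations without getting trapped in lattice-shifted local optima.
fit_template <- function(spots, sites, max_iter = 10L) {
  sxy <- cbind(sites$x, sites$y)
  pxy <- cbind(spots$x_nm, spots$y_nm)
  score <- function(shift) {
    moved <- sweep(pxy, 2, shift, "+")
    d2 <- outer(moved[, 1], sxy[, 1], "-")^2 + outer(moved[, 2], sxy[, 2], "-")^2
    nn <- max.col(-d2, ties.method = "first")
    resid <- sqrt(d2[cbind(seq_len(nrow(d2)), nn)])
    list(shift = shift, nn = nn, residuals = resid, mean_resid = mean(resid))
  }
  run <- function(shift) {
    for (it in seq_len(max_iter)) {
      moved <- sweep(pxy, 2, shift, "+")
      d2 <- outer(moved[, 1], sxy[, 1], "-")^2 + outer(moved[, 2], sxy[, 2], "-")^2
      nn <- max.col(-d2, ties.method = "first")
      new_shift <- shift + colMeans(sxy[nn, , drop = FALSE] - moved)
      if (sum((new_shift - shift)^2) < 1e-12) { shift <- new_shift; break }
      shift <- new_shift
    }
    score(shift)
  }
  f0 <- run(c(0, 0))
  if (f0$mean_resid < 0.9) return(f0)   # clean registration at zero offset
  # anchor search: candidate translations place spot 1 on each site
  cand <- sweep(sxy, 2, pxy[1, ], "-")
  cand_resid <- vapply(seq_len(nrow(cand)),
                       function(i) score(cand[i, ])$mean_resid, numeric(1))
  best <- f0
  for (i in order(cand_resid)[seq_len(min(3L, nrow(cand)))]) {
    fi <- run(cand[i, ])
    if (fi$mean_resid < best$mean_resid) best <- fi
  }
  best
}

min_pitch <- function(design) min(design$pitch_off, design$pitch_on)

#' Classify the conformation of a spot field
#'
#' Fits the spots to the OFF-, ON- and intermediate-lattice templates by
#' translation-only registration (optionally also with the pitch axes
#' swapped) and takes the category with the smallest mean nearest-site
#' residual — provided that residual is below `tol * min(pitch)` and that the
#' runner-up fit is not within the relative ambiguity band. Anything else,
#' including an empty field, is UC (uncertain conformation).
#'
#' @param field a `spot_field` (or anything with `$spots`).
#' @param design a [carrier_design()].
#' @param tol acceptance threshold as a fraction of the minimum pitch.
#' @param margin relative ambiguity band: if the two best fits are within
#'   this fraction of each other the call is UC.
#' @param allow_axis_swap also try templates with x/y pitches swapped
#'   (reading the carrier rotated by 90 degrees).
#' @return `"OFF"`, `"ON"`, `"IC"` or `"UC"`.
#' @export
classify_conformation <- function(field, design, tol = 0.35, margin = 0.10,
                                  allow_axis_swap = FALSE) {
  if (nrow(field$spots) == 0) return("UC")
  cats <- c("OFF", "ON", "IC")
  res <- vapply(cats, function(cc) {
    r <- fit_template(field$spots, template_sites(design, cc))$mean_resid
    if (allow_axis_swap) {
      r <- min(r, fit_template(field$spots,
                               template_sites(design, cc, swap_axes = TRUE))$mean_resid)
    }
    r
  }, numeric(1))
  o <- order(res)
  best <- res[o[1]]; second <- res[o[2]]
  if (best > tol * min_pitch(design)) return("UC")
  if (second > 0 && (second - best) / second < margin) return("UC")
  cats[o[1]]
}

#' Call bits by assigning spots to lattice sites
#'
#' Registers the spots on the template of the called conformation, assigns
#' each spot to its nearest site within `tol * min(pitch)` (ties break toward
#' the lower `(row, col)` index), and calls a site 1 when at least one spot
#' lands on it. Multiple spots on one site collapse to a single 1; spots
#' assigned to no site (or to a marker site) are counted as noise/markers,
#' not data.
#'
#' @param field a `spot_field`.
#' @param design a [carrier_design()].
#' @param category the called conformation, `"OFF"` or `"ON"` (or `"IC"`,
#'   using the intermediate template).
#' @param tol assignment radius as a fraction of the minimum pitch.
#' @return list with `bits` (message matrix), `address` (address-row matrix),
#'   `n_noise`, `n_multi`, `n_marker_spots`, `shift`, `mean_residual_nm`.
#' @export
assign_spots <- function(field, design, category, tol = 0.35) {
  sites <- template_sites(design, category)
  fit <- fit_template(field$spots, sites)
  ok <- fit$residuals <= tol * min_pitch(design)
  assigned <- fit$nn[ok]
  bits <- matrix(0L, design$grid_rows, design$grid_cols)
  address <- matrix(0L, design$address_rows, design$grid_cols)
  n_marker <- 0L
  for (s in assigned) {
    if (sites$marker[s]) { n_marker <- n_marker + 1L; next }
    r <- sites$row[s]; cc <- sites$col[s]
    if (r < 0) address[-r, cc + 1L] <- 1L else bits[r + 1L, cc + 1L] <- 1L
  }
  n_multi <- sum(duplicated(assigned[!sites$marker[assigned]]))
  list(bits = bits, address = address,
       n_noise = sum(!ok), n_multi = n_multi, n_marker_spots = n_marker,
       shift = fit$shift, mean_residual_nm = fit$mean_resid)
}

#' Decode a spot field to plaintext
#'
#' Full observation chain: classify the conformation, assign spots to sites,
#' read the address row, descramble, and decode the word. Plaintext is
#' produced only from the ON conformation — an OFF carrier still yields bit
#' calls, but they remain ciphertext. When the ground-truth grid is supplied
#' (e.g. from a simulated field), `corrinfo` records the success criterion:
#' conformation ON *and* every site of the data + address array called
#' correctly.
#'
#' @param field a `spot_field`.
#' @param design a [carrier_design()].
#' @param scheme the [encoding_scheme()] of the stored data.
#' @param truth optional ground-truth (physical, scrambled) `message_grid`;
#'   defaults to the field's own truth grid when present.
#' @param tol,margin classifier/assignment settings, see
#'   [classify_conformation()].
#' @return a `readout_call`: `category`, `bit_calls` (message + address),
#'   `word_index`, `decoded_text` (`NULL` unless ON), `assignment_residual_nm`,
#'   `corrinfo` (`NA` without truth).
#' @export
decode_message <- function(field, design, scheme = encoding_scheme("a5"),
                           truth = NULL, tol = 0.35, margin = 0.10) {
  if (is.null(truth) && !is.null(field$truth)) truth <- field$truth$grid
  category <- classify_conformation(field, design, tol = tol, margin = margin)
  call <- list(category = category, bit_calls = NULL, word_index = NA_integer_,
               decoded_text = NULL, assignment_residual_nm = NA_real_,
               corrinfo = NA)
  if (category %in% c("OFF", "ON")) {
    asg <- assign_spots(field, design, category, tol = tol)
    call$bit_calls <- asg
    call$assignment_residual_nm <- asg$mean_residual_nm
    if (category == "ON") {
      g <- new_message_grid(asg$bits, asg$address, scrambled = TRUE,
                            scheme_id = scheme$scheme_id)
      g <- descramble(g)
      call$word_index <- g$word_index
      call$decoded_text <- decode_word(g, scheme)
    }
  }
  if (!is.null(truth)) {
    call$corrinfo <- category == "ON" &&
      !is.null(call$bit_calls) &&
      all(call$bit_calls$bits == truth$bits) &&
      all(call$bit_calls$address == truth$address)
  }
  structure(call, class = "readout_call")
}

#' @export
print.readout_call <- function(x, ...) {
  cat(sprintf("<readout_call %s%s%s>\n", x$category,
              if (!is.null(x$decoded_text)) paste0(' "', x$decoded_text, '"') else "",
              if (!is.na(x$corrinfo)) paste0(" corrinfo=", x$corrinfo) else ""))
  invisible(x)
}

#' Detect spots in a rendered raster
#'
#' Simple local-maximum peak finder for synthetic rasters from
#' [render_raster()]: pixels that are strict 8-neighbourhood maxima and
#' exceed `threshold * max(image)` become spots at their pixel centres.
#'
#' @param img raster matrix with `x_nm` / `y_nm` attributes.
#' @param threshold relative intensity threshold in (0, 1).
#' @return a `spot_field` with the detected coordinates (no truth).
#' @export
detect_spots <- function(img, threshold = 0.1) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3 || max(img) <= 0) {
    return(structure(list(spots = data.frame(x_nm = numeric(0), y_nm = numeric(0)),
                          truth = NULL), class = "spot_field"))
  }
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  is_max <- core > threshold * max(img)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    is_max <- is_max & (core >= nb) & (core > nb | (dr < 0 | (dr == 0 & dc < 0)))
  }
  idx <- which(is_max, arr.ind = TRUE)
  structure(list(spots = data.frame(x_nm = attr(img, "x_nm")[idx[, 2]],
                                    y_nm = attr(img, "y_nm")[idx[, 1]]),
                 truth = NULL),
            class = "spot_field")
}
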