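# Plain-text serialization: grids (JSON and text dump), carrier designs,
# keys, spot fields (CSV), scaffolds (FASTA via Biostrings).

#' Write / read message grids as JSON
#'
#' Structured JSON: one record per grid with `scheme_id`, `word_index`,
#' `bits`, `address`, `scrambled`, `spaced`, `carrier_ref`.
#'
#' @param grids list of `message_grid` objects.
#' @param path file path.
#' @return `write_grids_json` the path, invisibly; `read_grids_json` a list
#'   of `message_grid` objects.
#' @export
write_grids_json <- function(grids, path) {
  recs <- lapply(grids, function(g) {
    list(scheme_id = g$scheme_id,
         word_index = if (is.na(g$word_index)) NULL else g$word_index,
         bits = unname(apply(g$bits, 1, as.integer, simplify = FALSE)),
         address = unname(apply(g$address, 1, as.integer, simplify = FALSE)),
         scrambled = g$scrambled, spaced = g$spaced,
         carrier_ref = if (is.na(g$carrier_ref)) NULL else g$carrier_ref)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grids_json
#' @export
read_grids_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    new_message_grid(do.call(rbind, lapply(r$bits, unlist)),
                     do.call(rbind, lapply(r$address, unlist)),
                     scrambled = isTRUE(r$scrambled),
                     scheme_id = r$scheme_id,
                     word_index = r$word_index %||% NA_integer_,
                     carrier_ref = r$carrier_ref %||% NA_character_,
                     spaced = isTRUE(r$spaced))
  })
}

#' Plain-text dump of a grid
#'
#' Rows of 0/1, address row(s) prefixed `A:`; the inverse of
#' [parse_grid_text()].
#'
#' @param grid a `message_grid`.
#' @return character vector of lines.
#' @export
format_grid_text <- function(grid) {
  c(paste("A:", apply(grid$address, 1, paste, collapse = " ")),
    apply(grid$bits, 1, paste, collapse = " "))
}

#' @rdname format_grid_text
#' @param lines character vector as produced by [format_grid_text()].
#' @param scheme_id scheme identifier to attach.
#' @export
parse_grid_text <- function(lines, scheme_id = "a5") {
  is_addr <- startsWith(lines, "A:")
  parse_row <- function(s) as.integer(strsplit(trimws(sub("^A:", "", s)), " +")[[1]])
  new_message_grid(do.call(rbind, lapply(lines[!is_addr], parse_row)),
                   do.call(rbind, lapply(lines[is_addr], parse_row)),
                   scheme_id = scheme_id)
}

#' Write / read a carrier design file
#'
#' Versioned JSON schema (`ddc-design/1`) holding every [carrier_design()]
#' field; `inst/extdata/DDC-1.json` and `DDC-2.json` ship two
#' sequence-resolved designs on the same synthetic scaffold with shifted
#' breakpoints.
#'
#' @param design a [carrier_design()].
#' @param path file path.
#' @return `write_carrier_design` the path, invisibly; `read_carrier_design`
#'   a [carrier_design()].
#' @export
write_carrier_design <- function(design, path) {
  rec <- unclass(design)
  rec$schema <- "ddc-design/1"
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_carrier_design
#' @export
read_carrier_design <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(r$schema, "ddc-design/1")) {
    ddc_error("not a ddc-design/1 file", "ddc_design_error")
  }
  carrier_design(design_id = r$design_id,
                 grid_rows = r$grid_rows, grid_cols = r$grid_cols,
                 address_rows = r$address_rows,
                 n_edge_staples = r$n_edge_staples,
                 overhang_domain_ids = r$overhang_domain_ids,
                 domain_seqs = if (length(r$domain_seqs)) unlist(r$domain_seqs) else NULL,
                 gap_region_seqs = if (length(r$gap_region_seqs)) unlist(r$gap_region_seqs) else NULL,
                 n_gaps = r$n_gaps,
                 scaffold_id = r$scaffold_id, breakpoint = r$breakpoint,
                 pitch_off = r$pitch_off, pitch_on = r$pitch_on,
                 marker_sites = lapply(seq_len(nrow(r$marker_sites)),
                                       function(i) r$marker_sites[i, ]))
}

#' Write / read a key file
#'
#' JSON `{mode, target_design_id, competing_strands, invading_strands}` for
#' user keys, `{mode: "admin", label, params}` for admin keys.
#'
#' @param key an [admin_key()] or [user_key()].
#' @param path file path.
#' @return `write_key_json` the path, invisibly; `read_key_json` a key.
#' @export
write_key_json <- function(key, path) {
  rec <- if (inherits(key, "admin_key")) {
    list(mode = "admin", label = key$label, params = key$params)
  } else {
    list(mode = key$mode, target_design_id = key$target_design_id,
         competing_strands = key$competing_strands,
         invading_strands = key$invading_strands)
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_key_json
#' @export
read_key_json <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(r$mode, "admin")) {
    admin_key(label = r$label, params = r$params)
  } else {
    user_key(target_design_id = r$target_design_id,
             competing_strands = unlist(r$competing_strands),
             invading_strands = unlist(r$invading_strands),
             mode = r$mode)
  }
}

#' Write / read a spot field as CSV
#'
#' Columns `x_nm, y_nm`, plus `truth_category` and `truth_corrinfo` when
#' truth annotations are present and `truth = TRUE`.
#'
#' @param field a `spot_field`.
#' @param path file path.
#' @param truth include ground-truth columns when available.
#' @return `write_spot_csv` the path, invisibly; `read_spot_csv` a
#'   `spot_field`.
#' @export
write_spot_csv <- function(field, path, truth = FALSE) {
  df <- field$spots
  if (truth && !is.null(field$truth)) {
    df$truth_category <- field$truth$category
    df$truth_corrinfo <- field$truth$corrinfo
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  df <- utils::read.csv(path)
  truth <- NULL
  if ("truth_category" %in% names(df)) {
    truth <- list(category = df$truth_category[1],
                  corrinfo = isTRUE(df$truth_corrinfo[1]))
  }
  structure(list(spots = data.frame(x_nm = df$x_nm, y_nm = df$y_nm),
                 truth = truth),
            class = "spot_field")
}

#' Read / write scaffolds as FASTA
#'
#' Thin wrappers over Biostrings for the standard format; the first record of
#' the file becomes the circular scaffold sequence.
#'
#' @param path FASTA file path.
#' @param scaffold_id identifier for the resulting model (defaults to the
#'   FASTA record name).
#' @return `read_scaffold_fasta` a [scaffold_model()].
#' @export
read_scaffold_fasta <- function(path, scaffold_id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    ddc_error("FASTA support needs the Biostrings package", "ddc_io_error")
  }
  ss <- Biostrings::readDNAStringSet(path)
  scaffold_model(scaffold_id = scaffold_id %||% names(ss)[1],
                 length_nt = Biostrings::width(ss)[1],
                 sequence = as.character(ss[[1]]))
}

#' @rdname read_scaffold_fasta
#' @param scaffold a [scaffold_model()].
#' @export
write_scaffold_fasta <- function(scaffold, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    ddc_error("FASTA support needs the Biostrings package", "ddc_io_error")
  }
  ss <- Biostrings::DNAStringSet(paste(scaffold$chars, collapse = ""))
  names(ss) <- scaffold$scaffold_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
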