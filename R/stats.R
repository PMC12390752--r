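# Yield statistics and experiment harnesses.
#
# Two quantities anchor every experiment table: the observed yield
# y_exp = M / N (M structures with the expected conformation or pattern out
# of N intact structures) and the theoretical correct-information yield
# y_theo = p * q^n (p = transformation ratio of the trigger, q = per-site
# STV binding probability, n = number of biotin sites in the data + address
# array). y_theo decreases in n, which is why sparse words read out better
# than dense ones.

#' Observed yield with a Wilson interval
#'
#' `y_exp = M / N` plus a 95% Wilson score interval (appropriate for the
#' small AFM-style counts these experiments produce).
#'
#' @param M count of structures with the expected conformation or pattern.
#' @param N total number of intact structures (>= 1).
#' @param conf_level confidence level for the Wilson interval.
#' @return object of class `yield_estimate`: `M`, `N`, `y_exp`, `ci_low`,
#'   `ci_high`.
#' @export
yield_exp <- function(M, N, conf_level = 0.95) {
  if (N < 1) ddc_error("yield undefined for N = 0", "ddc_count_error")
  if (M < 0 || M > N) ddc_error("M must lie in [0, N]", "ddc_count_error")
  ci <- suppressWarnings(
    stats::prop.test(M, N, conf.level = conf_level, correct = FALSE)$conf.int)
  structure(list(M = as.integer(M), N = as.integer(N), y_exp = M / N,
                 ci_low = ci[1], ci_high = ci[2]),
            class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat(sprintf("y_exp = %d/%d = %.4f  [%.4f, %.4f]\n",
              x$M, x$N, x$y_exp, x$ci_low, x$ci_high))
  invisible(x)
}

#' Count the biotin sites of a grid
#'
#' `n` of the theoretical yield: 1-bits across the message *and* address
#' arrays. The two conformation markers are biotinylated too but tallied
#' separately in marker-only experiments, so their inclusion is optional and
#' off by default.
#'
#' @param grid a `message_grid`.
#' @param include_markers add the marker-pair count.
#' @param n_markers number of marker sites.
#' @return integer site count.
#' @export
count_biotin_sites <- function(grid, include_markers = FALSE, n_markers = 2L) {
  n <- sum(grid$bits) + sum(grid$address)
  if (include_markers) n <- n + n_markers
  as.integer(n)
}

#' Theoretical correct-information yield
#'
#' `y_theo = p * q^n`: the probability that a structure transforms (p) and
#' all n biotin sites bind STV independently (q each). Degenerate cases:
#' `n = 0` or `q = 1` give `y_theo = p`.
#'
#' @param p transformation ratio in `[0, 1]`.
#' @param q per-site binding probability in `[0, 1]`.
#' @param n non-negative integer count of biotin sites.
#' @return object of class `theo_yield`: `p`, `q`, `n`, `y_theo`.
#' @export
yield_theo <- function(p, q, n) {
  if (p < 0 || p > 1 || q < 0 || q > 1) {
    ddc_error("p and q must lie in [0, 1]", "ddc_parameter_error")
  }
  if (n < 0 || n != round(n)) {
    ddc_error("n must be a non-negative integer", "ddc_parameter_error")
  }
  structure(list(p = p, q = q, n = as.integer(n), y_theo = p * q^n),
            class = "theo_yield")
}

#' @export
print.theo_yield <- function(x, ...) {
  cat(sprintf("y_theo = %.3g * %.3g^%d = %.4f\n", x$p, x$q, x$n, x$y_theo))
  invisible(x)
}

#' Simulate and fully decode one experimental condition
#'
#' Ensemble simulation followed by the observation-side decoder on every
#' field: tabulates OFF/ON/IC/UC fractions (as the classifier calls them),
#' the CorrInfo fraction with its Wilson interval, and the matched
#' theoretical yield `p * q^n`.
#'
#' @inheritParams simulate_ensemble
#' @param scheme the [encoding_scheme()] of the stored data.
#' @param label condition label for the output row.
#' @return one-row data frame (a YieldTable row).
#' @export
run_condition <- function(design, grid, key = NULL, params = readout_params(),
                          n_structures = 1000L, seed = NULL,
                          scheme = encoding_scheme("a5"), label = NULL) {
  ens <- simulate_ensemble(design, grid, key, params, n_structures,
                           seed = seed, keep_fields = TRUE)
  calls <- lapply(ens$fields, decode_message, design = design, scheme = scheme)
  cats <- vapply(calls, function(x) x$category, character(1))
  ci_flags <- vapply(calls, function(x) isTRUE(x$corrinfo), logical(1))
  ye <- yield_exp(sum(ci_flags), n_structures)
  n_bits <- count_biotin_sites(grid)
  p_key <- key_transform_prob(key, design, params)
  data.frame(label = label %||% design$design_id,
             n = n_structures,
             OFF = sum(cats == "OFF"), ON = sum(cats == "ON"),
             IC = sum(cats == "IC"), UC = sum(cats == "UC"),
             frac_OFF = mean(cats == "OFF"), frac_ON = mean(cats == "ON"),
             frac_IC = mean(cats == "IC"), frac_UC = mean(cats == "UC"),
             CorrInfo = ye$M, frac_CorrInfo = ye$y_exp,
             ci_low = ye$ci_low, ci_high = ye$ci_high,
             p = p_key, q = params$q, n_biotin = n_bits,
             y_theo = yield_theo(p_key, params$q, n_bits)$y_theo,
             stringsAsFactors = FALSE)
}

#' CorrInfo permission matrix for a multi-user scenario
#'
#' Simulates every key against every carrier and returns the matrix of
#' CorrInfo fractions (simulator truth tallies). With one admin key and one
#' user key per design, the admin row reflects `p_admin`-level access to
#' every carrier, the diagonal user entries `p_user`-level access, and the
#' off-diagonal user entries only the spontaneous baseline — the hierarchy.
#'
#' @param designs list of [carrier_design()] objects.
#' @param grids list of physical `message_grid`s, one per design.
#' @param keys named list of keys (e.g. one [admin_key()] and one
#'   [user_key()] per design).
#' @param params a [readout_params()].
#' @param n_structures structures per cell.
#' @param seed root seed (per-cell seeds are derived from it).
#' @return numeric matrix, rows = keys, columns = designs.
#' @export
hierarchy_matrix <- function(designs, grids, keys, params = readout_params(),
                             n_structures = 1000L, seed = NULL) {
  stopifnot(length(designs) == length(grids))
  if (!is.null(seed)) set.seed(seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max,
                                  length(keys) * length(designs)),
                       nrow = length(keys))
  m <- matrix(NA_real_, nrow = length(keys), ncol = length(designs),
              dimnames = list(names(keys),
                              vapply(designs, function(d) d$design_id, character(1))))
  for (i in seq_along(keys)) {
    for (j in seq_along(designs)) {
      ens <- simulate_ensemble(designs[[j]], grids[[j]], keys[[i]], params,
                               n_structures, seed = cell_seeds[i, j],
                               keep_fields = FALSE)
      m[i, j] <- ens$tally$CorrInfo / n_structures
    }
  }
  m
}

#' Run a shipped experiment configuration
#'
#' Reads a JSON experiment config (see `inst/extdata/fig*.json`) and runs it.
#' Two config types are supported: `"conditions"` (a list of key conditions
#' against one encoded message, one [run_condition()] row per word and
#' condition) and `"hierarchy"` (a multi-user permission matrix via
#' [hierarchy_matrix()]).
#'
#' @param config path to a JSON config or an already-parsed list.
#' @return a YieldTable data frame (`"conditions"`) or a matrix
#'   (`"hierarchy"`).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  config$keys <- unlist(config$keys)
  config$texts <- unlist(config$texts)
  params <- do.call(readout_params, lapply(as.list(config$params %||% list()), unlist))
  scheme <- encoding_scheme(config$scheme %||% "a5")
  make_key <- function(kc, design) {
    switch(kc,
           none = NULL,
           admin = admin_key(),
           user = user_key(design$design_id),
           ddc_error(sprintf("unknown key condition '%s'", kc), "ddc_parameter_error"))
  }
  if (identical(config$type, "conditions")) {
    design <- do.call(carrier_design, lapply(as.list(config$design %||% list()), unlist))
    if (nzchar(config$text)) {
      grids <- encode_message(config$text, scheme)
      words <- strsplit(config$text, " ", fixed = TRUE)[[1]]
    } else {
      # marker-only condition: blank data array, conformation markers only
      grids <- list(scramble(assign_address(empty_grid(scheme), 0L, scheme)))
      words <- "blank"
    }
    rows <- list()
    for (kc in config$keys) {
      for (w in seq_along(grids)) {
        rows[[length(rows) + 1L]] <-
          run_condition(design, grids[[w]], make_key(kc, design), params,
                        n_structures = config$n_structures,
                        seed = config$seed + 100L * w + match(kc, config$keys),
                        scheme = scheme,
                        label = sprintf("%s/%s", kc, words[w]))
      }
    }
    do.call(rbind, rows)
  } else if (identical(config$type, "hierarchy")) {
    designs <- lapply(config$designs, function(dd) {
      do.call(carrier_design, lapply(as.list(dd), unlist))
    })
    grids <- lapply(seq_along(designs), function(i) {
      g <- encode_message(config$texts[i], scheme)[[1]]
      g$carrier_ref <- designs[[i]]$design_id
      g
    })
    keys <- c(list(admin = admin_key()),
              stats::setNames(lapply(designs, function(d) user_key(d$design_id)),
                              paste0("user_", vapply(designs, function(d) d$design_id,
                                                     character(1)))))
    hierarchy_matrix(designs, grids, keys, params,
                     n_structures = config$n_structures, seed = config$seed)
  } else {
    ddc_error("config$type must be 'conditions' or 'hierarchy'", "ddc_parameter_error")
  }
}
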