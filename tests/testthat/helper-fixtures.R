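# Shared fixtures and independent oracles (all generated in code).

default_design <- function() carrier_design()
default_scheme <- function() encoding_scheme("a5")

# Physical (scrambled) carrier grids for a message, spacing warnings silenced.
phrase_grids <- function(text = "DNA NANO TECH", scheme = default_scheme()) {
  suppressWarnings(encode_message(text, scheme))
}

# Random encodable message: 1-3 words of 1-5 letters.
random_message <- function() {
  n_words <- sample(1:3, 1)
  paste(vapply(seq_len(n_words), function(i) {
    paste(sample(LETTERS, sample(1:5, 1), replace = TRUE), collapse = "")
  }, character(1)), collapse = " ")
}

# Random bit grid (physical layout, arbitrary content).
random_grid <- function(scheme = default_scheme(), p1 = 0.4) {
  g <- ddcaccess:::empty_grid(scheme)
  g$bits <- matrix(rbinom(scheme$grid_rows * scheme$grid_cols, 1, p1),
                   scheme$grid_rows, scheme$grid_cols)
  g
}

# Random design with valid geometry (ON stretches the row axis).
random_design <- function() {
  po <- c(runif(1, 4, 8), runif(1, 4, 8))
  carrier_design(design_id = sprintf("RD%06d", sample.int(1e6, 1)),
                 pitch_off = po,
                 pitch_on = c(po[1], po[2] * runif(1, 1.6, 2.5)))
}

random_strand <- function(len = 16) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- independent oracles -----------------------------------------------------

# Quadratic-time longest-shared-substring oracle: enumerate every substring
# of x and look for it verbatim in y.
quad_shared_substring <- function(x, y) {
  n <- nchar(x)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L <= best) next
      if (grepl(substr(x, i, j), y, fixed = TRUE)) best <- j - i + 1L
    }
  }
  best
}

# Oracle counterpart of cross_hybridization: a strand of key a binds the
# region targeted by a strand of key b iff a substring of the strand is the
# reverse complement of a substring of that region; the region is
# revcomp(strand_b), so search strand_a's substrings inside strand_b after
# undoing the revcomp with Biostrings (the independent reverse-complement
# implementation).
oracle_cross_hyb <- function(a, b) {
  sa <- c(a$competing_strands, a$invading_strands)
  regions_b <- vapply(c(b$competing_strands, b$invading_strands), function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  best <- 0L
  for (x in sa) {
    rcx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    for (r in regions_b) {
      # substring of x whose revcomp occurs in region r  <=>  substring of
      # revcomp(x) occurring in r (searched quadratically)
      best <- max(best, quad_shared_substring(rcx, r))
    }
  }
  best
}

# Independent template coordinates (no package internals): full lattice plus
# marker pair under a conformation's pitch.
oracle_sites <- function(design, category) {
  p <- if (category == "OFF") design$pitch_off else design$pitch_on
  rows <- c(-(seq_len(design$address_rows)), seq_len(design$grid_rows) - 1L)
  g <- expand.grid(row = rows, col = seq_len(design$grid_cols) - 1L)
  mk <- do.call(rbind, design$marker_sites)
  data.frame(row = c(g$row, mk[, 1]), col = c(g$col, mk[, 2]),
             x = c(g$col, mk[, 2]) * p[1], y = c(g$row, mk[, 1]) * p[2],
             marker = c(rep(FALSE, nrow(g)), rep(TRUE, nrow(mk))))
}

# Exhaustive optimal-assignment oracle for small fields: each spot may take
# any site within the tolerance radius or be declared noise (at radius
# cost); enumerate every injective combination and minimise total distance.
oracle_assignment_bits <- function(field, design, category, tol = 0.35) {
  sites <- oracle_sites(design, category)
  radius <- tol * min(design$pitch_off, design$pitch_on)
  sp <- field$spots
  stopifnot(nrow(sp) <= 8)
  cand <- lapply(seq_len(nrow(sp)), function(i) {
    d <- sqrt((sites$x - sp$x_nm[i])^2 + (sites$y - sp$y_nm[i])^2)
    c(which(d <= radius), NA)   # NA = noise
  })
  costs <- lapply(seq_len(nrow(sp)), function(i) {
    d <- sqrt((sites$x - sp$x_nm[i])^2 + (sites$y - sp$y_nm[i])^2)
    c(d[d <= radius], radius)
  })
  combos <- expand.grid(lapply(cand, seq_along))
  best_cost <- Inf; best <- NULL
  for (r in seq_len(nrow(combos))) {
    pick <- vapply(seq_len(nrow(sp)), function(i) cand[[i]][combos[r, i]], numeric(1))
    used <- pick[!is.na(pick)]
    if (anyDuplicated(used)) next
    cost <- sum(vapply(seq_len(nrow(sp)), function(i) costs[[i]][combos[r, i]],
                       numeric(1)))
    if (cost < best_cost) { best_cost <- cost; best <- pick }
  }
  bits <- matrix(0L, design$grid_rows, design$grid_cols)
  address <- matrix(0L, design$address_rows, design$grid_cols)
  for (s in best[!is.na(best)]) {
    if (sites$marker[s]) next
    rr <- sites$row[s]; cc <- sites$col[s]
    if (rr < 0) address[-rr, cc + 1L] <- 1L else bits[rr + 1L, cc + 1L] <- 1L
  }
  list(bits = bits, address = address)
}

# Binomial 3-standard-error band check.
within_3se <- function(obs_frac, expected, n) {
  se <- sqrt(expected * (1 - expected) / n)
  abs(obs_frac - expected) <= 3 * se + 1e-12
}
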